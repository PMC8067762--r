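test_that("relaxation trace sampling matches the generating model", {
  m <- model_rate1e8()
  tr <- generate_relaxation_trace(m, duration = 1000, dt = 1, noise_sd = 0)
  expect_s3_class(tr, "relaxation_trace")
  expect_equal(nrow(tr), 1001L)
  expect_equal(tr$modulus[1], 0.930)
  expect_equal(tr$modulus, predict(m, tr$time))
  # long-term limit reached within 1e-4 ten relaxation times out
  tr2 <- generate_relaxation_trace(m, duration = 10 * 87.866, dt = 87.866 / 10)
  expect_lt(abs(tail(tr2$modulus, 1) - 0.103), 1e-4)
  # noiseless trace of a non-negative model is non-increasing
  expect_true(all(diff(tr$modulus) <= 0))
})

test_that("trace generation is seeded and reproducible bit-for-bit", {
  m <- model_rate1e8()
  a <- generate_relaxation_trace(m, noise_sd = 0.05, seed = 7)
  b <- generate_relaxation_trace(m, noise_sd = 0.05, seed = 7)
  expect_identical(a$modulus, b$modulus)
  c2 <- generate_relaxation_trace(m, noise_sd = 0.05, seed = 8)
  expect_false(identical(a$modulus, c2$modulus))
})

test_that("trace generator rejects bad sampling parameters", {
  m <- model_rate1e8()
  expect_error(generate_relaxation_trace(m, duration = -1), "> 0")
  expect_error(generate_relaxation_trace(m, dt = 0), "> 0")
  expect_error(generate_relaxation_trace(m, duration = 10, dt = 20),
               "exceed")
  expect_error(generate_relaxation_trace(m, noise_sd = -0.1), ">= 0")
})

test_that("mean of noisy traces converges to the noiseless trace", {
  m <- model_rate1e8()
  noiseless <- generate_relaxation_trace(m, duration = 200, dt = 2)
  N <- 1000L
  sd <- 0.05
  set.seed(90)
  acc <- matrix(0, N, nrow(noiseless))
  for (k in seq_len(N))
    acc[k, ] <- generate_relaxation_trace(m, duration = 200, dt = 2,
                                          noise_sd = sd)$modulus
  dev <- abs(colMeans(acc) - noiseless$modulus)
  # 1/sqrt(N) convergence: nearly every point within 3 sd/sqrt(N), none far
  # beyond it, and the rms error at the predicted scale
  expect_lt(mean(dev > 3 * sd / sqrt(N)), 0.02)
  expect_lt(max(dev), 5 * sd / sqrt(N))
  expect_lt(sqrt(mean(dev^2)), 1.5 * sd / sqrt(N))
})

test_that("tensile curve is continuous piecewise linear with the set slopes", {
  cv <- generate_tensile_curve(max_strain = 2, unfold_end_strain = 1.5,
                               unfold_slope = 0.05, stretch_slope = 0.5,
                               fluctuation_sd = 0, n_points = 401)
  expect_s3_class(cv, "stress_strain_curve")
  expect_equal(cv$stress[1], 0)
  # stress at final strain: unfolding stage + stretching stage
  expect_equal(tail(cv$stress, 1), 0.05 * 1.5 + 0.5 * 0.5)
  # continuity at the breakpoint: left/right limits agree
  i <- which.min(abs(cv$strain - 1.5))
  expect_lt(abs(cv$stress[i] - 0.05 * 1.5), 0.01)
  # expected slopes on each stage
  lo <- cv$strain <= 1.5
  expect_equal(unname(coef(lm(cv$stress[lo] ~ cv$strain[lo]))[2]), 0.05)
})

test_that("least squares recovers the stretching slope of a noisy curve", {
  cv <- generate_tensile_curve(max_strain = 2, unfold_end_strain = 1,
                               unfold_slope = 0.05, stretch_slope = 0.5,
                               fluctuation_sd = 0.02, n_points = 500, seed = 1)
  hi <- cv$strain >= 1
  slope <- unname(coef(lm(cv$stress[hi] ~ cv$strain[hi]))[2])
  expect_lt(abs(slope - 0.5), 0.05)
})

test_that("tensile generator enforces its invariants", {
  expect_error(generate_tensile_curve(max_strain = 0), "> 0")
  expect_error(generate_tensile_curve(max_strain = 1, unfold_end_strain = 1.5),
               "unfold_end_strain")
  expect_error(generate_tensile_curve(unfold_slope = 0.5, stretch_slope = 0.3),
               "exceed")
})

test_that("generated frames carry the prescribed group stress exactly", {
  # uniform assignment: isotropic prescription recovered identically
  frames <- generate_frames(8, 20, list(diag(3)), seed = 3, randomize = FALSE)
  vols <- voronoi_volumes(frames[[1]])
  gs <- group_stress(frames[[1]], 1:8, vols)
  expect_equal(unname(gs[1:3]), rep(1, 3))
  expect_equal(unname(gs[4:6]), rep(0, 3))
  # zero prescription -> zero tensor
  fr0 <- generate_frames(5, 15, list(rep(0, 6)), seed = 3)
  expect_lt(max(abs(group_stress(fr0[[1]], 1:5, voronoi_volumes(fr0[[1]])))),
            1e-15)
})

test_that("randomized per-atom partition preserves the volume-weighted sum", {
  tgt <- c(1.2, -0.4, 0.7, 0.1, -0.2, 0.05)
  frames <- generate_frames(50, 30, list(tgt), seed = 3)
  fr <- frames[[1]]
  vols <- voronoi_volumes(fr)
  # direct summation oracle: -(sum stress*volume)/(sum volume) * atm->GPa
  direct <- -colSums(fr$stress_pv) / sum(vols) * ATM_GPA
  expect_rel_equal(unname(direct), tgt, 1e-9)
  expect_rel_equal(unname(group_stress(fr, 1:50, vols)), tgt, 1e-9)
  # per-atom stresses do fluctuate around the target
  per_atom <- -fr$stress_pv / vols * ATM_GPA
  expect_gt(stats::sd(per_atom[, 1]), 0.01)
  # atoms lie inside the box
  expect_true(all(fr$coords >= 0 & fr$coords <= 30))
})

test_that("frame generator rejects an empty stress history", {
  expect_error(generate_frames(4, 10, list()), "non-empty")
})

test_that("generator specs load from flat YAML configs", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("kind: relaxation", "long_term: 0.103",
               "moduli: [0.827]", "tau: [87.866]",
               "duration: 100", "dt: 1", "noise_sd: 0", "seed: 4"), f)
  spec <- read_gen_spec(f)
  expect_equal(spec$kind, "relaxation")
  tr <- do.call(generate_relaxation_trace, spec$args)
  expect_equal(nrow(tr), 101L)
  expect_equal(tr$modulus[1], 0.930)
  f2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("kind: tensile", "strain_rate: 1.0e+8", "max_strain: 2",
               "fluctuation_sd: 0", "n_points: 50"), f2)
  spec2 <- read_gen_spec(f2)
  cv <- do.call(generate_tensile_curve, spec2$args)
  expect_equal(nrow(cv), 50L)
  expect_error(read_gen_spec({
    f3 <- withr::local_tempfile(fileext = ".yaml")
    writeLines("foo: 1", f3); f3
  }), "kind")
})
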