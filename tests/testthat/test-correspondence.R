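test_that("shear conversion scales moduli by 1/(2(1+nu))", {
  g <- to_shear(model_rate1e9(), 0.48)
  expect_equal(g$moduli, 2 / (2 * 1.48))
  expect_equal(g$tau, 100)
  # printed-table agreement: 0.676 rounds to the published 0.68
  expect_lt(abs(g$moduli - 0.68), 0.005)
  # nu = 0: G(t) = E(t)/2 pointwise
  m <- model_rate1e8()
  tt <- c(0, 1, 50, 800)
  expect_equal(predict(to_shear(m, 0), tt), predict(m, tt) / 2)
  # constant model
  expect_equal(to_shear(prony_model(1), 0.25)$long_term, 0.4)
})

test_that("bulk conversion scales moduli by 1/(3(1-2nu))", {
  k <- to_bulk(model_rate1e8(), 0.48)
  expect_equal(k$long_term, 0.103 / 0.12)
  expect_equal(k$moduli, 0.827 / 0.12)
  expect_equal(k$tau, 87.866)
  # printed-table agreement
  expect_lt(abs(k$long_term - 0.858), 0.001)
  expect_lt(abs(k$moduli - 6.889), 0.005)
  expect_equal(to_bulk(model_rate1e9(), 0.48)$moduli, 2 / 0.12)
  # nu = 0: K(t) = E(t)/3
  m <- model_rate1e8()
  tt <- c(0, 3, 90)
  expect_equal(predict(to_bulk(m, 0), tt), predict(m, tt) / 3)
})

test_that("the incompressible limit is a singularity error", {
  expect_error(to_bulk(model_rate1e8(), 0.5), "diverge")
  expect_error(to_bulk(model_rate1e8(), 0.55), "diverge")
  expect_error(to_shear(model_rate1e8(), -0.1), ">= 0")
  expect_error(to_shear(model_rate1e8(), 0.5), "< 0.5")
})

test_that("conversion satisfies the correspondence round trip", {
  set.seed(11)
  tt <- c(0, 0.5, 5, 50, 500)
  for (rep in 1:5) {
    m <- prony_model(runif(1, 0, 1), runif(2, 0.1, 2),
                     sort(runif(2, 1, 500)))
    nu <- runif(1, 0, 0.49)
    G <- to_shear(m, nu); K <- to_bulk(m, nu)
    expect_equal(2 * (1 + nu) * predict(G, tt), predict(m, tt))
    expect_equal(3 * (1 - 2 * nu) * predict(K, tt), predict(m, tt))
    # relaxation times are never altered
    expect_identical(G$tau, m$tau)
    expect_identical(K$tau, m$tau)
    # elastic identity at each time: E = 9KG/(3K+G)
    Gt <- predict(G, tt); Kt <- predict(K, tt)
    expect_equal(9 * Kt * Gt / (3 * Kt + Gt), predict(m, tt))
  }
})

test_that("K increases and G decreases with Poisson's ratio", {
  m <- model_rate1e8()
  nus <- c(0, 0.2, 0.33, 0.48)
  G0 <- vapply(nus, function(nu) predict(to_shear(m, nu), 10), numeric(1))
  K0 <- vapply(nus, function(nu) predict(to_bulk(m, nu), 10), numeric(1))
  expect_true(all(diff(G0) < 0))
  expect_true(all(diff(K0) > 0))
})

test_that("numerical inverse Laplace agrees with the closed form", {
  tt <- c(1, 50, 500)
  for (m in list(model_rate1e8(), model_rate1e9()))
    for (nu in c(0.33, 0.48)) {
      chk <- inverse_laplace_check(m, nu, tt)
      expect_lt(max(chk$G_rel_err), 1e-6)
      expect_lt(max(chk$K_rel_err), 1e-6)
      expect_false(any(chk$unstable))
    }
  # constant long-term modulus inverts to a constant
  chk <- inverse_laplace_check(prony_model(0.7), 0.33, tt)
  expect_equal(chk$G_num, rep(0.7 / (2 * 1.33), 3), tolerance = 1e-9)
  # nu = 0 proportionality
  chk0 <- inverse_laplace_check(model_rate1e8(), 0, tt)
  expect_equal(chk0$G_num, predict(model_rate1e8(), tt) / 2,
               tolerance = 1e-6)
  expect_error(inverse_laplace_check(model_rate1e8(), 0.33, c(0, 1)),
               "positive")
})

test_that("an independent inversion route confirms the Talbot contour", {
  # de Hoog inversion from pracma as a second, unrelated numerical route
  m <- model_rate1e8()
  nu <- 0.33
  Eb <- function(s) (m$long_term / s + m$moduli / (s + 1 / m$tau)) /
    (2 * (1 + nu))
  out <- pracma::invlap(Eb, 1, 1000, 60)
  closed <- predict(to_shear(m, nu), out$x)
  expect_lt(max(abs(out$y / closed - 1)), 1e-4)
  talbot <- inverse_laplace_check(m, nu, out$x)
  expect_lt(max(abs(talbot$G_num / closed - 1)), 1e-6)
})

test_that("the conversion table collects both moduli across nu", {
  tab <- moduli_table(list(rate1e8 = model_rate1e8(),
                           rate1e9 = model_rate1e9()),
                      poisson = c(0.33, 0.48))
  expect_equal(dim(tab), c(6L, 5L))
  expect_equal(tab$quantity,
               c("G1_GPa", "G2_GPa", "tau_G_ps", "K1_GPa", "K2_GPa",
                 "tau_K_ps"))
  col <- tab[["rate1e8_nu0.33"]]
  expect_equal(col, c(0.103 / 2.66, 0.827 / 2.66, 87.866,
                      0.103 / 1.02, 0.827 / 1.02, 87.866))
})

test_that("converted moduli JSON carries both parameter sets", {
  f <- withr::local_tempfile(fileext = ".json")
  write_converted_json(converted_moduli(model_rate1e8(), 0.48), f)
  x <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(x$poisson, 0.48)
  expect_equal(x$shear$moduli, 0.827 / 2.96)
  expect_equal(x$bulk$moduli, 0.827 / 0.12)
})
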