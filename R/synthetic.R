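## Synthetic-data generators: stand-ins for the MD output so every pipeline
## stage runs at desk scale with known ground truth. Defaults mirror the
## study conditions: 1 ns relaxation holds sampled every ps, 80% hold strain,
## nominal pulling rates in the 1e8-1e9 /s range, moduli on the GPa scale.

#' Generate a synthetic relaxation trace
#'
#' Samples \eqn{E(t)} from a [prony_model] on a uniform grid with optional
#' additive i.i.d. Gaussian noise on the modulus. The noiseless expectation
#' at every sample equals the model evaluation; identical seeds give
#' identical traces.
#'
#' @param model a [prony_model] (ground truth).
#' @param duration hold duration (ps), > 0; default 1000 (a 1 ns hold).
#' @param dt sample spacing (ps), > 0 and <= duration; default 1.
#' @param noise_sd Gaussian noise standard deviation (GPa), >= 0.
#' @param hold_strain constant hold strain tag, default 0.8.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return a [relaxation_trace()] with `floor(duration/dt) + 1` samples.
#' @export
generate_relaxation_trace <- function(model, duration = 1000, dt = 1,
                                      noise_sd = 0, hold_strain = 0.8,
                                      seed = NULL) {
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(dt, "dt", positive = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  if (dt > duration) stop_param("dt must not exceed duration")
  t <- seq(0, by = dt, length.out = floor(duration / dt) + 1L)
  y <- predict(model, t)
  if (noise_sd > 0)
    y <- y + with_seed(seed, rnorm(length(t), 0, noise_sd))
  relaxation_trace(t, y, hold_strain)
}

#' Generate a synthetic two-stage tensile curve
#'
#' Piecewise-linear stress-strain curve emulating simultaneous unfolding and
#' stretching: a shallow unfolding slope up to `unfold_end_strain`, then a
#' steeper stretching slope to `max_strain`, continuous at the breakpoint,
#' with optional additive Gaussian fluctuation. Curves generated with a
#' larger `stretch_slope` at a larger nominal `strain_rate` reproduce the
#' stiffer-at-higher-rate behaviour of the pulled sidearms.
#'
#' @param strain_rate nominal rate tag (1/s); default 1e8.
#' @param max_strain final strain, > 0; default 2.17 (a ~220% pull).
#' @param unfold_end_strain breakpoint strain, in (0, `max_strain`);
#'   default 1.
#' @param unfold_slope unfolding-stage slope (GPa), >= 0; default 0.05.
#' @param stretch_slope stretching-stage slope (GPa), > `unfold_slope`;
#'   default 0.5.
#' @param fluctuation_sd additive stress noise sd (GPa); default 0.02.
#' @param n_points samples on the strain grid; default 500.
#' @param label curve tag; default `"synthetic"`.
#' @param seed integer seed or `NULL`.
#' @return a [stress_strain_curve()].
#' @export
generate_tensile_curve <- function(strain_rate = 1e8, max_strain = 2.17,
                                   unfold_end_strain = 1,
                                   unfold_slope = 0.05, stretch_slope = 0.5,
                                   fluctuation_sd = 0.02, n_points = 500L,
                                   label = "synthetic", seed = NULL) {
  check_scalar(max_strain, "max_strain", positive = TRUE)
  check_scalar(unfold_end_strain, "unfold_end_strain", positive = TRUE)
  if (unfold_end_strain >= max_strain)
    stop_param("unfold_end_strain must be < max_strain")
  check_scalar(unfold_slope, "unfold_slope", nonneg = TRUE)
  check_scalar(stretch_slope, "stretch_slope", positive = TRUE)
  if (stretch_slope <= unfold_slope)
    stop_param("stretch_slope must exceed unfold_slope")
  check_scalar(fluctuation_sd, "fluctuation_sd", nonneg = TRUE)
  eps <- seq(0, max_strain, length.out = as.integer(n_points))
  sig <- tensile_mean_stress(eps, unfold_end_strain, unfold_slope, stretch_slope)
  if (fluctuation_sd > 0)
    sig <- sig + with_seed(seed, rnorm(length(eps), 0, fluctuation_sd))
  stress_strain_curve(eps, sig, strain_rate, label)
}

## Noiseless two-stage stress: continuous piecewise-linear in strain.
tensile_mean_stress <- function(eps, breakpoint, s1, s2) {
  ifelse(eps <= breakpoint, s1 * eps, s1 * breakpoint + s2 * (eps - breakpoint))
}

#' Generate toy trajectory frames with prescribed group stress
#'
#' Builds a sequence of [atom_frame]s whose extraction ground truth is known:
#' atoms are placed uniformly in a cubic periodic box (positions held fixed
#' across frames), per-atom Voronoi volumes are computed, and each frame's
#' per-atom stress*volume entries are assigned so the volume-weighted mean
#' per-atom stress equals the prescribed group stress tensor for that frame
#' exactly. With `randomize = TRUE` the per-atom stresses fluctuate around
#' the target (the volume-weighted mean is projected back onto the
#' prescription); otherwise every atom carries the target stress.
#'
#' @param n_atoms number of atoms, >= 1.
#' @param box_edge cubic box edge (Angstrom), > 0.
#' @param stress_history list of prescribed group stress tensors (GPa), each
#'   a length-6 vector (xx, yy, zz, xy, xz, yz) or symmetric 3x3 matrix; one
#'   frame per entry. Must be non-empty.
#' @param seed integer seed or `NULL`.
#' @param randomize randomize the per-atom partition of the stress (default
#'   `TRUE`).
#' @return list of [atom_frame], timesteps `0, 1, 2, ...`.
#' @export
generate_frames <- function(n_atoms, box_edge, stress_history, seed = NULL,
                            randomize = TRUE) {
  check_scalar(n_atoms, "n_atoms", positive = TRUE)
  check_scalar(box_edge, "box_edge", positive = TRUE)
  if (length(stress_history) == 0L)
    stop_param("stress_history must be non-empty")
  targets <- lapply(stress_history, as_voigt6)
  with_seed(seed, {
    X <- matrix(runif(3 * n_atoms, 0, box_edge), ncol = 3L)
    bb <- cbind(rep(0, 3), rep(box_edge, 3))
    probe <- atom_frame(0L, bb, seq_len(n_atoms), X,
                        matrix(0, n_atoms, 6L))
    vols <- voronoi_volumes(probe, periodic = TRUE)
    lapply(seq_along(targets), function(f) {
      tgt <- targets[[f]]
      S <- matrix(rep(tgt, each = n_atoms), n_atoms, 6L)   # GPa per atom
      if (randomize && n_atoms > 1L) {
        noise <- matrix(rnorm(n_atoms * 6L, 0,
                              0.5 * pmax(abs(tgt), 0.1)[col(S)]),
                        n_atoms, 6L)
        # project out the volume-weighted mean so the prescription is exact
        noise <- noise - rep(colSums(noise * vols) / sum(vols), each = n_atoms)
        S <- S + noise
      }
      spv <- -S / ATM_TO_GPA * vols     # back to atm*A^3, virial sign
      atom_frame(f - 1L, bb, seq_len(n_atoms), X, spv)
    })
  })
}

#' Read a generator spec from a flat YAML config
#'
#' The config is a flat key-value mapping with a `kind` key naming the
#' generator (`relaxation`, `tensile` or `frames`); the remaining keys are
#' the generator's arguments. For `relaxation`, the model is given as keys
#' `long_term`, `moduli`, `tau`.
#'
#' @param path YAML file path.
#' @return list with elements `kind` and `args`, ready for
#'   `do.call(generate_*, args)`.
#' @export
read_gen_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$kind) ||
      !cfg$kind %in% c("relaxation", "tensile", "frames"))
    stop_format("config must set kind: relaxation | tensile | frames")
  kind <- cfg$kind
  cfg$kind <- NULL
  if (kind == "relaxation") {
    model <- prony_model(cfg$long_term %||% 0,
                         unlist(cfg$moduli), unlist(cfg$tau))
    cfg$long_term <- NULL; cfg$moduli <- NULL; cfg$tau <- NULL
    cfg <- c(list(model = model), cfg)
  }
  if (kind == "frames" && !is.null(cfg$stress_history))
    cfg$stress_history <- lapply(cfg$stress_history, unlist)
  list(kind = kind, args = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
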