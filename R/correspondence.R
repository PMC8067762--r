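## Elastic-viscoelastic correspondence: with a constant Poisson's ratio the
## Laplace-domain relations G*(s) = E*(s)/(2(1+nu)) and
## K*(s) = E*(s)/(3(1-2nu)) invert in closed form, so a Prony relaxation
## modulus converts branch by branch with the relaxation times unchanged.

check_poisson <- function(poisson, for_bulk = FALSE) {
  check_scalar(poisson, "poisson")
  if (poisson < 0) stop_param("Poisson's ratio must be >= 0, got ", poisson)
  if (poisson >= 0.5) {
    if (for_bulk)
      stop_param("Poisson's ratio ", poisson, " >= 0.5: the bulk modulus ",
                 "diverges at the incompressible limit (K ~ 1/(1-2*nu))")
    stop_param("Poisson's ratio must be < 0.5, got ", poisson)
  }
  invisible(poisson)
}

#' Convert a relaxation modulus to the shear relaxation modulus
#'
#' Under the correspondence principle with constant Poisson's ratio,
#' \eqn{G(t) = E(t) / (2(1+\nu))}: the long-term modulus and every branch
#' modulus scale by \eqn{1/(2(1+\nu))} and the relaxation times are
#' unchanged.
#'
#' @param model a [prony_model] for E(t) (GPa, ps).
#' @param poisson Poisson's ratio \eqn{\nu}, in [0, 0.5).
#' @return a [prony_model] for G(t).
#' @export
to_shear <- function(model, poisson) {
  check_poisson(poisson)
  f <- 1 / (2 * (1 + poisson))
  prony_model(model$long_term * f, model$moduli * f, model$tau)
}

#' Convert a relaxation modulus to the bulk relaxation modulus
#'
#' Under the correspondence principle with constant Poisson's ratio,
#' \eqn{K(t) = E(t) / (3(1-2\nu))}; the relaxation times are unchanged. The
#' bulk modulus diverges as \eqn{\nu \to 0.5} (incompressible limit).
#'
#' @inheritParams to_shear
#' @return a [prony_model] for K(t).
#' @export
to_bulk <- function(model, poisson) {
  check_poisson(poisson, for_bulk = TRUE)
  f <- 1 / (3 * (1 - 2 * poisson))
  prony_model(model$long_term * f, model$moduli * f, model$tau)
}

#' Shear and bulk Prony parameters for a Poisson's ratio
#'
#' Bundles [to_shear()] and [to_bulk()] for one source model and one
#' Poisson's ratio.
#'
#' @inheritParams to_shear
#' @return an object of class `converted_moduli`: list with `poisson`,
#'   `shear`, `bulk`, `source` (all moduli GPa, times ps).
#' @export
converted_moduli <- function(model, poisson) {
  structure(list(poisson = poisson,
                 shear = to_shear(model, poisson),
                 bulk = to_bulk(model, poisson),
                 source = model),
            class = "converted_moduli")
}

#' @export
print.converted_moduli <- function(x, digits = 4, ...) {
  cat(sprintf("Converted moduli at nu = %s\n", format(x$poisson)))
  cat("shear G(t): "); print(x$shear, digits = digits)
  cat("bulk K(t):  "); print(x$bulk, digits = digits)
  invisible(x)
}

#' Tabulate converted moduli across models and Poisson's ratios
#'
#' Builds the conversion summary table: rows `G1, G2, tau_G, K1, K2, tau_K`,
#' one column per (Poisson's ratio, model) combination. Only single-branch
#' models are tabulated in this shape.
#'
#' @param models named list of single-branch [prony_model]s (names label the
#'   columns, e.g. by nominal strain rate).
#' @param poisson numeric vector of Poisson's ratios.
#' @return data frame with a `quantity` column and one column per
#'   combination, named `<model>_nu<poisson>`.
#' @export
moduli_table <- function(models, poisson) {
  if (is.null(names(models)) || any(names(models) == ""))
    names(models) <- paste0("model", seq_along(models))
  cols <- list(quantity = c("G1_GPa", "G2_GPa", "tau_G_ps",
                            "K1_GPa", "K2_GPa", "tau_K_ps"))
  for (nu in poisson) {
    for (nm in names(models)) {
      m <- models[[nm]]
      if (length(m$moduli) != 1L)
        stop_param("moduli_table expects single-branch models")
      cm <- converted_moduli(m, nu)
      cols[[sprintf("%s_nu%s", nm, format(nu))]] <-
        c(cm$shear$long_term, cm$shear$moduli, cm$shear$tau,
          cm$bulk$long_term, cm$bulk$moduli, cm$bulk$tau)
    }
  }
  as.data.frame(cols, check.names = FALSE)
}

#' Write converted moduli as JSON
#'
#' @param x a [converted_moduli()] object or list of them.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_converted_json <- function(x, path) {
  if (inherits(x, "converted_moduli")) x <- list(x)
  payload <- lapply(x, function(cm)
    list(poisson = cm$poisson,
         shear = list(long_term = cm$shear$long_term,
                      moduli = cm$shear$moduli, tau = cm$shear$tau),
         bulk = list(long_term = cm$bulk$long_term,
                     moduli = cm$bulk$moduli, tau = cm$bulk$tau),
         source = list(long_term = cm$source$long_term,
                       moduli = cm$source$moduli, tau = cm$source$tau),
         units = list(modulus = "GPa", time = "ps")))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## Laplace transform of a Prony relaxation modulus:
## Ebar(s) = E1/s + sum_i Ei/(s + 1/tau_i). Works for complex s.
prony_laplace <- function(model) {
  function(s) {
    out <- model$long_term / s
    for (i in seq_along(model$moduli))
      out <- out + model$moduli[i] / (s + 1 / model$tau[i])
    out
  }
}

## Fixed-Talbot numerical inverse Laplace transform (Abate-Valko). M around
## 24 is the double-precision sweet spot for these transforms; much larger M
## loses accuracy to cancellation in exp(r t).
talbot_invert <- function(Fs, t, M = 24L) {
  vapply(t, function(tt) {
    r <- 2 * M / (5 * tt)
    k <- seq_len(M - 1L)
    th <- k * pi / M
    ct <- cos(th) / sin(th)
    s <- r * th * (ct + 1i)
    sig <- th + (th * ct - 1) * ct
    term0 <- 0.5 * Re(exp(r * tt) * Fs(r + 0i))
    (r / M) * (term0 + sum(Re(exp(tt * s) * Fs(s) * (1 + 1i * sig))))
  }, numeric(1))
}

#' Numerical inverse-Laplace check of the correspondence conversion
#'
#' Independently recovers \eqn{G(t)} and \eqn{K(t)} by numerically inverting
#' \eqn{\bar{E}(s)/(2(1+\nu))} and \eqn{\bar{E}(s)/(3(1-2\nu))} with a
#' fixed-Talbot contour method, and compares them pointwise with the
#' closed-form constant-\eqn{\nu} conversion. Points where two contour
#' resolutions disagree beyond `stability_tol` are flagged unstable rather
#' than smoothed.
#'
#' @inheritParams to_shear
#' @param t_grid times (ps), all > 0.
#' @param M Talbot contour resolution (terms); default 24.
#' @param stability_tol relative disagreement between the `M` and `M - 8`
#'   contours above which a point is flagged; default 1e-8.
#' @return data frame with columns `time`, `G_num`, `K_num`, `G_closed`,
#'   `K_closed`, `G_rel_err`, `K_rel_err`, `unstable`.
#' @export
inverse_laplace_check <- function(model, poisson, t_grid, M = 24L,
                                  stability_tol = 1e-8) {
  check_poisson(poisson, for_bulk = TRUE)
  t_grid <- as.numeric(t_grid)
  if (any(t_grid <= 0)) stop_param("t_grid must be strictly positive")
  Eb <- prony_laplace(model)
  fg <- function(s) Eb(s) / (2 * (1 + poisson))
  fk <- function(s) Eb(s) / (3 * (1 - 2 * poisson))
  G_num <- talbot_invert(fg, t_grid, M)
  K_num <- talbot_invert(fk, t_grid, M)
  G_lo <- talbot_invert(fg, t_grid, M - 8L)
  K_lo <- talbot_invert(fk, t_grid, M - 8L)
  G_cl <- predict(to_shear(model, poisson), t_grid)
  K_cl <- predict(to_bulk(model, poisson), t_grid)
  relerr <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.eps)
  data.frame(time = t_grid,
             G_num = G_num, K_num = K_num,
             G_closed = G_cl, K_closed = K_cl,
             G_rel_err = relerr(G_num, G_cl),
             K_rel_err = relerr(K_num, K_cl),
             unstable = relerr(G_num, G_lo) > stability_tol |
                        relerr(K_num, K_lo) > stability_tol)
}
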