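#' Relaxation modulus from a constant-strain hold
#'
#' For a one-dimensional relaxation test at constant hold strain
#' \eqn{\epsilon_0}, the relaxation modulus is
#' \eqn{E(t) = \sigma(t)/\epsilon_0} with time re-zeroed at the start of the
#' hold. Samples before `hold_start` (the loading phase) are excluded: at
#' high pulling rates the loading-region response is ignored in the
#' viscoelastic characterization.
#'
#' @param stress a [group_stress_series()] covering the hold period.
#' @param hold_strain the constant hold strain \eqn{\epsilon_0}, > 0.
#' @param hold_start time (ps) at which the hold begins; default the first
#'   sample.
#' @return a [relaxation_trace()].
#' @export
relaxation_modulus <- function(stress, hold_strain, hold_start = NULL) {
  check_scalar(hold_strain, "hold_strain", positive = TRUE)
  if (is.null(hold_start)) hold_start <- stress$time[1]
  keep <- stress$time >= hold_start - 1e-12
  if (!any(keep)) stop_param("stress series does not cover the hold period")
  t <- stress$time[keep] - stress$time[keep][1]
  relaxation_trace(t, stress$axial[keep] / hold_strain, hold_strain)
}

## Deterministic, scale-free starting values: long-term from the tail of the
## trace, instantaneous drop from the first sample, tau from the 1/e crossing.
prony_start <- function(time, y, n_branches) {
  ntail <- max(1L, ceiling(0.1 * length(y)))
  E1 <- max(mean(tail(y, ntail)), 0)
  E2 <- y[1] - E1
  # no apparent decay: start the branch near zero instead of inventing one
  if (E2 <= 0) E2 <- 1e-3 * max(abs(y[1]), 1e-5)
  cross <- which(y <= E1 + E2 / exp(1))
  tau0 <- if (length(cross) > 0 && time[cross[1]] > 0) time[cross[1]]
          else max(time) / 3
  if (n_branches == 1L) {
    list(long_term = E1, moduli = E2, tau = tau0)
  } else {
    # split the decaying part evenly over log-spaced time constants
    taus <- exp(seq(log(tau0 / 4), log(min(tau0 * 4, max(time))),
                    length.out = n_branches))
    list(long_term = E1, moduli = rep(E2 / n_branches, n_branches), tau = taus)
  }
}

## Pack/unpack: moduli enter squared and tau log-transformed so the simplex
## search is unconstrained while the model stays in the feasible region.
pack_params <- function(long_term, moduli, tau, pin_long_term) {
  th <- c(if (!pin_long_term) sqrt(long_term), sqrt(moduli), log(tau))
  th
}

unpack_params <- function(theta, n_branches, pin_long_term) {
  i <- 0L
  long_term <- if (pin_long_term) 0 else {i <- 1L; theta[1]^2}
  moduli <- theta[i + seq_len(n_branches)]^2
  tau <- exp(theta[i + n_branches + seq_len(n_branches)])
  list(long_term = long_term, moduli = moduli, tau = tau)
}

prony_objective <- function(theta, time, y, n_branches, pin_long_term) {
  p <- unpack_params(theta, n_branches, pin_long_term)
  pred <- rep(p$long_term, length(time))
  for (i in seq_len(n_branches))
    pred <- pred + p$moduli[i] * exp(-time / p$tau[i])
  sqrt(sum((pred - y)^2))
}

#' Fit a Prony series to a relaxation trace
#'
#' Fits \eqn{E(t) = E_1 + \sum_i E_i e^{-t/\tau_i}} to a relaxation trace by
#' minimizing the L2 norm of the residual with a derivative-free Nelder-Mead
#' simplex search, multi-started from deterministic initial guesses jittered
#' multiplicatively. Non-negativity of all moduli and positivity of all
#' relaxation times are enforced by construction (moduli are squared and
#' relaxation times log-parameterized inside the search). The best restart
#' is returned; with `select = TRUE` the fitted long-term modulus is tested
#' against `threshold_frac * E(0)` and, when negligible, the model is refit
#' with the long-term modulus pinned to zero (the two-parameter form).
#'
#' @param trace a [relaxation_trace()], or a data frame with columns `time`
#'   and `modulus`.
#' @param n_branches number of exponential branches; default 1 (the
#'   three-parameter model).
#' @param restarts number of jittered starts (default 8).
#' @param seed integer seed driving the restart jitter, or `NULL`.
#' @param select run the model-form selection after fitting (default `TRUE`).
#' @param threshold_frac long-term modulus threshold as a fraction of
#'   \eqn{E(0)} for the two-parameter call; default 0.01.
#' @param pin_long_term force the long-term modulus to zero.
#' @param control overrides for the `stats::optim` Nelder-Mead control list;
#'   defaults: `reltol = 1e-10`, `maxit = 1e4`.
#' @return an object of class `prony_fit`: the fitted [prony_model] in
#'   `$model`, the residual L2 norm in `$objective` (GPa), `$n_restarts_used`,
#'   `$selected_form` (`"two_parameter"` or `"three_parameter"`; for
#'   `n_branches > 1`, `"n_parameter"` naming the count), plus the trace and
#'   call for the methods.
#' @seealso [select_form()], [predict.prony_fit()], [simulate.prony_fit()]
#' @examples
#' tr <- generate_relaxation_trace(prony_model(0.103, 0.827, 87.866))
#' fit <- prony_fit(tr)
#' coef(fit)
#' @export
prony_fit <- function(trace, n_branches = 1L, restarts = 8L, seed = NULL,
                      select = TRUE, threshold_frac = 0.01,
                      pin_long_term = FALSE, control = list()) {
  time <- trace$time
  y <- trace$modulus
  n_branches <- as.integer(n_branches)
  if (n_branches < 1L) stop_param("n_branches must be >= 1")
  n_params <- 1L + 2L * n_branches
  if (length(time) < 3L * n_params)
    stop_param("trace too short: need at least ", 3L * n_params,
               " points for ", n_params, " parameters")
  ctrl <- utils::modifyList(list(reltol = 1e-10, maxit = 1e4), control)
  st <- prony_start(time, y, n_branches)
  jit <- with_seed(seed, matrix(runif((restarts - 1L) * n_params, 0.5, 2),
                                nrow = max(restarts - 1L, 0L)))
  best <- NULL
  tried <- 0L
  objectives <- numeric(0)
  for (r in seq_len(max(restarts, 1L))) {
    fac <- if (r == 1L) rep(1, n_params) else jit[r - 1L, ]
    th0 <- pack_params(max(st$long_term * fac[1], 1e-12),
                       pmax(st$moduli * fac[1L + seq_len(n_branches)], 1e-12),
                       st$tau * fac[1L + n_branches + seq_len(n_branches)],
                       pin_long_term)
    opt <- tryCatch({
      o <- optim(th0, prony_objective, time = time, y = y,
                 n_branches = n_branches, pin_long_term = pin_long_term,
                 method = "Nelder-Mead", control = ctrl)
      # restart the simplex at the optimum to sharpen convergence
      optim(o$par, prony_objective, time = time, y = y,
            n_branches = n_branches, pin_long_term = pin_long_term,
            method = "Nelder-Mead", control = ctrl)
    }, error = function(e) NULL)
    if (is.null(opt)) next
    tried <- tried + 1L
    objectives <- c(objectives, opt$value)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("Prony fit failed to converge from any start; trace length ",
         length(y), ", ", n_branches, " branch(es), ", restarts, " restarts")
  p <- unpack_params(best$par, n_branches, pin_long_term)
  model <- prony_model(p$long_term, p$moduli, p$tau)
  fit <- structure(list(model = model,
                        objective = best$value,
                        n_restarts_used = tried,
                        restart_objectives = objectives,
                        selected_form = default_form_name(model, n_branches),
                        trace = trace,
                        n_branches = n_branches,
                        threshold_frac = threshold_frac,
                        seed = seed,
                        call = match.call()),
                   class = "prony_fit")
  if (select && !pin_long_term) fit <- select_form(fit, threshold_frac)
  fit
}

default_form_name <- function(model, n_branches) {
  if (n_branches > 1L) return(sprintf("%d_parameter", 1L + 2L * n_branches))
  if (model$long_term == 0) "two_parameter" else "three_parameter"
}

#' Model-form selection: two- vs three-parameter
#'
#' Declares the fit two-parameter when the fitted long-term modulus is below
#' `threshold_frac * E(0)`; the model is then refit with the long-term
#' modulus pinned to zero. Otherwise the three-parameter (or n-parameter)
#' form stands.
#'
#' @param fit a [prony_fit()] result.
#' @param threshold_frac fraction of the instantaneous modulus E(0) below
#'   which the long-term modulus counts as zero; default 0.01.
#' @return the (possibly refitted) `prony_fit`, with `$selected_form` set.
#' @export
select_form <- function(fit, threshold_frac = 0.01) {
  E0 <- instantaneous_modulus(fit$model)
  if (fit$model$long_term < threshold_frac * E0) {
    refit <- prony_fit(fit$trace, n_branches = fit$n_branches,
                       restarts = fit$n_restarts_used, seed = fit$seed,
                       select = FALSE, pin_long_term = TRUE)
    refit$selected_form <- if (fit$n_branches == 1L) "two_parameter"
                           else sprintf("%d_parameter", 2L * fit$n_branches)
    refit$threshold_frac <- threshold_frac
    refit
  } else {
    fit$selected_form <- default_form_name(fit$model, fit$n_branches)
    if (fit$n_branches == 1L) fit$selected_form <- "three_parameter"
    fit
  }
}

#' @export
print.prony_fit <- function(x, digits = 4, ...) {
  cat("Prony-series relaxation fit\n")
  cat(sprintf("  selected form: %s\n", x$selected_form))
  print(x$model, digits = digits)
  cat(sprintf("  residual L2 norm: %s GPa (%d restart(s))\n",
              format(x$objective, digits = digits), x$n_restarts_used))
  invisible(x)
}

#' @export
summary.prony_fit <- function(object, ...) {
  res <- residuals(object)
  structure(list(fit = object,
                 coef = coef(object),
                 n = nrow(object$trace),
                 residual_rms = sqrt(mean(res^2)),
                 residual_range = range(res)),
            class = "summary.prony_fit")
}

#' @export
print.summary.prony_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  n = %d samples; residual rms %s GPa, range [%s, %s]\n",
              x$n, format(x$residual_rms, digits = digits),
              format(x$residual_range[1], digits = digits),
              format(x$residual_range[2], digits = digits)))
  invisible(x)
}

#' @export
coef.prony_fit <- function(object, ...) coef(object$model)

#' Predict from a fitted Prony model
#'
#' @param object a [prony_fit()] result.
#' @param newdata times (ps) at which to evaluate; default the fitted
#'   trace's time grid.
#' @param ... unused.
#' @return numeric vector of moduli (GPa).
#' @export
predict.prony_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$trace$time else newdata
  predict(object$model, t)
}

#' @export
fitted.prony_fit <- function(object, ...) predict(object)

#' @export
residuals.prony_fit <- function(object, ...)
  object$trace$modulus - fitted(object)

#' Plot a Prony fit
#'
#' Trace samples with the fitted relaxation curve overlaid.
#'
#' @param x a [prony_fit()] result.
#' @param ... further arguments to `plot`.
#' @export
plot.prony_fit <- function(x, ...) {
  plot(x$trace$time, x$trace$modulus, pch = 16, cex = 0.4, col = "grey40",
       xlab = "time (ps)", ylab = "relaxation modulus E(t) (GPa)", ...)
  tt <- seq(0, max(x$trace$time), length.out = 400)
  lines(tt, predict(x$model, tt), col = "firebrick", lwd = 2)
  legend("topright", bty = "n",
         legend = c("trace", sprintf("fit (%s)", x$selected_form)),
         col = c("grey40", "firebrick"), pch = c(16, NA), lty = c(NA, 1))
  invisible(x)
}

#' Simulate relaxation traces from a fitted model
#'
#' Draws noisy traces from the fitted Prony model on the fitted time grid;
#' the noise sd defaults to the fit's residual rms.
#'
#' @param object a [prony_fit()] result.
#' @param nsim number of traces.
#' @param seed integer seed or `NULL`.
#' @param noise_sd noise level (GPa); default residual rms of the fit.
#' @param ... unused.
#' @return list of [relaxation_trace()] of length `nsim`.
#' @export
simulate.prony_fit <- function(object, nsim = 1, seed = NULL,
                               noise_sd = NULL, ...) {
  if (is.null(noise_sd)) noise_sd <- sqrt(mean(residuals(object)^2))
  hs <- attr(object$trace, "hold_strain") %||% 0.8
  dur <- max(object$trace$time)
  dt <- object$trace$time[2] - object$trace$time[1]
  with_seed(seed, lapply(seq_len(nsim), function(k)
    generate_relaxation_trace(object$model, duration = dur, dt = dt,
                              noise_sd = noise_sd, hold_strain = hs)))
}

#' Write a fit result as JSON
#'
#' Records parameters, objective, selected form, restart count and seed.
#'
#' @param fit a [prony_fit()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(long_term = fit$model$long_term,
         moduli = fit$model$moduli,
         tau = fit$model$tau,
         objective = fit$objective,
         selected_form = fit$selected_form,
         n_restarts_used = fit$n_restarts_used,
         seed = if (is.null(fit$seed)) NULL else fit$seed,
         units = list(modulus = "GPa", time = "ps")),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
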