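#' Build a stress-strain curve from stress and strain series
#'
#' Pairs the axial stress with the strain on the strain series' time grid;
#' when the grids differ the stress is linearly interpolated onto the strain
#' grid. The two series must overlap in time.
#'
#' @param stress a [group_stress_series()].
#' @param strain a [strain_series_df()].
#' @param strain_rate nominal pulling rate tag (1/s).
#' @param label curve label.
#' @return a [stress_strain_curve()].
#' @export
build_curve <- function(stress, strain, strain_rate, label = "synthetic") {
  if (nrow(stress) == 0L || nrow(strain) == 0L)
    stop_param("alignment error: empty series")
  if (min(stress$time) > max(strain$time) ||
      max(stress$time) < min(strain$time))
    stop_param("alignment error: stress and strain time ranges are disjoint")
  keep <- strain$time >= min(stress$time) & strain$time <= max(stress$time)
  tt <- strain$time[keep]
  if (length(tt) < 1L)
    stop_param("alignment error: no strain samples inside the stress range")
  sig <- approx(stress$time, stress$axial, xout = tt)$y
  eps <- strain$strain[keep]
  ord <- order(eps)
  stress_strain_curve(eps[ord], sig[ord], strain_rate, label)
}

#' Tangent stiffness over a strain window
#'
#' Ordinary least-squares slope of stress on strain over the window; the
#' slope is the tangent modulus (GPa) on that strain interval.
#'
#' @param curve a [stress_strain_curve()].
#' @param window length-2 numeric strain interval `c(lo, hi)`; default the
#'   curve's full strain range.
#' @return an object of class `stiffness_estimate`: list with `window`,
#'   `slope` (GPa), `intercept` (GPa), `residual_rms` (GPa), `n_points`,
#'   `strain_rate`, `label`.
#' @export
stiffness <- function(curve, window = range(curve$strain)) {
  window <- sort(as.numeric(window))
  if (length(window) != 2L || any(!is.finite(window)))
    stop_param("window must be a finite strain interval c(lo, hi)")
  inside <- curve$strain >= window[1] & curve$strain <= window[2]
  if (sum(inside) < 3L)
    stop_param("insufficient data: fewer than 3 points inside the window [",
               window[1], ", ", window[2], "]")
  f <- lm(stress ~ strain, data = curve[inside, , drop = FALSE])
  structure(list(window = window,
                 slope = unname(coef(f)[2]),
                 intercept = unname(coef(f)[1]),
                 residual_rms = sqrt(mean(residuals(f)^2)),
                 n_points = sum(inside),
                 strain_rate = attr(curve, "strain_rate"),
                 label = attr(curve, "label")),
            class = "stiffness_estimate")
}

#' @export
print.stiffness_estimate <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Stiffness '%s' (rate %.3g /s): slope %s GPa over strain [%s, %s]\n",
    x$label, x$strain_rate, format(x$slope, digits = digits),
    format(x$window[1]), format(x$window[2])))
  cat(sprintf("  intercept %s GPa, residual rms %s GPa, n = %d\n",
              format(x$intercept, digits = digits),
              format(x$residual_rms, digits = digits), x$n_points))
  invisible(x)
}

#' Compare stiffness across nominal strain rates
#'
#' Estimates the stiffness of each curve over a common strain window, orders
#' the report by nominal rate, and flags any violation of the expected
#' monotone rate-to-stiffness ordering (a stiffer response at higher rate).
#' Curves sharing a nominal rate are reported as ties, labeled separately,
#' never merged.
#'
#' @param curves list of [stress_strain_curve()]s (at least 2, with at least
#'   2 distinct rates for the ordering check).
#' @param window common strain window for [stiffness()]; default the
#'   intersection of the curves' strain ranges.
#' @return data frame with one row per curve (`label`, `strain_rate`,
#'   `slope`, `intercept`, `residual_rms`, `n_points`), sorted by rate, with
#'   attributes `ordering_violation` (logical), `ties` (logical) and
#'   `window`.
#' @export
compare_rates <- function(curves, window = NULL) {
  if (length(curves) < 2L) stop_param("need at least 2 curves to compare")
  if (is.null(window)) {
    lo <- max(vapply(curves, function(cv) min(cv$strain), numeric(1)))
    hi <- min(vapply(curves, function(cv) max(cv$strain), numeric(1)))
    if (hi <= lo) stop_param("curves have no common strain window")
    window <- c(lo, hi)
  }
  est <- lapply(curves, stiffness, window = window)
  df <- data.frame(
    label = vapply(est, `[[`, character(1), "label"),
    strain_rate = vapply(est, `[[`, numeric(1), "strain_rate"),
    slope = vapply(est, `[[`, numeric(1), "slope"),
    intercept = vapply(est, `[[`, numeric(1), "intercept"),
    residual_rms = vapply(est, `[[`, numeric(1), "residual_rms"),
    n_points = vapply(est, `[[`, integer(1), "n_points"))
  df <- df[order(df$strain_rate, df$label), , drop = FALSE]
  rownames(df) <- NULL
  ties <- anyDuplicated(df$strain_rate) > 0L
  # violation: stiffness strictly decreasing between successively higher rates
  viol <- FALSE
  if (length(unique(df$strain_rate)) >= 2L) {
    by_rate <- tapply(df$slope, df$strain_rate, mean)
    viol <- any(diff(by_rate[order(as.numeric(names(by_rate)))]) < 0)
  }
  structure(df, ordering_violation = viol, ties = ties, window = window)
}

#' Plot stress-strain curves by rate
#'
#' @param curves list of [stress_strain_curve()]s.
#' @param ... further plot arguments.
#' @export
plot_curves <- function(curves, ...) {
  xr <- range(unlist(lapply(curves, function(cv) cv$strain)))
  yr <- range(unlist(lapply(curves, function(cv) cv$stress)))
  plot(NA, xlim = xr, ylim = yr, xlab = "engineering strain",
       ylab = "stress (GPa)", ...)
  cols <- seq_along(curves) + 1L
  for (i in seq_along(curves))
    lines(curves[[i]]$strain, curves[[i]]$stress, col = cols[i])
  legend("topleft", bty = "n",
         legend = vapply(curves, function(cv)
           sprintf("%s @ %.2g /s", attr(cv, "label"), attr(cv, "strain_rate")),
           character(1)),
         col = cols, lty = 1)
  invisible(curves)
}
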