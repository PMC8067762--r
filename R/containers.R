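#' Relaxation-modulus trace
#'
#' Time-stamped relaxation modulus E(t) recorded during a constant-strain
#' hold. Time starts at 0 (beginning of the hold) and is strictly increasing.
#'
#' @param time times from the start of the hold (ps); `time[1]` must be 0.
#' @param modulus relaxation modulus E(t) (GPa).
#' @param hold_strain the constant engineering strain of the hold
#'   (dimensionless, > 0).
#' @return a data frame of class `relaxation_trace` with columns `time`,
#'   `modulus` and attribute `hold_strain`.
#' @export
relaxation_trace <- function(time, modulus, hold_strain) {
  time <- as.numeric(time); modulus <- as.numeric(modulus)
  if (length(time) != length(modulus) || length(time) < 1L)
    stop_param("time and modulus must be equal-length, non-empty")
  if (any(!is.finite(time)) || any(diff(time) <= 0))
    stop_param("time must be finite and strictly increasing")
  if (abs(time[1]) > 1e-12)
    stop_param("trace time must start at 0 (start of the hold)")
  check_scalar(hold_strain, "hold_strain", positive = TRUE)
  structure(data.frame(time = time, modulus = modulus),
            hold_strain = hold_strain,
            class = c("relaxation_trace", "data.frame"))
}

#' @export
print.relaxation_trace <- function(x, ...) {
  cat(sprintf("Relaxation trace: %d samples over %s ps, hold strain %s\n",
              nrow(x), format(max(x$time)), format(attr(x, "hold_strain"))))
  NextMethod()
}

#' Stress-strain curve at a nominal strain rate
#'
#' Paired engineering strain and stress from a tensile pull, tagged with the
#' nominal strain rate and an isoform label.
#'
#' @param strain engineering strain (dimensionless), non-decreasing.
#' @param stress stress (GPa), same length as `strain`.
#' @param strain_rate nominal pulling rate (1/s).
#' @param label curve tag, e.g. `"NF-L"`, `"NF-H"` or `"synthetic"`.
#' @return a data frame of class `stress_strain_curve` with columns `strain`,
#'   `stress` and attributes `strain_rate`, `label`.
#' @export
stress_strain_curve <- function(strain, stress, strain_rate, label = "synthetic") {
  strain <- as.numeric(strain); stress <- as.numeric(stress)
  if (length(strain) != length(stress) || length(strain) < 1L)
    stop_param("strain and stress must be equal-length, non-empty")
  if (any(!is.finite(strain)) || any(diff(strain) < 0))
    stop_param("strain must be finite and non-decreasing")
  check_scalar(strain_rate, "strain_rate", positive = TRUE)
  structure(data.frame(strain = strain, stress = stress),
            strain_rate = strain_rate, label = as.character(label),
            class = c("stress_strain_curve", "data.frame"))
}

#' @export
print.stress_strain_curve <- function(x, ...) {
  cat(sprintf("Stress-strain curve '%s': %d points, strain 0..%s, rate %.3g /s\n",
              attr(x, "label"), nrow(x), format(max(x$strain)),
              attr(x, "strain_rate")))
  NextMethod()
}

#' Group stress time series
#'
#' Per-frame group stress tensor (GPa) of an atom group, with the axial
#' normal component along the pulling axis broken out.
#'
#' @param time frame times (ps), strictly increasing.
#' @param tensors numeric matrix, one row per frame, six columns
#'   (xx, yy, zz, xy, xz, yz), GPa.
#' @param axis pulling axis, one of `"x"`, `"y"`, `"z"`.
#' @return a data frame of class `group_stress_series` with columns `time`,
#'   the six tensor components, and `axial`; attribute `axis`.
#' @export
group_stress_series <- function(time, tensors, axis = "x") {
  time <- as.numeric(time)
  tensors <- as.matrix(tensors)
  if (ncol(tensors) != 6L) stop_param("tensors must have 6 columns")
  if (nrow(tensors) != length(time))
    stop_param("one tensor row per time point required")
  if (any(diff(time) <= 0)) stop_param("time must be strictly increasing")
  axis <- match.arg(axis, c("x", "y", "z"))
  colnames(tensors) <- TENSOR_COMPONENTS
  axial <- tensors[, match(axis, c("x", "y", "z"))]
  structure(cbind(data.frame(time = time), as.data.frame(tensors),
                  data.frame(axial = axial)),
            axis = axis,
            class = c("group_stress_series", "data.frame"))
}

#' Strain time series
#'
#' Engineering strain of the pulled group over time; strain is zero at the
#' first frame by construction.
#'
#' @param time frame times (ps), strictly increasing.
#' @param strain dimensionless engineering strain; `strain[1]` must be 0.
#' @return a data frame of class `strain_series` with columns `time`, `strain`.
#' @export
strain_series_df <- function(time, strain) {
  time <- as.numeric(time); strain <- as.numeric(strain)
  if (length(time) != length(strain)) stop_param("time/strain length mismatch")
  if (any(diff(time) <= 0)) stop_param("time must be strictly increasing")
  if (abs(strain[1]) > 1e-12) stop_param("strain must be 0 at the first frame")
  structure(data.frame(time = time, strain = strain),
            class = c("strain_series", "data.frame"))
}

#' Write / read two-column series as CSV
#'
#' Traces, curves and series round-trip as plain CSV with a header; model
#' attributes (`hold_strain`, `strain_rate`, `label`) are carried in comment
#' metadata lines prefixed `#` when present.
#'
#' @param x a `relaxation_trace`, `stress_strain_curve`, `strain_series` or
#'   `group_stress_series`.
#' @param path file path.
#' @return `write_series_csv` returns `path` invisibly; `read_trace_csv` and
#'   `read_curve_csv` rebuild the classed object.
#' @export
write_series_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- character(0)
  if (!is.null(attr(x, "hold_strain")))
    meta <- c(meta, paste0("# hold_strain=", format(attr(x, "hold_strain"), digits = 17)))
  if (!is.null(attr(x, "strain_rate")))
    meta <- c(meta, paste0("# strain_rate=", format(attr(x, "strain_rate"), digits = 17)))
  if (!is.null(attr(x, "label")))
    meta <- c(meta, paste0("# label=", attr(x, "label")))
  if (!is.null(attr(x, "axis")))
    meta <- c(meta, paste0("# axis=", attr(x, "axis")))
  writeLines(meta, con)
  write.csv(as.data.frame(x), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_series_meta <- function(path) {
  lines <- readLines(path, n = 10L)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub("=.*$", "", kv)
    val <- sub("^[^=]*=", "", kv)
    meta[[key]] <- val
  }
  meta
}

#' @rdname write_series_csv
#' @export
read_trace_csv <- function(path) {
  meta <- read_series_meta(path)
  df <- read.csv(path, comment.char = "#")
  if (is.null(meta$hold_strain))
    stop_format("trace CSV lacks the '# hold_strain=' metadata line")
  relaxation_trace(df$time, df$modulus, as.numeric(meta$hold_strain))
}

#' @rdname write_series_csv
#' @export
read_curve_csv <- function(path) {
  meta <- read_series_meta(path)
  df <- read.csv(path, comment.char = "#")
  if (is.null(meta$strain_rate))
    stop_format("curve CSV lacks the '# strain_rate=' metadata line")
  stress_strain_curve(df$strain, df$stress, as.numeric(meta$strain_rate),
                      if (is.null(meta$label)) "synthetic" else meta$label)
}
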