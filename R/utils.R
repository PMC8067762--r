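## Internal helpers shared across modules.

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

stop_param <- function(...) {
  stop(structure(class = c("sidearm_parameter_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("sidearm_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param(name, " must be a finite numeric scalar")
  if (positive && x <= 0) stop_param(name, " must be > 0, got ", format(x))
  if (nonneg && x < 0) stop_param(name, " must be >= 0, got ", format(x))
  invisible(x)
}

## Names of the six symmetric tensor components, LAMMPS ordering.
TENSOR_COMPONENTS <- c("sxx", "syy", "szz", "sxy", "sxz", "syz")

## Accept a length-6 vector (xx,yy,zz,xy,xz,yz) or a symmetric 3x3 matrix.
as_voigt6 <- function(x, name = "stress") {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(3L, 3L))) stop_param(name, " matrix must be 3x3")
    if (max(abs(x - t(x))) > 1e-8 * (1 + max(abs(x))))
      stop_param(name, " matrix must be symmetric")
    x <- c(x[1, 1], x[2, 2], x[3, 3], x[1, 2], x[1, 3], x[2, 3])
  }
  x <- as.numeric(x)
  if (length(x) != 6L || any(!is.finite(x)))
    stop_param(name, " must have 6 finite components (xx,yy,zz,xy,xz,yz)")
  names(x) <- TENSOR_COMPONENTS
  x
}

voigt_to_matrix <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3L, 3L)
}

## md5 of an object's canonical JSON form (used to stamp pipeline artifacts).
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(f))
}
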