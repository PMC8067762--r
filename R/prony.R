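#' Prony-series (generalized Maxwell) relaxation model
#'
#' Constructs a Prony-series relaxation modulus
#' \deqn{E(t) = E_1 + \sum_i E_i\, e^{-t/\tau_i}}
#' i.e. a long-term modulus plus decaying exponential branches. One branch
#' gives the three-parameter model \eqn{E(t) = E_1 + E_2 e^{-t/\tau}}; a zero
#' long-term modulus with one branch is the two-parameter model. Moduli are in
#' GPa and relaxation times in ps throughout.
#'
#' Branches are stored in canonical form, sorted by increasing relaxation
#' time; the represented function is unchanged by branch order.
#'
#' @param long_term long-term (equilibrium) modulus \eqn{E_1}, GPa; must be
#'   >= 0.
#' @param moduli numeric vector of branch moduli \eqn{E_i} (GPa), >= 0.
#' @param tau numeric vector of branch relaxation times \eqn{\tau_i} (ps),
#'   > 0; same length as `moduli`.
#' @return An object of class `prony_model`: a list with elements
#'   `long_term`, `moduli`, `tau`.
#' @examples
#' m <- prony_model(0.103, 0.827, 87.866)
#' predict(m, c(0, 87.866, 1000))
#' @export
prony_model <- function(long_term, moduli = numeric(), tau = numeric()) {
  check_scalar(long_term, "long_term", nonneg = TRUE)
  moduli <- as.numeric(moduli)
  tau <- as.numeric(tau)
  if (length(moduli) != length(tau))
    stop_param("moduli and tau must have the same length")
  if (any(!is.finite(moduli)) || any(moduli < 0))
    stop_param("branch moduli must be finite and >= 0")
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop_param("relaxation times must be finite and > 0")
  ord <- order(tau)
  structure(list(long_term = long_term,
                 moduli = moduli[ord],
                 tau = tau[ord]),
            class = "prony_model")
}

#' @export
print.prony_model <- function(x, digits = 4, ...) {
  nb <- length(x$moduli)
  form <- if (nb == 0L) "constant"
          else if (nb == 1L && x$long_term == 0) "two-parameter"
          else if (nb == 1L) "three-parameter"
          else sprintf("%d-branch", nb)
  cat(sprintf("Prony relaxation model (%s)\n", form))
  cat(sprintf("  long-term modulus E1: %s GPa\n",
              format(x$long_term, digits = digits)))
  if (nb > 0L)
    for (i in seq_len(nb))
      cat(sprintf("  branch %d: E = %s GPa, tau = %s ps\n", i,
                  format(x$moduli[i], digits = digits),
                  format(x$tau[i], digits = digits)))
  cat(sprintf("  E(0) = %s GPa\n",
              format(x$long_term + sum(x$moduli), digits = digits)))
  invisible(x)
}

#' Evaluate a Prony relaxation model
#'
#' Evaluates \eqn{E(t) = E_1 + \sum_i E_i e^{-t/\tau_i}} on a vector of
#' non-negative times.
#'
#' @param object a [prony_model].
#' @param t times (ps), all >= 0.
#' @param ... unused.
#' @return numeric vector of moduli (GPa), one per element of `t`.
#' @export
predict.prony_model <- function(object, t, ...) {
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0))
    stop_param("t must be finite and >= 0 (relaxation modulus domain)")
  out <- rep(object$long_term, length(t))
  for (i in seq_along(object$moduli))
    out <- out + object$moduli[i] * exp(-t / object$tau[i])
  out
}

#' @export
coef.prony_model <- function(object, ...) {
  nb <- length(object$moduli)
  if (nb == 1L)
    c(E1 = object$long_term, E2 = object$moduli, tau = object$tau)
  else
    c(E1 = object$long_term,
      setNames(object$moduli, paste0("E", seq_len(nb) + 1L)),
      setNames(object$tau, paste0("tau", seq_len(nb))))
}

## Instantaneous modulus E(0).
instantaneous_modulus <- function(model) model$long_term + sum(model$moduli)

#' Read / write a Prony model as JSON
#'
#' Parameter files carry the long-term modulus, branch moduli, and relaxation
#' times; units GPa / ps.
#'
#' @param model a [prony_model].
#' @param path file path.
#' @return `read_prony_json` returns a [prony_model]; `write_prony_json`
#'   returns `path` invisibly.
#' @export
write_prony_json <- function(model, path) {
  jsonlite::write_json(
    list(long_term = model$long_term, moduli = model$moduli, tau = model$tau,
         units = list(modulus = "GPa", time = "ps")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_prony_json
#' @export
read_prony_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  prony_model(x$long_term, x$moduli, x$tau)
}
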