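#' Logit and inverse-logit transforms
#'
#' Methylation beta values live in (0,1); all modeling is done on the logit
#' (M-value) scale, `log(beta / (1 - beta))`, which stabilises variance and
#' makes a Gaussian location-scale model reasonable.
#'
#' `logit()` refuses boundary values: clipping to `[epsilon, 1 - epsilon]`
#' is an input-handling concern, done once at I/O or generation time (see
#' [clip_beta()]), never silently inside the transform.
#'
#' @param beta Numeric vector with all values strictly in (0,1).
#' @param x Numeric vector on the logit scale.
#' @return Numeric vector of the same length.
#' @examples
#' logit(0.5)
#' inv_logit(logit(0.73))
#' @export
logit <- function(beta) {
  if (!is.numeric(beta)) abort("`beta` must be numeric.")
  if (any(!is.finite(beta)) || any(beta <= 0) || any(beta >= 1)) {
    abort("logit() requires values strictly in (0,1); clip at I/O with clip_beta().")
  }
  log(beta / (1 - beta))
}

#' @rdname logit
#' @export
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Clip beta values away from the unit-interval boundary
#'
#' @param beta Numeric vector in \[0,1\].
#' @param epsilon Half-width of the exclusion zone at each boundary.
#' @return `beta` with values forced into `[epsilon, 1 - epsilon]`.
#' @export
clip_beta <- function(beta, epsilon = 1e-6) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0, epsilon < 0.5)
  pmin(pmax(beta, epsilon), 1 - epsilon)
}
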