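#' Sample from the Polya-Gamma distribution PG(1, z)
#'
#' Draws from PG(1, z) by the exact rejection sampler (no truncation of the
#' infinite sum).  The PG latent variable is what turns the Bernoulli-logit
#' likelihood into a conditionally Gaussian one inside the Gibbs sampler:
#' given omega_i ~ PG(1, eta_i), the conditional posterior of all linear
#' predictor coefficients is multivariate normal.  The mean of PG(1, z) is
#' tanh(z/2) / (2 z) (1/4 at z = 0).
#'
#' @param z numeric vector of tilt parameters (finite; one draw per element).
#' @return numeric vector of positive draws, one per element of `z`;
#'   reproducible under [set.seed()].
#' @examples
#' set.seed(1)
#' mean(sample_polya_gamma(rep(0, 1e4)))  # ~ 0.25
#' @export
sample_polya_gamma <- function(z) {
  if (!is.numeric(z)) stop("`z` must be numeric", call. = FALSE)
  rpg_devroye(as.numeric(z))
}

#' Bernoulli deviance
#'
#' `-2 * sum(y * log(p) + (1 - y) * log(1 - p))`, the saturated-model-free
#' deviance of a Bernoulli fit, used both per-draw (for the posterior mean
#' deviance) and at the posterior-mean parameters (for the DIC plug-in).
#'
#' @param y 0/1 outcome vector.
#' @param p success probabilities; a probability of exactly 0 or 1 that
#'   conflicts with the observed outcome makes the deviance infinite and is
#'   an error.
#' @return nonnegative scalar.
#' @export
deviance_bernoulli <- function(y, p) {
  if (length(y) != length(p)) stop("`y` and `p` differ in length", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("`y` must be 0/1", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]", call. = FALSE)
  if (any((p == 0 & y == 1) | (p == 1 & y == 0))) {
    stop("probability 0/1 conflicts with outcome: infinite deviance", call. = FALSE)
  }
  ll <- ifelse(y == 1, log(p), log1p(-p))
  -2 * sum(ll)
}
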