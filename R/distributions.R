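#' Negative binomial log-pmf via its Gamma-Poisson decomposition
#'
#' Log probability mass of the marginal of a Poisson whose rate is drawn from
#' a Gamma distribution with shape `alpha` and rate `beta` — the negative
#' binomial law used for raw RNA UMI counts. The marginal has mean
#' `alpha / beta` and variance `alpha / beta * (1 + 1 / beta)`, so it is
#' over-dispersed relative to Poisson for any finite `beta`.
#'
#' @param x Non-negative integer counts (vector or matrix).
#' @param alpha Gamma shape parameter(s), strictly positive.
#' @param beta Gamma rate parameter(s), strictly positive.
#' @return Log-probabilities with the common shape of the arguments.
#' @examples
#' nb_log_pmf(0:3, alpha = 1, beta = 1) # geometric(1/2)
#' @export
nb_log_pmf <- function(x, alpha, beta) {
  if (any(x < 0) || any(x != round(x))) {
    stop("`x` must contain non-negative integer counts")
  }
  if (any(alpha <= 0) || any(beta <= 0)) stop("`alpha` and `beta` must be > 0")
  lgamma(x + alpha) - lgamma(x + 1) - lgamma(alpha) +
    alpha * log(beta / (1 + beta)) - x * log1p(beta)
}

#' Zero-inflated Poisson log-pmf
#'
#' Mixture of a structural zero (probability `1 - tau`) and a Poisson with
#' rate `mu` (probability `tau`), used for discretised TF-IDF peak signals.
#' For `y > 0` the mass is `tau * dpois(y, mu)`; at zero it is
#' `(1 - tau) + tau * exp(-mu)`.
#'
#' @param y Non-negative integer counts.
#' @param mu Poisson rate(s), strictly positive.
#' @param tau Probability of NOT being a structural zero, in (0, 1).
#' @return Log-probabilities with the common shape of the arguments.
#' @examples
#' zip_log_pmf(0, mu = 1, tau = 0.5) # log(0.5 + 0.5 * exp(-1))
#' @export
zip_log_pmf <- function(y, mu, tau) {
  if (any(y < 0) || any(y != round(y))) {
    stop("`y` must contain non-negative integer counts")
  }
  if (any(tau <= 0) || any(tau >= 1)) stop("`tau` must lie strictly in (0, 1)")
  if (any(mu <= 0)) stop("`mu` must be > 0")
  shp <- y + mu + tau # broadcast to common shape
  y <- y + 0 * shp; mu <- mu + 0 * shp; tau <- tau + 0 * shp
  out <- log(tau) + y * log(mu) - mu - lgamma(y + 1)
  z <- y == 0
  if (any(z)) {
    # log((1-tau) + tau*exp(-mu)) via log-sum-exp for stability
    a <- log1p(-tau[z])
    b <- log(tau[z]) - mu[z]
    m <- pmax(a, b)
    out[z] <- m + log(exp(a - m) + exp(b - m))
  }
  out
}
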