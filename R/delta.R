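#' Delta-method standard deviation of transformed beta variables
#'
#' Closed-form first-order approximations to the standard deviation of a
#' transformed beta-distributed variable \eqn{Y} with mean \eqn{\mu} and
#' dispersion \eqn{\sigma} (so \eqn{Var(Y) = \mu(1-\mu)\sigma^2}):
#' \describe{
#'   \item{raw}{\eqn{\sigma\sqrt{\mu(1-\mu)}}}
#'   \item{logit2}{\eqn{\sigma / \{\ln 2\,\sqrt{\mu(1-\mu)}\}}}
#'   \item{arcsine}{\eqn{\sigma/2}, independent of \eqn{\mu}}
#' }
#' These are the quantities a variable-scale Gaussian model on the respective
#' response scale implicitly models as its residual scale. Their dependence on
#' \eqn{\mu} (raw, logit2) or lack thereof (arcsine) explains why covariate
#' effects on the mean leak into scale tests for the former but not for the
#' latter.
#'
#' @param kind \code{"raw"}, \code{"logit2"} or \code{"arcsine"}.
#' @param mu,sigma beta parameters, strictly inside (0,1); vectorized.
#' @return numeric vector of approximate standard deviations on the
#'   transformed scale.
#' @examples
#' delta_sd("arcsine", mu = 0.2, sigma = 0.2)  # 0.1, whatever mu
#' delta_sd("raw", mu = 0.5, sigma = 0.1)      # 0.05
#' @export
delta_sd <- function(kind = c("raw", "logit2", "arcsine"), mu, sigma) {
  kind <- match.arg(kind)
  if (any(mu <= 0) || any(mu >= 1) || any(sigma <= 0) || any(sigma >= 1))
    stop("'mu' and 'sigma' must lie strictly inside (0, 1)")
  switch(kind,
    raw     = sigma * sqrt(mu * (1 - mu)),
    logit2  = sigma / (log(2) * sqrt(mu * (1 - mu))),
    arcsine = rep_len(sigma / 2, length(mu * sigma)))
}
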