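#' The beta distribution in mean-dispersion parametrisation
#'
#' Density, distribution function, quantile function and random generation for
#' the beta distribution parametrised by its mean \code{mu} and a dispersion
#' parameter \code{sigma}, both in (0,1), with
#' \deqn{E(Y) = \mu, \qquad Var(Y) = \mu(1-\mu)\sigma^2.}
#' This is the parametrisation used throughout the package for beta regression
#' of methylation beta-values. It maps to the standard shape parametrisation
#' via \eqn{a = \mu(1/\sigma^2 - 1)}, \eqn{b = (1-\mu)(1/\sigma^2 - 1)}.
#'
#' \code{sigma = sqrt(1/3)} with \code{mu = 0.5} recovers the uniform
#' distribution; \code{sigma -> 0} concentrates the distribution at \code{mu}.
#'
#' @param x,q vector of quantiles in (0,1).
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param mu mean parameter, in (0,1).
#' @param sigma dispersion parameter, in (0,1).
#' @param log,log.p logical; return log-scale values.
#' @param lower.tail logical; as in \code{\link[stats]{pbeta}}.
#' @return \code{dbetams} the (log-)density, \code{pbetams} the CDF,
#'   \code{qbetams} quantiles, \code{rbetams} random draws,
#'   \code{betams_shapes} a list with elements \code{shape1}, \code{shape2},
#'   \code{betams_moments} a list with elements \code{mean}, \code{variance}.
#' @examples
#' dbetams(0.3, mu = 0.5, sigma = sqrt(1/3))  # uniform density: 1
#' betams_moments(0.9, 0.2)                   # mean 0.9, variance 0.0036
#' @name betams
NULL

#' @rdname betams
#' @export
betams_shapes <- function(mu, sigma) {
  if (!all(is.finite(mu)) || !all(is.finite(sigma)))
    stop("'mu' and 'sigma' must be finite")
  if (any(mu <= 0) || any(mu >= 1))
    stop("'mu' must lie strictly inside (0, 1)")
  if (any(sigma <= 0) || any(sigma >= 1))
    stop("'sigma' must lie strictly inside (0, 1); sigma^2 >= 1 gives non-positive shapes")
  phi <- 1 / sigma^2 - 1
  list(shape1 = mu * phi, shape2 = (1 - mu) * phi)
}

#' @rdname betams
#' @export
betams_moments <- function(mu, sigma) {
  betams_shapes(mu, sigma)  # argument checks
  list(mean = mu, variance = mu * (1 - mu) * sigma^2)
}

#' @rdname betams
#' @export
dbetams <- function(x, mu, sigma, log = FALSE) {
  s <- betams_shapes(mu, sigma)
  stats::dbeta(x, s$shape1, s$shape2, log = log)
}

#' @rdname betams
#' @export
pbetams <- function(q, mu, sigma, lower.tail = TRUE, log.p = FALSE) {
  s <- betams_shapes(mu, sigma)
  stats::pbeta(q, s$shape1, s$shape2, lower.tail = lower.tail, log.p = log.p)
}

#' @rdname betams
#' @export
qbetams <- function(p, mu, sigma, lower.tail = TRUE, log.p = FALSE) {
  s <- betams_shapes(mu, sigma)
  stats::qbeta(p, s$shape1, s$shape2, lower.tail = lower.tail, log.p = log.p)
}

#' @rdname betams
#' @export
rbetams <- function(n, mu, sigma) {
  s <- betams_shapes(mu, sigma)
  stats::rbeta(n, s$shape1, s$shape2)
}
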