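## S3 methods for "methlss" fits.

#' @export
print.methlss <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  if (!is.null(x$call)) {
    cat("Call:\n"); print(x$call); cat("\n")
  }
  cat(sprintf("Location-scale %s model (%s scale), n = %d, logLik = %.3f\n",
              x$family, x$scale_mode, x$n, x$loglik))
  cat("\nLocation (mu) coefficients:\n")
  print(round(x$coefficients$mu, digits))
  cat("\nScale (sigma) coefficients:\n")
  print(round(x$coefficients$sigma, digits))
  if (!x$converged) cat("\nWarning: fit did not converge\n")
  invisible(x)
}

#' @export
coef.methlss <- function(object, submodel = c("full", "mu", "sigma"), ...) {
  submodel <- match.arg(submodel)
  cf <- object$coefficients
  switch(submodel,
         mu = cf$mu,
         sigma = cf$sigma,
         full = c(stats::setNames(cf$mu, paste0("mu:", names(cf$mu))),
                  stats::setNames(cf$sigma, paste0("sigma:", names(cf$sigma)))))
}

#' @export
vcov.methlss <- function(object, ...) object$vcov

#' @export
logLik.methlss <- function(object, ...) {
  structure(object$loglik, df = object$p1 + object$p2, nobs = object$n,
            class = "logLik")
}

#' @export
nobs.methlss <- function(object, ...) object$n

#' Fitted distribution parameters
#'
#' @param object a \code{methlss} fit.
#' @param parameter \code{"mu"} or \code{"sigma"}.
#' @param ... unused.
#' @return numeric vector of per-observation fitted values of the requested
#'   distribution parameter, on the parameter scale (not the link scale).
#' @export
fitted.methlss <- function(object, parameter = c("mu", "sigma"), ...) {
  parameter <- match.arg(parameter)
  eta <- if (parameter == "mu") drop(object$X1 %*% object$coefficients$mu)
         else drop(object$X2 %*% object$coefficients$sigma)
  if (object$family == "gaussian") {
    if (parameter == "mu") eta else exp(eta)
  } else {
    stats::plogis(eta)
  }
}

#' Predict distribution parameters for new data
#'
#' Only available for fits created through the formula interface
#' (\code{\link{methlss}}).
#'
#' @param object a \code{methlss} fit.
#' @param newdata a \code{data.frame} of covariates; omitted = training data.
#' @param parameter \code{"mu"} or \code{"sigma"}.
#' @param ... unused.
#' @export
predict.methlss <- function(object, newdata = NULL,
                            parameter = c("mu", "sigma"), ...) {
  parameter <- match.arg(parameter)
  if (is.null(newdata)) return(fitted(object, parameter))
  if (is.null(object$terms))
    stop("predict() needs a fit from the formula interface")
  tt <- stats::delete.response(object$terms[[parameter]])
  mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
  X <- stats::model.matrix(tt, mf)
  cf <- object$coefficients[[parameter]]
  eta <- drop(X[, names(cf), drop = FALSE] %*% cf)
  if (object$family == "gaussian") {
    if (parameter == "mu") eta else exp(eta)
  } else stats::plogis(eta)
}

#' Normalized quantile residuals
#'
#' Residuals defined as the standard-normal quantile of the fitted conditional
#' CDF evaluated at each observation, \eqn{r_i = \Phi^{-1}\{F(y_i; \hat\mu_i,
#' \hat\sigma_i)\}}. Under a correctly specified model they are approximately
#' iid N(0,1), which makes them the natural input to normality-based
#' goodness-of-fit checks across both families. For the Gaussian family they
#' reduce exactly to the standardized residuals \eqn{(y_i-\hat\mu_i)/\hat\sigma_i}.
#' CDF values that underflow to 0 or 1 are mapped to residuals of -8 / +8 with
#' a warning. The response is continuous, so no randomization is involved.
#'
#' @param object a \code{methlss} fit.
#' @param type \code{"quantile"} (default) or \code{"response"}
#'   (\eqn{y_i - \hat\mu_i}).
#' @param ... unused.
#' @export
residuals.methlss <- function(object, type = c("quantile", "response"), ...) {
  type <- match.arg(type)
  mu <- fitted(object, "mu")
  if (type == "response") return(object$y - mu)
  sigma <- fitted(object, "sigma")
  if (object$family == "gaussian") {
    (object$y - mu) / sigma
  } else {
    u <- pbetams(object$y, pmin(pmax(mu, 1e-10), 1 - 1e-10),
                 pmin(pmax(sigma, 1e-10), 1 - 1e-10))
    bad <- u <= 0 | u >= 1
    r <- stats::qnorm(u)
    if (any(bad)) {
      warning(sum(bad), " residual(s) at numerically degenerate CDF values set to +/-8")
      r[bad] <- ifelse(u[bad] >= 1, 8, -8)
    }
    r
  }
}

#' Simulate responses from a fitted location-scale model
#'
#' Parametric draws at the fitted per-observation (mu, sigma). Gaussian fits
#' simulate on their transformed response scale; beta fits on the beta-value
#' scale.
#'
#' @param object a \code{methlss} fit.
#' @param nsim number of response vectors.
#' @param seed optional RNG seed (an integer), applied locally.
#' @param ... unused.
#' @return a \code{data.frame} with \code{nsim} columns as in
#'   \code{\link[stats]{simulate}}.
#' @export
simulate.methlss <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  mu <- fitted(object, "mu")
  sigma <- fitted(object, "sigma")
  n <- object$n
  out <- replicate(nsim, {
    if (object$family == "gaussian") stats::rnorm(n, mu, sigma)
    else rbetams(n, mu, sigma)
  })
  as.data.frame(matrix(out, nrow = n,
                       dimnames = list(NULL, paste0("sim_", seq_len(nsim)))))
}

#' Diagnostic plots for a location-scale fit
#'
#' Normal Q-Q plot of the quantile residuals and residuals against fitted
#' location values.
#'
#' @param x a \code{methlss} fit.
#' @param ... passed to the base plotting calls.
#' @export
plot.methlss <- function(x, ...) {
  r <- residuals(x)
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  stats::qqnorm(r, main = "Quantile residuals", ...)
  stats::qqline(r)
  graphics::plot(fitted(x, "mu"), r, xlab = "Fitted mu",
                 ylab = "Quantile residual", main = "Residuals vs fitted", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Wald test for a single coefficient
#'
#' Two-sided Wald test of H0: coefficient = 0 for a named or indexed
#' coefficient of the location or scale submodel, using the t reference
#' distribution with \code{n - p1 - p2} degrees of freedom.
#'
#' @param fit a converged \code{methlss} fit.
#' @param parameter submodel: \code{"mu"} or \code{"sigma"}.
#' @param term coefficient name or integer index within the submodel.
#' @return a list with \code{estimate}, \code{se}, \code{statistic},
#'   \code{df}, \code{p.value}.
#' @export
wald_test <- function(fit, parameter = c("mu", "sigma"), term) {
  stopifnot(inherits(fit, "methlss"))
  parameter <- match.arg(parameter)
  if (!fit$converged) stop("Wald test requires a converged fit")
  cf <- fit$coefficients[[parameter]]
  se <- fit$se[[parameter]]
  if (is.character(term)) {
    if (!term %in% names(cf)) stop("no coefficient '", term, "' in the ", parameter, " submodel")
    j <- match(term, names(cf))
  } else j <- as.integer(term)
  if (is.na(j) || j < 1L || j > length(cf)) stop("invalid 'term'")
  if (!is.finite(se[j]) || se[j] <= 0) stop("zero or undefined standard error")
  stat <- unname(cf[j] / se[j])
  df <- fit$df.residual
  list(estimate = unname(cf[j]), se = unname(se[j]), statistic = stat,
       df = df, p.value = 2 * stats::pt(-abs(stat), df))
}

#' @export
summary.methlss <- function(object, ...) {
  mk <- function(parameter) {
    cf <- object$coefficients[[parameter]]
    se <- object$se[[parameter]]
    stat <- cf / se
    p <- 2 * stats::pt(-abs(stat), object$df.residual)
    cbind(Estimate = cf, `Std. Error` = se, `t value` = stat, `Pr(>|t|)` = p)
  }
  structure(list(call = object$call, family = object$family,
                 scale_mode = object$scale_mode, transform = object$transform,
                 n = object$n, df = object$df.residual, loglik = object$loglik,
                 converged = object$converged,
                 coefficients = list(mu = mk("mu"), sigma = mk("sigma"))),
            class = "summary.methlss")
}

#' @export
print.summary.methlss <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  if (!is.null(x$call)) { cat("Call:\n"); print(x$call); cat("\n") }
  cat(sprintf("%s family, %s scale%s; n = %d, logLik = %.3f, df = %d\n\n",
              x$family, x$scale_mode,
              if (!is.null(x$transform) && x$family == "gaussian")
                paste0(", ", x$transform, " response") else "",
              x$n, x$loglik, x$df))
  cat("Location submodel (mu):\n")
  stats::printCoefmat(x$coefficients$mu, digits = digits)
  cat("\nScale submodel (sigma):\n")
  stats::printCoefmat(x$coefficients$sigma, digits = digits)
  if (!x$converged) cat("\nWarning: fit did not converge\n")
  invisible(x)
}

#' Serialize a fit to a flat coefficient table
#'
#' One row per coefficient (submodel, term, estimate, SE, t statistic,
#' p-value), suitable for writing with \code{write.table}.
#'
#' @param fit a \code{methlss} fit.
#' @export
coef_table <- function(fit) {
  s <- summary(fit)
  rows <- lapply(c("mu", "sigma"), function(pp) {
    m <- s$coefficients[[pp]]
    data.frame(submodel = pp, term = rownames(m), estimate = m[, 1L],
               se = m[, 2L], statistic = m[, 3L], p.value = m[, 4L],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## local RNG bookkeeping -----------------------------------------------------

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
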