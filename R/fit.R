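## Joint ML fitting of the two-submodel location-scale models.
## Gaussian family:  mu = X1 g1 (identity link),  log sigma = X2 g2.
## Beta family:      logit mu = X1 g1,            logit sigma = X2 g2,
## with the (mu, sigma) parametrisation of beta-ms.R.

.EPS <- 1e-12

## log-likelihoods and analytic gradients on theta = c(g1, g2) --------------

.ll_gaussian <- function(theta, y, X1, X2) {
  p1 <- ncol(X1)
  mu <- drop(X1 %*% theta[seq_len(p1)])
  eta2 <- drop(X2 %*% theta[-seq_len(p1)])
  sum(stats::dnorm(y, mu, exp(eta2), log = TRUE))
}

.gr_gaussian <- function(theta, y, X1, X2) {
  p1 <- ncol(X1)
  mu <- drop(X1 %*% theta[seq_len(p1)])
  eta2 <- drop(X2 %*% theta[-seq_len(p1)])
  s2 <- exp(2 * eta2)
  e <- y - mu
  c(drop(crossprod(X1, e / s2)), drop(crossprod(X2, e^2 / s2 - 1)))
}

.ll_beta <- function(theta, y, X1, X2) {
  p1 <- ncol(X1)
  mu <- pmin(pmax(stats::plogis(drop(X1 %*% theta[seq_len(p1)])), .EPS), 1 - .EPS)
  sigma <- pmin(pmax(stats::plogis(drop(X2 %*% theta[-seq_len(p1)])), .EPS), 1 - .EPS)
  phi <- 1 / sigma^2 - 1
  a <- mu * phi
  b <- (1 - mu) * phi
  ll <- sum(lgamma(phi) - lgamma(a) - lgamma(b) +
              (a - 1) * log(y) + (b - 1) * log1p(-y))
  if (!is.finite(ll)) -.Machine$double.xmax else ll
}

.gr_beta <- function(theta, y, X1, X2) {
  p1 <- ncol(X1)
  mu <- pmin(pmax(stats::plogis(drop(X1 %*% theta[seq_len(p1)])), .EPS), 1 - .EPS)
  sigma <- pmin(pmax(stats::plogis(drop(X2 %*% theta[-seq_len(p1)])), .EPS), 1 - .EPS)
  phi <- 1 / sigma^2 - 1
  a <- mu * phi
  b <- (1 - mu) * phi
  ly <- log(y); l1y <- log1p(-y)
  dl_dmu <- phi * (digamma(b) - digamma(a) + ly - l1y)
  dl_dphi <- digamma(phi) - mu * digamma(a) - (1 - mu) * digamma(b) +
    mu * ly + (1 - mu) * l1y
  g1 <- drop(crossprod(X1, dl_dmu * mu * (1 - mu)))
  g2 <- drop(crossprod(X2, dl_dphi * (-2 * (1 - sigma) / sigma^2)))
  out <- c(g1, g2)
  out[!is.finite(out)] <- 0
  out
}

.methlss_loglik <- function(family, coef_mu, coef_sigma, y, X1, X2) {
  theta <- c(coef_mu, coef_sigma)
  if (family == "gaussian") .ll_gaussian(theta, y, X1, X2)
  else .ll_beta(theta, y, X1, X2)
}

.check_design <- function(X, label) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix ", label, " is rank-deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(qrX)
}

.intercept_col <- function(X) {
  ones <- which(apply(X, 2L, function(v) all(v == 1)))
  if (length(ones)) ones[1L] else NA_integer_
}

## Gaussian family: alternating WLS / Newton scoring, closed-form blocks -----

.fit_gaussian <- function(y, X1, X2, control) {
  n <- length(y); p1 <- ncol(X1); p2 <- ncol(X2)
  g1 <- qr.coef(qr(X1), y)
  e <- y - drop(X1 %*% g1)
  g2 <- numeric(p2)
  ic <- .intercept_col(X2)
  if (!is.na(ic)) g2[ic] <- 0.5 * log(mean(e^2)) else g2[] <- 0
  theta <- c(g1, g2)
  ll <- .ll_gaussian(theta, y, X1, X2)
  iter <- 0L
  XtX2 <- crossprod(X2)
  repeat {
    iter <- iter + 1L
    eta2 <- drop(X2 %*% g2)
    w <- exp(-2 * eta2)
    g1 <- qr.coef(qr(X1 * sqrt(w)), y * sqrt(w))
    e <- y - drop(X1 %*% g1)
    ## Newton step for g2 with expected information 2 * X2'X2
    z <- e^2 * w - 1
    step <- drop(solve(2 * XtX2, crossprod(X2, z)))
    fac <- 1
    repeat {
      cand <- g2 + fac * step
      ll_new <- .ll_gaussian(c(g1, cand), y, X1, X2)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      fac <- fac / 2
      if (fac < 1e-4) { cand <- g2; ll_new <- .ll_gaussian(c(g1, g2), y, X1, X2); break }
    }
    g2 <- cand
    done <- abs(ll_new - ll) < control$reltol * (abs(ll) + 1)
    ll <- ll_new
    if (done || iter >= control$scoring_iter) break
  }
  theta <- c(g1, g2)
  gr <- .gr_gaussian(theta, y, X1, X2)
  if (control$polish && max(abs(gr)) > control$gradtol * (1 + abs(ll))) {
    opt <- stats::optim(theta, fn = function(th) -.ll_gaussian(th, y, X1, X2),
                        gr = function(th) -.gr_gaussian(th, y, X1, X2),
                        method = "BFGS",
                        control = list(maxit = control$maxit, reltol = 1e-12))
    theta <- opt$par
    ll <- -opt$value
    gr <- .gr_gaussian(theta, y, X1, X2)
  }
  ## observed information, analytic
  g1 <- theta[seq_len(p1)]; g2 <- theta[-seq_len(p1)]
  s2 <- exp(2 * drop(X2 %*% g2))
  e <- y - drop(X1 %*% g1)
  I11 <- crossprod(X1, X1 / s2)
  I12 <- crossprod(X1, X2 * (2 * e / s2))
  I22 <- crossprod(X2, X2 * (2 * e^2 / s2))
  info <- rbind(cbind(I11, I12), cbind(t(I12), I22))
  list(theta = theta, loglik = ll, grad = gr, info = info, iterations = iter)
}

## Beta family: OLS-on-logit start, alternating block BFGS, joint polish -----

.fit_beta <- function(y, X1, X2, control) {
  n <- length(y); p1 <- ncol(X1); p2 <- ncol(X2)
  yl <- stats::qlogis(y)
  g1 <- qr.coef(qr(X1), yl)
  mu <- pmin(pmax(stats::plogis(drop(X1 %*% g1)), 0.01), 0.99)
  s2hat <- mean((y - mu)^2 / (mu * (1 - mu)))
  s0 <- sqrt(min(max(s2hat, 1e-4), 0.9))
  g2 <- numeric(p2)
  ic <- .intercept_col(X2)
  if (!is.na(ic)) g2[ic] <- stats::qlogis(s0)
  i1 <- seq_len(p1)
  ## alternating scoring between the two submodels (one quasi-Newton sweep each)
  for (k in 1:2) {
    o1 <- stats::optim(g1, fn = function(g) -.ll_beta(c(g, g2), y, X1, X2),
                       gr = function(g) -.gr_beta(c(g, g2), y, X1, X2)[i1],
                       method = "BFGS", control = list(maxit = 15))
    g1 <- o1$par
    o2 <- stats::optim(g2, fn = function(g) -.ll_beta(c(g1, g), y, X1, X2),
                       gr = function(g) -.gr_beta(c(g1, g), y, X1, X2)[-i1],
                       method = "BFGS", control = list(maxit = 15))
    g2 <- o2$par
  }
  ## joint quasi-Newton polish on the full likelihood
  opt <- stats::optim(c(g1, g2), fn = function(th) -.ll_beta(th, y, X1, X2),
                      gr = function(th) -.gr_beta(th, y, X1, X2),
                      method = "BFGS",
                      control = list(maxit = control$maxit, reltol = 1e-12))
  theta <- opt$par
  ll <- -opt$value
  gr <- .gr_beta(theta, y, X1, X2)
  info <- stats::optimHess(theta, fn = function(th) -.ll_beta(th, y, X1, X2),
                           gr = function(th) -.gr_beta(th, y, X1, X2))
  list(theta = theta, loglik = ll, grad = gr, info = info,
       iterations = opt$counts[["function"]])
}

#' Control parameters for the location-scale fitter
#'
#' @param maxit maximum iterations of the joint quasi-Newton polish.
#' @param reltol relative log-likelihood change declaring the alternating
#'   scoring converged.
#' @param gradtol gradient max-norm tolerance, relative to \code{1 + |loglik|}.
#' @param scoring_iter maximum alternating-scoring sweeps (Gaussian family).
#' @param polish run the joint quasi-Newton polish even when scoring converged.
#' @return a list of class \code{"methlss_control"}.
#' @export
methlss_control <- function(maxit = 200L, reltol = 1e-10, gradtol = 1e-6,
                            scoring_iter = 50L, polish = TRUE) {
  structure(list(maxit = maxit, reltol = reltol, gradtol = gradtol,
                 scoring_iter = scoring_iter, polish = polish),
            class = "methlss_control")
}

#' Low-level location-scale model fitter
#'
#' Fits the two-submodel location-scale model by joint maximum likelihood for
#' a response vector and explicit design matrices, without any formula
#' processing. The Gaussian family expects the response already on the
#' modelling scale (raw, M-value or A-value); the beta family expects values
#' strictly inside (0,1). Both design matrices must contain an intercept
#' column and be of full column rank; a fixed-scale model is obtained by
#' passing an all-ones single-column \code{X2}.
#'
#' Estimation alternates scoring steps between the two submodels and finishes
#' with a joint BFGS polish of the full likelihood using analytic gradients;
#' standard errors come from the inverse observed information at the optimum.
#' Fitting is deterministic.
#'
#' @param y numeric response vector.
#' @param X1 location design matrix (n x p1).
#' @param X2 scale design matrix (n x p2).
#' @param family \code{"gaussian"} or \code{"beta"}.
#' @param control a \code{\link{methlss_control}} list.
#' @return an object of class \code{"methlss"}; see \code{\link{methlss}}.
#' @export
methlss_fit <- function(y, X1, X2 = NULL, family = c("gaussian", "beta"),
                        control = methlss_control()) {
  family <- match.arg(family)
  y <- as.numeric(y)
  X1 <- as.matrix(X1)
  if (is.null(X2)) X2 <- matrix(1, length(y), 1L, dimnames = list(NULL, "(Intercept)"))
  X2 <- as.matrix(X2)
  n <- length(y)
  if (nrow(X1) != n || nrow(X2) != n)
    stop("design matrices and response have different numbers of rows")
  if (!all(is.finite(y))) stop("'y' must be finite")
  if (family == "beta" && (any(y <= 0) || any(y >= 1)))
    stop("beta-family response must lie strictly inside (0, 1)")
  if (is.null(colnames(X1))) colnames(X1) <- paste0("x1_", seq_len(ncol(X1)))
  if (is.null(colnames(X2))) colnames(X2) <- paste0("x2_", seq_len(ncol(X2)))
  .check_design(X1, "X1")
  .check_design(X2, "X2")
  p1 <- ncol(X1); p2 <- ncol(X2)
  if (n <= p1 + p2) stop("need more observations than parameters (n > p1 + p2)")

  res <- if (family == "gaussian") .fit_gaussian(y, X1, X2, control)
         else .fit_beta(y, X1, X2, control)

  ## Newton decrement: the expected log-likelihood gain of one more Newton
  ## step; scale-invariant, so it works across transforms and sample sizes.
  decrement <- tryCatch(0.5 * sum(res$grad * solve(res$info, res$grad)),
                        error = function(e) Inf)
  converged <- is.finite(res$loglik) && is.finite(decrement) &&
    decrement >= 0 && decrement < 1e-6 * (1 + abs(res$loglik))
  vc <- tryCatch(solve(res$info), error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(vc)) || any(diag(vc) <= 0)) {
    converged <- FALSE
    vc <- matrix(NA_real_, p1 + p2, p1 + p2)
  }
  vc <- (vc + t(vc)) / 2
  nm <- c(paste0("mu:", colnames(X1)), paste0("sigma:", colnames(X2)))
  dimnames(vc) <- list(nm, nm)
  se <- sqrt(diag(vc))

  coef_mu <- stats::setNames(res$theta[seq_len(p1)], colnames(X1))
  coef_sigma <- stats::setNames(res$theta[-seq_len(p1)], colnames(X2))
  structure(list(
    coefficients = list(mu = coef_mu, sigma = coef_sigma),
    se = list(mu = stats::setNames(se[seq_len(p1)], colnames(X1)),
              sigma = stats::setNames(se[-seq_len(p1)], colnames(X2))),
    vcov = vc, loglik = res$loglik, converged = converged,
    iterations = res$iterations, n = n, p1 = p1, p2 = p2,
    df.residual = n - p1 - p2, family = family,
    scale_mode = if (p2 == 1L && !is.na(.intercept_col(X2))) "fixed" else "variable",
    y = y, X1 = X1, X2 = X2
  ), class = "methlss")
}

#' Location-scale regression for methylation beta-values
#'
#' Fits one of the eight competing models for site-level DNA methylation:
#' Gaussian regression on raw, binary-logit (M-value) or arcsine-square-root
#' (A-value) transformed beta-values, or beta regression in the
#' mean-dispersion parametrisation, each with the scale parameter either fixed
#' or regressed on covariates. Both submodels are linear in the covariates:
#' \deqn{g_1(\mu) = X_1\gamma_1, \qquad g_2(\sigma) = X_2\gamma_2,}
#' with identity/log links for the Gaussian family and logit/logit links for
#' the beta family.
#'
#' The response passed in \code{formula} must consist of methylation
#' beta-values strictly inside (0,1); the transformation implied by the model
#' is applied internally. Rows with missing values in any model variable are
#' dropped listwise (with a message), matching the site-by-site fitting
#' strategy of EWAS screens.
#'
#' @param formula model formula for the location submodel, response =
#'   beta-values.
#' @param data a \code{data.frame} containing response and covariates.
#' @param scale one-sided formula for the scale submodel; the default
#'   \code{~ 1} gives a fixed-scale (location-only) model. Ignored (forced to
#'   \code{~ 1}) when \code{model} names a fixed-scale code.
#' @param model optional short code (\code{"ra"}, \code{"lo"}, \code{"ar"},
#'   \code{"be"}, \code{"ra+"}, \code{"lo+"}, \code{"ar+"}, \code{"be+"}, see
#'   \code{\link{model_spec}}); when given, it determines family and
#'   transformation, and for \code{"+"} codes the scale formula defaults to
#'   the location covariates if \code{scale} was left at \code{~ 1}.
#' @param family,transform used when \code{model} is \code{NULL}:
#'   \code{"gaussian"} with transform \code{"raw"}/\code{"logit2"}/
#'   \code{"arcsine"}, or \code{"beta"} (raw response only).
#' @param control a \code{\link{methlss_control}} list.
#' @return an object of class \code{"methlss"} with components including
#'   \code{coefficients} (list \code{mu}, \code{sigma}), \code{se},
#'   \code{vcov}, \code{loglik}, \code{converged}, \code{n}, \code{p1},
#'   \code{p2} and the model frame ingredients needed by the methods.
#' @examples
#' set.seed(1)
#' d <- data.frame(bmi = rnorm(300, 28, 5))
#' d$y <- rbetams(300, plogis(-1 + 0.02 * (d$bmi - 28)), 0.15)
#' fit <- methlss(y ~ bmi, data = d, scale = ~ bmi, model = "be+")
#' summary(fit)
#' @export
methlss <- function(formula, data, scale = ~ 1, model = NULL,
                    family = c("gaussian", "beta"),
                    transform = c("raw", "logit2", "arcsine"),
                    control = methlss_control()) {
  if (!is.null(model)) {
    spec <- model_spec(model)
    family <- spec$family
    transform <- spec$transform
    if (spec$scale_mode == "fixed") {
      scale <- ~ 1
    } else if (length(all.vars(scale)) == 0L) {
      scale <- stats::formula(stats::delete.response(stats::terms(formula, data = data)))
    }
  } else {
    family <- match.arg(family)
    transform <- match.arg(transform)
    if (family == "beta" && transform != "raw")
      stop("the beta family models raw beta-values; 'transform' must be \"raw\"")
    spec <- NULL
  }
  if (missing(data)) data <- environment(formula)

  vars <- unique(c(all.vars(formula), all.vars(scale)))
  if (is.data.frame(data)) {
    keep <- stats::complete.cases(data[, intersect(vars, names(data)), drop = FALSE])
    if (!all(keep)) {
      message("methlss: dropping ", sum(!keep), " incomplete observation(s)")
      data <- data[keep, , drop = FALSE]
    }
  }
  mf <- stats::model.frame(formula, data)
  y_beta <- stats::model.response(mf)
  if (any(y_beta <= 0) || any(y_beta >= 1))
    stop("response beta-values must lie strictly inside (0, 1); see clamp_unit()")
  X1 <- stats::model.matrix(formula, mf)
  X2 <- stats::model.matrix(scale, stats::model.frame(scale, data))
  y <- if (family == "gaussian") transform_beta(y_beta, transform) else y_beta

  fit <- methlss_fit(y, X1, X2, family = family, control = control)
  fit$transform <- transform
  fit$y_beta <- as.numeric(y_beta)
  fit$call <- match.call()
  fit$formula <- formula
  fit$scale_formula <- scale
  fit$terms <- list(mu = stats::terms(formula, data = data),
                    sigma = stats::terms(scale, data = data))
  fit$xlevels <- stats::.getXlevels(fit$terms$mu, mf)
  fit$spec <- spec
  fit
}
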