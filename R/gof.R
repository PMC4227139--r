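#' Shapiro-Wilk normality check for quantile residuals
#'
#' Thin wrapper with the input checks needed in per-site screening loops:
#' at least three finite values, non-constant input.
#'
#' @param x numeric vector of residuals (3 to 5000 finite values).
#' @return list with \code{statistic} (W) and \code{p.value}.
#' @export
residual_normality <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) stop("need at least 3 finite values")
  if (length(x) > 5000L) stop("Shapiro-Wilk is defined for at most 5000 values")
  if (stats::sd(x) == 0) stop("residuals are constant")
  sw <- stats::shapiro.test(x)
  list(statistic = unname(sw$statistic), p.value = sw$p.value)
}

#' Likelihood-based pseudo-R2
#'
#' Cox-Snell-type pseudo-R2
#' \deqn{R^2 = 1 - \exp\{-2(\ell_{fit} - \ell_{null})/m\},}
#' measuring the likelihood improvement of a fitted location-scale model over
#' the intercept-only model (both submodels intercept-only) of the same family
#' and transformation, evaluated on \code{m} observations. Evaluated on the
#' training data it is non-negative; evaluated on held-out data (training
#' coefficients, test likelihood) it may be negative. The Nagelkerke-rescaled
#' variant divides by \eqn{1 - \exp\{2\ell_{null}/m\}}.
#'
#' @param fit a \code{methlss} fit.
#' @param null_fit the intercept-only fit of the same family/transformation
#'   (both submodels intercept-only).
#' @param y,X1,X2 optional evaluation data (response on the fitted model's
#'   response scale plus design matrices); defaults to the training data
#'   stored in \code{fit}.
#' @param type \code{"coxsnell"} (default) or \code{"nagelkerke"}.
#' @return a single numeric value.
#' @export
pseudo_r2 <- function(fit, null_fit, y = NULL, X1 = NULL, X2 = NULL,
                      type = c("coxsnell", "nagelkerke")) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "methlss"), inherits(null_fit, "methlss"))
  if (fit$family != null_fit$family)
    stop("'fit' and 'null_fit' have different families")
  tf <- function(f) if (is.null(f$transform)) "raw" else f$transform
  if (fit$family == "gaussian" && tf(fit) != tf(null_fit))
    stop("'fit' and 'null_fit' use different response transformations")
  if (null_fit$p1 != 1L || null_fit$p2 != 1L)
    stop("'null_fit' must be intercept-only in both submodels")
  if (is.null(y)) { y <- fit$y; X1 <- fit$X1; X2 <- fit$X2 }
  m <- length(y)
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  ll_fit <- .methlss_loglik(fit$family, fit$coefficients$mu,
                            fit$coefficients$sigma, y, X1, X2)
  ones <- matrix(1, m, 1L)
  ll_null <- .methlss_loglik(null_fit$family, null_fit$coefficients$mu,
                             null_fit$coefficients$sigma, y, ones, ones)
  r2 <- 1 - exp(-2 * (ll_fit - ll_null) / m)
  if (type == "nagelkerke") r2 <- r2 / (1 - exp(2 * ll_null / m))
  r2
}

.fit_null <- function(y, family, control = methlss_control()) {
  ones <- matrix(1, length(y), 1L, dimnames = list(NULL, "(Intercept)"))
  methlss_fit(y, ones, ones, family = family, control = control)
}

## Fit on a training index set; pseudo-R2 on train and held-out halves,
## plus residual-normality p of the training fit.
.split_eval <- function(y, X1, X2, family, itrain, control = methlss_control()) {
  itest <- setdiff(seq_along(y), itrain)
  Xtr1 <- X1[itrain, , drop = FALSE]
  Xtr2 <- X2[itrain, , drop = FALSE]
  if (qr(Xtr1)$rank < ncol(Xtr1) || qr(Xtr2)$rank < ncol(Xtr2))
    stop("training half is rank-deficient")
  fit <- methlss_fit(y[itrain], Xtr1, Xtr2, family = family, control = control)
  null_fit <- .fit_null(y[itrain], family, control)
  train_r2 <- pseudo_r2(fit, null_fit)
  test_r2 <- pseudo_r2(fit, null_fit, y = y[itest],
                       X1 = X1[itest, , drop = FALSE],
                       X2 = X2[itest, , drop = FALSE])
  rn <- tryCatch(residual_normality(residuals(fit))$p.value,
                 error = function(e) NA_real_)
  list(train_r2 = train_r2, test_r2 = test_r2, resid_norm_p = rn,
       converged = fit$converged)
}

#' Train/test split evaluation of one model at one site
#'
#' Fits the model and the intercept-only reference on a random training
#' subsample (default 50\%) and evaluates the pseudo-R2 on the training and
#' held-out halves; held-out evaluation re-uses the training-fitted
#' coefficients in the test-set likelihood. Reproducible for a fixed seed.
#'
#' @param y response on the model's response scale (transformed values for
#'   Gaussian models, beta-values for the beta family).
#' @param X1,X2 design matrices (full data).
#' @param family \code{"gaussian"} or \code{"beta"}.
#' @param split training fraction in (0, 1).
#' @param seed optional integer seed, applied locally.
#' @param control a \code{\link{methlss_control}} list.
#' @return list with \code{train_r2}, \code{test_r2}, \code{resid_norm_p}
#'   (Shapiro-Wilk p of the training-fit quantile residuals), \code{converged}.
#' @export
split_performance <- function(y, X1, X2 = NULL, family = c("gaussian", "beta"),
                              split = 0.5, seed = NULL,
                              control = methlss_control()) {
  family <- match.arg(family)
  if (split <= 0 || split >= 1) stop("'split' must lie in (0, 1)")
  if (is.null(X2)) X2 <- matrix(1, length(y), 1L)
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  itrain <- sample(length(y), floor(split * length(y)))
  .split_eval(y, as.matrix(X1), as.matrix(X2), family, itrain, control)
}

#' Compare the competing models site-by-site
#'
#' Runs the train/test pseudo-R2 evaluation for each requested model at each
#' site, with one split per site shared across models, and tallies for each
#' model the proportion of sites where it attains the largest training
#' pseudo-R2, the largest held-out pseudo-R2 and the best residual-normality
#' fit (largest Shapiro-Wilk p). Ties go to the first model in \code{models}
#' (the conventional ra, lo, ar, be, ra+, lo+, ar+, be+ ordering) and are
#' counted.
#'
#' @param methylation a \code{\link{methylation_table}} of beta-values or a
#'   site x sample numeric matrix.
#' @param covariates \code{data.frame} of per-sample covariates (rows aligned
#'   with the methylation columns).
#' @param formula one-sided covariate formula for the location submodel
#'   (e.g. \code{~ bmi + age}).
#' @param models character vector of model codes, see \code{\link{model_codes}}.
#' @param scale one-sided formula for the scale submodel of the variable-scale
#'   models; default: same covariates as \code{formula}.
#' @param split training fraction.
#' @param seed integer seed making the per-site splits reproducible.
#' @return list of class \code{"methlss_benchmark"}: \code{per_site}
#'   (data.frame with site, model, train_r2, test_r2, resid_norm_p),
#'   \code{tallies} (per-model win proportions), \code{n_ties},
#'   \code{failed_sites}.
#' @export
benchmark_models <- function(methylation, covariates, formula,
                             models = model_codes(), scale = NULL,
                             split = 0.5, seed = 1L) {
  values <- if (inherits(methylation, "methylation_table")) methylation$values
            else as.matrix(methylation)
  if (length(models) < 1L) stop("need at least one model code")
  if (is.null(scale)) scale <- formula
  X1 <- stats::model.matrix(formula, covariates)
  X2v <- stats::model.matrix(scale, covariates)
  X2f <- matrix(1, nrow(X1), 1L, dimnames = list(NULL, "(Intercept)"))
  specs <- lapply(models, model_spec)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  n <- ncol(values)
  rows <- vector("list", nrow(values) * length(models))
  failed <- character(0)
  k <- 0L
  for (s in seq_len(nrow(values))) {
    yb <- values[s, ]
    itrain <- sample(n, floor(split * n))
    site_id <- rownames(values)[s]
    if (is.null(site_id)) site_id <- paste0("site", s)
    for (mi in seq_along(specs)) {
      sp <- specs[[mi]]
      res <- tryCatch({
        yt <- if (sp$family == "gaussian") transform_beta(yb, sp$transform) else yb
        X2 <- if (sp$scale_mode == "variable") X2v else X2f
        .split_eval(yt, X1, X2, sp$family, itrain)
      }, error = function(e) NULL)
      k <- k + 1L
      if (is.null(res)) {
        failed <- c(failed, paste0(site_id, ":", sp$code))
        rows[[k]] <- data.frame(site = site_id, model = sp$code,
                                train_r2 = NA_real_, test_r2 = NA_real_,
                                resid_norm_p = NA_real_,
                                stringsAsFactors = FALSE)
      } else {
        rows[[k]] <- data.frame(site = site_id, model = sp$code,
                                train_r2 = res$train_r2, test_r2 = res$test_r2,
                                resid_norm_p = res$resid_norm_p,
                                stringsAsFactors = FALSE)
      }
    }
  }
  per_site <- do.call(rbind, rows)
  tally <- function(col, decreasing = TRUE) {
    wins <- stats::setNames(numeric(length(models)), models)
    ties <- 0L
    for (site in unique(per_site$site)) {
      v <- per_site[per_site$site == site, col]
      if (all(is.na(v))) next
      best <- if (decreasing) max(v, na.rm = TRUE) else min(v, na.rm = TRUE)
      hits <- which(!is.na(v) & v == best)
      if (length(hits) > 1L) ties <- ties + 1L
      wins[hits[1L]] <- wins[hits[1L]] + 1
    }
    list(proportion = wins / max(sum(wins), 1L), ties = ties)
  }
  t_train <- tally("train_r2")
  t_test <- tally("test_r2")
  t_resid <- tally("resid_norm_p")
  structure(list(per_site = per_site,
                 tallies = list(train_r2 = t_train$proportion,
                                test_r2 = t_test$proportion,
                                resid_norm = t_resid$proportion),
                 n_ties = c(train_r2 = t_train$ties, test_r2 = t_test$ties,
                            resid_norm = t_resid$ties),
                 failed_sites = failed),
            class = "methlss_benchmark")
}

#' @export
print.methlss_benchmark <- function(x, ...) {
  cat("Model benchmark over", length(unique(x$per_site$site)), "sites\n")
  cat("\nShare of sites won (held-out pseudo-R2):\n")
  print(round(x$tallies$test_r2, 3))
  cat("\nShare of sites won (training pseudo-R2):\n")
  print(round(x$tallies$train_r2, 3))
  if (length(x$failed_sites))
    cat("\n", length(x$failed_sites), "site/model fits failed\n")
  invisible(x)
}
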