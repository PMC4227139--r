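#' Simulate beta-distributed methylation responses for one site
#'
#' Parametric draws for one CpG site under the variable-scale beta model:
#' per subject \eqn{i},
#' \deqn{\mathrm{logit}\,\mu_i = \mathrm{logit}(\mu_0) + \gamma_\mu c_i,\qquad
#'       \mathrm{logit}\,\sigma_i = \mathrm{logit}(\sigma_0) + \gamma_\sigma c_i,}
#' \eqn{y_i \sim Beta(\mu_i, \sigma_i)} in the mean-dispersion
#' parametrisation, where \eqn{c_i} is the manipulated covariate (centered by
#' default, so baselines keep their interpretation). Additional per-subject
#' shifts on either linear predictor can be passed through the offsets, which
#' is how the study generator layers non-manipulated covariate and SNP
#' effects.
#'
#' Numerically induced boundary parameters are clamped into (1e-6, 1-1e-6) and
#' counted; draws that underflow to 0/1 are redrawn once, then clamped. Counts
#' are returned in the \code{"n_clamped"} attribute.
#'
#' @param covariate numeric vector, one value per subject.
#' @param mu0,sigma0 baseline location/scale, scalar or per-subject vectors in
#'   (0,1).
#' @param gamma_mu,gamma_sigma effects of the covariate on logit mu / logit
#'   sigma, per covariate unit.
#' @param offset_mu,offset_sigma extra per-subject terms added to the linear
#'   predictors (default 0).
#' @param center center the covariate before applying the effects.
#' @param seed optional integer seed, applied locally.
#' @return numeric vector of responses strictly inside (0,1).
#' @export
simulate_beta_site <- function(covariate, mu0, sigma0, gamma_mu = 0,
                               gamma_sigma = 0, offset_mu = 0,
                               offset_sigma = 0, center = TRUE, seed = NULL) {
  n <- length(covariate)
  stopifnot(length(mu0) %in% c(1L, n), length(sigma0) %in% c(1L, n))
  if (any(mu0 <= 0) || any(mu0 >= 1) || any(sigma0 <= 0) || any(sigma0 >= 1))
    stop("'mu0' and 'sigma0' must lie strictly inside (0, 1)")
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  cc <- if (center) covariate - mean(covariate) else covariate
  eta1 <- stats::qlogis(mu0) + gamma_mu * cc + offset_mu
  eta2 <- stats::qlogis(sigma0) + gamma_sigma * cc + offset_sigma
  mu <- stats::plogis(eta1)
  sigma <- stats::plogis(eta2)
  n_par_clamped <- sum(mu <= 1e-6 | mu >= 1 - 1e-6) +
    sum(sigma <= 1e-6 | sigma >= 1 - 1e-6)
  if (n_par_clamped > 0L)
    warning(n_par_clamped, " induced parameter value(s) clamped into (0, 1)")
  mu <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
  sigma <- pmin(pmax(sigma, 1e-6), 1 - 1e-6)
  y <- rbetams(n, mu, sigma)
  bad <- which(y <= 0 | y >= 1)
  if (length(bad)) {
    y[bad] <- rbetams(length(bad), mu[bad], sigma[bad])
    y <- pmin(pmax(y, 1e-12), 1 - 1e-12)
  }
  attr(y, "n_clamped") <- c(parameters = n_par_clamped, draws = length(bad))
  y
}

#' Rank-based reassignment of observed values to subjects
#'
#' The subject with the k-th smallest simulated value receives the k-th
#' smallest originally observed value. The output is an exact permutation of
#' the original values (the marginal distribution is preserved) while the rank
#' structure — and hence, to the extent ranks carry it, the covariate
#' dependence — of the simulated values is imposed. Ties in the simulated
#' values are broken by input order (\code{ties = "stable"}, the default) or
#' by a local random shuffle (\code{ties = "random"} with \code{seed}).
#'
#' @param original numeric vector of observed values.
#' @param simulated numeric vector of simulated values, same length.
#' @param ties tie-breaking rule for the simulated ranks.
#' @param seed optional integer seed for \code{ties = "random"}.
#' @return permutation of \code{original} ordered by the ranks of
#'   \code{simulated}.
#' @examples
#' rank_reassign(c(0.1, 0.9, 0.5), c(3, 1, 2))  # 0.9 0.1 0.5
#' @export
rank_reassign <- function(original, simulated, ties = c("stable", "random"),
                          seed = NULL) {
  ties <- match.arg(ties)
  if (length(original) != length(simulated))
    stop("'original' and 'simulated' must have the same length")
  ord <- if (ties == "random") {
    if (!is.null(seed)) {
      old <- .save_rng(); on.exit(.restore_rng(old))
      set.seed(seed)
    }
    order(simulated, stats::runif(length(simulated)))
  } else order(simulated)
  out <- numeric(length(original))
  out[ord] <- sort(original)
  out
}

#' Rejection proportion of a set of p-values
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param alpha significance level in (0, 1).
#' @return list with \code{rate} (proportion strictly below \code{alpha}),
#'   \code{mc_se} (binomial Monte-Carlo standard error
#'   \eqn{\sqrt{\hat p(1-\hat p)/n}}) and \code{n}.
#' @export
rejection_rate <- function(p, alpha = 0.05) {
  p <- p[!is.na(p)]
  if (length(p) == 0L) stop("no p-values supplied")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  rate <- mean(p < alpha)
  list(rate = rate, mc_se = sqrt(rate * (1 - rate) / length(p)), n = length(p))
}

#' One simulation setting of the effect grid
#'
#' A single cell of the simulation grid: which parameter's covariate
#' coefficient is tested, and the generating effects of the manipulated
#' covariate on logit mu and logit sigma (per covariate unit; the grid used in
#' the type-I error and power study crosses the values 0, 0.005 and 0.05).
#'
#' @param tested \code{"mu"} or \code{"sigma"}.
#' @param gamma_mu,gamma_sigma generating effects on logit mu / logit sigma.
#' @param label optional display label.
#' @export
sim_setting <- function(tested = c("mu", "sigma"), gamma_mu = 0,
                        gamma_sigma = 0, label = NULL) {
  tested <- match.arg(tested)
  if (is.null(label))
    label <- sprintf("%s-test|gmu=%g,gsig=%g", tested, gamma_mu, gamma_sigma)
  structure(list(tested = tested, gamma_mu = gamma_mu,
                 gamma_sigma = gamma_sigma, label = label),
            class = "sim_setting")
}

#' Type-I error / power experiment over the model grid
#'
#' For each simulation setting and each site: draw per-site baselines
#' (mu0, sigma0) from the synthetic calibration, simulate a beta-distributed
#' response with the setting's covariate effects (optionally followed by
#' rank-reassignment of caller-supplied "original" responses, reproducing the
#' real-data-distributed setting), fit each requested model with intercept +
#' manipulated covariate in the active submodels, Wald-test the covariate's
#' coefficient on the tested parameter, and tabulate the rejection proportion
#' at \code{alpha}.
#'
#' Fixed-scale models carry no covariate in the scale submodel, so
#' \code{tested = "sigma"} settings report \code{NA} for them. Non-converged
#' fits are excluded and counted; cells losing more than 10\% of their sites
#' are flagged. Fully reproducible for a fixed \code{seed}.
#'
#' @param settings a \code{\link{sim_setting}} or list of them.
#' @param models character vector of model codes (\code{\link{model_codes}}).
#' @param n_sites sites (Monte-Carlo replicates) per cell.
#' @param n_subjects subjects per site.
#' @param calibration baseline generator, see \code{\link{synthetic_config}};
#'   its mixture for logit(mu0), distribution of logit(sigma0) and manipulated
#'   covariate specification are used.
#' @param data_setting \code{"beta"} (parametric draws) or \code{"real_data"}
#'   (rank-reassign the columns of \code{original} onto the simulated draws).
#' @param original site x subject matrix of observed responses, required for
#'   \code{data_setting = "real_data"}; recycled over sites if it has fewer
#'   rows than \code{n_sites}.
#' @param alpha significance level.
#' @param seed integer seed.
#' @return data.frame of class \code{"error_rate_table"} with one row per
#'   (setting, model): rejection \code{rate}, binomial \code{mc_se},
#'   \code{n_used}, \code{n_nonconverged}, \code{flagged}.
#' @export
run_error_rate_experiment <- function(settings, models = model_codes(),
                                      n_sites = 1000L, n_subjects = 1763L,
                                      calibration = synthetic_config(),
                                      data_setting = c("beta", "real_data"),
                                      original = NULL, alpha = 0.05,
                                      seed = 1L) {
  data_setting <- match.arg(data_setting)
  if (inherits(settings, "sim_setting")) settings <- list(settings)
  if (data_setting == "real_data" && is.null(original))
    stop("data_setting = \"real_data\" needs an 'original' response matrix")
  specs <- lapply(models, model_spec)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  cov_spec <- calibration$covariates[[calibration$manipulated]]
  covariate <- stats::rnorm(n_subjects, cov_spec$mean, cov_spec$sd)
  cc <- covariate - mean(covariate)
  X1 <- cbind("(Intercept)" = 1, cov = cc)
  X2f <- X1[, 1L, drop = FALSE]

  out <- vector("list", length(settings))
  for (si in seq_along(settings)) {
    st <- settings[[si]]
    pmat <- matrix(NA_real_, n_sites, length(specs),
                   dimnames = list(NULL, models))
    nonconv <- stats::setNames(integer(length(specs)), models)
    for (s in seq_len(n_sites)) {
      mu0 <- .draw_mu0(1L, calibration)
      sigma0 <- .draw_sigma0(1L, calibration)
      yb <- simulate_beta_site(covariate, mu0, sigma0,
                               gamma_mu = st$gamma_mu,
                               gamma_sigma = st$gamma_sigma)
      if (data_setting == "real_data") {
        orig <- original[((s - 1L) %% nrow(original)) + 1L, ]
        yb <- rank_reassign(orig, yb)
        yb <- pmin(pmax(yb, 1e-12), 1 - 1e-12)
      }
      for (mi in seq_along(specs)) {
        sp <- specs[[mi]]
        if (st$tested == "sigma" && sp$scale_mode == "fixed") next
        p <- tryCatch({
          yt <- if (sp$family == "gaussian") transform_beta(yb, sp$transform) else yb
          X2 <- if (sp$scale_mode == "variable") X1 else X2f
          fit <- methlss_fit(yt, X1, X2, family = sp$family)
          if (!fit$converged) NA_real_
          else wald_test(fit, st$tested, "cov")$p.value
        }, error = function(e) NA_real_)
        if (is.na(p)) nonconv[mi] <- nonconv[mi] + 1L
        pmat[s, mi] <- p
      }
    }
    rows <- lapply(seq_along(specs), function(mi) {
      sp <- specs[[mi]]
      if (st$tested == "sigma" && sp$scale_mode == "fixed")
        return(data.frame(setting = st$label, tested = st$tested,
                          gamma_mu = st$gamma_mu, gamma_sigma = st$gamma_sigma,
                          model = sp$code, rate = NA_real_, mc_se = NA_real_,
                          n_used = 0L, n_nonconverged = NA_integer_,
                          flagged = FALSE, stringsAsFactors = FALSE))
      rr <- rejection_rate(pmat[, mi], alpha)
      data.frame(setting = st$label, tested = st$tested,
                 gamma_mu = st$gamma_mu, gamma_sigma = st$gamma_sigma,
                 model = sp$code, rate = rr$rate, mc_se = rr$mc_se,
                 n_used = rr$n, n_nonconverged = nonconv[mi],
                 flagged = nonconv[mi] > 0.1 * n_sites,
                 stringsAsFactors = FALSE)
    })
    out[[si]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("error_rate_table", "data.frame")
  attr(res, "alpha") <- alpha
  attr(res, "n_subjects") <- n_subjects
  res
}

#' @export
print.error_rate_table <- function(x, ...) {
  cat("Rejection rates at alpha =", attr(x, "alpha"),
      "(n =", attr(x, "n_subjects"), "subjects per site)\n\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}
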