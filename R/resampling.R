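#' Greedy selection of correlated candidate covariates
#'
#' Forward selection of up to \code{k} columns of a candidate matrix
#' (typically cis-SNP genotypes) showing successively the strongest
#' association with a response: the first pick maximizes the absolute Pearson
#' correlation with \code{y}; each further pick maximizes the absolute
#' correlation with the residual of \code{y} after linear adjustment for the
#' already selected columns. Deterministic; ties go to the lowest column
#' index. Constant columns are skipped with a warning.
#'
#' @param y numeric response vector.
#' @param candidates n x m numeric matrix of candidate covariates.
#' @param k number of columns to select.
#' @return integer vector of selected column indices, in selection order
#'   (shorter than \code{k}, with a warning, if fewer usable columns exist).
#' @export
select_correlated_covariates <- function(y, candidates, k = 3L) {
  candidates <- as.matrix(candidates)
  if (nrow(candidates) != length(y))
    stop("'candidates' must have one row per observation")
  if (k < 0L) stop("'k' must be non-negative")
  if (k == 0L) return(integer(0))
  sds <- apply(candidates, 2L, stats::sd)
  usable <- which(is.finite(sds) & sds > 0)
  if (length(usable) < ncol(candidates))
    warning(ncol(candidates) - length(usable), " constant candidate column(s) skipped")
  if (k > length(usable)) {
    warning("only ", length(usable), " usable candidate column(s); returning fewer than k")
    k <- length(usable)
  }
  selected <- integer(0)
  r <- y
  for (step in seq_len(k)) {
    pool <- setdiff(usable, selected)
    if (!length(pool)) break
    cors <- abs(suppressWarnings(stats::cor(r, candidates[, pool, drop = FALSE])))
    cors[!is.finite(cors)] <- -Inf
    selected <- c(selected, pool[which.max(cors)])
    X <- cbind(1, candidates[, selected, drop = FALSE])
    r <- y - X %*% qr.coef(qr(X), y)
  }
  selected
}

#' Restrict candidate variants to a genomic window around a site
#'
#' @param site_pos 1-based position of the CpG site.
#' @param candidate_pos vector of 1-based variant positions.
#' @param half_width window half-width in bases (default 5 Mb), inclusive.
#' @return integer indices of candidates within the window.
#' @export
window_candidates <- function(site_pos, candidate_pos, half_width = 5e6) {
  which(abs(candidate_pos - site_pos) <= half_width)
}

#' Resampling-based p-value for a location-scale coefficient
#'
#' Bootstrap inference for models for location and scale that does not rely
#' on the (unknown) true response distribution. The algorithm:
#' \enumerate{
#'   \item Fit the full model; record the Wald statistic \eqn{t_{obs}} of the
#'     tested coefficient.
#'   \item Refit under the null with the tested coefficient constrained to
#'     zero (its column removed from the corresponding design matrix),
#'     yielding null parameter surfaces \eqn{(\hat\mu^0_i, \hat\sigma^0_i)}.
#'   \item For \eqn{b = 1, \dots, B}: draw a parametric bootstrap sample from
#'     the fitted null family, reassign the originally observed responses to
#'     the subjects according to the ranks of the bootstrap draws (so every
#'     replicate is an exact permutation of the observed values), refit the
#'     full model, and record the Wald statistic \eqn{t^*_b}.
#'   \item \eqn{p = (1 + \#\{|t^*_b| \ge |t_{obs}|\}) / (B + 1)}.
#' }
#' The rank reassignment keeps the empirical marginal distribution of the
#' data while imposing the null's covariate structure, which is what protects
#' the test against false positives driven by distributional misspecification
#' (outliers, unmodeled mixture components) leaking between the two
#' submodels.
#'
#' Non-converged bootstrap refits are redrawn up to 3 times, then dropped
#' with \code{B} decremented; fewer than \code{B/2} effective replicates is
#' an error. P-values live on \{1/(B_eff+1), ..., 1\} and are never zero.
#'
#' @param fit a converged variable-scale \code{methlss} fit.
#' @param parameter submodel of the tested coefficient: \code{"mu"} or
#'   \code{"sigma"}.
#' @param term coefficient name (or index) within that submodel.
#' @param B number of bootstrap replicates (default 100).
#' @param seed optional integer seed, applied locally.
#' @param control fitting control for the refits.
#' @return list of class \code{"methlss_resample"} with \code{p.value},
#'   \code{t_obs}, \code{statistics} (the \eqn{t^*_b}), \code{B},
#'   \code{B_effective}.
#' @export
resample_pvalue <- function(fit, parameter = c("mu", "sigma"), term, B = 100L,
                            seed = NULL, control = methlss_control()) {
  stopifnot(inherits(fit, "methlss"))
  parameter <- match.arg(parameter)
  if (B < 1L) stop("'B' must be at least 1")
  if (fit$scale_mode != "variable")
    warning("resampling inference is intended for variable-scale models")
  w <- wald_test(fit, parameter, term)
  t_obs <- w$statistic
  X <- if (parameter == "mu") fit$X1 else fit$X2
  j <- if (is.character(term)) match(term, colnames(X)) else as.integer(term)
  if (is.na(j)) stop("tested coefficient not found")
  if (ncol(X) < 2L) stop("cannot remove the only column of the design")

  X1_null <- if (parameter == "mu") fit$X1[, -j, drop = FALSE] else fit$X1
  X2_null <- if (parameter == "sigma") fit$X2[, -j, drop = FALSE] else fit$X2
  null_fit <- methlss_fit(fit$y, X1_null, X2_null, family = fit$family,
                          control = control)
  mu0 <- fitted(null_fit, "mu")
  sigma0 <- fitted(null_fit, "sigma")
  if (fit$family == "beta") {
    mu0 <- pmin(pmax(mu0, 1e-10), 1 - 1e-10)
    sigma0 <- pmin(pmax(sigma0, 1e-10), 1 - 1e-10)
  }

  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  n <- fit$n
  stats_b <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    for (attempt in 1:4) {
      ystar <- if (fit$family == "gaussian") stats::rnorm(n, mu0, sigma0)
               else rbetams(n, mu0, sigma0)
      yb <- rank_reassign(fit$y, ystar)
      tb <- tryCatch({
        refit <- methlss_fit(yb, fit$X1, fit$X2, family = fit$family,
                             control = control)
        if (!refit$converged) NA_real_
        else wald_test(refit, parameter, term)$statistic
      }, error = function(e) NA_real_)
      if (!is.na(tb)) break
      if (attempt == 4L) tb <- NA_real_
    }
    stats_b[b] <- tb
  }
  ok <- !is.na(stats_b)
  B_eff <- sum(ok)
  if (B_eff < B / 2)
    stop("fewer than B/2 bootstrap refits converged (", B_eff, " of ", B, ")")
  p <- (1 + sum(abs(stats_b[ok]) >= abs(t_obs))) / (B_eff + 1)
  structure(list(p.value = p, t_obs = t_obs, statistics = stats_b[ok],
                 B = B, B_effective = B_eff, parameter = parameter,
                 term = if (is.character(term)) term else colnames(X)[j]),
            class = "methlss_resample")
}

#' @export
print.methlss_resample <- function(x, ...) {
  cat(sprintf("Resampling test for %s-submodel coefficient '%s'\n",
              x$parameter, x$term))
  cat(sprintf("  t_obs = %.3f, B_effective = %d, p = %.4g\n",
              x$t_obs, x$B_effective, x$p.value))
  invisible(x)
}

#' Per-site screening with asymptotic and resampling inference
#'
#' The per-site engine behind \code{\link{run_ewas}}: for every site, fit the
#' requested model, optionally augmenting both submodels with the genetic
#' candidates most correlated with that site's (transformed) methylation
#' (greedy selection, fixed across bootstrap replicates), and report
#' estimates, asymptotic Wald p-values for the tested covariate's mu and
#' sigma coefficients, and — when a resampling configuration is supplied —
#' resampling p-values. Per-site failures are logged, never fatal.
#'
#' @param methylation a \code{\link{methylation_table}} of beta-values or a
#'   site x sample matrix.
#' @param covariates data.frame of per-sample covariates, rows aligned with
#'   the methylation columns.
#' @param formula one-sided covariate formula (location submodel).
#' @param tested name(s) of tested covariate coefficient(s) (design-matrix
#'   column names).
#' @param model model code; variable-scale codes test both submodels.
#' @param scale one-sided scale formula; default = \code{formula} for
#'   variable-scale models.
#' @param genetic optional site x sample genotype matrix of candidate
#'   variants shared by all sites, or a list with one candidate matrix
#'   (samples x variants) per site.
#' @param k_genetic candidates greedily added per site (default 3).
#' @param resampling \code{NULL} or list with elements \code{B} (default
#'   100), \code{parameters} (subset of \code{c("mu","sigma")}).
#' @param seed integer seed driving the per-site resampling seeds.
#' @return data.frame with one row per site x tested term x submodel:
#'   estimate, se, asymptotic p, resampling p (NA when not run),
#'   B_effective, selected candidate IDs, convergence flag, failure reason.
#' @export
screen_sites <- function(methylation, covariates, formula, tested,
                         model = "lo+", scale = NULL, genetic = NULL,
                         k_genetic = 3L, resampling = NULL, seed = 1L) {
  values <- if (inherits(methylation, "methylation_table")) methylation$values
            else as.matrix(methylation)
  sp <- model_spec(model)
  if (is.null(scale)) scale <- formula
  X1 <- stats::model.matrix(formula, covariates)
  X2 <- if (sp$scale_mode == "variable") stats::model.matrix(scale, covariates)
        else matrix(1, nrow(X1), 1L, dimnames = list(NULL, "(Intercept)"))
  if (!all(tested %in% colnames(X1)))
    stop("tested term(s) not in the design: ",
         paste(setdiff(tested, colnames(X1)), collapse = ", "))
  B <- if (is.null(resampling)) NULL else if (is.null(resampling$B)) 100L else resampling$B
  rs_par <- if (is.null(resampling)) character(0)
            else if (is.null(resampling$parameters)) c("mu", "sigma")
            else resampling$parameters
  submodels <- if (sp$scale_mode == "variable") c("mu", "sigma") else "mu"

  rows <- list()
  for (s in seq_len(nrow(values))) {
    site_id <- rownames(values)[s]
    if (is.null(site_id)) site_id <- paste0("site", s)
    res <- tryCatch({
      yb <- values[s, ]
      yt <- if (sp$family == "gaussian") transform_beta(yb, sp$transform) else yb
      X1s <- X1; X2s <- X2
      snp_ids <- character(0)
      if (!is.null(genetic) && k_genetic > 0L) {
        cand <- if (is.list(genetic) && !is.matrix(genetic)) genetic[[s]]
                else t(genetic)
        sel <- select_correlated_covariates(yt, cand, k = k_genetic)
        if (length(sel)) {
          G <- cand[, sel, drop = FALSE]
          snp_ids <- colnames(G)
          if (is.null(snp_ids)) snp_ids <- paste0("snp", sel)
          colnames(G) <- snp_ids
          X1s <- cbind(X1, G)
          if (sp$scale_mode == "variable") X2s <- cbind(X2, G)
        }
      }
      fit <- methlss_fit(yt, X1s, X2s, family = sp$family)
      site_rows <- list()
      for (term in tested) {
        for (pp in submodels) {
          wt <- tryCatch(wald_test(fit, pp, term), error = function(e) NULL)
          rp <- NA_real_; beff <- NA_integer_
          if (!is.null(wt) && pp %in% rs_par) {
            rs <- tryCatch(
              resample_pvalue(fit, pp, term, B = B,
                              seed = seed + 7L * s + match(pp, c("mu", "sigma"))),
              error = function(e) NULL)
            if (!is.null(rs)) { rp <- rs$p.value; beff <- rs$B_effective }
          }
          site_rows[[length(site_rows) + 1L]] <- data.frame(
            site = site_id, term = term, submodel = pp,
            estimate = if (is.null(wt)) NA_real_ else wt$estimate,
            se = if (is.null(wt)) NA_real_ else wt$se,
            p_asymptotic = if (is.null(wt)) NA_real_ else wt$p.value,
            p_resampling = rp, B_effective = beff,
            genetic_covariates = paste(snp_ids, collapse = ";"),
            converged = fit$converged, failure = "",
            stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, site_rows)
    }, error = function(e) {
      data.frame(site = site_id, term = tested[1L], submodel = NA_character_,
                 estimate = NA_real_, se = NA_real_, p_asymptotic = NA_real_,
                 p_resampling = NA_real_, B_effective = NA_integer_,
                 genetic_covariates = "", converged = FALSE,
                 failure = conditionMessage(e), stringsAsFactors = FALSE)
    })
    rows[[s]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
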