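#' Configuration of the synthetic methylation study generator
#'
#' Defines the data-generating process used to emulate a population-scale
#' 450K methylation study: per-site baseline locations drawn from a bimodal
#' mixture on the logit scale (most CpG sites sit near a low or a high
#' methylation state), small per-site dispersions, a small set of subject
#' covariates with effects on both distribution parameters, an optional
#' cis-SNP with an additive effect on logit mu (producing the multimodal
#' marginals seen at genotype-driven sites), and optional outlier
#' contamination.
#'
#' Defaults are the package's documented calibration: logit(mu0) from an
#' equal-weight mixture of N(-2.2, 0.6^2) and N(+2.2, 0.6^2) (baseline
#' methylation ~0.10 or ~0.90), logit(sigma0) ~ N(-1.6, 0.3^2) (sigma0 around
#' 0.17), and a BMI-like manipulated covariate N(28, 5^2) used centered.
#' Non-manipulated covariates (an age-like and a binary sex-like variable)
#' carry small effects within the range regarded as moderate in the effect
#' grid.
#'
#' @param n_subjects,n_sites study dimensions.
#' @param mu0_mixture list with \code{means}, \code{sds}, \code{weights} on
#'   the logit scale; weights must sum to 1.
#' @param sigma0 list with \code{mean}, \code{sd} on the logit scale.
#' @param covariates named list; each element a list with \code{type}
#'   (\code{"continuous"}, \code{"binary"} or \code{"categorical"}) and its
#'   distribution parameters (\code{mean}/\code{sd}, \code{prob}, or
#'   \code{levels}/\code{probs}).
#' @param effects named list (same names as covariates) of
#'   \code{c(mu = , sigma = )} effects on the logit linear predictors per
#'   covariate unit.
#' @param manipulated name of the covariate manipulated in simulation
#'   experiments.
#' @param snp \code{NULL} or list(\code{maf}, \code{effect_mu}) for an
#'   additive genotype effect on logit mu.
#' @param outliers \code{NULL} or list(\code{fraction}, \code{displacement})
#'   on the logit scale; fraction at most 0.1.
#' @param seed default seed used by \code{\link{generate_study}}.
#' @return list of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(n_subjects = 1763L, n_sites = 100L,
                             mu0_mixture = list(means = c(-2.2, 2.2),
                                                sds = c(0.6, 0.6),
                                                weights = c(0.5, 0.5)),
                             sigma0 = list(mean = -1.6, sd = 0.3),
                             covariates = list(
                               bmi = list(type = "continuous", mean = 28, sd = 5),
                               age = list(type = "continuous", mean = 61, sd = 9),
                               sex = list(type = "binary", prob = 0.5)),
                             effects = list(bmi = c(mu = 0, sigma = 0),
                                            age = c(mu = 0.002, sigma = 0.001),
                                            sex = c(mu = 0.05, sigma = 0.02)),
                             manipulated = "bmi",
                             snp = NULL, outliers = NULL, seed = 1L) {
  if (abs(sum(mu0_mixture$weights) - 1) > 1e-8)
    stop("mixture weights must sum to 1")
  if (any(mu0_mixture$sds <= 0) || sigma0$sd <= 0)
    stop("mixture standard deviations must be positive")
  if (!manipulated %in% names(covariates))
    stop("'manipulated' must name one of the covariates")
  if (!is.null(snp)) {
    if (snp$maf <= 0 || snp$maf > 0.5)
      stop("minor allele frequency must lie in (0, 0.5]")
  }
  if (!is.null(outliers)) {
    if (outliers$fraction < 0 || outliers$fraction > 0.1)
      stop("outlier fraction must lie in [0, 0.1]")
    if (outliers$displacement <= 0)
      stop("outlier displacement must be positive")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_sites = as.integer(n_sites),
                 mu0_mixture = mu0_mixture, sigma0 = sigma0,
                 covariates = covariates, effects = effects,
                 manipulated = manipulated, snp = snp, outliers = outliers,
                 seed = seed),
            class = "synthetic_config")
}

.draw_mu0 <- function(n, config) {
  mx <- config$mu0_mixture
  comp <- sample.int(length(mx$weights), n, replace = TRUE, prob = mx$weights)
  stats::plogis(stats::rnorm(n, mx$means[comp], mx$sds[comp]))
}

.draw_sigma0 <- function(n, config) {
  stats::plogis(stats::rnorm(n, config$sigma0$mean, config$sigma0$sd))
}

#' Draw per-site baseline parameters
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param n_sites number of sites; default from the config.
#' @param seed optional integer seed, applied locally.
#' @return data.frame with columns \code{mu0}, \code{sigma0}, all strictly
#'   inside (0,1).
#' @export
sample_site_parameters <- function(config, n_sites = config$n_sites,
                                   seed = NULL) {
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  data.frame(mu0 = .draw_mu0(n_sites, config),
             sigma0 = .draw_sigma0(n_sites, config))
}

#' Draw a subject covariate table
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param n_subjects number of subjects; default from the config.
#' @param seed optional integer seed, applied locally.
#' @return data.frame, one row per subject; binary covariates coded 0/1,
#'   categorical covariates as factors.
#' @export
sample_covariates <- function(config, n_subjects = config$n_subjects,
                              seed = NULL) {
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  cols <- lapply(config$covariates, function(sp) {
    switch(sp$type,
      continuous = stats::rnorm(n_subjects, sp$mean, sp$sd),
      binary = stats::rbinom(n_subjects, 1L, sp$prob),
      categorical = {
        if (abs(sum(sp$probs) - 1) > 1e-8)
          stop("category probabilities must sum to 1")
        factor(sample(sp$levels, n_subjects, replace = TRUE, prob = sp$probs),
               levels = sp$levels)
      },
      stop("unknown covariate type: ", sp$type))
  })
  out <- as.data.frame(cols, stringsAsFactors = FALSE)
  rownames(out) <- paste0("S", seq_len(n_subjects))
  out
}

#' Hardy-Weinberg genotype draws
#'
#' Additively coded genotypes 0/1/2 with frequencies \eqn{((1-q)^2,
#' 2q(1-q), q^2)} for minor allele frequency \eqn{q}.
#'
#' @param n number of subjects.
#' @param maf minor allele frequency in (0, 0.5].
#' @param seed optional integer seed, applied locally.
#' @export
generate_genotypes <- function(n, maf, seed = NULL) {
  if (maf <= 0 || maf > 0.5) stop("'maf' must lie in (0, 0.5]")
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  probs <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  sample(0:2, n, replace = TRUE, prob = probs)
}

#' Outlier contamination on the logit scale
#'
#' Displaces a random subset of entries by +/- \code{displacement} on the
#' logit scale and maps back to (0,1); sites near a boundary therefore show
#' the one-sided outlier patterns typical of contaminated methylation data.
#'
#' @param y beta-values strictly inside (0,1).
#' @param fraction fraction of entries to displace, in [0, 0.1]; the count is
#'   \code{floor(fraction * length(y))}.
#' @param displacement positive displacement on the logit scale.
#' @param seed optional integer seed, applied locally.
#' @return list with \code{y} (contaminated values, still inside (0,1)) and
#'   \code{index} (positions displaced).
#' @export
inject_outliers <- function(y, fraction, displacement, seed = NULL) {
  if (fraction < 0 || fraction > 0.1) stop("'fraction' must lie in [0, 0.1]")
  if (displacement <= 0) stop("'displacement' must be positive")
  if (any(y <= 0) || any(y >= 1)) stop("'y' must lie strictly inside (0, 1)")
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  k <- floor(fraction * length(y))
  if (k == 0L) return(list(y = y, index = integer(0)))
  idx <- sample(length(y), k)
  sgn <- sample(c(-1, 1), k, replace = TRUE)
  yl <- stats::qlogis(y[idx]) + sgn * displacement
  y[idx] <- pmin(pmax(stats::plogis(yl), 1e-12), 1 - 1e-12)
  list(y = y, index = sort(idx))
}

#' Generate a complete synthetic methylation study
#'
#' Draws covariates, per-site baselines, optional genotypes, and site-by-
#' sample beta-values from the variable-scale beta model implied by the
#' configuration (all covariate effects applied on the logit scale of both
#' parameters, SNP effect additive on logit mu), followed by optional outlier
#' injection. Every generating parameter is kept in the returned truth
#' record so that recovery can be tested.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param seed integer seed; default from the config. Byte-identical outputs
#'   for identical seeds.
#' @return list with \code{methylation} (a \code{\link{methylation_table}}),
#'   \code{covariates} (data.frame), \code{genotypes} (site x subject matrix
#'   or NULL), and \code{truth} (per-site baselines, effect sizes, outlier
#'   indices).
#' @export
generate_study <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  n <- config$n_subjects
  covars <- sample_covariates(config)
  sites <- sample_site_parameters(config)
  ns <- config$n_sites

  ## per-subject linear-predictor offsets from the non-manipulated covariates
  eff <- config$effects
  off_mu <- off_sigma <- numeric(n)
  for (nm in names(eff)) {
    v <- covars[[nm]]
    v <- if (is.factor(v)) as.numeric(v != levels(v)[1L]) else as.numeric(v)
    vc <- v - mean(v)
    off_mu <- off_mu + eff[[nm]][["mu"]] * vc
    off_sigma <- off_sigma + eff[[nm]][["sigma"]] * vc
  }

  genotypes <- NULL
  if (!is.null(config$snp))
    genotypes <- t(vapply(seq_len(ns), function(s)
      generate_genotypes(n, config$snp$maf), numeric(n)))

  values <- matrix(NA_real_, ns, n)
  outlier_idx <- vector("list", ns)
  for (s in seq_len(ns)) {
    o_mu <- off_mu
    if (!is.null(genotypes))
      o_mu <- o_mu + config$snp$effect_mu *
        (genotypes[s, ] - mean(genotypes[s, ]))
    y <- simulate_beta_site(covariate = numeric(n), mu0 = sites$mu0[s],
                            sigma0 = sites$sigma0[s], gamma_mu = 0,
                            gamma_sigma = 0, offset_mu = o_mu,
                            offset_sigma = off_sigma, center = FALSE)
    y <- as.numeric(y)
    if (!is.null(config$outliers) && config$outliers$fraction > 0) {
      oi <- inject_outliers(y, config$outliers$fraction,
                            config$outliers$displacement)
      y <- oi$y
      outlier_idx[[s]] <- oi$index
    } else outlier_idx[[s]] <- integer(0)
    values[s, ] <- y
  }
  site_ids <- sprintf("cg%06d", seq_len(ns))
  rownames(values) <- site_ids
  colnames(values) <- rownames(covars)
  if (!is.null(genotypes)) {
    rownames(genotypes) <- site_ids
    colnames(genotypes) <- rownames(covars)
  }
  list(methylation = methylation_table(values, scale = "beta"),
       covariates = covars, genotypes = genotypes,
       truth = list(sites = cbind(site_id = site_ids, sites),
                    effects = eff, snp = config$snp,
                    outliers = outlier_idx, seed = seed))
}
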