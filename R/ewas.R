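#' EWAS-style genome-wide screen for DMCs and DVCs
#'
#' Site-by-site location-scale fits across a methylation matrix with Wald
#' tests for the tested covariate's effect on methylation level (mu submodel)
#' and, for variable-scale models, variability (sigma submodel). Sites whose
#' asymptotic p-value falls below \code{threshold} are flagged as
#' differentially methylated (DMC, mu term) or differentially variable (DVC,
#' sigma term) CpG sites. When a resampling configuration is given, the
#' resampling p-value is computed for the flagged sites only (the expensive
#' confirmation step). The multiple-testing threshold is an explicit
#' argument — typically \code{0.05 / n_sites_genome} — never inferred from
#' the input dimensions.
#'
#' @inheritParams screen_sites
#' @param threshold per-test significance threshold for flagging.
#' @return data.frame as from \code{\link{screen_sites}} with additional
#'   logical columns \code{dmc} and \code{dvc} (per row: flag for the row's
#'   submodel), of class \code{"ewas_result"}.
#' @export
run_ewas <- function(methylation, covariates, formula, tested,
                     model = "lo+", scale = NULL, threshold = 0.05,
                     genetic = NULL, k_genetic = 3L, resampling = NULL,
                     seed = 1L) {
  if (threshold <= 0 || threshold >= 1) stop("'threshold' must lie in (0, 1)")
  res <- screen_sites(methylation, covariates, formula, tested, model = model,
                      scale = scale, genetic = genetic, k_genetic = k_genetic,
                      resampling = NULL, seed = seed)
  res$dmc <- !is.na(res$p_asymptotic) & res$submodel == "mu" &
    res$p_asymptotic < threshold
  res$dvc <- !is.na(res$p_asymptotic) & res$submodel == "sigma" &
    res$p_asymptotic < threshold
  if (!is.null(resampling)) {
    flagged <- which(res$dmc | res$dvc)
    values <- if (inherits(methylation, "methylation_table")) methylation$values
              else as.matrix(methylation)
    for (i in flagged) {
      sub <- screen_sites(values[res$site[i], , drop = FALSE], covariates,
                          formula, tested = res$term[i], model = model,
                          scale = scale, genetic = genetic,
                          k_genetic = k_genetic,
                          resampling = list(B = resampling$B,
                                            parameters = res$submodel[i]),
                          seed = seed + match(res$site[i], rownames(values)))
      hit <- sub$submodel == res$submodel[i] & sub$term == res$term[i]
      res$p_resampling[i] <- sub$p_resampling[hit][1L]
      res$B_effective[i] <- sub$B_effective[hit][1L]
    }
  }
  class(res) <- c("ewas_result", "data.frame")
  attr(res, "threshold") <- threshold
  res
}

#' @export
print.ewas_result <- function(x, ...) {
  cat("EWAS screen:", length(unique(x$site)), "sites, threshold =",
      format(attr(x, "threshold")), "\n")
  cat("  DMC flags:", sum(x$dmc, na.rm = TRUE),
      " DVC flags:", sum(x$dvc, na.rm = TRUE), "\n")
  invisible(x)
}

#' Fisher's exact enrichment test on a 2x2 table
#'
#' Two-sided exact test (summing hypergeometric probabilities no larger than
#' the observed table's) with the conditional odds ratio, for tables such as
#' resampling-significant x validated association counts.
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise:
#'   \code{matrix(c(a, b, c, d), 2, byrow = TRUE)}.
#' @return list with \code{odds_ratio} and \code{p.value}.
#' @examples
#' fisher_enrichment(5, 0, 0, 5)  # p = 2/252
#' @export
fisher_enrichment <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  if (sum(counts) == 0) stop("at least one margin must be nonzero")
  ft <- stats::fisher.test(matrix(counts, 2L, 2L, byrow = TRUE))
  list(odds_ratio = unname(ft$estimate), p.value = ft$p.value)
}

#' Bartlett's test after a median split of a covariate
#'
#' The two-group variance-homogeneity comparison used as a simpler contrast
#' to the model-based variability screen: the samples are divided at the
#' median of the grouping covariate (ties to the lower group) and Bartlett's
#' equal-variance statistic is referred to chi-square with 1 df.
#'
#' @param y numeric response vector.
#' @param covariate numeric grouping covariate, split at its median.
#' @return list with \code{statistic}, \code{p.value}, \code{n_low},
#'   \code{n_high}.
#' @export
bartlett_median_split <- function(y, covariate) {
  if (length(y) != length(covariate)) stop("length mismatch")
  g <- factor(covariate <= stats::median(covariate),
              levels = c(TRUE, FALSE), labels = c("low", "high"))
  if (any(table(g) < 2L)) stop("both groups need at least 2 observations")
  if (any(tapply(y, g, stats::var) == 0)) stop("a group has zero variance")
  bt <- stats::bartlett.test(y, g)
  list(statistic = unname(bt$statistic), p.value = bt$p.value,
       n_low = sum(g == "low"), n_high = sum(g == "high"))
}

#' Compare discovery and replication screens
#'
#' Joins two \code{\link{run_ewas}} result tables by site/term/submodel,
#' marks a discovery association as validated when its replication
#' asymptotic p-value is below \code{replication_threshold}, and tests for
#' enrichment of validated associations among the resampling-significant
#' discovery associations with Fisher's exact test.
#'
#' @param discovery,replication \code{ewas_result} tables.
#' @param replication_threshold nominal replication threshold (default 0.05).
#' @param resampling_threshold threshold on the discovery resampling p.
#' @return list with the merged table, the 2x2 \code{counts}
#'   (resampling-significant x validated) and the Fisher \code{enrichment}.
#' @export
validate_associations <- function(discovery, replication,
                                  replication_threshold = 0.05,
                                  resampling_threshold = 0.05) {
  key <- function(d) paste(d$site, d$term, d$submodel, sep = "\r")
  m <- match(key(discovery), key(replication))
  merged <- discovery
  merged$p_replication <- replication$p_asymptotic[m]
  merged$validated <- !is.na(merged$p_replication) &
    merged$p_replication < replication_threshold
  merged$resampling_significant <- !is.na(merged$p_resampling) &
    merged$p_resampling < resampling_threshold
  use <- !is.na(merged$p_resampling) & !is.na(merged$p_replication)
  a <- sum(use & merged$resampling_significant & merged$validated)
  b <- sum(use & merged$resampling_significant & !merged$validated)
  cc <- sum(use & !merged$resampling_significant & merged$validated)
  d <- sum(use & !merged$resampling_significant & !merged$validated)
  enr <- if (a + b + cc + d > 0) fisher_enrichment(a, b, cc, d) else NULL
  list(table = merged, counts = matrix(c(a, b, cc, d), 2L, byrow = TRUE,
         dimnames = list(c("resampling_sig", "not_sig"),
                         c("validated", "not_validated"))),
       enrichment = enr)
}
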