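#' Methylation beta-values and M-values from signal intensities
#'
#' Combine methylated and unmethylated fluorescence intensities into the two
#' standard site-level summaries of Infinium-type methylation arrays.
#' Negative intensities are floored at zero before any ratio is formed.
#'
#' The beta-value is
#' \deqn{\beta = \max(M,0) / (\max(M,0) + \max(U,0) + \alpha_\beta)}
#' with a stabilising offset \eqn{\alpha_\beta} (default 100) guarding against
#' near-zero total signal; it lies in [0,1) and reads as the proportion of
#' methylation at the site. The M-value is
#' \deqn{M\mathrm{-value} = \log_2\{(\max(M,0)+\alpha_M) / (\max(U,0)+\alpha_M)\}}
#' with offset \eqn{\alpha_M} (default 1), unbounded and approximately the
#' binary logit of the beta-value when the offsets are ignored.
#'
#' @param meth,unmeth numeric vectors of methylated / unmethylated intensities.
#' @param offset positive stabilising offset (\eqn{\alpha_\beta} resp.
#'   \eqn{\alpha_M}).
#' @return numeric vector of beta-values in [0,1) or M-values.
#' @examples
#' signals_to_beta(900, 100)      # 0.8181818
#' signals_to_m(1023, 255)        # 2
#' @export
signals_to_beta <- function(meth, unmeth, offset = 100) {
  .check_signals(meth, unmeth, offset)
  m <- pmax(meth, 0)
  u <- pmax(unmeth, 0)
  m / (m + u + offset)
}

#' @rdname signals_to_beta
#' @export
signals_to_m <- function(meth, unmeth, offset = 1) {
  .check_signals(meth, unmeth, offset)
  log2((pmax(meth, 0) + offset) / (pmax(unmeth, 0) + offset))
}

.check_signals <- function(meth, unmeth, offset) {
  if (!all(is.finite(meth)) || !all(is.finite(unmeth)))
    stop("signal intensities must be finite")
  if (!is.numeric(offset) || length(offset) != 1L || !is.finite(offset) || offset <= 0)
    stop("'offset' must be a single positive number")
  invisible(TRUE)
}

#' Transformations between the beta-, M- and A-value scales
#'
#' \code{transform_beta} maps beta-values in (0,1) onto the response scale of
#' the Gaussian models: \code{"raw"} (identity), \code{"logit2"}
#' (\eqn{\log_2\{y/(1-y)\}}, the M-value scale) or \code{"arcsine"}
#' (\eqn{\sin^{-1}\sqrt{y}}, the variance-stabilising A-value scale, mapping
#' (0,1) to (0, \eqn{\pi/2})). \code{inverse_transform_beta} is the exact
#' inverse. Values on the closed boundary are rejected; use
#' \code{\link{clamp_unit}} first if the data contain exact 0 or 1.
#'
#' @param y beta-values strictly inside (0,1).
#' @param x transformed values (for \code{"arcsine"}: inside (0, pi/2)).
#' @param kind one of \code{"raw"}, \code{"logit2"}, \code{"arcsine"}.
#' @return numeric vector on the transformed (resp. beta) scale.
#' @examples
#' transform_beta(0.8, "logit2")            # 2
#' inverse_transform_beta(pi/6, "arcsine")  # 0.25
#' @export
transform_beta <- function(y, kind = c("raw", "logit2", "arcsine")) {
  kind <- match.arg(kind)
  if (!all(is.finite(y)))
    stop("'y' must be finite")
  if (any(y <= 0) || any(y >= 1))
    stop("'y' must lie strictly inside (0, 1); use clamp_unit() for boundary values")
  switch(kind,
    raw     = y,
    logit2  = log2(y / (1 - y)),
    arcsine = asin(sqrt(y)))
}

#' @rdname transform_beta
#' @export
inverse_transform_beta <- function(x, kind = c("raw", "logit2", "arcsine")) {
  kind <- match.arg(kind)
  if (!all(is.finite(x)))
    stop("'x' must be finite")
  switch(kind,
    raw = {
      if (any(x <= 0) || any(x >= 1)) stop("raw values must lie in (0, 1)")
      x
    },
    logit2 = stats::plogis(x * log(2)),
    arcsine = {
      if (any(x <= 0) || any(x >= pi / 2))
        stop("arcsine-scale values must lie in (0, pi/2)")
      sin(x)^2
    })
}

#' Clamp unit-interval values into the open interval (0, 1)
#'
#' Values at or near the boundary are moved to \code{epsilon} /
#' \code{1 - epsilon} so that logit-type transforms and the beta likelihood are
#' defined. Clamping is deliberately not applied automatically anywhere in the
#' package; callers opt in and the number of affected entries is reported via
#' the \code{"n_clamped"} attribute and a message.
#'
#' @param y numeric vector in [0, 1].
#' @param epsilon small positive value in (0, 0.5).
#' @param quiet suppress the message when entries are clamped.
#' @return \code{y} with boundary values clamped; attribute \code{"n_clamped"}
#'   carries the count of modified entries.
#' @export
clamp_unit <- function(y, epsilon = 1e-6, quiet = FALSE) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0 || epsilon >= 0.5)
    stop("'epsilon' must be a single value in (0, 0.5)")
  if (!all(is.finite(y)))
    stop("'y' must be finite")
  if (any(y < 0) || any(y > 1))
    stop("'y' must lie in [0, 1]")
  n_clamped <- sum(y < epsilon | y > 1 - epsilon)
  out <- pmin(pmax(y, epsilon), 1 - epsilon)
  if (n_clamped > 0L && !quiet)
    message("clamp_unit: ", n_clamped, " value(s) moved into (0, 1)")
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Site-by-sample methylation tables
#'
#' A light container for a site x sample matrix of methylation values plus the
#' scale they live on. Construct directly from a matrix or read from a
#' delimited text file with sites as rows (first column = site ID) and samples
#' as columns, the layout of common 450K matrix exports.
#'
#' @param values numeric matrix, sites in rows, samples in columns.
#' @param site_ids,sample_ids character vectors; default to dimnames.
#' @param scale one of \code{"beta"}, \code{"m"}, \code{"a"}.
#' @return an object of class \code{"methylation_table"}: a list with elements
#'   \code{values}, \code{site_ids}, \code{sample_ids}, \code{scale}.
#' @export
methylation_table <- function(values, site_ids = rownames(values),
                              sample_ids = colnames(values),
                              scale = c("beta", "m", "a")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(site_ids)) site_ids <- paste0("site", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(ncol(values)))
  site_ids <- as.character(site_ids)
  sample_ids <- as.character(sample_ids)
  if (length(site_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("dimension mismatch between 'values' and the ID vectors")
  if (anyDuplicated(site_ids))
    stop("duplicated site IDs: ", paste(unique(site_ids[duplicated(site_ids)]), collapse = ", "))
  fin <- values[is.finite(values)]
  if (scale == "beta" && length(fin) && (any(fin <= 0) || any(fin >= 1)))
    stop("beta-scale values must lie strictly inside (0, 1)")
  if (scale == "a" && length(fin) && (any(fin <= 0) || any(fin >= pi / 2)))
    stop("a-scale values must lie strictly inside (0, pi/2)")
  dimnames(values) <- list(site_ids, sample_ids)
  structure(list(values = values, site_ids = site_ids,
                 sample_ids = sample_ids, scale = scale),
            class = "methylation_table")
}

#' @export
print.methylation_table <- function(x, ...) {
  cat("Methylation table:", length(x$site_ids), "sites x",
      length(x$sample_ids), "samples on the", x$scale, "scale\n")
  invisible(x)
}

.detect_sep <- function(file) {
  first <- readLines(file, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read and write methylation matrices and covariate tables
#'
#' \code{read_methylation} reads a sites-as-rows delimited text matrix (first
#' column = site ID, header = sample IDs); tab or comma separation is
#' auto-detected. Duplicate site IDs are an error. Sites with missing values
#' are dropped (default), kept, or rejected, per \code{na}.
#' \code{read_covariates} reads a samples-as-rows table (first column = sample
#' ID). \code{align_samples} intersects and orders the samples of both; a
#' warning reports samples present in only one of the two.
#' \code{write_methylation} writes the same layout back (tab-separated,
#' 10 significant digits), so that a write/read round trip reproduces the
#' values to at worst 1e-9 relative error.
#'
#' @param file path to a delimited text file.
#' @param sep field separator; \code{NULL} auto-detects tab vs comma.
#' @param scale scale of the stored values, see \code{\link{methylation_table}}.
#' @param na how to treat sites containing missing values.
#' @param x a \code{methylation_table}.
#' @return \code{read_methylation} a \code{methylation_table};
#'   \code{read_covariates} a \code{data.frame} with sample IDs as row names;
#'   \code{align_samples} a list with elements \code{methylation},
#'   \code{covariates} restricted to the common samples, in matching order.
#' @export
read_methylation <- function(file, sep = NULL, scale = "beta",
                             na = c("drop_sites", "keep", "error")) {
  na <- match.arg(na)
  if (!file.exists(file)) stop("file not found: ", file)
  if (is.null(sep)) sep <- .detect_sep(file)
  tab <- utils::read.table(file, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  site_ids <- as.character(tab[[1L]])
  if (anyDuplicated(site_ids))
    stop("duplicated site IDs in ", file)
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  incomplete <- !stats::complete.cases(values)
  if (any(incomplete)) {
    if (na == "error") stop(sum(incomplete), " site(s) contain missing values")
    if (na == "drop_sites") {
      message("read_methylation: dropping ", sum(incomplete), " site(s) with missing values")
      values <- values[!incomplete, , drop = FALSE]
      site_ids <- site_ids[!incomplete]
    }
  }
  methylation_table(values, site_ids, colnames(values), scale = scale)
}

#' @rdname read_methylation
#' @export
read_covariates <- function(file, sep = NULL) {
  if (!file.exists(file)) stop("file not found: ", file)
  if (is.null(sep)) sep <- .detect_sep(file)
  tab <- utils::read.table(file, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) stop("duplicated sample IDs in ", file)
  out <- tab[, -1L, drop = FALSE]
  rownames(out) <- ids
  out
}

#' @rdname read_methylation
#' @param methylation a \code{methylation_table}.
#' @param covariates a covariate \code{data.frame} with sample IDs as row names.
#' @export
align_samples <- function(methylation, covariates) {
  stopifnot(inherits(methylation, "methylation_table"), is.data.frame(covariates))
  common <- intersect(methylation$sample_ids, rownames(covariates))
  if (length(common) == 0L)
    stop("methylation and covariate tables share no sample IDs")
  n_drop <- (length(methylation$sample_ids) - length(common)) +
    (nrow(covariates) - length(common))
  if (n_drop > 0L)
    warning("align_samples: ", n_drop,
            " sample(s) present in only one table were dropped", call. = FALSE)
  meth <- methylation_table(methylation$values[, common, drop = FALSE],
                            methylation$site_ids, common, scale = methylation$scale)
  list(methylation = meth, covariates = covariates[common, , drop = FALSE])
}

#' @rdname read_methylation
#' @export
write_methylation <- function(x, file, sep = "\t") {
  stopifnot(inherits(x, "methylation_table"))
  df <- data.frame(site_id = x$site_ids,
                   signif(x$values, 10),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname read_methylation
#' @param covariate_file path the covariate table is written to.
#' @param covariates_df covariate \code{data.frame}, sample IDs as row names.
#' @export
write_covariates <- function(covariates_df, covariate_file, sep = "\t") {
  df <- data.frame(sample_id = rownames(covariates_df), covariates_df,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, covariate_file, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(covariate_file)
}
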