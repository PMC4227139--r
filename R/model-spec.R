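#' The eight competing model specifications
#'
#' Short codes for the eight location-scale models compared throughout the
#' package: Gaussian regression on raw (\code{"ra"}), binary-logit
#' (\code{"lo"}, M-values) or arcsine-square-root (\code{"ar"}, A-values)
#' transformed beta-values, and beta regression (\code{"be"}); a trailing
#' \code{"+"} marks the variable-scale variant in which the scale parameter is
#' regressed on covariates as well. Links are fixed by the family: identity
#' (mu) and log (sigma) for the Gaussian models, logit for both parameters of
#' the beta models.
#'
#' @param model one of \code{"ra"}, \code{"lo"}, \code{"ar"}, \code{"be"},
#'   \code{"ra+"}, \code{"lo+"}, \code{"ar+"}, \code{"be+"}.
#' @return an object of class \code{"methlss_spec"}: a list with elements
#'   \code{code}, \code{family} (\code{"gaussian"} or \code{"beta"}),
#'   \code{transform} (\code{"raw"}, \code{"logit2"}, \code{"arcsine"}) and
#'   \code{scale_mode} (\code{"fixed"} or \code{"variable"}).
#' @examples
#' model_spec("lo+")
#' model_codes()
#' @export
model_spec <- function(model) {
  codes <- model_codes()
  if (!is.character(model) || length(model) != 1L || !model %in% codes)
    stop("'model' must be one of: ", paste(codes, collapse = ", "))
  base <- sub("\\+$", "", model)
  structure(list(
    code = model,
    family = if (base == "be") "beta" else "gaussian",
    transform = switch(base, ra = "raw", lo = "logit2", ar = "arcsine", be = "raw"),
    scale_mode = if (endsWith(model, "+")) "variable" else "fixed"
  ), class = "methlss_spec")
}

#' @rdname model_spec
#' @export
model_codes <- function() c("ra", "lo", "ar", "be", "ra+", "lo+", "ar+", "be+")

#' @export
print.methlss_spec <- function(x, ...) {
  cat(sprintf("Model '%s': %s family, %s response, %s scale\n",
              x$code, x$family, x$transform, x$scale_mode))
  invisible(x)
}
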