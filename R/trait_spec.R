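#' Describe a trait's measurement scale
#'
#' A trait spec records whether a phenotype is analyzed on the continuous
#' scale (bivariate-normal likelihood) or as an ordinal liability-threshold
#' trait, how many ordered categories it has, and which covariate (age in
#' years or birth cohort) is regressed on the means or thresholds.
#'
#' @param trait_id character identifier.
#' @param scale \code{"continuous"} or \code{"ordinal"}.
#' @param n_categories number of ordered categories (ordinal only,
#'   \code{>= 2}); must be \code{NULL} for continuous traits.
#' @param covariate_kind \code{"age"}, \code{"cohort"} or \code{"none"}.
#' @return object of class \code{trait_spec}.
#' @examples
#' trait_spec("height", "continuous", covariate_kind = "age")
#' trait_spec("migraine", "ordinal", n_categories = 2)
#' @export
trait_spec <- function(trait_id, scale = c("continuous", "ordinal"),
                       n_categories = NULL,
                       covariate_kind = c("age", "cohort", "none")) {
  scale <- match.arg(scale)
  covariate_kind <- match.arg(covariate_kind)
  stopifnot(is.character(trait_id), length(trait_id) == 1L, nzchar(trait_id))
  if (scale == "ordinal") {
    if (is.null(n_categories) || length(n_categories) != 1L ||
        n_categories < 2 || n_categories != round(n_categories))
      stop("ordinal traits need an integer n_categories >= 2", call. = FALSE)
    n_categories <- as.integer(n_categories)
  } else if (!is.null(n_categories)) {
    stop("n_categories must be absent for continuous traits", call. = FALSE)
  }
  structure(list(trait_id = trait_id, scale = scale,
                 n_categories = n_categories,
                 covariate_kind = covariate_kind),
            class = "trait_spec")
}

#' @export
print.trait_spec <- function(x, ...) {
  cat("<trait_spec> ", x$trait_id, ": ", x$scale,
      if (x$scale == "ordinal") paste0(" (", x$n_categories, " categories)"),
      ", covariate = ", x$covariate_kind, "\n", sep = "")
  invisible(x)
}
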