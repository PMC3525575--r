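#' Likelihood-ratio test between nested twin-model fits
#'
#' The statistic is the difference in \eqn{-2 \log L} between the constrained
#' (nested) and the more general (full) model, referred to a chi-square with
#' df equal to the difference in free-parameter counts. Small negative
#' differences (optimizer slop within \code{tol}) are clamped to zero; larger
#' ones indicate an under-optimized full model and raise an error rather than
#' a silently wrong p-value.
#'
#' Tests of a variance component against zero, or of gamma/phi against the
#' 0.5/1 boundary, use this naive chi-square reference by default (the
#' convention of the classic twin-modeling workflow); see
#' \code{\link{run_ladder}} for the boundary-mixture option.
#'
#' @param nested,full \code{twin_fit} objects fitted to the same dataset,
#'   \code{nested} a constrained version of \code{full}.
#' @param tol clamp tolerance for negative chi-square values.
#' @return object of class \code{lrt_result}: \code{chi2}, \code{df},
#'   \code{p_value}, \code{nested_label}, \code{full_label}.
#' @examples
#' # chi2 = 5.2 on 1 df -> p = 0.0226
#' pchisq(5.2, 1, lower.tail = FALSE)
#' @export
lrt <- function(nested, full, tol = 1e-6) {
  stopifnot(inherits(nested, "twin_fit"), inherits(full, "twin_fit"))
  if (nested$n_pairs_used != full$n_pairs_used ||
      nested$spec$trait_id != full$spec$trait_id)
    stop("fits are not on the same dataset", call. = FALSE)
  if (!.is_nested(nested, full))
    stop("models are not nested: ", nested$label, " vs ", full$label,
         call. = FALSE)
  df <- full$n_free_params - nested$n_free_params
  if (df <= 0L)
    stop("nested model must have fewer free parameters", call. = FALSE)
  chi2 <- nested$minus2LL - full$minus2LL
  if (chi2 < 0) {
    if (chi2 < -tol)
      stop(sprintf(paste0("negative chi-square (%.3g) beyond tolerance: ",
                          "refit the full model"), chi2), call. = FALSE)
    chi2 <- 0
  }
  structure(list(chi2 = chi2, df = df,
                 p_value = pchisq(chi2, df, lower.tail = FALSE),
                 nested_label = nested$label, full_label = full$label),
            class = "lrt_result")
}

# constraint-lattice nesting check
.is_nested <- function(nested, full) {
  if (nested$family == "saturated" && full$family == "saturated") {
    fc <- setdiff(full$constraint_set, "none")
    nc <- setdiff(nested$constraint_set, "none")
    return(all(fc %in% nc) && length(nc) > length(fc))
  }
  if (nested$family == "ace" && full$family == "saturated") {
    # the ACE covariance structure constrains the saturated correlations
    return(length(setdiff(full$constraint_set, "none")) == 0L)
  }
  if (nested$family == "ace" && full$family == "ace") {
    fm <- full$model; nm <- nested$model
    allowed <- list(
      full_gamma = c("homogeneous", "no_c", "no_a", "qualitative_constrained"),
      full_phi = c("homogeneous", "no_c", "no_a", "qualitative_constrained"),
      homogeneous = c("no_c", "no_a"))
    if (!fm %in% names(allowed)) return(FALSE)
    if (!nm %in% allowed[[fm]]) return(FALSE)
    # reduced models must carry the full model's free qualitative parameter
    if (fm == "full_gamma" && nested$qual == "phi") return(FALSE)
    if (fm == "full_phi" && nested$qual == "gamma") return(FALSE)
    return(TRUE)
  }
  FALSE
}

#' @export
print.lrt_result <- function(x, ...) {
  cat("<lrt> ", x$nested_label, " vs ", x$full_label, "\n", sep = "")
  cat(sprintf("  chi2 = %.4f, df = %d, p = %.4g\n", x$chi2, x$df, x$p_value))
  invisible(x)
}
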