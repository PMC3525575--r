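#' Serialize a fit to JSON
#'
#' Writes parameters, \eqn{-2 \log L}, free-parameter count, convergence
#' diagnostics and (for ACE fits) the standardized component table with
#' standard errors, in a schema shared by saturated and ACE fits.
#'
#' @param fit a \code{twin_fit}.
#' @param path output path.
#' @param force overwrite an existing file.
#' @return \code{path}, invisibly.
#' @export
write_fit_json <- function(fit, path, force = FALSE) {
  stopifnot(inherits(fit, "twin_fit"))
  if (file.exists(path) && !force)
    stop("output exists (use force = TRUE): ", path, call. = FALSE)
  payload <- list(
    family = fit$family,
    label = fit$label,
    constraint_set = fit$constraint_set,
    trait_id = fit$spec$trait_id,
    scale = fit$spec$scale,
    minus2LL = fit$minus2LL,
    n_free_params = fit$n_free_params,
    n_pairs_used = fit$n_pairs_used,
    n_singles = fit$n_singles,
    converged = fit$converged,
    boundary = as.list(fit$boundary),
    diagnostics = fit$diagnostics[c("optim_convergence", "restarts")],
    params = fit$params)
  if (!is.null(fit$se)) payload$se <- as.list(fit$se)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
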