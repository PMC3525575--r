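#' Per-trait nested testing ladder for sex differences
#'
#' Runs the screening procedure on one trait. Starting from the saturated
#' model (model 1), the ladder tests, sequentially and carrying forward each
#' retained constraint:
#' \enumerate{
#'   \item model 1a (continuous only): equal male/female variances;
#'   \item model 2: \eqn{r_{DZM} = r_{DZF}};
#'   \item model 3: \eqn{r_{DZM} = r_{DZF} = r_{DOS}}.
#' }
#' A constraint is retained when its LRT p-value is \eqn{\ge}
#' \code{alpha_saturated}. If the model-3 step is rejected \emph{and} the
#' estimated DOS correlation lies below the pooled same-sex DZ correlation,
#' the ACE sequence is fitted: a full sex-limitation model with the
#' qualitative parameter chosen by
#' \code{\link{choose_qualitative_parameter}}, against the
#' gamma = 0.5 / phi = 1 null, tested at \code{alpha_parsimony}. Traits whose
#' DOS correlation exceeds the same-sex DZ correlations are flagged but no
#' genetic model is fitted (such patterns point at rater-contrast or
#' sib-interaction mechanisms outside this model space).
#'
#' @param ds a \code{\link{twin_dataset}}.
#' @param alpha_saturated significance level for the saturated-model
#'   constraint tests (default 0.05).
#' @param alpha_parsimony level for the ACE qualitative-parameter test
#'   (default 0.01, the parsimony convention).
#' @param control optimizer settings forwarded to the fitters.
#' @return object of class \code{trait_verdict}: fitted models
#'   (\code{$fits}), the ordered LRT ladder (\code{$ladder}), the retained
#'   constraint set and parsimonious model label, \code{dos_lower} /
#'   \code{dos_higher} flags, and \code{qualitative_mechanism} (list with
#'   \code{type} in \code{none/genetic/environmental} and the \code{gamma}
#'   or \code{phi} \code{estimate}).
#' @export
run_ladder <- function(ds, alpha_saturated = 0.05, alpha_parsimony = 0.01,
                       control = list()) {
  stopifnot(inherits(ds, "twin_dataset"))
  ds <- standardize_covariate(ds)
  fits <- list()
  ladder <- list()
  retained <- character(0)

  step <- function(tag, cons, parent) {
    fit <- fit_saturated(ds, constraints = c(retained, cons), start = parent,
                         control = control)
    test <- lrt(fit, parent)
    fits[[tag]] <<- fit
    ladder[[tag]] <<- test
    test
  }

  m1 <- fit_saturated(ds, "none", control = control)
  fits$saturated <- m1
  current <- m1

  if (ds$spec$scale == "continuous") {
    t1a <- step("equal_variances", "equal_variances", current)
    if (t1a$p_value >= alpha_saturated) {
      retained <- c(retained, "equal_variances")
      current <- fits$equal_variances
    }
  }
  t2 <- step("rdz_equal", "rdz_equal", current)
  m2 <- fits$rdz_equal
  # model 3 adds the DOS constraint on top of model 2 (retained or not):
  # this step is the DZss-vs-DZos test
  t3 <- tryCatch({
    fit3 <- fit_saturated(ds, constraints = c(retained, "rdz_all_equal"),
                          start = m2, control = control)
    fits$rdz_all_equal <- fit3
    lrt(fit3, m2)
  }, error = function(e) stop("ladder position model 3: ",
                              conditionMessage(e), call. = FALSE))
  ladder$rdz_all_equal <- t3
  if (t2$p_value >= alpha_saturated) retained <- c(retained, "rdz_equal")
  dz_rejected <- t3$p_value < alpha_saturated
  if (!dz_rejected) retained <- c(retained, "rdz_all_equal")

  r2 <- m2$params$cor
  dos_lower <- isTRUE(r2[["DOS"]] < r2[["DZM"]])   # DZM = DZF pooled in m2
  dos_higher <- isTRUE(r2[["DOS"]] > r2[["DZM"]])

  mech <- list(type = "none", estimate = NA_real_)
  parsimonious <- paste0("saturated[",
                         if (length(retained)) paste(sort(retained),
                                                     collapse = "+")
                         else "none", "]")
  if (dz_rejected && dos_lower) {
    full <- fit_ace(ds, "full_gamma", se = FALSE, control = control)
    pick <- suppressMessages(choose_qualitative_parameter(full))
    if (pick == "phi")
      full <- fit_ace(ds, "full_phi", start = full, se = FALSE,
                      control = control)
    null <- fit_ace(ds, "qualitative_constrained", start = full,
                    control = control)
    homog <- fit_ace(ds, "homogeneous", qual = pick, start = full,
                     control = control)
    fits$ace_full <- full
    fits$ace_qual_null <- null
    fits$ace_homogeneous <- homog
    ladder$qualitative <- lrt(null, full)
    ladder$quantitative <- lrt(homog, full)
    if (ladder$qualitative$p_value < alpha_parsimony) {
      mech <- if (pick == "gamma")
        list(type = "genetic", estimate = full$params$gamma)
      else list(type = "environmental", estimate = full$params$phi)
      parsimonious <- full$label
    }
  }

  structure(list(trait_id = ds$spec$trait_id,
                 fits = fits, ladder = ladder,
                 retained = retained,
                 parsimonious_model = parsimonious,
                 cor_saturated = m1$params$cor,
                 dz_rejected = dz_rejected,
                 dos_lower = dos_lower, dos_higher = dos_higher,
                 qualitative_mechanism = mech,
                 alpha_saturated = alpha_saturated,
                 alpha_parsimony = alpha_parsimony),
            class = "trait_verdict")
}

#' @export
print.trait_verdict <- function(x, ...) {
  cat("<trait_verdict> ", x$trait_id, "\n", sep = "")
  cat("  saturated correlations:\n")
  print(round(x$cor_saturated, 4))
  for (nm in names(x$ladder)) {
    t <- x$ladder[[nm]]
    cat(sprintf("  %-16s chi2 = %7.3f  df = %d  p = %.4g\n",
                nm, t$chi2, t$df, t$p_value))
  }
  cat("  parsimonious model:", x$parsimonious_model, "\n")
  if (x$dz_rejected)
    cat("  DOS correlation significantly different (",
        if (x$dos_lower) "lower" else if (x$dos_higher) "higher" else "equal",
        " than DZss)\n", sep = "")
  cat("  qualitative mechanism:", x$qualitative_mechanism$type,
      if (x$qualitative_mechanism$type != "none")
        sprintf("(estimate %.3f)", x$qualitative_mechanism$estimate), "\n")
  invisible(x)
}

#' Screen many traits for sex differences in genetic architecture
#'
#' Applies \code{\link{run_ladder}} to each dataset and summarizes: how many
#' traits show DZ-correlation heterogeneity, how many show a DOS-specific
#' deficit, and how many resolve to a qualitative genetic
#' (\eqn{\gamma < 0.5}) or shared-environmental (\eqn{\phi < 1}) mechanism.
#' Also tabulates, per trait, the observed DOS correlation against its
#' expectation under no sex difference, taken as the mean of the two same-sex
#' DZ correlations from the saturated fit.
#'
#' No multiple-testing correction is applied across traits (per-trait alpha
#' matches the screening convention in which about 5\% of null traits are
#' expected to be flagged); set \code{bonferroni = TRUE} to divide
#' \code{alpha_saturated} by the number of traits.
#'
#' @param datasets list of \code{\link{twin_dataset}}s.
#' @param alpha_saturated,alpha_parsimony see \code{\link{run_ladder}}.
#' @param bonferroni divide \code{alpha_saturated} by the number of traits.
#' @param control optimizer settings.
#' @return object of class \code{screen_report}: \code{verdicts} (list),
#'   \code{summary} (named counts), and \code{dos_table} (data.frame of
#'   observed vs expected DOS correlations).
#' @export
run_screen <- function(datasets, alpha_saturated = 0.05,
                       alpha_parsimony = 0.01, bonferroni = FALSE,
                       control = list()) {
  stopifnot(length(datasets) >= 1L)
  alpha <- if (bonferroni) alpha_saturated / length(datasets)
           else alpha_saturated
  verdicts <- lapply(datasets, run_ladder, alpha_saturated = alpha,
                     alpha_parsimony = alpha_parsimony, control = control)
  names(verdicts) <- vapply(verdicts, `[[`, "", "trait_id")

  mech <- vapply(verdicts, function(v) v$qualitative_mechanism$type, "")
  p2 <- vapply(verdicts, function(v) v$ladder$rdz_equal$p_value, 0)
  p3 <- vapply(verdicts, function(v) v$ladder$rdz_all_equal$p_value, 0)
  summary <- c(
    n_traits = length(verdicts),
    n_dz_heterogeneity = sum(p2 < alpha | p3 < alpha),
    n_dos_flagged = sum(p3 < alpha),
    n_dos_lower = sum(p3 < alpha &
                        vapply(verdicts, `[[`, TRUE, "dos_lower")),
    n_qual_genetic = sum(mech == "genetic"),
    n_qual_environmental = sum(mech == "environmental"))

  dos_table <- data.frame(
    trait_id = names(verdicts),
    r_dos_observed = vapply(verdicts, function(v)
      v$cor_saturated[["DOS"]], 0),
    r_dos_expected = vapply(verdicts, function(v)
      mean(v$cor_saturated[c("DZM", "DZF")]), 0),
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(verdicts = verdicts, summary = summary,
                 dos_table = dos_table, alpha_saturated = alpha,
                 alpha_parsimony = alpha_parsimony),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report> ", x$summary[["n_traits"]], " traits\n", sep = "")
  cat(sprintf("  DZ-correlation heterogeneity: %d\n",
              x$summary[["n_dz_heterogeneity"]]))
  cat(sprintf("  DOS flagged (DZss vs DZos test at alpha = %g): %d (%.1f%%)\n",
              x$alpha_saturated, x$summary[["n_dos_flagged"]],
              100 * x$summary[["n_dos_flagged"]] / x$summary[["n_traits"]]))
  cat(sprintf("  qualitative genetic (gamma < 0.5): %d\n",
              x$summary[["n_qual_genetic"]]))
  cat(sprintf("  shared-environmental (phi < 1):    %d\n",
              x$summary[["n_qual_environmental"]]))
  invisible(x)
}

#' @export
as.data.frame.screen_report <- function(x, ...) {
  rows <- lapply(x$verdicts, function(v) {
    gam <- if (!is.null(v$fits$ace_full)) v$fits$ace_full$params$gamma
           else NA_real_
    phi <- if (!is.null(v$fits$ace_full)) v$fits$ace_full$params$phi
           else NA_real_
    data.frame(
      trait_id = v$trait_id,
      r_mzm = v$cor_saturated[["MZM"]], r_mzf = v$cor_saturated[["MZF"]],
      r_dzm = v$cor_saturated[["DZM"]], r_dzf = v$cor_saturated[["DZF"]],
      r_dos = v$cor_saturated[["DOS"]],
      p_equal_variances = if (!is.null(v$ladder$equal_variances))
        v$ladder$equal_variances$p_value else NA_real_,
      p_rdz_equal = v$ladder$rdz_equal$p_value,
      p_dos = v$ladder$rdz_all_equal$p_value,
      p_qualitative = if (!is.null(v$ladder$qualitative))
        v$ladder$qualitative$p_value else NA_real_,
      dos_lower = v$dos_lower, dos_higher = v$dos_higher,
      mechanism = v$qualitative_mechanism$type,
      gamma_hat = gam, phi_hat = phi,
      parsimonious_model = v$parsimonious_model,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a screen report to TSV and JSON
#'
#' @param report a \code{screen_report}.
#' @param tsv_path,json_path output paths (either may be \code{NULL} to
#'   skip).
#' @param force overwrite existing files.
#' @return invisibly, the per-trait data.frame.
#' @export
write_screen_report <- function(report, tsv_path = NULL, json_path = NULL,
                                force = FALSE) {
  df <- as.data.frame(report)
  for (p in c(tsv_path, json_path))
    if (!is.null(p) && file.exists(p) && !force)
      stop("output exists (use force = TRUE): ", p, call. = FALSE)
  if (!is.null(tsv_path))
    write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(summary = as.list(report$summary),
           alpha_saturated = report$alpha_saturated,
           alpha_parsimony = report$alpha_parsimony,
           traits = df, dos_table = report$dos_table),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(df)
}
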