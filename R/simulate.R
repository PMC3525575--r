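#' Generating model for ACE-structured twin pairs
#'
#' A generative config fixes the population from which
#' \code{\link{simulate_pairs}} draws: standardized variance components per
#' sex (\code{a2 + c2 + e2 = 1}), the opposite-sex additive-genetic
#' correlation \code{gamma} (0.5 under the null of shared genes) and
#' shared-environment correlation \code{phi} (1 under the null), sex-specific
#' means/SDs (continuous) or thresholds (ordinal), fixed-effect slopes of the
#' standardized age/cohort covariate, and group sample sizes.
#'
#' The defaults describe a null trait with moderate familiality
#' (\eqn{a^2 = 0.4}, \eqn{c^2 = 0.2}, \eqn{e^2 = 0.4} in both sexes,
#' \eqn{\gamma = 0.5}, \eqn{\phi = 1}) and 1000 pairs per zygosity group.
#'
#' @param a2_m,c2_m,e2_m standardized variance components, males.
#' @param a2_f,c2_f,e2_f standardized variance components, females.
#' @param gamma additive-genetic correlation in opposite-sex DZ pairs,
#'   in \eqn{[0, 0.5]}.
#' @param phi shared-environment correlation in opposite-sex DZ pairs,
#'   in \eqn{[0, 1]}.
#' @param mean_m,mean_f,sd_m,sd_f trait mean and SD per sex (continuous).
#' @param beta_age_m,beta_age_f slope of the standardized covariate on the
#'   mean (continuous) or on the thresholds (ordinal; a positive slope
#'   raises thresholds, lowering high-category prevalence with age).
#' @param thresholds_m,thresholds_f strictly increasing liability thresholds
#'   (ordinal traits; length \code{n_categories - 1}).
#' @param n_pairs_per_group named integer vector over
#'   \code{MZM, MZF, DZM, DZF, DOS}.
#' @param age_mean,age_sd distribution of the raw covariate (normal).
#' @param seed integer RNG seed; part of the config so a dataset is a pure
#'   function of its config.
#' @return object of class \code{generative_config}.
#' @export
generative_config <- function(a2_m = 0.4, c2_m = 0.2, e2_m = 1 - a2_m - c2_m,
                              a2_f = a2_m, c2_f = c2_m,
                              e2_f = 1 - a2_f - c2_f,
                              gamma = 0.5, phi = 1,
                              mean_m = 0, mean_f = 0, sd_m = 1, sd_f = 1,
                              beta_age_m = 0, beta_age_f = 0,
                              thresholds_m = NULL, thresholds_f = NULL,
                              n_pairs_per_group = c(MZM = 1000, MZF = 1000,
                                                    DZM = 1000, DZF = 1000,
                                                    DOS = 1000),
                              age_mean = 35, age_sd = 10, seed = 1L) {
  cfg <- structure(as.list(environment()), class = "generative_config")
  .check_gen_config(cfg)
  cfg
}

.check_gen_config <- function(cfg) {
  chk <- function(cond, what) if (!cond) stop("invalid generative config: ",
                                              what, call. = FALSE)
  for (s in c("m", "f")) {
    comp <- c(cfg[[paste0("a2_", s)]], cfg[[paste0("c2_", s)]],
              cfg[[paste0("e2_", s)]])
    chk(all(comp >= 0), paste0("negative variance component (", s, ")"))
    chk(comp[3] > 0, paste0("e2 must be > 0 (", s, ")"))
    chk(abs(sum(comp) - 1) <= 1e-12,
        paste0("a2 + c2 + e2 != 1 (", s, ")"))
  }
  chk(cfg$gamma >= 0 && cfg$gamma <= 0.5, "gamma outside [0, 0.5]")
  chk(cfg$phi >= 0 && cfg$phi <= 1, "phi outside [0, 1]")
  chk(cfg$sd_m > 0 && cfg$sd_f > 0, "non-positive sd")
  chk(cfg$age_sd > 0, "non-positive age_sd")
  for (thr in list(cfg$thresholds_m, cfg$thresholds_f))
    if (!is.null(thr))
      chk(all(diff(thr) > 0) || length(thr) == 1L,
          "thresholds not strictly increasing")
  chk(all(.GROUPS %in% names(cfg$n_pairs_per_group)),
      "n_pairs_per_group must name all five groups")
  chk(all(cfg$n_pairs_per_group >= 0), "negative group size")
  invisible(cfg)
}

#' Simulate twin pairs under the ACE sex-limitation model
#'
#' Draws, per zygosity group, latent additive-genetic (A), common-environment
#' (C) and unique-environment (E) standard-normal deviates with
#' \eqn{corr(A_1, A_2)} = 1 (MZ), 0.5 (same-sex DZ) or \eqn{\gamma} (DOS);
#' \eqn{corr(C_1, C_2)} = 1 (same-sex) or \eqn{\phi} (DOS); E uncorrelated.
#' The standardized liability is \eqn{\sqrt{a^2} A + \sqrt{c^2} C +
#' \sqrt{e^2} E}. Continuous phenotypes are
#' \code{mean_sex + beta_sex * z_age + sd_sex * liability}; ordinal
#' phenotypes count the sex-specific thresholds (shifted by
#' \code{beta_sex * z_age}) that the liability exceeds. Co-twins share one
#' age, drawn per pair; the stored covariate is the raw age (standardize
#' before fitting with \code{\link{standardize_covariate}}, which reproduces
#' the z-scores used in generation).
#'
#' The population twin correlations implied by the draw are
#' \eqn{r_{MZ} = a^2 + c^2}, \eqn{r_{DZss} = 0.5 a^2 + c^2} and
#' \eqn{r_{DOS} = \gamma \sqrt{a^2_m a^2_f} + \phi \sqrt{c^2_m c^2_f}} on the
#' liability scale.
#'
#' @param cfg a \code{\link{generative_config}}.
#' @param spec a \code{\link{trait_spec}}; ordinal specs need matching
#'   threshold lengths in \code{cfg}.
#' @return a \code{\link{twin_dataset}}.
#' @export
simulate_pairs <- function(cfg, spec) {
  stopifnot(inherits(cfg, "generative_config"), inherits(spec, "trait_spec"))
  .check_gen_config(cfg)
  if (spec$scale == "ordinal") {
    for (s in c("m", "f")) {
      thr <- cfg[[paste0("thresholds_", s)]]
      if (is.null(thr) || length(thr) != spec$n_categories - 1L)
        stop("thresholds_", s, " must have length n_categories - 1",
             call. = FALSE)
    }
  }
  set.seed(cfg$seed)
  comp <- list(M = c(a = cfg$a2_m, c = cfg$c2_m, e = cfg$e2_m),
               F = c(a = cfg$a2_f, c = cfg$c2_f, e = cfg$e2_f))
  rA <- c(MZM = 1, MZF = 1, DZM = 0.5, DZF = 0.5, DOS = cfg$gamma)
  rC <- c(MZM = 1, MZF = 1, DZM = 1, DZF = 1, DOS = cfg$phi)

  blocks <- lapply(.GROUPS, function(g) {
    n <- as.integer(cfg$n_pairs_per_group[[g]])
    if (n == 0L) return(NULL)
    sx <- .GROUP_SEXES[[g]]
    draw_pair <- function(r) {
      u1 <- rnorm(n)
      u2 <- r * u1 + sqrt(1 - r^2) * rnorm(n)
      cbind(u1, u2)
    }
    A <- draw_pair(rA[[g]])
    C <- draw_pair(rC[[g]])
    E <- cbind(rnorm(n), rnorm(n))
    age <- rnorm(n, cfg$age_mean, cfg$age_sd)
    L <- sapply(1:2, function(i) {
      k <- comp[[sx[i]]]
      sqrt(k["a"]) * A[, i] + sqrt(k["c"]) * C[, i] + sqrt(k["e"]) * E[, i]
    })
    list(group = g, sex = sx, L = matrix(L, ncol = 2), age = age)
  })
  blocks <- Filter(Negate(is.null), blocks)
  if (!length(blocks)) stop("all group sizes zero", call. = FALSE)

  all_age <- unlist(lapply(blocks, function(b) rep(b$age, 2)))
  age_m <- mean(all_age)
  # population SD, as standardize_covariate() computes, so the z-scores the
  # phenotypes are built from are reproduced exactly downstream
  age_s <- sqrt(mean((all_age - age_m)^2))
  mu <- c(M = cfg$mean_m, F = cfg$mean_f)
  sdv <- c(M = cfg$sd_m, F = cfg$sd_f)
  beta <- c(M = cfg$beta_age_m, F = cfg$beta_age_f)
  thr <- list(M = cfg$thresholds_m, F = cfg$thresholds_f)

  rows <- lapply(blocks, function(b) {
    n <- length(b$age)
    z <- (b$age - age_m) / age_s
    y <- sapply(1:2, function(i) {
      s <- b$sex[i]
      if (spec$scale == "continuous")
        mu[[s]] + beta[[s]] * z + sdv[[s]] * b$L[, i]
      else
        findInterval(b$L[, i] - beta[[s]] * z, thr[[s]])
    })
    y <- matrix(y, ncol = 2)
    data.frame(trait_id = spec$trait_id, group = b$group,
               y1 = y[, 1], y2 = y[, 2],
               sex1 = b$sex[1], sex2 = b$sex[2],
               covar1 = if (spec$covariate_kind == "none") NA_real_ else b$age,
               covar2 = if (spec$covariate_kind == "none") NA_real_ else b$age,
               stringsAsFactors = FALSE)
  })
  twin_dataset(do.call(rbind, rows), spec)
}

#' Simulate a multi-trait screen
#'
#' Generates one independent dataset per config, with per-trait seeds derived
#' deterministically from \code{master_seed} so the whole screen is
#' reproducible from a single integer.
#'
#' @param cfgs list of \code{\link{generative_config}}s.
#' @param specs list of \code{\link{trait_spec}}s (one, recycled, or one per
#'   config); trait ids must be unique.
#' @param master_seed integer.
#' @return list of \code{\link{twin_dataset}}s, named by trait id.
#' @export
simulate_screen <- function(cfgs, specs, master_seed = 1L) {
  if (inherits(cfgs, "generative_config")) cfgs <- list(cfgs)
  if (inherits(specs, "trait_spec")) specs <- list(specs)
  n <- length(cfgs)
  if (length(specs) == 1L && n > 1L) {
    base <- specs[[1L]]
    specs <- lapply(seq_len(n), function(i) {
      s <- base
      s$trait_id <- sprintf("%s_%03d", base$trait_id, i)
      s
    })
  }
  stopifnot(length(specs) == n)
  ids <- vapply(specs, `[[`, "", "trait_id")
  if (anyDuplicated(ids))
    stop("duplicate trait_id in screen configs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  set.seed(as.integer(master_seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  out <- lapply(seq_len(n), function(i) {
    cfg <- cfgs[[i]]
    cfg$seed <- seeds[i]
    simulate_pairs(cfg, specs[[i]])
  })
  names(out) <- ids
  out
}
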