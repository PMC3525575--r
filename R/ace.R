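#' Twin correlations implied by ACE sex-limitation parameters
#'
#' On the standardized scale the model implies
#' \eqn{r_{MZ} = a^2 + c^2}, \eqn{r_{DZss} = 0.5 a^2 + c^2} (additive-genetic
#' sharing weighted by 0.5 in same-sex DZ pairs) and, for opposite-sex pairs,
#' \eqn{r_{DOS} = \gamma \sqrt{a^2_m a^2_f} + \phi \sqrt{c^2_m c^2_f}}, which
#' reduces to \eqn{\gamma h^2 + \phi c^2} when components are equal across
#' sex. \eqn{\gamma < 0.5} signals a qualitative genetic sex difference
#' (partially different genes active in men and women); \eqn{\phi < 1}
#' signals that opposite-sex pairs share fewer environments.
#'
#' @param a2_m additive-genetic proportion in males, or a fitted ACE
#'   \code{twin_fit} from which all parameters are taken.
#' @param c2_m common-environment proportion in males.
#' @param a2_f,c2_f female components (default: equal to male).
#' @param gamma additive-genetic correlation in DOS pairs, \eqn{[0, 0.5]}.
#' @param phi shared-environment correlation in DOS pairs, \eqn{[0, 1]}.
#' @return named numeric vector of the five group correlations
#'   (\code{MZM, MZF, DZM, DZF, DOS}).
#' @examples
#' expected_correlations(0.4, 0.2)                # r_DZss = 0.4, r_DOS = 0.4
#' expected_correlations(0.4, 0, gamma = 0.36)    # gamma < 0.5 lowers r_DOS
#' @export
expected_correlations <- function(a2_m, c2_m, a2_f = a2_m, c2_f = c2_m,
                                  gamma = 0.5, phi = 1) {
  if (inherits(a2_m, "twin_fit")) {
    stopifnot(a2_m$family == "ace")
    p <- a2_m$params
    return(expected_correlations(p$a2[["M"]], p$c2[["M"]],
                                 p$a2[["F"]], p$c2[["F"]],
                                 p$gamma, p$phi))
  }
  stopifnot(a2_m >= 0, c2_m >= 0, a2_f >= 0, c2_f >= 0,
            a2_m + c2_m <= 1 + 1e-12, a2_f + c2_f <= 1 + 1e-12,
            gamma >= 0, gamma <= 0.5, phi >= 0, phi <= 1)
  c(MZM = a2_m + c2_m,
    MZF = a2_f + c2_f,
    DZM = 0.5 * a2_m + c2_m,
    DZF = 0.5 * a2_f + c2_f,
    DOS = gamma * sqrt(a2_m * a2_f) + phi * sqrt(c2_m * c2_f))
}

.ACE_MODELS <- c("full_gamma", "full_phi", "homogeneous", "no_c", "no_a",
                 "qualitative_constrained")

#' Fit an ACE sex-limitation model
#'
#' Maximum-likelihood decomposition of twin resemblance into additive-genetic
#' (A), common-environment (C) and unique-environment (E) variance with sex
#' limitation. Group covariances follow
#' \code{\link{expected_correlations}}. For continuous traits the total
#' variance is free per sex (components are standardized afterwards); for
#' ordinal traits the liability variance is fixed at 1 and components are
#' estimated directly on the standardized scale. Means/thresholds and
#' covariate slopes are re-estimated within every ACE fit.
#'
#' Models:
#' \describe{
#'   \item{\code{full_gamma}}{sex-specific A, C, E; \eqn{\gamma} free in
#'     \eqn{[0, 0.5]}, \eqn{\phi = 1}.}
#'   \item{\code{full_phi}}{sex-specific A, C, E; \eqn{\phi} free in
#'     \eqn{[0, 1]}, \eqn{\gamma = 0.5}.}
#'   \item{\code{homogeneous}}{components equated across sex; the parameter
#'     named by \code{qual} stays free.}
#'   \item{\code{no_c}, \code{no_a}}{homogeneous model without C
#'     (resp. A).}
#'   \item{\code{qualitative_constrained}}{sex-specific components with
#'     \eqn{\gamma = 0.5} and \eqn{\phi = 1}: the no-qualitative-difference
#'     null of the full models.}
#' }
#' Gamma and phi are confounded and never both free in one model; which one
#' is estimated is the \code{qual} choice (see
#' \code{\link{choose_qualitative_parameter}}).
#'
#' @param ds a \code{\link{twin_dataset}} with at least two pairs in each of
#'   the five zygosity groups.
#' @param model one of the labels above.
#' @param qual which qualitative parameter (\code{"gamma"} or \code{"phi"})
#'   remains free in \code{homogeneous}/\code{no_c}/\code{no_a} fits.
#' @param start optional less-constrained \code{twin_fit} used to warm-start.
#' @param se compute standard errors of the standardized components and of
#'   gamma/phi from the observed information (delta method).
#' @param control optimizer settings (see \code{\link{fit_saturated}}).
#' @return a \code{twin_fit} whose \code{params} hold standardized
#'   \code{a2}, \code{c2}, \code{e2} per sex, \code{gamma}, \code{phi},
#'   total \code{var} (continuous) or thresholds (ordinal), and the implied
#'   group correlations in \code{params$cor}.
#' @export
fit_ace <- function(ds, model = c("full_gamma", "full_phi", "homogeneous",
                                  "no_c", "no_a", "qualitative_constrained"),
                    qual = c("gamma", "phi"), start = NULL, se = FALSE,
                    control = list()) {
  stopifnot(inherits(ds, "twin_dataset"))
  model <- match.arg(model)
  qual <- match.arg(qual)
  ds <- standardize_covariate(ds)
  st <- .prep_data(ds)
  few <- .GROUPS[vapply(.GROUPS, function(g) (st$groups[[g]]$n %||% 0L) < 2L,
                        TRUE)]
  if (length(few))
    stop("ACE sex-limitation needs >= 2 pairs in every group; short: ",
         paste(few, collapse = ", "), call. = FALSE)
  scale <- ds$spec$scale

  sex_specific <- model %in% c("full_gamma", "full_phi",
                               "qualitative_constrained")
  has_a <- model != "no_a"
  has_c <- model != "no_c"
  free_qual <- switch(model,
    full_gamma = "gamma", full_phi = "phi",
    qualitative_constrained = "none",
    # reduced models: the chosen parameter stays free where it still exists
    if ((qual == "gamma" && has_a) || (qual == "phi" && has_c)) qual
    else "none")

  nat0 <- if (inherits(start, "twin_fit")) .fit_to_natural(start, ds$spec)
          else .moment_natural(ds, st)
  cs <- .ace_component_start(nat0, start)

  pb <- .par_builder()
  sexes <- c("M", "F")
  if (scale == "continuous") {
    for (s in sexes) pb$add(paste0("mu_", s), nat0$mean[[s]])
    if (st$has_cov) for (s in sexes) pb$add(paste0("beta_", s), nat0$beta[[s]])
    suff <- if (sex_specific) sexes else "P"  # P = pooled across sexes
    for (s in suff) {
      sdref <- if (s == "P") mean(nat0$sd[sexes]) else nat0$sd[[s]]
      k <- if (s == "F") "F" else "M"
      if (has_a) pb$add(paste0("pa_", s), sqrt(cs$a2[[k]]) * sdref, 0, Inf)
      if (has_c) pb$add(paste0("pc_", s), sqrt(cs$c2[[k]]) * sdref, 0, Inf)
      pb$add(paste0("pe_", s), sqrt(cs$e2[[k]]) * sdref, 1e-6, Inf)
    }
  } else {
    for (s in sexes) {
      ts <- .par_to_thr_start(nat0$thresholds[[s]])
      pb$add(paste0("thra_", s), ts$anchor, -8, 8)
      for (j in seq_along(ts$loginc))
        pb$add(paste0("thri_", s, "_", j), ts$loginc[j], -12, 4)
    }
    if (st$has_cov) for (s in sexes) pb$add(paste0("btr_", s),
                                            nat0$beta_thr[[s]])
    suff <- if (sex_specific) sexes else "P"
    for (s in suff) {
      if (has_a && has_c) {
        fam <- cs$a2[["M"]] + cs$c2[["M"]]
        pb$add(paste0("qf_", s), qlogis(min(max(fam, 0.02), 0.95)), -15, 15)
        pb$add(paste0("qa_", s),
               qlogis(min(max(cs$a2[["M"]] / fam, 0.05), 0.95)), -15, 15)
      } else {
        only <- if (has_a) cs$a2[["M"]] else cs$c2[["M"]]
        pb$add(paste0("qf_", s), qlogis(min(max(only, 0.02), 0.95)), -15, 15)
      }
    }
  }
  if (free_qual == "gamma") pb$add("gamma", cs$gamma, 0, 0.5)
  if (free_qual == "phi") pb$add("phi", cs$phi, 0, 1)

  unpack <- function(par) {
    out <- list()
    comp_of <- function(s) {
      if (scale == "continuous") {
        va <- if (has_a) unname(par[paste0("pa_", s)])^2 else 0
        vc <- if (has_c) unname(par[paste0("pc_", s)])^2 else 0
        ve <- unname(par[paste0("pe_", s)])^2
        tot <- va + vc + ve
        c(a2 = va / tot, c2 = vc / tot, e2 = ve / tot, var = tot)
      } else {
        if (has_a && has_c) {
          fam <- plogis(unname(par[paste0("qf_", s)]))
          ash <- plogis(unname(par[paste0("qa_", s)]))
          c(a2 = fam * ash, c2 = fam * (1 - ash), e2 = 1 - fam, var = 1)
        } else {
          only <- plogis(unname(par[paste0("qf_", s)]))
          c(a2 = if (has_a) only else 0, c2 = if (has_c) only else 0,
            e2 = 1 - only, var = 1)
        }
      }
    }
    cm <- comp_of(if (sex_specific) "M" else "P")
    cf <- if (sex_specific) comp_of("F") else cm
    out$a2 <- c(M = cm[["a2"]], F = cf[["a2"]])
    out$c2 <- c(M = cm[["c2"]], F = cf[["c2"]])
    out$e2 <- c(M = cm[["e2"]], F = cf[["e2"]])
    out$var <- c(M = cm[["var"]], F = cf[["var"]])
    out$gamma <- if (free_qual == "gamma")
      min(max(unname(par["gamma"]), 0), 0.5)
    else if (!has_a) NA_real_ else 0.5
    out$phi <- if (free_qual == "phi") min(max(unname(par["phi"]), 0), 1)
               else if (!has_c) NA_real_ else 1
    out$rg <- expected_correlations(out$a2[["M"]], out$c2[["M"]],
                                    out$a2[["F"]], out$c2[["F"]],
                                    if (is.na(out$gamma)) 0.5 else out$gamma,
                                    if (is.na(out$phi)) 1 else out$phi)
    if (scale == "continuous") {
      out$mu <- c(M = unname(par["mu_M"]), F = unname(par["mu_F"]))
      out$beta <- if (st$has_cov)
        c(M = unname(par["beta_M"]), F = unname(par["beta_F"]))
      else c(M = 0, F = 0)
      out$sdv <- sqrt(out$var)
    } else {
      out$thr <- lapply(setNames(sexes, sexes), function(s) {
        inc <- par[grep(paste0("^thri_", s, "_"), names(par))]
        .thr_from_par(unname(par[paste0("thra_", s)]), unname(inc))
      })
      out$btr <- if (st$has_cov)
        c(M = unname(par["btr_M"]), F = unname(par["btr_F"]))
      else c(M = 0, F = 0)
    }
    out
  }

  nll <- if (scale == "continuous") {
    function(par) {
      q <- unpack(par)
      .cont_nll(st, q$mu, q$beta, q$sdv, q$rg)
    }
  } else {
    function(par) {
      q <- unpack(par)
      .ord_nll(st, q$thr, q$btr, q$rg)
    }
  }

  gr <- if (scale == "continuous") {
    # analytic gradient in the natural parameters, chained through a numeric
    # jacobian of the (cheap, data-free) parameter map
    natvec <- function(par) {
      q <- unpack(par)
      c(q$mu, q$beta, q$sdv, q$rg)
    }
    function(par) {
      q <- unpack(par)
      g <- .cont_nll_grad(st, q$mu, q$beta, q$sdv, q$rg)
      gn <- c(g$mu, g$beta, g$sd, g$r)
      J <- pracma::jacobian(natvec, par)
      as.vector(gn %*% J)
    }
  } else NULL

  res <- .ml_optim(pb$env$start, nll, pb$env$lower, pb$env$upper, control,
                   gr = gr)
  q <- unpack(res$par)

  boundary <- character(0)
  for (s in c("M", "F")) {
    if (has_a && q$a2[[s]] < 1e-6) boundary <- c(boundary, paste0("a2_", s))
    if (has_c && q$c2[[s]] < 1e-6) boundary <- c(boundary, paste0("c2_", s))
  }
  if (free_qual == "gamma" && (q$gamma < 1e-4 || q$gamma > 0.5 - 1e-4))
    boundary <- c(boundary, "gamma")
  if (free_qual == "phi" && (q$phi < 1e-4 || q$phi > 1 - 1e-4))
    boundary <- c(boundary, "phi")
  boundary <- unique(boundary)

  params <- list(a2 = q$a2, c2 = q$c2, e2 = q$e2,
                 gamma = q$gamma, phi = q$phi, cor = q$rg)
  if (scale == "continuous") {
    params$mean <- q$mu; params$var <- q$var; params$beta <- q$beta
  } else {
    params$thresholds <- q$thr; params$beta_thr <- q$btr
  }

  fit <- .new_fit(family = "ace", label = paste0("ace[", model, "]"),
                  constraint_set = model, params = params,
                  minus2LL = res$value,
                  n_free_params = length(pb$env$start),
                  st = st, res = res, boundary = boundary, spec = ds$spec,
                  internal = list(par = res$par, unpack = unpack, nll = nll,
                                  lower = pb$env$lower, upper = pb$env$upper),
                  extra = list(model = model, qual = free_qual))
  if (se) fit$se <- .ace_se(fit)
  fit
}

.ace_component_start <- function(nat0, start) {
  if (inherits(start, "twin_fit") && start$family == "ace") {
    p <- start$params
    return(list(a2 = pmax(p$a2, 0.02), c2 = pmax(p$c2, 0.02),
                e2 = pmax(p$e2, 0.05),
                gamma = if (is.na(p$gamma)) 0.4 else min(max(p$gamma, 0.05),
                                                         0.45),
                phi = if (is.na(p$phi)) 0.9 else min(max(p$phi, 0.1), 0.95)))
  }
  r_mz <- mean(nat0$cor[c("MZM", "MZF")], na.rm = TRUE)
  r_dz <- mean(nat0$cor[c("DZM", "DZF", "DOS")], na.rm = TRUE)
  if (!is.finite(r_mz)) r_mz <- 0.5
  if (!is.finite(r_dz)) r_dz <- 0.25
  a2 <- min(max(2 * (r_mz - r_dz), 0.05), 0.85)
  c2 <- min(max(r_mz - a2, 0.02), 0.9 - a2)
  e2 <- max(1 - a2 - c2, 0.05)
  list(a2 = c(M = a2, F = a2), c2 = c(M = c2, F = c2), e2 = c(M = e2, F = e2),
       gamma = 0.4, phi = 0.9)
}

# delta-method SEs for (a2, c2, e2 per sex, gamma, phi) from the observed
# information of the -2LL surface
.ace_se <- function(fit) {
  tryCatch({
    H <- optimHess(fit$internal$par, fit$internal$nll)
    V <- 2 * solve(H)  # -2LL curvature -> 2 * inverse
    natmap <- function(par) {
      q <- fit$internal$unpack(par)
      c(a2_M = q$a2[["M"]], c2_M = q$c2[["M"]], e2_M = q$e2[["M"]],
        a2_F = q$a2[["F"]], c2_F = q$c2[["F"]], e2_F = q$e2[["F"]],
        gamma = if (is.na(q$gamma)) 0 else q$gamma,
        phi = if (is.na(q$phi)) 0 else q$phi)
    }
    J <- pracma::jacobian(natmap, fit$internal$par)
    Vn <- J %*% V %*% t(J)
    se <- sqrt(pmax(diag(Vn), 0))
    names(se) <- names(natmap(fit$internal$par))
    se
  }, error = function(e) NULL)
}

#' Pick the free qualitative parameter from a full ACE fit
#'
#' Decides which opposite-sex correlation parameter should be freed when a
#' trait shows a DOS deficit: the shared-environment correlation \code{phi}
#' when the pooled common-environment component exceeds the pooled
#' additive-genetic component, and the genetic correlation \code{gamma}
#' otherwise (ties go to \code{gamma}). The comparison pools components as
#' the unweighted mean of the two sexes; both estimates are reported in a
#' message so the decision is auditable.
#'
#' @param full_fit an ACE \code{twin_fit} with both A and C present.
#' @return \code{"gamma"} or \code{"phi"}.
#' @export
choose_qualitative_parameter <- function(full_fit) {
  stopifnot(inherits(full_fit, "twin_fit"), full_fit$family == "ace")
  if (full_fit$model %in% c("no_a", "no_c"))
    stop("full fit must include both A and C", call. = FALSE)
  a2p <- mean(full_fit$params$a2)
  c2p <- mean(full_fit$params$c2)
  pick <- if (c2p > a2p) "phi" else "gamma"
  message(sprintf("pooled a2 = %.3f, pooled c2 = %.3f -> freeing %s",
                  a2p, c2p, pick))
  pick
}
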