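.SAT_CONSTRAINTS <- c("none", "equal_variances", "rdz_equal", "rdz_all_equal")

.norm_constraints <- function(constraints, scale) {
  bad <- setdiff(constraints, .SAT_CONSTRAINTS)
  if (length(bad))
    stop("unknown constraint set(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cons <- setdiff(constraints, "none")
  if ("rdz_all_equal" %in% cons) cons <- union(cons, "rdz_equal")
  if ("equal_variances" %in% cons && scale == "ordinal")
    stop("equal_variances applies to continuous traits only", call. = FALSE)
  sort(cons)
}

# moment estimators used as starting values (sample means/SDs, Pearson
# correlations, inverse-normal marginal prevalences for thresholds)
.moment_natural <- function(ds, st) {
  p <- ds$pairs
  has_cov <- st$has_cov
  ind <- data.frame(
    y = c(p$y1, p$y2),
    z = if (has_cov) c(p$covar1, p$covar2) else rep(0, 2L * nrow(p)),
    sex = c(p$sex1, p$sex2), stringsAsFactors = FALSE)
  ind <- ind[!is.na(ind$y), , drop = FALSE]
  nat <- list(mean = c(M = NA_real_, F = NA_real_),
              sd = c(M = NA_real_, F = NA_real_),
              beta = c(M = 0, F = 0),
              thresholds = list(M = NULL, F = NULL),
              beta_thr = c(M = 0, F = 0),
              cor = setNames(rep(NA_real_, 5L), .GROUPS))
  for (s in c("M", "F")) {
    yi <- ind$y[ind$sex == s]
    zi <- ind$z[ind$sex == s]
    if (!length(yi)) next
    if (ds$spec$scale == "continuous") {
      nat$mean[[s]] <- mean(yi)
      nat$sd[[s]] <- max(sd(yi), 1e-3)
      if (is.na(nat$sd[[s]])) nat$sd[[s]] <- 1
      if (has_cov && var(zi) > 0)
        nat$beta[[s]] <- cov(yi, zi) / var(zi)
    } else {
      K <- st$K
      cum <- cumsum(tabulate(yi + 1L, nbins = K) / length(yi))[-K]
      thr <- qnorm(pmin(pmax(cum, 1e-3), 1 - 1e-3))
      # enforce strict increase for degenerate margins
      for (j in seq_along(thr)[-1])
        if (thr[j] <= thr[j - 1]) thr[j] <- thr[j - 1] + 0.02
      nat$thresholds[[s]] <- thr
    }
  }
  for (g in names(st$groups)) {
    i <- p$group == g & !is.na(p$y1) & !is.na(p$y2)
    if (sum(i) >= 3L && sd(p$y1[i]) > 0 && sd(p$y2[i]) > 0) {
      r <- cor(p$y1[i], p$y2[i])
      nat$cor[[g]] <- min(max(r, -0.9), 0.9)
    } else nat$cor[[g]] <- 0
  }
  nat
}

# small helper assembling a named parameter vector with box bounds
.par_builder <- function() {
  e <- new.env(parent = emptyenv())
  e$start <- numeric(0); e$lower <- numeric(0); e$upper <- numeric(0)
  add <- function(name, start, lo = -Inf, hi = Inf) {
    e$start[name] <- start
    e$lower[name] <- lo
    e$upper[name] <- hi
  }
  list(add = add, env = e)
}

.ZR_MAX <- 7  # atanh scale; tanh(7) = 0.9999983

#' Fit the saturated twin model
#'
#' Maximum-likelihood fit of the baseline model: sex-specific means,
#' variances and covariate slopes (continuous traits) or sex-specific
#' thresholds with covariate slopes on the threshold location (ordinal
#' traits; liability fixed at N(0,1)), plus one correlation per zygosity
#' group. Pairs with a missing co-twin enter through their marginal
#' likelihood. Correlations are optimized on the arctanh scale; thresholds
#' via an anchor plus log-increments, keeping every iterate admissible.
#'
#' Constraint sets reproduce the model ladder used when screening for sex
#' differences: \code{"equal_variances"} (model 1a, continuous only) equates
#' male and female variances, \code{"rdz_equal"} (model 2) sets
#' \eqn{r_{DZM} = r_{DZF}}, and \code{"rdz_all_equal"} (model 3) sets
#' \eqn{r_{DZM} = r_{DZF} = r_{DOS}}. Constraints may be combined, e.g.
#' \code{c("equal_variances", "rdz_all_equal")}.
#'
#' @param ds a \code{\link{twin_dataset}}.
#' @param constraints character vector of constraint labels (see Details);
#'   \code{"none"} fits the unconstrained model.
#' @param start optional \code{twin_fit} of a less constrained model used to
#'   warm-start the optimizer.
#' @param control optimizer settings passed to the internal L-BFGS-B driver
#'   (\code{maxit}, \code{factr}, \code{restarts}).
#' @return object of class \code{twin_fit} with elements \code{params}
#'   (means/variances or thresholds, slopes and the five group correlations),
#'   \code{minus2LL}, \code{n_free_params}, \code{n_pairs_used},
#'   \code{converged}, \code{boundary} and \code{constraint_set}.
#' @examples
#' cfg <- generative_config(n_pairs_per_group = c(MZM = 200, MZF = 200,
#'   DZM = 200, DZF = 200, DOS = 200), seed = 7)
#' ds <- simulate_pairs(cfg, trait_spec("ex", "continuous",
#'   covariate_kind = "none"))
#' fit_saturated(ds)
#' @export
fit_saturated <- function(ds, constraints = "none", start = NULL,
                          control = list()) {
  stopifnot(inherits(ds, "twin_dataset"))
  cons <- .norm_constraints(constraints, ds$spec$scale)
  ds <- standardize_covariate(ds)
  st <- .prep_data(ds)
  if (st$n_pairs + st$n_singles == 0L) stop("empty dataset", call. = FALSE)
  one_pair <- names(st$groups)[vapply(st$groups, function(g) g$n, 0) < 2L]
  if (length(one_pair))
    stop("under-identified: group(s) with a free correlation but < 2 pairs: ",
         paste(one_pair, collapse = ", "), call. = FALSE)

  nat0 <- if (inherits(start, "twin_fit")) .fit_to_natural(start, ds$spec)
          else .moment_natural(ds, st)
  sexes <- sort(unique(c(unlist(.GROUP_SEXES[names(st$groups)]),
                         names(st$singles))), decreasing = TRUE)  # M before F

  blk <- setNames(paste0("zr_", .GROUPS), .GROUPS)
  if ("rdz_all_equal" %in% cons) {
    blk[c("DZM", "DZF", "DOS")] <- "zr_DZ"
  } else if ("rdz_equal" %in% cons) {
    blk[c("DZM", "DZF")] <- "zr_DZ"
  }

  pb <- .par_builder()
  scale <- ds$spec$scale
  if (scale == "continuous") {
    for (s in sexes) pb$add(paste0("mu_", s), nat0$mean[[s]])
    if ("equal_variances" %in% cons) {
      pb$add("lsd", log(mean(nat0$sd[sexes])), -12, 12)
    } else {
      for (s in sexes) pb$add(paste0("lsd_", s), log(nat0$sd[[s]]), -12, 12)
    }
    if (st$has_cov)
      for (s in sexes) pb$add(paste0("beta_", s), nat0$beta[[s]])
  } else {
    for (s in sexes) {
      ts <- .par_to_thr_start(nat0$thresholds[[s]])
      pb$add(paste0("thra_", s), ts$anchor, -8, 8)
      for (j in seq_along(ts$loginc))
        pb$add(paste0("thri_", s, "_", j), ts$loginc[j], -12, 4)
    }
    if (st$has_cov)
      for (s in sexes) pb$add(paste0("btr_", s), nat0$beta_thr[[s]])
  }
  for (b in unique(blk[names(st$groups)])) {
    covered <- names(st$groups)[blk[names(st$groups)] == b]
    r0 <- mean(nat0$cor[covered], na.rm = TRUE)
    if (!is.finite(r0)) r0 <- 0
    pb$add(b, atanh(min(max(r0, -0.99), 0.99)), -.ZR_MAX, .ZR_MAX)
  }

  unpack <- function(par) {
    out <- list()
    if (scale == "continuous") {
      out$mu <- c(M = unname(par["mu_M"]), F = unname(par["mu_F"]))
      if ("equal_variances" %in% cons) {
        out$sdv <- c(M = exp(unname(par["lsd"])), F = exp(unname(par["lsd"])))
      } else {
        out$sdv <- c(M = exp(unname(par["lsd_M"])),
                     F = exp(unname(par["lsd_F"])))
      }
      out$beta <- if (st$has_cov)
        c(M = unname(par["beta_M"]), F = unname(par["beta_F"]))
      else c(M = 0, F = 0)
      out$beta[is.na(out$beta)] <- 0
    } else {
      out$thr <- lapply(setNames(c("M", "F"), c("M", "F")), function(s) {
        a <- par[paste0("thra_", s)]
        if (is.na(a)) return(NULL)
        inc <- par[grep(paste0("^thri_", s, "_"), names(par))]
        unname(.thr_from_par(unname(a), unname(inc)))
      })
      out$btr <- if (st$has_cov)
        c(M = unname(par["btr_M"]), F = unname(par["btr_F"]))
      else c(M = 0, F = 0)
      out$btr[is.na(out$btr)] <- 0
    }
    rg <- setNames(rep(NA_real_, 5L), .GROUPS)
    for (g in names(st$groups)) rg[[g]] <- tanh(unname(par[blk[[g]]]))
    out$rg <- rg
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
    function(par) {
      q <- unpack(par)
      g <- .cont_nll_grad(st, q$mu, q$beta, q$sdv, q$rg)
      out <- setNames(numeric(length(par)), names(par))
      for (s in sexes) {
        out[paste0("mu_", s)] <- g$mu[[s]]
        if (st$has_cov) out[paste0("beta_", s)] <- g$beta[[s]]
      }
      if ("equal_variances" %in% cons) {
        out["lsd"] <- sum(g$sd[sexes] * q$sdv[sexes])
      } else {
        for (s in sexes) out[paste0("lsd_", s)] <- g$sd[[s]] * q$sdv[[s]]
      }
      for (b in unique(blk[names(st$groups)])) {
        covered <- names(st$groups)[blk[names(st$groups)] == b]
        out[b] <- sum(g$r[covered] * (1 - q$rg[covered]^2))
      }
      out
    }
  } else NULL

  res <- .ml_optim(pb$env$start, nll, pb$env$lower, pb$env$upper, control,
                   gr = gr)
  q <- unpack(res$par)

  params <- if (scale == "continuous") {
    list(mean = q$mu, var = q$sdv^2, beta = q$beta, cor = q$rg)
  } else {
    list(thresholds = q$thr, beta_thr = q$btr, cor = q$rg)
  }
  boundary <- names(q$rg)[!is.na(q$rg) & abs(q$rg) > 0.999]
  if (length(boundary)) boundary <- paste0("r_", boundary)

  .new_fit(family = "saturated",
           label = paste0("saturated[",
                          if (length(cons)) paste(cons, collapse = "+")
                          else "none", "]"),
           constraint_set = if (length(cons)) cons else "none",
           params = params, minus2LL = res$value,
           n_free_params = length(pb$env$start),
           st = st, res = res, boundary = boundary,
           spec = ds$spec,
           internal = list(par = res$par, unpack = unpack, nll = nll,
                           lower = pb$env$lower, upper = pb$env$upper))
}

# translate a parent fit's estimates into moment-style start values
.fit_to_natural <- function(fit, spec) {
  p <- fit$params
  if (fit$family == "ace") {
    rg <- expected_correlations(fit)
    if (spec$scale == "continuous")
      return(list(mean = p$mean, sd = sqrt(p$var), beta = p$beta,
                  thresholds = list(M = NULL, F = NULL),
                  beta_thr = c(M = 0, F = 0), cor = rg))
    return(list(mean = c(M = NA, F = NA), sd = c(M = NA, F = NA),
                beta = c(M = 0, F = 0), thresholds = p$thresholds,
                beta_thr = p$beta_thr, cor = rg))
  }
  if (spec$scale == "continuous")
    list(mean = p$mean, sd = sqrt(p$var), beta = p$beta,
         thresholds = list(M = NULL, F = NULL), beta_thr = c(M = 0, F = 0),
         cor = p$cor)
  else
    list(mean = c(M = NA, F = NA), sd = c(M = NA, F = NA),
         beta = c(M = 0, F = 0), thresholds = p$thresholds,
         beta_thr = p$beta_thr, cor = p$cor)
}

.new_fit <- function(family, label, constraint_set, params, minus2LL,
                     n_free_params, st, res, boundary, spec, internal,
                     extra = list()) {
  out <- c(list(
    family = family, label = label, constraint_set = constraint_set,
    params = params, minus2LL = minus2LL, n_free_params = n_free_params,
    n_pairs_used = st$n_pairs, n_singles = st$n_singles,
    group_n = st$group_n,
    converged = res$convergence == 0L,
    boundary = boundary,
    diagnostics = list(optim_convergence = res$convergence,
                       message = res$message %||% "",
                       restarts = res$restarts %||% 0L,
                       counts = res$counts),
    spec = spec, internal = internal), extra)
  class(out) <- "twin_fit"
  out
}

#' @export
print.twin_fit <- function(x, ...) {
  cat("<twin_fit> ", x$label, "  trait ", x$spec$trait_id, "\n", sep = "")
  cat("  -2 log L = ", formatC(x$minus2LL, format = "f", digits = 3),
      "  (", x$n_free_params, " free parameters, ", x$n_pairs_used,
      " pairs", if (x$n_singles) paste0(" + ", x$n_singles, " singles"),
      ")\n", sep = "")
  if (!x$converged) cat("  ** optimizer did not converge **\n")
  if (length(x$boundary))
    cat("  boundary solution: ", paste(x$boundary, collapse = ", "), "\n",
        sep = "")
  cat("  correlations:\n")
  print(round(x$params$cor %||% expected_correlations(x), 4))
  if (x$family == "ace") {
    cat("  standardized components:\n")
    m <- rbind(M = c(a2 = x$params$a2[["M"]], c2 = x$params$c2[["M"]],
                     e2 = x$params$e2[["M"]]),
               F = c(a2 = x$params$a2[["F"]], c2 = x$params$c2[["F"]],
                     e2 = x$params$e2[["F"]]))
    print(round(m, 4))
    cat("  gamma = ", round(x$params$gamma, 4),
        ", phi = ", round(x$params$phi, 4), "\n", sep = "")
  }
  invisible(x)
}
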