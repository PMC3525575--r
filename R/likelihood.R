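# Likelihood internals shared by fit_saturated() and fit_ace().
#
# Continuous traits: the bivariate-normal log-likelihood depends on the data
# only through per-group cross-products of (1, z1, y1, z2, y2), so those are
# computed once per fit and every objective evaluation is O(#groups). This is
# an exact algebraic identity, not an approximation. Ordinal traits without a
# covariate aggregate to K x K contingency tables per group; with a covariate
# every pair keeps its own shifted thresholds.

.prep_data <- function(ds) {
  ds <- standardize_covariate(ds)
  p <- ds$pairs
  has_cov <- ds$spec$covariate_kind != "none"
  z1 <- if (has_cov) p$covar1 else rep(0, nrow(p))
  z2 <- if (has_cov) p$covar2 else rep(0, nrow(p))
  complete <- !is.na(p$y1) & !is.na(p$y2)
  K <- ds$spec$n_categories

  groups <- list()
  for (g in .GROUPS) {
    i <- complete & p$group == g
    n <- sum(i)
    if (n == 0L) next
    if (ds$spec$scale == "continuous") {
      X <- cbind(1, z1[i], p$y1[i], z2[i], p$y2[i])
      groups[[g]] <- list(n = n, S = crossprod(X))
    } else if (!has_cov) {
      tab <- table(factor(p$y1[i], levels = 0:(K - 1)),
                   factor(p$y2[i], levels = 0:(K - 1)))
      groups[[g]] <- list(n = n, tab = unclass(tab))
    } else {
      groups[[g]] <- list(n = n, y1 = p$y1[i], y2 = p$y2[i],
                          z1 = z1[i], z2 = z2[i])
    }
  }

  # single-twin (missing co-twin) marginal contributions, pooled by sex
  singles <- list()
  only1 <- !is.na(p$y1) & is.na(p$y2)
  only2 <- is.na(p$y1) & !is.na(p$y2)
  sy <- c(p$y1[only1], p$y2[only2])
  sz <- c(z1[only1], z2[only2])
  ss <- c(p$sex1[only1], p$sex2[only2])
  for (s in c("M", "F")) {
    i <- ss == s
    n <- sum(i)
    if (n == 0L) next
    if (ds$spec$scale == "continuous") {
      X <- cbind(1, sz[i], sy[i])
      singles[[s]] <- list(n = n, S = crossprod(X))
    } else if (!has_cov) {
      singles[[s]] <- list(n = n,
                           counts = tabulate(sy[i] + 1L, nbins = K))
    } else {
      singles[[s]] <- list(n = n, y = sy[i], z = sz[i])
    }
  }

  list(scale = ds$spec$scale, K = K, has_cov = has_cov,
       groups = groups, singles = singles,
       n_pairs = sum(complete), n_singles = sum(only1) + sum(only2),
       group_n = vapply(.GROUPS, function(g) groups[[g]]$n %||% 0L,
                        numeric(1)))
}

# natural continuous parameters: mu, beta, sdv named c(M=, F=); rg named by group
.cont_nll <- function(st, mu, beta, sdv, rg) {
  nll <- 0
  for (g in names(st$groups)) {
    gg <- st$groups[[g]]
    sx <- .GROUP_SEXES[[g]]
    v1 <- c(-mu[[sx[1]]], -beta[[sx[1]]], 1, 0, 0)
    v2 <- c(-mu[[sx[2]]], 0, 0, -beta[[sx[2]]], 1)
    Q11 <- drop(v1 %*% gg$S %*% v1)
    Q22 <- drop(v2 %*% gg$S %*% v2)
    Q12 <- drop(v1 %*% gg$S %*% v2)
    r <- rg[[g]]
    s1 <- sdv[[sx[1]]]; s2 <- sdv[[sx[2]]]
    om <- 1 - r * r
    nll <- nll + gg$n * (log(2 * pi) + log(s1) + log(s2) + 0.5 * log(om)) +
      (Q11 / s1^2 - 2 * r * Q12 / (s1 * s2) + Q22 / s2^2) / (2 * om)
  }
  for (s in names(st$singles)) {
    sg <- st$singles[[s]]
    v <- c(-mu[[s]], -beta[[s]], 1)
    Q <- drop(v %*% sg$S %*% v)
    nll <- nll + sg$n * (0.5 * log(2 * pi) + log(sdv[[s]])) +
      Q / (2 * sdv[[s]]^2)
  }
  2 * nll  # -2 log L
}

# analytic gradient of .cont_nll with respect to the natural parameters
# (means, slopes, SDs per sex; correlation per group), exact given the same
# sufficient statistics
.cont_nll_grad <- function(st, mu, beta, sdv, rg) {
  d_mu <- c(M = 0, F = 0); d_beta <- c(M = 0, F = 0); d_sd <- c(M = 0, F = 0)
  d_r <- setNames(rep(0, 5L), .GROUPS)
  for (g in names(st$groups)) {
    gg <- st$groups[[g]]
    sx <- .GROUP_SEXES[[g]]
    v1 <- c(-mu[[sx[1]]], -beta[[sx[1]]], 1, 0, 0)
    v2 <- c(-mu[[sx[2]]], 0, 0, -beta[[sx[2]]], 1)
    Sv1 <- gg$S %*% v1
    Sv2 <- gg$S %*% v2
    Q11 <- drop(crossprod(v1, Sv1)); Q22 <- drop(crossprod(v2, Sv2))
    Q12 <- drop(crossprod(v1, Sv2))
    r <- rg[[g]]; s1 <- sdv[[sx[1]]]; s2 <- sdv[[sx[2]]]
    om <- 1 - r * r
    den <- 2 * om
    d_mu[sx[1]] <- d_mu[sx[1]] +
      (-2 * Sv1[1] / s1^2 + 2 * r * Sv2[1] / (s1 * s2)) / den
    d_mu[sx[2]] <- d_mu[sx[2]] +
      (-2 * Sv2[1] / s2^2 + 2 * r * Sv1[1] / (s1 * s2)) / den
    d_beta[sx[1]] <- d_beta[sx[1]] +
      (-2 * Sv1[2] / s1^2 + 2 * r * Sv2[2] / (s1 * s2)) / den
    d_beta[sx[2]] <- d_beta[sx[2]] +
      (-2 * Sv2[4] / s2^2 + 2 * r * Sv1[4] / (s1 * s2)) / den
    d_sd[sx[1]] <- d_sd[sx[1]] + gg$n / s1 +
      (-2 * Q11 / s1^3 + 2 * r * Q12 / (s1^2 * s2)) / den
    d_sd[sx[2]] <- d_sd[sx[2]] + gg$n / s2 +
      (-2 * Q22 / s2^3 + 2 * r * Q12 / (s1 * s2^2)) / den
    C <- Q11 / s1^2 - 2 * r * Q12 / (s1 * s2) + Q22 / s2^2
    d_r[g] <- -gg$n * r / om - Q12 / (s1 * s2 * om) + C * r / om^2
  }
  for (s in names(st$singles)) {
    sg <- st$singles[[s]]
    v <- c(-mu[[s]], -beta[[s]], 1)
    Sv <- sg$S %*% v
    Q <- drop(crossprod(v, Sv))
    sdev <- sdv[[s]]
    d_mu[s] <- d_mu[s] - Sv[1] / sdev^2
    d_beta[s] <- d_beta[s] - Sv[2] / sdev^2
    d_sd[s] <- d_sd[s] + sg$n / sdev - Q / sdev^3
  }
  # objective is -2 log L
  list(mu = 2 * d_mu, beta = 2 * d_beta, sd = 2 * d_sd, r = 2 * d_r)
}

# ordinal: thr = list(M =, F =) interior thresholds; btr named slopes on the
# threshold location; liability ~ N(0, 1)
.ord_nll <- function(st, thr, btr, rg) {
  K <- st$K
  ext <- lapply(thr, function(t) c(-Inf, t, Inf))
  nll <- 0
  for (g in names(st$groups)) {
    gg <- st$groups[[g]]
    sx <- .GROUP_SEXES[[g]]
    r <- rg[[g]]
    if (!st$has_cov) {
      t1 <- ext[[sx[1]]]; t2 <- ext[[sx[2]]]
      corner <- matrix(pbvnorm(rep(t1, times = K + 1),
                               rep(t2, each = K + 1), r),
                       nrow = K + 1)
      P <- corner[-1, -1, drop = FALSE] + corner[-(K + 1), -(K + 1), drop = FALSE] -
        corner[-1, -(K + 1), drop = FALSE] - corner[-(K + 1), -1, drop = FALSE]
      P <- pmax(P, 1e-300)
      nll <- nll - sum(gg$tab * log(P))
    } else {
      l1 <- ext[[sx[1]]][gg$y1 + 1L] + btr[[sx[1]]] * gg$z1
      u1 <- ext[[sx[1]]][gg$y1 + 2L] + btr[[sx[1]]] * gg$z1
      l2 <- ext[[sx[2]]][gg$y2 + 1L] + btr[[sx[2]]] * gg$z2
      u2 <- ext[[sx[2]]][gg$y2 + 2L] + btr[[sx[2]]] * gg$z2
      pr <- pbvnorm(u1, u2, r) - pbvnorm(l1, u2, r) -
        pbvnorm(u1, l2, r) + pbvnorm(l1, l2, r)
      nll <- nll - sum(log(pmax(pr, 1e-300)))
    }
  }
  for (s in names(st$singles)) {
    sg <- st$singles[[s]]
    te <- ext[[s]]
    if (!st$has_cov) {
      pr <- pmax(diff(pnorm(te)), 1e-300)
      nll <- nll - sum(sg$counts * log(pr))
    } else {
      pr <- pnorm(te[sg$y + 2L] + btr[[s]] * sg$z) -
        pnorm(te[sg$y + 1L] + btr[[s]] * sg$z)
      nll <- nll - sum(log(pmax(pr, 1e-300)))
    }
  }
  2 * nll
}

# thresholds parameterized as anchor + cumulated log-increments so they stay
# strictly increasing on the optimizer's unconstrained scale
.thr_from_par <- function(anchor, loginc) {
  if (length(loginc)) anchor + c(0, cumsum(exp(loginc))) else anchor
}

.par_to_thr_start <- function(thr) {
  if (length(thr) == 1L) list(anchor = thr, loginc = numeric(0))
  else list(anchor = thr[1], loginc = log(pmax(diff(thr), 0.02)))
}

# generic bounded quasi-Newton driver; jittered (deterministic, so fits never
# touch the RNG stream) restarts on non-convergence
.ml_optim <- function(par, fn, lower, upper, control = list(), gr = NULL) {
  ctl <- modifyList(list(maxit = 1000L, factr = 1e3, restarts = 3L), control)
  safe_fn <- function(p) {
    v <- fn(p)
    if (!is.finite(v)) 1e12 else v
  }
  run <- function(p0) {
    tryCatch(
      optim(p0, safe_fn, gr = gr, method = "L-BFGS-B", lower = lower,
            upper = upper,
            control = list(maxit = ctl$maxit, factr = ctl$factr)),
      error = function(e) list(par = p0, value = Inf, convergence = 99L,
                               message = conditionMessage(e)))
  }
  best <- run(par)
  restarts <- 0L
  while (best$convergence != 0L && restarts < ctl$restarts) {
    restarts <- restarts + 1L
    jit <- par + 0.25 * sin(seq_along(par) * (restarts + 0.7) * 2.3)
    jit <- pmin(pmax(jit, lower + 1e-8), upper - 1e-8)
    cand <- run(jit)
    if (cand$convergence == 0L && cand$value <= best$value + 1e-6) {
      best <- cand
    } else if (cand$value < best$value) {
      best <- cand
    }
  }
  best$restarts <- restarts
  best
}
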