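#' Polychoric / tetrachoric correlation of a contingency table
#'
#' Full maximum-likelihood estimate of the latent bivariate-normal
#' correlation for a K x K table of ordinal counts: thresholds for the row
#' and column margins and the correlation are estimated jointly, with no
#' covariates. Serves as an independent cross-check for
#' \code{\link{fit_saturated}} on ordinal data when covariate effects are
#' zero (the pair likelihood then depends on the data only through this
#' table).
#'
#' @param tab square matrix of non-negative counts; rows index twin 1's
#'   category, columns twin 2's.
#' @param symmetric if \code{TRUE}, row and column thresholds are constrained
#'   equal, matching a same-sex twin group where both members share the
#'   sex-specific thresholds.
#' @param control optimizer settings (see \code{\link{fit_saturated}}).
#' @return object of class \code{polychoric_fit}: list with \code{rho},
#'   \code{thresholds_row}, \code{thresholds_col}, \code{minus2LL},
#'   \code{converged} and \code{boundary} (TRUE when \code{rho} is pinned at
#'   \eqn{\pm 1} numerically).
#' @examples
#' polychoric_corr(matrix(c(25, 25, 25, 25), 2))$rho  # 0
#' @export
polychoric_corr <- function(tab, symmetric = FALSE, control = list()) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == ncol(tab), all(tab >= 0), nrow(tab) >= 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: empty row or column margin", call. = FALSE)
  K <- nrow(tab)
  n <- sum(tab)

  thr_start <- function(marg) {
    cum <- cumsum(marg / sum(marg))[-K]
    thr <- qnorm(pmin(pmax(cum, 1e-4), 1 - 1e-4))
    for (j in seq_along(thr)[-1])
      if (thr[j] <= thr[j - 1]) thr[j] <- thr[j - 1] + 0.02
    thr
  }
  # crude score correlation for a start
  idx <- which(tab > 0, arr.ind = TRUE)
  w <- tab[tab > 0]
  mr <- sum(idx[, 1] * w) / n; mc <- sum(idx[, 2] * w) / n
  vr <- sum((idx[, 1] - mr)^2 * w); vc <- sum((idx[, 2] - mc)^2 * w)
  r0 <- if (vr > 0 && vc > 0)
    sum((idx[, 1] - mr) * (idx[, 2] - mc) * w) / sqrt(vr * vc) else 0
  r0 <- min(max(r0, -0.95), 0.95)

  pb <- .par_builder()
  tr <- .par_to_thr_start(thr_start(rowSums(tab)))
  pb$add("ra", tr$anchor, -8, 8)
  for (j in seq_along(tr$loginc)) pb$add(paste0("ri_", j), tr$loginc[j], -12, 4)
  if (!symmetric) {
    tc <- .par_to_thr_start(thr_start(colSums(tab)))
    pb$add("ca", tc$anchor, -8, 8)
    for (j in seq_along(tc$loginc)) pb$add(paste0("ci_", j), tc$loginc[j], -12, 4)
  }
  pb$add("zr", atanh(r0), -.ZR_MAX, .ZR_MAX)

  unpack <- function(par) {
    tr <- .thr_from_par(unname(par["ra"]),
                        unname(par[grep("^ri_", names(par))]))
    tc <- if (symmetric) tr else
      .thr_from_par(unname(par["ca"]), unname(par[grep("^ci_", names(par))]))
    list(tr = tr, tc = tc, rho = tanh(unname(par["zr"])))
  }
  nll <- function(par) {
    q <- unpack(par)
    t1 <- c(-Inf, q$tr, Inf); t2 <- c(-Inf, q$tc, Inf)
    corner <- matrix(pbvnorm(rep(t1, times = K + 1), rep(t2, each = K + 1),
                             q$rho), nrow = K + 1)
    P <- corner[-1, -1] + corner[-(K + 1), -(K + 1)] -
      corner[-1, -(K + 1)] - corner[-(K + 1), -1]
    -2 * sum(tab * log(pmax(P, 1e-300)))
  }
  res <- .ml_optim(pb$env$start, nll, pb$env$lower, pb$env$upper, control)
  q <- unpack(res$par)
  structure(list(rho = q$rho, thresholds_row = q$tr, thresholds_col = q$tc,
                 minus2LL = res$value, converged = res$convergence == 0L,
                 boundary = abs(q$rho) > 0.999, n = n),
            class = "polychoric_fit")
}

#' @export
print.polychoric_fit <- function(x, ...) {
  cat("<polychoric_fit> rho =", round(x$rho, 4),
      if (x$boundary) "(boundary)", "\n")
  cat("  row thresholds:", round(x$thresholds_row, 4), "\n")
  cat("  col thresholds:", round(x$thresholds_col, 4), "\n")
  invisible(x)
}
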