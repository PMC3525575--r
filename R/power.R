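#' Per-pair noncentrality for the DZss-vs-DZos correlation test
#'
#' Expected likelihood-ratio statistic per pair for testing a common DZ
#' correlation against distinct same-sex (\code{r_ss}) and opposite-sex
#' (\code{r_os}) correlations. Computed by the "fit the false model to exact
#' population statistics" device: the constrained correlation is the value
#' maximizing the expected (population) log-likelihood under the stated mix
#' of pair types, and the noncentrality is twice the resulting expected
#' log-likelihood deficit — the Kullback-Leibler divergence of the equal-
#' correlation model, per pair.
#'
#' The continuous formulation works on standardized pairs (means and
#' variances known and equal across groups, matching the 1-df test). The
#' binary variant replaces densities by 2 x 2 cell probabilities at a given
#' prevalence threshold.
#'
#' @param r_ss true same-sex DZ correlation.
#' @param r_os true opposite-sex DZ correlation.
#' @param group_ratio length-2 ratio of DZss to DZos pairs, e.g.
#'   \code{c(2, 1)}; only relative size matters.
#' @param scale \code{"continuous"} or \code{"binary"}.
#' @param prevalence trait prevalence defining the liability threshold
#'   (binary scale only).
#' @return per-pair noncentrality (numeric scalar) with attribute
#'   \code{"pooled_r"}, the constrained-model correlation. Zero when
#'   \code{r_ss == r_os}.
#' @examples
#' ncp_per_pair(0.4, 0.2)
#' @export
ncp_per_pair <- function(r_ss, r_os, group_ratio = c(1, 1),
                         scale = c("continuous", "binary"),
                         prevalence = 0.5) {
  scale <- match.arg(scale)
  stopifnot(abs(r_ss) < 1, abs(r_os) < 1, length(group_ratio) == 2L,
            all(group_ratio > 0))
  w <- group_ratio / sum(group_ratio)

  if (scale == "continuous") {
    # expected log-likelihood of a standardized pair with true correlation
    # rho under a model with correlation r
    el <- function(r, rho)
      -log(2 * pi) - 0.5 * log(1 - r^2) - (1 - r * rho) / (1 - r^2)
    obj <- function(r) -(w[1] * el(r, r_ss) + w[2] * el(r, r_os))
    r_hat <- optimize(obj, c(-0.9999, 0.9999), tol = 1e-12)$minimum
    ncp <- 2 * (w[1] * (el(r_ss, r_ss) - el(r_hat, r_ss)) +
                  w[2] * (el(r_os, r_os) - el(r_hat, r_os)))
  } else {
    stopifnot(prevalence > 0, prevalence < 1)
    thr <- qnorm(1 - prevalence)
    cellp <- function(r) {
      p11 <- pbvnorm(thr, thr, r)  # both below threshold
      p1 <- pnorm(thr)
      p <- c(p11, p1 - p11, p1 - p11, 1 - 2 * p1 + p11)
      pmax(p, 1e-300)
    }
    el <- function(r, rho) sum(cellp(rho) * log(cellp(r)))
    obj <- function(r) -(w[1] * el(r, r_ss) + w[2] * el(r, r_os))
    r_hat <- optimize(obj, c(-0.9999, 0.9999), tol = 1e-12)$minimum
    ncp <- 2 * (w[1] * (el(r_ss, r_ss) - el(r_hat, r_ss)) +
                  w[2] * (el(r_os, r_os) - el(r_hat, r_os)))
  }
  ncp <- max(ncp, 0)
  if (r_ss == r_os || ncp < 1e-15) {
    ncp <- 0
    attr(ncp, "pooled_r") <- r_ss
    attr(ncp, "flagged") <- "zero noncentrality: r_ss == r_os"
    return(ncp)
  }
  attr(ncp, "pooled_r") <- r_hat
  ncp
}

#' Twin pairs required to detect a DZss-DZos correlation difference
#'
#' For each target power, finds the smallest total number of DZ pairs (at
#' the stated DZss:DZos mix) for which the 1-df likelihood-ratio test of
#' equal correlations attains that power at level \code{alpha}, using the
#' noncentral chi-square distribution with noncentrality
#' \code{N * ncp_per_pair}.
#'
#' @param r_ss,r_os,group_ratio,scale,prevalence see
#'   \code{\link{ncp_per_pair}}.
#' @param alpha significance level of the test (default 0.05).
#' @param power_targets strictly increasing power levels in (0, 1); default
#'   covers .75 to .99.
#' @return data.frame of class \code{power_requirement} with columns
#'   \code{power}, \code{ncp_required} (total noncentrality needed) and
#'   \code{n_pairs} (total pairs, rounded up, minimal); attribute
#'   \code{"ncp_per_pair"} carries the per-pair noncentrality. When
#'   \code{r_ss == r_os} the requirement is undefined: \code{n_pairs} is
#'   \code{Inf} and the result carries a \code{"flagged"} attribute.
#' @examples
#' required_pairs(0.4, 0.2)
#' @export
required_pairs <- function(r_ss, r_os, alpha = 0.05,
                           power_targets = c(0.75, 0.80, 0.90, 0.95, 0.99),
                           group_ratio = c(1, 1),
                           scale = c("continuous", "binary"),
                           prevalence = 0.5) {
  stopifnot(alpha > 0, alpha < 1, all(power_targets > 0),
            all(power_targets < 1), !is.unsorted(power_targets,
                                                 strictly = TRUE))
  lambda <- ncp_per_pair(r_ss, r_os, group_ratio, scale, prevalence)
  crit <- qchisq(1 - alpha, df = 1)
  pwr <- function(ncp) pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)

  ncp_req <- vapply(power_targets, function(target)
    uniroot(function(d) pwr(d) - target, c(1e-8, 200),
            tol = 1e-10)$root, 0)

  if (as.numeric(lambda) == 0) {
    out <- data.frame(power = power_targets, ncp_required = ncp_req,
                      n_pairs = Inf)
    class(out) <- c("power_requirement", "data.frame")
    attr(out, "ncp_per_pair") <- 0
    attr(out, "flagged") <- "undefined requirement: zero noncentrality"
    return(out)
  }

  n <- vapply(seq_along(power_targets), function(i) {
    N <- ceiling(ncp_req[i] / as.numeric(lambda))
    while (N > 1 && pwr((N - 1) * as.numeric(lambda)) >= power_targets[i])
      N <- N - 1
    while (pwr(N * as.numeric(lambda)) < power_targets[i])
      N <- N + 1
    N
  }, 0)

  out <- data.frame(power = power_targets, ncp_required = ncp_req,
                    n_pairs = as.integer(n))
  class(out) <- c("power_requirement", "data.frame")
  attr(out, "ncp_per_pair") <- as.numeric(lambda)
  attr(out, "pooled_r") <- attr(lambda, "pooled_r")
  out
}

#' Required-pairs table over a correlation grid
#'
#' Convenience wrapper producing the classic power table: one row per
#' \code{(r_ss, r_os)} pair, one column of required total pairs per power
#' target.
#'
#' @param grid data.frame (or 2-column matrix) of \code{r_ss}, \code{r_os}
#'   values.
#' @param ... passed to \code{\link{required_pairs}}.
#' @return data.frame with columns \code{r_ss}, \code{r_os} and
#'   \code{power_<target>} required-pair counts.
#' @export
power_table <- function(grid, ...) {
  grid <- as.data.frame(grid)
  names(grid)[1:2] <- c("r_ss", "r_os")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    rp <- required_pairs(grid$r_ss[i], grid$r_os[i], ...)
    stats::setNames(as.list(rp$n_pairs), paste0("power_", rp$power))
  })
  cbind(grid, do.call(rbind, lapply(rows, as.data.frame)))
}
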