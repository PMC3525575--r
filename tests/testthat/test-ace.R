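test_that("expected correlations follow the sex-limitation identities", {
  r <- expected_correlations(0.4, 0.2)
  expect_equal(unname(r[c("MZM", "MZF")]), c(0.6, 0.6), tolerance = 1e-15)
  expect_equal(unname(r[c("DZM", "DZF")]), c(0.4, 0.4), tolerance = 1e-15)
  expect_equal(unname(r[["DOS"]]), 0.5 * 0.4 + 0.2, tolerance = 1e-15)

  # equal components: r_dzss = 0.5 h2 + c2 and r_dos = gamma h2 + phi c2,
  # exactly, over a parameter sweep
  for (a2 in c(0, 0.15, 0.4, 0.7)) for (c2 in c(0, 0.1, 0.25)) {
    for (gamma in c(0, 0.2, 0.5)) for (phi in c(0.3, 1)) {
      r <- expected_correlations(a2, c2, gamma = gamma, phi = phi)
      expect_equal(unname(r[["DZM"]]), 0.5 * a2 + c2, tolerance = 1e-15)
      expect_equal(unname(r[["DOS"]]), gamma * a2 + phi * c2,
                   tolerance = 1e-15)
    }
  }

  # gamma/phi values in the observed range of adult traits
  r1 <- expected_correlations(0.4, 0, gamma = 0.36)
  expect_equal(unname(r1[["DOS"]]), 0.144, tolerance = 1e-15)
  expect_lt(r1[["DOS"]], r1[["DZM"]])
  r2 <- expected_correlations(0, 0.5, phi = 0.66)
  expect_equal(unname(r2[["DOS"]]), 0.33, tolerance = 1e-15)
  expect_lt(r2[["DOS"]], r2[["DZM"]])
})

test_that("expected_correlations validates its parameter space", {
  expect_error(expected_correlations(0.7, 0.4), "a2_m")
  expect_error(expected_correlations(0.4, 0.2, gamma = 0.6), "gamma")
  expect_error(expected_correlations(0.4, 0.2, phi = 1.2), "phi")
})

test_that("full gamma model recovers generating parameters within 3 SE", {
  cfg <- null_cfg(n = 10000, seed = 71, a2_m = 0.5, c2_m = 0.1, gamma = 0.2)
  ds <- simulate_pairs(cfg, cont_spec())
  fit <- fit_ace(ds, "full_gamma", se = TRUE)
  expect_true(fit$converged)
  expect_equal(unname(fit$params$gamma), 0.2,
               tolerance = 3 * fit$se[["gamma"]] / 0.2)
  expect_equal(unname(fit$params$a2[["M"]]), 0.5,
               tolerance = 3 * fit$se[["a2_M"]] / 0.5)
  expect_equal(unname(fit$params$c2[["F"]]), 0.1,
               tolerance = 3 * fit$se[["c2_F"]] / 0.1)
  expect_equal(unname(fit$params$phi), 1)  # fixed in full_gamma
})

test_that("phi model recovers a shared-environment deficit", {
  cfg <- null_cfg(n = 10000, seed = 72, a2_m = 0.1, c2_m = 0.5, phi = 0.7)
  ds <- simulate_pairs(cfg, cont_spec())
  fit <- fit_ace(ds, "full_phi", se = TRUE)
  expect_equal(unname(fit$params$gamma), 0.5)  # fixed in full_phi
  expect_equal(unname(fit$params$phi), 0.7,
               tolerance = 3 * fit$se[["phi"]] / 0.7)
})

test_that("nested ACE models never beat their nesting model", {
  cfg <- null_cfg(n = 2000, seed = 73, a2_m = 0.45, c2_m = 0.15,
                  a2_f = 0.35, c2_f = 0.25, gamma = 0.35)
  ds <- simulate_pairs(cfg, cont_spec())
  full <- fit_ace(ds, "full_gamma")
  homog <- fit_ace(ds, "homogeneous", qual = "gamma", start = full)
  noc <- fit_ace(ds, "no_c", qual = "gamma", start = homog)
  noa <- fit_ace(ds, "no_a", qual = "gamma", start = homog)
  qnull <- fit_ace(ds, "qualitative_constrained", start = full)
  expect_gte(homog$minus2LL, full$minus2LL - 1e-6)
  expect_gte(noc$minus2LL, homog$minus2LL - 1e-6)
  expect_gte(noa$minus2LL, homog$minus2LL - 1e-6)
  expect_gte(qnull$minus2LL, full$minus2LL - 1e-6)
  # and the ACE structure is itself nested in the saturated model
  sat <- fit_saturated(ds)
  expect_gte(full$minus2LL, sat$minus2LL - 1e-6)
})

test_that("ACE-implied correlations match the saturated fit when null holds", {
  cfg <- null_cfg(n = 10000, seed = 74)
  ds <- simulate_pairs(cfg, cont_spec())
  ace <- fit_ace(ds, "qualitative_constrained")
  sat <- fit_saturated(ds)
  se3 <- 3 / sqrt(10000)
  for (g in c("MZM", "MZF", "DZM", "DZF", "DOS"))
    expect_lt(abs(ace$params$cor[[g]] - sat$params$cor[[g]]), se3)
})

test_that("qualitative parameter choice follows the C-vs-A rule", {
  fake <- function(a2, c2) structure(
    list(family = "ace", model = "full_gamma",
         params = list(a2 = c(M = a2, F = a2), c2 = c(M = c2, F = c2))),
    class = "twin_fit")
  expect_message(p1 <- choose_qualitative_parameter(fake(0.4, 0.1)),
                 "freeing gamma")
  expect_identical(p1, "gamma")
  expect_identical(
    suppressMessages(choose_qualitative_parameter(fake(0.05, 0.45))), "phi")
  # exact tie breaks to gamma
  expect_identical(
    suppressMessages(choose_qualitative_parameter(fake(0.3, 0.3))), "gamma")
  ae <- structure(list(family = "ace", model = "no_c", params = list()),
                  class = "twin_fit")
  expect_error(choose_qualitative_parameter(ae), "both A and C")
})

test_that("qualitative-constrained vs full LRT is not anticonservative
           under the null", {
  # truth gamma = 0.5 sits on the boundary of [0, 0.5]; the naive chi-square
  # reference is then conservative, so the rejection rate must not exceed
  # alpha (plus Monte Carlo error)
  n_rep <- 60
  alpha <- 0.05
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    ds <- simulate_pairs(null_cfg(n = 600, seed = 7000 + i), cont_spec())
    full <- fit_ace(ds, "full_gamma")
    nullf <- fit_ace(ds, "qualitative_constrained", start = full)
    rej[i] <- lrt(nullf, full)$p_value < alpha
  }
  expect_lte(mean(rej), alpha + 3 * sqrt(alpha * (1 - alpha) / n_rep))
})

test_that("ordinal ACE decomposes liability correlations", {
  cfg <- null_cfg(n = 8000, seed = 75, a2_m = 0.4, c2_m = 0.2,
                  thresholds_m = 0.2, thresholds_f = 0.4)
  ds <- simulate_pairs(cfg, bin_spec())
  fit <- fit_ace(ds, "qualitative_constrained")
  expect_true(fit$converged)
  expect_equal(unname(fit$params$a2[["M"]]), 0.4, tolerance = 0.3)
  expect_equal(unname(fit$params$c2[["M"]]), 0.2, tolerance = 0.5)
  expect_equal(unname(fit$params$e2[["M"]]) + unname(fit$params$a2[["M"]]) +
                 unname(fit$params$c2[["M"]]), 1, tolerance = 1e-8)
})

test_that("boundary component estimates are reported", {
  cfg <- null_cfg(n = 4000, seed = 76, a2_m = 0.6, c2_m = 0)
  ds <- simulate_pairs(cfg, cont_spec())
  fit <- fit_ace(ds, "full_gamma")
  # with no common environment the C path typically collapses to zero
  expect_true(fit$params$c2[["M"]] < 0.05 || fit$params$c2[["F"]] < 0.05)
  if (any(fit$params$c2 < 1e-6))
    expect_true(any(grepl("^c2_", fit$boundary)))
})
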