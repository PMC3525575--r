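test_that("single-group fit reproduces the closed-form exchangeable MLEs", {
  set.seed(21)
  n <- 400
  r <- 0.5
  y1 <- rnorm(n)
  y2 <- r * y1 + sqrt(1 - r^2) * rnorm(n) + 0.3
  y1 <- y1 + 0.3
  df <- data.frame(trait_id = "t", group = "MZM", y1 = y1, y2 = y2,
                   sex1 = "M", sex2 = "M", covar1 = NA_real_,
                   covar2 = NA_real_)
  ds <- twin_dataset(df, cont_spec("t"))
  fit <- fit_saturated(ds, control = list(factr = 1))
  # exchangeable bivariate normal MLEs (grand mean, biased-n pooled
  # variance, intraclass-type ML correlation)
  mu_hat <- mean(c(y1, y2))
  var_hat <- mean(c((y1 - mu_hat)^2, (y2 - mu_hat)^2))
  r_hat <- mean((y1 - mu_hat) * (y2 - mu_hat)) / var_hat
  expect_equal(unname(fit$params$mean[["M"]]), mu_hat, tolerance = 1e-6)
  expect_equal(unname(fit$params$var[["M"]]), var_hat, tolerance = 1e-6)
  expect_equal(unname(fit$params$cor[["MZM"]]), r_hat, tolerance = 1e-6)
  expect_equal(fit$n_free_params, 3L)
})

test_that("continuous fit recovers generating correlations within 3 SE", {
  n <- 5000
  cfg <- null_cfg(n = n, seed = 31, a2_m = 0.4, c2_m = 0.2)  # r_dz = 0.40
  ds <- simulate_pairs(cfg, cont_spec())
  fit <- fit_saturated(ds)
  expect_true(fit$converged)
  se3 <- 3 * (1 - 0.4^2) / sqrt(n)
  for (g in c("DZM", "DZF", "DOS"))
    expect_equal(unname(fit$params$cor[[g]]), 0.40, tolerance = se3 / 0.4)
  expect_equal(unname(fit$params$mean[["M"]]), 0, tolerance = 3 / sqrt(n))
  expect_equal(unname(fit$params$var[["M"]]), 1, tolerance = 9 / sqrt(n))
})

test_that("covariate slopes on the mean are recovered per sex", {
  cfg <- null_cfg(n = 3000, seed = 32, beta_age_m = 0.3, beta_age_f = -0.1,
                  mean_m = 1, mean_f = 0.5)
  ds <- simulate_pairs(cfg, cont_spec(cov = "age"))
  fit <- fit_saturated(ds)
  expect_equal(unname(fit$params$beta[["M"]]), 0.3, tolerance = 0.05)
  expect_equal(unname(fit$params$beta[["F"]]), -0.1, tolerance = 0.5)
  expect_equal(unname(fit$params$mean[["M"]]), 1, tolerance = 0.05)
})

test_that("likelihood is invariant to swapping twins within same-sex pairs", {
  cfg <- null_cfg(n = 300, seed = 33)
  ds <- simulate_pairs(cfg, cont_spec())
  swapped <- ds
  i <- swapped$pairs$group %in% c("MZM", "MZF", "DZM", "DZF")
  tmp <- swapped$pairs$y1[i]
  swapped$pairs$y1[i] <- swapped$pairs$y2[i]
  swapped$pairs$y2[i] <- tmp
  f1 <- fit_saturated(ds)
  f2 <- fit_saturated(swapped)
  expect_equal(f1$minus2LL, f2$minus2LL, tolerance = 1e-8)
  expect_equal(f1$params$cor, f2$params$cor, tolerance = 1e-5)
})

test_that("perfectly correlated MZ pairs hit the boundary and are flagged", {
  cfg <- null_cfg(n = 200, seed = 34)
  ds <- simulate_pairs(cfg, cont_spec())
  i <- ds$pairs$group %in% c("MZM", "MZF")
  ds$pairs$y2[i] <- ds$pairs$y1[i]
  fit <- fit_saturated(ds)
  expect_gt(fit$params$cor[["MZM"]], 0.999)
  expect_true(any(c("r_MZM", "r_MZF") %in% fit$boundary))
})

test_that("binary threshold model recovers sex-specific thresholds", {
  n <- 20000
  cfg <- null_cfg(n = n, seed = 35, thresholds_m = 0, thresholds_f = 0.5)
  ds <- simulate_pairs(cfg, bin_spec())
  fit <- fit_saturated(ds)
  # thresholds within 3 SE of truth; SE of a threshold near Phi^-1(p) is
  # sqrt(p(1-p)/n)/dnorm(thr) with n = 4n individuals per sex
  m_ind <- 4 * n
  se_m <- sqrt(0.5 * 0.5 / m_ind) / dnorm(0)
  se_f <- sqrt(pnorm(0.5) * pnorm(-0.5) / m_ind) / dnorm(0.5)
  expect_equal(fit$params$thresholds$M, 0, tolerance = 3 * se_m + 1e-9)
  expect_equal(fit$params$thresholds$F, 0.5, tolerance = 3 * se_f / 0.5)
  # implied prevalences of category 0
  expect_equal(pnorm(fit$params$thresholds$M), 0.5, tolerance = 0.02)
  expect_equal(pnorm(fit$params$thresholds$F), pnorm(0.5), tolerance = 0.02)
  expect_true(fit$converged)
})

test_that("ordinal fit with a covariate recovers the threshold slope", {
  cfg <- null_cfg(n = 1500, seed = 36, thresholds_m = 0.2, thresholds_f = 0.2,
                  beta_age_m = 0.4, beta_age_f = 0.4)
  ds <- simulate_pairs(cfg, bin_spec(cov = "age"))
  fit <- fit_saturated(ds)
  expect_true(fit$converged)
  expect_equal(unname(fit$params$beta_thr[["M"]]), 0.4, tolerance = 0.25)
  expect_equal(unname(fit$params$beta_thr[["F"]]), 0.4, tolerance = 0.25)
})

test_that("adding constraints never decreases -2 log L", {
  cfg <- null_cfg(n = 800, seed = 37)
  ds <- simulate_pairs(cfg, cont_spec())
  f0 <- fit_saturated(ds)
  f1a <- fit_saturated(ds, "equal_variances", start = f0)
  f2 <- fit_saturated(ds, "rdz_equal", start = f0)
  f3 <- fit_saturated(ds, c("equal_variances", "rdz_all_equal"), start = f1a)
  expect_gte(f1a$minus2LL, f0$minus2LL - 1e-6)
  expect_gte(f2$minus2LL, f0$minus2LL - 1e-6)
  expect_gte(f3$minus2LL, f1a$minus2LL - 1e-6)
  expect_gte(f3$minus2LL, f2$minus2LL - 1e-6)
  # free-parameter bookkeeping: 9 unconstrained, each constraint drops one
  expect_equal(f0$n_free_params, 9L)
  expect_equal(f1a$n_free_params, 8L)
  expect_equal(f2$n_free_params, 8L)
  expect_equal(f3$n_free_params, 6L)
})

test_that("constraint handling rejects misuse", {
  cfg <- null_cfg(n = 100, seed = 38, thresholds_m = 0, thresholds_f = 0)
  ds <- simulate_pairs(cfg, bin_spec())
  expect_error(fit_saturated(ds, "equal_variances"), "continuous")
  ds2 <- simulate_pairs(null_cfg(n = 50, seed = 39), cont_spec())
  expect_error(fit_saturated(ds2, "rdz_some"), "unknown constraint")
})

test_that("a group with a single pair is reported as under-identified", {
  df <- data.frame(trait_id = "t",
                   group = c(rep("MZM", 5), "DOS"),
                   y1 = rnorm(6), y2 = rnorm(6),
                   sex1 = c(rep("M", 5), "M"), sex2 = c(rep("M", 5), "F"),
                   covar1 = NA_real_, covar2 = NA_real_)
  ds <- twin_dataset(df, cont_spec("t"))
  expect_error(fit_saturated(ds), "under-identified.*DOS")
})
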