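five_row_csv <- function(path) {
  writeLines(c(
    "trait_id,group,y1,y2,sex1,sex2,covar1,covar2",
    "t,MZM,0.1,0.2,M,M,30,30",
    "t,MZF,-0.3,0.4,F,F,41,41",
    "t,DZM,1.1,0.0,M,M,25,25",
    "t,DZF,0.6,-0.2,F,F,33,33",
    "t,DOS,0.2,0.9,M,F,28,28"), path)
  path
}

test_that("a one-pair-per-group CSV reads into unit group counts", {
  path <- five_row_csv(withr::local_tempfile(fileext = ".csv"))
  ds <- read_pairs(path, cont_spec("t", cov = "age"))
  expect_s3_class(ds, "twin_dataset")
  expect_equal(unname(ds$group_counts), rep(1L, 5))
  expect_equal(sum(ds$group_counts), nrow(ds$pairs))
})

test_that("group/sex invariant violations are rejected with row numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("trait_id,group,y1,y2,sex1,sex2,covar1,covar2",
               "t,DOS,0.1,0.2,F,F,30,30",
               "t,MZM,0.1,0.2,M,F,30,30"), path)
  expect_error(read_pairs(path, cont_spec("t", cov = "age")),
               "row\\(s\\): 1, 2")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("trait_id,group,y1,y2,sex1,sex2,covar1,covar2",
               "t,DZX,0.1,0.2,M,M,30,30"), path2)
  expect_error(read_pairs(path2, cont_spec("t", cov = "age")), "DZX")
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("trait_id,group,y1,y2,sex1,sex2",
               "t,MZM,0.1,0.2,M,M"), path3)
  expect_error(read_pairs(path3, cont_spec("t", cov = "age")),
               "required column")
})

test_that("DOS pairs supplied female-first are stored male-first", {
  df <- data.frame(trait_id = "t", group = "DOS", y1 = 1, y2 = 2,
                   sex1 = "F", sex2 = "M", covar1 = 40, covar2 = 41)
  ds <- twin_dataset(df, cont_spec("t", cov = "age"))
  expect_equal(ds$pairs$sex1, "M")
  expect_equal(ds$pairs$y1, 2)
  expect_equal(ds$pairs$covar1, 41)
})

test_that("write/read round trip is the identity to full precision", {
  cfg <- null_cfg(n = 40, seed = 77, beta_age_m = 0.2)
  ds <- simulate_pairs(cfg, cont_spec("t", cov = "age"))
  # inject missingness: a single-phenotype pair and a missing covariate
  ds$pairs$y2[3] <- NA
  ds$pairs$covar1[5] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_pairs(ds, path)
  back <- read_pairs(path, cont_spec("t", cov = "age"))
  expect_identical(back$pairs, ds$pairs)
  # and for tab-separated output
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_pairs(ds, path2)
  expect_identical(read_pairs(path2, cont_spec("t", cov = "age"))$pairs,
                   ds$pairs)
})

test_that("pairs with both phenotypes missing are dropped", {
  df <- data.frame(trait_id = "t", group = c("MZM", "MZM", "DZF"),
                   y1 = c(1, NA, 2), y2 = c(2, NA, NA),
                   sex1 = c("M", "M", "F"), sex2 = c("M", "M", "F"),
                   covar1 = NA_real_, covar2 = NA_real_)
  expect_message(ds <- twin_dataset(df, cont_spec("t")), "dropped")
  expect_equal(nrow(ds$pairs), 2L)
})

test_that("ordinal category codes outside 0..K-1 are rejected", {
  df <- data.frame(trait_id = "t", group = "MZM", y1 = 2, y2 = 0,
                   sex1 = "M", sex2 = "M", covar1 = NA_real_,
                   covar2 = NA_real_)
  expect_error(twin_dataset(df, bin_spec("t")), "ordinal codes")
})

test_that("covariate standardization gives pooled z-scores", {
  df <- data.frame(trait_id = "t", group = c("MZM", "DZF"),
                   y1 = c(1, 2), y2 = c(2, 1),
                   sex1 = c("M", "F"), sex2 = c("M", "F"),
                   covar1 = c(20, 40), covar2 = c(30, NA))
  ds <- standardize_covariate(twin_dataset(df, cont_spec("t", cov = "age")))
  # pooled values {20, 40, 30}: mean 30, population SD sqrt(200/3),
  # so z = {-1.2247, +1.2247, 0}
  expect_equal(ds$pairs$covar1, c(-1, 1) * sqrt(1.5), tolerance = 1e-12)
  expect_equal(ds$pairs$covar2[1], 0, tolerance = 1e-12)
  # missing imputed at the mean and flagged
  expect_equal(ds$pairs$covar2[2], 0)
  expect_true(attr(ds, "covar_imputed")[2, "covar2"])
})

test_that("standardization recenters to mean 0, variance 1, idempotently", {
  cfg <- null_cfg(n = 100, seed = 5)
  ds <- simulate_pairs(cfg, cont_spec("t", cov = "age"))
  ds <- standardize_covariate(ds)
  z <- c(ds$pairs$covar1, ds$pairs$covar2)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(mean(z^2) - mean(z)^2 - 1), 1e-12)
  ds2 <- standardize_covariate(ds)
  expect_equal(ds2$pairs, ds$pairs, tolerance = 1e-10)
})

test_that("degenerate covariates raise errors", {
  df <- data.frame(trait_id = "t", group = "MZM", y1 = 1, y2 = 2,
                   sex1 = "M", sex2 = "M", covar1 = 30, covar2 = 30)
  ds <- twin_dataset(df, cont_spec("t", cov = "age"))
  expect_error(standardize_covariate(ds), "zero variance")
  df$covar1 <- NA_real_; df$covar2 <- NA_real_
  ds2 <- twin_dataset(df, cont_spec("t", cov = "age"))
  expect_error(standardize_covariate(ds2), "missing")
})
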