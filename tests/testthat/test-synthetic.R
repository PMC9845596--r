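test_that("log-normal parameters reproduce the printed median and quartiles", {
  p <- lognormal_from_quartiles(1.70, 1.24, 2.35)
  expect_equal(unname(p["mu"]), 0.53063, tolerance = 1e-4)
  expect_equal(unname(p["sigma"]), 0.47392, tolerance = 1e-4)
  p2 <- lognormal_from_quartiles(1.39, 1.05, 2.05)
  expect_equal(unname(p2["mu"]), 0.32930, tolerance = 1e-4)
  expect_equal(unname(p2["sigma"]), 0.49597, tolerance = 1e-4)
  # degenerate spread
  p3 <- lognormal_from_quartiles(2, 2, 2)
  expect_equal(unname(p3), c(log(2), 0))
  # the fit matches the median exactly and the quartile ratio (the two
  # parameters of the log-normal); log-symmetric inputs round-trip fully
  set.seed(31)
  for (i in 1:20) {
    q1 <- runif(1, 0.5, 5); med <- q1 * runif(1, 1, 2); q3 <- med * runif(1, 1, 2)
    p <- lognormal_from_quartiles(med, q1, q3)
    q <- qlnorm(c(0.25, 0.5, 0.75), p["mu"], p["sigma"])
    expect_equal(q[2], med, tolerance = 1e-6)
    expect_equal(q[3] / q[1], q3 / q1, tolerance = 1e-6)
    r <- runif(1, 1, 3)
    psym <- lognormal_from_quartiles(med, med / r, med * r)
    expect_equal(qlnorm(c(0.25, 0.5, 0.75), psym["mu"], psym["sigma"]),
                 c(med / r, med, med * r), tolerance = 1e-6)
  }
  expect_error(lognormal_from_quartiles(1, 2, 3), "quartiles")
})

test_that("correlation repair is idempotent on PD input and fixes indefinite input", {
  expect_identical(repair_correlation(diag(3)), diag(3))
  R <- matrix(c(1, 0.99, 0.99, 1), 2)
  expect_identical(repair_correlation(R), R)
  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3)
  fixed <- repair_correlation(bad)
  expect_gt(min(eigen(fixed, symmetric = TRUE)$values), 0)
  expect_equal(diag(fixed), rep(1, 3))
  expect_true(isSymmetric(fixed))
  # repair of repaired input is a no-op
  expect_identical(repair_correlation(fixed), fixed)
  expect_error(repair_correlation(matrix(c(1, 0.2, 0.3, 1), 2)), "symmetric")
})

test_that("default configs transcribe the published summary columns", {
  old <- default_config("older")
  expect_equal(old$n, 284L)
  expect_equal(old$marginals$waist$mean, 104.6)
  expect_equal(old$marginals$waist$sd, 15.4)
  expect_equal(old$marginals$triglycerides$median, 1.70)
  young <- default_config("young")
  expect_equal(young$n, 167L)
  expect_equal(young$age_range, c(16L, 30L))
  expect_equal(young$marginals$triglycerides$q1, 1.05)
  expect_equal(young$marginals$triglycerides$q3, 2.05)
  expect_equal(young$dm_fraction, 0)
  expect_gt(old$dm_fraction, 0)
  # latent correlation matrix is PD with unit diagonal
  expect_gt(min(eigen(old$correlation, symmetric = TRUE)$values), 0)
  expect_equal(diag(old$correlation), setNames(rep(1, ncol(old$correlation)),
                                               colnames(old$correlation)))
})

test_that("generation is seed-deterministic and seed-sensitive", {
  cfg <- default_config("young", n = 40, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(a, f1); write_cohort(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  cfg2 <- cfg
  cfg2$seed <- 100L
  expect_false(identical(generate_cohort(cfg2)$waist, a$waist))
  empty <- generate_cohort(default_config("young", n = 0, seed = 1))
  expect_equal(nrow(empty), 0)
})

test_that("generated records satisfy the positivity and range invariants", {
  co <- generate_cohort(default_config("older", n = 500, seed = 12))
  numeric_cols <- names(co)[vapply(co, is.numeric, logical(1))]
  for (col in numeric_cols) expect_true(all(co[[col]] > 0), label = col)
  expect_true(all(co$sex %in% c("male", "female")))
  expect_true(all(co$age >= 31 & co$age <= 75))
  expect_true(all(co$hdl >= 0.4))
  # weight consistent with generated height and implied BMI
  expect_true(all(compute_bmi(co$weight, co$height) > 15))
})

test_that("marginal means/medians are recovered at n = 10,000", {
  for (group in c("young", "older")) {
    cfg <- default_config(group, n = 10000, seed = 848)
    cfg$ifg_fraction <- cfg$igt_fraction <- cfg$dm_fraction <- 0
    co <- generate_cohort(cfg)
    co$bmi <- compute_bmi(co$weight, co$height)
    for (m in cfg$marginals) {
      x <- co[[m$name]]
      if (m$family == "normal") {
        target <- tnorm_mean(m$mean, m$sd, m$lower)
        expect_lt(abs(mean(x) - target), 3 * m$sd / sqrt(10000),
                  label = paste(group, m$name, "mean"))
      } else {
        expect_lt(abs(median(x) - m$median) / m$median, 0.03,
                  label = paste(group, m$name, "median"))
      }
    }
  }
})

test_that("latent dependence is recovered as Spearman correlation at n = 10,000", {
  cfg <- default_config("older", n = 10000, seed = 849)
  cfg$ifg_fraction <- cfg$igt_fraction <- cfg$dm_fraction <- 0
  co <- generate_cohort(cfg)
  co$bmi <- compute_bmi(co$weight, co$height)
  R <- cfg$correlation
  vars <- colnames(R)
  S <- cor(as.matrix(co[vars]), method = "spearman")
  configured <- which(abs(R) > 1e-8 & upper.tri(R), arr.ind = TRUE)
  expect_gt(nrow(configured), 40) # the default map is non-trivial
  for (k in seq_len(nrow(configured))) {
    i <- configured[k, 1]; j <- configured[k, 2]
    expect_lt(abs(S[i, j] - R[i, j]), 0.05,
              label = paste(vars[i], vars[j]))
  }
})

test_that("cohort-mean waist obeys the CLT bound at n = 10,000", {
  cfg <- default_config("older", n = 10000, seed = 850)
  co <- generate_cohort(cfg)
  expect_lt(abs(mean(co$waist) - 104.6), 3 * 15.4 / sqrt(10000))
})

test_that("induced glycoregulation subgroups classify to the configured categories", {
  cfg <- default_config("older", n = 4000, seed = 77)
  co <- classify_cohort(score_cohort(generate_cohort(cfg)))
  prev <- table(factor(co$glyco_label,
                       levels = c("normal", "IFG", "IGT", "DM"))) / nrow(co)
  expect_lt(abs(prev[["DM"]] - cfg$dm_fraction), 0.015)
  expect_lt(abs(prev[["IFG"]] - cfg$ifg_fraction), 0.015)
  expect_lt(abs(prev[["IGT"]] - cfg$igt_fraction), 0.015)
  expect_gt(unname(prev["normal"]), 0.85)
})
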