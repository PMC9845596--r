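two_group_df <- function(x, y) {
  data.frame(g = rep(c("a", "b"), c(length(x), length(y))), v = c(x, y))
}

test_that("t test handles identical and degenerate groups", {
  r <- compare_groups(two_group_df(1:3, 1:3), "g", "v", "t_test")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r <- compare_groups(two_group_df(c(2, 2), c(2, 2)), "g", "v", "t_test")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r <- compare_groups(two_group_df(c(2, 2), c(5, 5)), "g", "v", "t_test")
  expect_equal(r$p_value, 0)
  expect_error(compare_groups(two_group_df(1, 1:3), "g", "v", "t_test"),
               "at least 2")
})

test_that("pooled t test matches stats::t.test and Welch is available", {
  set.seed(41)
  x <- rnorm(20); y <- rnorm(25, 0.5)
  r <- compare_groups(two_group_df(x, y), "g", "v", "t_test")
  ht <- t.test(x, y, var.equal = TRUE)
  expect_equal(r$statistic, unname(ht$statistic))
  expect_equal(r$p_value, ht$p.value)
  rw <- compare_groups(two_group_df(x, y), "g", "v", "t_test",
                       var_equal = FALSE)
  expect_equal(rw$p_value, t.test(x, y)$p.value)
})

test_that("separated small samples give the enumerated exact Mann-Whitney p", {
  r <- compare_groups(two_group_df(c(1, 2, 3), c(4, 5, 6)), "g", "v",
                      "mann_whitney")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)
  expect_equal(mw_exact_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
})

test_that("exact Mann-Whitney p equals full enumeration for all n + m <= 10", {
  set.seed(42)
  for (n in 2:8) {
    for (m in 2:(10 - n)) {
      vals <- sample(seq_len(100), n + m) # distinct, no ties
      x <- vals[seq_len(n)]; y <- vals[-seq_len(n)]
      r <- compare_groups(two_group_df(x, y), "g", "v", "mann_whitney")
      expect_equal(r$p_value, mw_exact_p(x, y),
                   label = sprintf("n=%d m=%d", n, m))
    }
  }
})

test_that("Fisher's exact test on a fully separated 2x2 table matches hypergeometric enumeration", {
  df <- data.frame(g = rep(c("a", "b"), each = 10),
                   v = rep(c("x", "y"), each = 10))
  r <- compare_groups(df, "g", "v", "fisher_exact")
  expect_equal(r$p_value, 2 / choose(20, 10), tolerance = 1e-10)
  expect_equal(r$p_value, 1.083e-5, tolerance = 1e-3)
})

test_that("chi-square uses no continuity correction unless asked", {
  df <- data.frame(g = rep(c("a", "b"), each = 30),
                   v = c(rep(c("x", "y"), c(20, 10)),
                         rep(c("x", "y"), c(10, 20))))
  r <- compare_groups(df, "g", "v", "chi_square")
  tab <- table(df$g, df$v)
  expect_equal(r$statistic,
               unname(chisq.test(tab, correct = FALSE)$statistic))
  rc <- compare_groups(df, "g", "v", "chi_square", correct = TRUE)
  expect_equal(rc$statistic, unname(chisq.test(tab)$statistic))
})

test_that("comparisons are symmetric in group labelling", {
  set.seed(43)
  x <- rnorm(15); y <- rnorm(12, 0.8)
  df <- two_group_df(x, y)
  df_swapped <- df
  df_swapped$g <- ifelse(df$g == "a", "b", "a")
  for (test in c("t_test", "mann_whitney")) {
    r1 <- compare_groups(df, "g", "v", test)
    r2 <- compare_groups(df_swapped, "g", "v", test)
    expect_equal(r1$p_value, r2$p_value)
    expect_true(r1$p_value >= 0 && r1$p_value <= 1)
  }
  t1 <- compare_groups(df, "g", "v", "t_test")
  t2 <- compare_groups(df_swapped, "g", "v", "t_test")
  expect_equal(t1$statistic, -t2$statistic)
})

test_that("empty or single-level groups are rejected", {
  df <- data.frame(g = rep("a", 5), v = rnorm(5))
  expect_error(compare_groups(df, "g", "v", "t_test"), "two")
})

test_that("correlations match hand computation and record n", {
  df <- data.frame(sims = c(1, 2, 3), y = c(1, 3, 2))
  r <- correlate(df, "y", method = "pearson")
  expect_equal(r$r, 0.5)
  rs <- correlate(df, "y", method = "spearman")
  expect_equal(rs$r, 0.5)
  expect_equal(r$n_used, 3)
  df2 <- data.frame(sims = rnorm(20))
  df2$y <- 2 * df2$sims + 1
  expect_equal(correlate(df2, "y")$r, 1.0)
  expect_error(correlate(data.frame(sims = 1:2, y = 1:2), "y"), "3")
})

test_that("correlation is invariant under affine and monotone maps", {
  set.seed(44)
  df <- data.frame(sims = rnorm(50), y = rnorm(50))
  base_p <- correlate(df, "y", method = "pearson")$r
  base_s <- correlate(df, "y", method = "spearman")$r
  df$y2 <- 3 * df$y - 7
  expect_equal(correlate(df, "y2", method = "pearson")$r, base_p)
  df$y3 <- -2 * df$y + 1
  expect_equal(correlate(df, "y3", method = "pearson")$r, -base_p)
  df$y4 <- exp(df$y) # strictly monotone, nonlinear
  expect_equal(correlate(df, "y4", method = "spearman")$r, base_s)
})

test_that("null correlation at n = 10,000 is near zero and zero variance is flagged", {
  set.seed(45)
  df <- data.frame(sims = rnorm(10000), y = rnorm(10000))
  expect_lt(abs(correlate(df, "y")$r), 0.05)
  dfc <- data.frame(sims = rep(1, 10), y = rnorm(10))
  expect_warning(r <- correlate(dfc, "y"), "zero variance")
  expect_true(is.na(r$r))
})

test_that("the baseline table maps variables to the published test types", {
  cohort <- classify_cohort(score_cohort(
    rbind(generate_cohort(default_config("young", n = 120, seed = 5)),
          generate_cohort(default_config("older", n = 150, seed = 6)))))
  t1 <- build_table1(cohort)
  expect_equal(t1$test[t1$variable == "sims"], "t_test")
  expect_equal(t1$test[t1$variable == "triglycerides"], "mann_whitney")
  expect_equal(t1$test[t1$variable == "glyco_label"], "fisher_exact")
  expect_equal(t1$test[t1$variable == "obesity_label"], "chi_square")
  expect_true(all(t1$p_value >= 0 & t1$p_value <= 1, na.rm = TRUE))
  expect_true(all(c("summary1", "summary2", "label") %in% names(t1)))
  # single age group is a usage error
  young_only <- cohort[cohort$age_group == "young", ]
  expect_error(build_table1(young_only), "two-level")
  # unknown spec variables are skipped with a warning
  sp <- table1_spec()
  sp$variable[1] <- "nonexistent"
  expect_warning(t1b <- build_table1(cohort, spec = sp), "nonexistent")
  expect_false("nonexistent" %in% t1b$variable)
})

test_that("siMS-by-glycoregulation summaries respect category structure", {
  co <- data.frame(
    sims = c(3.0, 3.2, 2.8, 4.1, 4.3, 3.9, 5.0),
    glyco_label = c("normal", "normal", "normal", "IFG", "IFG", "IGT", "DM"),
    age_group = c("young", "young", "older", "older", "older", "young",
                  "older"))
  t2 <- sims_by_glyco(co)
  tot <- t2[t2$age_group == "total", ]
  expect_equal(tot$mean[tot$glyco_label == "normal"], 3.0)
  expect_equal(tot$mean[tot$glyco_label == "IFG"], 4.2)
  # single-member category has NA sd; empty cells are absent
  expect_true(is.na(tot$sd[tot$glyco_label == "DM"]))
  expect_false(any(t2$age_group == "young" & t2$glyco_label == "DM"))
  # all-equal siMS gives equal category means
  co$sims <- rep(3, 7)
  t2e <- sims_by_glyco(co)
  expect_true(all(abs(t2e$mean - 3) < 1e-12))
})

test_that("the correlation screen covers the mapped variables per group", {
  cohort <- classify_cohort(score_cohort(
    generate_cohort(default_config("older", n = 200, seed = 9))))
  cohort$age_group <- rep(c("young", "older"), length.out = nrow(cohort))
  corr <- build_correlations(cohort)
  expect_setequal(unique(corr$group), c("total", "young", "older"))
  expect_true(all(corr$r >= -1 & corr$r <= 1))
  expect_true(all(corr$n_used >= 3))
  expect_equal(unique(corr$method[corr$y_variable == "log_fli"]), "pearson")
  expect_equal(unique(corr$method[corr$y_variable == "homa_ir"]), "spearman")
  bh <- build_correlations(cohort, adjust = "BH")
  expect_true(all(bh$p_adjusted >= bh$p_value - 1e-12))
})
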