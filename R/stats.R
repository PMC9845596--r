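# Group-comparison and correlation stage: per-variable two-group tests
# with the variable -> test map shipped as data, siMS by glycoregulation
# category, and the siMS correlation screen. Standard tests are delegated
# to stats:: (t.test, wilcox.test, chisq.test, fisher.test, cor.test).

fmt_num <- function(x, digits = 2) {
  formatC(x, format = "f", digits = digits)
}

summarise_mean_sd <- function(x, digits = 2) {
  x <- x[!is.na(x)]
  sprintf("%s ± %s", fmt_num(mean(x), digits), fmt_num(stats::sd(x), digits))
}

summarise_median_iqr <- function(x, digits = 2) {
  x <- x[!is.na(x)]
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  sprintf("%s (%s-%s)", fmt_num(q[2], digits), fmt_num(q[1], digits),
          fmt_num(q[3], digits))
}

summarise_counts <- function(x) {
  x <- x[!is.na(x)]
  tab <- table(x)
  paste(sprintf("%s %d (%.1f%%)", names(tab), as.integer(tab),
                100 * as.integer(tab) / length(x)), collapse = "; ")
}

#' Two-group comparison of one variable
#'
#' Runs the requested test between the two groups of `group` and returns
#' one tidy result row. Continuous tests: `t_test` (pooled variance by
#' default, Welch with `var_equal = FALSE`) and `mann_whitney` (exact null
#' when the smaller group has at most 8 observations and there are no
#' ties, normal approximation with tie correction otherwise). Categorical
#' tests: `chi_square` (Pearson, no continuity correction unless
#' `correct = TRUE`) and `fisher_exact` on the 2 x k contingency table of
#' group by value.
#'
#' Degenerate continuous input (both groups constant and equal) yields
#' statistic 0 and p = 1; constant but unequal groups give p = 0.
#'
#' @param data A data frame.
#' @param group Name of the two-level grouping column.
#' @param variable Name of the analysed column.
#' @param test One of `"t_test"`, `"mann_whitney"`, `"chi_square"`,
#'   `"fisher_exact"`.
#' @param var_equal Pooled-variance t test if `TRUE` (default).
#' @param correct Continuity correction for the chi-square test
#'   (default off).
#' @return One-row data frame: `variable`, `test`, group labels and
#'   summaries, `statistic`, `p_value`, `n1`, `n2`.
#' @export
compare_groups <- function(data, group, variable,
                           test = c("t_test", "mann_whitney", "chi_square",
                                    "fisher_exact"),
                           var_equal = TRUE, correct = FALSE) {
  test <- match.arg(test)
  g <- data[[group]]
  v <- data[[variable]]
  if (is.null(g) || is.null(v)) {
    stop(sprintf("column `%s` or `%s` not found",
                 group, variable), call. = FALSE)
  }
  keep <- !is.na(g) & !is.na(v)
  g <- g[keep]; v <- v[keep]
  levels_g <- sort(unique(as.character(g)))
  if (length(levels_g) != 2) {
    stop("grouping column must have exactly two observed levels",
         call. = FALSE)
  }
  x <- v[g == levels_g[1]]
  y <- v[g == levels_g[2]]
  if (length(x) == 0 || length(y) == 0) {
    stop("empty group in comparison", call. = FALSE)
  }

  if (test %in% c("t_test", "mann_whitney")) {
    x <- as.numeric(x); y <- as.numeric(y)
    if (length(x) < 2 || length(y) < 2) {
      stop("continuous tests need at least 2 observations per group",
           call. = FALSE)
    }
    if (test == "t_test") {
      if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        statistic <- if (mean(x) == mean(y)) 0 else
          sign(mean(x) - mean(y)) * Inf
        p <- if (mean(x) == mean(y)) 1 else 0
      } else {
        ht <- stats::t.test(x, y, var.equal = var_equal)
        statistic <- unname(ht$statistic)
        p <- ht$p.value
      }
      s1 <- summarise_mean_sd(x); s2 <- summarise_mean_sd(y)
    } else {
      ties <- anyDuplicated(c(x, y)) > 0
      exact <- min(length(x), length(y)) <= 8 && !ties
      ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                                correct = !exact))
      statistic <- unname(ht$statistic)
      p <- ht$p.value
      s1 <- summarise_median_iqr(x); s2 <- summarise_median_iqr(y)
    }
  } else {
    tab <- table(factor(g, levels = levels_g), v)
    if (any(dim(tab) < 2)) {
      statistic <- 0; p <- 1
    } else if (test == "chi_square") {
      ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
      statistic <- unname(ht$statistic)
      p <- ht$p.value
    } else {
      ht <- stats::fisher.test(tab, workspace = 2e7)
      statistic <- NA_real_
      p <- ht$p.value
    }
    s1 <- summarise_counts(v[g == levels_g[1]])
    s2 <- summarise_counts(v[g == levels_g[2]])
  }

  data.frame(variable = variable, test = test,
             group1 = levels_g[1], group2 = levels_g[2],
             summary1 = s1, summary2 = s2,
             statistic = statistic, p_value = p,
             n1 = length(x), n2 = length(y),
             stringsAsFactors = FALSE)
}

#' Correlation of the siMS score with one covariate
#'
#' Pearson (two-sided t approximation) or Spearman (Pearson on mid-ranks)
#' correlation after listwise deletion. Zero variance in either variable
#' yields an `NA` correlation with a warning rather than a number.
#'
#' @param data A data frame.
#' @param y Name of the covariate column.
#' @param x Name of the score column (default `"sims"`).
#' @param method `"pearson"` or `"spearman"`.
#' @return One-row data frame: `x_variable`, `y_variable`, `method`, `r`,
#'   `p_value`, `n_used`.
#' @export
correlate <- function(data, y, x = "sims",
                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.null(data[[x]]) || is.null(data[[y]])) {
    stop(sprintf("column `%s` or `%s` not found", x, y), call. = FALSE)
  }
  xv <- as.numeric(data[[x]])
  yv <- as.numeric(data[[y]])
  keep <- !is.na(xv) & !is.na(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3) {
    stop("need at least 3 complete pairs for a correlation", call. = FALSE)
  }
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    warning(sprintf("zero variance: correlation of `%s` with `%s` undefined",
                    x, y), call. = FALSE)
    r <- NA_real_; p <- NA_real_
  } else {
    ht <- suppressWarnings(stats::cor.test(xv, yv, method = method))
    r <- unname(ht$estimate)
    p <- ht$p.value
  }
  data.frame(x_variable = x, y_variable = y, method = method,
             r = r, p_value = p, n_used = length(xv),
             stringsAsFactors = FALSE)
}

#' Variable-to-test map for the baseline characteristics table
#'
#' Ships the table layout as data: one row per variable with its test
#' (t test for mean +/- SD rows, Mann-Whitney for median rows, Fisher's
#' exact test for the glycoregulation distribution, Pearson chi-square
#' for the obesity proportion) and summary style, mirroring the published
#' table's footnotes.
#'
#' @return Data frame with columns `variable`, `label`, `test`, `digits`.
#' @export
table1_spec <- function() {
  s <- rbind(
    c("weight", "Body weight (kg)", "t_test", 1),
    c("bmi", "BMI (kg/m2)", "t_test", 2),
    c("obesity_label", "Obese", "chi_square", 0),
    c("waist", "WC (cm)", "t_test", 1),
    c("sbp", "SBP (mmHg)", "t_test", 1),
    c("dbp", "DBP (mmHg)", "t_test", 1),
    c("cholesterol", "Cholesterol (mmol/L)", "t_test", 1),
    c("hdl", "HDL-chol. (mmol/L)", "t_test", 1),
    c("ldl", "LDL-chol. (mmol/L)", "t_test", 1),
    c("triglycerides", "Triglycerides (mmol/L)", "mann_whitney", 2),
    c("glucose_0", "Glycaemia 0' (mmol/L)", "t_test", 1),
    c("glucose_30", "Glycaemia 30' (mmol/L)", "t_test", 1),
    c("glucose_120", "Glycaemia 120' (mmol/L)", "t_test", 1),
    c("insulin_0", "Insulin 0' (mIU/L)", "mann_whitney", 1),
    c("insulin_30", "Insulin 30' (mIU/L)", "mann_whitney", 1),
    c("insulin_120", "Insulin 120' (mIU/L)", "mann_whitney", 2),
    c("insulin_mean", "Insulin average (mIU/L)", "mann_whitney", 2),
    c("homa_ir", "HOMA IR", "mann_whitney", 2),
    c("hba1c", "HbA1c (%)", "t_test", 2),
    c("glyco_label", "Glycoregulation impairment", "fisher_exact", 0),
    c("crp", "CRP (mg/L)", "mann_whitney", 1),
    c("urea", "Urea (mmol/L)", "t_test", 1),
    c("creatinine", "Creatinine (umol/L)", "t_test", 1),
    c("creatinine_clearance", "Creatinine clearance (mL/min)", "t_test", 1),
    c("microalbuminuria", "Microalbuminuria (mg/24 h)", "mann_whitney", 2),
    c("alt", "ALT (U/L)", "mann_whitney", 0),
    c("ast", "AST (U/L)", "mann_whitney", 0),
    c("ggt", "Gamma-GT (U/L)", "mann_whitney", 0),
    c("fli", "Fatty liver index", "mann_whitney", 2),
    c("uric_acid", "Uric acid (umol/L)", "t_test", 1),
    c("homocysteine", "Homocysteine (umol/L)", "t_test", 1),
    c("pai1", "PAI-1 (U/mL)", "t_test", 1),
    c("sims", "siMS score", "t_test", 2)
  )
  data.frame(variable = s[, 1], label = s[, 2], test = s[, 3],
             digits = as.integer(s[, 4]), stringsAsFactors = FALSE)
}

#' Baseline characteristics table with age-group comparisons
#'
#' One row per variable of [table1_spec()] (or a custom map), comparing
#' the two levels of `by` with the mapped test. Variables absent from the
#' cohort are skipped with a warning.
#'
#' @param cohort A scored, classified cohort data frame.
#' @param by Name of the two-level grouping column (default
#'   `"age_group"`).
#' @param spec Variable-to-test map, defaults to [table1_spec()].
#' @return Data frame of comparison rows (see [compare_groups()]) plus a
#'   `label` column.
#' @export
build_table1 <- function(cohort, by = "age_group", spec = table1_spec()) {
  if (is.null(cohort[[by]]) || length(unique(stats::na.omit(cohort[[by]]))) < 2) {
    stop(sprintf("cohort must contain a two-level `%s` column", by),
         call. = FALSE)
  }
  rows <- vector("list", nrow(spec))
  for (i in seq_len(nrow(spec))) {
    v <- spec$variable[i]
    if (is.null(cohort[[v]])) {
      warning(sprintf("variable `%s` not in cohort; skipped", v),
              call. = FALSE)
      next
    }
    data <- cohort
    if (v == "obesity_label") {
      data[[v]] <- factor(data[[v]] == "obese", levels = c(FALSE, TRUE),
                          labels = c("not obese", "obese"))
    }
    row <- compare_groups(data, by, v, test = spec$test[i])
    row$label <- spec$label[i]
    rows[[i]] <- row
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' siMS score by glycoregulation category
#'
#' Mean +/- SD of the siMS score within each OGTT category (normal, IFG,
#' IGT, newly detected DM), overall and per age group. Empty cells are
#' omitted; single-subject cells report an `NA` SD.
#'
#' @param cohort A scored cohort with `glyco_label` and `age_group`
#'   columns.
#' @return Long data frame: `age_group` (`"total"`, `"young"`,
#'   `"older"`), `glyco_label`, `n`, `mean`, `sd`.
#' @export
sims_by_glyco <- function(cohort) {
  stopifnot(!is.null(cohort$sims), !is.null(cohort$glyco_label))
  groups <- list(total = rep(TRUE, nrow(cohort)))
  if (!is.null(cohort$age_group)) {
    for (g in c("young", "older")) {
      groups[[g]] <- !is.na(cohort$age_group) & cohort$age_group == g
    }
  }
  cats <- c("normal", "IFG", "IGT", "DM")
  out <- list()
  for (gname in names(groups)) {
    sel <- groups[[gname]]
    for (cat in cats) {
      s <- cohort$sims[sel & !is.na(cohort$glyco_label) &
                         cohort$glyco_label == cat]
      s <- s[!is.na(s)]
      if (length(s) == 0) next
      out[[length(out) + 1]] <- data.frame(
        age_group = gname, glyco_label = cat, n = length(s),
        mean = mean(s), sd = if (length(s) > 1) stats::sd(s) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Correlation map for the siMS screen
#'
#' Which covariates the siMS score is correlated against and with which
#' method: Pearson for approximately symmetric variables and the
#' log-transformed ones, Spearman for skewed raw variables.
#'
#' @return Data frame with columns `variable`, `method`.
#' @export
table2_spec <- function() {
  pearson <- c("weight", "bmi", "waist", "sbp", "dbp", "glucose_0",
               "hba1c", "cholesterol", "hdl", "ldl", "uric_acid", "pai1",
               "homocysteine", "creatinine", "creatinine_clearance",
               "log_homa_ir", "log_alt", "log_ggt", "log_fli", "log_crp")
  spearman <- c("triglycerides", "insulin_0", "insulin_mean", "homa_ir",
                "alt", "ggt", "fli", "crp", "microalbuminuria")
  data.frame(variable = c(pearson, spearman),
             method = c(rep("pearson", length(pearson)),
                        rep("spearman", length(spearman))),
             stringsAsFactors = FALSE)
}

#' siMS correlation screen
#'
#' Correlates the siMS score with every covariate of [table2_spec()],
#' overall and within each level of `by`. Raw p-values are reported (the
#' source reports unadjusted p-values); Benjamini-Hochberg adjusted
#' values can be appended with `adjust = "BH"`. Rows with p below
#' `alpha` are annotated as significant; nothing is filtered.
#'
#' @param cohort A scored cohort.
#' @param by Optional grouping column (default `"age_group"`); use `NULL`
#'   for overall only.
#' @param spec Correlation map, defaults to [table2_spec()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @param alpha Significance annotation threshold (default 0.05).
#' @return Data frame of correlation rows with `group` and `significant`
#'   columns (and `p_adjusted` if requested).
#' @export
build_correlations <- function(cohort, by = "age_group",
                               spec = table2_spec(), adjust = "none",
                               alpha = 0.05) {
  groups <- list(total = rep(TRUE, nrow(cohort)))
  if (!is.null(by) && !is.null(cohort[[by]])) {
    for (g in sort(unique(stats::na.omit(as.character(cohort[[by]]))))) {
      groups[[g]] <- !is.na(cohort[[by]]) & cohort[[by]] == g
    }
  }
  out <- list()
  for (gname in names(groups)) {
    sub <- cohort[groups[[gname]], , drop = FALSE]
    for (i in seq_len(nrow(spec))) {
      v <- spec$variable[i]
      if (is.null(sub[[v]])) {
        warning(sprintf("variable `%s` not in cohort; skipped", v),
                call. = FALSE)
        next
      }
      row <- tryCatch(correlate(sub, y = v, method = spec$method[i]),
                      error = function(e) {
                        warning(sprintf(
                          "correlation of `%s` in group `%s` skipped: %s",
                          v, gname, conditionMessage(e)), call. = FALSE)
                        NULL
                      })
      if (is.null(row)) next
      row$group <- gname
      out[[length(out) + 1]] <- row
    }
  }
  res <- do.call(rbind, out)
  if (identical(adjust, "BH")) {
    res$p_adjusted <- stats::ave(res$p_value, res$group,
                                 FUN = function(p) stats::p.adjust(p, "BH"))
  }
  res$significant <- !is.na(res$p_value) & res$p_value < alpha
  res
}
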