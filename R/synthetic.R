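# Seeded Gaussian-copula cohort generator. Marginals are transcribed from
# the published age-group summary columns (normal rows as mean +/- SD,
# skewed rows as median and quartiles inverted to log-normal parameters);
# dependence is a documented default latent correlation matrix, since the
# source reports marginals only.

Z75 <- stats::qnorm(0.75)

#' Log-normal parameters from median and quartiles
#'
#' Inverts median (Q1--Q3) reporting: for a log-normal variable,
#' `mu = log(median)` and `sigma = (log(q3) - log(q1)) / (2 * z_0.75)`
#' with `z_0.75 = qnorm(0.75) ~ 0.67449`. The implied distribution
#' reproduces the three input quantiles.
#'
#' @param median,q1,q3 Median and quartiles on the data scale;
#'   `0 < q1 <= median <= q3`.
#' @return Named numeric vector `c(mu =, sigma =)` (log-scale mean and SD).
#' @export
lognormal_from_quartiles <- function(median, q1, q3) {
  if (!(q1 > 0 && q1 <= median && median <= q3)) {
    stop("quartiles must satisfy 0 < q1 <= median <= q3", call. = FALSE)
  }
  c(mu = log(median), sigma = (log(q3) - log(q1)) / (2 * Z75))
}

#' Marginal specifications
#'
#' Declare one variable's marginal for the cohort generator: `normal`
#' (optionally truncated below at `lower`, a physiologic floor) or
#' log-normal parameterised by its median and quartiles as printed in
#' summary tables.
#'
#' @param name Variable id (a cohort dictionary column).
#' @param mean,sd Mean and SD on the data scale (`sd > 0`).
#' @param lower Truncation floor; sampling uses the exactly truncated
#'   distribution (so the realised mean of a floored variable is the
#'   truncated-normal mean, not `mean`).
#' @param median,q1,q3 Quartile summary for skewed variables.
#' @return A `marginal_spec` list.
#' @export
marginal_normal <- function(name, mean, sd, lower = -Inf) {
  stopifnot(is.character(name), sd > 0, lower < mean)
  structure(list(name = name, family = "normal", mean = mean, sd = sd,
                 lower = lower), class = "marginal_spec")
}

#' @rdname marginal_normal
#' @export
marginal_lognormal <- function(name, median, q1, q3) {
  p <- lognormal_from_quartiles(median, q1, q3)
  structure(list(name = name, family = "lognormal",
                 median = median, q1 = q1, q3 = q3,
                 mu = unname(p["mu"]), sigma = unname(p["sigma"])),
            class = "marginal_spec")
}

# quantile function of a marginal, with optional truncation override
qmarginal <- function(u, spec, lower = NULL, upper = NULL) {
  if (spec$family == "lognormal") {
    return(stats::qlnorm(u, spec$mu, spec$sigma))
  }
  lo <- if (is.null(lower)) spec$lower else lower
  hi <- if (is.null(upper)) Inf else upper
  p_lo <- stats::pnorm(lo, spec$mean, spec$sd)
  p_hi <- stats::pnorm(hi, spec$mean, spec$sd)
  stats::qnorm(p_lo + u * (p_hi - p_lo), spec$mean, spec$sd)
}

#' Repair a correlation matrix to positive definiteness
#'
#' Eigenvalue clipping: eigenvalues below a small floor are raised to it,
#' the matrix is reconstructed and rescaled to unit diagonal, iterating
#' until positive definite. Already-PD input is returned unchanged.
#'
#' @param mat Symmetric matrix with unit diagonal.
#' @param eps Eigenvalue floor (default 1e-6).
#' @return A positive-definite correlation matrix with unit diagonal.
#' @export
repair_correlation <- function(mat, eps = 1e-6) {
  if (!is.matrix(mat) || !isSymmetric(unname(mat), tol = 1e-10)) {
    stop("correlation matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(mat) - 1) > 1e-10)) {
    stop("correlation matrix must have unit diagonal", call. = FALSE)
  }
  e <- eigen(mat, symmetric = TRUE)
  if (min(e$values) > eps) return(mat)
  out <- mat
  for (i in seq_len(100)) {
    e <- eigen(out, symmetric = TRUE)
    if (min(e$values) > eps) break
    v <- pmax(e$values, 2 * eps)
    out <- e$vectors %*% diag(v) %*% t(e$vectors)
    d <- 1 / sqrt(diag(out))
    out <- out * tcrossprod(d)
    diag(out) <- 1
    out <- (out + t(out)) / 2
  }
  if (min(eigen(out, symmetric = TRUE)$values) <= 0) {
    stop("correlation matrix could not be repaired to positive definite",
         call. = FALSE)
  }
  dimnames(out) <- dimnames(mat)
  out
}

# default latent correlation targets: moderate magnitudes encoding the
# directions asserted for metabolic-syndrome physiology (adiposity, insulin
# resistance, dyslipidaemia, inflammation positively coupled; HDL negative).
default_correlation_pairs <- function() {
  p <- rbind(
    c("waist", "bmi", 0.6), c("waist", "height", 0.2),
    c("waist", "insulin_0", 0.4), c("bmi", "insulin_0", 0.4),
    c("waist", "glucose_0", 0.3), c("bmi", "glucose_0", 0.25),
    c("insulin_0", "insulin_30", 0.6), c("insulin_0", "insulin_120", 0.5),
    c("insulin_30", "insulin_120", 0.6),
    c("glucose_0", "glucose_30", 0.45), c("glucose_0", "glucose_120", 0.4),
    c("glucose_30", "glucose_120", 0.5), c("glucose_0", "hba1c", 0.5),
    c("insulin_0", "glucose_0", 0.3),
    c("waist", "triglycerides", 0.3), c("bmi", "triglycerides", 0.25),
    c("triglycerides", "hdl", -0.4), c("triglycerides", "insulin_0", 0.3),
    c("triglycerides", "glucose_0", 0.2),
    c("waist", "hdl", -0.3), c("bmi", "hdl", -0.3),
    c("hdl", "insulin_0", -0.25),
    c("sbp", "dbp", 0.6), c("waist", "sbp", 0.3), c("bmi", "sbp", 0.3),
    c("sbp", "glucose_0", 0.2),
    c("alt", "ast", 0.6), c("alt", "ggt", 0.5), c("ast", "ggt", 0.4),
    c("waist", "ggt", 0.3), c("bmi", "alt", 0.3),
    c("triglycerides", "ggt", 0.3), c("alt", "insulin_0", 0.3),
    c("waist", "crp", 0.3), c("bmi", "crp", 0.35),
    c("crp", "insulin_0", 0.25),
    c("waist", "uric_acid", 0.3), c("uric_acid", "triglycerides", 0.25),
    c("waist", "pai1", 0.3), c("pai1", "triglycerides", 0.25),
    c("pai1", "insulin_0", 0.25), c("pai1", "hdl", -0.2),
    c("microalbuminuria", "glucose_0", 0.2), c("microalbuminuria", "sbp", 0.2),
    c("homocysteine", "sbp", 0.2), c("homocysteine", "creatinine", 0.25),
    c("cholesterol", "ldl", 0.8), c("cholesterol", "triglycerides", 0.3),
    c("cholesterol", "hdl", 0.2), c("ldl", "triglycerides", 0.2),
    c("creatinine", "creatinine_clearance", -0.3), c("urea", "creatinine", 0.4)
  )
  data.frame(a = p[, 1], b = p[, 2], rho = as.numeric(p[, 3]))
}

#' Default latent correlation matrix for the cohort generator
#'
#' Builds the documented default dependence structure over the given
#' variables from pairwise targets (see
#' `simscore:::default_correlation_pairs`) and repairs it to positive
#' definiteness. Pairs not listed are independent on the latent scale.
#'
#' @param vars Character vector of variable names (matrix order).
#' @return A positive-definite correlation matrix.
#' @export
default_correlation <- function(vars) {
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  pr <- default_correlation_pairs()
  for (i in seq_len(nrow(pr))) {
    a <- pr$a[i]; b <- pr$b[i]
    if (a %in% vars && b %in% vars) {
      R[a, b] <- R[b, a] <- pr$rho[i]
    }
  }
  repair_correlation(R)
}

#' Default generator configuration per age group
#'
#' Transcribes the published cohort's age-group summary column into a
#' generator configuration: mean +/- SD rows as (floored) normal
#' marginals, median (Q1--Q3) rows as log-normal marginals, group sizes
#' 167 (young, ages 16--30) and 284 (older, ages 31--75), an even sex
#' mix, glycoregulation subgroup fractions at the published prevalences,
#' and the default latent correlation matrix. Height, which the summary
#' does not report, is normal with mean implied by the printed weight and
#' BMI means (173.1 cm young, 169.7 cm older) and SD 9 cm.
#'
#' @param age_group `"young"` (16--30) or `"older"` (31--75).
#' @param n Cohort size; defaults to the published group size.
#' @param seed Integer RNG seed stored in the config.
#' @return A `sims_generator_config` list with elements `n`, `seed`,
#'   `sex_ratio`, `age_range`, `marginals`, `correlation`,
#'   `ifg_fraction`, `igt_fraction`, `dm_fraction`,
#'   `lipid_therapy_fraction`, `antihypertensive_fraction`.
#' @export
default_config <- function(age_group = c("young", "older"), n = NULL,
                           seed = 1L) {
  age_group <- match.arg(age_group)
  mn <- marginal_normal
  ml <- marginal_lognormal
  if (age_group == "young") {
    marginals <- list(
      mn("height", 173.1, 9, 140),
      mn("bmi", 33.35, 7.07, 15),
      mn("waist", 104.0, 17.7, 50),
      mn("sbp", 124.8, 14.9, 80),
      mn("dbp", 81.6, 10.5, 40),
      mn("cholesterol", 5.1, 1.1, 2),
      mn("hdl", 1.2, 0.4, 0.4),
      mn("ldl", 3.2, 0.9, 0.5),
      ml("triglycerides", 1.39, 1.05, 2.05),
      mn("glucose_0", 4.9, 0.7, 2.5),
      mn("glucose_30", 7.4, 1.5, 2.5),
      mn("glucose_120", 4.9, 1.3, 2.0),
      ml("insulin_0", 22.6, 17.5, 35.3),
      ml("insulin_30", 86.5, 47.0, 149.2),
      ml("insulin_120", 26.75, 17.30, 67.90),
      mn("hba1c", 5.17, 0.48, 3.5),
      ml("crp", 4.4, 2.2, 7.3),
      mn("urea", 4.3, 1.1, 1),
      mn("creatinine", 83.4, 23.5, 30),
      mn("creatinine_clearance", 124.1, 50.0, 20),
      ml("microalbuminuria", 37.9, 9.2, 47.8),
      ml("alt", 26, 18, 40),
      ml("ast", 21, 18, 28),
      ml("ggt", 24, 16, 33),
      mn("uric_acid", 337.0, 90.6, 100),
      mn("homocysteine", 11.3, 3.6, 3),
      mn("pai1", 6.4, 1.3, 0.5)
    )
    n_default <- 167L
    age_range <- c(16L, 30L)
    fr <- c(ifg = 4 / 167, igt = 8 / 167, dm = 0)
    therapy <- c(lipid = 0.05, bp = 0.05)
  } else {
    marginals <- list(
      mn("height", 169.7, 9, 140),
      mn("bmi", 33.18, 6.85, 15),
      mn("waist", 104.6, 15.4, 50),
      mn("sbp", 130.9, 17.4, 80),
      mn("dbp", 84.7, 11.9, 40),
      mn("cholesterol", 6.1, 1.2, 2),
      mn("hdl", 1.3, 0.3, 0.4),
      mn("ldl", 3.8, 1.2, 0.5),
      ml("triglycerides", 1.70, 1.24, 2.35),
      mn("glucose_0", 5.2, 1.1, 2.5),
      mn("glucose_30", 8.2, 1.9, 2.5),
      mn("glucose_120", 5.4, 2.5, 2.0),
      ml("insulin_0", 18.3, 13.2, 25.7),
      ml("insulin_30", 60.3, 39.3, 102.0),
      ml("insulin_120", 27.15, 17.0, 51.05),
      mn("hba1c", 5.60, 0.77, 3.5),
      ml("crp", 3.5, 1.9, 7.2),
      mn("urea", 4.9, 1.3, 1),
      mn("creatinine", 80.9, 16.9, 30),
      mn("creatinine_clearance", 113.3, 51.4, 20),
      ml("microalbuminuria", 17.85, 8.80, 56.3),
      ml("alt", 23, 18, 32),
      ml("ast", 21, 18, 24),
      ml("ggt", 23, 16, 32),
      mn("uric_acid", 316.2, 82.4, 100),
      mn("homocysteine", 12.7, 3.5, 3),
      mn("pai1", 5.8, 1.8, 0.5)
    )
    n_default <- 284L
    age_range <- c(31L, 75L)
    fr <- c(ifg = 4 / 284, igt = 5 / 284, dm = 16 / 284)
    therapy <- c(lipid = 0.15, bp = 0.20)
  }
  names(marginals) <- vapply(marginals, `[[`, character(1), "name")
  cfg <- list(
    age_group = age_group,
    n = if (is.null(n)) n_default else as.integer(n),
    seed = as.integer(seed),
    sex_ratio = 0.5,
    age_range = age_range,
    marginals = marginals,
    correlation = default_correlation(names(marginals)),
    ifg_fraction = unname(fr["ifg"]),
    igt_fraction = unname(fr["igt"]),
    dm_fraction = unname(fr["dm"]),
    lipid_therapy_fraction = unname(therapy["lipid"]),
    antihypertensive_fraction = unname(therapy["bp"])
  )
  class(cfg) <- "sims_generator_config"
  cfg
}

validate_config <- function(config) {
  stopifnot(is.list(config), !is.null(config$n), !is.null(config$marginals))
  vars <- names(config$marginals)
  R <- config$correlation
  if (is.null(R)) {
    R <- diag(length(vars))
    dimnames(R) <- list(vars, vars)
    config$correlation <- R
  }
  if (!identical(rownames(R), vars) || !identical(colnames(R), vars)) {
    stop("correlation matrix dimnames must match the marginal names, in order",
         call. = FALSE)
  }
  config$correlation <- repair_correlation(R)
  for (f in c("ifg_fraction", "igt_fraction", "dm_fraction")) {
    if (is.null(config[[f]])) config[[f]] <- 0
  }
  fr <- c(config$ifg_fraction, config$igt_fraction, config$dm_fraction)
  if (any(fr < 0) || sum(fr) >= 1) {
    stop("glycoregulation subgroup fractions must be >= 0 and sum below 1",
         call. = FALSE)
  }
  if (is.null(config$sex_ratio)) config$sex_ratio <- 0.5
  if (is.null(config$age_range)) config$age_range <- c(16L, 75L)
  if (is.null(config$lipid_therapy_fraction)) config$lipid_therapy_fraction <- 0
  if (is.null(config$antihypertensive_fraction)) config$antihypertensive_fraction <- 0
  config
}

#' Generate a synthetic cohort
#'
#' Gaussian-copula sampling: a latent multivariate normal vector with the
#' configured correlation is drawn per subject and each coordinate is
#' pushed through its marginal's quantile function (exact truncated-normal
#' quantiles where a floor is set, so rank dependence is preserved and the
#' realised marginal is exactly the configured truncated distribution).
#' Weight is computed from generated BMI and height; sex, age and
#' therapy flags are sampled independently. When the glycoregulation
#' subgroup fractions are positive, subjects are first assigned to
#' normal / IFG / IGT / newly-detected-DM subgroups and the glucose
#' coordinates of non-normal subjects are mapped through shifted,
#' range-restricted marginals so that downstream OGTT classification
#' recovers the configured prevalences.
#'
#' Output is deterministic given `config$seed`.
#'
#' @param config A `sims_generator_config`, e.g. from [default_config()].
#' @return A cohort data frame of [cohort_dictionary()] columns with
#'   exactly `config$n` rows.
#' @export
generate_cohort <- function(config) {
  config <- validate_config(config)
  n <- config$n
  if (!is.null(config$seed)) set.seed(config$seed)
  vars <- names(config$marginals)
  p <- length(vars)

  L <- chol(config$correlation)
  Z <- matrix(stats::rnorm(n * p), nrow = n, ncol = p) %*% L
  U <- matrix(stats::pnorm(Z), nrow = n, ncol = p)
  colnames(U) <- vars

  sex <- ifelse(stats::runif(n) < config$sex_ratio, "male", "female")
  age <- if (n > 0) {
    sample(seq(config$age_range[1], config$age_range[2]), n, replace = TRUE)
  } else integer(0)
  glyco <- sample(c("normal", "IFG", "IGT", "DM"), n, replace = TRUE,
                  prob = c(1 - config$ifg_fraction - config$igt_fraction -
                             config$dm_fraction,
                           config$ifg_fraction, config$igt_fraction,
                           config$dm_fraction))

  X <- matrix(NA_real_, nrow = n, ncol = p, dimnames = list(NULL, vars))
  for (v in vars) X[, v] <- qmarginal(U[, v], config$marginals[[v]])

  induce <- config$ifg_fraction + config$igt_fraction + config$dm_fraction > 0
  if (induce && n > 0 && all(c("glucose_0", "glucose_120") %in% vars)) {
    g0 <- config$marginals$glucose_0
    g120 <- config$marginals$glucose_120
    remap <- function(var_spec, u, mean = var_spec$mean, sd = var_spec$sd,
                      lower = var_spec$lower, upper = Inf) {
      qmarginal(u, marginal_normal(var_spec$name, mean, sd,
                                   lower = min(lower, mean - 1e-9)),
                lower = lower, upper = upper)
    }
    i <- glyco == "normal"
    X[i, "glucose_0"] <- remap(g0, U[i, "glucose_0"], upper = 5.6)
    X[i, "glucose_120"] <- remap(g120, U[i, "glucose_120"], upper = 7.8)
    i <- glyco == "IFG"
    X[i, "glucose_0"] <- remap(g0, U[i, "glucose_0"], mean = 6.2, sd = 0.4,
                               lower = 5.6, upper = 7.0)
    X[i, "glucose_120"] <- remap(g120, U[i, "glucose_120"], upper = 7.8)
    # IGT fasting glucose sits in the high-normal/IFG overlap zone
    # (2-h hyperglycaemia is accompanied by elevated fasting values)
    i <- glyco == "IGT"
    X[i, "glucose_0"] <- remap(g0, U[i, "glucose_0"], mean = 5.8, sd = 0.6,
                               upper = 7.0)
    X[i, "glucose_120"] <- remap(g120, U[i, "glucose_120"], mean = 8.8,
                                 sd = 0.9, lower = 7.8, upper = 11.1)
    i <- glyco == "DM"
    X[i, "glucose_0"] <- remap(g0, U[i, "glucose_0"], mean = 7.8, sd = 1.0,
                               lower = 7.0)
    X[i, "glucose_120"] <- remap(g120, U[i, "glucose_120"],
                                 mean = g120$mean + 3, sd = g120$sd,
                                 lower = g120$lower)
  }

  df <- as.data.frame(X)
  df$weight <- df$bmi * (df$height / 100)^2
  prefix <- if (is.null(config$age_group)) "SYN" else
    toupper(substr(config$age_group, 1, 1))
  out <- data.frame(
    id = sprintf("%s%04d", prefix, seq_len(n)),
    sex = sex,
    age = age,
    stringsAsFactors = FALSE
  )
  out$weight <- df$weight
  out$height <- df$height
  for (v in setdiff(vars, c("height", "bmi"))) out[[v]] <- df[[v]]
  out$on_lipid_therapy <- stats::runif(n) < config$lipid_therapy_fraction
  out$on_antihypertensive_therapy <-
    stats::runif(n) < config$antihypertensive_fraction
  out$known_dm2 <- rep(FALSE, n)
  out
}
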