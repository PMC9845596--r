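# Per-subject composite scores and indices: siMS, HOMA-IR, FLI, BMI,
# mean OGTT insulin, and the natural-log transforms used for correlation
# screens. All inputs are SI (mmol/L lipids and glucose, mIU/L insulin,
# cm lengths, mmHg pressures).

check_positive <- function(x, name) {
  if (is.logical(x) && all(is.na(x))) x <- as.numeric(x)
  if (!is.numeric(x)) {
    stop(sprintf("`%s` must be numeric", name), call. = FALSE)
  }
  if (any(!is.na(x) & x <= 0)) {
    stop(sprintf("`%s` must be strictly positive", name), call. = FALSE)
  }
  invisible(x)
}

check_sex <- function(sex) {
  if (any(is.na(sex)) || !all(sex %in% c("male", "female"))) {
    stop("`sex` must be \"male\" or \"female\"", call. = FALSE)
  }
  invisible(sex)
}

#' Body mass index
#'
#' BMI is body weight in kilograms divided by the square of body height in
#' metres.
#'
#' @param weight Body weight in kg.
#' @param height Body height in cm.
#' @return BMI in kg/m^2. Vectorised; `NA` inputs give `NA`.
#' @examples
#' compute_bmi(95.5, 169.65)
#' @export
compute_bmi <- function(weight, height) {
  check_positive(weight, "weight")
  check_positive(height, "height")
  weight / (height / 100)^2
}

#' Height implied by weight and BMI
#'
#' Inverts [compute_bmi()]: many clinical summary tables report weight and
#' BMI but not height, while the siMS waist-to-height term needs height.
#'
#' @param weight Body weight in kg.
#' @param bmi Body mass index in kg/m^2.
#' @return Height in cm; round-trips with [compute_bmi()].
#' @export
derive_height <- function(weight, bmi) {
  check_positive(weight, "weight")
  check_positive(bmi, "bmi")
  100 * sqrt(weight / bmi)
}

#' siMS score: continuous quantification of metabolic syndrome
#'
#' Each metabolic syndrome component is normalised by its diagnostic
#' reference value and the normalised components are summed, with waist
#' circumference normalised by half the body height:
#' \deqn{siMS = 2\,WC/height + Gly/5.6 + Tg/1.7 + SBP/130 - HDL/d,}
#' where \eqn{d} is 1.03 for men and 1.3 for women. A subject sitting
#' exactly at every reference value scores 3. The score increases with
#' waist, fasting glucose, triglycerides and systolic pressure and
#' decreases with HDL and height.
#'
#' @param waist Waist circumference, cm.
#' @param height Body height, cm (same unit as waist so the ratio is
#'   unitless).
#' @param glucose_0 Fasting (0-min) plasma glucose, mmol/L.
#' @param triglycerides Serum triglycerides, mmol/L.
#' @param sbp Systolic blood pressure, mmHg.
#' @param hdl HDL cholesterol, mmol/L.
#' @param sex `"male"` or `"female"`; selects the HDL reference (1.03 vs
#'   1.3 mmol/L).
#' @return Dimensionless score, typically 2--6 in obese cohorts.
#' @examples
#' compute_sims(86, 172, 5.6, 1.7, 130, 1.03, "male") # exactly 3
#' @export
compute_sims <- function(waist, height, glucose_0, triglycerides, sbp, hdl,
                         sex) {
  check_positive(waist, "waist")
  check_positive(height, "height")
  check_positive(glucose_0, "glucose_0")
  check_positive(triglycerides, "triglycerides")
  check_positive(sbp, "sbp")
  check_positive(hdl, "hdl")
  check_sex(sex)
  hdl_ref <- ifelse(sex == "male", 1.03, 1.3)
  2 * waist / height + glucose_0 / 5.6 + triglycerides / 1.7 +
    sbp / 130 - hdl / hdl_ref
}

#' HOMA-IR insulin resistance index
#'
#' Homeostatic model assessment: fasting insulin (mIU/L) times fasting
#' glucose (mmol/L) divided by 22.5.
#'
#' @param insulin_0 Fasting insulin, mIU/L.
#' @param glucose_0 Fasting glucose, mmol/L.
#' @return Dimensionless index; > 2.5--3 is commonly read as insulin
#'   resistance.
#' @export
compute_homa_ir <- function(insulin_0, glucose_0) {
  check_positive(insulin_0, "insulin_0")
  check_positive(glucose_0, "glucose_0")
  insulin_0 * glucose_0 / 22.5
}

#' Fatty liver index
#'
#' Logistic score of triglycerides, BMI, GGT and waist circumference
#' predicting hepatic steatosis:
#' \deqn{z = 0.953\ln Tg + 0.139\,BMI + 0.718\ln GGT + 0.053\,WC - 15.745}
#' \deqn{FLI = 100\,e^z / (1 + e^z).}
#'
#' Triglycerides enter in mmol/L, matching how the cohort's lipids are
#' reported; this compresses the index relative to the mg/dL convention
#' (cohort medians sit near 5 rather than near 50), so FLI values here are
#' comparable within the cohort, not against mg/dL-based cutoffs.
#'
#' @param triglycerides Serum triglycerides, mmol/L.
#' @param bmi Body mass index, kg/m^2.
#' @param ggt Gamma-glutamyl transpeptidase, U/L.
#' @param waist Waist circumference, cm.
#' @return FLI in (0, 100), strictly increasing in every argument.
#' @export
compute_fli <- function(triglycerides, bmi, ggt, waist) {
  check_positive(triglycerides, "triglycerides")
  check_positive(bmi, "bmi")
  check_positive(ggt, "ggt")
  check_positive(waist, "waist")
  z <- 0.953 * log(triglycerides) + 0.139 * bmi + 0.718 * log(ggt) +
    0.053 * waist - 15.745
  100 * stats::plogis(z)
}

#' Mean OGTT insulin
#'
#' Unweighted arithmetic mean of the 0-, 30- and 120-minute insulin values
#' of a 75 g oral glucose tolerance test.
#'
#' @param insulin_0,insulin_30,insulin_120 Insulin at the three OGTT time
#'   points, mIU/L. A missing time point yields `NA` rather than an error.
#' @return Mean insulin, mIU/L.
#' @export
compute_insulin_mean <- function(insulin_0, insulin_30, insulin_120) {
  check_positive(insulin_0, "insulin_0")
  check_positive(insulin_30, "insulin_30")
  check_positive(insulin_120, "insulin_120")
  (insulin_0 + insulin_30 + insulin_120) / 3
}

safe_log <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x) & x > 0
  out[ok] <- log(x[ok])
  out
}

#' Score a single patient record
#'
#' Computes every derived index the record supports: siMS, HOMA-IR, FLI,
#' BMI, mean OGTT insulin and natural-log transforms (log ALT, log GGT,
#' log FLI, log CRP, log HOMA-IR). Fields whose inputs are missing are
#' returned as `NA` rather than raising; height is derived from weight and
#' BMI when absent. Sex is required because the siMS HDL reference is
#' sex-specific.
#'
#' @param record A named list or one-row data frame with (a subset of) the
#'   cohort dictionary fields; see [cohort_dictionary()].
#' @return A named list (class `"score_panel"`) of derived quantities.
#' @export
score_record <- function(record) {
  record <- as.list(record)
  get1 <- function(name) {
    v <- record[[name]]
    if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v[[1]])
  }
  sex <- record[["sex"]]
  if (is.null(sex) || is.na(sex)) {
    stop("record lacks `sex`, required for the siMS score", call. = FALSE)
  }
  check_sex(sex)

  weight <- get1("weight")
  height <- get1("height")
  bmi <- get1("bmi")
  if (is.na(bmi) && !is.na(weight) && !is.na(height)) {
    bmi <- compute_bmi(weight, height)
  }
  if (is.na(height) && !is.na(weight) && !is.na(bmi)) {
    height <- derive_height(weight, bmi)
  }

  maybe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  sims <- maybe(compute_sims(get1("waist"), height, get1("glucose_0"),
                             get1("triglycerides"), get1("sbp"),
                             get1("hdl"), sex))
  homa <- maybe(compute_homa_ir(get1("insulin_0"), get1("glucose_0")))
  fli <- maybe(compute_fli(get1("triglycerides"), bmi, get1("ggt"),
                           get1("waist")))
  ins_mean <- maybe(compute_insulin_mean(get1("insulin_0"),
                                         get1("insulin_30"),
                                         get1("insulin_120")))
  panel <- list(
    sims = sims,
    homa_ir = homa,
    fli = fli,
    bmi = bmi,
    insulin_mean = ins_mean,
    log_alt = safe_log(get1("alt")),
    log_ggt = safe_log(get1("ggt")),
    log_fli = safe_log(fli),
    log_crp = safe_log(get1("crp")),
    log_homa_ir = safe_log(homa)
  )
  class(panel) <- "score_panel"
  panel
}

#' Score every record of a cohort
#'
#' Vectorised version of [score_record()]: appends the derived-score
#' columns (`bmi`, `sims`, `homa_ir`, `fli`, `insulin_mean`, `log_*`) to a
#' cohort data frame. Rows with missing inputs get `NA` in the affected
#' columns; non-positive measurement values are treated as missing with a
#' warning.
#'
#' @param cohort A cohort data frame (see [cohort_dictionary()]); must
#'   contain `sex`.
#' @return The cohort with score columns appended.
#' @export
score_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  if (is.null(cohort$sex)) {
    stop("cohort lacks `sex`, required for the siMS score", call. = FALSE)
  }
  check_sex(cohort$sex)

  num <- function(name) {
    v <- cohort[[name]]
    if (is.null(v)) return(rep(NA_real_, nrow(cohort)))
    v <- as.numeric(v)
    bad <- !is.na(v) & v <= 0
    if (any(bad)) {
      warning(sprintf("%d non-positive value(s) in `%s` treated as missing",
                      sum(bad), name), call. = FALSE)
      v[bad] <- NA_real_
    }
    v
  }

  weight <- num("weight")
  height <- num("height")
  bmi <- num("bmi")
  bmi <- ifelse(is.na(bmi) & !is.na(weight) & !is.na(height),
                weight / (height / 100)^2, bmi)
  height <- ifelse(is.na(height) & !is.na(weight) & !is.na(bmi),
                   100 * sqrt(weight / bmi), height)

  waist <- num("waist"); g0 <- num("glucose_0"); tg <- num("triglycerides")
  sbp <- num("sbp"); hdl <- num("hdl"); ggt <- num("ggt")
  ins0 <- num("insulin_0"); ins30 <- num("insulin_30")
  ins120 <- num("insulin_120"); crp <- num("crp"); alt <- num("alt")

  hdl_ref <- ifelse(cohort$sex == "male", 1.03, 1.3)
  out <- cohort
  out$bmi <- bmi
  out$height <- height
  out$sims <- 2 * waist / height + g0 / 5.6 + tg / 1.7 + sbp / 130 -
    hdl / hdl_ref
  out$homa_ir <- ins0 * g0 / 22.5
  z <- 0.953 * safe_log(tg) + 0.139 * bmi + 0.718 * safe_log(ggt) +
    0.053 * waist - 15.745
  out$fli <- 100 * stats::plogis(z)
  out$insulin_mean <- (ins0 + ins30 + ins120) / 3
  out$log_alt <- safe_log(alt)
  out$log_ggt <- safe_log(ggt)
  out$log_fli <- safe_log(out$fli)
  out$log_crp <- safe_log(crp)
  out$log_homa_ir <- safe_log(out$homa_ir)
  out
}
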