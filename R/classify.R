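# IDF metabolic-syndrome components and labels, OGTT glycoregulation
# categories, obesity grade and age-group assignment.

#' Evaluate the five IDF metabolic-syndrome component criteria
#'
#' Component thresholds (European IDF definition as applied here):
#' waist circumference >= 94 cm (men) / >= 80 cm (women); triglycerides
#' >= 1.7 mmol/L or lipid-lowering therapy; HDL < 1.03 (men) / < 1.29
#' (women) mmol/L or lipid-lowering therapy; SBP >= 135 or DBP >= 85 mmHg
#' or antihypertensive therapy; fasting glucose >= 5.6 mmol/L or known
#' type-2 diabetes. The blood-pressure thresholds are configurable.
#'
#' @param sex `"male"` or `"female"`.
#' @param waist Waist circumference, cm.
#' @param triglycerides Triglycerides, mmol/L.
#' @param hdl HDL cholesterol, mmol/L.
#' @param sbp,dbp Systolic/diastolic blood pressure, mmHg.
#' @param glucose_0 Fasting glucose, mmol/L.
#' @param on_lipid_therapy,on_antihypertensive_therapy,known_dm2 Logical
#'   therapy / diagnosis flags (default `FALSE`).
#' @param sbp_cutoff,dbp_cutoff Blood-pressure component thresholds
#'   (default 135/85 mmHg).
#' @return A data frame with logical columns `wc_flag`, `tg_flag`,
#'   `hdl_flag`, `bp_flag`, `gly_flag` and integer `n_criteria`.
#' @export
evaluate_idf_components <- function(sex, waist, triglycerides, hdl, sbp, dbp,
                                    glucose_0,
                                    on_lipid_therapy = FALSE,
                                    on_antihypertensive_therapy = FALSE,
                                    known_dm2 = FALSE,
                                    sbp_cutoff = 135, dbp_cutoff = 85) {
  check_sex(sex)
  args <- list(waist = waist, triglycerides = triglycerides, hdl = hdl,
               sbp = sbp, dbp = dbp, glucose_0 = glucose_0)
  missing_fields <- names(args)[vapply(args, function(x)
    is.null(x) || any(is.na(x)), logical(1))]
  if (length(missing_fields)) {
    stop("missing fields required for IDF components: ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  as_flag <- function(x) {
    x <- rep_len(as.logical(x), length(waist))
    x[is.na(x)] <- FALSE
    x
  }
  on_lipid_therapy <- as_flag(on_lipid_therapy)
  on_antihypertensive_therapy <- as_flag(on_antihypertensive_therapy)
  known_dm2 <- as_flag(known_dm2)

  wc_flag <- ifelse(sex == "male", waist >= 94, waist >= 80)
  tg_flag <- triglycerides >= 1.7 | on_lipid_therapy
  hdl_flag <- ifelse(sex == "male", hdl < 1.03, hdl < 1.29) |
    on_lipid_therapy
  bp_flag <- sbp >= sbp_cutoff | dbp >= dbp_cutoff |
    on_antihypertensive_therapy
  gly_flag <- glucose_0 >= 5.6 | known_dm2
  data.frame(wc_flag = wc_flag, tg_flag = tg_flag, hdl_flag = hdl_flag,
             bp_flag = bp_flag, gly_flag = gly_flag,
             n_criteria = as.integer(wc_flag) + tg_flag + hdl_flag +
               bp_flag + gly_flag)
}

#' Metabolic syndrome / pre-MS label from IDF component flags
#'
#' Central obesity (the waist criterion) is mandatory under the IDF
#' definition: MS requires `wc_flag` plus at least two of the other four
#' components. Subjects with at least one component but not MS are
#' labelled pre-MS; subjects with no component at all `no_criteria`
#' (such subjects do not occur in the source cohort, which was recruited
#' with at least one criterion, but the label keeps the rule total).
#'
#' @param flags Data frame (or list) with logical `wc_flag`, `tg_flag`,
#'   `hdl_flag`, `bp_flag`, `gly_flag`, as from
#'   [evaluate_idf_components()].
#' @return Character vector with levels `"MS"`, `"pre_MS"`,
#'   `"no_criteria"`.
#' @export
classify_ms <- function(flags) {
  flags <- as.data.frame(flags)
  need <- c("wc_flag", "tg_flag", "hdl_flag", "bp_flag", "gly_flag")
  stopifnot(all(need %in% names(flags)))
  n_other <- flags$tg_flag + flags$hdl_flag + flags$bp_flag + flags$gly_flag
  n_total <- n_other + flags$wc_flag
  ifelse(flags$wc_flag & n_other >= 2, "MS",
         ifelse(n_total >= 1, "pre_MS", "no_criteria"))
}

#' Glycoregulation category from the OGTT
#'
#' Categories from fasting and 2-hour glucose of a 75 g OGTT, with
#' standard WHO/ADA thresholds and precedence DM > IGT > IFG so each
#' subject gets exactly one label: DM if previously diagnosed, fasting
#' glucose >= 7.0 mmol/L or 2-h glucose >= 11.1 mmol/L; else IGT if 2-h
#' glucose in [7.8, 11.1); else IFG if fasting glucose in [5.6, 7.0);
#' else normal.
#'
#' @param glucose_0 Fasting glucose, mmol/L.
#' @param glucose_120 2-hour OGTT glucose, mmol/L; may be `NA` only for
#'   known diabetics.
#' @param known_dm2 Logical, previously diagnosed type-2 diabetes.
#' @return Character vector with levels `"normal"`, `"IFG"`, `"IGT"`,
#'   `"DM"`; `NA` where the 2-h value is missing without known diabetes.
#' @export
classify_glycoregulation <- function(glucose_0, glucose_120,
                                     known_dm2 = FALSE) {
  known_dm2 <- rep_len(as.logical(known_dm2), length(glucose_0))
  known_dm2[is.na(known_dm2)] <- FALSE
  out <- rep(NA_character_, length(glucose_0))
  dm <- known_dm2 |
    (!is.na(glucose_0) & glucose_0 >= 7.0) |
    (!is.na(glucose_120) & glucose_120 >= 11.1)
  out[dm] <- "DM"
  rest <- !dm & !is.na(glucose_0) & !is.na(glucose_120)
  out[rest & glucose_120 >= 7.8] <- "IGT"
  out[rest & glucose_120 < 7.8 & glucose_0 >= 5.6] <- "IFG"
  out[rest & glucose_120 < 7.8 & glucose_0 < 5.6] <- "normal"
  out
}

#' Obesity grade from BMI
#'
#' The cohort inclusion rule is BMI > 25 kg/m^2 (overweight), with
#' BMI > 30 kg/m^2 obese; both inequalities strict. Values at or below 25
#' fall outside the cohort definition and are labelled `out_of_cohort`.
#'
#' @param bmi Body mass index, kg/m^2.
#' @return Character vector: `"obese"`, `"overweight"` or
#'   `"out_of_cohort"`.
#' @export
classify_obesity <- function(bmi) {
  ifelse(is.na(bmi), NA_character_,
         ifelse(bmi > 30, "obese",
                ifelse(bmi > 25, "overweight", "out_of_cohort")))
}

#' Age-group assignment
#'
#' The study splits its cohort at age 30: group I (young) is 16--30
#' years, group II (older) 31--75 years.
#'
#' @param age Age in years.
#' @return `"young"` for age <= 30, `"older"` otherwise.
#' @export
assign_age_group <- function(age) {
  check_positive(age, "age")
  ifelse(is.na(age), NA_character_, ifelse(age <= 30, "young", "older"))
}

#' Classify every record of a cohort
#'
#' Appends the IDF component flags, the MS / pre-MS label, the OGTT
#' glycoregulation label, the obesity grade and the age group to a scored
#' cohort.
#'
#' @param cohort A cohort data frame; scoring columns (`bmi`) are added
#'   via [score_cohort()] if absent.
#' @inheritParams evaluate_idf_components
#' @return The cohort with columns `wc_flag` ... `gly_flag`,
#'   `n_criteria`, `ms_label`, `glyco_label`, `obesity_label`,
#'   `age_group` appended.
#' @export
classify_cohort <- function(cohort, sbp_cutoff = 135, dbp_cutoff = 85) {
  stopifnot(is.data.frame(cohort))
  if (is.null(cohort$bmi)) cohort <- score_cohort(cohort)
  lt <- if (is.null(cohort$on_lipid_therapy)) FALSE else
    cohort$on_lipid_therapy
  at <- if (is.null(cohort$on_antihypertensive_therapy)) FALSE else
    cohort$on_antihypertensive_therapy
  dm2 <- if (is.null(cohort$known_dm2)) FALSE else cohort$known_dm2
  flags <- evaluate_idf_components(
    cohort$sex, cohort$waist, cohort$triglycerides, cohort$hdl,
    cohort$sbp, cohort$dbp, cohort$glucose_0,
    on_lipid_therapy = lt, on_antihypertensive_therapy = at,
    known_dm2 = dm2, sbp_cutoff = sbp_cutoff, dbp_cutoff = dbp_cutoff)
  out <- cbind(cohort, flags)
  out$ms_label <- classify_ms(flags)
  out$glyco_label <- classify_glycoregulation(cohort$glucose_0,
                                              cohort$glucose_120, dm2)
  out$obesity_label <- classify_obesity(out$bmi)
  out$age_group <- assign_age_group(cohort$age)
  out
}
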