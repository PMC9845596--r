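# Cohort CSV dialect (RFC-4180, UTF-8, "." decimal), the data dictionary,
# and the end-to-end pipeline driver.

#' Cohort data dictionary
#'
#' Column names, types and units of the cohort CSV dialect. Measurement
#' columns are SI as reported clinically in Europe (mmol/L lipids and
#' glucose, mIU/L insulin, cm, mmHg); derived and label columns are
#' appended by [score_cohort()] and [classify_cohort()].
#'
#' @return Data frame with columns `column`, `type`, `unit`,
#'   `description`.
#' @export
cohort_dictionary <- function() {
  d <- rbind(
    c("id", "character", "", "subject identifier (unique)"),
    c("sex", "character", "", "male or female"),
    c("age", "numeric", "years", "age at examination"),
    c("weight", "numeric", "kg", "body weight"),
    c("height", "numeric", "cm", "body height"),
    c("waist", "numeric", "cm", "waist circumference"),
    c("sbp", "numeric", "mmHg", "systolic blood pressure"),
    c("dbp", "numeric", "mmHg", "diastolic blood pressure"),
    c("glucose_0", "numeric", "mmol/L", "fasting OGTT glucose"),
    c("glucose_30", "numeric", "mmol/L", "30-min OGTT glucose"),
    c("glucose_120", "numeric", "mmol/L", "120-min OGTT glucose"),
    c("insulin_0", "numeric", "mIU/L", "fasting OGTT insulin"),
    c("insulin_30", "numeric", "mIU/L", "30-min OGTT insulin"),
    c("insulin_120", "numeric", "mIU/L", "120-min OGTT insulin"),
    c("cholesterol", "numeric", "mmol/L", "total cholesterol"),
    c("hdl", "numeric", "mmol/L", "HDL cholesterol"),
    c("ldl", "numeric", "mmol/L", "LDL cholesterol"),
    c("triglycerides", "numeric", "mmol/L", "serum triglycerides"),
    c("hba1c", "numeric", "%", "glycated haemoglobin"),
    c("crp", "numeric", "mg/L", "C-reactive protein"),
    c("pai1", "numeric", "U/mL", "plasminogen activator inhibitor-1"),
    c("homocysteine", "numeric", "umol/L", "total homocysteine"),
    c("uric_acid", "numeric", "umol/L", "serum uric acid"),
    c("alt", "numeric", "U/L", "alanine aminotransferase"),
    c("ast", "numeric", "U/L", "aspartate aminotransferase"),
    c("ggt", "numeric", "U/L", "gamma-glutamyl transpeptidase"),
    c("urea", "numeric", "mmol/L", "serum urea"),
    c("creatinine", "numeric", "umol/L", "serum creatinine"),
    c("creatinine_clearance", "numeric", "mL/min", "creatinine clearance"),
    c("microalbuminuria", "numeric", "mg/24h", "24-h urinary albumin"),
    c("on_lipid_therapy", "logical", "", "lipid-lowering therapy"),
    c("on_antihypertensive_therapy", "logical", "", "antihypertensive therapy"),
    c("known_dm2", "logical", "", "previously diagnosed type-2 diabetes"),
    c("bmi", "numeric", "kg/m2", "body mass index (derived)"),
    c("sims", "numeric", "", "siMS score (derived)"),
    c("homa_ir", "numeric", "", "HOMA-IR (derived)"),
    c("fli", "numeric", "", "fatty liver index (derived)"),
    c("insulin_mean", "numeric", "mIU/L", "mean OGTT insulin (derived)"),
    c("log_alt", "numeric", "", "log ALT (derived)"),
    c("log_ggt", "numeric", "", "log GGT (derived)"),
    c("log_fli", "numeric", "", "log FLI (derived)"),
    c("log_crp", "numeric", "", "log CRP (derived)"),
    c("log_homa_ir", "numeric", "", "log HOMA-IR (derived)"),
    c("wc_flag", "logical", "", "IDF waist criterion"),
    c("tg_flag", "logical", "", "IDF triglyceride criterion"),
    c("hdl_flag", "logical", "", "IDF HDL criterion"),
    c("bp_flag", "logical", "", "IDF blood-pressure criterion"),
    c("gly_flag", "logical", "", "IDF glucose criterion"),
    c("n_criteria", "numeric", "", "number of IDF criteria met"),
    c("ms_label", "character", "", "MS / pre_MS / no_criteria"),
    c("glyco_label", "character", "", "normal / IFG / IGT / DM"),
    c("obesity_label", "character", "", "overweight / obese / out_of_cohort"),
    c("age_group", "character", "", "young (<=30) / older (31+)")
  )
  data.frame(column = d[, 1], type = d[, 2], unit = d[, 3],
             description = d[, 4], stringsAsFactors = FALSE)
}

#' Read a cohort CSV
#'
#' Reads the cohort dialect (header row, `.` decimal, UTF-8). Column
#' names are matched case-insensitively against [cohort_dictionary()];
#' unknown columns are preserved with a warning. `id`, `sex` and `age`
#' are mandatory. Sex accepts `male`/`female` and `M`/`F`. In lenient
#' mode unparseable cells become `NA` with a warning; in strict mode they
#' raise an error naming row and column.
#'
#' @param path CSV file path.
#' @param strict Error on unparseable cells (default `FALSE`).
#' @return A cohort data frame.
#' @export
read_cohort <- function(path, strict = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  dict <- cohort_dictionary()
  nm <- names(raw)
  canon <- dict$column[match(tolower(nm), tolower(dict$column))]
  unknown <- nm[is.na(canon)]
  if (length(unknown)) {
    warning("unknown column(s) preserved as-is: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  names(raw) <- ifelse(is.na(canon), nm, canon)
  mandatory <- c("id", "sex", "age")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss)) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  parse_col <- function(x, col, type) {
    if (type == "numeric") {
      v <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & x != "" & is.na(v))
    } else if (type == "logical") {
      lx <- tolower(x)
      v <- rep(NA, length(x))
      v[lx %in% c("true", "t", "1", "yes")] <- TRUE
      v[lx %in% c("false", "f", "0", "no")] <- FALSE
      bad <- which(!is.na(x) & x != "" & is.na(v))
    } else {
      return(ifelse(x == "", NA_character_, x))
    }
    if (length(bad)) {
      msg <- sprintf("unparseable value %s in column `%s`, row %s",
                     dQuote(x[bad[1]]), col, bad[1])
      if (strict) stop(msg, call. = FALSE)
      warning(paste0(msg, "; set to NA"), call. = FALSE)
    }
    v
  }
  for (col in names(raw)) {
    i <- match(col, dict$column)
    if (is.na(i)) next
    raw[[col]] <- parse_col(raw[[col]], col, dict$type[i])
  }
  sx <- tolower(raw$sex)
  sx[sx == "m"] <- "male"
  sx[sx == "f"] <- "female"
  raw$sex <- sx
  if (anyDuplicated(stats::na.omit(raw$id))) {
    warning("duplicate subject ids present", call. = FALSE)
  }
  raw
}

#' Write a cohort CSV
#'
#' RFC-4180 CSV with `.` decimal and empty string for missing values;
#' round-trips through [read_cohort()].
#'
#' @param cohort A cohort data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulate (or read) a cohort, score it, classify it, and write the
#' analysis artifacts: the scored and labelled cohort
#' (`cohort_scored.csv`), the baseline-characteristics comparisons
#' (`table1.csv`), siMS by glycoregulation category (`table2.csv`), the
#' correlation screen (`correlations.csv`), a markdown report
#' (`report.md`) and a JSON run log (`run_log.json`) recording the seed
#' and package version. Output is deterministic given the seed.
#'
#' @param input One of: a generator config ([default_config()]), a list
#'   of configs (groups are concatenated), a cohort data frame, or a path
#'   to a cohort CSV.
#' @param outdir Output directory, created if needed.
#' @param seed Integer seed overriding the config seed(s); config `i` of
#'   a list gets `seed + i - 1`.
#' @param by Grouping column for the comparison stage (default
#'   `"age_group"`).
#' @return Invisible named list of artifact paths.
#' @export
run_pipeline <- function(input, outdir, seed = NULL, by = "age_group") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  is_config <- function(x) inherits(x, "sims_generator_config")
  if (is.character(input)) {
    cohort <- read_cohort(input)
    say("read cohort: %d rows from %s", nrow(cohort), input)
    source_desc <- list(kind = "csv", path = input)
  } else if (is_config(input) || (is.list(input) && all(vapply(input, is_config, logical(1))))) {
    configs <- if (is_config(input)) list(input) else input
    parts <- vector("list", length(configs))
    for (i in seq_along(configs)) {
      if (!is.null(seed)) configs[[i]]$seed <- as.integer(seed) + i - 1L
      parts[[i]] <- generate_cohort(configs[[i]])
      say("simulated cohort %d: n = %d, seed = %d", i, nrow(parts[[i]]),
          configs[[i]]$seed)
    }
    cohort <- do.call(rbind, parts)
    cohort$id <- sprintf("S%04d", seq_len(nrow(cohort)))
    source_desc <- list(kind = "simulated",
                        seeds = vapply(configs, `[[`, integer(1), "seed"),
                        n = vapply(configs, `[[`, integer(1), "n"))
  } else if (is.data.frame(input)) {
    cohort <- input
    say("using in-memory cohort: %d rows", nrow(cohort))
    source_desc <- list(kind = "data.frame")
  } else {
    stop("`input` must be a config, list of configs, data frame or CSV path",
         call. = FALSE)
  }

  cohort <- score_cohort(cohort)
  cohort <- classify_cohort(cohort)
  say("scored and classified: %d rows, %d MS, %d pre-MS", nrow(cohort),
      sum(cohort$ms_label == "MS", na.rm = TRUE),
      sum(cohort$ms_label == "pre_MS", na.rm = TRUE))

  paths <- list(
    cohort = file.path(outdir, "cohort_scored.csv"),
    table1 = file.path(outdir, "table1.csv"),
    table2 = file.path(outdir, "table2.csv"),
    correlations = file.path(outdir, "correlations.csv"),
    report = file.path(outdir, "report.md"),
    log = file.path(outdir, "run_log.json")
  )
  write_cohort(cohort, paths$cohort)

  t1 <- build_table1(cohort, by = by)
  utils::write.csv(format_numeric_cols(t1), paths$table1, row.names = FALSE)
  t2 <- sims_by_glyco(cohort)
  utils::write.csv(format_numeric_cols(t2), paths$table2, row.names = FALSE)
  corr <- build_correlations(cohort, by = by)
  utils::write.csv(format_numeric_cols(corr), paths$correlations,
                   row.names = FALSE)
  say("comparisons: %d rows; correlations: %d rows", nrow(t1), nrow(corr))

  writeLines(render_report(cohort, t1, t2, corr), paths$report)
  log <- list(
    package = "simscore",
    version = as.character(utils::packageVersion("simscore")),
    seed = if (is.null(seed)) NA else as.integer(seed),
    source = source_desc,
    n = nrow(cohort),
    messages = log_lines
  )
  jsonlite::write_json(log, paths$log, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

# round numeric columns to a fixed precision so equal runs serialize
# byte-identically across platforms
format_numeric_cols <- function(df, digits = 6) {
  for (col in names(df)) {
    if (is.numeric(df[[col]])) df[[col]] <- round(df[[col]], digits)
  }
  df
}

render_report <- function(cohort, t1, t2, corr) {
  fmt_p <- function(p) ifelse(is.na(p), "NA",
                              ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
  lines <- c(
    "# Metabolic syndrome quantification report", "",
    sprintf("Cohort: %d subjects (%d young, %d older); %d MS, %d pre-MS.",
            nrow(cohort),
            sum(cohort$age_group == "young", na.rm = TRUE),
            sum(cohort$age_group == "older", na.rm = TRUE),
            sum(cohort$ms_label == "MS", na.rm = TRUE),
            sum(cohort$ms_label == "pre_MS", na.rm = TRUE)), "",
    "## Age-group comparisons", "",
    sprintf("| Variable | %s | %s | p |", t1$group1[1], t1$group2[1]),
    "|---|---|---|---|",
    sprintf("| %s | %s | %s | %s |", t1$label, t1$summary1, t1$summary2,
            fmt_p(t1$p_value)),
    "", "## siMS score by glycoregulation category", "",
    "| Group | Category | n | siMS |", "|---|---|---|---|",
    sprintf("| %s | %s | %d | %.2f ± %s |", t2$age_group, t2$glyco_label,
            t2$n, t2$mean, ifelse(is.na(t2$sd), "-", sprintf("%.2f", t2$sd))),
    "", "## siMS correlations", "",
    "| Group | Variable | Method | r | p |", "|---|---|---|---|---|",
    sprintf("| %s | %s | %s | %.3f | %s |%s", corr$group, corr$y_variable,
            corr$method, corr$r, fmt_p(corr$p_value),
            ifelse(corr$significant, " *", "")),
    "", "`*` p < 0.05 (annotation only; no filtering or adjustment).")
  lines
}
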