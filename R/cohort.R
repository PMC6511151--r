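# Column typing for the canonical cohort table. Unknown columns pass through.
cohort_numeric_cols <- c(
  "age", "bmi", "waist", "glucose_mgdl", "insulin_uUml", "tc_mgdl",
  "hdl_mgdl", "tg_mgdl", "ldl_mgdl", "crp_mgL", "acr_mg_per_g",
  "ohdg_ng_ml", "urine_creatinine_mg_ml"
)
cohort_logical_cols <- c("current_smoker", "diabetes_meds")

#' Read a cohort table from TSV or CSV
#'
#' Parses the canonical per-subject schema (see [simulate_cohort()] for the
#' column list). `"NA"`, `"."` and empty cells are treated as missing;
#' malformed numeric cells become missing and their count is reported in a
#' message. Genotype columns (any column named like `rs<digits>`) are coerced
#' to integer minor-allele counts. Unknown columns are preserved as-is.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"` or `"csv"`.
#' @return A typed cohort tibble.
#' @export
read_cohort <- function(path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "tsv"
  }
  reader <- if (format == "csv") readr::read_csv else readr::read_tsv
  tab <- reader(path, na = c("NA", ".", ""), col_types = readr::cols(.default = "c"),
                progress = FALSE, show_col_types = FALSE)
  miss <- setdiff(c("subject_id", "sex"), names(tab))
  if (length(miss) > 0) {
    abort(paste0("cohort file is missing mandatory column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(tab$subject_id)) {
    dup <- unique(tab$subject_id[duplicated(tab$subject_id)])
    abort(paste0("duplicate subject_id: ", paste(head(dup, 5), collapse = ", ")))
  }
  if (any(is.na(tab$sex))) abort("sex must be non-missing for every subject")

  n_bad <- 0L
  geno_cols <- grep("^rs[0-9]+$", names(tab), value = TRUE)
  for (cl in intersect(c(cohort_numeric_cols, geno_cols), names(tab))) {
    x <- suppressWarnings(as.numeric(tab[[cl]]))
    n_bad <- n_bad + sum(is.na(x) & !is.na(tab[[cl]]))
    tab[[cl]] <- x
  }
  for (cl in geno_cols) {
    bad <- !is.na(tab[[cl]]) & !tab[[cl]] %in% c(0, 1, 2)
    n_bad <- n_bad + sum(bad)
    tab[[cl]][bad] <- NA_real_
    tab[[cl]] <- as.integer(tab[[cl]])
  }
  for (cl in intersect(cohort_logical_cols, names(tab))) {
    x <- toupper(trimws(tab[[cl]]))
    out <- rep(NA, length(x))
    out[x %in% c("TRUE", "T", "1", "YES")] <- TRUE
    out[x %in% c("FALSE", "F", "0", "NO")] <- FALSE
    n_bad <- n_bad + sum(is.na(out) & !is.na(tab[[cl]]))
    tab[[cl]] <- out
  }
  if (n_bad > 0) {
    inform(paste0(n_bad, " malformed cell(s) set to missing while reading ", path))
  }
  tab
}

#' Write a cohort table
#'
#' @param table Cohort tibble.
#' @param path Output path; format follows the extension (`.csv` for CSV,
#'   anything else is TSV). Missing values are written as `NA`.
#' @return `table`, invisibly.
#' @export
write_cohort <- function(table, path) {
  stop_if_not_cohort(table)
  if (tolower(tools::file_ext(path)) == "csv") {
    readr::write_csv(table, path, na = "NA")
  } else {
    readr::write_tsv(table, path, na = "NA")
  }
  invisible(table)
}

#' Homeostasis model assessment of insulin resistance
#'
#' `HOMA-IR = fasting insulin (uU/mL) x fasting glucose (mmol/L) / 22.5`.
#' Glucose is supplied in mg/dL and converted with 18.016 mg/dL per mmol/L
#' (the molar mass of glucose).
#'
#' @param insulin_uUml Fasting serum insulin, uU/mL (>= 0).
#' @param glucose_mgdl Fasting plasma glucose, mg/dL (>= 0).
#' @return HOMA-IR (dimensionless), vectorised; `NA` propagates.
#' @export
#' @examples
#' compute_homa_ir(7.8, 92) # about 1.77
compute_homa_ir <- function(insulin_uUml, glucose_mgdl) {
  if (any(insulin_uUml < 0, na.rm = TRUE) || any(glucose_mgdl < 0, na.rm = TRUE)) {
    abort("insulin and glucose must be non-negative")
  }
  insulin_uUml * (glucose_mgdl / MGDL_PER_MMOL_GLUCOSE) / 22.5
}

#' Friedewald estimate of LDL cholesterol
#'
#' `LDL-C = TC - HDL-C - TG/5` (all mg/dL), valid only for TG <= 400 mg/dL.
#' Above that threshold the estimate is unreliable and LDL-C must be measured
#' directly: those entries are returned as `NA` and flagged in the
#' `requires_direct` attribute of the result.
#'
#' @param tc,hdl,tg Total cholesterol, HDL-C and triglycerides in mg/dL (>= 0).
#' @return Numeric vector of LDL-C estimates with attribute `requires_direct`
#'   (logical, `TRUE` where TG > 400 mg/dL).
#' @export
compute_friedewald_ldl <- function(tc, hdl, tg) {
  if (any(tc < 0, na.rm = TRUE) || any(hdl < 0, na.rm = TRUE) ||
      any(tg < 0, na.rm = TRUE)) {
    abort("lipid concentrations must be non-negative")
  }
  out <- tc - hdl - tg / 5
  direct <- !is.na(tg) & tg > 400
  out[direct] <- NA_real_
  attr(out, "requires_direct") <- direct
  out
}

#' Add derived clinical variables
#'
#' Computes HOMA-IR, the Friedewald LDL-C (only where `ldl_mgdl` is absent or
#' missing and TG <= 400), creatinine-normalised urinary 8-OHdG (ng/mg,
#' defined only where urine creatinine > 0), and the obesity stratum.
#'
#' @param table Cohort tibble.
#' @param obesity_cutoff BMI cutoff (kg/m^2) separating `obese` from
#'   `nonobese`; defaults to 27 (the Taiwanese Ministry of Health definition).
#' @return The table with columns `homa_ir`, `ldl_mgdl`,
#'   `ohdg_per_creatinine_ng_mg` and `obesity_stratum` added or filled.
#' @export
derive_traits <- function(table, obesity_cutoff = 27) {
  stop_if_not_cohort(table)
  if (all(c("insulin_uUml", "glucose_mgdl") %in% names(table))) {
    table$homa_ir <- compute_homa_ir(table$insulin_uUml, table$glucose_mgdl)
  }
  if (all(c("tc_mgdl", "hdl_mgdl", "tg_mgdl") %in% names(table))) {
    fw <- compute_friedewald_ldl(table$tc_mgdl, table$hdl_mgdl, table$tg_mgdl)
    if (!"ldl_mgdl" %in% names(table)) {
      table$ldl_mgdl <- as.numeric(fw)
    } else {
      fill <- is.na(table$ldl_mgdl)
      table$ldl_mgdl[fill] <- as.numeric(fw)[fill]
    }
  }
  if (all(c("ohdg_ng_ml", "urine_creatinine_mg_ml") %in% names(table))) {
    creat <- table$urine_creatinine_mg_ml
    ratio <- ifelse(!is.na(creat) & creat > 0, table$ohdg_ng_ml / creat, NA_real_)
    table$ohdg_per_creatinine_ng_mg <- ratio
  }
  if ("bmi" %in% names(table)) {
    table$obesity_stratum <- ifelse(is.na(table$bmi), NA_character_,
                                    ifelse(table$bmi >= obesity_cutoff,
                                           "obese", "nonobese"))
  }
  table
}

#' Apply the enrollment exclusion filters
#'
#' Removes subjects who fail any of the study's rules: age below 18 years,
#' CRP above 10 mg/L (acute inflammation), diabetes (fasting glucose at or
#' above 7.0 mmol/L, i.e. 126.1 mg/dL, or regular diabetes medication), or
#' macroalbuminuria (urinary albumin-creatinine ratio above 300 mg/g). A
#' missing value for a rule's field does not trigger that rule. The filter is
#' a pure conjunction, so it is idempotent and order-free; a subject failing
#' several rules is counted once per rule but removed once.
#'
#' @param table Cohort tibble.
#' @return The filtered tibble, with an `exclusion_log` attribute (a list with
#'   per-rule flag counts, total removed, and rows with missing rule fields);
#'   retrieve it with [exclusion_log()].
#' @export
apply_exclusions <- function(table) {
  stop_if_not_cohort(table)
  rule_field <- c(age_lt_18 = "age", crp_gt_10 = "crp_mgL",
                  diabetes = "glucose_mgdl", acr_gt_300 = "acr_mg_per_g")
  get <- function(col) if (col %in% names(table)) table[[col]] else
    rep(NA_real_, nrow(table))
  flags <- list(
    age_lt_18  = !is.na(get("age")) & get("age") < 18,
    crp_gt_10  = !is.na(get("crp_mgL")) & get("crp_mgL") > 10,
    diabetes   = (!is.na(get("glucose_mgdl")) &
                    get("glucose_mgdl") / MGDL_PER_MMOL_GLUCOSE >= 7.0) |
                 (!is.na(get("diabetes_meds")) & get("diabetes_meds") %in% TRUE),
    acr_gt_300 = !is.na(get("acr_mg_per_g")) & get("acr_mg_per_g") > 300
  )
  drop <- Reduce(`|`, flags)
  if (length(drop) == 0) drop <- logical(0)
  log <- list(
    n_input = nrow(table),
    n_removed = sum(drop),
    n_kept = sum(!drop),
    per_rule = lapply(flags, sum),
    n_missing_rule_field = lapply(setNames(as.list(unname(rule_field)),
                                           unname(rule_field)),
                                  function(col) sum(is.na(get(col))))
  )
  out <- table[!drop, , drop = FALSE]
  attr(out, "exclusion_log") <- log
  out
}

#' Retrieve the exclusion log of a filtered cohort
#'
#' @param table A table returned by [apply_exclusions()].
#' @return The exclusion log list, or `NULL` if absent.
#' @export
exclusion_log <- function(table) attr(table, "exclusion_log")

#' Write an exclusion log as JSON
#'
#' @param table A table returned by [apply_exclusions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(table, path) {
  log <- exclusion_log(table)
  if (is.null(log)) abort("table carries no exclusion log; run apply_exclusions() first")
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Add natural-log columns for skewed traits
#'
#' Adds `log_<trait>` columns for the requested traits (keywords from
#' [trait_registry()] or raw column names). Zero or negative values cannot be
#' log-transformed and become missing; their count is reported in a message.
#'
#' @param table Cohort tibble.
#' @param traits Character vector of trait keywords or column names.
#' @return The table with the log columns appended.
#' @export
log_transform_traits <- function(table, traits) {
  n_dropped <- 0L
  for (tr in traits) {
    reg <- trait_registry()
    col <- if (tr %in% reg$trait) reg$column[reg$trait == tr] else tr
    if (col == "ohdg_per_creatinine_ng_mg" && !col %in% names(table)) {
      table <- derive_traits(table)
    }
    if (!col %in% names(table)) abort(paste0("no column '", col, "' to transform"))
    x <- as.numeric(table[[col]])
    bad <- !is.na(x) & x <= 0
    n_dropped <- n_dropped + sum(bad)
    x[bad] <- NA_real_
    table[[paste0("log_", tr)]] <- log(x)
  }
  if (n_dropped > 0) {
    inform(paste0(n_dropped, " non-positive value(s) set to missing before log transform"))
  }
  table
}

#' Split a cohort into strata
#'
#' @param table Cohort tibble.
#' @param by `"sex"` (male/female) or `"obesity"` (BMI at or above vs below
#'   the cutoff).
#' @param bmi_cutoff Obesity cutoff in kg/m^2 (default 27).
#' @return A named list of tibbles forming a partition of the rows with a
#'   non-missing stratifier; subjects with a missing stratifier are dropped
#'   and their count reported in a message.
#' @export
stratify <- function(table, by = c("sex", "obesity"), bmi_cutoff = 27) {
  by <- match.arg(by)
  stop_if_not_cohort(table)
  if (by == "sex") {
    key <- ifelse(sex_indicator(table$sex) == 1, "male", "female")
    levels <- c("male", "female")
  } else {
    if (!"bmi" %in% names(table)) abort("obesity stratification needs a bmi column")
    key <- ifelse(is.na(table$bmi), NA_character_,
                  ifelse(table$bmi >= bmi_cutoff, "obese", "nonobese"))
    levels <- c("obese", "nonobese")
  }
  n_miss <- sum(is.na(key))
  if (n_miss > 0) {
    inform(paste0(n_miss, " subject(s) with missing ", by,
                  " stratifier dropped from strata"))
  }
  out <- lapply(levels, function(lv) table[which(key == lv), , drop = FALSE])
  names(out) <- levels
  out
}
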