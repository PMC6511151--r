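#' Traits known to the analysis layer
#'
#' Maps short trait keywords to cohort-table columns and records whether the
#' trait is analysed on the natural-log scale (skewed biomarkers are; total and
#' LDL cholesterol are approximately symmetric and are analysed raw).
#'
#' @return A tibble with columns `trait`, `column`, `log`, `label`.
#' @export
trait_registry <- function() {
  tibble::tribble(
    ~trait,    ~column,                      ~log,  ~label,
    "tc",      "tc_mgdl",                    FALSE, "Total cholesterol (mg/dL)",
    "ldl",     "ldl_mgdl",                   FALSE, "LDL-C (mg/dL)",
    "hdl",     "hdl_mgdl",                   TRUE,  "HDL-C (mg/dL)",
    "tg",      "tg_mgdl",                    TRUE,  "Triglycerides (mg/dL)",
    "ohdg",    "ohdg_per_creatinine_ng_mg",  TRUE,  "8-OHdG/creatinine (ng/mg)",
    "glucose", "glucose_mgdl",               TRUE,  "Fasting glucose (mg/dL)",
    "insulin", "insulin_uUml",               TRUE,  "Fasting insulin (uU/mL)",
    "crp",     "crp_mgL",                    TRUE,  "CRP (mg/L)",
    "homa",    "homa_ir",                    TRUE,  "HOMA-IR"
  )
}

# Resolve a trait keyword (or a raw column name) against a cohort table,
# returning the analysis-scale numeric vector. Nonpositive values of a
# log-scale trait become missing.
resolve_trait <- function(table, trait) {
  reg <- trait_registry()
  if (trait %in% reg$trait) {
    row <- reg[reg$trait == trait, ]
    col <- row$column
    take_log <- row$log
  } else if (trait %in% names(table)) {
    col <- trait
    take_log <- FALSE
  } else {
    abort(paste0("unknown trait '", trait, "'"))
  }
  if (col == "ohdg_per_creatinine_ng_mg" && !col %in% names(table)) {
    table <- derive_traits(table)
  }
  if (col == "homa_ir" && !col %in% names(table)) {
    table <- derive_traits(table)
  }
  if (!col %in% names(table)) {
    abort(paste0("cohort table has no column '", col, "' for trait '", trait, "'"))
  }
  x <- as.numeric(table[[col]])
  if (take_log) {
    x[!is.na(x) & x <= 0] <- NA_real_
    x <- log(x)
  }
  list(values = x, column = col, log = take_log)
}

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Numeric design column for sex: 1 = male, 0 = female.
sex_indicator <- function(sex) {
  s <- tolower(as.character(sex))
  out <- rep(NA_real_, length(s))
  out[s %in% c("male", "m")] <- 1
  out[s %in% c("female", "f")] <- 0
  out
}

stop_if_not_cohort <- function(table) {
  if (!is.data.frame(table)) abort("expected a cohort data frame")
  miss <- setdiff(c("subject_id", "sex"), names(table))
  if (length(miss) > 0) {
    abort(paste0("cohort table is missing mandatory column(s): ",
                 paste(miss, collapse = ", ")))
  }
  invisible(table)
}

# Restrict a cohort table to a named subgroup.
subgroup_filter <- function(table, subgroup, bmi_cutoff = 27) {
  subgroup <- match.arg(subgroup, c("all", "male", "female", "obese", "nonobese"))
  switch(subgroup,
    all      = table,
    male     = table[which(sex_indicator(table$sex) == 1), , drop = FALSE],
    female   = table[which(sex_indicator(table$sex) == 0), , drop = FALSE],
    obese    = table[which(!is.na(table$bmi) & table$bmi >= bmi_cutoff), , drop = FALSE],
    nonobese = table[which(!is.na(table$bmi) & table$bmi < bmi_cutoff), , drop = FALSE]
  )
}
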