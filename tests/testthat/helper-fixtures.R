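# Small deterministic cohort rows for I/O and filtering tests.
toy_cohort <- function(n = 6) {
  tibble::tibble(
    subject_id = sprintf("T%02d", seq_len(n)),
    sex = rep(c("male", "female"), length.out = n),
    age = seq(30, 30 + n - 1),
    bmi = seq(22, 22 + 0.5 * (n - 1), by = 0.5),
    waist = rep(85, n),
    current_smoker = rep(c(TRUE, FALSE), length.out = n),
    glucose_mgdl = rep(92, n),
    insulin_uUml = rep(7.8, n),
    tc_mgdl = rep(199.3, n),
    hdl_mgdl = rep(54, n),
    tg_mgdl = rep(114.5, n),
    ldl_mgdl = rep(122.4, n),
    crp_mgL = rep(0.6, n),
    acr_mg_per_g = rep(8, n),
    ohdg_ng_ml = rep(32.6, n),
    urine_creatinine_mg_ml = rep(1, n),
    diabetes_meds = rep(FALSE, n),
    rs2043085 = rep(c(0L, 1L, 2L), length.out = n)
  )
}

# Genotype vector from genotype counts (n_MM, n_Mm, n_mm).
geno_from_counts <- function(counts) {
  rep(c(0L, 1L, 2L), times = counts)
}
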