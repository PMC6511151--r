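#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set that drives [simulate_cohort()]. The
#' defaults describe a cohort of 572 adults (51.7% men) genotyped for three
#' candidate SNPs, with log-normal lipid and oxidative-stress biomarkers wired
#' together by the structural suppression model
#'
#' \deqn{\log TG = a_0 + \alpha D + c^T x + \epsilon_{TG}}
#' \deqn{\log HDL = b_0 + \beta \log TG + \gamma' D + c^T x + \epsilon_{HDL}}
#'
#' where `D` is the dominant-coded causal genotype, `x` the covariates
#' (centred age and BMI, sex, smoking), \eqn{\alpha > 0}, \eqn{\beta < 0} and
#' \eqn{\gamma' > 0}. With these signs the indirect effect \eqn{\alpha\beta}
#' is negative while the direct effect \eqn{\gamma'} is positive, so the total
#' genotype effect on log-HDL is attenuated: the mediator acts as a suppressor.
#' The default effect sizes (`alpha = 0.06`, `beta = -0.18`,
#' `gamma_prime = 0.022`) and residual noise scales are the "table5_like"
#' preset; the noise scales are calibrated so that at roughly 300 subjects the
#' standard errors of \eqn{\alpha}, \eqn{\beta} and \eqn{\gamma'} are about
#' 0.021, 0.021 and 0.008 respectively.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param snp_blocks A list of genotype blocks. Each block is either
#'   `list(snps = "rsID", maf = f)` for a SNP simulated at Hardy-Weinberg
#'   equilibrium independently of everything else, or
#'   `list(snps = c("rsA","rsB"), hap_freqs = c("11"=..,"10"=..,"01"=..,"00"=..))`
#'   for a two-SNP block whose haplotypes are drawn from the given frequencies
#'   ("1" marks the minor allele at that locus; frequencies must sum to 1).
#' @param causal_snp Name of the SNP whose dominant coding enters the
#'   structural equations. Must appear in `snp_blocks`.
#' @param alpha Effect of the dominant-coded causal genotype on log-TG.
#' @param beta Effect of log-TG on log-HDL-C.
#' @param gamma_prime Direct genotype effect on log-HDL-C.
#' @param delta_8ohdg Genotype effect on log urinary 8-OHdG/creatinine.
#' @param female_effect_scale Multiplier applied to `alpha`, `gamma_prime`
#'   and `delta_8ohdg` in women (1 = no sex modification).
#' @param obese_alpha_scale Multiplier applied to `alpha` in subjects with
#'   BMI at or above `obesity_cutoff` (1 = no adiposity modification).
#' @param obesity_cutoff BMI cutoff (kg/m^2) used by `obese_alpha_scale`.
#' @param covariate_params Named list of covariate distribution parameters:
#'   `age_mean`, `age_sd`, `bmi_mean`, `bmi_sd`, `bmi_sex_shift` (added to the
#'   BMI mean for men, subtracted for women).
#' @param sex_fraction Proportion of men in (0, 1).
#' @param smoking_prob_by_sex Named probabilities `c(male = , female = )` of
#'   being a current smoker.
#' @param noise_sd_tg,noise_sd_hdl,noise_sd_8ohdg Residual SDs of the three
#'   structural equations (log scale, > 0).
#' @param intercepts Named intercepts of the structural equations on the log
#'   scale (`tg`, `hdl`, `ohdg`), chosen so medians land near 114.5 mg/dL TG,
#'   54 mg/dL HDL-C, and 32.6 ng/mg 8-OHdG/creatinine.
#' @param covariate_effects Named list of per-equation covariate coefficients,
#'   each a numeric vector with entries `age` (per year, centred), `bmi`
#'   (per kg/m^2, centred), `male`, `smoker`.
#' @param missing_rate Probability that an eligible biomarker/genotype cell is
#'   set to missing (missing completely at random), in \[0, 1\].
#' @param seed Integer seed making the cohort fully reproducible.
#'
#' @return An object of class `simulation_config` (a validated named list).
#' @seealso [simulate_cohort()], [read_simulation_config()]
#' @export
#' @examples
#' cfg <- simulation_config(n_subjects = 200, seed = 1)
#' cohort <- simulate_cohort(cfg)
simulation_config <- function(n_subjects = 572,
                              snp_blocks = default_snp_blocks(),
                              causal_snp = "rs2043085",
                              alpha = 0.06,
                              beta = -0.18,
                              gamma_prime = 0.022,
                              delta_8ohdg = 0.08,
                              female_effect_scale = 1,
                              obese_alpha_scale = 1,
                              obesity_cutoff = 27,
                              covariate_params = list(age_mean = 45.7, age_sd = 9.7,
                                                      bmi_mean = 24.2, bmi_sd = 3.3,
                                                      bmi_sex_shift = 0.7),
                              sex_fraction = 296 / 572,
                              smoking_prob_by_sex = c(male = 0.338, female = 0.04),
                              noise_sd_tg = 0.165,
                              noise_sd_hdl = 0.06,
                              noise_sd_8ohdg = 0.44,
                              intercepts = c(tg = 4.62, hdl = 4.90, ohdg = 3.50),
                              covariate_effects = default_covariate_effects(),
                              missing_rate = 0.01,
                              seed = NULL) {
  cfg <- list(
    n_subjects = n_subjects, snp_blocks = snp_blocks, causal_snp = causal_snp,
    alpha = alpha, beta = beta, gamma_prime = gamma_prime,
    delta_8ohdg = delta_8ohdg,
    female_effect_scale = female_effect_scale,
    obese_alpha_scale = obese_alpha_scale, obesity_cutoff = obesity_cutoff,
    covariate_params = covariate_params, sex_fraction = sex_fraction,
    smoking_prob_by_sex = smoking_prob_by_sex,
    noise_sd_tg = noise_sd_tg, noise_sd_hdl = noise_sd_hdl,
    noise_sd_8ohdg = noise_sd_8ohdg,
    intercepts = intercepts, covariate_effects = covariate_effects,
    missing_rate = missing_rate, seed = seed
  )
  validate_simulation_config(cfg)
}

#' Default genotype blocks
#'
#' Two SNPs in strong linkage disequilibrium (haplotype frequencies chosen to
#' give minor-allele frequencies 0.464 and 0.457 with D' close to 1) plus a
#' third SNP simulated independently at MAF 0.363. No published pairwise D'/r2
#' exists for these loci, so the third SNP is left unlinked.
#'
#' @return A list of SNP block specifications (see [simulation_config()]).
#' @export
default_snp_blocks <- function() {
  list(
    list(snps = c("rs2043085", "rs1532085"),
         hap_freqs = c("11" = 0.450, "10" = 0.014, "01" = 0.007, "00" = 0.529)),
    list(snps = "rs1800588", maf = 0.363)
  )
}

#' Default covariate coefficients of the structural equations
#'
#' Small effects (per centred year of age, per centred BMI unit, for male sex
#' and current smoking) so that covariate adjustment is consequential without
#' dominating the genotype signal.
#'
#' @return Named list with elements `tg`, `hdl`, `ohdg`.
#' @export
default_covariate_effects <- function() {
  list(
    tg   = c(age = 0.002, bmi = 0.012, male = 0.15,  smoker = 0.05),
    hdl  = c(age = 0.000, bmi = -0.006, male = -0.15, smoker = -0.02),
    ohdg = c(age = 0.001, bmi = -0.010, male = -0.15, smoker = 0.05)
  )
}

validate_simulation_config <- function(cfg) {
  if (!is.numeric(cfg$n_subjects) || length(cfg$n_subjects) != 1 ||
      cfg$n_subjects < 1 || cfg$n_subjects != round(cfg$n_subjects)) {
    abort("n_subjects must be a positive integer")
  }
  if (!is.list(cfg$snp_blocks) || length(cfg$snp_blocks) == 0) {
    abort("snp_blocks must be a non-empty list")
  }
  all_snps <- character(0)
  for (blk in cfg$snp_blocks) {
    if (!is.list(blk) || is.null(blk$snps)) abort("each SNP block needs a 'snps' field")
    all_snps <- c(all_snps, blk$snps)
    if (length(blk$snps) == 1) {
      if (is.null(blk$maf) || blk$maf < 0 || blk$maf > 1) {
        abort(paste0("block for ", blk$snps, " needs a maf in [0, 1]"))
      }
    } else if (length(blk$snps) == 2) {
      hf <- blk$hap_freqs
      lab <- paste(blk$snps, collapse = "-")
      if (is.null(hf) || length(hf) != 4 ||
          !setequal(names(hf), c("11", "10", "01", "00"))) {
        abort(paste0("block ", lab,
                     " needs hap_freqs named '11','10','01','00'"))
      }
      if (any(hf < 0) || any(hf > 1)) {
        abort(paste0("haplotype frequencies for ", lab, " must lie in [0, 1]"))
      }
      if (abs(sum(hf) - 1) > 1e-12) {
        abort(paste0("haplotype frequencies for SNP pair ", lab,
                     " sum to ", format(sum(hf)), ", not 1"))
      }
    } else {
      abort("SNP blocks support one or two loci")
    }
  }
  if (anyDuplicated(all_snps)) abort("duplicated SNP id across blocks")
  if (!cfg$causal_snp %in% all_snps) {
    abort(paste0("causal_snp '", cfg$causal_snp, "' is not in snp_blocks"))
  }
  for (nm in c("noise_sd_tg", "noise_sd_hdl", "noise_sd_8ohdg")) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0) abort(paste0(nm, " must be > 0"))
  }
  if (cfg$sex_fraction < 0 || cfg$sex_fraction > 1) {
    abort("sex_fraction must lie in [0, 1]")
  }
  if (any(cfg$smoking_prob_by_sex < 0) || any(cfg$smoking_prob_by_sex > 1)) {
    abort("smoking probabilities must lie in [0, 1]")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1) {
    abort("missing_rate must lie in [0, 1]")
  }
  if (cfg$covariate_params$age_sd <= 0 || cfg$covariate_params$bmi_sd <= 0) {
    abort("covariate SDs must be > 0")
  }
  structure(cfg, class = "simulation_config")
}

#' Read a simulation configuration from YAML or JSON
#'
#' Fields present in the file override the defaults of [simulation_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `simulation_config` object.
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such config file: ", path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    abort("config must be a .yaml/.yml or .json file")
  }
  # coerce block/effect lists that arrive as plain lists of lists
  if (!is.null(raw$snp_blocks)) {
    raw$snp_blocks <- lapply(raw$snp_blocks, function(blk) {
      if (!is.null(blk$hap_freqs)) blk$hap_freqs <- unlist(blk$hap_freqs)
      blk$snps <- unlist(blk$snps)
      blk
    })
  }
  for (nm in c("smoking_prob_by_sex", "intercepts")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  if (!is.null(raw$covariate_effects)) {
    raw$covariate_effects <- lapply(raw$covariate_effects, unlist)
  }
  do.call(simulation_config, raw)
}

#' Simulate genotypes under Hardy-Weinberg equilibrium with optional LD
#'
#' Each subject receives two gametes per block: for a two-SNP block the two
#' haplotypes are drawn from the configured haplotype frequencies (so each
#' locus is marginally at Hardy-Weinberg proportions and the pair carries the
#' configured linkage disequilibrium); single-SNP blocks draw two independent
#' Bernoulli(MAF) alleles. Genotypes are coded as minor-allele counts 0/1/2.
#'
#' @param config A [simulation_config()] object.
#' @return A tibble with `subject_id` and one integer column per SNP.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_subjects
  draw <- function() {
    cols <- list(subject_id = sprintf("S%04d", seq_len(n)))
    for (blk in config$snp_blocks) {
      if (length(blk$snps) == 1) {
        g <- rbinom(n, 1L, blk$maf) + rbinom(n, 1L, blk$maf)
        cols[[blk$snps]] <- as.integer(g)
      } else {
        hf <- blk$hap_freqs[c("11", "10", "01", "00")]
        # two gametes per subject
        hap <- matrix(sample.int(4L, 2L * n, replace = TRUE, prob = hf),
                      ncol = 2)
        minor1 <- c(1L, 1L, 0L, 0L)  # minor-allele indicator at locus 1
        minor2 <- c(1L, 0L, 1L, 0L)
        cols[[blk$snps[1]]] <- minor1[hap[, 1]] + minor1[hap[, 2]]
        cols[[blk$snps[2]]] <- minor2[hap[, 1]] + minor2[hap[, 2]]
      }
    }
    tibble::as_tibble(cols)
  }
  if (is.null(config$seed)) draw() else with_seed(config$seed, draw())
}

#' Simulate phenotypes on top of a genotype table
#'
#' Applies the structural suppression model described in
#' [simulation_config()]: log-TG depends on the dominant-coded causal genotype
#' and covariates; log-HDL-C depends on log-TG, the genotype and covariates;
#' log 8-OHdG/creatinine depends on the genotype and covariates. All
#' biomarkers are returned on the natural (exponentiated) scale. Total
#' cholesterol is generated as `ldl + hdl + tg/5` so that the Friedewald
#' relation holds exactly in the error-free cohort. When the config carries a
#' seed the result is bit-reproducible; the phenotype stream uses `seed + 1`
#' so it does not reuse the genotype stream.
#'
#' @param genotypes Output of [simulate_genotypes()] (or any tibble with
#'   `subject_id` plus the configured SNP columns).
#' @param config The same [simulation_config()] object.
#' @return A cohort tibble (one row per subject) with demographics, biomarkers
#'   and genotype columns. No missingness is injected here; see
#'   [inject_missing()] and [simulate_cohort()].
#' @export
simulate_phenotypes <- function(genotypes, config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_subjects
  if (nrow(genotypes) != n) {
    abort(paste0("genotype table has ", nrow(genotypes),
                 " rows but config expects ", n, " subjects"))
  }
  if (!config$causal_snp %in% names(genotypes)) {
    abort(paste0("genotype table lacks causal SNP column ", config$causal_snp))
  }
  build <- function() {
    cp <- config$covariate_params
    male <- as.integer(runif(n) < config$sex_fraction)
    age <- rnorm(n, cp$age_mean, cp$age_sd)
    bmi <- rnorm(n, cp$bmi_mean + ifelse(male == 1, cp$bmi_sex_shift,
                                         -cp$bmi_sex_shift), cp$bmi_sd)
    smoker <- runif(n) < ifelse(male == 1,
                                config$smoking_prob_by_sex[["male"]],
                                config$smoking_prob_by_sex[["female"]])
    waist <- 42 + 1.77 * bmi + 1.5 * male + rnorm(n, 0, 4)

    D <- as.integer(genotypes[[config$causal_snp]] >= 1)  # dominant coding
    # effect modification (defaults are homogeneous: scales of 1)
    a_i <- config$alpha *
      ifelse(male == 1, 1, config$female_effect_scale) *
      ifelse(bmi >= config$obesity_cutoff, config$obese_alpha_scale, 1)
    g_i <- config$gamma_prime * ifelse(male == 1, 1, config$female_effect_scale)
    d_i <- config$delta_8ohdg * ifelse(male == 1, 1, config$female_effect_scale)

    cage <- age - cp$age_mean
    cbmi <- bmi - cp$bmi_mean
    covs <- cbind(age = cage, bmi = cbmi, male = male, smoker = as.numeric(smoker))
    lin <- function(eq) drop(covs %*% config$covariate_effects[[eq]][colnames(covs)])

    log_tg <- config$intercepts[["tg"]] + a_i * D + lin("tg") +
      rnorm(n, 0, config$noise_sd_tg)
    log_hdl <- config$intercepts[["hdl"]] + config$beta * log_tg + g_i * D +
      lin("hdl") + rnorm(n, 0, config$noise_sd_hdl)
    log_ratio <- config$intercepts[["ohdg"]] + d_i * D + lin("ohdg") +
      rnorm(n, 0, config$noise_sd_8ohdg)

    tg <- exp(log_tg)
    hdl <- exp(log_hdl)
    ldl <- pmax(rnorm(n, 116.5, 30), 10)
    tc <- ldl + hdl + tg / 5  # Friedewald identity holds by construction
    glucose <- exp(rnorm(n, log(92), 0.10))
    insulin <- exp(rnorm(n, log(7.8), 0.35))
    crp <- exp(rnorm(n, log(0.6), 1.2))
    acr <- exp(rnorm(n, log(8), 1.2))
    ucreat <- exp(rnorm(n, log(1.0), 0.5))
    ohdg <- exp(log_ratio) * ucreat
    diabetes_meds <- runif(n) < 0.02

    out <- tibble::tibble(
      subject_id = genotypes$subject_id,
      sex = ifelse(male == 1, "male", "female"),
      age = round(age, 1),
      bmi = round(bmi, 1),
      waist = round(waist, 1),
      current_smoker = as.logical(smoker),
      glucose_mgdl = round(glucose, 1),
      insulin_uUml = round(insulin, 2),
      tc_mgdl = tc,
      hdl_mgdl = hdl,
      tg_mgdl = tg,
      ldl_mgdl = ldl,
      crp_mgL = round(crp, 3),
      acr_mg_per_g = round(acr, 2),
      ohdg_ng_ml = ohdg,
      urine_creatinine_mg_ml = ucreat,
      diabetes_meds = diabetes_meds
    )
    dplyr::bind_cols(out, genotypes[setdiff(names(genotypes), "subject_id")])
  }
  if (is.null(config$seed)) build() else with_seed(config$seed + 1L, build())
}

#' Inject missing values completely at random
#'
#' Every eligible cell is independently set to missing with probability
#' `rate`. Subject ids and sex are never touched (the downstream analyses
#' assume sex is observed). Missingness is MCAR, under which the listwise
#' deletion used by the model fits is unbiased.
#'
#' @param table A cohort tibble.
#' @param rate Missingness probability in \[0, 1\].
#' @param seed Optional integer seed.
#' @param cols Columns eligible for missingness; defaults to everything except
#'   `subject_id` and `sex`.
#' @return The table with missing cells.
#' @export
inject_missing <- function(table, rate, seed = NULL,
                           cols = setdiff(names(table), c("subject_id", "sex"))) {
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0 || rate > 1) {
    abort("rate must be a single number in [0, 1]")
  }
  if (rate == 0) return(table)
  punch <- function() {
    for (cl in cols) {
      hit <- runif(nrow(table)) < rate
      table[[cl]][hit] <- NA
    }
    table
  }
  if (is.null(seed)) punch() else with_seed(seed, punch())
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper: [simulate_genotypes()], then [simulate_phenotypes()],
#' then [inject_missing()] at the configured `missing_rate` (seeded with
#' `seed + 2` so all three stages are reproducible from the one config seed).
#'
#' @param config A [simulation_config()] object.
#' @return A cohort tibble.
#' @export
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_subjects = 100, seed = 7))
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  g <- simulate_genotypes(config)
  tab <- simulate_phenotypes(g, config)
  if (config$missing_rate > 0) {
    tab <- inject_missing(tab, config$missing_rate,
                          seed = if (is.null(config$seed)) NULL else config$seed + 2L)
  }
  tab
}
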