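test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- simulation_config(n_subjects = 150, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  # and the RNG state of the caller is untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate_cohort(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("fully coupled haplotypes produce perfectly correlated genotypes", {
  blocks <- list(list(snps = c("snpA", "snpB"),
                      hap_freqs = c("11" = 0.5, "10" = 0, "01" = 0, "00" = 0.5)))
  cfg <- simulation_config(n_subjects = 10000, snp_blocks = blocks,
                           causal_snp = "snpA", seed = 3)
  g <- simulate_genotypes(cfg)
  expect_identical(g$snpA, g$snpB)
  expect_gt(cor(g$snpA, g$snpB)^2, 0.999)
})

test_that("independent loci at MAF 0.5 show Hardy-Weinberg genotype fractions", {
  blocks <- list(list(snps = "snpA", maf = 0.5))
  cfg <- simulation_config(n_subjects = 20000, snp_blocks = blocks,
                           causal_snp = "snpA", seed = 5)
  g <- simulate_genotypes(cfg)$snpA
  frac <- tabulate(g + 1, 3) / length(g)
  expect_equal(frac, c(0.25, 0.5, 0.25), tolerance = 0.05)
})

test_that("simulated genotype counts pass the HWE test at the nominal rate", {
  blocks <- list(list(snps = "snpA", maf = 0.464))
  nonsig <- vapply(seq_len(1000), function(s) {
    cfg <- simulation_config(n_subjects = 562, snp_blocks = blocks,
                             causal_snp = "snpA", seed = s)
    g <- simulate_genotypes(cfg)$snpA
    hwe_test(c(sum(g == 0), sum(g == 1), sum(g == 2)))$p > 0.05
  }, logical(1))
  expect_gte(mean(nonsig), 0.94)
})

test_that("haplotype frequency misspecification is rejected with the pair named", {
  blocks <- list(list(snps = c("snpA", "snpB"),
                      hap_freqs = c("11" = 0.5, "10" = 0.2, "01" = 0.2, "00" = 0.2)))
  expect_error(simulation_config(snp_blocks = blocks, causal_snp = "snpA"),
               "snpA-snpB")
})

test_that("a null configuration yields genotype coefficients within 3 SE of zero", {
  cfg <- simulation_config(n_subjects = 2000, alpha = 0, beta = 0,
                           gamma_prime = 0, delta_8ohdg = 0,
                           missing_rate = 0, seed = 21)
  cohort <- simulate_cohort(cfg)
  m <- run_mediation(cohort, "rs2043085")
  expect_lt(abs(m$alpha), 3 * m$se_alpha)
  expect_lt(abs(m$beta), 3 * m$se_beta)
  expect_lt(abs(m$gamma_prime), 3 * m$se_gamma_prime)
})

test_that("the criterion regressions recover the generative parameters", {
  cfg <- simulation_config(n_subjects = 5000, seed = 31)
  cohort <- simulate_cohort(cfg)
  m <- run_mediation(cohort, "rs2043085")
  expect_lt(abs(m$alpha - cfg$alpha), 3 * m$se_alpha)
  expect_lt(abs(m$beta - cfg$beta), 3 * m$se_beta)
  expect_lt(abs(m$gamma_prime - cfg$gamma_prime), 3 * m$se_gamma_prime)
})

test_that("shape mismatch between genotypes and config is an error", {
  cfg <- simulation_config(n_subjects = 100, seed = 1)
  g <- simulate_genotypes(cfg)
  cfg2 <- simulation_config(n_subjects = 99, seed = 1)
  expect_error(simulate_phenotypes(g, cfg2), "99 subjects")
})

test_that("sex effect modification attenuates the genotype-TG slope in women", {
  cfg <- simulation_config(n_subjects = 8000, female_effect_scale = 0.25,
                           missing_rate = 0, seed = 41)
  cohort <- simulate_cohort(cfg)
  men <- run_mediation(cohort, "rs2043085", subgroup = "male")
  women <- suppressMessages(run_mediation(cohort, "rs2043085", subgroup = "female"))
  expect_lt(abs(men$alpha - cfg$alpha), 3 * men$se_alpha)
  expect_lt(abs(women$alpha - 0.25 * cfg$alpha), 3 * women$se_alpha)
  expect_gt(men$alpha, women$alpha)
})

test_that("inject_missing honours its rate contract", {
  cohort <- simulate_cohort(simulation_config(n_subjects = 100, missing_rate = 0,
                                              seed = 7))
  expect_identical(inject_missing(cohort, 0), cohort)

  all_gone <- inject_missing(cohort, 1, seed = 1)
  eligible <- setdiff(names(cohort), c("subject_id", "sex"))
  expect_true(all(vapply(all_gone[eligible], function(x) all(is.na(x)), logical(1))))
  expect_identical(all_gone$subject_id, cohort$subject_id)
  expect_identical(all_gone$sex, cohort$sex)

  # 10,000 eligible cells at rate 0.1: count inside the central 99% binomial band
  big <- simulate_cohort(simulation_config(n_subjects = 1000, missing_rate = 0,
                                           seed = 8))
  cols <- eligible[1:10]
  holey <- inject_missing(big, 0.1, seed = 2, cols = cols)
  n_missing <- sum(vapply(holey[cols], function(x) sum(is.na(x)), integer(1)))
  band <- qbinom(c(0.005, 0.995), 10000, 0.1)
  expect_gte(n_missing, band[1])
  expect_lte(n_missing, band[2])

  expect_error(inject_missing(cohort, -0.1), "rate")
  expect_error(inject_missing(cohort, 1.5), "rate")
})

test_that("config round-trips through YAML and JSON files", {
  cfg <- simulation_config(n_subjects = 64, alpha = 0.1, seed = 9)
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_subjects = 64, alpha = 0.1, seed = 9), yml)
  cfg_y <- read_simulation_config(yml)
  expect_s3_class(cfg_y, "simulation_config")
  expect_identical(simulate_cohort(cfg_y), simulate_cohort(cfg))

  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(n_subjects = 64, alpha = 0.1, seed = 9), js,
                       auto_unbox = TRUE)
  cfg_j <- read_simulation_config(js)
  expect_identical(simulate_cohort(cfg_j), simulate_cohort(cfg))
})
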