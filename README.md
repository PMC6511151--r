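# lipidmed

Candidate-gene association and mediation–suppression analysis for lipid and
oxidative-stress biomarker cohorts.

## The problem

Hepatic lipase is a negative regulator of HDL cholesterol, and common variants
near *LIPC* associate with HDL-C, triglycerides (TG) and markers of oxidative
stress such as urinary 8-OHdG. These associations are tangled: the same allele
that raises TG also raises HDL-C once TG is held fixed, so the marginal
genotype → HDL-C association is weak or absent. This is a *suppression*
pattern — the mediator (TG) masks the association until it is adjusted for.

`lipidmed` implements the full analysis pipeline for studies of this kind:

- **Mediation / suppression** — the four-criterion regression framework. With
  dominant-coded genotype *D*, mediator *M* = log TG and outcome *Y* = log
  HDL-C, three covariate-adjusted OLS fits on one common complete-case sample
  give

  - criterion 1: *M* = α·*D* + **c**ᵀ**x** + ε (genotype must predict the mediator),
  - criterion 2: *Y* = β·*M* + γ′·*D* + **c**ᵀ**x** + ε (mediator must predict the
    outcome given the genotype; γ′ is the direct effect),
  - criterion 3: *Y* = τ·*D* + **c**ᵀ**x** + ε (total effect; τ = γ′ + αβ exactly),
  - criterion 4: the indirect effect αβ must be significant by the Sobel test,
    z = αβ / δ with δ = √(α²·SE(β)² + β²·SE(α)²).

  Suppression is flagged when |γ′| > |τ| and αβ has the opposite sign to γ′.
- **Association engine** — covariate-adjusted linear models per SNP × trait
  under additive or dominant coding, the P1 (age, sex, BMI, smoking) and P2
  (P1 + complementary lipid) adjustment sets, sex and adiposity subgroups,
  Benjamini–Hochberg FDR within (model, subgroup) families, plus the usual
  group-comparison tests (t/ANOVA, chi-square, Kolmogorov–Smirnov).
- **Genotype QC** — genotype counts and MAF, Hardy–Weinberg chi-square (and
  exact) tests, and two-locus haplotype frequency / D′ / r² estimation by EM
  over unphased genotypes.
- **Cohort preprocessing** — typed TSV/CSV I/O, HOMA-IR, Friedewald LDL-C
  (with the TG > 400 mg/dL validity bound), creatinine-normalised 8-OHdG,
  enrollment exclusion filters, log transforms, stratification.
- **Synthetic cohorts** — a seeded generator producing cohorts with the exact
  structural suppression topology above (HWE genotypes with configurable LD,
  log-normal biomarkers, covariate effects, effect modification, MCAR
  missingness), so every stage is testable without individual-level data.

Everything takes a data frame first and returns tibbles; fitted objects have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

```r
library(lipidmed)

clean <- simulate_cohort(simulation_config(n_subjects = 572, seed = 2026)) |>
  derive_traits() |>
  apply_exclusions()

run_mediation(clean, "rs2043085")
#> Mediation of rs2043085 -> hdl through tg (dominant coding, subgroup: all, n = 522)
#>
#>   Criterion 1  alpha (genotype -> mediator)    0.057 (SE 0.016), p = 0.00036
#>   Criterion 2  beta  (mediator -> outcome | G) -0.210 (SE 0.016), p = <1e-16
#>                gamma' (direct effect)          0.027 (SE 0.006), p = 8e-06
#>   Criterion 3  total effect (alpha*beta+gamma') 0.015 (SE 0.007), p = 0.028
#>   Criterion 4  indirect effect alpha*beta      -0.012 (SE 0.003), Sobel z = -3.456, p = 0.00055
#>
#>   Suppression pattern: YES (|direct| > |total|, opposite-signed indirect)
```

Read this as the suppression story in miniature: minor-allele carriers have
higher log-TG (α = 0.057), higher TG predicts lower log-HDL-C (β = −0.210),
and the direct genotype effect on HDL-C (γ′ = 0.027) is larger than the total
effect (0.015) because the negative indirect path αβ = −0.012 partially
cancels it. The Sobel test rejects αβ = 0 (z = −3.46).

Genotype QC and the association grid:

```r
hwe_test(summarize_snp(clean$rs2043085, "rs2043085"))   # chi2, df, p
estimate_ld(clean$rs2043085, clean$rs1532085)
#> Two-locus LD (EM over unphased genotypes)
#>   n = 539, MAF = 0.468 / 0.457
#>   haplotype freqs: 11=0.4517 10=0.0159 01=0.0057 00=0.5268
#>   D = 0.2379, D' = 0.977, r2 = 0.916 (8 iterations, converged)

scan <- association_scan(clean, c("rs2043085", "rs1532085", "rs1800588"),
                         subgroups = c("all", "male", "female"))
dplyr::filter(scan, sig_fdr)   # FDR < 0.05 rows
autoplot(scan)                 # tile heatmap of -log10 p
```

Published summary statistics can be fed in directly, e.g. the Sobel test from
printed regression output:

```r
sobel_test(0.059, 0.021, -0.181, 0.021)
#> # A tibble: 1 × 4
#>        ab   delta     z p_value
#> 1 -0.0107 0.00400 -2.67 0.00754
```

## Package layout

- `R/simulate.R` — synthetic-cohort generator and configuration
- `R/cohort.R` — I/O, derived variables, exclusions, transforms, strata
- `R/genetics.R` — SNP summaries, HWE, genotype coding, EM linkage disequilibrium
- `R/association.R` — linear-model association engine, FDR, group tests
- `R/mediation.R` — four-criterion mediation, Sobel test, suppression, bootstrap
- `vignettes/mediation-suppression.Rmd` — the methods vignette
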