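---
title: "Suppression by a mediator: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Suppression by a mediator: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidmed)
```

## The model

`lipidmed` analyses candidate-SNP cohorts in which a biomarker mediates — and
can *suppress* — a genotype–outcome association. The running example is
hepatic-lipase biology: minor alleles of *LIPC*-region SNPs raise serum
triglycerides (TG), TG is strongly negatively related to HDL cholesterol, and
the same alleles have a positive direct effect on HDL-C. With dominant-coded
genotype $D$, covariates $x$ (age, sex, BMI, current smoking) and natural-log
traits, the structural model is

$$\log TG = a_0 + \alpha D + c_1^T x + \varepsilon_1,$$
$$\log HDL = b_0 + \beta \log TG + \gamma' D + c_2^T x + \varepsilon_2,$$

with $\alpha > 0$, $\beta < 0$, $\gamma' > 0$. The indirect (mediated) effect
is $\alpha\beta < 0$ and the total effect is $\tau = \gamma' + \alpha\beta$,
so the marginal genotype–HDL association is attenuated — possibly to
non-significance — even though both paths are real. This sign configuration
is *suppression* (inconsistent mediation): adjusting for the mediator makes
the genotype association stronger, not weaker.

`run_mediation()` fits the framework as three OLS regressions and evaluates
four criteria: (1) the genotype predicts the mediator ($\alpha$); (2) the
mediator predicts the outcome given the genotype ($\beta$, and $\gamma'$ as
the direct effect); (3) the genotype's total effect on the outcome ($\tau$);
(4) the indirect effect is significant by the Sobel test,

$$z = \frac{\alpha\beta}{\delta}, \qquad
  \delta = \sqrt{\alpha^2\,SE(\beta)^2 + \beta^2\,SE(\alpha)^2}.$$

`classify_suppression()` flags $|\gamma'| > |\tau|$ together with
$\mathrm{sign}(\alpha\beta) \ne \mathrm{sign}(\gamma')$; given the exact
decomposition the two conditions are equivalent, and both are checked.

### The common-sample rule

All three regressions are fitted on a *single* complete-case sample (listwise
deletion across every variable any of them uses). This is what makes
$\tau = \gamma' + \alpha\beta$ an algebraic identity of OLS rather than an
approximation; the package asserts it to $10^{-10}$ and a property-style test
checks it on randomly parameterised cohorts. If each regression dropped its
own missing rows separately, the decomposition would hold only in
expectation, and the "direct vs total" comparison that defines suppression
would be contaminated by sample-composition differences. Listwise deletion is
unbiased under the missing-completely-at-random mechanism, which is exactly
what the synthetic generator produces.

### Sobel variant and alternatives

The classic first-order Sobel standard error is the default because its
headline statistic is what the widely used interactive calculators report.
The Aroian ($+SE_\alpha^2 SE_\beta^2$ under the root) and Goodman
($-SE_\alpha^2 SE_\beta^2$) variants are available via the `variant`
argument; they bracket the classic value. A percentile bootstrap
(`bootstrap_indirect()`) is provided as an optional cross-check — the Sobel
normal approximation is known to be conservative near $\alpha\beta = 0$ —
but is not the default, because the primary framework is defined in terms of
the Sobel criterion. Two-sided p-values are used throughout.

## The association engine

`association_scan()` fits `trait ~ genotype + covariates` per SNP × trait ×
adjustment model × subgroup. Two adjustment sets mirror standard practice:

- **P1**: age, sex, BMI, current smoking;
- **P2**: P1 plus the complementary lipid — log-TG when the outcome is HDL-C
  or 8-OHdG, log-HDL-C when the outcome is TG.

In the suppression configuration the P2 association is *stronger* than P1:
conditioning on the suppressor unmasks the genotype effect. The P2 line for
HDL-C with dominant coding is numerically identical to the $\gamma'$ line of
`run_mediation()` on the same data (a cross-module consistency test asserts
this to $10^{-12}$).

Design details, each of which is tested:

- Skewed biomarkers (TG, HDL-C, 8-OHdG, glucose, insulin, CRP, HOMA-IR) are
  analysed on the natural-log scale; total and LDL cholesterol raw. The log
  base is irrelevant for t statistics and p-values (tested), and the TG→HDL
  slope $\beta$ in a log–log regression is base-invariant; natural logs are
  used everywhere for definiteness.
- Within sex strata the sex covariate is constant and is dropped (with a
  message) rather than fitted as a degenerate column.
- Rank-deficient designs are an error naming the collinear columns — a
  silently dropped coefficient in an epidemiological model is a wrong model.
- p-values use the t reference with residual degrees of freedom, not a
  normal approximation.
- Benjamini–Hochberg FDR is applied within each (model, subgroup) family:
  one P1 family pools all traits × SNPs of a subgroup (15 values for five
  traits × three SNPs) and one P2 family pools the three P2-eligible traits ×
  SNPs (9 values). These family definitions reproduce exactly the adjusted
  values of the published association grid the package's acceptance tests
  reconstruct, and are therefore the defaults. The fixed threshold
  $p \le 0.005$ used for genetic associations is flagged separately
  (`sig_strict`).

## Genotype QC

- `hwe_test()` is the 1-df Pearson chi-square against $(np^2, 2npq, nq^2)$
  with the allele frequency estimated from the same counts and no continuity
  correction — the behaviour of standard genetic-analysis software. An exact
  test (enumeration of heterozygote counts given the minor-allele count) is
  available behind `method = "exact"` but is not the default. An exhaustive
  test compares the chi-square to a from-scratch oracle on every genotype
  triple with $n \le 30$.
- `estimate_ld()` estimates two-locus haplotype frequencies from unphased
  genotypes by EM. Only the double heterozygote is phase-ambiguous; the
  E-step splits it between the coupling and repulsion phases in proportion to
  $f_{11}f_{00}$ vs $f_{10}f_{01}$. The EM is initialised at
  linkage-equilibrium frequencies with tolerance $10^{-8}$ and at most 1000
  iterations; it is deterministic, with no random restarts, because the
  two-locus likelihood is unimodal in practice. The likelihood trace is
  returned and tested to be non-decreasing; frequencies sum to 1 within
  $10^{-10}$. Monomorphic input is an error (LD undefined), not a silent NA.
- Minor-allele orientation is taken from the data at hand; a column whose
  nominal minor allele exceeds frequency 0.5 is relabelled with a message,
  and a tie at exactly 0.5 keeps the supplied orientation.

## The synthetic cohort generator

No individual-level data are deposited for studies of this design, so the
generator *is* the test bed: it emits cohorts with precisely the structure
the analysis assumes, which is what makes the pipeline falsifiable.

What it emulates, with defaults:

- **Cohort composition** — 572 subjects, 51.7% men; age 45.7 ± 9.7 y; BMI
  24.2 ± 3.3 kg/m² with a ±0.7 sex shift; smoking 33.8% (men) / 4% (women).
- **Genotypes** — haplotype-pair sampling per subject, so each locus is
  marginally at Hardy–Weinberg proportions and SNP pairs carry the
  configured LD. Defaults: a tightly linked pair (MAFs 0.464/0.457, D′ ≈
  0.97) and a third SNP at MAF 0.363 simulated unlinked — no published D′/r²
  anchors exist for it, so independence is the parsimonious choice.
- **Structural effects** — $\alpha = 0.06$, $\beta = -0.18$,
  $\gamma' = 0.022$ (the suppression preset), an 8-OHdG genotype effect of
  0.08 on the log scale, and small covariate coefficients so adjustment is
  consequential but not dominant.
- **Noise scales** — `noise_sd_tg = 0.165`, `noise_sd_hdl = 0.06`, chosen so
  the criterion-regression standard errors at roughly 300 subjects are about
  0.021, 0.021 and 0.008 for $\alpha$, $\beta$ and $\gamma'$ — i.e. the
  sampling precision of a male-only subgroup of a ~570-subject cohort. At
  those scales the Sobel test has ~80% power at $n = 300$ and essentially
  full power at $n = 5000$, while a null cohort ($\alpha = 0$) rejects at or
  below the nominal 5%.
- **Derived identities** — total cholesterol is generated as
  $LDL + HDL + TG/5$, so the Friedewald estimate agrees with generated LDL
  to $10^{-9}$ (tested); urinary 8-OHdG is generated as a
  creatinine-normalised ratio times a log-normal creatinine.
- **Effect modification** — multipliers `female_effect_scale` (on $\alpha$,
  $\gamma'$, and the 8-OHdG effect) and `obese_alpha_scale` default to 1.
  Homogeneous defaults keep the whole-cohort regression coefficient equal to
  the configured parameter, which the recovery and power properties rely on;
  setting the female scale to 0.25 reproduces the male-dominant association
  pattern, and a test does exactly that.
- **Missingness** — MCAR at rate 0.01 by default via `inject_missing()`;
  subject id and sex are never blanked.

What it does **not** emulate — and hence what passing tests do not show about
real data: assay-specific measurement error, non-MCAR missingness,
population stratification or relatedness, genotype–environment correlation,
non-log-normal tails, and the empirical covariance of the nuisance
biomarkers (glucose, insulin, CRP, ACR are drawn independently, merely so
the exclusion filters and derived variables have realistic ranges). One
deliberate side effect of calibrating the residual scales to the criterion
standard errors is that the *marginal* dispersion of log-TG and log-HDL is
smaller than in a real cohort; the inferential geometry (which the package
is about) is preserved, the descriptive spread is not.

Reproducibility: a config seed makes the cohort bit-identical across runs.
The genotype, phenotype and missingness stages consume `seed`, `seed + 1`
and `seed + 2` so they can also be invoked separately without stream reuse.

## Numerical choices and degenerate inputs

- Friedewald LDL above the TG = 400 mg/dL validity bound returns `NA` with a
  `requires_direct` flag instead of an extrapolated number.
- Glucose exclusion uses the 7.0 mmol/L threshold with the 18.016 mg/dL per
  mmol/L conversion (molar mass of glucose); the boundary value itself is
  excluded (≥).
- The obesity cutoff is BMI ≥ 27 kg/m² (the Taiwanese Ministry of Health
  definition), configurable everywhere it appears.
- Exclusion rules form a pure conjunction: order-free, idempotent, a subject
  counted once per failed rule but removed once; missing rule fields do not
  trigger the rule and are counted in the log.
- A zero-residual fit (outcome equals a linear combination of predictors) is
  flagged with a warning rather than reported with spuriously tiny p-values.
- `sobel_test(0, se, 0, se)` returns $z = 0$, $p = 1$ by convention
  (0/0 guarded).

## Problem sizes

The test suite and acceptance script use: exhaustive HWE oracle up to
$n = 30$; 1000 simulated cohorts for HWE calibration at $n = 562$; 500 null
and 500 study-scale ($n = 300$) cohorts plus 200 cohorts at $n = 5000$ for
the Sobel operating characteristics; $n = 2000$ for EM recovery; every
p-value family of size ≤ 8 over a six-point grid for the Benjamini–Hochberg
oracle. These sizes give Monte-Carlo standard errors comfortably inside the
asserted margins while keeping a full run in the low minutes.

## Known limitations

Single mediator, single ancestry-unstructured cohort, linear homoscedastic
models only; no sensitivity analysis for sequential ignorability, no
moderated mediation, no multi-allelic variants, no imputation. The Sobel
p-value is asymptotic and conservative near the null; for small samples the
bootstrap cross-check is the better-calibrated tool.
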