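#' Ordinary least-squares fit with listwise deletion
#'
#' Thin, contract-enforcing wrapper around [stats::lm()]: rows with any
#' missing value among the outcome and predictors are dropped (listwise
#' deletion), an intercept is always included, standard errors come from the
#' residual variance, and two-sided p-values use the t distribution with the
#' residual degrees of freedom. A rank-deficient design is an error naming
#' the collinear columns rather than a silently dropped coefficient.
#'
#' @param data A data frame holding outcome and predictors.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor column names.
#' @param label Optional adjustment-set label carried into the result.
#' @return An object of class `regression_fit` with [tidy()] and [glance()]
#'   methods; `tidy()` returns one row per term (`term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`).
#' @export
fit_linear_model <- function(data, outcome, predictors, label = NULL) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c(outcome, predictors), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("column(s) not in data: ", paste(missing_cols, collapse = ", ")))
  }
  frame <- data[, c(outcome, predictors), drop = FALSE]
  frame <- frame[complete.cases(frame), , drop = FALSE]
  n_used <- nrow(frame)
  if (n_used < length(predictors) + 2) {
    abort(paste0("only ", n_used, " complete case(s) for ",
                 length(predictors) + 1, " coefficients"))
  }
  fml <- stats::reformulate(paste0("`", predictors, "`"),
                            response = paste0("`", outcome, "`"))
  fit <- lm(fml, data = frame)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(gsub("`", "", bad), collapse = ", ")))
  }
  s <- summary(fit)
  ct <- s$coefficients
  zero_resid <- s$sigma < 1e-10
  if (zero_resid) {
    warn("residual variance is (numerically) zero; standard errors are degenerate")
  }
  tidy_tbl <- tibble::tibble(
    term = gsub("`", "", rownames(ct)),
    estimate = unname(ct[, 1]), std_error = unname(ct[, 2]),
    statistic = unname(ct[, 3]), p_value = unname(ct[, 4])
  )
  structure(list(
    tidy = tidy_tbl, n_used = n_used, df_residual = fit$df.residual,
    sigma = s$sigma, r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
    zero_residual = zero_resid, adjustment = label %||% "custom",
    outcome = outcome, predictors = predictors
  ), class = "regression_fit")
}

#' @method tidy regression_fit
#' @export
tidy.regression_fit <- function(x, ...) x$tidy

#' @method glance regression_fit
#' @export
glance.regression_fit <- function(x, ...) {
  tibble::tibble(
    n_used = x$n_used, df_residual = x$df_residual, sigma = x$sigma,
    r_squared = x$r_squared, adj_r_squared = x$adj_r_squared,
    adjustment = x$adjustment
  )
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("Linear model: %s ~ %s  [%s]\n", x$outcome,
              paste(x$predictors, collapse = " + "), x$adjustment))
  cat(sprintf("  n = %d (complete cases), residual df = %d, sigma = %.4g\n",
              x$n_used, x$df_residual, x$sigma))
  print(x$tidy)
  invisible(x)
}

# Build the analysis frame for one SNP x trait model. P1 covariates are age,
# sex, BMI and current smoking; within a sex stratum the sex covariate is
# constant and is dropped. P2 adds the complementary lipid on the log scale:
# log-TG when the outcome is HDL-C or 8-OHdG, log-HDL-C when it is TG.
build_association_frame <- function(table, snp, trait, model, coding,
                                    subgroup, bmi_cutoff) {
  stop_if_not_cohort(table)
  if (!snp %in% names(table)) abort(paste0("no genotype column '", snp, "'"))
  table <- subgroup_filter(table, subgroup, bmi_cutoff)
  if (nrow(table) == 0) abort(paste0("subgroup '", subgroup, "' is empty"))
  y <- resolve_trait(table, trait)
  g <- code_genotypes(table[[snp]], coding)
  frame <- tibble::tibble(.outcome = y$values, genotype = g,
                          age = table$age, bmi = table$bmi,
                          sex_male = sex_indicator(table$sex),
                          smoker = as.numeric(table$current_smoker))
  covs <- c("age", "sex_male", "bmi", "smoker")
  if (subgroup %in% c("male", "female")) covs <- setdiff(covs, "sex_male")
  if (model == "P2") {
    extra <- switch(trait, hdl = "tg", ohdg = "tg", tg = "hdl",
                    abort(paste0("the P2 adjustment set is defined only for ",
                                 "hdl, tg and ohdg outcomes, not '", trait, "'")))
    frame$.extra_lipid <- resolve_trait(table, extra)$values
    covs <- c(covs, ".extra_lipid")
  }
  list(frame = frame, covariates = covs, trait = y)
}

#' Covariate-adjusted SNP-trait association
#'
#' Fits the general linear model `trait ~ genotype + covariates` by ordinary
#' least squares with listwise deletion and returns the genotype term. Under
#' the `P1` model the covariates are age, sex, BMI and current smoking; `P2`
#' additionally adjusts for the complementary lipid (log-TG for HDL-C and
#' 8-OHdG outcomes, log-HDL-C for the TG outcome). Skewed traits are analysed
#' on the natural-log scale (see [trait_registry()]). Within sex strata the
#' sex covariate is dropped.
#'
#' @param table Cohort tibble.
#' @param snp Genotype column name.
#' @param trait Trait keyword (e.g. `"hdl"`, `"tg"`, `"ohdg"`, `"tc"`, `"ldl"`).
#' @param model `"P1"` or `"P2"`.
#' @param coding `"additive"` (default) or `"dominant"`.
#' @param subgroup One of `"all"`, `"male"`, `"female"`, `"obese"`, `"nonobese"`.
#' @param bmi_cutoff BMI cutoff for the obesity subgroups (default 27).
#' @return A one-row tibble: `snp_id`, `trait`, `coding`, `model`, `subgroup`,
#'   `n_used`, `estimate`, `std_error`, `p_raw`.
#' @export
snp_trait_association <- function(table, snp, trait, model = c("P1", "P2"),
                                  coding = c("additive", "dominant"),
                                  subgroup = "all", bmi_cutoff = 27) {
  model <- match.arg(model)
  coding <- match.arg(coding)
  parts <- build_association_frame(table, snp, trait, model, coding,
                                   subgroup, bmi_cutoff)
  ok <- parts$frame$.outcome[!is.na(parts$frame$.outcome)]
  if (length(ok) > 0 && var(ok) == 0) {
    abort(paste0("trait '", trait, "' is constant in subgroup '", subgroup, "'"))
  }
  fit <- fit_linear_model(parts$frame, ".outcome",
                          c("genotype", parts$covariates), label = model)
  row <- fit$tidy[fit$tidy$term == "genotype", ]
  tibble::tibble(
    snp_id = snp, trait = trait, coding = coding, model = model,
    subgroup = subgroup, n_used = fit$n_used,
    estimate = row$estimate, std_error = row$std_error, p_raw = row$p_value
  )
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment: the i-th smallest p-value becomes
#' `min over j >= i of min(1, p_(j) * m / j)`; order-preserving and capped at
#' 1. Adjustment families should be defined per model and subgroup (the
#' default in [association_scan()]).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) abort("empty p-value family")
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Run the full SNP x trait association grid
#'
#' Fits every combination of SNP, trait, adjustment model and subgroup, then
#' applies Benjamini-Hochberg FDR within each (model, subgroup) family --
#' i.e. the P1 family pools all traits x SNPs of a subgroup and the P2 family
#' pools the three P2-eligible traits x SNPs. Also flags the stricter fixed
#' threshold p <= 0.005 used for genetic association.
#'
#' @param table Cohort tibble.
#' @param snps Genotype column names.
#' @param traits Trait keywords; default the five headline traits. Traits
#'   without a defined P2 adjustment are skipped under P2.
#' @param models Subset of `c("P1", "P2")`.
#' @param subgroups Subset of `c("all", "male", "female", "obese", "nonobese")`.
#' @param coding Genotype coding (default additive).
#' @param bmi_cutoff BMI cutoff for obesity subgroups.
#' @return An `association_scan` tibble: one row per SNP x trait x model x
#'   subgroup with `p_raw`, `p_fdr`, `sig_fdr` (FDR < 0.05) and `sig_strict`
#'   (p_raw <= 0.005).
#' @export
association_scan <- function(table, snps,
                             traits = c("tc", "ldl", "hdl", "tg", "ohdg"),
                             models = c("P1", "P2"), subgroups = "all",
                             coding = "additive", bmi_cutoff = 27) {
  p2_traits <- intersect(traits, c("hdl", "tg", "ohdg"))
  grid <- tidyr::expand_grid(snp = snps, trait = traits, model = models,
                             subgroup = subgroups)
  grid <- grid[!(grid$model == "P2" & !grid$trait %in% p2_traits), ]
  rows <- purrr::pmap(grid, function(snp, trait, model, subgroup) {
    snp_trait_association(table, snp, trait, model = model, coding = coding,
                          subgroup = subgroup, bmi_cutoff = bmi_cutoff)
  })
  out <- dplyr::bind_rows(rows) %>%
    dplyr::group_by(.data$model, .data$subgroup) %>%
    dplyr::mutate(p_fdr = bh_adjust(.data$p_raw)) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(sig_fdr = .data$p_fdr < 0.05,
                  sig_strict = .data$p_raw <= 0.005)
  class(out) <- c("association_scan", class(out))
  out
}

#' Compare a continuous variable across groups
#'
#' Two groups: classic pooled-variance two-sample t test. Three or more:
#' one-way ANOVA. Two-sided p-values.
#'
#' @param values Numeric vector.
#' @param groups Group labels (same length); pairs with a missing value or
#'   label are dropped.
#' @return A one-row tibble: `method`, `statistic`, `df1`, `df2`, `p_value`.
#' @export
compare_groups_continuous <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.factor(as.character(groups[keep]))
  sizes <- table(groups)
  if (length(sizes) < 2) abort("need at least two non-empty groups")
  if (any(sizes < 2)) abort("every group needs at least two observations")
  if (length(sizes) == 2) {
    tt <- stats::t.test(values ~ groups, var.equal = TRUE)
    tibble::tibble(method = "two-sample t (pooled)",
                   statistic = unname(tt$statistic),
                   df1 = 1, df2 = unname(tt$parameter),
                   p_value = tt$p.value)
  } else {
    ow <- stats::oneway.test(values ~ groups, var.equal = TRUE)
    tibble::tibble(method = "one-way ANOVA",
                   statistic = unname(ow$statistic),
                   df1 = unname(ow$parameter[1]), df2 = unname(ow$parameter[2]),
                   p_value = ow$p.value)
  }
}

#' Pearson chi-square test on a contingency table
#'
#' No continuity correction; df = (rows - 1)(cols - 1). Used for differences
#' in categorical variables and genotype/allele frequency comparisons.
#'
#' @param tab A matrix (at least 2x2) of non-negative integer counts.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
compare_groups_categorical <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) abort("need at least a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("counts must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("zero-margin row or column: chi-square undefined")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value)
}

#' Kolmogorov-Smirnov check against a fitted normal
#'
#' One-sample KS statistic against a normal distribution with the sample mean
#' and SD plugged in. Used as a descriptive normality screen for biomarkers
#' before/after log transformation; note that estimating the parameters from
#' the same sample makes the classic KS p-value conservative.
#'
#' @param values Numeric vector, at least 5 non-missing values, non-constant.
#' @return A one-row tibble: `statistic`, `p_value`, `n`.
#' @export
ks_normality <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 5) abort("need at least 5 non-missing values")
  if (sd(x) == 0) abort("constant vector: normality test undefined")
  kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), sd(x)))
  tibble::tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
                 n = length(x))
}

#' Heatmap of an association scan
#'
#' Tiles of -log10 raw p by SNP and trait, faceted by adjustment model and
#' subgroup, with FDR-significant cells outlined.
#'
#' @param object An [association_scan()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot association_scan
#' @export
autoplot.association_scan <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$trait, y = .data$snp_id,
                               fill = -log10(.data$p_raw))) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$sig_fdr, signif(.data$p_fdr, 2), "")), size = 2.6) +
    ggplot2::facet_grid(model ~ subgroup) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 name = expression(-log[10] * "p")) +
    ggplot2::labs(x = "trait", y = NULL,
                  title = "SNP-trait associations (FDR-significant cells labelled)") +
    ggplot2::theme_minimal()
}
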