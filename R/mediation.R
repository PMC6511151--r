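#' Sobel product-of-coefficients test
#'
#' Tests the null hypothesis that the mediated (indirect) effect
#' \eqn{\alpha\beta} is zero. The classic first-order standard error is
#' \eqn{\delta = \sqrt{\alpha^2 SE_\beta^2 + \beta^2 SE_\alpha^2}}; the
#' Aroian variant adds \eqn{SE_\alpha^2 SE_\beta^2} under the root and the
#' Goodman variant subtracts it. \eqn{z = \alpha\beta / \delta} is referred
#' to the standard normal, two-sided. When both coefficients are exactly zero
#' the statistic is defined as 0 (p = 1).
#'
#' @param alpha Coefficient of the genotype in the mediator regression.
#' @param se_alpha Its standard error (> 0).
#' @param beta Coefficient of the mediator in the outcome regression
#'   (adjusted for the genotype).
#' @param se_beta Its standard error (> 0).
#' @param variant `"sobel"` (default), `"aroian"` or `"goodman"`.
#' @return A one-row tibble: `ab` (indirect effect), `delta` (its SE),
#'   `z`, `p_value`.
#' @export
#' @examples
#' sobel_test(0.059, 0.021, -0.181, 0.021) # ab ~ -0.011, delta ~ 0.004
sobel_test <- function(alpha, se_alpha, beta, se_beta,
                       variant = c("sobel", "aroian", "goodman")) {
  variant <- match.arg(variant)
  if (se_alpha <= 0 || se_beta <= 0) abort("standard errors must be > 0")
  ab <- alpha * beta
  v <- alpha^2 * se_beta^2 + beta^2 * se_alpha^2
  v <- switch(variant,
              sobel = v,
              aroian = v + se_alpha^2 * se_beta^2,
              goodman = v - se_alpha^2 * se_beta^2)
  if (v < 0) abort("negative variance under the Goodman correction")
  delta <- sqrt(v)
  z <- if (delta == 0) 0 else ab / delta
  tibble::tibble(ab = ab, delta = delta, z = z,
                 p_value = 2 * pnorm(-abs(z)))
}

#' Classify a suppression (inconsistent mediation) pattern
#'
#' Suppression holds when the direct effect exceeds the total effect in
#' magnitude and the indirect effect has the opposite sign to the direct
#' effect, so that omitting the mediator masks the genotype-outcome
#' association. Given the exact decomposition `total = gamma_prime + ab` the
#' two conditions are equivalent; both are checked.
#'
#' @param x Either a `mediation_result` from [run_mediation()], or the direct
#'   effect \eqn{\gamma'}.
#' @param ab Indirect effect \eqn{\alpha\beta} (when `x` is numeric).
#' @param total Total effect; defaults to `x + ab`.
#' @return Logical.
#' @export
#' @examples
#' classify_suppression(0.022, ab = -0.011, total = 0.011) # TRUE
classify_suppression <- function(x, ab = NULL, total = NULL) {
  if (inherits(x, "mediation_result")) {
    gp <- x$gamma_prime; ab <- x$ab; total <- x$total
  } else {
    gp <- x
    if (is.null(ab)) abort("supply the indirect effect 'ab'")
    if (is.null(total)) total <- gp + ab
  }
  abs(gp) > abs(total) && sign(ab) * sign(gp) < 0
}

#' Four-criterion mediation / suppression analysis
#'
#' Implements the regression-based mediation framework on a single
#' complete-case sample (listwise deletion over every variable used by any of
#' the three fits, so the effect decomposition is exact):
#'
#' 1. the genotype must predict the mediator:
#'    `mediator ~ genotype + covariates` gives \eqn{\alpha};
#' 2. the mediator must predict the outcome adjusting for the genotype:
#'    `outcome ~ mediator + genotype + covariates` gives \eqn{\beta} and the
#'    direct effect \eqn{\gamma'};
#' 3. the genotype's total effect on the outcome:
#'    `outcome ~ genotype + covariates`;
#' 4. the indirect effect \eqn{\alpha\beta} must be significant by the
#'    [sobel_test()].
#'
#' On the shared sample `total = gamma_prime + alpha * beta` holds to machine
#' precision. The suppression flag applies [classify_suppression()].
#'
#' @param table Cohort tibble.
#' @param snp Genotype column name.
#' @param mediator,outcome Trait keywords (default TG mediating HDL-C); both
#'   are analysed on the natural-log scale per [trait_registry()].
#' @param covariates Covariate set; any of `"age"`, `"sex"`, `"bmi"`,
#'   `"smoker"` (default all four). A covariate that is constant in the
#'   analysis sample (e.g. sex within a sex subgroup) is dropped.
#' @param coding Genotype coding; `"dominant"` by default for mediation.
#' @param subgroup Subgroup to analyse (default `"all"`).
#' @param bmi_cutoff BMI cutoff for obesity subgroups.
#' @param sobel_variant Passed to [sobel_test()].
#' @return An object of class `mediation_result` with fields `snp_id`,
#'   `alpha`, `se_alpha`, `p_alpha`, `beta`, `se_beta`, `p_beta`,
#'   `gamma_prime`, `se_gamma_prime`, `p_gamma_prime`, `total`, `se_total`,
#'   `p_total`, `ab`, `delta`, `sobel_z`, `sobel_p`, `suppression`, `n_used`,
#'   plus the three underlying `regression_fit`s. Has [tidy()], [glance()],
#'   [autoplot()] and print methods.
#' @export
run_mediation <- function(table, snp, mediator = "tg", outcome = "hdl",
                          covariates = c("age", "sex", "bmi", "smoker"),
                          coding = c("dominant", "additive"),
                          subgroup = "all", bmi_cutoff = 27,
                          sobel_variant = "sobel") {
  coding <- match.arg(coding)
  stop_if_not_cohort(table)
  if (!snp %in% names(table)) abort(paste0("no genotype column '", snp, "'"))
  table <- subgroup_filter(table, subgroup, bmi_cutoff)

  med <- resolve_trait(table, mediator)
  out <- resolve_trait(table, outcome)
  frame <- tibble::tibble(.m = med$values, .y = out$values,
                          genotype = code_genotypes(table[[snp]], coding))
  cov_cols <- c(age = "age", sex = "sex_male", bmi = "bmi", smoker = "smoker")
  covariates <- match.arg(covariates, names(cov_cols), several.ok = TRUE)
  if ("age" %in% covariates) frame$age <- table$age
  if ("bmi" %in% covariates) frame$bmi <- table$bmi
  if ("sex" %in% covariates) frame$sex_male <- sex_indicator(table$sex)
  if ("smoker" %in% covariates) frame$smoker <- as.numeric(table$current_smoker)

  # one common complete-case sample for all three regressions
  frame <- frame[complete.cases(frame), , drop = FALSE]
  if (nrow(frame) == 0) abort("no complete cases for the mediation sample")
  if (var(frame$.m) == 0) abort("mediator is constant in the analysis sample")
  covs <- unname(cov_cols[covariates])
  constant <- covs[vapply(covs, function(cl) var(frame[[cl]]) == 0, logical(1))]
  if (length(constant) > 0) {
    inform(paste0("dropping constant covariate(s): ",
                  paste(constant, collapse = ", ")))
    covs <- setdiff(covs, constant)
  }

  fit_m <- fit_linear_model(frame, ".m", c("genotype", covs),
                            label = "criterion 1: mediator ~ genotype")
  fit_y <- fit_linear_model(frame, ".y", c(".m", "genotype", covs),
                            label = "criterion 2: outcome ~ mediator + genotype")
  fit_t <- fit_linear_model(frame, ".y", c("genotype", covs),
                            label = "criterion 3: outcome ~ genotype (total)")
  pick <- function(fit, term) fit$tidy[fit$tidy$term == term, ]
  a <- pick(fit_m, "genotype"); b <- pick(fit_y, ".m")
  gp <- pick(fit_y, "genotype"); tot <- pick(fit_t, "genotype")

  sob <- sobel_test(a$estimate, a$std_error, b$estimate, b$std_error,
                    variant = sobel_variant)
  res <- structure(list(
    snp_id = snp, mediator = mediator, outcome = outcome,
    coding = coding, subgroup = subgroup, covariates = covs,
    n_used = nrow(frame),
    alpha = a$estimate, se_alpha = a$std_error, p_alpha = a$p_value,
    beta = b$estimate, se_beta = b$std_error, p_beta = b$p_value,
    gamma_prime = gp$estimate, se_gamma_prime = gp$std_error,
    p_gamma_prime = gp$p_value,
    total = tot$estimate, se_total = tot$std_error, p_total = tot$p_value,
    ab = sob$ab, delta = sob$delta, sobel_z = sob$z, sobel_p = sob$p_value,
    fits = list(mediator = fit_m, outcome = fit_y, total = fit_t)
  ), class = "mediation_result")
  res$suppression <- classify_suppression(res)
  res
}

#' @method tidy mediation_result
#' @export
tidy.mediation_result <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "beta", "gamma_prime", "total", "indirect"),
    estimate = c(x$alpha, x$beta, x$gamma_prime, x$total, x$ab),
    std_error = c(x$se_alpha, x$se_beta, x$se_gamma_prime, x$se_total, x$delta),
    p_value = c(x$p_alpha, x$p_beta, x$p_gamma_prime, x$p_total, x$sobel_p)
  )
}

#' @method glance mediation_result
#' @export
glance.mediation_result <- function(x, ...) {
  tibble::tibble(
    snp_id = x$snp_id, mediator = x$mediator, outcome = x$outcome,
    coding = x$coding, subgroup = x$subgroup, n_used = x$n_used,
    ab = x$ab, delta = x$delta, sobel_z = x$sobel_z, sobel_p = x$sobel_p,
    suppression = x$suppression
  )
}

#' @export
print.mediation_result <- function(x, digits = 3, ...) {
  f <- function(v) formatC(v, digits = digits, format = "f")
  p <- function(v) format.pval(v, digits = 2, eps = 1e-16)
  cat(sprintf("Mediation of %s -> %s through %s (%s coding, subgroup: %s, n = %d)\n\n",
              x$snp_id, x$outcome, x$mediator, x$coding, x$subgroup, x$n_used))
  cat(sprintf("  Criterion 1  alpha (genotype -> mediator)    %s (SE %s), p = %s\n",
              f(x$alpha), f(x$se_alpha), p(x$p_alpha)))
  cat(sprintf("  Criterion 2  beta  (mediator -> outcome | G) %s (SE %s), p = %s\n",
              f(x$beta), f(x$se_beta), p(x$p_beta)))
  cat(sprintf("               gamma' (direct effect)          %s (SE %s), p = %s\n",
              f(x$gamma_prime), f(x$se_gamma_prime), p(x$p_gamma_prime)))
  cat(sprintf("  Criterion 3  total effect (alpha*beta+gamma') %s (SE %s), p = %s\n",
              f(x$total), f(x$se_total), p(x$p_total)))
  cat(sprintf("  Criterion 4  indirect effect alpha*beta      %s (SE %s), Sobel z = %s, p = %s\n",
              f(x$ab), f(x$delta), f(x$sobel_z), p(x$sobel_p)))
  cat(sprintf("\n  Suppression pattern: %s\n",
              if (x$suppression) "YES (|direct| > |total|, opposite-signed indirect)"
              else "no"))
  invisible(x)
}

#' Percentile-bootstrap confidence interval for the indirect effect
#'
#' Optional cross-check of the Sobel test: resamples subjects with
#' replacement, refits the mediator and outcome regressions, and returns the
#' percentile interval of \eqn{\alpha\beta}.
#'
#' @param table,snp,mediator,outcome,covariates,coding,subgroup,bmi_cutoff
#'   As in [run_mediation()].
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional seed.
#' @return A one-row tibble: `ab`, `lower`, `upper`, `n_boot`,
#'   `excludes_zero`.
#' @export
bootstrap_indirect <- function(table, snp, mediator = "tg", outcome = "hdl",
                               covariates = c("age", "sex", "bmi", "smoker"),
                               coding = "dominant", subgroup = "all",
                               bmi_cutoff = 27, n_boot = 1000, conf = 0.95,
                               seed = NULL) {
  base <- run_mediation(table, snp, mediator, outcome, covariates, coding,
                        subgroup, bmi_cutoff)
  run <- function() {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(nrow(table), replace = TRUE)
      boot <- table[idx, , drop = FALSE]
      boot$subject_id <- sprintf("B%05d", seq_len(nrow(boot)))
      r <- tryCatch(
        suppressMessages(run_mediation(boot, snp, mediator, outcome,
                                       covariates, coding, subgroup, bmi_cutoff)),
        error = function(e) NULL)
      if (is.null(r)) NA_real_ else r$ab
    }, numeric(1))
  }
  abs_boot <- if (is.null(seed)) run() else with_seed(seed, run())
  qs <- stats::quantile(abs_boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE)
  tibble::tibble(ab = base$ab, lower = qs[[1]], upper = qs[[2]],
                 n_boot = sum(!is.na(abs_boot)),
                 excludes_zero = qs[[1]] > 0 || qs[[2]] < 0)
}

#' Path diagram of a mediation result
#'
#' Draws the three-variable triangle (genotype, mediator, outcome) with the
#' estimated path coefficients: \eqn{\alpha} on the genotype-to-mediator
#' edge, \eqn{\beta} on the mediator-to-outcome edge, and the direct effect
#' \eqn{\gamma'} with the total effect on the genotype-to-outcome edge.
#'
#' @param object A `mediation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mediation_result
#' @export
autoplot.mediation_result <- function(object, ...) {
  stars <- function(p) if (p < 0.01) "*" else ""
  node_labels <- c(object$snp_id, paste0("log ", toupper(object$mediator)),
                   paste0("log ", toupper(object$outcome)))
  edge_labels <- c(
    sprintf("alpha == %.3f%s", object$alpha, stars(object$p_alpha)),
    sprintf("beta == %.3f%s", object$beta, stars(object$p_beta)),
    sprintf("gamma*minute == %.3f%s~~(total == %.3f)", object$gamma_prime,
            stars(object$p_gamma_prime), object$total)
  )
  nodes <- tibble::tibble(x = c(0, 1, 2), y = c(0, 1, 0), label = node_labels)
  edges <- tibble::tibble(
    x = c(0.12, 1.12, 0.25), y = c(0.12, 0.88, 0),
    xend = c(0.88, 1.88, 1.75), yend = c(0.88, 0.12, 0),
    label = edge_labels,
    lx = c(0.35, 1.68, 1.0), ly = c(0.62, 0.62, -0.14)
  )
  x <- object
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "in")),
      linewidth = 0.6) +
    ggplot2::geom_label(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
                        size = 3.6) +
    ggplot2::geom_text(data = edges,
                       ggplot2::aes(x = .data$lx, y = .data$ly, label = .data$label),
                       parse = TRUE, size = 3.3) +
    ggplot2::annotate("text", x = 1, y = 1.32, size = 3.4, label = sprintf(
      "Sobel z = %.2f, p = %.3g%s", x$sobel_z, x$sobel_p,
      if (x$suppression) " (suppression)" else "")) +
    ggplot2::xlim(-0.35, 2.35) + ggplot2::ylim(-0.3, 1.4) +
    ggplot2::theme_void()
}
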