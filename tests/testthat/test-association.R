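test_that("OLS coefficients match the normal-equations solution on tiny data", {
  d <- tibble::tibble(y = c(1, 3, 2, 5), x = c(0, 1, 2, 3))
  fit <- fit_linear_model(d, "y", "x")
  X <- cbind(1, d$x)
  want <- drop(solve(crossprod(X), crossprod(X, d$y)))
  got <- tidy(fit)
  expect_equal(got$estimate, unname(want), tolerance = 1e-12)
  # residual-df t reference
  sigma2 <- sum((d$y - X %*% want)^2) / (4 - 2)
  se <- sqrt(diag(sigma2 * solve(crossprod(X))))
  expect_equal(got$std_error, unname(se), tolerance = 1e-12)
  expect_equal(got$p_value,
               2 * pt(-abs(want / se), df = 2), tolerance = 1e-12)
})

test_that("an outcome identical to a predictor is flagged as zero-residual", {
  d <- tibble::tibble(y = c(1, 2, 3, 4), x = c(1, 2, 3, 4))
  w <- testthat::capture_warnings(fit <- fit_linear_model(d, "y", "x"))
  expect_true(any(grepl("residual variance", w)))
  expect_equal(tidy(fit)$estimate[2], 1)
  expect_true(fit$zero_residual)
})

test_that("rank-deficient designs error naming the collinear columns", {
  d <- tibble::tibble(y = rnorm(10), a = 1:10, b = 2 * (1:10))
  expect_error(fit_linear_model(d, "y", c("a", "b")), "collinear.*b")
})

test_that("listwise deletion drops exactly the incomplete rows", {
  d <- tibble::tibble(y = c(1, 2, NA, 4, 5, 7), x = c(1, NA, 3, 4, 5, 6),
                      z = c(1, 1, 0, 0, 1, 0))
  fit <- fit_linear_model(d, "y", c("x", "z"))
  expect_equal(fit$n_used, 4)
  expect_equal(fit$df_residual, 1)
  # too few complete cases for the requested coefficients is an error
  expect_error(fit_linear_model(d[1:4, ], "y", c("x", "z")), "complete case")
})

test_that("the genotype p-value is uniform under permutation of the outcome", {
  d <- withr::with_seed(77, tibble::tibble(
    g = sample(0:2, 60, replace = TRUE, prob = c(0.3, 0.5, 0.2)),
    y = rnorm(60)))
  rejections <- withr::with_seed(78, {
    sum(vapply(seq_len(1000), function(i) {
      d$yp <- sample(d$y)
      fit <- fit_linear_model(d, "yp", "g")
      tidy(fit)$p_value[2] < 0.05
    }, logical(1)))
  })
  band <- qbinom(c(0.005, 0.995), 1000, 0.05)
  expect_gte(rejections, band[1])
  expect_lte(rejections, band[2])
})

test_that("bh_adjust equals the literal step-up definition on all small families", {
  # brute-force oracle: adjusted_(i) = min_{j >= i} min(1, p_(j) * m / j)
  bh_oracle <- function(p) {
    m <- length(p)
    ord <- order(p)
    ps <- p[ord]
    adj <- numeric(m)
    for (i in seq_len(m)) {
      adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
    }
    out <- numeric(m)
    out[ord] <- adj
    out
  }
  grid <- c(0.001, 0.01, 0.04, 0.2, 0.5, 1)
  for (k in 1:8) {
    # all multisets of size k from the grid, via the stars-and-bars bijection
    fams <- utils::combn(seq_len(length(grid) + k - 1), k, simplify = FALSE)
    for (idx in fams) {
      p <- grid[idx - seq(0, k - 1)]
      expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-14)
    }
  }
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))
  expect_error(bh_adjust(numeric(0)), "empty")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("BH adjustment is order-preserving and monotone in its input", {
  p <- c(0.03, 0.001, 0.2, 0.04, 0.9)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_equal(order(adj), order(p))
})

test_that("association p-values are invariant to the base of the log transform", {
  cohort <- simulate_cohort(simulation_config(n_subjects = 400, seed = 51))
  d <- tibble::tibble(g = code_genotypes(cohort$rs2043085, "additive"),
                      ln_y = log(cohort$tg_mgdl),
                      l10_y = log10(cohort$tg_mgdl),
                      age = cohort$age, bmi = cohort$bmi)
  f_ln <- fit_linear_model(d, "ln_y", c("g", "age", "bmi"))
  f_10 <- fit_linear_model(d, "l10_y", c("g", "age", "bmi"))
  expect_equal(tidy(f_ln)$p_value, tidy(f_10)$p_value, tolerance = 1e-9)
  expect_equal(tidy(f_ln)$statistic, tidy(f_10)$statistic, tolerance = 1e-9)
})

test_that("snp_trait_association enforces its preconditions", {
  cohort <- simulate_cohort(simulation_config(n_subjects = 200, seed = 53))
  expect_error(snp_trait_association(cohort, "rs9999999", "tg"), "rs9999999")
  expect_error(snp_trait_association(cohort, "rs2043085", "tc", model = "P2"),
               "P2")
  male_only <- dplyr::filter(cohort, sex == "male")
  expect_error(snp_trait_association(male_only, "rs2043085", "tg",
                                     subgroup = "female"), "empty")
  flat <- cohort
  flat$tg_mgdl <- 100
  expect_error(snp_trait_association(flat, "rs2043085", "tg"), "constant")
})

test_that("the association scan applies FDR within (model, subgroup) families", {
  cohort <- simulate_cohort(simulation_config(n_subjects = 600, seed = 55))
  scan <- association_scan(cohort, c("rs2043085", "rs1532085", "rs1800588"),
                           subgroups = c("all", "male"))
  # P1 families: 5 traits x 3 SNPs; P2 families: 3 traits x 3 SNPs
  sizes <- dplyr::count(scan, model, subgroup)
  expect_setequal(sizes$n[sizes$model == "P1"], 15)
  expect_setequal(sizes$n[sizes$model == "P2"], 9)
  for (key in split(scan, paste(scan$model, scan$subgroup))) {
    expect_equal(key$p_fdr, bh_adjust(key$p_raw))
  }
  expect_true(all(scan$p_fdr >= scan$p_raw))
})

test_that("group comparison tests behave at their anchors", {
  x <- c(1, 2, 3, 4)
  r <- compare_groups_continuous(c(x, x), rep(c("a", "b"), each = 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  big <- withr::with_seed(61, c(rnorm(1000, 0), rnorm(1000, 1)))
  r2 <- compare_groups_continuous(big, rep(c("a", "b"), each = 1000))
  expect_lt(r2$p_value, 1e-10)

  expect_error(compare_groups_continuous(c(1, 2, 3), c("a", "a", "b")),
               "at least two observations")
})

test_that("three-group ANOVA holds its type-I rate under equal means", {
  rej <- vapply(1:500, function(s) {
    y <- withr::with_seed(s + 1000, rnorm(60))
    compare_groups_continuous(y, rep(c("a", "b", "c"), each = 20))$p_value < 0.05
  }, logical(1))
  band <- qbinom(c(0.005, 0.995), 500, 0.05) / 500
  expect_gte(mean(rej), band[1])
  expect_lte(mean(rej), band[2])
})

test_that("categorical comparisons use the Pearson chi-square without correction", {
  prop <- matrix(c(10, 20, 30, 60), 2, byrow = TRUE)  # proportional rows
  expect_equal(compare_groups_categorical(prop)$statistic, 0, tolerance = 1e-12)

  # genotype-by-sex table: oracle computed from the literal Pearson formula
  tab <- matrix(c(73, 150, 67, 86, 134, 52), nrow = 2, byrow = TRUE)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  want <- sum((tab - e)^2 / e)
  got <- compare_groups_categorical(tab)
  expect_equal(got$statistic, want, tolerance = 1e-12)
  expect_equal(got$statistic, 3.2819, tolerance = 1e-3)
  expect_equal(got$p_value, 0.1938, tolerance = 1e-3)
  expect_equal(got$df, 2)

  perfect <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(compare_groups_categorical(perfect)$statistic, 20)

  expect_error(compare_groups_categorical(matrix(c(5, 0, 7, 0), 2)),
               "zero-margin")
  expect_error(compare_groups_categorical(matrix(1:3, 1)), "2x2")
})

test_that("the KS normality screen is calibrated-or-conservative and has power", {
  rej <- vapply(1:200, function(s) {
    x <- withr::with_seed(s + 2000, rnorm(1000))
    ks_normality(x)$p_value < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.07)  # plug-in parameters make classic KS conservative

  heavy <- withr::with_seed(63, exp(rnorm(500, 0, 1)))
  expect_lt(ks_normality(heavy)$p_value, 0.01)

  expect_error(ks_normality(c(1, 2, 3, 4)), "at least 5")
  expect_error(ks_normality(rep(1, 10)), "constant")
})
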