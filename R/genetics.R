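#' Summarise a biallelic SNP
#'
#' Counts genotypes and computes the minor-allele frequency. Input genotypes
#' are minor-allele copy counts 0/1/2; if the putative minor allele turns out
#' to be the major one in the data at hand (frequency above 0.5) the coding is
#' flipped so that MAF <= 0.5 by construction, and the relabelling is
#' reported. Ties at exactly 0.5 keep the supplied orientation.
#'
#' @param genotypes Integer/numeric vector with values in 0/1/2 or `NA`.
#' @param snp_id Label used in the output row.
#' @return A one-row tibble: `snp_id`, `n_MM`, `n_Mm`, `n_mm`, `maf`,
#'   `n_missing`, `relabelled`.
#' @export
summarize_snp <- function(genotypes, snp_id = "snp") {
  g <- genotypes
  if (!all(is.na(g) | g %in% c(0, 1, 2))) {
    abort("genotypes must be 0, 1, 2 or missing")
  }
  n_missing <- sum(is.na(g))
  g <- g[!is.na(g)]
  if (length(g) == 0) abort(paste0("all genotypes missing for ", snp_id))
  maf <- (2 * sum(g == 2) + sum(g == 1)) / (2 * length(g))
  relabelled <- FALSE
  if (maf > 0.5) {
    g <- 2 - g
    maf <- 1 - maf
    relabelled <- TRUE
    inform(paste0(snp_id, ": supplied minor allele has frequency > 0.5; ",
                  "alleles relabelled so that MAF <= 0.5"))
  }
  tibble::tibble(
    snp_id = snp_id,
    n_MM = sum(g == 0), n_Mm = sum(g == 1), n_mm = sum(g == 2),
    maf = maf, n_missing = n_missing, relabelled = relabelled
  )
}

#' Hardy-Weinberg equilibrium test
#'
#' Pearson 1-df chi-square of the observed genotype counts against the
#' Hardy-Weinberg expectations \eqn{(n\hat p^2, 2n\hat p\hat q, n\hat q^2)}
#' with the allele frequency estimated from the same counts; no continuity
#' correction (matching common genetic-analysis software). An exact test
#' (enumeration of heterozygote counts conditional on the minor-allele count)
#' is available with `method = "exact"`.
#'
#' @param counts Genotype counts `c(n_MM, n_Mm, n_mm)` (major homozygote,
#'   heterozygote, minor homozygote), or a row from [summarize_snp()].
#' @param method `"chisq"` (default) or `"exact"`.
#' @return A one-row tibble: `chi2`, `df`, `p` (for the exact test `chi2` and
#'   `df` are `NA`).
#' @export
#' @examples
#' hwe_test(c(159, 284, 119)) # chi2 about 0.14, p about 0.71
hwe_test <- function(counts, method = c("chisq", "exact")) {
  method <- match.arg(method)
  if (is.data.frame(counts)) counts <- c(counts$n_MM, counts$n_Mm, counts$n_mm)
  if (length(counts) != 3 || any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be three non-negative integers (n_MM, n_Mm, n_mm)")
  }
  n <- sum(counts)
  if (n == 0) abort("total genotype count is zero")
  q <- (2 * counts[3] + counts[2]) / (2 * n)
  p <- 1 - q
  if (method == "chisq") {
    expected <- n * c(p^2, 2 * p * q, q^2)
    if (q %in% c(0, 1)) {
      # monomorphic: observed equals expected by construction
      chi2 <- 0
    } else {
      chi2 <- sum((counts - expected)^2 / expected)
    }
    return(tibble::tibble(chi2 = chi2, df = 1L,
                          p = pchisq(chi2, df = 1, lower.tail = FALSE)))
  }
  # exact test: conditional distribution of heterozygote count given
  # n subjects and n_minor minor alleles
  n_minor <- 2 * counts[3] + counts[2]
  n_het_obs <- counts[2]
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  logprob <- vapply(hets, function(h) {
    hom_m <- (n_minor - h) / 2
    hom_M <- n - h - hom_m
    lgamma(n + 1) - lgamma(hom_M + 1) - lgamma(h + 1) - lgamma(hom_m + 1) +
      h * log(2)
  }, numeric(1))
  prob <- exp(logprob - max(logprob))
  prob <- prob / sum(prob)
  p_exact <- sum(prob[prob <= prob[hets == n_het_obs] * (1 + 1e-12)])
  tibble::tibble(chi2 = NA_real_, df = NA_integer_, p = min(1, p_exact))
}

#' Code genotypes for regression
#'
#' Additive coding is the number of minor-allele copies (0/1/2); dominant
#' coding is minor-allele carrier status (0 for major homozygotes, 1 for
#' heterozygotes and minor homozygotes). Missing genotypes propagate.
#'
#' @param genotypes Vector of 0/1/2 minor-allele counts (or `NA`).
#' @param mode `"additive"` or `"dominant"`.
#' @return Numeric vector.
#' @export
code_genotypes <- function(genotypes, mode = c("additive", "dominant")) {
  mode <- match.arg(mode)
  if (!all(is.na(genotypes) | genotypes %in% c(0, 1, 2))) {
    abort("genotypes must be 0, 1, 2 or missing")
  }
  g <- as.numeric(genotypes)
  if (mode == "additive") g else as.numeric(g >= 1)
}

#' Two-locus linkage disequilibrium from unphased genotypes
#'
#' Estimates the four haplotype frequencies of a SNP pair by
#' expectation-maximisation over the double-heterozygote phase ambiguity
#' (every other genotype combination resolves its two haplotypes uniquely),
#' then derives \eqn{D = p_{11} - p_1 p_2}, \eqn{D'} and \eqn{r^2}. The EM is
#' initialised at linkage-equilibrium frequencies and is deterministic; the
#' two-locus likelihood is well behaved so no restarts are used.
#'
#' @param geno1,geno2 Vectors of 0/1/2 minor-allele counts; pairs with a
#'   missing value at either locus are dropped.
#' @param tol Convergence tolerance on the maximum haplotype-frequency change
#'   (default 1e-8).
#' @param max_iter Maximum EM iterations (default 1000).
#' @return An object of class `ld_result`: a list with `hap_freqs` (named
#'   `"11"`, `"10"`, `"01"`, `"00"`; 1 = minor allele), `maf1`, `maf2`, `D`,
#'   `D_prime`, `r2`, `em_iterations`, `converged`, `log_likelihood`
#'   (per-iteration trace), `n_used`.
#' @export
estimate_ld <- function(geno1, geno2, tol = 1e-8, max_iter = 1000) {
  keep <- !is.na(geno1) & !is.na(geno2)
  g1 <- geno1[keep]; g2 <- geno2[keep]
  if (!all(g1 %in% 0:2) || !all(g2 %in% 0:2)) {
    abort("genotypes must be 0, 1 or 2")
  }
  n <- length(g1)
  if (n == 0) abort("no complete genotype pairs")
  if (length(unique(g1)) == 1 || length(unique(g2)) == 1) {
    abort("monomorphic SNP: linkage disequilibrium is undefined")
  }
  cnt <- matrix(0, 3, 3)  # cnt[i+1, j+1] = subjects with i, j minor copies
  for (k in seq_len(n)) cnt[g1[k] + 1, g2[k] + 1] <- cnt[g1[k] + 1, g2[k] + 1] + 1

  # fixed haplotype contributions from unambiguous genotypes
  base <- c("11" = 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3],
            "10" = 2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1],
            "01" = 2 * cnt[1, 3] + cnt[1, 2] + cnt[2, 3],
            "00" = 2 * cnt[1, 1] + cnt[1, 2] + cnt[2, 1])
  n_dh <- cnt[2, 2]  # double heterozygotes: phase ambiguous

  p1 <- (2 * sum(cnt[3, ]) + sum(cnt[2, ])) / (2 * n)
  p2 <- (2 * sum(cnt[, 3]) + sum(cnt[, 2])) / (2 * n)
  f <- c("11" = p1 * p2, "10" = p1 * (1 - p2),
         "01" = (1 - p1) * p2, "00" = (1 - p1) * (1 - p2))

  loglik <- function(f) {
    pg <- function(i, j) {
      if (i == 1 && j == 1) return(2 * (f["11"] * f["00"] + f["10"] * f["01"]))
      # enumerate compatible ordered haplotype pairs
      haps <- expand.grid(a1 = 0:1, a2 = 0:1, b1 = 0:1, b2 = 0:1)
      haps <- haps[haps$a1 + haps$b1 == i & haps$a2 + haps$b2 == j, , drop = FALSE]
      key <- function(x, y) paste0(x, y)
      sum(f[key(haps$a1, haps$a2)] * f[key(haps$b1, haps$b2)])
    }
    ll <- 0
    for (i in 0:2) for (j in 0:2) {
      if (cnt[i + 1, j + 1] > 0) ll <- ll + cnt[i + 1, j + 1] * log(pg(i, j))
    }
    ll
  }

  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    denom <- f["11"] * f["00"] + f["10"] * f["01"]
    p_cis <- if (denom > 0) f["11"] * f["00"] / denom else 0.5
    cnts <- base + n_dh * c("11" = p_cis, "10" = 1 - p_cis,
                            "01" = 1 - p_cis, "00" = p_cis)
    f_new <- cnts / (2 * n)
    ll_trace <- c(ll_trace, loglik(f_new))
    if (max(abs(f_new - f)) < tol) {
      f <- f_new
      converged <- TRUE
      break
    }
    f <- f_new
  }

  D <- unname(f["11"] - p1 * p2)
  d_max <- if (D >= 0) min(p1 * (1 - p2), (1 - p1) * p2) else
    min(p1 * p2, (1 - p1) * (1 - p2))
  structure(list(
    hap_freqs = f, maf1 = p1, maf2 = p2,
    D = D,
    D_prime = if (d_max > 0) abs(D) / d_max else NA_real_,
    r2 = D^2 / (p1 * (1 - p1) * p2 * (1 - p2)),
    em_iterations = iter, converged = converged,
    log_likelihood = ll_trace, n_used = n
  ), class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat("Two-locus LD (EM over unphased genotypes)\n")
  cat(sprintf("  n = %d, MAF = %.3f / %.3f\n", x$n_used, x$maf1, x$maf2))
  cat(sprintf("  haplotype freqs: 11=%.4f 10=%.4f 01=%.4f 00=%.4f\n",
              x$hap_freqs["11"], x$hap_freqs["10"],
              x$hap_freqs["01"], x$hap_freqs["00"]))
  cat(sprintf("  D = %.4f, D' = %.3f, r2 = %.3f (%d iterations%s)\n",
              x$D, x$D_prime, x$r2, x$em_iterations,
              if (x$converged) ", converged" else ", NOT converged"))
  invisible(x)
}

#' @method tidy ld_result
#' @export
tidy.ld_result <- function(x, ...) {
  tibble::tibble(
    haplotype = names(x$hap_freqs), frequency = unname(x$hap_freqs),
    D = x$D, D_prime = x$D_prime, r2 = x$r2
  )
}
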