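#' Per-SNP fixation index between two populations
#'
#' Default `"nei"` estimator (GST from allele frequencies):
#' `FST = (HT - HS) / HT` with `HT = 2 pbar (1 - pbar)`,
#' `HS = mean(2 p_i (1 - p_i))` and `pbar` the unweighted mean frequency;
#' bounded in `[0, 1]` and equal to 0 when both populations are
#' monomorphic for the same allele (`HT = 0`). The `"weir_cockerham"`
#' option applies the two-population sample-size-corrected
#' variance-components estimator (theta-hat); it needs per-population
#' sample sizes, may be negative for undifferentiated SNPs, and uses
#' Hardy-Weinberg expected heterozygosity unless observed heterozygote
#' frequencies are supplied.
#'
#' @param p_a,p_b allele frequency vectors (same length) in the two
#'   populations; `NA` entries yield `NA` FST.
#' @param estimator `"nei"` (default) or `"weir_cockerham"`.
#' @param n_a,n_b numbers of diploid individuals behind `p_a`, `p_b`
#'   (required for `"weir_cockerham"`).
#' @param het_a,het_b observed heterozygote proportions (optional,
#'   `"weir_cockerham"` only).
#' @return Numeric vector of per-SNP FST values.
#' @export
fst_per_snp <- function(p_a, p_b, estimator = c("nei", "weir_cockerham"),
                        n_a = NULL, n_b = NULL,
                        het_a = NULL, het_b = NULL) {
  estimator <- match.arg(estimator)
  stopifnot(length(p_a) == length(p_b))
  if (estimator == "nei") {
    pbar <- (p_a + p_b) / 2
    ht <- 2 * pbar * (1 - pbar)
    hs <- (2 * p_a * (1 - p_a) + 2 * p_b * (1 - p_b)) / 2
    ifelse(ht > 0, (ht - hs) / ht, 0)
  } else {
    if (is.null(n_a) || is.null(n_b)) {
      stop("weir_cockerham estimator needs sample sizes n_a and n_b")
    }
    if (is.null(het_a)) het_a <- 2 * p_a * (1 - p_a)
    if (is.null(het_b)) het_b <- 2 * p_b * (1 - p_b)
    r <- 2
    nbar <- (n_a + n_b) / 2
    nc <- (r * nbar - (n_a^2 + n_b^2) / (r * nbar)) / (r - 1)
    pbar <- (n_a * p_a + n_b * p_b) / (r * nbar)
    s2 <- (n_a * (p_a - pbar)^2 + n_b * (p_b - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n_a * het_a + n_b * het_b) / (r * nbar)
    a_comp <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b_comp <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    c_comp <- hbar / 2
    denom <- a_comp + b_comp + c_comp
    ifelse(denom != 0, a_comp / denom, 0)
  }
}

#' Multi-locus FST by ratio of sums
#'
#' Combines per-SNP variance components across loci before taking the
#' ratio (the standard multi-locus form, far less biased than averaging
#' per-SNP ratios). For `"weir_cockerham"` without sample sizes the
#' infinite-sample limit of the components is used, appropriate when the
#' inputs are model frequencies rather than sample estimates; under the
#' Balding-Nichols model with parameter `F` in each of two populations
#' its expectation is `F` itself, so it is the estimator used for
#' differentiation-parameter recovery. `"nei"` gives `sum(HT - HS) /
#' sum(HT)`.
#'
#' @inheritParams fst_per_snp
#' @return Single overall FST value.
#' @export
fst_overall <- function(p_a, p_b, estimator = c("weir_cockerham", "nei"),
                        n_a = NULL, n_b = NULL) {
  estimator <- match.arg(estimator)
  ok <- !(is.na(p_a) | is.na(p_b))
  p_a <- p_a[ok]; p_b <- p_b[ok]
  if (estimator == "nei") {
    pbar <- (p_a + p_b) / 2
    ht <- 2 * pbar * (1 - pbar)
    hs <- (2 * p_a * (1 - p_a) + 2 * p_b * (1 - p_b)) / 2
    return(sum(ht - hs) / sum(ht))
  }
  if (is.null(n_a) || is.null(n_b)) {
    # infinite-sample limit: a = s2, b = pq - s2/2 - h/2, c = h/2
    pbar <- (p_a + p_b) / 2
    s2 <- (p_a - p_b)^2 / 2
    h <- (2 * p_a * (1 - p_a) + 2 * p_b * (1 - p_b)) / 2
    a <- s2
    b <- pbar * (1 - pbar) - s2 / 2 - h / 2
    c <- h / 2
  } else {
    r <- 2
    nbar <- (n_a + n_b) / 2
    nc <- (r * nbar - (n_a^2 + n_b^2) / (r * nbar)) / (r - 1)
    pbar <- (n_a * p_a + n_b * p_b) / (r * nbar)
    s2 <- (n_a * (p_a - pbar)^2 + n_b * (p_b - pbar)^2) / ((r - 1) * nbar)
    h <- (n_a * 2 * p_a * (1 - p_a) + n_b * 2 * p_b * (1 - p_b)) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - h / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * h)
    c <- h / 2
  }
  sum(a) / sum(a + b + c)
}

#' Difference in association-p rankings between two populations
#'
#' Restricts both rankings to their shared SNPs, re-ranks each within the
#' intersection (p ascending, ties by chromosome then position), and
#' returns the per-SNP absolute rank difference. Absolute value makes
#' "DRP above its mean" a two-sided measure of discordant association.
#'
#' @param ranked_a,ranked_b rankings from [rank_snps()].
#' @return data.frame with columns `snp`, `rank_a`, `rank_b`, `drp`.
#' @export
drp <- function(ranked_a, ranked_b) {
  shared <- intersect(ranked_a$snp, ranked_b$snp)
  if (length(shared) == 0L) stop("rankings share no SNPs")
  rerank <- function(r) {
    r <- r[r$snp %in% shared, , drop = FALSE]
    r <- r[order(r$p, r$chr, r$pos), , drop = FALSE]
    stats::setNames(seq_len(nrow(r)), r$snp)
  }
  ra <- rerank(ranked_a); rb <- rerank(ranked_b)
  data.frame(snp = shared, rank_a = as.integer(ra[shared]),
             rank_b = as.integer(rb[shared]),
             drp = abs(as.integer(ra[shared]) - as.integer(rb[shared])),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Chi-square test of dependence between differentiation and rank difference
#'
#' Dichotomizes FST and DRP at their means (strictly greater = "high";
#' ties at the mean fall in "low"), builds the 2x2 table, and applies the
#' Pearson chi-square with 1 df (no continuity correction by default).
#' An observed high-high count above its expectation, with a significant
#' p, indicates that strongly differentiated SNPs also tend to differ in
#' their association ranking between the populations.
#'
#' @param fst,drp_values per-SNP vectors of equal length; `NA` pairs are
#'   dropped with a message.
#' @param yates apply the continuity correction (default FALSE).
#' @return List with `table` (2x2 counts, rows = DRP low/high, columns =
#'   FST low/high), `observed` and `expected` (high-high cell), `chi2`,
#'   `p`, `n`. Degenerate dichotomizations (an empty margin) give `NA`
#'   chi2/p with a warning.
#' @export
dependence_test <- function(fst, drp_values, yates = FALSE) {
  stopifnot(length(fst) == length(drp_values))
  ok <- !(is.na(fst) | is.na(drp_values))
  if (any(!ok)) message(sum(!ok), " SNP(s) with undefined FST or DRP dropped")
  fst <- fst[ok]; drp_values <- drp_values[ok]
  hi_f <- fst > mean(fst)
  hi_d <- drp_values > mean(drp_values)
  tab <- table(factor(hi_d, levels = c(FALSE, TRUE),
                      labels = c("drp_low", "drp_high")),
               factor(hi_f, levels = c(FALSE, TRUE),
                      labels = c("fst_low", "fst_high")))
  n <- sum(tab)
  expected_hh <- sum(tab["drp_high", ]) * sum(tab[, "fst_high"]) / n
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    warning("degenerate dichotomization: a margin is empty")
    return(list(table = tab, observed = tab["drp_high", "fst_high"],
                expected = expected_hh, chi2 = NA_real_, p = NA_real_,
                n = n))
  }
  ct <- stats::chisq.test(tab, correct = yates)
  list(table = tab, observed = as.integer(tab["drp_high", "fst_high"]),
       expected = expected_hh, chi2 = unname(ct$statistic),
       p = unname(ct$p.value), n = n)
}

#' FST x DRP summary for a population pair
#'
#' Computes per-SNP FST (from parents or affected offspring) and DRP over
#' the SNPs shared by two cohorts' rankings, then the mean-dichotomized
#' dependence test — one row of a differentiation-association report.
#'
#' @param cohort_a,cohort_b [trio_cohort()]s.
#' @param ranked_a,ranked_b rankings from [rank_snps()] for the two
#'   cohorts.
#' @param who `"parents"` or `"offspring"`: frequency source for FST.
#' @param estimator passed to [fst_per_snp()].
#' @return List with `records` (data.frame: snp, fst, drp) and the
#'   [dependence_test()] result plus `mean_fst`, `median_fst`,
#'   `fst_range`.
#' @export
fst_drp_summary <- function(cohort_a, cohort_b, ranked_a, ranked_b,
                            who = c("parents", "offspring"),
                            estimator = c("nei", "weir_cockerham")) {
  who <- match.arg(who); estimator <- match.arg(estimator)
  d <- drp(ranked_a, ranked_b)
  fa <- allele1_freq(cohort_a, who)[match(d$snp, cohort_a$markers$snp)]
  fb <- allele1_freq(cohort_b, who)[match(d$snp, cohort_b$markers$snp)]
  n_a <- if (who == "parents") 2L * n_trios(cohort_a) else n_trios(cohort_a)
  n_b <- if (who == "parents") 2L * n_trios(cohort_b) else n_trios(cohort_b)
  fst <- fst_per_snp(fa, fb, estimator, n_a = n_a, n_b = n_b)
  dep <- dependence_test(fst, d$drp)
  c(list(records = data.frame(snp = d$snp, fst = fst, drp = d$drp,
                              stringsAsFactors = FALSE),
         mean_fst = mean(fst, na.rm = TRUE),
         median_fst = stats::median(fst, na.rm = TRUE),
         fst_range = range(fst, na.rm = TRUE)),
    dep[c("table", "observed", "expected", "chi2", "p", "n")])
}
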