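#' SNP quality-control criteria
#'
#' @param max_missing maximum tolerated missing-call proportion per SNP,
#'   computed over all individuals (parents and offspring). Default 0.15.
#' @param hwe_min_p minimum Hardy-Weinberg equilibrium p-value on parental
#'   genotypes. Default 1e-6.
#' @return A `qc_criteria` list.
#' @export
qc_criteria <- function(max_missing = 0.15, hwe_min_p = 1e-6) {
  if (max_missing <= 0 || max_missing >= 1) stop("max_missing must be in (0, 1)")
  if (hwe_min_p <= 0 || hwe_min_p >= 1) stop("hwe_min_p must be in (0, 1)")
  structure(list(max_missing = max_missing, hwe_min_p = hwe_min_p),
            class = "qc_criteria")
}

#' Hardy-Weinberg goodness-of-fit on genotype counts
#'
#' Asymptotic 1-df chi-square comparing observed genotype counts with
#' Hardy-Weinberg expectations at the estimated allele frequency.
#' Monomorphic markers have chi-square 0 and p = 1 by construction.
#' An exact (Fisher-style enumeration over heterozygote counts) variant is
#' available for small founder counts.
#'
#' @param n_aa,n_ab,n_bb genotype counts (allele1 homozygote, heterozygote,
#'   allele2 homozygote).
#' @param method `"chisq"` (default) or `"exact"`.
#' @return List with `chi2` (NA for exact) and `p`.
#' @export
hwe_test <- function(n_aa, n_ab, n_bb, method = c("chisq", "exact")) {
  method <- match.arg(method)
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(list(chi2 = NA_real_, p = NA_real_))
  p <- (2 * n_aa + n_ab) / (2 * n)
  if (p == 0 || p == 1) return(list(chi2 = 0, p = 1))
  if (method == "chisq") {
    expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    chi2 <- sum((c(n_aa, n_ab, n_bb) - expected)^2 / expected)
    list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
  } else {
    list(chi2 = NA_real_, p = hwe_exact_p(n_aa, n_ab, n_bb))
  }
}

# Exact HWE p: sum of probabilities of heterozygote counts no more likely
# than the observed one, conditional on allele counts (Wigginton et al. style).
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  hets <- seq(n_a %% 2L, min(n_a, 2 * n - n_a), by = 2L)
  logp <- vapply(hets, function(h) {
    haa <- (n_a - h) / 2; hbb <- n - haa - h
    lchoose(n, haa) + lchoose(n - haa, h) + h * log(2) -
      lchoose(2 * n, n_a)
  }, numeric(1))
  prob <- exp(logp - max(logp)); prob <- prob / sum(prob)
  sum(prob[prob <= prob[hets == n_ab] * (1 + 1e-12)])
}

genotype_count_matrix <- function(g) {
  # g: n x m dosage matrix; returns m x 4 counts (n0, n1, n2, n_miss)
  cbind(n2 = colSums(g == 2L, na.rm = TRUE),
        n1 = colSums(g == 1L, na.rm = TRUE),
        n0 = colSums(g == 0L, na.rm = TRUE),
        nmiss = colSums(is.na(g)))
}

#' Per-SNP quality-control filter
#'
#' A SNP passes when its missing-call proportion over all individuals is
#' below `criteria$max_missing` and the parental-genotype HWE p-value
#' exceeds `criteria$hwe_min_p`. Monomorphic SNPs pass HWE trivially and
#' are flagged.
#'
#' @param cohort a [trio_cohort()].
#' @param criteria a [qc_criteria()].
#' @param hwe_method `"chisq"` (default) or `"exact"`, see [hwe_test()].
#' @return data.frame with columns `snp`, `missing_prop`, `hwe_p`,
#'   `monomorphic`, `qc_pass`, `reason` (`""` when passing).
#' @export
filter_snps <- function(cohort, criteria = qc_criteria(),
                        hwe_method = c("chisq", "exact")) {
  hwe_method <- match.arg(hwe_method)
  if (n_trios(cohort) == 0L || n_snps(cohort) == 0L) {
    stop("cohort has no trios or no SNPs")
  }
  n_ind <- 3L * n_trios(cohort)
  miss <- (colSums(is.na(cohort$father)) + colSums(is.na(cohort$mother)) +
             colSums(is.na(cohort$offspring))) / n_ind
  pf <- genotype_count_matrix(cohort$father)
  pm <- genotype_count_matrix(cohort$mother)
  n_aa <- pf[, "n2"] + pm[, "n2"]
  n_ab <- pf[, "n1"] + pm[, "n1"]
  n_bb <- pf[, "n0"] + pm[, "n0"]
  mono <- (n_ab + n_bb == 0L) | (n_ab + n_aa == 0L)
  if (hwe_method == "chisq") {
    n <- n_aa + n_ab + n_bb
    p <- ifelse(n > 0, (2 * n_aa + n_ab) / (2 * pmax(n, 1L)), NA_real_)
    hwe_p <- rep(1, n_snps(cohort))
    poly <- !is.na(p) & p > 0 & p < 1
    if (any(poly)) {
      e_aa <- n[poly] * p[poly]^2
      e_ab <- n[poly] * 2 * p[poly] * (1 - p[poly])
      e_bb <- n[poly] * (1 - p[poly])^2
      chi2 <- (n_aa[poly] - e_aa)^2 / e_aa + (n_ab[poly] - e_ab)^2 / e_ab +
        (n_bb[poly] - e_bb)^2 / e_bb
      hwe_p[poly] <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
    }
  } else {
    hwe_p <- mapply(function(a, b, c) hwe_test(a, b, c, "exact")$p,
                    n_aa, n_ab, n_bb)
  }
  fail_miss <- miss >= criteria$max_missing
  fail_hwe <- hwe_p <= criteria$hwe_min_p
  reason <- rep("", n_snps(cohort))
  reason[fail_hwe] <- "hwe"
  reason[fail_miss] <- "missingness"
  reason[fail_miss & fail_hwe] <- "missingness;hwe"
  data.frame(snp = cohort$markers$snp, missing_prop = miss, hwe_p = hwe_p,
             monomorphic = mono, qc_pass = !(fail_miss | fail_hwe),
             reason = reason, stringsAsFactors = FALSE, row.names = NULL)
}

# Vectorized transmission counting over all SNPs.
# Returns an m x 5 matrix with columns a, b, c, d, q where q is the number
# of complete, Mendelian-consistent trios contributing at that SNP.
transmission_count_matrix <- function(cohort) {
  gf <- cohort$father; gm <- cohort$mother; gc <- cohort$offspring
  complete <- !(is.na(gf) | is.na(gm) | is.na(gc))
  hf <- !is.na(gf) & gf == 1L
  hm <- !is.na(gm) & gm == 1L
  # transmitted allele1 counts forced by homozygous parents
  tf_min <- ifelse(hf, 0L, gf %/% 2L); tf_max <- ifelse(hf, 1L, gf %/% 2L)
  tm_min <- ifelse(hm, 0L, gm %/% 2L); tm_max <- ifelse(hm, 1L, gm %/% 2L)
  consistent <- complete & gc >= (tf_min + tm_min) & gc <= (tf_max + tm_max)

  # a: M1M1 parents, d: M2M2 parents (each contributes its transmitted =
  # non-transmitted allele), in consistent trios only
  a <- colSums(consistent & gf == 2L) + colSums(consistent & gm == 2L)
  d <- colSums(consistent & gf == 0L) + colSums(consistent & gm == 0L)

  # heterozygous parents: transmitted allele resolved by subtracting the
  # other parent's forced contribution; double-het with het child is
  # phase-ambiguous and contributes one b and one c
  one_het_f <- consistent & hf & !hm
  one_het_m <- consistent & hm & !hf
  both_het <- consistent & hf & hm
  tf <- gc - gm %/% 2L  # valid where one_het_f
  tm <- gc - gf %/% 2L  # valid where one_het_m
  b <- colSums(one_het_f & tf == 1L) + colSums(one_het_m & tm == 1L) +
    colSums(both_het & gc == 2L) * 2L + colSums(both_het & gc == 1L)
  c <- colSums(one_het_f & tf == 0L) + colSums(one_het_m & tm == 0L) +
    colSums(both_het & gc == 0L) * 2L + colSums(both_het & gc == 1L)
  q <- colSums(consistent)
  cbind(a = a, b = b, c = c, d = d, q = q)
}

#' Transmission counts at one SNP
#'
#' Classifies each parental transmission at the given SNP into the 2x2
#' transmitted x non-transmitted table over alleles M1 (`allele1`) and M2:
#' `a` = M1/M1, `b` = M1/M2, `c` = M2/M1, `d` = M2/M2. Only heterozygous
#' parents contribute to `b` or `c`. Trios with a missing member genotype
#' or a Mendelian inconsistency at this SNP are excluded from all counts.
#' The double-heterozygote trio with a heterozygous child is phase-ambiguous
#' and contributes one `b` and one `c`.
#'
#' @param cohort a [trio_cohort()].
#' @param snp_id marker identifier.
#' @return List with integer counts `a`, `b`, `c`, `d` and `q` (number of
#'   contributing trios); `a + b + c + d == 2 * q`.
#' @export
count_transmissions <- function(cohort, snp_id) {
  j <- snp_index(cohort, snp_id)
  sub <- trio_subset(cohort, j)
  m <- transmission_count_matrix(sub)
  as.list(m[1, ])
}

trio_subset <- function(cohort, cols) {
  structure(list(markers = cohort$markers[cols, , drop = FALSE],
                 father = cohort$father[, cols, drop = FALSE],
                 mother = cohort$mother[, cols, drop = FALSE],
                 offspring = cohort$offspring[, cols, drop = FALSE],
                 population = cohort$population),
            class = "trio_cohort")
}

#' TDT statistic from transmission counts
#'
#' The transmission disequilibrium statistic `(b - c)^2 / (b + c)`,
#' referred to the chi-square distribution with 1 df. When `b + c == 0`
#' the SNP is uninformative and both values are `NA` (no heterozygous
#' parental transmissions).
#'
#' @param counts list or vector with elements `b` and `c`.
#' @return List with `chi2` and `p`.
#' @export
tdt_statistic <- function(counts) {
  b <- counts[["b"]]; c <- counts[["c"]]
  if (b + c == 0) return(list(chi2 = NA_real_, p = NA_real_))
  chi2 <- (b - c)^2 / (b + c)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Minor-allele frequency from a cohort subset
#'
#' Allele-count MAF among non-missing genotypes of the selected
#' individuals: `min(f, 1 - f)` where `f` is the frequency of `allele1`.
#'
#' @param cohort a [trio_cohort()].
#' @param snp_id marker identifier; `NULL` returns all SNPs.
#' @param who `"offspring"` (default, as used for reporting) or
#'   `"parents"`.
#' @return MAF (scalar for one SNP, vector otherwise); `NA` when the
#'   subset is entirely missing.
#' @export
compute_maf <- function(cohort, snp_id = NULL, who = c("offspring", "parents")) {
  who <- match.arg(who)
  f <- allele1_freq(cohort, who)
  maf <- unname(pmin(f, 1 - f))
  if (!is.null(snp_id)) maf[snp_index(cohort, snp_id)] else maf
}

allele1_freq <- function(cohort, who = c("offspring", "parents")) {
  who <- match.arg(who)
  if (who == "offspring") {
    tot <- colSums(cohort$offspring, na.rm = TRUE)
    n <- colSums(!is.na(cohort$offspring))
  } else {
    tot <- colSums(cohort$father, na.rm = TRUE) +
      colSums(cohort$mother, na.rm = TRUE)
    n <- colSums(!is.na(cohort$father)) + colSums(!is.na(cohort$mother))
  }
  unname(ifelse(n > 0, tot / (2 * n), NA_real_))
}

#' Genomic inflation factor
#'
#' `lambda = median(chi2) / qchisq(0.5, 1)`, the ratio of the median
#' observed 1-df association statistic to its null median (about 0.4549).
#' Values near 1 indicate no systematic inflation.
#'
#' @param chi2_values vector of 1-df chi-square statistics; `NA`s dropped.
#' @return Scalar lambda.
#' @export
genomic_inflation <- function(chi2_values) {
  chi2_values <- chi2_values[!is.na(chi2_values)]
  if (length(chi2_values) == 0L) stop("no valid chi-square statistics")
  stats::median(chi2_values) / stats::qchisq(0.5, df = 1)
}

#' Per-cohort TDT association table
#'
#' Applies QC, counts transmissions, and computes the TDT statistic and
#' offspring MAF for every SNP in one cohort. Genomic-control-corrected
#' p-values (`p_gc`) are reported as an extra column when
#' `genomic_control = TRUE`; they never affect ranking, which is scale
#' invariant.
#'
#' @param cohort a [trio_cohort()].
#' @param criteria a [qc_criteria()].
#' @param genomic_control add a `p_gc` column with chi2 / lambda p-values.
#' @param hwe_method passed to [filter_snps()].
#' @return data.frame with columns `snp`, `chr`, `pos`, `a`, `b`, `c`,
#'   `d`, `q`, `chi2`, `p`, `maf_offspring`, `qc_pass`, `reason` (and
#'   optionally `p_gc`).
#' @export
tdt_cohort <- function(cohort, criteria = qc_criteria(),
                       genomic_control = FALSE,
                       hwe_method = c("chisq", "exact")) {
  qc <- filter_snps(cohort, criteria, hwe_method = match.arg(hwe_method))
  tc <- transmission_count_matrix(cohort)
  bc <- tc[, "b"] + tc[, "c"]
  chi2 <- ifelse(bc > 0, (tc[, "b"] - tc[, "c"])^2 / pmax(bc, 1L), NA_real_)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  res <- data.frame(
    snp = cohort$markers$snp, chr = cohort$markers$chr,
    pos = cohort$markers$pos,
    a = tc[, "a"], b = tc[, "b"], c = tc[, "c"], d = tc[, "d"], q = tc[, "q"],
    chi2 = chi2, p = p,
    maf_offspring = compute_maf(cohort, who = "offspring"),
    qc_pass = qc$qc_pass, reason = qc$reason,
    stringsAsFactors = FALSE, row.names = NULL)
  if (genomic_control) {
    lambda <- genomic_inflation(res$chi2[res$qc_pass])
    res$p_gc <- stats::pchisq(res$chi2 / max(lambda, 1),
                              df = 1, lower.tail = FALSE)
  }
  res
}

#' Pooled mega-analysis across cohorts
#'
#' Restricts to SNPs passing QC in every cohort, sums transmission counts
#' across cohorts, and computes the TDT on the pooled counts. The TDT
#' remains valid on pooled samples because transmissions are conditioned
#' on parental genotypes, so population structure does not confound it.
#'
#' @param cohorts list of [trio_cohort()]s sharing a marker id space.
#' @param criteria a [qc_criteria()].
#' @return data.frame as in [tdt_cohort()] (without MAF), restricted to
#'   SNPs passing QC in all cohorts; empty (with a warning) when no SNP
#'   passes everywhere.
#' @export
mega_tdt <- function(cohorts, criteria = qc_criteria()) {
  stopifnot(length(cohorts) >= 1L)
  pass_ids <- lapply(cohorts, function(x) {
    qc <- filter_snps(x, criteria)
    qc$snp[qc$qc_pass]
  })
  shared <- Reduce(intersect, pass_ids)
  if (length(shared) == 0L) {
    warning("no SNPs pass QC in every cohort; mega-analysis table is empty")
    return(data.frame(snp = character(), chr = character(), pos = integer(),
                      a = integer(), b = integer(), c = integer(),
                      d = integer(), q = integer(), chi2 = numeric(),
                      p = numeric(), stringsAsFactors = FALSE))
  }
  mk <- cohorts[[1]]$markers
  mk <- mk[match(shared, mk$snp), , drop = FALSE]
  tot <- matrix(0, nrow = length(shared), ncol = 5,
                dimnames = list(NULL, c("a", "b", "c", "d", "q")))
  for (x in cohorts) {
    idx <- match(shared, x$markers$snp)
    if (anyNA(idx)) stop("cohorts do not share a marker identifier space")
    tc <- transmission_count_matrix(trio_subset(x, idx))
    tot <- tot + tc
  }
  bc <- tot[, "b"] + tot[, "c"]
  chi2 <- ifelse(bc > 0, (tot[, "b"] - tot[, "c"])^2 / pmax(bc, 1), NA_real_)
  data.frame(snp = shared, chr = mk$chr, pos = mk$pos,
             a = tot[, "a"], b = tot[, "b"], c = tot[, "c"], d = tot[, "d"],
             q = tot[, "q"], chi2 = chi2,
             p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
             stringsAsFactors = FALSE, row.names = NULL)
}
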