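test_that("QC filters follow the missingness and HWE rules", {
  # 25 trios, one SNP in perfect HWE among the 50 parents (p = 0.5:
  # 12/13 AA is impossible, use 16 het of 32 parents -> p = 0.5, exact
  # proportions 8/16/8)
  n <- 16L
  gf <- matrix(c(rep(2L, 4), rep(1L, 8), rep(0L, 4)), ncol = 1)
  gm <- matrix(c(rep(2L, 4), rep(1L, 8), rep(0L, 4)), ncol = 1)
  gc <- matrix(rep(1L, n), ncol = 1)
  coh <- make_cohort(gf, gm, gc)
  qc <- filter_snps(coh)
  expect_true(qc$qc_pass)
  expect_equal(qc$hwe_p, 1)
  expect_identical(qc$reason, "")

  # 16% missing calls fail with reason "missingness"
  coh2 <- sim_null_cohort(200, 50, seed = 2)
  n_calls <- 3 * 50
  n_mask <- ceiling(0.16 * n_calls)
  coh2$offspring[seq_len(n_mask), 1] <- NA_integer_
  qc2 <- filter_snps(coh2)
  expect_false(qc2$qc_pass[1])
  expect_identical(qc2$reason[1], "missingness")

  # monomorphic SNP passes QC with the flag set
  coh3 <- make_cohort(matrix(2L, 10, 1), matrix(2L, 10, 1),
                      matrix(2L, 10, 1))
  qc3 <- filter_snps(coh3)
  expect_true(qc3$qc_pass)
  expect_true(qc3$monomorphic)
  expect_equal(qc3$hwe_p, 1)

  # gross HWE violation (all parents heterozygous) fails
  k <- 200L
  coh4 <- make_cohort(matrix(1L, k, 1), matrix(1L, k, 1),
                      matrix(1L, k, 1))
  qc4 <- filter_snps(coh4)
  expect_false(qc4$qc_pass)
  expect_identical(qc4$reason, "hwe")
  # all-het chi-square equals the parent count
  expect_lt(qc4$hwe_p, pchisq(2 * k, 1, lower.tail = FALSE) * 1.01)
})

test_that("exact HWE test matches enumeration and flags the same gross violations", {
  # exact p by the package vs naive full enumeration over het counts
  p_pkg <- hwe_test(5, 20, 25, method = "exact")$p
  n <- 50; na <- 30
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  probs <- vapply(hets, function(h) {
    haa <- (na - h) / 2; hbb <- n - haa - h
    exp(lfactorial(n) - lfactorial(haa) - lfactorial(h) - lfactorial(hbb) +
          h * log(2) + lfactorial(na) + lfactorial(2 * n - na) -
          lfactorial(2 * n))
  }, numeric(1))
  p_oracle <- sum(probs[probs <= probs[hets == 20] * (1 + 1e-12)])
  expect_equal(p_pkg, p_oracle, tolerance = 1e-10)
  expect_equal(hwe_test(10, 0, 0, method = "exact")$p, 1)
})

test_that("transmission counting matches the 27-configuration enumeration oracle", {
  # spec-level examples first
  coh <- make_cohort(2L, 2L, 2L)
  expect_equal(count_transmissions(coh, "s001"),
               list(a = 2L, b = 0L, c = 0L, d = 0L, q = 1L))
  coh <- make_cohort(1L, 2L, 2L)  # father het transmits M1, mother a
  expect_equal(count_transmissions(coh, "s001"),
               list(a = 1L, b = 1L, c = 0L, d = 0L, q = 1L))
  coh <- make_cohort(1L, 1L, 1L)  # double het, het child: one b one c
  expect_equal(count_transmissions(coh, "s001"),
               list(a = 0L, b = 1L, c = 1L, d = 0L, q = 1L))

  # every ordered configuration of (father, mother, child) dosages
  for (gf in 0:2) for (gm in 0:2) for (gc in 0:2) {
    coh <- make_cohort(gf, gm, gc)
    got <- count_transmissions(coh, "s001")
    want <- oracle_count_transmissions(coh, 1L)
    expect_equal(got, want,
                 info = sprintf("config f=%d m=%d c=%d", gf, gm, gc))
    expect_equal(got$a + got$b + got$c + got$d, 2L * got$q)
  }

  # missing member or Mendelian inconsistency excludes the trio
  coh <- make_cohort(c(2L, 2L), c(2L, NA), c(0L, 2L))
  expect_equal(count_transmissions(coh, "s001"),
               list(a = 0L, b = 0L, c = 0L, d = 0L, q = 0L))
  expect_error(count_transmissions(coh, "zzz"), "unknown SNP")
})

test_that("vectorized transmission counts equal the per-trio recount oracle", {
  coh <- sim_null_cohort(60, 80, seed = 4, missing_rate = 0.05)
  # inject Mendelian errors to exercise exclusion
  coh2 <- simulate_trios(simulate_ancestral_frequencies(60, 0.1, 0.5, seed = 4),
                         80, missing_rate = 0.05, mendel_error_rate = 0.05,
                         seed = 5)
  for (c in list(coh, coh2)) {
    tc <- triorank:::transmission_count_matrix(c)
    for (j in seq_len(n_snps(c))) {
      expect_equal(as.list(tc[j, ]), oracle_count_transmissions(c, j))
    }
  }
})

test_that("the TDT statistic follows (b - c)^2 / (b + c)", {
  expect_equal(tdt_statistic(list(b = 7, c = 7)), list(chi2 = 0, p = 1))
  r <- tdt_statistic(list(b = 16, c = 4))
  expect_equal(r$chi2, 7.2)
  expect_equal(r$p, pchisq(7.2, 1, lower.tail = FALSE))
  # asymptotic p agrees with the exact two-sided binomial tail in order
  # of magnitude
  exact <- 2 * sum(dbinom(16:20, 20, 0.5))
  expect_gt(r$p / exact, 0.1)
  expect_lt(r$p / exact, 10)
  un <- tdt_statistic(list(b = 0, c = 0))
  expect_true(is.na(un$chi2) && is.na(un$p))
})

test_that("allele-label swap exchanges (a,d) and (b,c) but not chi2 or p", {
  coh <- sim_null_cohort(40, 60, seed = 8, missing_rate = 0.03)
  swapped <- coh
  swapped$father <- 2L - coh$father
  swapped$mother <- 2L - coh$mother
  swapped$offspring <- 2L - coh$offspring
  t1 <- triorank:::transmission_count_matrix(coh)
  t2 <- triorank:::transmission_count_matrix(swapped)
  expect_equal(t1[, "a"], t2[, "d"])
  expect_equal(t1[, "b"], t2[, "c"])
  expect_equal(t1[, "q"], t2[, "q"])
  tab1 <- tdt_cohort(coh); tab2 <- tdt_cohort(swapped)
  expect_equal(tab1$chi2, tab2$chi2)
  expect_equal(tab1$p, tab2$p)
})

test_that("MAF estimation counts alleles in the selected subset", {
  coh <- make_cohort(matrix(0L, 10, 1), matrix(2L, 10, 1),
                     matrix(1L, 10, 1))
  expect_equal(compute_maf(coh, "s001", who = "offspring"), 0.5)
  off <- matrix(c(rep(2L, 2), rep(1L, 4), rep(0L, 4)), ncol = 1)
  coh2 <- make_cohort(matrix(1L, 10, 1), matrix(1L, 10, 1), off)
  expect_equal(compute_maf(coh2, "s001", who = "offspring"), 0.4)
  coh3 <- make_cohort(matrix(0L, 5, 1), matrix(0L, 5, 1), matrix(0L, 5, 1))
  expect_equal(compute_maf(coh3, "s001"), 0)
  coh3$offspring[] <- NA_integer_
  expect_true(is.na(compute_maf(coh3, "s001", who = "offspring")))
  expect_equal(compute_maf(coh3, "s001", who = "parents"), 0)
})

test_that("genomic inflation is the median chi-square ratio", {
  med <- qchisq(0.5, 1)
  expect_equal(genomic_inflation(rep(med, 5)), 1)
  x <- rchisq(1e5, 1)
  lam <- genomic_inflation(x)
  expect_lt(abs(lam - 1), 0.02)
  expect_equal(genomic_inflation(2 * x), 2 * lam)
  expect_error(genomic_inflation(NA_real_), "no valid")
})

test_that("mega-analysis pools counts over QC-shared SNPs", {
  coh <- sim_null_cohort(50, 40, seed = 14)
  single <- mega_tdt(list(coh))
  per <- tdt_cohort(coh)
  keep <- per$qc_pass
  expect_equal(single$snp, per$snp[keep])
  expect_equal(single$chi2, per$chi2[keep])

  # additivity: counts (b=5, c=1) + (b=3, c=3) -> chi2 = 16/12
  mk <- make_markers(1)
  c1 <- make_cohort(matrix(1L, 6, 1), matrix(0L, 6, 1),
                    matrix(c(rep(1L, 5), 0L), ncol = 1), markers = mk)
  c2 <- make_cohort(matrix(1L, 6, 1), matrix(0L, 6, 1),
                    matrix(c(rep(1L, 3), rep(0L, 3)), ncol = 1), markers = mk)
  t1 <- count_transmissions(c1, "s001"); t2 <- count_transmissions(c2, "s001")
  expect_equal(c(t1$b, t1$c, t2$b, t2$c), c(5, 1, 3, 3))
  mega <- mega_tdt(list(c1, c2), qc_criteria(hwe_min_p = 1e-300))
  expect_equal(mega$b, 8); expect_equal(mega$c, 4)
  expect_equal(mega$chi2, 16 / 12)

  # SNP failing QC in one cohort is absent from the mega output
  cohA <- sim_null_cohort(30, 40, seed = 15)
  cohB <- sim_null_cohort(30, 40, seed = 16)
  cohB$offspring[1:38, 2] <- NA_integer_  # >15% missing in B only
  m <- mega_tdt(list(cohA, cohB))
  ids <- cohA$markers$snp
  expect_false(ids[2] %in% m$snp)
  expect_true(ids[3] %in% m$snp)
})

test_that("TDT power is monotone in the transmission distortion", {
  taus <- c(0.5, 0.55, 0.6, 0.65)
  rate <- vapply(seq_along(taus), function(i) {
    mk <- make_markers(800)
    risk <- risk_model(mk$snp, tau = taus[i])
    coh <- simulate_trios(rep(0.3, 800), 200, risk = risk, markers = mk,
                          seed = 100 + i)
    tab <- tdt_cohort(coh)
    mean(tab$p < 0.05, na.rm = TRUE)
  }, numeric(1))
  # allow small simulation wiggle at the null end
  expect_true(all(diff(rate) > -0.02))
  expect_gt(rate[4], rate[1] + 0.3)
})
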