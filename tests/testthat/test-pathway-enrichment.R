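# shared miniature instance: 120 genes, one SNP-gene mapping with
# variable SNP counts per gene, and a p-ranking over the SNPs
enrichment_fixture <- function(seed = 123, snps_per_gene = NULL) {
  set.seed(seed)
  genes <- sprintf("G%03d", 1:120)
  if (is.null(snps_per_gene)) {
    snps_per_gene <- sample(1:8, 120, replace = TRUE)
  }
  mapping <- data.frame(
    snp = sprintf("s%04d", seq_len(sum(snps_per_gene))),
    gene = rep(genes, snps_per_gene), distance = 0L,
    stringsAsFactors = FALSE)
  res <- data.frame(snp = mapping$snp, chr = 1L,
                    pos = seq_len(nrow(mapping)) * 10L,
                    p = runif(nrow(mapping)), stringsAsFactors = FALSE)
  list(genes = genes, mapping = mapping, ranked = rank_snps(res))
}

test_that("noteworthy genes are exactly those with a top-n SNP", {
  fx <- enrichment_fixture()
  n_all <- nrow(fx$ranked)
  expect_equal(declare_noteworthy(fx$mapping, fx$ranked, n_all),
               sort(unique(fx$mapping$gene)))

  for (n in c(10, 50, 200)) {
    nw <- declare_noteworthy(fx$mapping, fx$ranked, n)
    top <- fx$ranked$snp[seq_len(n)]
    # brute-force double loop over genes x top SNPs
    brute <- sort(unique(unlist(lapply(unique(fx$mapping$gene), function(g) {
      snps_g <- fx$mapping$snp[fx$mapping$gene == g]
      if (any(snps_g %in% top)) g else NULL
    }))))
    expect_equal(nw, brute)
    # equivalence: best-SNP-in-top iff any-SNP-in-top
    for (g in brute) {
      snps_g <- fx$mapping$snp[fx$mapping$gene == g]
      best <- snps_g[which.min(fx$ranked$p[match(snps_g, fx$ranked$snp)])]
      expect_true(best %in% top)
    }
  }

  # boundary: gene whose single SNP has rank n + 1 is not noteworthy
  gene_at <- fx$mapping$gene[fx$mapping$snp == fx$ranked$snp[51]]
  single <- fx$mapping[fx$mapping$gene == gene_at[1], ]
  if (nrow(single) == 1L) {
    expect_false(gene_at[1] %in% declare_noteworthy(fx$mapping, fx$ranked, 50))
  }
})

test_that("over-representation p equals the hypergeometric tail enumeration", {
  universe <- sprintf("u%03d", 1:100)
  gene_set <- universe[1:10]
  noteworthy <- c(universe[1:5], universe[11:25])  # overlap 5, draws 20
  r <- overrepresentation_test(noteworthy, gene_set, universe)
  expect_equal(r$observed, 5)
  expect_equal(r$p, oracle_hyper_upper(5, 10, 100, 20), tolerance = 1e-12)

  # no overlap -> p = 1; set = universe -> certainty, p = 1
  expect_equal(overrepresentation_test(universe[51:60], gene_set, universe)$p, 1)
  full <- overrepresentation_test(noteworthy, universe, universe)
  expect_equal(full$observed, 20)
  expect_equal(full$p, 1)
  expect_message(overrepresentation_test(c(noteworthy, "alien"),
                                         gene_set, universe), "dropped")
})

test_that("resampling null is deterministic, floored and 1 for empty observation", {
  fx <- enrichment_fixture(5)
  sets <- generate_gene_sets(fx$genes, 20, c(5, 20), seed = 6)
  e1 <- resampling_null(fx$mapping, fx$ranked, 40, sets, reps = 200,
                        mode = "snp", seed = 7)
  e2 <- resampling_null(fx$mapping, fx$ranked, 40, sets, reps = 200,
                        mode = "snp", seed = 7)
  expect_identical(e1, e2)
  expect_true(all(e1$emp_p >= 1 / 201))
  expect_true(all(e1$emp_p <= 1))
  expect_equal(e1$emp_p[e1$observed == 0], rep(1, sum(e1$observed == 0)))
  # hypergeometric column agrees with the standalone test
  universe <- sort(unique(fx$mapping$gene))
  nw <- declare_noteworthy(fx$mapping, fx$ranked, 40)
  i <- which.max(e1$observed)
  expect_equal(e1$hyper_p[i],
               overrepresentation_test(nw, sets[[i]], universe)$p)
})

test_that("SNP-mode null preserves gene-size bias, gene mode does not", {
  # half the genes carry 8 SNPs, half carry 1
  fx <- enrichment_fixture(8, snps_per_gene = rep(c(8L, 1L), 60))
  big <- fx$genes[seq(1, 120, by = 2)]
  set.seed(9)
  freq_in_null <- function(mode) {
    hits <- numeric(0)
    for (r in 1:300) {
      null <- triorank:::sample_null_genes(
        mode, 30, sort(unique(fx$mapping$gene)),
        names(split(fx$mapping$gene, fx$mapping$snp)),
        split(fx$mapping$gene, fx$mapping$snp))
      hits <- c(hits, mean(null %in% big))
    }
    mean(hits)
  }
  expect_gt(freq_in_null("snp"), 0.65)   # big genes dominate
  expect_lt(abs(freq_in_null("gene") - 0.5), 0.05)

  # unbiased regime: one SNP per gene -> the two nulls agree
  fx1 <- enrichment_fixture(10, snps_per_gene = rep(1L, 120))
  sets <- generate_gene_sets(fx1$genes, 10, c(10, 30), seed = 11)
  eg <- resampling_null(fx1$mapping, fx1$ranked, 30, sets, reps = 400,
                        mode = "gene", seed = 12)
  es <- resampling_null(fx1$mapping, fx1$ranked, 30, sets, reps = 400,
                        mode = "snp", seed = 13)
  # Monte-Carlo error of an empirical p at 400 reps is ~sqrt(p(1-p)/400)
  expect_true(all(abs(eg$emp_p - es$emp_p) <
                    3 * sqrt(pmax(eg$emp_p * (1 - eg$emp_p), 0.01) / 400) + 0.01))
})

test_that("gene-set ranking orders by empirical then hypergeometric p", {
  tab <- function(emp, hyp) {
    data.frame(set = c("S1", "S2", "S3"), size = 10L, observed = 1L,
               hyper_p = hyp, emp_p = emp, bh_q = emp, reps = 100L,
               stringsAsFactors = FALSE)
  }
  same <- tab(c(0.5, 0.01, 0.2), c(0.3, 0.01, 0.2))
  rg <- rank_gene_sets(list(EA = same, AA = same), k_grid = c(1, 2, 3))
  expect_equal(rg$ranked$EA$set, c("S2", "S3", "S1"))
  expect_equal(rg$shared$shared, c(1, 2, 3))

  other <- tab(c(0.01, 0.5, 0.2), c(0.01, 0.3, 0.2))  # S1 top instead
  rg2 <- rank_gene_sets(list(EA = same, AA = other), k_grid = c(1, 3))
  expect_equal(rg2$shared$shared, c(0, 3))
  expect_error(rank_gene_sets(list(EA = same, AA = same[1:2, ])),
               "same gene-set")
})

test_that("empirical enrichment p-values are near-uniform under the null", {
  fx <- enrichment_fixture(14)
  sets <- generate_gene_sets(fx$genes, 150, c(10, 40), seed = 15)
  e <- resampling_null(fx$mapping, fx$ranked, 40, sets, reps = 200,
                       mode = "snp", seed = 16)
  # discreteness and the add-one floor push p upward; compare against the
  # conservative bound only
  ks <- suppressWarnings(ks.test(e$emp_p, "punif"))
  expect_gt(ks$p.value, 1e-4)
  expect_gt(mean(e$emp_p), 0.35)
})
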