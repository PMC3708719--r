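# Independent brute-force oracles and small fixture builders.
# These deliberately re-derive results by enumeration / scalar loops,
# not by calling the package's vectorized code paths.

make_markers <- function(m, chr = NULL, pos = NULL) {
  data.frame(snp = sprintf("s%03d", seq_len(m)),
             chr = if (is.null(chr)) rep(1L, m) else chr,
             pos = if (is.null(pos)) seq(1000L, by = 1000L, length.out = m) else pos,
             allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)
}

make_cohort <- function(father, mother, offspring, markers = NULL,
                        population = "TEST") {
  father <- rbind(father); mother <- rbind(mother)
  offspring <- rbind(offspring)
  if (is.null(markers)) markers <- make_markers(ncol(father))
  trio_cohort(markers, father, mother, offspring, population)
}

# Transmission recount for a single trio at a single SNP.
# Enumerates candidate (paternal, maternal) transmitted-allele pairs and
# resolves the transmitted allele of each parent by subtraction of the
# other parent's contribution. Returns NULL for incomplete or
# Mendelian-inconsistent trios, else a length-4 a/b/c/d tally.
oracle_trio_tally <- function(gf, gm, gc) {
  if (is.na(gf) || is.na(gm) || is.na(gc)) return(NULL)
  allowed <- function(g) if (g == 1L) c(0L, 1L) else g %/% 2L
  sols <- list()
  for (tf in allowed(gf)) for (tm in allowed(gm)) {
    if (tf + tm == gc) sols[[length(sols) + 1L]] <- c(tf, tm)
  }
  if (length(sols) == 0L) return(NULL)
  # counts are phase-invariant across solutions; tally the first
  tf <- sols[[1]][1]; tm <- sols[[1]][2]
  tally <- c(a = 0L, b = 0L, c = 0L, d = 0L)
  for (par in list(c(gf, tf), c(gm, tm))) {
    g <- par[1]; t <- par[2]; nt <- g - t
    cell <- if (t == 1L && nt == 1L) "a" else if (t == 1L) "b"
            else if (nt == 1L) "c" else "d"
    tally[cell] <- tally[cell] + 1L
  }
  tally
}

oracle_count_transmissions <- function(cohort, j) {
  tot <- c(a = 0L, b = 0L, c = 0L, d = 0L); q <- 0L
  for (i in seq_len(nrow(cohort$father))) {
    t <- oracle_trio_tally(cohort$father[i, j], cohort$mother[i, j],
                           cohort$offspring[i, j])
    if (!is.null(t)) { tot <- tot + t; q <- q + 1L }
  }
  c(as.list(tot), list(q = q))
}

# All-pairs SNP-gene window check (1-based SNP pos, BED half-open gene).
oracle_snp_gene_pairs <- function(snps, genes, window) {
  hits <- list()
  for (i in seq_len(nrow(snps))) for (k in seq_len(nrow(genes))) {
    if (snps$chr[i] != genes$chr[k]) next
    p0 <- snps$pos[i] - 1L
    if (p0 >= genes$start[k] - window && p0 < genes$end[k] + window) {
      hits[[length(hits) + 1L]] <- c(snps$snp[i], genes$gene[k])
    }
  }
  if (length(hits) == 0L) return(character(0))
  sort(vapply(hits, paste, character(1), collapse = "|"))
}

# Hypergeometric upper tail by direct combinatorial summation.
oracle_hyper_upper <- function(obs, set_size, universe, draws) {
  k <- obs:min(set_size, draws)
  sum(exp(lchoose(set_size, k) + lchoose(universe - set_size, draws - k) -
            lchoose(universe, draws)))
}

# Beta sampler via independent gammas (alternative route to rbeta).
oracle_rbeta_gamma <- function(n, shape1, shape2) {
  g1 <- rgamma(n, shape1); g2 <- rgamma(n, shape2)
  g1 / (g1 + g2)
}

nei_fst_scalar <- function(p1, p2) {
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  if (ht == 0) return(0)
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  (ht - hs) / ht
}

# Quick null cohort for reuse across tests.
sim_null_cohort <- function(n_snps, n_trios, seed, missing_rate = 0) {
  freqs <- simulate_ancestral_frequencies(n_snps, 0.1, 0.5, seed = seed)
  simulate_trios(freqs, n_trios, missing_rate = missing_rate,
                 seed = seed + 1L)
}
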