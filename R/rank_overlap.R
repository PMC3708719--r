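#' Rank SNPs by association p-value
#'
#' Orders SNPs from most to least significant. Ties in p are broken by
#' (chromosome, position) ascending so that rankings are deterministic
#' across runs and platforms. Uninformative SNPs (no heterozygous
#' transmissions, `p` undefined) are excluded.
#'
#' @param results a TDT result table as from [tdt_cohort()] (columns
#'   `snp`, `chr`, `pos`, `p`; rows failing QC should be removed first,
#'   or set `qc_only = TRUE` to drop them here).
#' @param qc_only drop rows with `qc_pass == FALSE` when the column is
#'   present (default TRUE).
#' @return data.frame with columns `snp`, `chr`, `pos`, `p`, `rank`
#'   (1 = most significant), ordered by rank.
#' @export
rank_snps <- function(results, qc_only = TRUE) {
  if (anyDuplicated(results$snp)) stop("duplicate SNP ids in result table")
  if (qc_only && "qc_pass" %in% names(results)) {
    results <- results[results$qc_pass, , drop = FALSE]
  }
  results <- results[!is.na(results$p), , drop = FALSE]
  ord <- order(results$p, results$chr, results$pos)
  out <- results[ord, c("snp", "chr", "pos", "p"), drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Top-n SNP set
#'
#' @param ranked a ranking from [rank_snps()].
#' @param n number of top SNPs, `1 <= n <= nrow(ranked)`.
#' @return Character vector of the first `n` SNP ids.
#' @export
top_n <- function(ranked, n) {
  if (n < 1 || n > nrow(ranked)) {
    stop("n must lie in [1, ", nrow(ranked), "]")
  }
  ranked$snp[seq_len(n)]
}

#' Observed overlaps between top-n sets
#'
#' Exact intersection cardinalities for every pair of sets and for the
#' full (all-way) intersection.
#'
#' @param sets named list (>= 2) of id vectors.
#' @return List with `pairwise` (data.frame: set_a, set_b, observed) and
#'   `allway` (single count).
#' @export
overlap_counts <- function(sets) {
  stopifnot(length(sets) >= 2L)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  sets <- lapply(sets, unique)
  combs <- utils::combn(names(sets), 2L)
  pairwise <- data.frame(
    set_a = combs[1, ], set_b = combs[2, ],
    observed = apply(combs, 2L, function(pr) {
      length(intersect(sets[[pr[1]]], sets[[pr[2]]]))
    }),
    stringsAsFactors = FALSE)
  list(pairwise = pairwise,
       allway = length(Reduce(intersect, sets)))
}

#' Expected overlap of independent random subsets
#'
#' Chance expectation when each population's top-n set is an independent
#' uniform random subset of its size from a universe of `N` shared SNPs:
#' `n_a * n_b / N` pairwise and `n_a * n_b * n_c / N^2` three-way (by
#' linearity: each element is in all sets with probability
#' `prod(n_i / N)`).
#'
#' @param ns vector of subset sizes (length 2 for pairwise, 3 for
#'   three-way).
#' @param N universe size; every `ns` must be `<= N`.
#' @return Expected overlap count.
#' @export
expected_overlap <- function(ns, N) {
  if (any(ns > N)) stop("subset sizes cannot exceed the universe size N")
  if (any(ns < 0) || N <= 0) stop("sizes must be non-negative and N positive")
  N * prod(ns / N)
}

#' Cross-population replication count at a nominal threshold
#'
#' Counts how many SNPs from one population's top set have p below
#' `alpha` in another population, alongside the null expectation
#' `|top_set| * alpha` (each null p falls below alpha with probability
#' alpha). Ids absent from the other cohort are dropped with a message.
#'
#' @param top_set character vector of SNP ids.
#' @param other_p named numeric vector (or data.frame with `snp`, `p`)
#'   of the other population's p-values.
#' @param alpha nominal threshold in (0, 1), default 0.05.
#' @return List with `observed`, `expected`, `n_used`, `n_dropped`.
#' @export
replication_count <- function(top_set, other_p, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (is.data.frame(other_p)) {
    other_p <- stats::setNames(other_p$p, other_p$snp)
  }
  top_set <- unique(top_set)
  found <- top_set[top_set %in% names(other_p)]
  dropped <- length(top_set) - length(found)
  if (dropped > 0L) {
    message(dropped, " top SNP(s) absent from the other cohort were dropped")
  }
  list(observed = sum(other_p[found] < alpha, na.rm = TRUE),
       expected = length(top_set) * alpha,
       n_used = length(found), n_dropped = dropped)
}

#' Overlap report across a grid of top-n sizes
#'
#' For each n in `n_grid`, extracts each population's top-n set, counts
#' pairwise and all-way overlaps, and attaches the chance expectations
#' for a shared universe of `N` SNPs.
#'
#' @param rankings named list of rankings from [rank_snps()], one per
#'   population, computed on a shared SNP universe.
#' @param n_grid vector of top-n sizes.
#' @param N universe size; defaults to the number of SNPs shared by all
#'   rankings.
#' @return data.frame: `n`, `comparison`, `observed`, `expected`,
#'   `universe`.
#' @export
overlap_report <- function(rankings, n_grid = c(1000L, 2000L, 5000L,
                                                10000L, 50000L),
                           N = NULL) {
  stopifnot(length(rankings) >= 2L)
  shared <- Reduce(intersect, lapply(rankings, `[[`, "snp"))
  if (is.null(N)) N <- length(shared)
  rows <- list()
  for (n in n_grid) {
    if (n > min(vapply(rankings, nrow, integer(1)))) next
    sets <- lapply(rankings, top_n, n = n)
    oc <- overlap_counts(sets)
    pw <- oc$pairwise
    pw$comparison <- paste(pw$set_a, pw$set_b, sep = " & ")
    rows[[length(rows) + 1L]] <- data.frame(
      n = n, comparison = c(pw$comparison, "all"),
      observed = c(pw$observed, oc$allway),
      expected = c(rep(expected_overlap(c(n, n), N), nrow(pw)),
                   expected_overlap(rep(n, length(rankings)), N)),
      universe = N, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
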