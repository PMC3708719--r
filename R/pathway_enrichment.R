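#' Declare noteworthy genes from a top-n SNP set
#'
#' A gene is noteworthy when its most significant mapped SNP is among the
#' top n SNPs of the ranking — equivalently, when any of its mapped SNPs
#' is in the top-n set (the best SNP is in the set iff some SNP is, since
#' the set is a p-ordered prefix of the same ranking).
#'
#' @param mapping SNP-gene mapping from [map_snps_to_genes()].
#' @param ranked a ranking from [rank_snps()].
#' @param n top-n size.
#' @return Character vector of noteworthy gene names (sorted).
#' @export
declare_noteworthy <- function(mapping, ranked, n) {
  top <- top_n(ranked, n)
  sort(unique(mapping$gene[mapping$snp %in% top]))
}

#' Hypergeometric over-representation test
#'
#' One-sided upper-tail probability that a uniform random draw of
#' `|noteworthy|` genes from the universe contains at least the observed
#' number of genes of the target set: `P(X >= obs)` with population size
#' `|universe|`, `|gene_set|` successes and `|noteworthy|` draws.
#'
#' @param noteworthy character vector of noteworthy genes.
#' @param gene_set character vector, one gene set.
#' @param universe character vector, all scorable genes (those with at
#'   least one mapped SNP). Genes of `gene_set` or `noteworthy` outside
#'   the universe are dropped with a message.
#' @return List with `observed` (in-set noteworthy count) and `p`.
#' @export
overrepresentation_test <- function(noteworthy, gene_set, universe) {
  universe <- unique(universe)
  gene_set <- unique(gene_set); noteworthy <- unique(noteworthy)
  n_out <- sum(!gene_set %in% universe) + sum(!noteworthy %in% universe)
  if (n_out > 0L) {
    message(n_out, " gene(s) outside the universe were dropped")
    gene_set <- intersect(gene_set, universe)
    noteworthy <- intersect(noteworthy, universe)
  }
  obs <- length(intersect(noteworthy, gene_set))
  p <- stats::phyper(obs - 1L, length(gene_set),
                     length(universe) - length(gene_set),
                     length(noteworthy), lower.tail = FALSE)
  list(observed = obs, p = p)
}

# Sample one null noteworthy gene list.
# mode "gene": uniform genes from the universe.
# mode "snp": a uniform SNP order, accumulating each SNP's mapped genes
# until the target number of distinct genes is reached (genes with more
# SNPs enter null lists more often, mirroring the gene-size bias of the
# observed noteworthy construction).
sample_null_genes <- function(mode, size, universe, snp_ids, snp_gene_list) {
  if (mode == "gene") return(sample(universe, size))
  ord <- sample.int(length(snp_ids))
  genes <- unlist(snp_gene_list[ord], use.names = FALSE)
  genes <- genes[!duplicated(genes)]
  genes[seq_len(size)]
}

#' Resampling empirical significance for gene-set over-representation
#'
#' For each replicate a null noteworthy gene list of the observed size is
#' drawn (see `mode`), every gene set is scored by its in-set count, and
#' the empirical p for a set is `(1 + #{replicates with count >= observed})
#' / (reps + 1)` — the add-one form keeps p at or above `1/(reps + 1)`.
#' This resampling null is far cheaper than permuting disease status and
#' directly controls the number of noteworthy genes.
#'
#' @param mapping SNP-gene mapping from [map_snps_to_genes()]; the SNP
#'   universe for mode `"snp"` is its mapped SNPs restricted to the
#'   ranking.
#' @param ranked a ranking from [rank_snps()].
#' @param n top-n size defining the observed noteworthy genes.
#' @param gene_sets named list of gene-id vectors (e.g. from
#'   [read_gmt()] or [generate_gene_sets()]).
#' @param reps number of resampling replicates (>= 1).
#' @param mode `"snp"` (default; preserves gene-size bias) or `"gene"`
#'   (uniform gene resampling).
#' @param seed optional integer seed.
#' @return data.frame with columns `set`, `size` (in-universe set size),
#'   `observed`, `hyper_p`, `emp_p`, `bh_q` (Benjamini-Hochberg over the
#'   empirical p-values), `reps`; ordered as supplied.
#' @export
resampling_null <- function(mapping, ranked, n, gene_sets, reps = 1000L,
                            mode = c("snp", "gene"), seed = NULL) {
  mode <- match.arg(mode)
  if (reps < 1L) stop("reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  mapping <- mapping[mapping$snp %in% ranked$snp, , drop = FALSE]
  universe <- sort(unique(mapping$gene))
  noteworthy <- declare_noteworthy(mapping, ranked, n)
  size <- length(noteworthy)
  if (size > length(universe)) {
    stop("noteworthy list larger than the gene universe")
  }
  sets_in <- lapply(gene_sets, function(s) intersect(unique(s), universe))
  observed <- vapply(sets_in, function(s) length(intersect(noteworthy, s)),
                     integer(1))
  hyper_p <- vapply(seq_along(sets_in), function(i) {
    stats::phyper(observed[i] - 1L, length(sets_in[[i]]),
                  length(universe) - length(sets_in[[i]]), size,
                  lower.tail = FALSE)
  }, numeric(1))

  # gene -> set-index inverted list for fast per-replicate scoring
  set_idx <- rep.int(seq_along(sets_in), lengths(sets_in))
  gene_of <- unlist(sets_in, use.names = FALSE)
  by_gene <- split(set_idx, factor(gene_of, levels = universe))
  snp_gene_list <- NULL; snp_ids <- NULL
  if (mode == "snp") {
    snp_gene_list <- split(mapping$gene, mapping$snp)
    snp_ids <- names(snp_gene_list)
  }
  exceed <- integer(length(sets_in))
  if (size > 0L) {
    for (r in seq_len(reps)) {
      null_genes <- sample_null_genes(mode, size, universe, snp_ids,
                                      snp_gene_list)
      counts <- tabulate(unlist(by_gene[null_genes], use.names = FALSE),
                         nbins = length(sets_in))
      exceed <- exceed + (counts >= observed)
    }
  } else {
    exceed <- rep(reps, length(sets_in))  # every null matches observed = 0
  }
  emp_p <- (1 + exceed) / (reps + 1)
  data.frame(set = names(gene_sets), size = lengths(sets_in),
             observed = observed, hyper_p = hyper_p, emp_p = emp_p,
             bh_q = stats::p.adjust(emp_p, method = "BH"), reps = reps,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank gene sets and count cross-population sharing among top-k
#'
#' Orders each population's enrichment table by empirical p (ties by
#' hypergeometric p, then set name) and counts the gene sets shared by
#' all populations among each population's top k, over a grid of k.
#'
#' @param results named list of enrichment tables from
#'   [resampling_null()], one per population, over the same gene-set
#'   collection.
#' @param k_grid vector of top-k sizes; defaults to 5, 10, ..., up to the
#'   collection size.
#' @return List with `ranked` (named list of ordered tables) and
#'   `shared` (data.frame: k, shared).
#' @export
rank_gene_sets <- function(results, k_grid = NULL) {
  stopifnot(length(results) >= 1L)
  sets0 <- sort(results[[1]]$set)
  for (r in results) {
    if (!identical(sort(r$set), sets0)) {
      stop("all populations must use the same gene-set collection")
    }
  }
  ranked <- lapply(results, function(r) {
    r <- r[order(r$emp_p, r$hyper_p, r$set), , drop = FALSE]
    rownames(r) <- NULL
    r
  })
  n_sets <- length(sets0)
  if (is.null(k_grid)) k_grid <- seq(5L, n_sets, by = 5L)
  k_grid <- k_grid[k_grid <= n_sets]
  shared <- vapply(k_grid, function(k) {
    tops <- lapply(ranked, function(r) r$set[seq_len(k)])
    length(Reduce(intersect, tops))
  }, integer(1))
  list(ranked = ranked,
       shared = data.frame(k = k_grid, shared = shared))
}
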