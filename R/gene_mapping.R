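#' Map SNPs to genes within a flanking window
#'
#' A SNP is assigned to a gene when it lies inside the gene body or within
#' `window` bp of either end (default 20 kb, the distance within which
#' most trait-associated loci fall relative to their gene). Gene
#' coordinates are 0-based half-open (BED); SNP positions are 1-based
#' (MAP convention) and converted internally, so a SNP exactly 20,000 bp
#' upstream of the gene start (or downstream of its end) is mapped and
#' one at 20,001 bp is not. A SNP may map to several genes.
#'
#' @param snps marker table with columns `snp`, `chr`, `pos` (1-based).
#' @param genes gene annotation with columns `gene`, `chr`, `start`,
#'   `end` (0-based half-open), as from [generate_gene_annotation()] or
#'   [read_bed()].
#' @param window flanking distance in bp, `>= 0`.
#' @return data.frame with columns `snp`, `gene`, `distance` (0 inside
#'   the gene body, bp to the nearest end otherwise).
#' @export
map_snps_to_genes <- function(snps, genes, window = 20000L) {
  if (window < 0) stop("window must be non-negative")
  out <- list()
  for (chr in unique(genes$chr)) {
    g <- genes[genes$chr == chr, , drop = FALSE]
    s <- snps[snps$chr == chr, , drop = FALSE]
    if (nrow(s) == 0L) next
    pos0 <- s$pos - 1L
    for (k in seq_len(nrow(g))) {
      hit <- pos0 >= (g$start[k] - window) & pos0 < (g$end[k] + window)
      if (!any(hit)) next
      p <- pos0[hit]
      dist <- pmax(0L, pmax(g$start[k] - p, p - (g$end[k] - 1L)))
      out[[length(out) + 1L]] <- data.frame(
        snp = s$snp[hit], gene = g$gene[k], distance = dist,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(snp = character(), gene = character(),
                      distance = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gene-level p-values from mapped SNPs
#'
#' The gene-level statistic is the minimum association p over the gene's
#' mapped SNPs, with the best SNP recorded; ties broken by (chromosome,
#' position). No correction for the number of SNPs per gene is applied
#' at this stage (the count is reported so gene-size bias can be judged;
#' the enrichment stage's SNP-resampling null corrects for it).
#'
#' @param mapping SNP-gene mapping from [map_snps_to_genes()].
#' @param tdt_results table with columns `snp`, `chr`, `pos`, `p`.
#' @return data.frame with columns `gene`, `best_snp`, `p`, `n_snps`,
#'   genes with no mapped SNP in `tdt_results` absent.
#' @export
gene_level_p <- function(mapping, tdt_results) {
  keep <- !is.na(tdt_results$p)
  res <- tdt_results[keep, , drop = FALSE]
  m <- mapping[mapping$snp %in% res$snp, , drop = FALSE]
  if (nrow(m) == 0L) {
    return(data.frame(gene = character(), best_snp = character(),
                      p = numeric(), n_snps = integer(),
                      stringsAsFactors = FALSE))
  }
  idx <- match(m$snp, res$snp)
  m$p <- res$p[idx]; m$chr <- res$chr[idx]; m$pos <- res$pos[idx]
  m <- m[order(m$p, m$chr, m$pos), , drop = FALSE]
  first <- !duplicated(m$gene)
  out <- data.frame(gene = m$gene[first], best_snp = m$snp[first],
                    p = m$p[first],
                    n_snps = as.vector(table(m$gene)[m$gene[first]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes hit by a top SNP set
#'
#' Returns the genes having at least one mapped SNP in the given top set,
#' with per-gene counts of top SNPs, and the number of top SNPs that
#' mapped to at least one gene.
#'
#' @param mapping SNP-gene mapping from [map_snps_to_genes()].
#' @param top_set character vector of SNP ids.
#' @return List with `genes` (data.frame: gene, n_top_snps) and
#'   `n_top_snps_mapped`.
#' @export
genes_from_top_snps <- function(mapping, top_set) {
  m <- mapping[mapping$snp %in% top_set, , drop = FALSE]
  if (nrow(m) == 0L) {
    return(list(genes = data.frame(gene = character(),
                                   n_top_snps = integer(),
                                   stringsAsFactors = FALSE),
                n_top_snps_mapped = 0L))
  }
  tab <- table(m$gene)
  list(genes = data.frame(gene = names(tab),
                          n_top_snps = as.integer(tab),
                          stringsAsFactors = FALSE, row.names = NULL),
       n_top_snps_mapped = length(unique(m$snp)))
}

#' Observed and expected gene-level overlap across populations
#'
#' Intersections of per-population gene sets together with their chance
#' expectations under independent uniform random gene subsets of the
#' observed sizes from a universe of `gene_universe` genes (same product
#' form as [expected_overlap()]).
#'
#' @param gene_sets named list (>= 2) of per-population gene-name vectors.
#' @param gene_universe number of genes in the universe; defaults must be
#'   supplied by the caller (typically all annotated genes).
#' @return data.frame: `comparison`, `observed`, `expected`, `universe`.
#' @export
gene_overlap <- function(gene_sets, gene_universe) {
  stopifnot(length(gene_sets) >= 2L)
  oc <- overlap_counts(gene_sets)
  pw <- oc$pairwise
  sizes <- vapply(gene_sets, function(s) length(unique(s)), integer(1))
  exp_pw <- mapply(function(a, b) expected_overlap(c(sizes[[a]], sizes[[b]]),
                                                   gene_universe),
                   pw$set_a, pw$set_b)
  data.frame(
    comparison = c(paste(pw$set_a, pw$set_b, sep = " & "), "all"),
    observed = c(pw$observed, oc$allway),
    expected = c(exp_pw, expected_overlap(sizes, gene_universe)),
    universe = gene_universe, stringsAsFactors = FALSE)
}
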