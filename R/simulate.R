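#' Draw ancestral allele frequencies
#'
#' Samples per-SNP ancestral minor-allele frequencies uniformly on
#' `[maf_low, maf_high]`. These are the frequencies around which each
#' population's own frequencies are dispersed by [draw_population_frequencies()].
#'
#' @param n_snps number of SNPs.
#' @param maf_low,maf_high frequency bounds, `0 < maf_low <= maf_high <= 0.5`.
#' @param seed optional integer seed for reproducibility.
#' @return Numeric vector of length `n_snps`.
#' @export
simulate_ancestral_frequencies <- function(n_snps, maf_low = 0.05,
                                           maf_high = 0.5, seed = NULL) {
  if (n_snps < 0) stop("n_snps must be non-negative")
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5)) {
    stop("require 0 < maf_low <= maf_high <= 0.5")
  }
  if (!is.null(seed)) set.seed(seed)
  stats::runif(n_snps, maf_low, maf_high)
}

#' Draw population allele frequencies under the Balding-Nichols model
#'
#' Given ancestral frequencies `p` and a differentiation parameter `F`,
#' each population frequency is drawn independently per SNP from
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`. The Beta has mean `p` and
#' variance `F p (1 - p)`, so `F` is the expected fixation index between
#' two populations drawn from the same ancestral frequency. `F = 0`
#' returns the ancestral vector unchanged (the degenerate Beta limit).
#'
#' @param ancestral vector of ancestral frequencies, all in (0, 1).
#' @param fst_param differentiation parameter `F` in `[0, 1)`.
#' @param seed optional integer seed.
#' @return Vector of population frequencies in `[0, 1]`.
#' @export
draw_population_frequencies <- function(ancestral, fst_param, seed = NULL) {
  if (fst_param < 0 || fst_param >= 1) stop("fst_param must be in [0, 1)")
  if (any(ancestral <= 0) || any(ancestral >= 1)) {
    stop("ancestral frequencies must lie strictly in (0, 1)")
  }
  if (fst_param == 0) return(ancestral)
  if (!is.null(seed)) set.seed(seed)
  scale <- (1 - fst_param) / fst_param
  stats::rbeta(length(ancestral), ancestral * scale, (1 - ancestral) * scale)
}

#' Risk model for planted association signal
#'
#' Describes which markers carry a planted transmission distortion. At a
#' risk SNP, a heterozygous parent transmits the `allele1` (risk) allele to
#' the affected offspring with probability `tau` instead of the Mendelian
#' 0.5; `tau = 0.5` is the TDT null.
#'
#' @param risk_snp_ids character vector of causal marker ids (may be empty).
#' @param tau transmission probability of the risk allele from a
#'   heterozygous parent, in (0, 1).
#' @param planted_gene_set_id optional name of the gene set enriched for
#'   risk genes (used by [generate_gene_sets()] bookkeeping).
#' @return A `risk_model` list.
#' @export
risk_model <- function(risk_snp_ids = character(), tau = 0.5,
                       planted_gene_set_id = NULL) {
  if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)")
  structure(list(risk_snp_ids = as.character(risk_snp_ids), tau = tau,
                 planted_gene_set_id = planted_gene_set_id),
            class = "risk_model")
}

default_marker_map <- function(n_snps, n_chr = 22L) {
  chr <- rep(seq_len(n_chr), length.out = n_snps)
  chr <- sort(chr)
  pos <- integer(n_snps)
  for (c in unique(chr)) {
    k <- sum(chr == c)
    pos[chr == c] <- seq(10000L, by = 5000L, length.out = k)
  }
  data.frame(snp = sprintf("rs%06d", seq_len(max(n_snps, 1L))[seq_len(n_snps)]),
             chr = chr, pos = pos,
             allele1 = "A", allele2 = "B",
             stringsAsFactors = FALSE)
}

#' Simulate an affected-offspring trio cohort
#'
#' Parents are drawn under Hardy-Weinberg equilibrium at the supplied
#' population frequencies; each parent transmits one allele to the
#' offspring. Heterozygous parents transmit `allele1` with probability 0.5
#' at null SNPs and with probability `risk$tau` at planted risk SNPs
#' (affected-offspring ascertainment is modelled directly as transmission
#' distortion). Genotype calls are then masked missing independently at
#' `missing_rate`; `mendel_error_rate` optionally replaces offspring calls
#' with a random dosage to exercise Mendelian-inconsistency handling.
#'
#' @param pop_freqs per-SNP frequency of `allele1` in this population.
#' @param n_trios number of trios.
#' @param risk a [risk_model()]; defaults to the global null.
#' @param missing_rate per-call missing probability in `[0, 1)`.
#' @param mendel_error_rate per-offspring-call probability of replacement
#'   by a uniform random dosage (default 0).
#' @param markers optional marker map (as in [trio_cohort()]); defaults to
#'   evenly spaced markers across 22 autosomes.
#' @param population cohort label.
#' @param seed optional integer seed.
#' @return A [trio_cohort()].
#' @export
simulate_trios <- function(pop_freqs, n_trios, risk = risk_model(),
                           missing_rate = 0, mendel_error_rate = 0,
                           markers = NULL, population = "POP",
                           seed = NULL) {
  if (any(pop_freqs < 0) || any(pop_freqs > 1)) {
    stop("pop_freqs must lie in [0, 1]")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  m <- length(pop_freqs)
  if (is.null(markers)) markers <- default_marker_map(m)
  if (nrow(markers) != m) stop("marker map length does not match pop_freqs")
  unknown <- setdiff(risk$risk_snp_ids, markers$snp)
  if (length(unknown) > 0L) {
    stop("risk SNP id(s) not in marker list: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)

  # theta[j]: probability a heterozygous parent transmits allele1 at SNP j
  theta <- rep(0.5, m)
  theta[markers$snp %in% risk$risk_snp_ids] <- risk$tau

  pmat <- matrix(pop_freqs, nrow = n_trios, ncol = m, byrow = TRUE)
  father <- matrix(stats::rbinom(n_trios * m, 2L, pmat), n_trios, m)
  mother <- matrix(stats::rbinom(n_trios * m, 2L, pmat), n_trios, m)
  tmat <- matrix(theta, nrow = n_trios, ncol = m, byrow = TRUE)
  transmit <- function(g) {
    t <- g %/% 2L                       # hom: transmitted allele forced
    het <- g == 1L
    n_het <- sum(het)
    if (n_het > 0L) t[het] <- stats::rbinom(n_het, 1L, tmat[het])
    t
  }
  offspring <- transmit(father) + transmit(mother)

  if (mendel_error_rate > 0) {
    hit <- stats::runif(n_trios * m) < mendel_error_rate
    offspring[hit] <- sample(0:2, sum(hit), replace = TRUE)
  }
  if (missing_rate > 0) {
    mask <- function(g) {
      g[stats::runif(length(g)) < missing_rate] <- NA_integer_
      g
    }
    father <- mask(father); mother <- mask(mother); offspring <- mask(offspring)
  }
  trio_cohort(markers, father, mother, offspring, population)
}

#' Generate a non-overlapping gene annotation
#'
#' Places `n_genes` genes on the given chromosomes with uniform random
#' lengths, no overlaps, and at least `min_gap` bp between consecutive
#' genes. Coordinates are stored 0-based half-open (BED convention).
#'
#' @param n_genes number of genes.
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param gene_length_range length-2 vector, bp bounds on gene length.
#' @param min_gap minimum gap between consecutive genes (bp).
#' @param seed optional integer seed.
#' @return data.frame with columns `gene`, `chr`, `start`, `end`
#'   (0-based half-open), sorted by (chr, start).
#' @export
generate_gene_annotation <- function(n_genes, chrom_lengths,
                                     gene_length_range = c(5000L, 50000L),
                                     min_gap = 1000L, seed = NULL) {
  if (n_genes == 0L) {
    return(data.frame(gene = character(), chr = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  if (!is.null(seed)) set.seed(seed)
  chrs <- names(chrom_lengths)
  if (is.null(chrs)) chrs <- as.character(seq_along(chrom_lengths))
  # spread genes over chromosomes proportionally to length
  n_per <- as.vector(table(factor(
    sample(chrs, n_genes, replace = TRUE, prob = chrom_lengths / sum(chrom_lengths)),
    levels = chrs)))
  max_len <- gene_length_range[2]
  out <- vector("list", length(chrs))
  for (k in seq_along(chrs)) {
    g <- n_per[k]
    if (g == 0L) next
    L <- chrom_lengths[k]
    lens <- sample(seq(gene_length_range[1], gene_length_range[2]), g,
                   replace = TRUE)
    slack <- L - sum(lens) - (g - 1L) * min_gap
    if (slack < 0) {
      stop("infeasible gene packing on chromosome ", chrs[k],
           ": total span exceeds chromosome length")
    }
    # distribute the slack as random extra gaps before each gene
    cuts <- sort(sample.int(slack + 1L, g, replace = TRUE) - 1L)
    starts <- cuts + c(0L, cumsum(lens[-g] + min_gap))
    out[[k]] <- data.frame(chr = chrs[k], start = starts,
                           end = starts + lens, stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, out)
  ann <- ann[order(ann$chr, ann$start), , drop = FALSE]
  ann <- data.frame(gene = sprintf("GENE%04d", seq_len(nrow(ann))),
                    ann, stringsAsFactors = FALSE)
  rownames(ann) <- NULL
  ann
}

#' Generate named gene sets with an optional planted set
#'
#' Draws `n_sets` gene sets of uniform random sizes from the annotation's
#' gene namespace. When `planted_genes` is supplied, exactly one set (the
#' first, named `planted_set_name`) contains all of them, padded with
#' random genes up to its drawn size.
#'
#' @param genes a gene annotation (data.frame with a `gene` column) or a
#'   character vector of gene names.
#' @param n_sets number of sets.
#' @param size_range length-2 integer vector of set-size bounds.
#' @param planted_genes optional character vector of genes that must
#'   co-occur in one set.
#' @param planted_set_name name for the planted set.
#' @param seed optional integer seed.
#' @return Named list of character vectors (a gene-set collection).
#' @export
generate_gene_sets <- function(genes, n_sets, size_range = c(10L, 50L),
                               planted_genes = NULL,
                               planted_set_name = "PLANTED_SET",
                               seed = NULL) {
  pool <- if (is.data.frame(genes)) genes$gene else as.character(genes)
  if (size_range[1] < 1 || size_range[2] > length(pool)) {
    stop("size_range must lie within [1, number of genes]")
  }
  if (!is.null(planted_genes) && length(planted_genes) > size_range[2]) {
    stop("planted gene list exceeds the maximum set size")
  }
  if (!is.null(seed)) set.seed(seed)
  sizes <- sample(seq(size_range[1], size_range[2]), n_sets, replace = TRUE)
  sets <- vector("list", n_sets)
  names(sets) <- sprintf("SET%04d", seq_len(n_sets))
  start <- 1L
  if (!is.null(planted_genes)) {
    sz <- max(sizes[1], length(planted_genes))
    pad <- sample(setdiff(pool, planted_genes), sz - length(planted_genes))
    sets[[1]] <- sample(c(planted_genes, pad))
    names(sets)[1] <- planted_set_name
    start <- 2L
  }
  for (i in seq(from = start, length.out = n_sets - start + 1L)) {
    s <- sample(pool, sizes[i])
    # keep the planted set unique: no other set may contain all planted genes
    while (!is.null(planted_genes) && all(planted_genes %in% s)) {
      s <- sample(pool, sizes[i])
    }
    sets[[i]] <- s
  }
  sets
}
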