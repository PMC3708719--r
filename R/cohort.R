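#' Trio cohort container
#'
#' A `trio_cohort` holds genotypes for father/mother/affected-offspring
#' triples across a common marker map, for one population. Genotypes are
#' stored as integer matrices (trios in rows, SNPs in columns) counting
#' copies of `allele1` (the "M1" allele): 0, 1, 2 or `NA` for a missing
#' call.
#'
#' @param markers data.frame with columns `snp`, `chr`, `pos`, `allele1`,
#'   `allele2`; positions must be strictly increasing within a chromosome.
#' @param father,mother,offspring integer matrices of allele1 dosages,
#'   one row per trio, one column per marker; `NA` = missing call.
#' @param population single character label for the cohort.
#'
#' @return An object of class `trio_cohort`.
#' @export
trio_cohort <- function(markers, father, mother, offspring, population) {
  stopifnot(is.data.frame(markers))
  required <- c("snp", "chr", "pos", "allele1", "allele2")
  missing_cols <- setdiff(required, names(markers))
  if (length(missing_cols) > 0L) {
    stop("markers is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(markers$snp)) {
    stop("duplicate SNP identifiers in marker map")
  }
  for (chr in unique(markers$chr)) {
    pos <- markers$pos[markers$chr == chr]
    if (is.unsorted(pos, strictly = TRUE)) {
      stop("marker positions must be strictly increasing within chromosome ", chr)
    }
  }
  father <- as.matrix(father); mother <- as.matrix(mother)
  offspring <- as.matrix(offspring)
  dims <- list(father = dim(father), mother = dim(mother),
               offspring = dim(offspring))
  if (!all(vapply(dims, function(d) identical(d, dim(father)), logical(1)))) {
    stop("father/mother/offspring genotype matrices must share dimensions")
  }
  if (ncol(father) != nrow(markers)) {
    stop("genotype matrices have ", ncol(father), " columns but marker map has ",
         nrow(markers), " rows")
  }
  for (m in list(father, mother, offspring)) {
    bad <- m[!is.na(m)]
    if (length(bad) > 0L && (any(bad < 0L) || any(bad > 2L))) {
      stop("genotype dosages must be 0, 1, 2 or NA")
    }
  }
  mode(father) <- "integer"; mode(mother) <- "integer"
  mode(offspring) <- "integer"
  colnames(father) <- colnames(mother) <- colnames(offspring) <- markers$snp
  structure(
    list(markers = markers, father = father, mother = mother,
         offspring = offspring, population = as.character(population)[1]),
    class = "trio_cohort"
  )
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf("<trio_cohort> population '%s': %d trios x %d SNPs on %d chromosome(s)\n",
              x$population, n_trios(x), n_snps(x),
              length(unique(x$markers$chr))))
  n_miss <- sum(is.na(x$father)) + sum(is.na(x$mother)) + sum(is.na(x$offspring))
  cat(sprintf("  missing calls: %d (%.2f%%)\n", n_miss,
              100 * n_miss / (3 * n_trios(x) * max(1L, n_snps(x)))))
  invisible(x)
}

#' @rdname trio_cohort
#' @param x a `trio_cohort`.
#' @export
n_trios <- function(x) nrow(x$father)

#' @rdname trio_cohort
#' @export
n_snps <- function(x) nrow(x$markers)

snp_index <- function(cohort, snp_id) {
  i <- match(snp_id, cohort$markers$snp)
  if (is.na(i)) stop("unknown SNP id: ", snp_id)
  i
}
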