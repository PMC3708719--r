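#' Cohort and marker accounting summary
#'
#' Totals a per-population table of trio counts and genotyped-SNP counts
#' and reports the percentage of SNPs shared by all populations — the
#' standard opening summary of a multi-population trio study.
#'
#' @param trios named vector of per-population affected-offspring trio
#'   counts.
#' @param snps_genotyped optional named vector of per-population
#'   genotyped SNP counts (not summed across populations; the total is
#'   the union size, supplied separately).
#' @param snps_total total number of SNPs passing inclusion across
#'   populations.
#' @param snps_shared number of SNPs shared by all populations.
#' @return List with `total_trios`, `shared_percent` (rounded to one
#'   decimal, as conventionally reported), and the assembled `table`.
#' @export
study_accounting <- function(trios, snps_genotyped = NULL,
                             snps_total = NULL, snps_shared = NULL) {
  total_trios <- sum(trios)
  shared_percent <- if (!is.null(snps_total) && !is.null(snps_shared)) {
    if (snps_shared > snps_total) stop("shared SNPs cannot exceed the total")
    round(100 * snps_shared / snps_total, 1)
  }
  tab <- data.frame(population = names(trios), trios = as.integer(trios),
                    stringsAsFactors = FALSE)
  if (!is.null(snps_genotyped)) {
    tab$snps_genotyped <- as.integer(snps_genotyped[tab$population])
  }
  list(total_trios = total_trios, shared_percent = shared_percent,
       table = tab)
}
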