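#' Write a trio cohort as PLINK text PED/MAP
#'
#' One PED row per individual with the six leading columns family id,
#' individual id, father id, mother id, sex and phenotype (offspring
#' phenotype 2 = affected, parents 1 = unaffected), then two allele
#' columns per SNP; missing alleles are written `0`. The MAP file has
#' columns chromosome, SNP id, genetic distance (0) and position.
#'
#' @param cohort a [trio_cohort()].
#' @param ped_path,map_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_ped_map <- function(cohort, ped_path, map_path) {
  mk <- cohort$markers
  utils::write.table(
    data.frame(mk$chr, mk$snp, 0L, mk$pos),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  dosage_to_alleles <- function(g, a1, a2) {
    # g: n x m dosage matrix -> n x 2m character matrix of alleles
    n <- nrow(g); m <- ncol(g)
    first <- ifelse(is.na(g), "0", ifelse(g >= 1L, rep(a1, each = n),
                                          rep(a2, each = n)))
    second <- ifelse(is.na(g), "0", ifelse(g == 2L, rep(a1, each = n),
                                           rep(a2, each = n)))
    out <- matrix("", n, 2L * m)
    out[, seq(1L, 2L * m, by = 2L)] <- first
    out[, seq(2L, 2L * m, by = 2L)] <- second
    out
  }
  q <- n_trios(cohort)
  fam <- sprintf("FAM%05d", seq_len(q))
  rows <- list(
    cbind(fam, paste0(fam, "_F"), "0", "0", "1", "1",
          dosage_to_alleles(cohort$father, mk$allele1, mk$allele2)),
    cbind(fam, paste0(fam, "_M"), "0", "0", "2", "1",
          dosage_to_alleles(cohort$mother, mk$allele1, mk$allele2)),
    cbind(fam, paste0(fam, "_C"), paste0(fam, "_F"), paste0(fam, "_M"),
          "1", "2",
          dosage_to_alleles(cohort$offspring, mk$allele1, mk$allele2)))
  ped <- do.call(rbind, rows)
  ord <- order(rep(seq_len(q), times = 3L))  # group rows by family
  utils::write.table(ped[ord, , drop = FALSE], ped_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a PLINK text PED/MAP pair into a trio cohort
#'
#' Accepts arbitrary whitespace separation. Trio structure is recovered
#' from the father/mother id columns: each individual naming two parents
#' present in the same family becomes an offspring. Orphan offspring
#' (a named parent record absent), duplicate individual ids, and allele
#' symbols other than the marker alleles or `0` are reported with PED
#' line numbers.
#'
#' @param ped_path,map_path input paths.
#' @param population cohort label for the result.
#' @param allele1,allele2 allele symbols; dosage counts `allele1` (M1).
#' @return A [trio_cohort()].
#' @export
read_ped_map <- function(ped_path, map_path, population = "POP",
                         allele1 = "A", allele2 = "B") {
  map <- utils::read.table(map_path, header = FALSE,
                           col.names = c("chr", "snp", "gd", "pos"),
                           stringsAsFactors = FALSE)
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf != 6L + 2L * m)
  if (length(bad) > 0L) {
    stop("PED line(s) ", paste(utils::head(bad, 5L), collapse = ", "),
         " have ", nf[bad[1]], " fields; expected ", 6L + 2L * m)
  }
  ped <- do.call(rbind, fields)
  fam <- ped[, 1]; id <- ped[, 2]; fid <- ped[, 3]; mid <- ped[, 4]
  key <- paste(fam, id)
  if (anyDuplicated(key)) {
    stop("duplicate individual id(s) in PED: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  alle <- ped[, -(1:6), drop = FALSE]
  ok <- alle %in% c(allele1, allele2, "0")
  if (!all(ok)) {
    bad_lines <- unique(which(matrix(!ok, nrow = nrow(alle)),
                              arr.ind = TRUE)[, 1])
    stop("unexpected allele symbol(s) on PED line(s) ",
         paste(utils::head(sort(bad_lines), 5L), collapse = ", "))
  }
  a1 <- alle[, seq(1L, 2L * m, by = 2L), drop = FALSE]
  a2 <- alle[, seq(2L, 2L * m, by = 2L), drop = FALSE]
  dosage <- (a1 == allele1) + (a2 == allele1)
  dosage[a1 == "0" | a2 == "0"] <- NA_integer_

  is_off <- fid != "0" & mid != "0"
  off_rows <- which(is_off)
  if (length(off_rows) == 0L) stop("no offspring rows (father and mother ids set) in PED")
  f_rows <- match(paste(fam[off_rows], fid[off_rows]), key)
  m_rows <- match(paste(fam[off_rows], mid[off_rows]), key)
  orphan <- is.na(f_rows) | is.na(m_rows)
  if (any(orphan)) {
    stop("offspring with missing parent record(s): ",
         paste(key[off_rows[orphan]], collapse = ", "))
  }
  markers <- data.frame(snp = map$snp, chr = map$chr, pos = map$pos,
                        allele1 = allele1, allele2 = allele2,
                        stringsAsFactors = FALSE)
  trio_cohort(markers,
              father = dosage[f_rows, , drop = FALSE],
              mother = dosage[m_rows, , drop = FALSE],
              offspring = dosage[off_rows, , drop = FALSE],
              population = population)
}

#' Read / write a 4-column BED gene annotation
#'
#' Standard BED: chromosome, start, end (0-based half-open), name.
#'
#' @param path file path.
#' @return `read_bed`: data.frame with columns `gene`, `chr`, `start`,
#'   `end`.
#' @export
read_bed <- function(path) {
  b <- utils::read.table(path, header = FALSE, sep = "\t",
                         col.names = c("chr", "start", "end", "gene"),
                         colClasses = c("character", "integer", "integer",
                                        "character"))
  data.frame(gene = b$gene, chr = b$chr, start = b$start, end = b$end,
             stringsAsFactors = FALSE)
}

#' @rdname read_bed
#' @param genes gene annotation data.frame (`gene`, `chr`, `start`, `end`).
#' @export
write_bed <- function(genes, path) {
  utils::write.table(genes[, c("chr", "start", "end", "gene")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' GMT: one set per line — set name, description, then tab-separated
#' member gene names.
#'
#' @param path file path.
#' @return `read_gmt`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop("GMT line(s) without members: ", paste(short, collapse = ", "))
  }
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[[`, character(1), 1L))
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  writeLines(vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
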