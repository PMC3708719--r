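#' Pipeline configuration
#'
#' Collects every tunable of the comparison pipeline. Defaults follow the
#' study design this package models: QC at <15% missingness and HWE
#' p > 1e-6, a top-n grid from 1,000 to 50,000, a 20-kb gene window,
#' replication at nominal alpha 0.05, SNP-resampling enrichment null,
#' and the Nei FST estimator computed from parents.
#'
#' @param cohort_files named list mapping population label to
#'   `list(ped = , map = )` paths (may be `NULL` when cohorts are passed
#'   in memory).
#' @param annotation_path optional BED gene annotation path.
#' @param gene_set_path optional GMT path.
#' @param criteria a [qc_criteria()].
#' @param top_n_grid top-n sizes for the overlap report.
#' @param noteworthy_n top-n size defining noteworthy genes.
#' @param gene_window SNP-to-gene window in bp.
#' @param replication_alpha nominal replication threshold.
#' @param enrichment_reps resampling replicates.
#' @param enrichment_mode `"snp"` or `"gene"`.
#' @param fst_estimator `"nei"` or `"weir_cockerham"`.
#' @param fst_who `"parents"` or `"offspring"`.
#' @param master_seed integer master seed; stage seeds are derived from
#'   it by stable hashing of stage names.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort_files = NULL, annotation_path = NULL,
                            gene_set_path = NULL,
                            criteria = qc_criteria(),
                            top_n_grid = c(1000L, 2000L, 5000L, 10000L,
                                           50000L),
                            noteworthy_n = 1000L, gene_window = 20000L,
                            replication_alpha = 0.05,
                            enrichment_reps = 1000L,
                            enrichment_mode = c("snp", "gene"),
                            fst_estimator = c("nei", "weir_cockerham"),
                            fst_who = c("parents", "offspring"),
                            master_seed = 1L) {
  paths <- c(unlist(cohort_files), annotation_path, gene_set_path)
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing) > 0L) {
    stop("config references missing file(s): ",
         paste(missing, collapse = ", "))
  }
  structure(list(
    cohort_files = cohort_files, annotation_path = annotation_path,
    gene_set_path = gene_set_path, criteria = criteria,
    top_n_grid = as.integer(top_n_grid),
    noteworthy_n = as.integer(noteworthy_n),
    gene_window = as.integer(gene_window),
    replication_alpha = replication_alpha,
    enrichment_reps = as.integer(enrichment_reps),
    enrichment_mode = match.arg(enrichment_mode),
    fst_estimator = match.arg(fst_estimator),
    fst_who = match.arg(fst_who),
    master_seed = as.integer(master_seed)), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(y$criteria)) y$criteria <- do.call(qc_criteria, y$criteria)
  do.call(pipeline_config, y)
}

#' Derive a stage seed from the master seed
#'
#' Stable hash of the stage name folded into the master seed, kept below
#' 2^31 so it is a valid R integer seed; distinct stages get independent
#' streams while the whole pipeline stays reproducible.
#'
#' @param master_seed integer master seed.
#' @param stage stage name.
#' @return Integer seed.
#' @export
stage_seed <- function(master_seed, stage) {
  bytes <- utf8ToInt(stage)
  acc <- 0
  for (b in bytes) acc <- (acc * 31 + b) %% 2147483647
  as.integer((acc + as.numeric(master_seed)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full comparison pipeline
#'
#' Executes QC and per-cohort TDT, the pooled mega-analysis, p-value
#' ranking, top-n SNP overlap, gene mapping and gene-level overlap,
#' pathway enrichment, replication counting, and the FST x DRP
#' dependence analysis, writing one TSV per stage plus Manhattan-plot
#' data tables and a JSON run manifest. With a single cohort the
#' cross-population stages are skipped with a logged notice.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param cohorts optional named list of in-memory [trio_cohort()]s;
#'   when `NULL`, cohorts are read from `config$cohort_files`.
#' @param annotation optional in-memory gene annotation.
#' @param gene_sets optional in-memory gene-set collection.
#' @return Invisibly, a list with all stage results (`tdt`, `mega`,
#'   `rankings`, `overlap`, `mapping`, `gene_overlap`, `enrichment`,
#'   `replication`, `fst_drp`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, cohorts = NULL,
                         annotation = NULL, gene_sets = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_note <- function(...) message("[triorank] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (is.null(cohorts)) {
    cohorts <- stage("load", {
      lapply(stats::setNames(nm = names(config$cohort_files)), function(nm) {
        f <- config$cohort_files[[nm]]
        read_ped_map(f$ped, f$map, population = nm)
      })
    })
  }
  if (is.null(annotation) && !is.null(config$annotation_path)) {
    annotation <- read_bed(config$annotation_path)
  }
  if (is.null(gene_sets) && !is.null(config$gene_set_path)) {
    gene_sets <- read_gmt(config$gene_set_path)
  }
  pops <- names(cohorts)

  tdt <- stage("tdt", lapply(cohorts, tdt_cohort, criteria = config$criteria))
  for (nm in pops) {
    write_tsv(tdt[[nm]], file.path(out_dir, paste0("tdt_", nm, ".tsv")))
    manh <- tdt[[nm]][tdt[[nm]]$qc_pass & !is.na(tdt[[nm]]$p),
                      c("chr", "pos", "p")]
    manh$neglog10p <- -log10(manh$p)
    write_tsv(manh[, c("chr", "pos", "neglog10p")],
              file.path(out_dir, paste0("manhattan_", nm, ".tsv")))
  }
  lambdas <- vapply(tdt, function(t) genomic_inflation(t$chi2[t$qc_pass]),
                    numeric(1))

  mega <- stage("mega", mega_tdt(cohorts, config$criteria))
  write_tsv(mega, file.path(out_dir, "tdt_mega.tsv"))

  rankings <- stage("rank", lapply(tdt, rank_snps))

  results <- list(tdt = tdt, mega = mega, rankings = rankings,
                  lambdas = lambdas)

  if (length(cohorts) >= 2L) {
    shared <- Reduce(intersect, lapply(rankings, `[[`, "snp"))
    grid <- config$top_n_grid
    grid <- grid[grid <= min(vapply(rankings, nrow, integer(1)))]
    results$overlap <- stage("overlap",
                             overlap_report(rankings, grid,
                                            N = length(shared)))
    write_tsv(results$overlap, file.path(out_dir, "snp_overlap.tsv"))

    rep_rows <- list()
    for (a in pops) {
      top100 <- top_n(rankings[[a]], min(100L, nrow(rankings[[a]])))
      for (b in setdiff(pops, a)) {
        rc <- replication_count(top100, rankings[[b]],
                                alpha = config$replication_alpha)
        rep_rows[[length(rep_rows) + 1L]] <- data.frame(
          top_population = a, tested_in = b, observed = rc$observed,
          expected = rc$expected, n_used = rc$n_used,
          stringsAsFactors = FALSE)
      }
    }
    results$replication <- do.call(rbind, rep_rows)
    write_tsv(results$replication, file.path(out_dir, "replication.tsv"))
  } else {
    log_note("single cohort: overlap, replication, enrichment and FST-DRP stages skipped")
  }

  if (!is.null(annotation)) {
    mapping <- stage("map-genes", {
      lapply(rankings, function(r) {
        map_snps_to_genes(r[, c("snp", "chr", "pos")], annotation,
                          window = config$gene_window)
      })
    })
    results$mapping <- mapping
    gl <- lapply(pops, function(nm) gene_level_p(mapping[[nm]], tdt[[nm]]))
    names(gl) <- pops
    results$gene_level <- gl
    for (nm in pops) {
      write_tsv(gl[[nm]], file.path(out_dir, paste0("gene_level_", nm, ".tsv")))
    }
    if (length(cohorts) >= 2L) {
      n_note <- min(config$noteworthy_n,
                    min(vapply(rankings, nrow, integer(1))))
      top_genes <- lapply(pops, function(nm) {
        genes_from_top_snps(mapping[[nm]],
                            top_n(rankings[[nm]], n_note))$genes$gene
      })
      names(top_genes) <- pops
      results$gene_overlap <- stage("gene-overlap",
                                    gene_overlap(top_genes,
                                                 length(unique(annotation$gene))))
      write_tsv(results$gene_overlap, file.path(out_dir, "gene_overlap.tsv"))

      if (!is.null(gene_sets)) {
        enr <- stage("enrich", {
          lapply(stats::setNames(nm = pops), function(nm) {
            resampling_null(mapping[[nm]], rankings[[nm]], n_note,
                            gene_sets, reps = config$enrichment_reps,
                            mode = config$enrichment_mode,
                            seed = stage_seed(config$master_seed,
                                              paste0("enrich:", nm)))
          })
        })
        results$enrichment <- enr
        for (nm in pops) {
          write_tsv(enr[[nm]], file.path(out_dir,
                                         paste0("enrichment_", nm, ".tsv")))
        }
        rgs <- rank_gene_sets(enr)
        results$shared_pathways <- rgs$shared
        write_tsv(rgs$shared, file.path(out_dir, "shared_pathways.tsv"))
      }
    }
  }

  if (length(cohorts) >= 2L) {
    fd_rows <- list(); fd <- list()
    prs <- utils::combn(pops, 2L)
    for (k in seq_len(ncol(prs))) {
      a <- prs[1, k]; b <- prs[2, k]
      s <- stage("fst-drp",
                 fst_drp_summary(cohorts[[a]], cohorts[[b]],
                                 rankings[[a]], rankings[[b]],
                                 who = config$fst_who,
                                 estimator = config$fst_estimator))
      fd[[paste(a, b, sep = "_vs_")]] <- s
      fd_rows[[k]] <- data.frame(
        pair = paste(a, b, sep = " vs "), source = config$fst_who,
        mean_fst = s$mean_fst, median_fst = s$median_fst,
        fst_min = s$fst_range[1], fst_max = s$fst_range[2],
        observed = s$observed, expected = s$expected,
        chi2 = s$chi2, p = s$p, stringsAsFactors = FALSE)
    }
    results$fst_drp <- fd
    results$fst_drp_table <- do.call(rbind, fd_rows)
    write_tsv(results$fst_drp_table, file.path(out_dir, "fst_drp.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("triorank")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    master_seed = config$master_seed,
    config = config[setdiff(names(config), "criteria")],
    criteria = unclass(config$criteria),
    populations = pops,
    n_trios = vapply(cohorts, n_trios, integer(1)),
    n_snps = vapply(cohorts, n_snps, integer(1)),
    lambda = lambdas,
    input_hashes = if (!is.null(config$cohort_files)) {
      lapply(config$cohort_files, function(f) {
        as.list(tools::md5sum(unlist(f)))
      })
    })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  results$manifest <- manifest
  invisible(results)
}
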