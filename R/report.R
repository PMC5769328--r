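#' Flatten a genotype report to a table
#'
#' @param report a `genotype_report`.
#' @return `data.table(gene, allele_1, allele_2, ambiguity, quality_value,
#'   quality, null_flags)`; for a gene with tied top pairs the first
#'   (lexicographically smallest) call fills `allele_1`/`allele_2` and all
#'   tied calls are joined in `ambiguity`.
#' @export
format_report <- function(report) {
  stopifnot(inherits(report, "genotype_report"))
  rows <- lapply(report$calls, function(cl) {
    if (cl$untypeable || length(cl$alleles) == 0L) {
      return(data.table(gene = cl$gene, allele_1 = NA_character_,
                        allele_2 = NA_character_, ambiguity = "",
                        quality_value = cl$quality_value,
                        quality = cl$quality, null_flags = ""))
    }
    reps <- sort(vapply(cl$alleles, paste, character(1), collapse = "/"))
    first <- strsplit(reps[1], "/", fixed = TRUE)[[1]]
    data.table(gene = cl$gene, allele_1 = first[1],
               allele_2 = if (length(first) > 1L) first[2] else first[1],
               ambiguity = paste(reps, collapse = ";"),
               quality_value = cl$quality_value, quality = cl$quality,
               null_flags = paste(cl$null_flags, collapse = ";"))
  })
  out <- rbindlist(rows)
  setorder(out, gene)
  out[]
}

#' Write a genotype report as TSV and JSON
#'
#' @param report a `genotype_report`.
#' @param tsv,json output paths (either may be `NULL`).
#' @export
write_report <- function(report, tsv = NULL, json = NULL) {
  tab <- format_report(report)
  if (!is.null(tsv))
    utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json)) {
    obj <- list(
      config = unclass(report$cfg),
      passes = report$passes,
      converged = report$converged,
      calls = lapply(report$calls, function(cl)
        list(gene = cl$gene,
             alleles = lapply(cl$alleles, as.list),
             quality_value = cl$quality_value,
             quality = cl$quality,
             untypeable = cl$untypeable,
             null_flags = as.list(cl$null_flags)))
    )
    jsonlite::write_json(obj, json, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(tab)
}

#' First-base coverage of core exons
#'
#' The capture-complexity metric: the fraction of exon positions that are
#' the 5'-leftmost start of at least one end-to-end mapped read. By
#' convention the metric is restricted to the core exons (biological exon
#' numbers 2, 3 and 4, i.e. 0-based exon indices 1-3) where they exist.
#'
#' @param db an [hla_db()] holding the alleles to evaluate (typically the
#'   truth or reported alleles).
#' @param rs a `read_set`.
#' @param cfg a [pipeline_config()].
#' @param exon_numbers biological (1-based) exon numbers to include;
#'   default `c(2, 3, 4)`.
#' @return named numeric vector: per-gene fraction in `[0, 1]`.
#' @export
first_base_coverage <- function(db, rs, cfg = pipeline_config(),
                                exon_numbers = c(2, 3, 4)) {
  hits <- map_end_to_end(rs, db, min_contig = cfg$full_read_len)
  ex <- exon_seq_table(db)[exon_index %in% (exon_numbers - 1L)]
  vapply(stats::setNames(nm = db_genes(db)), function(g) {
    exg <- ex[allele %chin% db_alleles(db, g)]
    if (nrow(exg) == 0L) return(NA_real_)
    total <- 0L
    hit <- 0L
    for (i in seq_len(nrow(exg))) {
      span <- exg$start[i]:(exg$end[i] - 1L)
      starts <- hits[allele == exg$allele[i], unique(start)]
      total <- total + length(span)
      hit <- hit + sum(span %in% starts)
    }
    hit / total
  }, numeric(1))
}

#' Run the complete typing pipeline on files
#'
#' Reads the allele database and the sequencing reads, deduplicates,
#' applies the two candidate-screening stages, the reciprocal-screening
#' genotyper, the cross-paralog correction and the null-allele check, and
#' writes per-stage survivor tables plus the final genotype report.
#'
#' @param reads_path FASTQ or FASTA of single-end reads.
#' @param fasta_path allele CDS FASTA.
#' @param exon_table_path exon annotation TSV (required; see
#'   [read_allele_fasta()]).
#' @param out_dir output directory (created if absent).
#' @param config_path optional YAML pipeline configuration.
#' @param null_table_path optional null-allele signature TSV.
#' @param ... passed to [read_allele_fasta()].
#' @return the `genotype_report`, invisibly; side effect: writes
#'   `survivors_stage1.tsv`, `survivors_stage2.tsv`, `genotypes.tsv`,
#'   `genotypes.json` and `run_log.txt` under `out_dir`.
#' @export
run_typing <- function(reads_path, fasta_path, exon_table_path, out_dir,
                       config_path = NULL, null_table_path = NULL, ...) {
  if (is.null(exon_table_path) || !file.exists(exon_table_path))
    stop("exon annotations required", call. = FALSE)
  cfg <- if (is.null(config_path)) pipeline_config() else read_pipeline_config(config_path)
  db <- read_allele_fasta(fasta_path, exon_table_path, ...)
  rs <- deduplicate(reads_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(out_dir, "run_log.txt")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = log, append = TRUE)
  cat("", file = log)

  logline("alleles: %d  genes: %d  reads: %d distinct (%d raw)",
          length(db$seqs), length(db$gene_set), nrow(rs$reads), sum(rs$reads$mult))
  s1 <- coverage_filter(db, rs, cfg)
  logline("stage1 (coverage filter, rule=%s): %d -> %d candidates",
          cfg$stage1_rule, length(db$seqs), length(s1))
  stage_tab <- data.table(gene = unname(db$genes[names(db$seqs)]),
                          allele = names(db$seqs),
                          status = ifelse(names(db$seqs) %in% s1, "retained", "stage1"))
  utils::write.table(stage_tab[order(gene, allele)],
                     file.path(out_dir, "survivors_stage1.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  s2 <- window_filter(db, s1, rs, cfg)
  logline("stage2 (window filter, window=%d): %d -> %d candidates",
          cfg$window_len, length(s1), length(s2$survivors))
  stage_tab[allele %in% s1 & !allele %in% s2$survivors, status := "stage2"]
  utils::write.table(stage_tab[order(gene, allele)],
                     file.path(out_dir, "survivors_stage2.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  report <- call_genotypes(db, s2$survivors, rs, cfg)
  logline("stage3 (reciprocal screen): %d pool pass(es), converged=%s",
          report$passes, report$converged)

  if (!is.null(null_table_path)) {
    table <- read_null_signature_table(null_table_path)
    report <- check_null_alleles(report, rs, table, cfg)
    logline("null-allele check: %d signature row(s)", nrow(table))
  }
  write_report(report,
               tsv = file.path(out_dir, "genotypes.tsv"),
               json = file.path(out_dir, "genotypes.json"))
  for (cl in report$calls)
    logline("call %s: %s [%.3g %s]", cl$gene,
            if (cl$untypeable) "untypeable"
            else paste(vapply(cl$alleles, paste, character(1), collapse = "/"),
                       collapse = " | "),
            cl$quality_value, cl$quality)
  invisible(report)
}
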