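#' Specification of a diploid read simulation
#'
#' @param truth named list: gene symbol -> character vector of two allele
#'   names (repeat one name for a homozygote). Every allele must exist in
#'   the database the spec is used with.
#' @param depth mean first-base coverage per allele copy; the simulator
#'   draws about `depth * cds_len / read_len` reads per copy.
#' @param read_len read length in bp (single-end). Default 100.
#' @param dup_rate fraction of reads additionally emitted as an exact PCR
#'   duplicate (same sequence, distinct identifier). Default 0.
#' @param error_rate per-base substitution probability. Default 0: the
#'   pipeline's matching contract is exact, so clean reads are the
#'   reference condition.
#' @param strand_fraction probability a read is emitted as the reverse
#'   complement of its template. Default 0.5.
#' @param seed integer seed; simulation is deterministic given the seed.
#' @return an object of class `sim_spec`.
#' @export
sim_spec <- function(truth, depth, read_len = 100L, dup_rate = 0,
                     error_rate = 0, strand_fraction = 0.5, seed = 1L) {
  stopifnot(is.list(truth), length(truth) > 0, depth > 0,
            dup_rate >= 0, dup_rate <= 1, error_rate >= 0, error_rate <= 1,
            strand_fraction >= 0, strand_fraction <= 1)
  if (!all(lengths(truth) == 2L))
    stop("each truth genotype must list exactly two alleles", call. = FALSE)
  structure(list(truth = truth, depth = depth, read_len = as.integer(read_len),
                 dup_rate = dup_rate, error_rate = error_rate,
                 strand_fraction = strand_fraction, seed = as.integer(seed)),
            class = "sim_spec")
}

mutate_reads <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0L) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(stats::runif(n) < error_rate)
    if (length(hit) == 0L) return(s)
    substitute_bases(s, hit)
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate single-end reads from a diploid truth genotype
#'
#' Draws reads uniformly over each truth allele's CDS (start positions
#' uniform on `[0, len - read_len]`), flips each to the reverse complement
#' with probability `strand_fraction`, optionally applies substitution
#' errors, and appends exact PCR duplicates at rate `dup_rate`. The truth
#' genotype and the per-read source are recorded in the returned manifest.
#'
#' @param db an [hla_db()].
#' @param spec a [sim_spec()].
#' @return a list of class `sim_reads` with elements
#'   * `reads`: `data.table(read_id, seq_, source_allele, start0, is_reverse, is_dup)`
#'   * `truth`: `data.table(gene, allele1, allele2)`
#' @examples
#' db <- make_toy_database(1, 4, 400, 3, seed = 2)
#' sp <- sim_spec(list(A = c("A*01:01", "A*02:01")), depth = 5, seed = 3)
#' sim <- simulate_reads(db, sp)
#' nrow(sim$reads)
#' @export
simulate_reads <- function(db, spec) {
  stopifnot(inherits(db, "hla_db"), inherits(spec, "sim_spec"))
  truth_alleles <- unlist(spec$truth, use.names = FALSE)
  missing <- setdiff(truth_alleles, names(db$seqs))
  if (length(missing))
    stop("truth allele absent from database: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (spec$read_len > min(nchar(db$seqs[truth_alleles])))
    stop("read_len exceeds shortest truth-allele CDS", call. = FALSE)

  with_seed(spec$seed, {
    rows <- list()
    for (g in sort(names(spec$truth))) {
      pair <- spec$truth[[g]]
      for (copy in 1:2) {
        a <- pair[copy]
        cds <- db$seqs[[a]]
        len <- nchar(cds)
        n <- max(1L, round(spec$depth * len / spec$read_len))
        start0 <- sample.int(len - spec$read_len + 1L, n, replace = TRUE) - 1L
        seqs <- substring(cds, start0 + 1L, start0 + spec$read_len)
        rev <- stats::runif(n) < spec$strand_fraction
        if (any(rev)) seqs[rev] <- revcomp(seqs[rev])
        seqs <- mutate_reads(seqs, spec$error_rate)
        rows[[paste(g, copy)]] <- data.table(
          read_id = sprintf("%s|c%d|r%04d", a, copy, seq_len(n)),
          seq_ = seqs, source_allele = a, start0 = start0,
          is_reverse = rev, is_dup = FALSE)
      }
    }
    reads <- rbindlist(rows)
    if (spec$dup_rate > 0) {
      dup <- reads[stats::runif(.N) < spec$dup_rate]
      if (nrow(dup)) {
        dup[, read_id := paste0(read_id, "|dup")]
        dup[, is_dup := TRUE]
        reads <- rbind(reads, dup)
      }
    }
    truth <- data.table(gene = sort(names(spec$truth)),
                        allele1 = vapply(sort(names(spec$truth)), function(g)
                          sort(spec$truth[[g]])[1], character(1)),
                        allele2 = vapply(sort(names(spec$truth)), function(g)
                          sort(spec$truth[[g]])[2], character(1)))
    structure(list(reads = reads, truth = truth), class = "sim_reads")
  })
}

#' Write simulated reads as FASTQ plus truth manifests
#'
#' Quality strings are constant `"I"`: the pipeline never reads qualities.
#'
#' @param sim a `sim_reads` object from [simulate_reads()].
#' @param fastq output FASTQ path.
#' @param truth_tsv output TSV path for the genotype manifest
#'   (`gene`, `allele1`, `allele2`); optional.
#' @param sources_tsv output TSV path for the per-read source table; optional.
#' @export
write_sim_fastq <- function(sim, fastq, truth_tsv = NULL, sources_tsv = NULL) {
  stopifnot(inherits(sim, "sim_reads"))
  con <- file(fastq, "w")
  on.exit(close(con))
  qual <- strrep("I", nchar(sim$reads$seq_))
  writeLines(paste0("@", sim$reads$read_id, "\n", sim$reads$seq_, "\n+\n", qual), con)
  if (!is.null(truth_tsv))
    utils::write.table(sim$truth, truth_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sources_tsv))
    utils::write.table(sim$reads[, .(read_id, source_allele, start0, is_reverse, is_dup)],
                       sources_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fastq)
}
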