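#' Collapse PCR duplicates into a deduplicated read set
#'
#' Reads are collapsed by literal forward-strand sequence identity: one
#' representative per distinct sequence (the first seen), with the original
#' copy count retained as `mult`. Every downstream stage of the pipeline
#' operates on the deduplicated set.
#'
#' @param x reads in any of these forms: a FASTQ/FASTA file path, a
#'   `sim_reads` object from [simulate_reads()], a `data.frame`/`data.table`
#'   with columns `read_id` and `seq_`, or a (optionally named) character
#'   vector of sequences.
#' @return an object of class `read_set`: a list with element `reads`, a
#'   `data.table(read_id, seq_, mult)`.
#' @examples
#' rs <- deduplicate(c("ACGT", "ACGT", "TTTT"))
#' rs$reads$mult
#' @export
deduplicate <- function(x) {
  if (inherits(x, "read_set")) return(x)
  if (inherits(x, "sim_reads")) {
    dt <- x$reads[, .(read_id, seq_)]
  } else if (is.character(x) && length(x) == 1L && file.exists(x)) {
    first <- substr(readLines(x, n = 1L), 1L, 1L)
    fmt <- if (identical(first, "@")) "fastq" else "fasta"
    ss <- Biostrings::readDNAStringSet(x, format = fmt)
    dt <- data.table(read_id = sub("[ \t].*$", "", names(ss)),
                     seq_ = toupper(as.character(ss)))
  } else if (is.character(x)) {
    ids <- names(x) %||% sprintf("read%04d", seq_along(x))
    dt <- data.table(read_id = ids, seq_ = toupper(unname(x)))
  } else {
    dt <- as.data.table(x)[, .(read_id, seq_ = toupper(seq_))]
  }
  if (nrow(dt) == 0L) {
    return(structure(list(reads = data.table(read_id = character(0),
                                             seq_ = character(0),
                                             mult = integer(0))),
                     class = "read_set"))
  }
  dedup <- dt[, .(read_id = read_id[1L], mult = .N), by = seq_]
  structure(list(reads = dedup[, .(read_id, seq_, mult)]), class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d distinct reads (%d before deduplication)\n",
              nrow(x$reads), sum(x$reads$mult)))
  invisible(x)
}

#' End-to-end exact mapping of whole reads onto allele coding sequences
#'
#' A hit is reported at every position of every allele where the entire
#' read (or its reverse complement) matches contiguously with zero
#' mismatches -- the exact-match, report-all-placements contract. Reads
#' shorter than `min_contig` yield no hits.
#'
#' @param rs a [deduplicate()]d `read_set`.
#' @param db an [hla_db()].
#' @param min_contig minimum read length (bp) eligible for mapping; the
#'   initial-screening stage uses the full read length so only intact reads
#'   count.
#' @return `data.table(read_id, allele, start, match_len, is_reverse)` with
#'   `start` the 0-based CDS offset of the leftmost matched base.
#' @export
map_end_to_end <- function(rs, db, min_contig) {
  stopifnot(inherits(rs, "read_set"), inherits(db, "hla_db"))
  reads <- rs$reads[nchar(seq_) >= min_contig]
  out <- list()
  for (L in sort(unique(nchar(reads$seq_)))) {
    ref <- kmer_table(db$seqs, L)
    setkey(ref, kmer)
    rl <- reads[nchar(seq_) == L]
    for (strand in c(FALSE, TRUE)) {
      q <- data.table(read_id = rl$read_id,
                      kmer = if (strand) revcomp(rl$seq_) else rl$seq_)
      hit <- ref[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
      if (nrow(hit))
        out[[length(out) + 1L]] <- hit[, .(read_id, allele = name, start = start0,
                                           match_len = L, is_reverse = strand)]
    }
  }
  res <- if (length(out)) rbindlist(out) else
    data.table(read_id = character(0), allele = character(0),
               start = integer(0), match_len = integer(0), is_reverse = logical(0))
  setorder(res, read_id, allele, start, is_reverse)
  res[]
}

# exon sequence table: allele, exon_index, start, end, len, seq_
exon_seq_table <- function(db) {
  ex <- copy(db$exons)
  ex[, len := end - start]
  ex[, seq_ := substring(db$seqs[allele], start + 1L, end)]
  ex
}

#' Enumerate all artificial reads tiled over large exons
#'
#' For every exon of length `L >= large_exon_min`, emits the
#' `L - artificial_read_len + 1` k-mers of length `artificial_read_len`
#' together with their exon offsets. These tiles are the probes of the
#' coverage-filter stage: an allele can only survive if its large exons are
#' fully reconstructible from the sequenced reads.
#'
#' @param db an [hla_db()].
#' @param cfg a [pipeline_config()].
#' @return `data.table(allele, exon_index, offset, seq_)`, `offset` 0-based
#'   on the exon.
#' @export
make_artificial_reads <- function(db, cfg = pipeline_config()) {
  ex <- exon_seq_table(db)[len >= cfg$large_exon_min]
  k <- cfg$artificial_read_len
  if (nrow(ex) == 0L)
    return(data.table(allele = character(0), exon_index = integer(0),
                      offset = integer(0), seq_ = character(0)))
  counts <- ex$len - k + 1L
  out <- data.table(
    allele = rep(ex$allele, counts),
    exon_index = rep(ex$exon_index, counts),
    offset = unlist(lapply(counts, function(n) 0:(n - 1L)), use.names = FALSE)
  )
  out[, seq_ := substring(rep(ex$seq_, counts), offset + 1L, offset + k)]
  out[]
}

#' Match artificial reads against the sequenced read set
#'
#' An artificial read is matched iff it, or its reverse complement, occurs
#' as an exact substring of at least one deduplicated sequencing read; a
#' single witness suffices. Only the exon offsets of matched artificial
#' reads are retained.
#'
#' @param art output of [make_artificial_reads()].
#' @param rs a `read_set`.
#' @param cfg a [pipeline_config()] (supplies `artificial_read_len`).
#' @return `data.table(allele, exon_index, offset)` of matched tiles,
#'   sorted by allele, exon and offset.
#' @export
match_artificial_to_reads <- function(art, rs, cfg = pipeline_config()) {
  stopifnot(inherits(rs, "read_set"))
  if (nrow(art) == 0L)
    return(data.table(allele = character(0), exon_index = integer(0), offset = integer(0)))
  k <- cfg$artificial_read_len
  pool <- unique(unlist(lapply(rs$reads$seq_, seq_kmers, k = k), use.names = FALSE))
  hit <- art$seq_ %chin% pool | revcomp(art$seq_) %chin% pool
  out <- art[hit, .(allele, exon_index, offset)]
  setorder(out, allele, exon_index, offset)
  out[]
}

#' Local exact mapping of reads onto exons
#'
#' Formalises a local alignment whose penalties make any mismatch or gap
#' worse than ending the alignment, so a qualifying alignment is a maximal
#' exact shared contiguous substring between the read and an exon. The
#' qualification rule is exon-length dependent: exons of at least
#' `large_exon_min` bp accept any shared substring of at least
#' `large_exon_min` bp; shorter exons (at least `recip_exon_min` bp) must be
#' matched over their entire length; exons below `recip_exon_min` bp are
#' ignored. Both strands are considered and all qualifying placements are
#' reported.
#'
#' @param rs a `read_set`.
#' @param db an [hla_db()] (exon annotations required).
#' @param cfg a [pipeline_config()].
#' @return `data.table(read_id, allele, exon_index, start, match_len,
#'   is_reverse)`; `start` is the 0-based CDS offset of the leftmost matched
#'   base.
#' @export
map_local_exons <- function(rs, db, cfg = pipeline_config()) {
  stopifnot(inherits(rs, "read_set"), inherits(db, "hla_db"))
  ex <- exon_seq_table(db)
  reads <- rs$reads
  empty <- data.table(read_id = character(0), allele = character(0),
                      exon_index = integer(0), start = integer(0),
                      match_len = integer(0), is_reverse = logical(0))
  if (nrow(reads) == 0L || nrow(ex) == 0L) return(empty)
  out <- list(empty)

  # small exons: the full exon must appear inside a read
  small <- ex[len >= cfg$recip_exon_min & len < cfg$large_exon_min]
  for (L in sort(unique(small$len))) {
    rk <- kmer_table(stats::setNames(reads$seq_, reads$read_id), L)
    exl <- small[len == L]
    for (strand in c(FALSE, TRUE)) {
      q <- data.table(kmer = if (strand) revcomp(exl$seq_) else exl$seq_,
                      allele = exl$allele, exon_index = exl$exon_index,
                      start = exl$start)
      hit <- rk[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
      if (nrow(hit)) {
        hit <- unique(hit[, .(read_id = name, allele, exon_index, start,
                              match_len = L, is_reverse = strand)])
        out[[length(out) + 1L]] <- hit
      }
    }
  }

  # large exons: seed with large_exon_min-mers and merge seeds on the same
  # diagonal into maximal shared substrings
  k <- cfg$large_exon_min
  large <- ex[len >= k]
  if (nrow(large) && any(nchar(reads$seq_) >= k)) {
    counts <- large$len - k + 1L
    ek <- data.table(
      allele = rep(large$allele, counts),
      exon_index = rep(large$exon_index, counts),
      exon_start = rep(large$start, counts),
      epos = unlist(lapply(counts, function(n) 0:(n - 1L)), use.names = FALSE)
    )
    ek[, kmer := substring(rep(large$seq_, counts), epos + 1L, epos + k)]
    setkey(ek, kmer)
    for (strand in c(FALSE, TRUE)) {
      seqs <- if (strand) revcomp(reads$seq_) else reads$seq_
      rk <- kmer_table(stats::setNames(seqs, reads$read_id), k)
      seeds <- ek[rk, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
      if (nrow(seeds) == 0L) next
      seeds[, diag := epos - start0]
      setorder(seeds, name, allele, exon_index, diag, epos)
      seeds[, run := cumsum(c(1L, as.integer(diff(epos) != 1L))),
            by = .(name, allele, exon_index, diag)]
      runs <- seeds[, .(start = exon_start[1L] + min(epos),
                        match_len = max(epos) - min(epos) + k),
                    by = .(name, allele, exon_index, diag, run)]
      out[[length(out) + 1L]] <- runs[, .(read_id = name, allele, exon_index,
                                          start, match_len, is_reverse = strand)]
    }
  }
  res <- rbindlist(out)
  setorder(res, read_id, allele, exon_index, start, is_reverse)
  res[]
}

#' Per-read allele assignment from local-mapping hits
#'
#' @param hits output of [map_local_exons()].
#' @return unique `data.table(read_id, allele)` pairs.
#' @export
read_allele_map <- function(hits) {
  unique(hits[, .(read_id, allele)])
}

#' Dump mapping hits as a SAM-like TSV (debugging aid)
#' @param hits a hit table from [map_end_to_end()] or [map_local_exons()].
#' @param path output path.
#' @export
write_hits_tsv <- function(hits, path) {
  h <- copy(as.data.table(hits))
  h[, strand := ifelse(is_reverse, "-", "+")]
  h[, is_reverse := NULL]
  utils::write.table(h, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
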