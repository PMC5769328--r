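# Brute-force reference implementations used as oracles. They share no code
# with the package's matchers: everything is done by direct offset-by-offset
# string comparison.

library(data.table)

# every placement of every whole read (both strands) on every allele CDS;
# substring tables are cached per (allele, read length)
oracle_end_to_end <- function(rs, db, min_contig) {
  out <- list()
  rc_all <- revcomp(rs$reads$seq_)
  subs_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(rs$reads))) {
    rd <- rs$reads$seq_[i]
    L <- nchar(rd)
    if (L < min_contig) next
    for (strand in c(FALSE, TRUE)) {
      q <- if (strand) rc_all[i] else rd
      for (a in names(db$seqs)) {
        cds <- db$seqs[[a]]
        n <- nchar(cds)
        if (n < L) next
        key <- paste0(a, "#", L)
        if (is.null(subs_cache[[key]]))
          subs_cache[[key]] <- substring(cds, 1:(n - L + 1L), L:n)
        for (o in which(subs_cache[[key]] == q)) {
          out[[length(out) + 1L]] <- data.table(
            read_id = rs$reads$read_id[i], allele = a, start = o - 1L,
            match_len = L, is_reverse = strand)
        }
      }
    }
  }
  empty <- data.table(read_id = character(0), allele = character(0),
                      start = integer(0), match_len = integer(0),
                      is_reverse = logical(0))
  rbindlist(c(list(empty), out))
}

# maximal exact common substrings between read and exon via the full
# character-equality matrix: a maximal run on a diagonal starts at a cell
# whose upper-left neighbour mismatches and ends at one whose lower-right
# neighbour mismatches; the k-th start on a diagonal pairs with the k-th end
oracle_local_exons <- function(rs, db, cfg) {
  ex <- db$exons[, .(allele, exon_index, start, end)]
  out <- list()
  for (i in seq_len(nrow(rs$reads))) {
    for (strand in c(FALSE, TRUE)) {
      q <- if (strand) revcomp(rs$reads$seq_[i]) else rs$reads$seq_[i]
      rch <- strsplit(q, "")[[1]]
      m <- length(rch)
      for (j in seq_len(nrow(ex))) {
        eseq <- substring(db$seqs[[ex$allele[j]]], ex$start[j] + 1L, ex$end[j])
        elen <- nchar(eseq)
        if (elen < cfg$recip_exon_min) next
        thr <- if (elen >= cfg$large_exon_min) cfg$large_exon_min else elen
        ech <- strsplit(eseq, "")[[1]]
        eq <- outer(rch, ech, "==")
        ul <- matrix(FALSE, m, elen)
        if (m > 1L && elen > 1L) ul[2:m, 2:elen] <- eq[1:(m - 1L), 1:(elen - 1L)]
        dr <- matrix(FALSE, m, elen)
        if (m > 1L && elen > 1L) dr[1:(m - 1L), 1:(elen - 1L)] <- eq[2:m, 2:elen]
        s_idx <- which(eq & !ul, arr.ind = TRUE)
        e_idx <- which(eq & !dr, arr.ind = TRUE)
        if (nrow(s_idx) == 0L) next
        s_ord <- order(s_idx[, 2] - s_idx[, 1], s_idx[, 1])
        e_ord <- order(e_idx[, 2] - e_idx[, 1], e_idx[, 1])
        s_idx <- s_idx[s_ord, , drop = FALSE]
        e_idx <- e_idx[e_ord, , drop = FALSE]
        lens <- e_idx[, 1] - s_idx[, 1] + 1L
        keep <- lens >= thr
        if (!any(keep)) next
        out[[length(out) + 1L]] <- data.table(
          read_id = rs$reads$read_id[i], allele = ex$allele[j],
          exon_index = ex$exon_index[j],
          start = ex$start[j] + s_idx[keep, 2] - 1L,
          match_len = as.integer(lens[keep]), is_reverse = strand)
      }
    }
  }
  empty <- data.table(read_id = character(0), allele = character(0),
                      exon_index = integer(0), start = integer(0),
                      match_len = integer(0), is_reverse = logical(0))
  rbindlist(c(list(empty), out))
}

# a tile is matched iff it (or its reverse complement) occurs in any read
oracle_match_artificial <- function(art, rs) {
  if (nrow(art) == 0L)
    return(data.table(allele = character(0), exon_index = integer(0),
                      offset = integer(0)))
  haystack <- paste(rs$reads$seq_, collapse = "#")
  rc <- revcomp(art$seq_)
  hit <- vapply(seq_len(nrow(art)), function(i) {
    grepl(art$seq_[i], haystack, fixed = TRUE) ||
      grepl(rc[i], haystack, fixed = TRUE)
  }, logical(1))
  out <- art[hit, .(allele, exon_index, offset)]
  setorder(out, allele, exon_index, offset)
  out
}

# classic LCS dynamic programme = maximal matched bases under unit match
# score with free mismatches and gaps
oracle_max_matches <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  m <- length(x); n <- length(y)
  prev <- integer(n + 1L)
  for (i in seq_len(m)) {
    cur <- integer(n + 1L)
    for (j in seq_len(n)) {
      cur[j + 1L] <- max(prev[j] + (x[i] == y[j]), prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[n + 1L]
}

# normalise a hit table for set comparison
canon_hits <- function(h) {
  h <- unique(as.data.table(h))
  setorderv(h, names(h))
  h
}
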