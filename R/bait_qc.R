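#' Per-exon sequence identity between a bait allele and a query allele
#'
#' The bait-design question: how well does one allele's exon, used as a
#' capture bait, match the homologous exon of another allele? Identity is
#' the number of matched bases in the best global alignment (unit match
#' score, zero mismatch and gap scores, i.e. the maximal number of
#' alignable identical bases) divided by the query exon length, capped at
#' 1. Exon correspondence is by exon index; only query exons of length at
#' least `identity_exon_min` are recorded. A query exon with no
#' corresponding bait exon yields identity 0 with a warning.
#'
#' @param bait,query allele names present in `db`, or single-allele
#'   `hla_db` objects.
#' @param db an [hla_db()] containing both alleles (ignored when `bait` and
#'   `query` are databases).
#' @param cfg a [pipeline_config()].
#' @return `data.table(bait_allele, query_allele, exon_index, exon_len,
#'   identity)`.
#' @export
exon_identity <- function(bait, query, db = NULL, cfg = pipeline_config()) {
  get_exons <- function(x) {
    if (inherits(x, "hla_db")) {
      stopifnot(length(x$seqs) == 1L)
      exon_seq_table(x)
    } else {
      stopifnot(inherits(db, "hla_db"))
      exon_seq_table(db_subset(db, x))
    }
  }
  bx <- get_exons(bait)
  qx <- get_exons(query)
  qx <- qx[len >= cfg$identity_exon_min]
  res <- lapply(seq_len(nrow(qx)), function(i) {
    ei <- qx$exon_index[i]
    b <- bx[exon_index == ei]
    if (nrow(b) == 0L) {
      warning("bait allele lacks exon index ", ei, call. = FALSE)
      ident <- 0
    } else {
      ident <- min(1, max_match_bases(qx$seq_[i], b$seq_[1]) / qx$len[i])
    }
    data.table(bait_allele = bx$allele[1], query_allele = qx$allele[i],
               exon_index = ei, exon_len = qx$len[i], identity = ident)
  })
  rbindlist(c(list(data.table(bait_allele = character(0),
                              query_allele = character(0),
                              exon_index = integer(0), exon_len = integer(0),
                              identity = numeric(0))), res))
}

# maximal number of matched bases in a global alignment with unit match
# score and free mismatches/gaps; with free gaps this is the length of the
# longest common subsequence, computed here via Biostrings
max_match_bases <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0)
  al <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = 0,
                                      type = "global", scoreOnly = TRUE)
  as.integer(round(al))
}

#' Saturation coverage of a query allele's exons by a bait
#'
#' Verifies the capture-design guarantee that every exon base of a query
#' allele sits inside at least one fragment with enough contiguous exact
#' complementarity to the bait to hybridize. A base is covered iff some
#' contiguous exact shared substring of length at least `min_complementary`
#' between the query CDS and the bait CDS contains it.
#'
#' @param bait,query allele names in `db`, or single-allele `hla_db`s.
#' @param db an [hla_db()] (ignored when both arguments are databases).
#' @param min_complementary minimum contiguous complementarity in bp
#'   (default from `cfg`, 20 bp).
#' @param cfg a [pipeline_config()].
#' @return `data.table(query_allele, exon_index, exon_len, covered,
#'   n_uncovered)` with attribute `uncovered`: a named list of 0-based
#'   uncovered CDS positions per exon index.
#' @export
saturation_check <- function(bait, query, db = NULL, min_complementary = NULL,
                             cfg = pipeline_config()) {
  minc <- as.integer(min_complementary %||% cfg$min_complementary)
  get_db <- function(x) {
    if (inherits(x, "hla_db")) x else db_subset(db, x)
  }
  bdb <- get_db(bait)
  qdb <- get_db(query)
  stopifnot(length(bdb$seqs) == 1L, length(qdb$seqs) == 1L)
  qseq <- qdb$seqs[[1]]
  bseq <- bdb$seqs[[1]]
  qlen <- nchar(qseq)

  covered <- rep(FALSE, qlen)
  if (qlen >= minc && nchar(bseq) >= minc) {
    bk <- unique(seq_kmers(bseq, minc))
    qk <- seq_kmers(qseq, minc)
    hit <- qk %chin% bk
    for (i in which(hit)) covered[i:(i + minc - 1L)] <- TRUE
  }
  ex <- exon_seq_table(qdb)
  unc <- list()
  rows <- lapply(seq_len(nrow(ex)), function(i) {
    span <- (ex$start[i] + 1L):ex$end[i]
    u <- span[!covered[span]] - 1L
    unc[[as.character(ex$exon_index[i])]] <<- u
    data.table(query_allele = ex$allele[i], exon_index = ex$exon_index[i],
               exon_len = ex$len[i], covered = length(u) == 0L,
               n_uncovered = length(u))
  })
  out <- rbindlist(rows)
  setattr(out, "uncovered", unc)
  out[]
}
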