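#' Stage 1: remove alleles with insufficient tiling coverage of large exons
#'
#' Every exon of length >= `large_exon_min` of a candidate allele is tiled
#' into artificial reads of `artificial_read_len` bp; a tile counts as
#' matched when it (or its reverse complement) occurs inside at least one
#' deduplicated sequencing read. Under the default `stage1_rule = "gaps"`
#' an allele survives iff every large exon has at least one matched tile
#' and no two adjacent matched tiles are further apart than
#' `artificial_read_len`; under `"coverage"` the union of matched tile
#' intervals must additionally cover every exon base (see
#' [pipeline_config()] for when that stricter rule is appropriate). Alleles
#' without any large exon survive vacuously (reported in the `vacuous`
#' attribute).
#'
#' @param db an [hla_db()].
#' @param rs a [deduplicate()]d `read_set`.
#' @param cfg a [pipeline_config()].
#' @return character vector of surviving allele names, with attribute
#'   `vacuous` listing alleles that had no large exon.
#' @export
coverage_filter <- function(db, rs, cfg = pipeline_config()) {
  art <- make_artificial_reads(db, cfg)
  matched <- match_artificial_to_reads(art, rs, cfg)
  k <- cfg$artificial_read_len

  large <- exon_seq_table(db)[len >= cfg$large_exon_min, .(allele, exon_index, len)]
  vacuous <- setdiff(names(db$seqs), unique(large$allele))

  if (nrow(large) == 0L) {
    out <- names(db$seqs)
    attr(out, "vacuous") <- vacuous
    return(out)
  }
  cov <- merge(matched, large, by = c("allele", "exon_index"))[, .(ok = {
    o <- sort(offset)
    if (cfg$stage1_rule == "coverage") {
      o[1] == 0L && o[length(o)] == len[1] - k && all(diff(o) <= k)
    } else {
      all(diff(o) <= k)
    }
  }), by = .(allele, exon_index)]
  # exons with zero matched tiles never appear in `matched`: fail them
  status <- merge(large, cov, by = c("allele", "exon_index"), all.x = TRUE)
  status[is.na(ok), ok := FALSE]
  surv_large <- status[, .(ok = all(ok)), by = allele][ok == TRUE, allele]
  out <- intersect(names(db$seqs), c(surv_large, vacuous))
  attr(out, "vacuous") <- vacuous
  out
}

#' Per-gene candidate presence matrix
#'
#' Rows are base positions of the longest candidate allele of the gene
#' (raw CDS offsets, no realignment across alleles); columns are the
#' candidate alleles. A cell is 1 when a whole-read end-to-end hit starts
#' at that position on that allele. Positions beyond an allele's own length
#' (`null_mask`) are filled with 1 whenever any other allele of the gene
#' has a read starting there, so short alleles are not penalised for
#' positions they do not possess.
#'
#' @return an object of class `candidate_matrix`: a list with `gene`,
#'   `alleles`, `n_rows`, `presence` (allele x position 0/1 matrix) and
#'   `null_mask` (same shape, TRUE beyond the allele's length).
#' @param gene gene symbol.
#' @param alleles candidate allele names of the gene.
#' @param lens named integer vector of CDS lengths.
#' @param starts `data.table(allele, start)` of first-base hit positions.
#' @export
candidate_matrix <- function(gene, alleles, lens, starts) {
  n_rows <- max(lens[alleles])
  presence <- matrix(0L, nrow = length(alleles), ncol = n_rows,
                     dimnames = list(alleles, NULL))
  null_mask <- matrix(FALSE, nrow = length(alleles), ncol = n_rows,
                      dimnames = list(alleles, NULL))
  for (a in alleles) {
    p <- starts[allele == a, unique(start)]
    presence[a, p + 1L] <- 1L
    if (lens[[a]] < n_rows) null_mask[a, (lens[[a]] + 1L):n_rows] <- TRUE
  }
  any_hit <- as.integer(colSums(presence) > 0L)
  for (a in alleles) {
    m <- null_mask[a, ]
    if (any(m)) {
      # a null position borrows presence from other alleles of the gene
      others <- as.integer(colSums(presence[setdiff(alleles, a), m, drop = FALSE]) > 0L)
      presence[a, m] <- others
    }
  }
  structure(list(gene = gene, alleles = alleles, n_rows = n_rows,
                 presence = presence, null_mask = null_mask),
            class = "candidate_matrix")
}

#' Stage 2: windowed first-base presence screening
#'
#' Whole reads are exact-mapped end-to-end against the surviving alleles;
#' only the first-base (leftmost CDS) position of each hit is recorded.
#' Per gene, the presence matrix is scanned in non-overlapping windows of
#' `window_len` bp (the trailing short window included): an allele is
#' removed iff some window of it contains no first-base hit (after
#' null-mask filling) while at least one other allele of the same gene has
#' a hit in the same window. Genes with a single surviving candidate are
#' left untouched.
#'
#' @param db an [hla_db()].
#' @param survivors allele names surviving [coverage_filter()].
#' @param rs a `read_set`.
#' @param cfg a [pipeline_config()].
#' @return list with `survivors` (character vector) and `matrices` (named
#'   list of `candidate_matrix`, one per gene with >= 1 candidate).
#' @export
window_filter <- function(db, survivors, rs, cfg = pipeline_config()) {
  stopifnot(all(survivors %in% names(db$seqs)))
  sub <- db_subset(db, survivors)
  hits <- map_end_to_end(rs, sub, min_contig = cfg$full_read_len)
  lens <- nchar(db$seqs)

  keep <- character(0)
  matrices <- list()
  for (g in db_genes(db)) {
    cand <- sort(intersect(survivors, db_alleles(db, g)))
    if (length(cand) == 0L) next
    starts <- hits[allele %chin% cand, .(allele, start)]
    cm <- candidate_matrix(g, cand, lens, starts)
    matrices[[g]] <- cm
    if (length(cand) == 1L) {
      keep <- c(keep, cand)
      next
    }
    win <- (seq_len(cm$n_rows) - 1L) %/% cfg$window_len
    counts <- t(apply(cm$presence, 1L, function(row) tapply(row, win, sum)))
    # remove allele iff it has an empty window where any other allele has hits
    removed <- vapply(cand, function(a) {
      others <- counts[setdiff(cand, a), , drop = FALSE]
      any(counts[a, ] == 0L & apply(others, 2L, max) > 0L)
    }, logical(1))
    keep <- c(keep, cand[!removed])
  }
  list(survivors = sort(keep), matrices = matrices)
}
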