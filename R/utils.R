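# Internal helpers shared across modules.

#' @import data.table
#' @importFrom methods is
NULL

# data.table NSE variables used throughout; quiet R CMD check.
utils::globalVariables(c(
  ".", ".N", ".BY", "allele", "exon_index", "start", "end", "kmer", "offset",
  "read_id", "is_reverse", "match_len", "seq_", "gene", "pos", "matched",
  "n_alleles", "len", "signature", "null_name", "trigger_allele", "exon_len",
  "name", "start0", "exon_start", "epos", "run", "strand", "mult", "ok",
  "score", "status", "source_allele", "is_dup", "diag"
))

#' Reverse complement of plain character DNA sequences
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that
#' keeps sequences as ordinary character vectors, which is how this package
#' passes reads around.
#'
#' @param x character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# All k-mers of a single sequence as a character vector (empty if too short).
seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}

# k-mer table for a named character vector of sequences:
# data.table(name, start0, kmer) with 0-based start offsets.
kmer_table <- function(seqs, k) {
  stopifnot(!is.null(names(seqs)))
  keep <- nchar(seqs) >= k
  seqs <- seqs[keep]
  if (length(seqs) == 0L) {
    return(data.table(name = character(0), start0 = integer(0), kmer = character(0)))
  }
  counts <- nchar(seqs) - k + 1L
  dt <- data.table(
    name = rep(names(seqs), counts),
    start0 = unlist(lapply(counts, function(n) 0:(n - 1L)), use.names = FALSE)
  )
  dt[, kmer := substring(rep(seqs, counts), start0 + 1L, start0 + k)]
  dt
}

# Deterministic RNG scope: runs expr with the given seed and restores the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Validate a DNA string strictly over {A,C,G,T}: exact matching is undefined
# on ambiguity codes, so N is rejected rather than soft-masked.
assert_acgt <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T}: %s",
                 what, paste(utils::head(names(x)[bad] %||% which(bad), 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
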