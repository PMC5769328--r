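#' Read a null-allele signature table
#'
#' Null alleles (alleles producing no surface protein) are distinguished
#' from their parent alleles only by short intron/exon-boundary sequences,
#' so they are invisible to CDS-based typing. The pipeline therefore takes
#' a user-supplied table of discriminating signatures: when a trigger
#' allele is reported, the reads are searched for the signature and the
#' corresponding null allele flagged if enough distinct reads support it.
#' The table is a TSV with columns `trigger_allele`, `null_name`,
#' `signature` (DNA over `{A,C,G,T}`, typically <= 30 bases spanning an
#' intron/exon boundary); multiple rows per null allele give alternative
#' signatures.
#'
#' @param path TSV path.
#' @return `data.table(trigger_allele, null_name, signature)`.
#' @export
read_null_signature_table <- function(path) {
  dt <- as.data.table(utils::read.delim(path, stringsAsFactors = FALSE))
  req <- c("trigger_allele", "null_name", "signature")
  if (!all(req %in% names(dt)))
    stop("signature table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  dt[, signature := toupper(signature)]
  if (any(nchar(dt$signature) == 0L) || any(grepl("[^ACGT]", dt$signature)))
    stop("malformed signature: signatures must be non-empty over {A,C,G,T}",
         call. = FALSE)
  parse_allele_name(dt$trigger_allele)  # validates
  dt[, .(trigger_allele, null_name, signature)]
}

# distinct deduplicated reads containing any of the signatures, either strand
count_signature_support <- function(rs, signatures) {
  pats <- unique(c(signatures, revcomp(signatures)))
  hit <- rep(FALSE, nrow(rs$reads))
  for (p in pats) hit <- hit | grepl(p, rs$reads$seq_, fixed = TRUE)
  sum(hit)
}

#' Flag documented null alleles supported by signature-bearing reads
#'
#' For every reported allele matching a `trigger_allele` of the signature
#' table, counts the deduplicated reads containing any of its signatures
#' as an exact substring on either strand (duplicates never inflate
#' support: one distinct sequence counts once). The null allele is
#' appended to the gene's `null_flags` iff the count reaches
#' `null_support_min` (i.e. strictly more than three supporting reads at
#' the default).
#'
#' @param report a `genotype_report` from [call_genotypes()].
#' @param rs the [deduplicate()]d `read_set` of the run.
#' @param table signature table from [read_null_signature_table()] (or an
#'   equivalent `data.frame`); may be empty.
#' @param cfg a [pipeline_config()].
#' @return the updated `genotype_report`.
#' @export
check_null_alleles <- function(report, rs, table, cfg = pipeline_config()) {
  stopifnot(inherits(report, "genotype_report"))
  table <- as.data.table(table)
  if (nrow(table) == 0L) return(report)
  for (gi in seq_along(report$calls)) {
    cl <- report$calls[[gi]]
    if (cl$untypeable) next
    reported <- unique(unlist(cl$alleles, use.names = FALSE))
    trig <- table[trigger_allele %chin% reported]
    if (nrow(trig) == 0L) next
    flags <- character(0)
    for (nn in unique(trig$null_name)) {
      supp <- count_signature_support(rs, trig[null_name == nn, signature])
      if (supp >= cfg$null_support_min) flags <- c(flags, nn)
    }
    report$calls[[gi]]$null_flags <- sort(unique(flags))
  }
  report
}
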