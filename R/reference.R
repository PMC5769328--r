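#' Parse an HLA allele name
#'
#' Allele names follow the colon-separated field nomenclature
#' `GENE*f1:f2[:f3[:f4]]`, e.g. `"A*01:01:01"` or `"DRB1*04:01"`. At least
#' two numeric fields are required (two-field resolution is what the
#' pipeline reports).
#'
#' @param name character vector of allele names.
#' @return a `data.frame` with columns `name`, `gene`, and `n_fields`.
#' @examples
#' parse_allele_name("A*01:01:01")
#' @export
parse_allele_name <- function(name) {
  m <- regmatches(name, regexec("^([A-Za-z0-9-]+)\\*((?:[0-9]+)(?::[0-9A-Z]+)+)$", name))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad))
    stop("malformed allele name(s): ", paste(utils::head(name[bad], 3), collapse = ", "),
         call. = FALSE)
  gene <- vapply(m, `[`, character(1), 2L)
  fields <- vapply(m, `[`, character(1), 3L)
  data.frame(name = name, gene = gene,
             n_fields = lengths(strsplit(fields, ":", fixed = TRUE)) ,
             stringsAsFactors = FALSE)
}

#' Construct an allele database
#'
#' The database holds the coding sequence (CDS, concatenated exons) of every
#' allele together with its exon decomposition in 0-based half-open CDS
#' coordinates, plus the set of genes the typing run considers. Homologous
#' companion loci (by convention `H` and `Y`, which soak up reads that
#' cross-map from `A`) are ordinary genes flagged non-reportable.
#'
#' @param seqs named character vector: allele name -> CDS over `{A,C,G,T}`.
#' @param exons `data.frame`/`data.table` with columns `allele`,
#'   `exon_index` (0-based), `start`, `end` (0-based half-open on the CDS).
#' @param companion_genes genes present only to absorb cross-gene mapping;
#'   they are typed but never reported. Defaults to whichever of `H`, `Y`
#'   occur in `seqs`.
#' @param paralog_map named list mapping a reportable gene to the companion
#'   gene(s) used for its cross-paralog correction. Defaults to
#'   `list(A = c("H", "Y"), C = "B")`, the documented homology structure.
#' @return an object of class `hla_db`.
#' @export
hla_db <- function(seqs, exons, companion_genes = NULL, paralog_map = NULL) {
  if (length(seqs) == 0L) stop("empty allele database", call. = FALSE)
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("all allele sequences must be named", call. = FALSE)
  if (anyDuplicated(names(seqs)))
    stop("duplicate allele name: ",
         names(seqs)[duplicated(names(seqs))][1], call. = FALSE)
  seqs <- toupper(seqs)
  if (any(nchar(seqs) == 0L)) stop("empty CDS", call. = FALSE)
  names(seqs) -> nm
  assert_acgt(stats::setNames(seqs, nm), "allele CDS")

  parsed <- parse_allele_name(nm)
  genes <- stats::setNames(parsed$gene, nm)

  exons <- as.data.table(exons)[, .(allele, exon_index = as.integer(exon_index),
                                    start = as.integer(start), end = as.integer(end))]
  missing_ann <- setdiff(nm, unique(exons$allele))
  if (length(missing_ann))
    stop("exon annotations required for allele(s): ",
         paste(utils::head(missing_ann, 3), collapse = ", "), call. = FALSE)
  orphan <- setdiff(unique(exons$allele), nm)
  if (length(orphan))
    stop("exon table references unknown allele(s): ",
         paste(utils::head(orphan, 3), collapse = ", "), call. = FALSE)
  setkey(exons, allele, exon_index)
  for (a in nm) {
    ex <- exons[.(a)]
    if (!identical(ex$exon_index, seq_len(nrow(ex)) - 1L))
      stop("exon indices of ", a, " must be 0,1,2,...", call. = FALSE)
    if (ex$start[1] != 0L || ex$end[nrow(ex)] != nchar(seqs[[a]]) ||
        any(ex$end <= ex$start) ||
        (nrow(ex) > 1L && any(ex$start[-1] != ex$end[-nrow(ex)])))
      stop("non-contiguous exons for allele ", a, call. = FALSE)
  }

  gene_set <- sort(unique(unname(genes)))
  if (is.null(companion_genes)) companion_genes <- intersect(c("H", "Y"), gene_set)
  if (!all(companion_genes %in% gene_set))
    stop("companion_genes not present in database", call. = FALSE)
  if (is.null(paralog_map)) paralog_map <- list(A = c("H", "Y"), C = "B")
  paralog_map <- lapply(paralog_map, intersect, gene_set)
  paralog_map <- paralog_map[lengths(paralog_map) > 0 & names(paralog_map) %in% gene_set]

  structure(list(seqs = seqs, genes = genes, exons = exons,
                 gene_set = gene_set,
                 companion_genes = companion_genes,
                 paralog_map = paralog_map),
            class = "hla_db")
}

#' @export
print.hla_db <- function(x, ...) {
  cat(sprintf("hla_db: %d alleles, %d genes (%s)\n",
              length(x$seqs), length(x$gene_set),
              paste(x$gene_set, collapse = ", ")))
  if (length(x$companion_genes))
    cat("  non-reportable companions:", paste(x$companion_genes, collapse = ", "), "\n")
  invisible(x)
}

#' Genes of the database, optionally excluding non-reportable companions
#' @param db an `hla_db`.
#' @param reportable_only drop companion loci such as `H`/`Y`.
#' @return character vector of gene symbols.
#' @export
db_genes <- function(db, reportable_only = FALSE) {
  g <- db$gene_set
  if (reportable_only) g <- setdiff(g, db$companion_genes)
  g
}

#' Alleles of one gene
#' @param db an `hla_db`.
#' @param gene gene symbol.
#' @return character vector of allele names.
#' @export
db_alleles <- function(db, gene = NULL) {
  if (is.null(gene)) return(names(db$seqs))
  names(db$genes)[db$genes %in% gene]
}

#' Restrict a database to a subset of alleles
#'
#' The gene set, companion flags and paralog map are kept, so a subset
#' behaves like the full database for screening and genotyping.
#'
#' @param db an `hla_db`.
#' @param alleles allele names to keep.
#' @return an `hla_db`.
#' @export
db_subset <- function(db, alleles) {
  alleles <- intersect(names(db$seqs), alleles)
  out <- db
  out$seqs <- db$seqs[alleles]
  out$genes <- db$genes[alleles]
  out$exons <- db$exons[allele %chin% alleles]
  out
}

#' Read an allele database from FASTA plus an exon table
#'
#' Accepts both bare headers (`>A*01:01`) and the IMGT/HLA nucleotide-file
#' dialect (`>HLA:HLA00001 A*01:01:01:01 3503 bp`); the allele name is the
#' header token containing `*`. The exon table is a TSV with columns
#' `allele`, `exon_index`, `start`, `end` in 0-based half-open CDS
#' coordinates. Alleles lacking exon annotations, duplicate names and
#' sequences containing `N` (exact matching is undefined on `N`) are
#' rejected.
#'
#' @param path FASTA of allele coding sequences.
#' @param exon_table TSV exon annotation path.
#' @param ... passed to [hla_db()] (`companion_genes`, `paralog_map`).
#' @return an `hla_db`.
#' @export
read_allele_fasta <- function(path, exon_table, ...) {
  ss <- Biostrings::readDNAStringSet(path)
  headers <- names(ss)
  name <- vapply(strsplit(headers, "[ \t]+"), function(tok) {
    hit <- grep("*", tok, fixed = TRUE, value = TRUE)
    if (length(hit) == 0L) tok[1] else hit[1]
  }, character(1))
  if (anyDuplicated(name))
    stop("duplicate allele name: ", name[duplicated(name)][1], call. = FALSE)
  seqs <- stats::setNames(as.character(ss), name)
  ex <- utils::read.delim(exon_table, stringsAsFactors = FALSE)
  req <- c("allele", "exon_index", "start", "end")
  if (!all(req %in% names(ex)))
    stop("exon table must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  hla_db(seqs, ex, ...)
}

#' Write an allele database as FASTA plus an exon table
#'
#' Inverse of [read_allele_fasta()]: round-tripping reproduces sequences and
#' exon intervals exactly.
#'
#' @param db an `hla_db`.
#' @param path output FASTA path.
#' @param exon_table output TSV path.
#' @export
write_allele_fasta <- function(db, path, exon_table) {
  ss <- Biostrings::DNAStringSet(db$seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  ex <- as.data.frame(db$exons[order(allele, exon_index)])
  utils::write.table(ex, exon_table, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# substitute the bases at 1-based positions pos with different random bases
substitute_bases <- function(seq, pos) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

# deterministic exon tiling for a toy CDS: one short exon (45 bp, in the
# full-exon-rule regime) flanked by large exons of roughly equal size
toy_exon_tiling <- function(cds_len) {
  short <- 45L
  rem <- cds_len - short
  k <- max(2L, rem %/% 250L)
  base <- rem %/% k
  sizes <- rep(base, k)
  sizes[k] <- sizes[k] + rem - base * k
  lens <- c(sizes[1], short, sizes[-1])
  ends <- cumsum(lens)
  data.table(exon_index = seq_along(lens) - 1L,
             start = c(0L, ends[-length(ends)]), end = as.integer(ends))
}

#' Generate a deterministic toy allele database
#'
#' Emulates the structure that makes HLA typing hard: several genes, each
#' with many nearly identical alleles (fixed Hamming distance from a shared
#' gene ancestor), plus optional cross-gene paralog pairs whose ancestors
#' are 95%-identical copies (mimicking the homology of HLA-A with the
#' H and Y loci, and HLA-C with B). Exons are a fixed tiling containing at
#' least one short exon in the full-exon-match regime and several large
#' exons. The output is byte-identical for a fixed seed.
#'
#' @param n_genes number of primary genes (named `A`, `B`, `C`, `DQB1`,
#'   `DRB1`, ... in that order).
#' @param alleles_per_gene alleles generated per gene.
#' @param cds_len CDS length in bp; must be at least `3 * large_exon_min`.
#' @param divergence substitutions separating each allele from its gene
#'   ancestor (at distinct positions). Must be >= 1 when a gene has more
#'   than one allele.
#' @param paralog_pairs list of 2-vectors `c(gene, companion)`; a companion
#'   not among the primary gene names is created as a non-reportable locus
#'   whose ancestor is a 95%-identical copy of the gene's ancestor.
#' @param seed integer seed; the generator restores the caller's RNG state.
#' @param cfg a [pipeline_config()] supplying `large_exon_min`.
#' @return an `hla_db` with attribute `ancestors` (the per-gene ancestral
#'   sequences, useful for verifying homology structure).
#' @examples
#' db <- make_toy_database(2, 6, 800, 4, list(c("A", "H")), seed = 1)
#' db
#' @export
make_toy_database <- function(n_genes, alleles_per_gene, cds_len, divergence,
                              paralog_pairs = list(), seed = 1L,
                              cfg = pipeline_config()) {
  if (divergence < 1 && alleles_per_gene > 1)
    stop("divergence 0 with more than one allele per gene makes alleles indistinguishable",
         call. = FALSE)
  if (cds_len < 3L * cfg$large_exon_min)
    stop("cds_len must be at least 3 * large_exon_min", call. = FALSE)
  gene_names_pool <- c("A", "B", "C", "DQB1", "DRB1", "DPB1", "DQA1", "DPA1",
                       paste0("G", seq_len(max(0, n_genes - 8))))
  primary <- gene_names_pool[seq_len(n_genes)]
  companions <- character(0)
  for (pp in paralog_pairs) {
    if (!pp[1] %in% primary)
      stop("paralog pair references unknown gene: ", pp[1], call. = FALSE)
    if (!pp[2] %in% primary) companions <- union(companions, pp[2])
  }

  with_seed(seed, {
    ancestors <- stats::setNames(
      vapply(primary, function(g) random_dna(cds_len), character(1)), primary)
    for (pp in paralog_pairs) {
      if (pp[2] %in% names(ancestors)) {
        # both reportable: rewrite the companion's ancestor as a 95% copy
        nsub <- max(1L, round(0.05 * cds_len))
        ancestors[[pp[2]]] <- substitute_bases(ancestors[[pp[1]]],
                                               sample(cds_len, nsub))
      } else {
        nsub <- max(1L, round(0.05 * cds_len))
        ancestors[[pp[2]]] <- substitute_bases(ancestors[[pp[1]]],
                                               sample(cds_len, nsub))
      }
    }
    all_genes <- names(ancestors)
    seqs <- character(0)
    for (g in all_genes) {
      seen <- character(0)
      for (i in seq_len(alleles_per_gene)) {
        repeat {
          s <- substitute_bases(ancestors[[g]], sample(cds_len, divergence))
          if (!s %in% seen) break
        }
        seen <- c(seen, s)
        seqs[[sprintf("%s*%02d:01", g, i)]] <- s
      }
    }
    tiling <- toy_exon_tiling(cds_len)
    exons <- rbindlist(lapply(names(seqs), function(a) copy(tiling)[, allele := a]))
    pm <- list()
    for (pp in paralog_pairs) pm[[pp[1]]] <- union(pm[[pp[1]]], pp[2])
    db <- hla_db(seqs, exons,
                 companion_genes = companions,
                 paralog_map = if (length(pm)) pm else list())
    attr(db, "ancestors") <- ancestors
    db
  })
}
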