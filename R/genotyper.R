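#' Allele-specific read bookkeeping for the reciprocal screen
#'
#' Locally maps the deduplicated reads against the exons of the surviving
#' candidate alleles (all genes, including non-reportable companions) and
#' tabulates, per read, the set of alleles it maps to. From this table the
#' screen derives allele-specific reads (ASRs: within a candidate pair, the
#' reads mapping to exactly one member) by set difference, and
#' database-wide unique-read counts (reads mapping to exactly one allele
#' across the whole gene set).
#'
#' @param db an [hla_db()].
#' @param survivors allele names surviving the screening stages.
#' @param rs a [deduplicate()]d `read_set`.
#' @param cfg a [pipeline_config()].
#' @return an object of class `asr_table`: list with `read_map`
#'   (`data.table(read_id, allele, gene)`), `reads_of` (named list of read
#'   ids per allele), `unique_counts` (named integer), `candidates` (named
#'   list gene -> sorted candidate alleles; genes with zero survivors map
#'   to an empty vector and are reported untypeable downstream).
#' @export
build_asr_table <- function(db, survivors, rs, cfg = pipeline_config()) {
  stopifnot(all(survivors %in% names(db$seqs)))
  sub <- db_subset(db, survivors)
  hits <- map_local_exons(rs, sub, cfg)
  read_map <- read_allele_map(hits)
  read_map[, gene := unname(db$genes[allele])]

  reads_of <- lapply(stats::setNames(nm = sort(survivors)), function(a)
    sort(read_map[allele == a, read_id]))
  n_all <- read_map[, .(n_alleles = .N), by = read_id]
  uniq <- read_map[n_all, on = "read_id"][n_alleles == 1L, .N, by = allele]
  unique_counts <- stats::setNames(integer(length(reads_of)), names(reads_of))
  unique_counts[uniq$allele] <- uniq$N

  candidates <- lapply(stats::setNames(nm = db_genes(db)), function(g)
    sort(intersect(survivors, db_alleles(db, g))))
  structure(list(read_map = read_map, reads_of = reads_of,
                 unique_counts = unique_counts, candidates = candidates,
                 genes = db$genes),
            class = "asr_table")
}

#' Allele-specific reads of one pair member
#'
#' @param asr an `asr_table`.
#' @param x,y allele names forming the (unordered) pair; returns the reads
#'   mapping to `x` but not to `y` (empty for a self-pair).
#' @return character vector of read ids.
#' @export
asr_reads <- function(asr, x, y) {
  setdiff(asr$reads_of[[x]], asr$reads_of[[y]])
}

#' Seed the real allele pool from unique-read counts
#'
#' An allele whose database-wide unique mapped read count is at least
#' `pool_unique_min` (reads mapping to no other allele of any considered
#' gene) is taken as credibly present and seeds the pool of explaining
#' alleles.
#'
#' @param asr an `asr_table`.
#' @param cfg a [pipeline_config()].
#' @return character vector of allele names.
#' @export
seed_real_pool <- function(asr, cfg = pipeline_config()) {
  sort(names(asr$unique_counts)[asr$unique_counts >= cfg$pool_unique_min])
}

#' Exclude potential false alleles by reciprocal ASR imbalance
#'
#' Within each gene, every unordered pair of distinct candidates is
#' examined: an allele is marked a potential false allele iff there exists
#' a partner against which its ASR count is zero while the partner's is
#' non-zero, or the partner has at least `asr_fold` times as many ASRs.
#' Marking is decided simultaneously from the pre-exclusion table (no
#' cascade). If every candidate of a gene would be excluded, the allele(s)
#' with the maximal total ASR count are kept and a warning is raised.
#'
#' @param asr an `asr_table`.
#' @param cfg a [pipeline_config()].
#' @return a new `asr_table` with reduced per-gene candidate lists.
#' @export
exclude_false_alleles <- function(asr, cfg = pipeline_config()) {
  out <- asr
  for (g in names(asr$candidates)) {
    cand <- asr$candidates[[g]]
    if (length(cand) < 2L) next
    n <- matrix(0L, length(cand), length(cand), dimnames = list(cand, cand))
    for (x in cand) for (y in cand) if (x != y)
      n[x, y] <- length(asr_reads(asr, x, y))
    marked <- vapply(cand, function(x) {
      any(vapply(setdiff(cand, x), function(y)
        (n[x, y] == 0L && n[y, x] > 0L) ||
          (n[x, y] > 0L && n[y, x] >= cfg$asr_fold * n[x, y]),
        logical(1)))
    }, logical(1))
    if (all(marked)) {
      tot <- rowSums(n)
      keepers <- cand[tot == max(tot)]
      warning("all candidates of gene ", g,
              " marked as potential false alleles; keeping ",
              paste(keepers, collapse = ", "), call. = FALSE)
      out$candidates[[g]] <- keepers
    } else {
      out$candidates[[g]] <- cand[!marked]
    }
  }
  out
}

# all unordered pairs of a candidate set, self-pairs included, as a
# two-column character matrix in deterministic order
enumerate_pairs <- function(cand) {
  cand <- sort(cand)
  if (length(cand) == 0L) return(matrix(character(0), ncol = 2L))
  idx <- which(upper.tri(diag(length(cand)), diag = TRUE), arr.ind = TRUE)
  cbind(cand[idx[, "row"]], cand[idx[, "col"]])
}

#' Score candidate allele pairs by how completely they explain ASRs
#'
#' Every unordered candidate pair (self-pairs included, so homozygous
#' genotypes are expressible) is evaluated against every allele-instance of
#' the gene: for pair `P` and instance `a` of pair `Q`, the ASRs of `a`
#' within `Q` are explained when each maps locally to at least one allele
#' of `P` or of the real-allele pool restricted to other genes; if at most
#' `max_unexplained_asr` ASRs remain unexplained, `P` earns one point. A
#' pair explaining both instances of every pair attains the maximal score
#' `2 * n_pairs`.
#'
#' @param gene gene symbol.
#' @param candidates post-exclusion candidate alleles of the gene.
#' @param pool current real allele pool (alleles of any gene).
#' @param asr an `asr_table`.
#' @param cfg a [pipeline_config()].
#' @return `data.table(gene, a1, a2, score)` with a list-column `detail`
#'   holding the per-instance unexplained-ASR counts (named
#'   `"x|y:member"`).
#' @export
score_pairs <- function(gene, candidates, pool, asr, cfg = pipeline_config()) {
  pairs <- enumerate_pairs(candidates)
  if (nrow(pairs) == 0L)
    return(data.table(gene = character(0), a1 = character(0), a2 = character(0),
                      score = integer(0), detail = list()))
  # instances are independent of the explaining pair: precompute ASR sets
  # (two per pair, so a self-pair carries two vacuous instances)
  instances <- vector("list", 2L * nrow(pairs))
  inames <- character(2L * nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    x <- pairs[i, 1]; y <- pairs[i, 2]
    instances[[2L * i - 1L]] <- asr_reads(asr, x, y)
    instances[[2L * i]] <- asr_reads(asr, y, x)
    inames[2L * i - 1L] <- paste0(x, "|", y, ":1")
    inames[2L * i] <- paste0(x, "|", y, ":2")
  }
  names(instances) <- inames
  pool_other <- pool[asr$genes[pool] != gene]
  pool_reads <- unique(unlist(asr$reads_of[pool_other], use.names = FALSE))

  res <- lapply(seq_len(nrow(pairs)), function(i) {
    expl <- unique(c(pool_reads,
                     asr$reads_of[[pairs[i, 1]]],
                     asr$reads_of[[pairs[i, 2]]]))
    unexpl <- vapply(instances, function(ids) sum(!(ids %in% expl)), integer(1))
    list(score = sum(unexpl <= cfg$max_unexplained_asr), detail = unexpl)
  })
  data.table(gene = gene, a1 = pairs[, 1], a2 = pairs[, 2],
             score = vapply(res, `[[`, integer(1), "score"),
             detail = lapply(res, `[[`, "detail"))
}

top_pairs_of <- function(score_dt) {
  if (nrow(score_dt) == 0L) return(list())
  best <- score_dt[score == max(score)]
  lapply(seq_len(nrow(best)), function(i) c(best$a1[i], best$a2[i]))
}

#' Iterate pair scoring with a growing real allele pool
#'
#' Each pass scores all genes (lexicographic order, pool held fixed within
#' a pass) and then augments the pool with every gene's top-scoring
#' pair(s). Iteration stops when the per-gene top pairs are unchanged
#' between consecutive passes, or after `max_pool_passes` passes; in the
#' latter case the last pass is kept and the run is flagged so every gene
#' is reported NOT_PASS.
#'
#' @param asr an `asr_table` (post-exclusion).
#' @param cfg a [pipeline_config()].
#' @param pool initial pool; defaults to [seed_real_pool()].
#' @return list with `scores` (named list of per-gene score tables from the
#'   final pass), `top_pairs` (named list of lists of 2-vectors), `pool`
#'   (final pool), `passes`, `converged`.
#' @export
iterate_pool <- function(asr, cfg = pipeline_config(), pool = NULL) {
  seed <- pool %||% seed_real_pool(asr, cfg)
  genes <- sort(names(asr$candidates))
  pool_now <- seed
  prev_top <- NULL
  converged <- FALSE
  passes <- 0L
  scores <- NULL
  repeat {
    passes <- passes + 1L
    scores <- lapply(stats::setNames(nm = genes), function(g)
      score_pairs(g, asr$candidates[[g]], pool_now, asr, cfg))
    top <- lapply(scores, top_pairs_of)
    if (!is.null(prev_top) && identical(top, prev_top)) {
      converged <- TRUE
      break
    }
    if (passes >= cfg$max_pool_passes) break
    prev_top <- top
    pool_now <- sort(union(seed, unique(unlist(top, use.names = FALSE))))
  }
  list(scores = scores, top_pairs = lapply(scores, top_pairs_of),
       pool = pool_now, passes = passes, converged = converged)
}

#' Cross-paralog correction of a final allele pair
#'
#' Reads bled in from a highly homologous locus can prop up a spurious
#' member of a final pair. For a gene with configured companions (by
#' default `A` against `H`/`Y` and `C` against `B`): if exactly one member
#' of the final pair has its entire within-pair ASR set locally mapping
#' into the surviving alleles of the companion loci, that member is
#' dropped and the remaining allele reported alone.
#'
#' @param pair character vector of two allele names.
#' @param gene the pair's gene.
#' @param asr an `asr_table`.
#' @param db an [hla_db()] supplying `paralog_map`.
#' @return character vector of one or two allele names.
#' @export
paralog_correction <- function(pair, gene, asr, db) {
  comp_genes <- db$paralog_map[[gene]]
  if (is.null(comp_genes) || length(comp_genes) == 0L) return(pair)
  comp_alleles <- unlist(asr$candidates[comp_genes], use.names = FALSE)
  if (length(comp_alleles) == 0L) return(pair)
  comp_reads <- unique(unlist(asr$reads_of[comp_alleles], use.names = FALSE))
  fully <- vapply(1:2, function(i) {
    ids <- asr_reads(asr, pair[i], pair[3L - i])
    all(ids %in% comp_reads)
  }, logical(1))
  if (sum(fully) == 1L) pair[!fully] else pair
}

#' PASS/NOT-PASS quality statistic for one gene
#'
#' The quality value is the highest pair score divided by the number of
#' pairs evaluated in the final pass. A call is PASS iff the value is
#' exactly `pass_value` (integer arithmetic: top score equal to
#' `pass_value * n_pairs`), i.e. the winning pair explains both
#' allele-instances of every evaluated pair.
#'
#' @param score_dt a per-gene score table from [score_pairs()].
#' @param cfg a [pipeline_config()].
#' @return list with `quality_value` (numeric) and `quality`
#'   (`"PASS"`/`"NOT_PASS"`).
#' @export
quality_check <- function(score_dt, cfg = pipeline_config()) {
  n_pairs <- nrow(score_dt)
  if (n_pairs == 0L)
    return(list(quality_value = 0, quality = "NOT_PASS"))
  top <- max(score_dt$score)
  value <- top / n_pairs
  pass <- isTRUE(top == cfg$pass_value * n_pairs)
  list(quality_value = value, quality = if (pass) "PASS" else "NOT_PASS")
}

#' Call genotypes from a screened candidate set
#'
#' Runs the full reciprocal screen: ASR tabulation, false-allele
#' exclusion, pool-iterated pair scoring, cross-paralog correction and the
#' quality statistic, producing one call (possibly an ambiguity set of
#' tied pairs) per reportable gene.
#'
#' @param db an [hla_db()].
#' @param survivors alleles surviving [coverage_filter()] and
#'   [window_filter()].
#' @param rs a `read_set`.
#' @param cfg a [pipeline_config()].
#' @return an object of class `genotype_report`; see [format_report()].
#' @export
call_genotypes <- function(db, survivors, rs, cfg = pipeline_config()) {
  asr <- build_asr_table(db, survivors, rs, cfg)
  asr <- exclude_false_alleles(asr, cfg)
  it <- iterate_pool(asr, cfg)

  genes <- db_genes(db, reportable_only = TRUE)
  calls <- lapply(stats::setNames(nm = genes), function(g) {
    sc <- it$scores[[g]]
    if (is.null(sc) || nrow(sc) == 0L) {
      return(list(gene = g, pairs = list(), alleles = list(),
                  quality_value = 0, quality = "NOT_PASS",
                  untypeable = TRUE, null_flags = character(0)))
    }
    q <- quality_check(sc, cfg)
    if (!it$converged) q$quality <- "NOT_PASS"
    corrected <- lapply(it$top_pairs[[g]], paralog_correction,
                        gene = g, asr = asr, db = db)
    list(gene = g, pairs = it$top_pairs[[g]], alleles = corrected,
         quality_value = q$quality_value, quality = q$quality,
         untypeable = FALSE, null_flags = character(0))
  })
  structure(list(calls = calls, pool = it$pool, passes = it$passes,
                 converged = it$converged, asr = asr, cfg = cfg),
            class = "genotype_report")
}

#' @export
print.genotype_report <- function(x, ...) {
  cat("genotype_report (", x$passes, " pool pass(es)",
      if (!x$converged) ", NOT converged", "):\n", sep = "")
  for (cl in x$calls) {
    if (cl$untypeable) {
      cat(sprintf("  %-6s untypeable\n", cl$gene))
    } else {
      reps <- vapply(cl$alleles, paste, character(1), collapse = "/")
      cat(sprintf("  %-6s %s  [value %.3g, %s]%s\n", cl$gene,
                  paste(reps, collapse = " | "), cl$quality_value, cl$quality,
                  if (length(cl$null_flags))
                    paste0("  null: ", paste(cl$null_flags, collapse = ",")) else ""))
    }
  }
  invisible(x)
}
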