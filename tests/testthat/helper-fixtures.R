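# Fixtures are generated in code; heavyweight ones are cached per session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the standard study fixture: 3 genes x 12 alleles, ~800 bp CDS, divergence
# 4, one A/H-like paralog pair (H non-reportable)
std_toy_db <- function() {
  memo("std_toy_db",
       make_toy_database(3, 12, 800, 4, list(c("A", "H")), seed = 7))
}

std_truth_het <- function() {
  list(A = c("A*01:01", "A*02:01"),
       B = c("B*03:01", "B*04:01"),
       C = c("C*05:01", "C*06:01"))
}

std_truth_hom <- function() {
  list(A = c("A*01:01", "A*01:01"),
       B = c("B*03:01", "B*03:01"),
       C = c("C*05:01", "C*05:01"))
}

# run screening + genotyping, returning every intermediate of interest
run_pipeline <- function(db, rs, cfg = pipeline_config()) {
  s1 <- coverage_filter(db, rs, cfg)
  s2 <- window_filter(db, s1, rs, cfg)
  report <- call_genotypes(db, s2$survivors, rs, cfg)
  list(s1 = s1, s2 = s2, report = report, tab = format_report(report))
}

# the 20-seed standard heterozygous simulation study, computed once
std_het_runs <- function() {
  memo("std_het_runs", {
    db <- std_toy_db()
    truth <- std_truth_het()
    lapply(1:20, function(s) {
      sp <- sim_spec(truth, depth = 30, dup_rate = 0.2, seed = s)
      rs <- deduplicate(simulate_reads(db, sp))
      c(run_pipeline(db, rs), list(seed = s, rs = rs))
    })
  })
}

expected_call_tab <- function(truth) {
  g <- sort(names(truth))
  data.table::data.table(
    gene = g,
    allele_1 = vapply(g, function(x) sort(truth[[x]])[1], character(1)),
    allele_2 = vapply(g, function(x) sort(truth[[x]])[2], character(1)))
}

# a small random matcher instance: a toy database plus reads that are
# mutated substrings of its alleles mixed with fully random sequences
random_matcher_instance <- function(seed) {
  withr::with_seed(seed, {
    n_genes <- sample(1:2, 1)
    n_alleles <- sample(2:4, 1)
    cds_len <- sample(220:320, 1)
    db <- make_toy_database(n_genes, n_alleles, cds_len,
                            divergence = sample(1:6, 1),
                            seed = sample.int(1e6, 1))
    n_reads <- sample(8:25, 1)
    reads <- vapply(seq_len(n_reads), function(i) {
      if (runif(1) < 0.2) {
        paste(sample(c("A", "C", "G", "T"), sample(20:90, 1), TRUE), collapse = "")
      } else {
        a <- sample(names(db$seqs), 1)
        L <- sample(20:min(90, cds_len), 1)
        s0 <- sample.int(cds_len - L + 1L, 1)
        rd <- substring(db$seqs[[a]], s0, s0 + L - 1L)
        # sprinkle substitutions so some local matches truncate
        nmut <- sample(0:2, 1)
        if (nmut > 0) {
          ch <- strsplit(rd, "")[[1]]
          for (p in sample(L, nmut))
            ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
          rd <- paste(ch, collapse = "")
        }
        if (runif(1) < 0.5) revcomp(rd) else rd
      }
    }, character(1))
    list(db = db, rs = deduplicate(reads))
  })
}

# hand-built asr_table for boundary unit tests: reads_of is a named list of
# read-id vectors; candidate structure and unique counts given directly
manual_asr <- function(reads_of, candidates, unique_counts = NULL, genes = NULL) {
  alleles <- names(reads_of)
  if (is.null(genes))
    genes <- stats::setNames(sub("\\*.*$", "", alleles), alleles)
  rm_dt <- data.table::rbindlist(c(
    list(data.table::data.table(read_id = character(0), allele = character(0),
                                gene = character(0))),
    lapply(alleles, function(a) {
      if (length(reads_of[[a]]) == 0L) return(NULL)
      data.table::data.table(read_id = reads_of[[a]], allele = a,
                             gene = unname(genes[[a]]))
    })))
  if (is.null(unique_counts)) {
    cnt <- rm_dt[, .N, by = read_id]
    uniq <- rm_dt[cnt[N == 1L], on = "read_id"][, .N, by = allele]
    unique_counts <- stats::setNames(integer(length(alleles)), alleles)
    unique_counts[uniq$allele] <- uniq$N
  }
  structure(list(read_map = rm_dt, reads_of = reads_of,
                 unique_counts = unique_counts, candidates = candidates,
                 genes = genes),
            class = "asr_table")
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
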