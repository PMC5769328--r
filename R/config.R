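#' Pipeline configuration
#'
#' Collects every numeric threshold of the allele-calling pipeline in one
#' validated object. Defaults follow the published protocol for 100 bp
#' single-end reads captured over HLA coding regions.
#'
#' @param artificial_read_len length (bp) of the artificial k-mer reads tiled
#'   over large exons in the coverage-filter stage. Default 70.
#' @param large_exon_min minimum exon length (bp) for an exon to count as
#'   "large": such exons must be fully tiled by matched artificial reads and
#'   accept local matches of at least this length. Default 70.
#' @param recip_exon_min minimum exon length (bp) for an exon to participate
#'   in local (reciprocal-screening) mapping at all. Exons shorter than
#'   `large_exon_min` but at least this long must be matched over their full
#'   length. Default 30.
#' @param identity_exon_min minimum exon length (bp) considered by the bait
#'   identity analytics (exons longer than 23 bp). Default 24.
#' @param window_len window size (bp) of the first-base presence scan in the
#'   initial screening stage. Default 22.
#' @param full_read_len read length (bp); end-to-end hits require the whole
#'   read to match contiguously, so this is the minimum contiguous match for
#'   the presence matrix. Default 100.
#' @param asr_fold fold-difference in allele-specific read counts beyond
#'   which the poorer allele of a pair is marked as a potential false
#'   allele. Default 15.
#' @param pool_unique_min minimum database-wide unique mapped reads for an
#'   allele to seed the real allele pool. Default 6.
#' @param max_unexplained_asr maximum number of allele-specific reads that
#'   may remain unexplained for an allele instance to still award a point to
#'   the explaining pair. Default 8.
#' @param null_support_min minimum distinct (deduplicated) reads carrying a
#'   null-allele signature for the null allele to be reported, i.e. "more
#'   than three". Default 4.
#' @param pass_value quality ratio at which a call is marked PASS (top score
#'   divided by number of evaluated pairs). Default 2.
#' @param max_pool_passes maximum reciprocal-screening passes before the
#'   iteration is abandoned and the gene flagged NOT_PASS. Default 5.
#' @param min_complementary minimum contiguous exact complementarity (bp)
#'   assumed sufficient for hybridization capture in the bait saturation
#'   check. Default 20.
#' @param stage1_rule `"gaps"` (default) removes an allele when two adjacent
#'   matched artificial reads are more than `artificial_read_len` apart
#'   inside a large exon (or when an exon has no matched tile at all);
#'   `"coverage"` additionally requires the first and last tile of every
#'   large exon to be matched, i.e. complete coverage by the union of
#'   matched tiles. The stricter rule presumes fragments extending past the
#'   reference ends (as in real captured libraries); with reads drawn from
#'   within the CDS it systematically fails at the CDS extremities, so the
#'   adjacent-distance rule is the default.
#' @return an object of class `pipeline_config` (a validated named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$window_len
#' @export
pipeline_config <- function(artificial_read_len = 70L,
                            large_exon_min = 70L,
                            recip_exon_min = 30L,
                            identity_exon_min = 24L,
                            window_len = 22L,
                            full_read_len = 100L,
                            asr_fold = 15,
                            pool_unique_min = 6L,
                            max_unexplained_asr = 8L,
                            null_support_min = 4L,
                            pass_value = 2,
                            max_pool_passes = 5L,
                            min_complementary = 20L,
                            stage1_rule = c("gaps", "coverage")) {
  stage1_rule <- match.arg(stage1_rule)
  cfg <- list(
    artificial_read_len = as.integer(artificial_read_len),
    large_exon_min = as.integer(large_exon_min),
    recip_exon_min = as.integer(recip_exon_min),
    identity_exon_min = as.integer(identity_exon_min),
    window_len = as.integer(window_len),
    full_read_len = as.integer(full_read_len),
    asr_fold = as.numeric(asr_fold),
    pool_unique_min = as.integer(pool_unique_min),
    max_unexplained_asr = as.integer(max_unexplained_asr),
    null_support_min = as.integer(null_support_min),
    pass_value = as.numeric(pass_value),
    max_pool_passes = as.integer(max_pool_passes),
    min_complementary = as.integer(min_complementary),
    stage1_rule = stage1_rule
  )
  num <- cfg[setdiff(names(cfg), "stage1_rule")]
  if (any(vapply(num, function(x) !is.finite(x) || x <= 0, logical(1))))
    stop("all pipeline_config thresholds must be positive", call. = FALSE)
  if (cfg$artificial_read_len > cfg$full_read_len)
    stop("artificial_read_len must not exceed full_read_len", call. = FALSE)
  if (cfg$window_len >= cfg$full_read_len)
    stop("window_len must be smaller than full_read_len", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, x[[nm]]))
  invisible(x)
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML file carries a flat mapping whose keys mirror the
#' [pipeline_config()] arguments; absent keys keep their defaults.
#'
#' @param path file path.
#' @return `read_pipeline_config()` returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
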