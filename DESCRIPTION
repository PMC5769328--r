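Package: hlatyper
Title: HLA Genotyping from Capture-Enriched Short Reads by Exact-Match
    Candidate Filtration and Reciprocal Pair Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls two-field HLA genotypes from single-end short reads
    captured over the coding regions of highly homologous HLA genes.
    Candidate alleles are filtered by tiling k-mer coverage of large exons
    and by a windowed first-base presence matrix, then genotyped by an
    iterative reciprocal screen that scores allele pairs by how completely
    they (together with a growing pool of alleles believed present)
    explain the allele-specific reads of every candidate pair, with a
    cross-paralog correction for reads bled in from homologous loci and a
    PASS/NOT-PASS quality statistic. Also provides a deterministic toy
    allele-database generator, a diploid read simulator with PCR
    duplicates, bait-design identity and saturation-coverage analytics,
    and null-allele signature checking, so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
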