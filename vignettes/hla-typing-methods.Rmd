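---
title: "Calling HLA genotypes by exact-match filtration and reciprocal pair scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling HLA genotypes by exact-match filtration and reciprocal pair scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlatyper)
library(data.table)
```

## The typing problem and the model

HLA genes carry thousands of documented alleles that differ by a few
substitutions, and several pseudogene loci (H, Y) that are ~95% identical
to HLA-A. A short read captured over the coding region is therefore rarely
informative on its own: it maps exactly to many alleles, often across
genes. The pipeline's premise is that, with hybridization-captured
libraries, base-calling noise is low enough that *exact* matching is the
right primitive — any mismatch between a read and an allele is treated as
evidence that the read did not come from that allele. Every stage below is
defined in terms of exact contiguous matches on either strand, and the
genotype is chosen as the allele pair that, together with credible alleles
of the other genes, explains essentially all allele-specific reads.

All sequences are coding sequences (CDS, concatenated exons): capture
enriches coding regions, and exon structure is carried as 0-based
half-open intervals on the CDS. Ambiguity codes are rejected at load —
exact matching is undefined on `N`, and soft-masking would silently turn
the matching contract into a heuristic.

## Stage 1 — tiling coverage of large exons

Each exon of length $L \ge 70$ bp contributes $L - 69$ artificial 70-mers.
A 70-mer is *matched* when it or its reverse complement appears verbatim
in at least one deduplicated read. An allele is removed when, inside some
large exon, two adjacent matched 70-mers are more than 70 bp apart, or an
exon has no matched 70-mer at all (`stage1_rule = "gaps"`, the default).

A stricter variant (`stage1_rule = "coverage"`) additionally requires the
first and last tiles of every large exon to be matched, i.e. complete
coverage of the exon by the union of matched tiles. We do not default to
it for a structural reason: the terminal 70-mer of the first or last exon
is contained only in reads starting at essentially one CDS position. Real
captured fragments extend past the CDS ends into introns and UTRs, so in
real libraries the stricter rule is benign, but for reads drawn from the
CDS itself (this package's simulator, and any nuc-only reference) the
terminal tile is a coin flip even at high depth. The adjacent-distance
rule retains the intended power — an unmatched *interior* stretch longer
than one tile still removes the allele — without the edge artifact.

## Stage 2 — windowed first-base presence

Whole reads (`full_read_len`, default 100 bp) are exact-mapped end-to-end
against the surviving alleles; only the leftmost CDS position of each hit
is recorded. Per gene, a presence matrix over the positions of the longest
candidate is scanned in non-overlapping 22 bp windows (`window_len`;
the trailing short window is evaluated like any other). An allele is
removed exactly when one of its windows has no first-base hit while
another allele of the same gene has one in the same window; a gene with a
single candidate is left untouched. Positions beyond a shorter allele's
own length are "null" and borrow presence from any other allele of the
gene, so length differences alone never kill an allele.

Two deliberate simplifications: positions correspond across alleles by
raw CDS offset (no multiple alignment — indel-containing alleles may
misregister, which stage 3 re-tests), and windows tile rather than slide,
which keeps the scan linear and makes the removal criterion crisp.

The filter is statistically, not logically, sound: in a window containing
an allele's private variant, presence can only come from that allele's own
reads, and a 22 bp window is empty with probability
$(1 - w/(L - r + 1))^n$ — about $5 \times 10^{-4}$ per window under the
simulation defaults below. Accumulated over windows, alleles and genes
this produces a small per-call false-removal rate (of order 1–2% at depth
30), visible as occasional homozygote collapses in the acceptance run;
deeper sequencing drives it to zero exponentially.

## Stage 3 — the reciprocal screen

Reads are locally mapped against exons of the survivors of all genes
(companion loci included). The local-alignment contract is *maximal exact
shared contiguous substring*: the penalties this formalises make any
mismatch or gap worse than ending the alignment. An exon of 30–69 bp must
be matched over its full length; an exon ≥ 70 bp accepts any shared
substring ≥ 70 bp; exons < 30 bp are ignored. The per-read allele set
from this mapping drives everything that follows.

* **ASRs.** For an unordered candidate pair, a member's allele-specific
  reads are those mapping to it but not to the other member (empty for a
  self-pair). Pairs are enumerated exhaustively, self-pairs included, so
  homozygous genotypes are first-class; exhaustive enumeration is the
  deterministic completion of the random pairing the procedure describes.
* **Exclusion.** An allele is a potential false allele when some partner
  has non-zero ASRs while it has zero, or at least `asr_fold` (15) times
  as many. Marking is simultaneous from the pre-exclusion table — no
  cascade within one application, so the result cannot depend on a sweep
  order. If a gene would lose every candidate, the maximal-total-ASR
  allele(s) are kept with a warning.
* **Pool.** Alleles with at least `pool_unique_min` (6) reads mapping to
  them and to no other allele of any considered gene seed the *real allele
  pool* — the working hypothesis of what is present in the sample.
* **Scoring.** Pair `P` earns a point for each allele-instance (each
  member of each evaluated pair of the gene) whose ASR set has at most
  `max_unexplained_asr` (8) reads not mapping to any allele of `P` or of
  the pool restricted to *other* genes. Scores are recomputed after adding
  each gene's top pair(s) to the pool; within a pass the pool is held fixed
  (so gene order cannot matter) and iteration stops at the first pass whose
  top pairs repeat, or after `max_pool_passes` (5) passes, in which case
  every gene is conservatively flagged `NOT_PASS`.
* **Paralog correction.** For HLA-A (against surviving H and Y alleles)
  and HLA-C (against B): if exactly one member of the final pair has its
  entire within-pair ASR set locally mapping into the companions, that
  member is judged an artifact of cross-gene bleed-through and dropped.
* **Quality.** `quality_value` is the top score divided by the number of
  pairs evaluated in the final pass; `PASS` iff the top score equals
  `pass_value` (2) times the pair count, in exact integer arithmetic. Tied
  top pairs are all reported — that is the ambiguity set, and identical-CDS
  alleles tie exactly by construction.

## Null alleles

Null alleles are invisible to CDS-based typing: they differ from their
parent allele only near intron/exon boundaries. The pipeline accepts a
user-supplied signature table (`trigger_allele`, `null_name`, `signature`)
and, when a trigger allele is reported, counts deduplicated reads
containing a signature as an exact substring on either strand; the null
allele is flagged at `null_support_min` (4, i.e. strictly more than three)
distinct supporting reads. The package does not bundle real signatures —
curated discriminating sequences must be supplied by the user — so
`inst/extdata/` carries a header-only template and a clearly synthetic
demo table.

## Bait-design QC

Long CDS fragments of a single allele act as capture baits for all
alleles of the homologous gene group. Two analytics quantify whether that
works: per-exon *identity* — matched bases in the best global alignment
with unit match score and free mismatches/gaps (equivalently, the longest
common subsequence), divided by the query exon length, for exons ≥ 24 bp,
with exon correspondence by index — and *saturation coverage* — whether
every exon base lies inside some contiguous exact match of at least
`min_complementary` (20) bp between query and bait CDS, the length regime
where hybridization is efficient. Saturation verdicts are monotone
non-increasing in `min_complementary` by construction.

## The simulator and what passing tests mean

`simulate_reads()` draws single-end reads uniformly over each truth
allele's CDS (start positions uniform on $[0, L - r]$), reverse-complements
each with probability 0.5, optionally applies per-base substitution
errors, and appends exact PCR duplicates at a configurable rate. The
standard study conditions used by the test suite and the acceptance
script are: 3 genes × 12 alleles plus one H-like companion of gene A
(ancestors 95% identical), 800 bp CDS, 4 substitutions per allele from
the gene ancestor, 100 bp reads, depth 30 per allele copy, 20% duplicates,
no errors. Depth 30 corresponds to ~240 reads per allele copy — deep
enough that every interior 70-mer of a truth allele is observed, while
remaining small enough that the whole 20-seed study runs in seconds.

What the simulator does *not* emulate: fragments extending beyond the
CDS (hence the stage-1 rule discussion above), indels between alleles,
coverage bias from capture efficiency or GC content, base-calling errors
under the default, and genomic (intron-containing) references. Passing
the recovery tests therefore demonstrates the combinatorial correctness
of the filtration and scoring logic under the stated noise model, not
robustness to real library artifacts. One emergent property is worth
noting: uniform sampling at depth 30 yields ~25–30% first-base coverage
of exon positions, and the recovery tests all pass there — consistent
with first-base coverage being a usable sufficiency statistic for typing.

## Numerical choices and degenerate inputs

* Reads shorter than the relevant threshold, and reads containing `N`,
  simply never match; empty read files yield an untypeable `NOT_PASS`
  report rather than an error.
* Deduplication collapses literal forward-strand sequences, keeping the
  first-seen identifier and the copy count; identifiers never influence
  calls, so read input order cannot either (asserted by test).
* The matching engine is a keyed k-mer table join with seeds merged along
  diagonals into maximal runs; because the seed length equals the
  qualifying threshold, seed-and-merge is exact, and the whole engine is
  checked against offset-by-offset scanning oracles on randomized
  instances.
* Hit positions are reported as the leftmost matched CDS base for both
  strands (SAM convention).
* All thresholds sit at closed boundaries (≥ 6, ≥ 15-fold, ≤ 8, ≥ 4,
  = 2) and each boundary is pinned by a dedicated test.
* Zero evaluated pairs give `quality_value` 0 and `NOT_PASS`; a
  non-converged pool iteration keeps the last pass and forces `NOT_PASS`.

## Known limitations

Raw-offset position correspondence misregisters indel-containing alleles
in stage 2; two-field resolution only (intronic/synonymous fields are out
of scope); the window filter's small false-removal probability at shallow
depth, quantified above; and null-allele detection is only as good as the
signature table supplied.
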