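---
title: "Methods: super-enhancer calling and core regulatory circuitry mapping"
author: "secircuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: super-enhancer calling and core regulatory circuitry mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secircuit)
```

# The analysis

`secircuit` implements a complete two-condition super-enhancer (SE)
analysis: SE calling from H3K27ac enhancer peaks, integration of
differential SE-associated gene sets with RNA-seq differential expression,
prioritisation of the candidate genes, and mapping of the core
transcriptional regulatory circuitry (CRC) formed by self-regulating
transcription factors.  The motivating setting is an intervention study --
an ischemic stroke model condition versus an electroacupuncture-treated
condition -- but every stage is generic over two labelled conditions.

Because every stage consumes standard text formats (narrowPeak/BED,
FASTA, TSV, GMT, JASPAR motifs), the package is equally usable on real
data; the built-in generator exists so that the full pipeline is testable
against planted ground truth with no external downloads.

# Super-enhancer calling

## Stitching

Enhancer peaks within a stitching distance of 12,500 bp are merged
transitively into stitched regions (`stitchEnhancers()`).  Peaks lying
within ±2,500 bp of an annotated transcription start site are omitted
from stitching -- they remain in the analysis as standalone
single-constituent regions, they just never glue two flanking regions
together through a promoter.  Both parameters are exposed
(`stitchDistance`, `tssExclusion`) with the defaults above.

Coordinates are BED-convention 0-based half-open in every file read or
written; internally the package uses `GRanges` (1-based closed), the
Bioconductor norm, with conversion only at the I/O boundary.  Round-trip
tests on boundary intervals pin this down.

## Ranking and the inflection-point cutoff

Each stitched region is scored by its input-subtracted H3K27ac signal:
the sum over constituents of sample minus input signal, clamped at zero
(negative totals are noise).  With scores sorted ascending
$s_1 \le \dots \le s_n$ and both axes scaled to the unit square,
$x_i = (i-1)/(n-1)$, $y_i = (s_i - s_1)/(s_n - s_1)$, the cutoff is

$$ i^{*} = \arg\min_i \; (y_i - x_i), $$

the discrete point where a slope-1 tangent touches the scaled convex
rank curve.  Ties go to the largest index, i.e. the fewest
super-enhancers -- the conservative choice.  Entries scoring strictly
above $s_{i^*}$ are super-enhancers.  For the convex family
$s_i = x_i^k$ the tangent point is $x^{*} = (1/k)^{1/(k-1)}$, and the
discrete cutoff converges to it at rate $2/(n-1)$; the test suite checks
this and exhaustive-argmin equality on random score vectors.  Degenerate
inputs (fewer than 3 regions, constant scores) yield zero
super-enhancers with a warning rather than an error.

## Gene assignment

Each region is linked to the gene minimising the absolute distance from
the region midpoint (`floor((start+end)/2)`) to the TSS, on the same
chromosome; ties go to the smaller TSS coordinate, then the smaller gene
identifier.  The original tooling reports "adjacent genes" without a
metric; midpoint-to-TSS was chosen because it is deterministic and
brute-force checkable.  Whether the upstream tool used nearest-TSS or
nearest-gene-body is unknown, so results near equidistant gene pairs may
differ from it.  The TSS of a minus-strand gene is `txEnd - 1`, the last
transcribed base.

# Differential integration

`diffSEGenes()` computes the gained / lost / shared SE gene sets between
the conditions; `filterDEGs()` splits the DEG table at an adjusted-p
cutoff (default `qMax = 0.05`) with a strict sign rule
(`log2fc > lfcMin`, default 0, so zero fold change lands in neither
direction).  DEG tables in this field often carry two names ("Q" and
"FDR") for the same adjusted quantity; the filter treats them as a
single adjusted-p cutoff with the value exposed in the configuration.  The
DEG table is interpreted as the model-vs-treatment contrast: `up` genes
are up-regulated in the model condition, `down` genes after treatment.
`intersectCandidates()` intersects lost-SE genes with up-in-model genes
(the candidate rule) or gained-SE genes with up-after-treatment genes;
an empty intersection is a legitimate result, not an error.

# Candidate prioritisation

Two independent rankings over the candidate genes are intersected at
depth `k = 3`:

* **Gini importance** (`selectNtree()`, `rankGenesGini()`): a
  random-forest classifier (features = genes, classes = sample groups;
  `floor(sqrt(p))` features per split, unlimited depth -- the
  conventional defaults) is grown to 500 trees; the cumulative
  out-of-bag error for forests of size 1..500 is the error curve, and
  the selected size is the smallest tree count attaining the minimum
  (cheapest adequate forest, deterministic).  Genes are ranked by mean
  decrease in Gini, ties broken lexicographically.  The pipeline grows
  the importance forest with at least 100 trees even when the error
  curve bottoms out earlier: Gini importance from a near-empty forest is
  statistically meaningless, while the error-curve selection itself is
  reported unchanged.
* **Friends ranking** (`friendsRank()`): pairwise gene functional
  similarity using Wang's graph-based term similarity (edge weights 0.8
  for `is_a`, 0.6 for `part_of`, the conventional defaults of this
  measure) combined across term sets by
  best-match average; each gene is scored by its mean similarity to the
  other candidates and ranked descending.

`coreGeneIntersection()` intersects the two top-3 lists; the result may
be empty (reported with a warning).

# Core regulatory circuitry

The five-step CRC procedure (`mapCRC()`):

1. SE-assigned genes are the active gene set; those flagged as
   transcription factors with an available motif are the candidates
   (`identifySETFs()`).  A TF with several SEs keeps all of them and
   pools hits across them.
2. Motifs come from a JASPAR- or MEME-format library
   (`readMotifLibrary()`), pseudocount-regularised (default 0.001).
3. SE constituent sequences are scanned on both strands
   (`scanMotifs()`) at a FIMO-style p-value threshold of $10^{-4}$.
   The score threshold is exact: log2-odds scores are discretised at
   1/1000 log-odds units and the full background score distribution is
   computed by dynamic programming (`pwmThresholdScore()`), so the
   threshold is the smallest discretised score whose tail probability is
   at most the p-value.  `N` bases contribute zero log-odds (the
   background expectation).  The DP equals exhaustive $4^k$ enumeration
   exactly, which the tests assert up to k = 6.
4. A TF whose own SE constituents carry at least 3 instances of its own
   motif is self-regulating (`detectSelfRegulating()`); the same
   instance rule defines directed edges between self-regulating TFs
   (`buildTFGraph()`).  Reported in/out-degrees exclude self-loops
   (which every node has by construction); whether the original figures
   included them is unstated, and the choice is recorded in the output.
5. Fully interconnected circuits -- vertex sets in which every ordered
   pair is an edge -- are the maximal cliques of the bidirectional-edge
   graph, enumerated by recursive Bron-Kerbosch search with pivoting
   (`enumerateCircuits()`), checked against exhaustive subset
   enumeration and against an independent graph library in the tests.
   Circuits are scored by the mean membership frequency of their members
   across all enumerated circuits; the top circuit (ties: larger, then
   lexicographic) is the representative CRC.  The score is a documented
   reconstruction -- the original tool prints circuit scores without a
   formula -- and is labelled as such in the output metadata.

# Over-representation

`oraTest()` is a one-sided hypergeometric upper-tail test per gene set
with Benjamini-Hochberg adjustment across sets.  The raw-p rule
(p <= 0.05) is the default significance flag; the BH flag is emitted
alongside.  The universe defaults to all annotated genes and is
overridable.

# The synthetic study and its planted truth

`simulationConfig()` defines a two-layer synthetic study; one integer
seed fixes every emitted byte (per-stage seeds derive from it via a
stage-name hash, so stages are individually reproducible).

**Genomic layer.**  Four 6-Mb chromosomes of i.i.d. background sequence
(GC 0.5, so PWM p-values under the uniform background are exact), 160
genes on an even grid (at least 30 kb spacing; smaller chromosomes are
an error), 20% flagged as TFs.  Per condition, 500 typical enhancer
peaks and 12 planted SE clusters (2-6 constituents, sub-stitching gaps,
starting 5 kb downstream of the owner TSS; constituents never intersect
a non-owner TSS-exclusion window -- placement is redrawn up to 100 times
before erroring).  Planted constituent signal is the typical median
times `seSignalMultiplier` (default 10); input signal is 10% of sample
signal throughout.

Two deliberate departures from a naive noise model make the planted
truth recoverable *by construction*, which is what the recovery tests
require:

* **Winsorised signal law.**  Typical signal is log-normal(1, 1)
  winsorised at $e^{\mu+\sigma}$ (the ~84th percentile).  A raw
  log-normal tail overlaps the planted scores and -- more fundamentally
  -- the order-statistic spacing near the maximum of any continuous law
  diverges, so the tangent cutoff always admits part of the typical
  tail.  The winsorised law keeps the convex bulk, forms the
  hockey-stick plateau, and separates the planted tail cleanly.
* **Separated typical peaks.**  Typical peaks are placed with at least
  the stitching distance between any two, so each typical region has one
  constituent.  Merged typical pairs would otherwise form a sparse score
  tail above the plateau that the cutoff cannot exclude.  Stitching of
  clustered peaks is exercised separately by the brute-force oracle
  tests on arbitrary random layouts.

**Cohort layer.**  SE-associated gene sets of realistic full-landscape
sizes -- 403 model / 77 treated with 36 shared, hence 367 lost and 41
gained -- and a DEG table with 2,702 up-in-model and 53 up-after-treatment
genes over a 3,200-gene universe, with *exactly* 18 lost-SE genes
up-regulated in the model (the candidate set) and an empty
gained-by-treatment overlap.  The genomic owners are drawn from the
cohort sets so the layers agree.  This mirrors the bookkeeping of a full
ChIP-seq landscape at desk scale: the genomic layer realises a
subsample of the cohort explicitly, which keeps the caller and CRC
stages fast while the integration stages operate at the true set sizes.

**Planted regulatory circuit.**  Four TF genes among the model-only
owners form the clique: each member's SE constituents receive 3 exact
consensus insertions of *every* member's motif (high-information
10-mers, distinct across TFs), so the clique is fully interconnected and
self-regulating by construction.

**Prioritisation truth.**  The expression matrix covers the 18
candidates in three groups (sham, model, treated; 20 samples each); the
key gene's model-group mean is shifted by 3 within-group SDs, and two
designated expression decoys by 2 SDs, so the importance ranking has
deterministic runners-up.  The ontology annotates every candidate with a
subset of the key gene's 12 terms; because the best-match average does
not mathematically guarantee that a superset annotation maximises mean
similarity, the annotation layout is redrawn (seeded substreams, up to
50 draws) until the planted claim -- key gene first, two designated
annotation decoys as runners-up -- holds.  The two decoy pairs are
disjoint, so the top-3 intersection is exactly the key gene.

**Self-audit.**  Before returning, the generator re-verifies every
manifest claim against the emitted objects: set sizes and overlaps,
planted constituent gaps below the stitching distance, exact candidate
arithmetic, presence of the planted motif copies in the emitted
sequence, and the superset annotation.  A failed audit is an error, not
a warning.

**What the generator does not emulate**, and hence what green tests do
*not* show about real data: read-level noise and mappability artifacts,
copy-number effects on H3K27ac signal, realistic motif spacing and
co-occurrence, GC heterogeneity, correlated expression noise, and
ontology structure beyond a small two-root DAG.  Passing recovery tests
demonstrate the algorithms are correct on their stated geometry, not
that the thresholds are optimal for any particular tissue.

# Problem sizes and runtime choices

The test suite and acceptance script run the default study (24 Mb
genome, ~560 peaks per condition, 3,200-gene universe) in seconds per
run; multi-seed recovery tests (20 seeds) skip sequence emission
(`sequenceScope = "none"`) or restrict it to planted constituents
(`"se"`), which changes no coordinates or signals.  Oracle fuzz tests
use 1,000 random instances for stitching/cutoff/set algebra, 200 random
digraphs (<= 12 nodes) for circuit enumeration, exhaustive $4^k$
enumeration (k <= 6) for the PWM DP, and universes up to N = 30 for the
hypergeometric oracle.

# Known limitations

* Nearest-gene assignment is midpoint-to-TSS; tools that use
  gene-body distance can assign differently near equidistant pairs.
* The circuit score is a reconstruction (membership-frequency mean), not
  a verified reimplementation of the original tool's score.
* `enumerateCircuits()` is exact Bron-Kerbosch; dense graphs with many
  hundreds of self-regulating TFs would need the degeneracy-ordered
  variant.
* The exact PWM DP assumes base-independent backgrounds; Markov
  backgrounds are out of scope.
* Friends similarity recomputes term S-values per pair; for thousands of
  candidate genes a memoised implementation would be preferable.
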