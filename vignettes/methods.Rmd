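---
title: "Calling structural variants from optical genome maps of heterogeneous tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling structural variants from optical genome maps of heterogeneous tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omapsv)
```

## The problem

Nano-channel optical genome mapping reads the positions of fluorescent
labels — placed at enzyme recognition sites — along individual DNA molecules
hundreds of kilobases long. A molecule's ordered inter-label distances are a
barcode that can be aligned to the in-silico digest of a reference genome;
distances that disagree with the reference reveal insertions and deletions,
and molecules whose parts align to different places or orientations reveal
inversions, duplications and translocations.

Standard callers for this data type assume a genetically homogeneous sample:
a true variant should be supported by ~100% (homozygous) or ~50%
(heterozygous) of the molecules crossing its locus. Tumor samples violate
this in three ways: non-cancer cells dilute the signal (tumor purity),
sub-clones carry private variants present in only a fraction of the cancer
cells, and copy number changes rescale the expected fraction locally. The
fraction of SV-supporting molecules at a locus is therefore *unknown a
priori* and can easily be 10–15%. This package's two pipelines are designed
around that fact.

## The indel pipeline

Four steps, each operating across molecules rather than within one:

1. **Normalization and arbitration.** Each molecule is compressed or
   stretched by an unknown factor (incomplete linearization in the
   nano-channel). The factor is estimated as the median of per-interval
   observed/expected distance ratios — robust to the minority of intervals
   that carry a real indel — and divided out. An interval is *abnormal* when
   its deviation exceeds `max(abs_threshold_bp, rel_threshold * expected)`;
   both thresholds are needed because absolute sizing noise grows with
   distance (≈ `sizing_sd_per_kb * sqrt(d)`), so a pure ratio test is
   unstable for short intervals and a pure absolute test too lax for long
   ones. Abnormal intervals are then arbitrated across molecules: deviations
   at the same reference interval that agree in sign and magnitude across at
   least `min_support` molecules are indel candidates; an isolated deviation
   among many normal molecules is corrected to the consensus (a sizing
   error); a molecule whose intervals are mostly abnormal in inconsistent
   directions is discarded as mis-aligned. These three outcomes are what
   makes the pipeline robust to the elevated alignment error rate of cancer
   data.

2. **Candidate regions.** Overlapping candidate intervals merge into regions
   (interval union; each candidate pair belongs to exactly one region,
   which also prevents one break point from being called repeatedly from
   different label pairs). Each region's anchors are pulled outward to the
   nearest sites matched by at least `anchor_min_frac` of spanning
   molecules, so molecules that *miss* the labels nearest the break point
   still contribute an anchor-to-anchor distance. All spanning distances are
   pooled per region.

3. **Clustering.** The pooled distances are clustered in one dimension with
   a penalized Gaussian likelihood over k ∈ {1, 2, 3}. Because Gaussian
   clusters on a line are contiguous in sorted order, the search enumerates
   contiguous partitions exactly — no EM, no initialization sensitivity.
   The criterion is `sum_c [-n_c/2 (log(2π σ_c²) + 1)] − k log n` with the
   per-cluster sd floored at `sigma_floor_bp` (150 bp; label localization is
   never better than this, and it prevents degenerate zero-variance
   likelihoods). Accepted partitions must separate adjacent means by
   `min_separation_bp` and give every cluster `min_cluster_size` members;
   infeasible splits are effectively merged. Crucially, **no assumption is
   made about cluster proportions** — a 3-of-20 minority cluster is as
   acceptable as a 10-of-20 one, which is exactly the low-tumor-fraction
   regime.

4. **Typing, merging, scoring.** A cluster whose mean differs from the
   expected inter-anchor distance by `min_indel_size` (2 kb — roughly the
   smallest shift distinguishable from sizing noise at typical inter-anchor
   distances) is a variant allele; larger means insertion, smaller deletion.
   Variant clusters closer together than `min_indel_size` are first
   collapsed: they cannot represent distinct callable alleles, and without
   this guard sizing-noise tail splits inflate multi-allelic labels.
   Zygosity follows cluster structure (variant + reference-like → het;
   single all-molecule variant cluster → hom; a shifted minority cluster
   with no reference companion below `hom_af_threshold` support is labeled
   *unknown*, because tumor mixtures make hom/het inseparable without copy
   number input). The allele fraction is always reported from cluster
   sizes, never inferred from the zygosity label. Same-type calls with
   reciprocal overlap ≥ `merge_overlap_frac` merge, and each call gets a
   logistic confidence over interpretable features (log2 support, allele
   fraction, cluster separation in pooled-sd units, mean alignment
   confidence, relative coverage). The default weights are hand-set so that
   single-molecule calls fall below the report threshold; they can be re-fit
   by ordinary logistic regression on a labeled simulation, which is
   supported but not required.

## The complex-SV pipeline

Molecules (and optionally contigs) with split alignments are decomposed into
query-adjacent junctions. Each junction is classified by chromosome,
orientation pattern and the signed reference/query gap discrepancy:
different chromosomes → inter-chromosomal translocation break point;
orientation flip → inversion break point; reference spans overlapping by
≥ `dup_min_overlap_labels` matched sites → tandem-duplication break point;
re-ordered or wildly discrepant collinear segments → intra-chromosomal
translocation; moderate discrepancies (50 kb–1 Mb) → junction-scale indels,
which are routed to the indel namespace rather than duplicated as complex
calls. For `--` junctions the molecule is read in reverse, so the reference
gap sign is flipped before these rules apply.

Aligners often fail to split-align the second copy of a tandem repeat;
the pipeline therefore re-aligns unaligned molecule parts (≥
`realign_min_labels` labels) into the reference window of the adjacent
aligned segment with a banded dynamic-programming fit aligner. A confident
re-alignment overlapping the adjacent segment's span is duplication
evidence the split alignments missed.

Break points of the same type, locus pair, orientation pattern and segment
sides within `merge_window_bp` are clustered; refined positions are
support-weighted medians. Complementary clusters pair into events: the two
boundary junctions of an inversion (averaging them cancels the one-label-gap
bias each junction carries), and the two junctions flanking a
translocation's insertion point — distinguished from the moved span by the
segment *sides* (segments point inward along the moved span, outward around
the insertion point). An event with all break points present and consistent,
or witnessed end-to-end by full-span molecules, is `complete`; otherwise
`partial`. A tandem duplication creates exactly one novel junction, so its
completeness is decided by full-span evidence alone; its junction also
measures the full unit length (query gap minus reference gap) even where the
unit carries no labels, and that size is centered on the label-covered part
of the unit — the minimax placement, guaranteeing ≥ 50% overlap with the
true unit wherever its unlabeled remainder actually lies. Contigs give
long-range evidence but cancer assemblies carry errors, so an uncorroborated
contig counts as a single witness and caps its call at `partial`; once one
molecule corroborates, the contig weighs `min_bp_support` molecules.

Finally the two pipelines' outputs are unified: an insertion call whose
enclosing region overlaps a duplication of compatible size is *subsumed* —
the duplication is reported, the insertion suppressed with a cross-reference
— so the same event is never reported twice under two types. Gene intervals
(BED) can be attached by half-open interval overlap.

## The simulator

The simulator is label-space only (no sequence): it edits reference label
maps. Its stated world:

* **Clone evolution graph.** Four populations: normal cells (`sample1`,
  germline SVs), trunk cancer cells (`sample2` = sample1 + somatic trunk
  SVs), and two sub-clones (`sample3`, `sample4` = trunk + private SVs; a
  configurable fraction of trunk SVs may be lost, default 0). Mixture
  presets: `sample5` (high tumor content: 30/30/20/20), `sample6` (low tumor
  content, one sub-clone: 70/15/15), `sample7` (low tumor content, two
  sub-clones: 70/10/10/10).
* **Expected support.** For each SV, `f = Σ_c π_c m_c d_c/2 / Σ_c π_c m_c`
  over clones c with mixture fraction π, local copy multiplier m (whole-
  chromosome aneuploidy, default 1) and carrier haplotype count d. A
  support-fraction sweep (`make_support_series`) realizes any target f with
  a two-population mixture of an SV-free clone and a homozygous-variant
  clone.
* **Noise model** (all parametric forms are this package's choices, exposed
  in configuration): per-interval Gaussian sizing error with sd
  `sizing_sd_per_kb * sqrt(d/1 kb)` (default 100 — ~316 bp at 10 kb,
  realistic for the platform); per-label dropout (default 0.1); false labels
  as a Poisson process (default 1/100 kb); per-molecule uniform stretch
  (default [0.95, 1.05]); lognormal molecule lengths (median 200 kb, sdlog
  0.35, minimum 100 kb). Chimeric molecules are off by default (parameter
  exists); reverse-strand reads default off — orientation handling is
  exercised through inverted segments and the format/aligner tests.
* **Truth output.** Every molecule's noise-free correspondence to reference
  sites is emitted as (possibly split) alignments — the "correct alignments"
  control input — along with per-molecule clone/haplotype provenance and a
  truth table with expected support fractions.

Defaults emulate a DLE-1-like chemistry at 16 labels/100 kb on a 10 Mb
(2 × 5 Mb) toy genome; ~10/100 kb emulates Nt.BspQI. Benchmark scenarios use
SV sizes log-uniform in 2–50 kb (complex spans 10–50 kb): an event's anchors
must be spannable by ~200 kb molecules, and events approaching molecule
length induce reference-allele dropout (carriers of a large deletion span
its collapsed junction far more easily than reference molecules span the
full span) — a real effect the expected-fraction formula deliberately
ignores, which is also why the simulator's empirical-support checks use
small events. The generator-level default size range remains 2–200 kb.

### What a green test does and does not establish

The simulator emulates sizing noise, label dropout, false labels, stretch,
mixtures and sub-clones. It does **not** emulate: fragile-site molecule
breakage (beyond the molecule-length parameter), chimeric molecule
formation, locus-specific label efficiency, segmental duplications or other
reference repeat structure that confuses real aligners, or the error modes
of any particular alignment tool (end-to-end tests use the simulator's true
alignments, mirroring the correct-alignments control; the built-in fit
aligner is for windows, not genome-wide seeding). Green acceptance tests
therefore establish correctness of the calling logic under the stated noise
model, not performance on any real instrument run.

## Evaluation

Calls match truth greedily by ascending midpoint distance, one-to-one
(equivalent to optimal assignment on small instances, property-tested).
The rules are symmetric in calls and truth. Indels — label-resolution calls
whose enclosing region is wider than the event — match when either interval
contains the other within `breakpoint_tolerance_bp` slack and sizes agree
within 30% (or 2 kb); span types match by reciprocal overlap ≥ 0.5 (a
per-break-point tolerance would reject correct inversion calls whose
boundaries sit one label gap off); translocations match on both break
points, ignoring span. Precision/recall/F1 report `NA` for empty
denominators, never 0 by convention. Zygosity-aware mode additionally
requires zygosity equality; per-stage stratification splits recall by the
clone in which each SV arose. Acceptance experiments involving complex
calls use a 30 kb break-point tolerance — the 99th-percentile label gap at
16 labels/100 kb, i.e. the coordinate resolution the data actually has —
while the criteria default stays 10 kb.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive bp; arithmetic on doubles; formats print
  one decimal (round-trips are exact to 0.1 bp).
* The in-silico digest places a forward-match label at `start + offset + 1`
  and mirrors reverse-strand matches (`end − offset − 1`); the two strands
  of a palindromic site label ~1 bp apart and are collapsed to their
  midpoint (labels closer than `collapse_bp` = 1.5 bp are optically
  unresolvable).
* The fit aligner breaks ties toward fewer skipped labels, then the
  leftmost reference start; orientation ties prefer `+`. Its scoring
  (quadratic normalized sizing penalty, linear skip penalties) is calibrated
  so a noise-free 5-label sub-map always clears the minimum score while a
  random placement is strongly negative.
* Clustering of identical values returns one floored-sd cluster; regions
  with fewer than `min_coverage` spanning molecules are never called;
  alignments with fewer than 2 intervals pass through normalization flagged,
  with scale 1.
* All randomness is seeded; the same seed yields byte-identical BNX/truth
  outputs. Regions are processed in (chromosome, position) order.
* Per-molecule scale recovery has an information bound of ≈ 0.26% RMS per
  √(Mb of aligned length) at the default sizing noise (the spec'd median
  estimator pays a further 1.25×); tests assert attainment of that bound
  rather than a fixed constant.

## Known limitations

Genome-wide seeded alignment is out of scope (alignments are an input);
break points are label-resolution, not base-resolution; nested events
sharing a break point are reported independently; copy-number gains beyond
whole-chromosome dosage multipliers are not modeled in expected support;
the confidence model's default weights are hand-set, not trained.
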