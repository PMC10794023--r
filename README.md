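# omapsv

Structural variant calling from nano-channel optical genome mapping data of
**heterogeneous tumor samples**, plus the cancer-aware simulator and
benchmarking tools needed to validate it without external data.

## Why

Optical genome mapping images fluorescent labels on megabase-scale DNA
molecules; a molecule's ordered inter-label distances are aligned to the
in-silico digest of a reference, and distances or split alignments that
disagree with the reference reveal structural variants (SVs) far larger than
short reads can resolve. Callers built for germline samples assume each true
SV is supported by ~100% (hom) or ~50% (het) of the molecules at its locus.
Tumor samples break that assumption three ways — non-cancer cell admixture,
sub-clones with private SVs, and copy-number changes — so the supporting
fraction at a locus is unknown a priori and can be 10–15%.

## What it computes

**Indel pipeline** (alignment-based, four steps): per-molecule distance
normalization (median observed/expected ratio, robust to indel intervals);
cross-molecule arbitration of abnormal intervals into *candidate* /
*corrected* / *alignment-discarded*; merging of overlapping candidates into
anchor-flanked regions whose inter-anchor distances are pooled across
molecules (including molecules missing the labels nearest the break point);
exact 1-D penalized-likelihood clustering over k ∈ {1,2,3} of the pooled
distances **with no prior on cluster proportions**:

d_obs clusters at d_ref → no call; at d_ref + s → insertion of size s; at
d_ref − s → deletion; a reference-like plus a variant cluster → het; allele
fraction = variant-cluster size / total, whatever the zygosity.

**Complex-SV pipeline**: split-alignment junction classification
(orientation/chromosome/gap-discrepancy rules → inversion, duplication,
intra/inter-chromosomal translocation break points), targeted DP
re-alignment of unaligned molecule parts to rescue tandem duplications,
contig evidence with corroboration-dependent weighting, and break-point
consolidation into `complete` (all break points found, or full-span
molecules) vs `partial` calls — followed by cross-pipeline deduplication
(e.g. an insertion explained by a tandem duplication is reported once, as
the duplication).

**Simulator**: clone evolution graph (normal → trunk → two sub-clones),
mixture presets (`sample5`/`6`/`7` = high purity / low purity one sub-clone
/ low purity two sub-clones), supporting-fraction sweeps 10–90%,
configurable noise (sizing error ∝ √distance, dropout, false labels,
stretch), ground-truth SVs and true alignments.

**Formats**: BNX (molecules), CMAP (reference/contig maps), XMAP
(alignments) readers/writers; IUPAC-aware two-strand in-silico digestion;
SMAP-like TSV and VCF 4.2 (symbolic ALTs, BND pairs) export.

**Evaluation**: type-aware greedy matching (equivalent to optimal
assignment on small instances), precision/recall/F1 with honest `NA`s,
zygosity-aware mode, per-clone-of-origin stratification.

## Worked example

A 4 Mb toy genome, five homozygous indels private to the tumor clone, 15%
tumor fraction (so each SV is supported by ~15% of molecules), 80×
coverage, default noise:

```r
library(omapsv)
ref <- random_reference_genome(n_chrom = 2, chrom_length_bp = 2e6, seed = 42)
set.seed(43)
svs <- random_sv_set(ref, 5, types = c("insertion", "deletion"),
                     size_range = c(4000, 20000),
                     zygosity_probs = c(het = 0, hom = 1),
                     origin_clone = "sample2")
graph   <- clone_graph(trunk = svs)
mixture <- mixture_spec(c(sample1 = 0.85, sample2 = 0.15))
ds  <- simulate_dataset(ref, graph, mixture, noise_model(), coverage = 80, seed = 44)
res <- call_indels(ds$alignments, ds$molecules, ref)
res$calls
evaluate_calls(res$calls, ds$truth)$overall
```

Output (as printed by the code above):

```
   call_id   sv_type ref_id start_bp end_bp size_bp zygosity allele_fraction support confidence
1: indel_1  deletion   chr1    65036  74863    4789      het            0.22       5       0.96
2: indel_2 insertion   chr1   828100 842757    4799      het            0.15       9       0.99
3: indel_3  deletion   chr2   349057 366576    8971      het            0.12      10       0.99
4: indel_4  deletion   chr2   447901 458294    6025      het            0.12      10       0.99
precision 1.00 recall 0.80 f1 0.89
```

Reading it: `start_bp`–`end_bp` is the anchor-to-anchor *enclosing region*
(label resolution — the event lies inside it), `size_bp` the size estimated
from the variant cluster's mean inter-anchor distance (true sizes here:
4806, 5146, 9041, 6109 bp), and `allele_fraction` the observed supporting
fraction (~0.15 by construction). Zygosity reads `het` because a 15%
cluster alongside a reference-like cluster is what a heterozygous variant
in a 30%-pure tumor looks like — the allele fraction, not the label,
carries the quantitative information. Four of five planted SVs are
recovered with no false calls; the missed one is a 17 kb deletion whose
anchors fewer molecules span.

## Command line

```sh
RS=$(Rscript -e 'cat(system.file("cli", "omapsv.R", package = "omapsv"))')
Rscript $RS simulate --ref-map ref.cmap --scenario sample7.json --seed 7 --out sim/
Rscript $RS call-indel --xmap sim/true_alignments.xmap --bnx sim/molecules.bnx \
        --ref ref.cmap --out calls.tsv --vcf calls.vcf
Rscript $RS call-complex --xmap aln.xmap --bnx mol.bnx --ref ref.cmap \
        --genes genes.bed --out complex.tsv
Rscript $RS evaluate --calls calls.tsv --truth sim/truth.tsv --out metrics.json
```

Configuration files are JSON overrides of `om_config()`.

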