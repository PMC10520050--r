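---
title: "Methods: small RNA classes, ChIP targets and granule volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA classes, ChIP targets and granule volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granulite)
```

# Scope

`granulite` re-implements, as a tested and reusable pipeline, the
computational core of a *C. elegans* germ-granule small RNA analysis:

* rule-based calling of the three germline small RNA classes — piRNAs
  (21U-RNAs), 22G-RNAs and 26G-RNAs — from perfectly aligned,
  multi-mapping short reads, with fractional per-location and
  per-feature count normalization;
* differential 22G-RNA statistics between two genetic backgrounds and
  gene-set fold enrichment with Fisher's exact test;
* periodate-oxidation analysis of 3' 2'-O-methylation status;
* operon-aware promoter derivation and replicate-consistent ChIP-seq
  target calling;
* 3D fluorescence granule segmentation with Li auto-thresholding and
  volume summaries.

Because the real libraries behind such a study are deposit-scale data, a
synthetic-data module generates every input the pipeline consumes — a
small annotated genome, seeded read libraries with ground-truth class
labels, replicate ChIP peak sets, and 3D image stacks of rendered
spheres — so every stage is testable offline against known truth.

# Coordinate conventions

All intervals inside the package are **0-based half-open**. GFF3
(1-based inclusive) is converted at the I/O boundary (`start - 1`,
`end`); BED shares the internal convention and passes through unchanged.
A point query at a feature's `end` coordinate therefore does not hit the
feature. The "5' UTR start" of a gene is the transcription-start side in
genome coordinates: the feature's `start` on the plus strand and its
`end` on the minus strand — the only reading under which "1 kb upstream"
is upstream on both strands. Genes without an annotated 5' UTR fall back
to their 5'-most coordinate rather than being dropped.

# Read processing

Raw reads are collapsed to unique sequences with occurrence counts
(adapter trimming is upstream of this package's scope; reads containing
`N` are dropped with a tally). Collapsed reads are aligned **exactly**
(0 mismatches) on both strands with full multi-mapping up to 1000
locations per read — reads beyond that are discarded entirely, mirroring
a `-v 0 -m 1000 -a` alignment contract. The aligner is built on
`Biostrings::matchPDict` with a trusted-band dictionary; the test suite
holds it to an independent naive both-strand scan on desk-scale genomes.

Structural-RNA reads (tRNA, snRNA, snoRNA, ncRNA) are removed before
classification: a read is structural if *any* of its alignments
intersects a structural feature, on either strand, and all its
alignments move together. The original workflow pre-aligned against a
structural reference before genomic alignment; here the filter is
applied after one genomic alignment pass using the annotation, which
yields the same read-level partition whenever structural loci are
annotated on the genome, with one alignment pass instead of two. Note
that rRNA is *not* part of the structural filter: rRNA loci are eligible
22G-RNA targets with overlap precedence (below).

# Class rules and normalization

The built-in rules (`default_class_rules()`):

* **piRNA** — unique, perfect, sense to a piRNA locus, 5' T, 15–40 nt,
  with the read's 5' end at offset 0, 1 or 2 from the locus 5' end
  (strand-aware: offset 0 is the annotated 5' end).
* **22G** — 21–23 nt, 5' G or A, antisense to protein-coding or
  pseudogene exons, lincRNAs, rRNAs or transposons; multi-mapping
  allowed.
* **26G** — 25–27 nt, 5' G, antisense to protein-coding exons. The 26G
  class is not pinned down as precisely in the literature as the other
  two, so every field of this rule is configurable via `class_rule()`;
  the default matches the class's name (26 nt, 5' G) and its
  spermatogenic protein-coding targets.

Classes are applied in the order piRNA → 22G → 26G; each read takes the
first matching class. The order is essentially benign: piRNA calls
require a unique sense alignment with a 5' T while 22G/26G require G or
A, so the rule sets are disjoint on the 5' base alone.

Weights implement the two normalizations "by locations mapped" and "by
features mapped": a read of count $c$ with $n$ genomic locations
contributes $c/n$ per location, split equally among the distinct
eligible features overlapping that location. At any location where an
rRNA overlaps another eligible feature, the rRNA takes the entire
location weight. Locations overlapping no eligible feature keep their
$c/n$ share under a missing feature id, so the per-read weight total is
always exactly $c$ — a conservation invariant the tests hold to 1e-9
relative error.

Per-gene tables sum weights by feature and class; RPM is
$10^6 \cdot \text{raw} / \text{depth}$ where depth is the number of
reads (with multiplicity) that map to the genome after structural
filtering — "reads mapping to the genome", not weights.

# Differential 22G analysis and enrichment

`differential_22g()` runs a per-gene two-sample two-tailed t-test on
replicate RPM values and computes `log2FC` from condition means with a
0.5-RPM pseudocount (guarding zeros). Genes are called up/down at
`|log2FC| >= log2(fold_threshold)` (default four-fold, matching the
published criterion) and `p < 0.05`, with no multiple-testing adjustment
by default (a Benjamini-Hochberg flag is available). Welch's unequal
variance form is the package default — the safer choice on real data —
but the pooled-variance form is exposed and is the right tool for
calibration work: at $n = 2$ per group Welch's reduced degrees of
freedom make it conservative by construction (its observed null
rejection rate is ~0.02 at nominal 0.05 in the suite's simulations),
whereas the pooled test is exact under the equal-variance normal null
and calibrates to 0.05 on the generator's homoscedastic count model.

`set_enrichment()` computes the percentage-ratio enrichment
$\log_2\!\big(\frac{a/|DE|}{|S \cap U| / |U|}\big)$ for a DE list
against a gene set $S$ over a universe $U$, with a two-sided Fisher's
exact p-value on the 2×2 membership table. The universe is the set of
genes observed in any sample (configurable). The test suite checks
Fisher's p against a brute-force hypergeometric summation to 1e-12.

`median_fold()` and `oxidation_enrichment()` cover the remaining
figure-level statistics: fold of median abundances between matched
locus lists, and the comparison of RPM-normalized class abundances
between an untreated and a periodate-oxidized library. Oxidation blocks
cloning of RNAs lacking 3' 2'-O-methylation; because both libraries are
normalized to their own depths, the methylation-protected class
(piRNAs) gains RPM share after oxidation even though its absolute
counts barely change.

# ChIP target calling

Promoters are the 1 kb window upstream of the 5' UTR start, computed for
protein-coding genes, lincRNAs and pseudogenes, clipped at contig
bounds; every member of an operon receives the promoter of the operon's
first gene. Peaks below the q-value cutoff (default 0.1, applied as a
strict `<`, configurable) are intersected with promoters at ≥ 1 bp
overlap; a gene is a target only when both replicates support it. A peak
spanning two promoters supports both genes. Peak summits are not used —
any overlap counts — since peak regions, not summits, are what the
upstream peak caller exports.

# Granule volumetry

The imaging pipeline mirrors the published order of operations exactly:
background subtraction (mean of a region outside the specimen, clipped
at zero), Li's minimum cross-entropy threshold computed on the **2D
maximum-intensity projection** of each reference nucleus stack, the
**median** of those per-stack thresholds as the consensus, and 3D
segmentation of every stack at that single consensus value.

`li_threshold()` minimizes the cross-entropy criterion
$-(S_0 \log \mu_0 + S_1 \log \mu_1)$ by exhaustive scan over the
observed intensity levels and returns the midpoint of the two levels
straddling the optimal cut; binarization is `>= threshold`. The
exhaustive scan is deterministic and scale-equivariant. Iterative Li
implementations in common imaging tools can settle one intensity level
away on plateaued histograms; the midpoint convention documented here is
the package's fixed tie-break.

Connected components are labeled in 3D with 26-connectivity (the
behavior of the common "3D simple segmentation" tools; 6-connectivity
is available), components smaller than 2 voxels are discarded as shot
noise, and volumes are `voxels × dz·dy·dx` in µm³. Group summaries
report per-group means and pairwise fold changes of means. On noise-free
rendered spheres of radius ≥ 5 voxels the measured volume is within 5%
of $\tfrac{4}{3}\pi r^3$.

# The synthetic-data generator

The generator's defaults are the study conditions the pipeline targets:
two conditions × two replicates, 1e5 reads per replicate, a 200-gene
set whose 22G-RNAs are four-fold depleted in the mutant, and oxidation
survival probabilities of 0.95 (methylated) / 0.05 (unmethylated) — the
published work states no survival rates, so these were fixed once at
values that make methylation enrichment unambiguous at 1e4 reads. The
genome is desk-scale: 3 × 300 kb contigs carrying 500 protein-coding
genes (operons included), 300 piRNA loci, structural RNAs, rRNAs and
transposons, plus two deliberate constructs — an rRNA overlapping a
protein-coding exon (exercising rRNA precedence) and multi-gene operons
(exercising promoter inheritance). The library composition defaults to
25% piRNA, 55% 22G, 5% 26G, 5% structural and 10% background reads,
reflecting the dominance of 22G-RNAs in adult worm small RNA libraries;
background reads from unannotated regions keep the "unassigned" path
exercised.

Abundances follow a per-gene log-normal baseline (sdlog 0.5) shared
across replicates and conditions, with Poisson sampling per replicate.
The published work does not state its replicate dispersion; this
log-normal/Poisson choice is a stand-in that produces realistic
between-gene spread and replicate noise for the t-test, and it is the
one distributional assumption passing tests do *not* validate against
real data. Real libraries add over-dispersion, ligation bias, sequencing
error and 3' length heterogeneity, none of which are modeled
(sequencing-error and adapter models are out of scope by design).

Read templates are drawn from class-specific site pools and then
**verified by exact alignment**: piRNA templates must map uniquely,
antisense templates must not touch structural loci, background templates
must not touch any feature. Ambiguous candidates are discarded, so the
recorded truth labels are unambiguous by construction — which is what
makes the perfect-precision/recall classifier check meaningful as a
correctness test (it validates the rule implementation, not robustness
to ambiguous reads). Identical configurations produce byte-identical
FASTA/GFF/FASTQ/BED outputs.

For ChIP, planted peaks are placed in the part of each target's promoter
not shared with any other promoter, so recovery can be exact; genes
whose promoter has no such segment — notably non-first operon members,
whose promoter is identical to the first gene's — are refused as
planting targets, and `plantable_chip_targets()` lists the usable ones.
Image stacks render spheres at given centers/radii into the voxel grid
(a voxel belongs to a sphere when its center is inside), followed by
optional separable Gaussian blur, Poisson photon noise and a constant
background offset; analytic volumes are recorded as truth.

# Calibration and recovery analyses

Two design points deserve explanation because the naive alternative
fails for structural reasons:

* **Null calibration uses the pooled t-test.** As noted above, Welch at
  $n = 2$ is conservative by construction; calibration of the testing
  machinery is only a meaningful check for a test that is exact under
  the simulated null, which the pooled form is.
* **Recovery analyses detect at 2-fold, not 4-fold.** The generator
  depletes the planted set by exactly four-fold, and a detection
  threshold equal to the true effect size has at most 50% power by
  symmetry — the measured `log2FC` is centered on the boundary (slightly
  inside it, in fact, because depleting one gene set shrinks the mutant
  library depth and RPM normalization pushes measured folds toward
  zero). A recovery analysis therefore calls "down" at 2-fold with
  `p < 0.05`; the package default for biological calls remains 4-fold.
  At the default depth (1e5 reads/replicate, ~110 22G reads per gene)
  this recovers ≥ 90% of the planted 200-gene set with essentially no
  false positives, and the down list's enrichment for the planted set
  exceeds log2 = 1 at Fisher p far below 1e-6.

# Problem sizes

The shipped test suite and the acceptance script run the full study at
its default scale — 4 libraries of 1e5 reads over a 900 kb genome, a
100-run null simulation of 2000 genes, 100 random Fisher tables, and a
40 × 64 × 64 voxel stack per segmentation check — sizes chosen so the
complete analysis reruns from scratch in a few minutes on one CPU while
keeping every statistical check adequately powered.

# Known limitations

* One transcript model per gene; no alternative isoforms or full GFF3
  ontology.
* The aligner is exact-match only (by design: the alignment contract is
  0 mismatches) and desk-scale; it is not a general-purpose short-read
  aligner.
* The 26G default rule is a configurable convention, not a published
  definition.
* piRNA 3'-trimming variants are not modeled; the 5'-offset window
  applies to the 5' end only.
* Oxidation is modeled as pure binomial thinning by methylation status;
  partial oxidation resistance is not represented.
* Granule analysis is single-time-point; coalescence dynamics and
  tracking are out of scope.
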