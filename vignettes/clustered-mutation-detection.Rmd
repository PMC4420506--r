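---
title: "Detecting clustered deaminase mutations with mutclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting clustered deaminase mutations with mutclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutclust)
```

## The problem

AID/APOBEC cytosine deaminases attack single-stranded DNA. When such an
enzyme is expressed in a uracil-glycosylase-deficient (*ung1*) diploid yeast,
every deamination is fixed as a substitution: a cytosine deaminated on the
Watson (reference) strand reads out as C→T, one on the Crick strand as G→A.
Whole-genome sequencing of resistant clones therefore yields hundreds to
thousands of SNVs per ~12 Mb genome, many of them in localized,
strand-coordinated showers — the same phenomenon described as *kataegis* in
tumor genomes. mutclust implements a detector for these clusters, tuned for
the regime where the background mutation density is itself high, together
with the analytics used to characterize them: strand bias, metagene density
profiles around transcription starts, sequence context, rainfall plots, and
an expression–mutation association test.

## The detection cascade

Detection runs per chromosome on a pooled SNV set (clones induced by the same
mutagen are pooled to gain sensitivity; duplicate positions from different
clones are retained).

**Stage 1 — UPGMA and the cophenetic cut.** SNV coordinates are clustered
agglomeratively with average linkage: the distance between clusters $u$ and
$v$ is

$$d(u,v) = \frac{\sum_{i}\sum_{j} d(u_i, v_j)}{|u|\,|v|},$$

and the pair with minimal $d$ is merged at height $d$. On one-dimensional
coordinates the average distance between two non-interleaving clusters equals
the difference of their member means, so clusters are always contiguous along
the chromosome and `upgma_linkage()` needs only adjacent-pair comparisons —
no distance matrix, $O(n^2)$ time, deterministic leftmost tie-breaking. Flat
clusters are extracted with a *distance criterion*: the tree is cut at a
cophenetic threshold $t$ (default 1000 bp), i.e. every maximal subtree whose
root merge height is at most $t$ becomes a cluster, so all within-cluster
pairs have cophenetic distance ≤ $t$. The default was chosen where the count
of ≥3-member clusters plateaus in a 50–5000 bp threshold sweep
(`threshold_sweep()`); 1000 bp is *not* a cap on cluster length.

**Stage 2 — inconsistency refinement.** Each extracted cluster is
re-clustered from scratch and subclusters are taken to adjust borders, using
the inconsistency coefficient at threshold 0.8 and depth 2. For depth $d$,
a link of height $h$ is compared against the set $H$ containing the link
itself and its descendant links fewer than $d$ levels below (leaves
contribute nothing): the coefficient is $(h - \bar H)/\mathrm{sd}(H)$ with
the *sample* standard deviation, and 0 when $H$ has no spread. A subtree is
kept whole only if every link inside it has coefficient ≤ 0.8; otherwise it
is broken at its root, recursively. These are exactly the semantics of the
standard hierarchical-clustering toolkits; the implementation is validated
link-for-link against frozen reference values
(`tests/testthat/fixtures/hier_oracle.json`).

**Stage 3 — filtering.** (a) Clusters with one or more SNV in a masked
(repeat/low-confidence) region are removed. (b) In deaminase mode, clusters
with more than one distinct non-deaminase-like variant (neither C→T nor G→A)
are removed as likely call errors; if the single such variant is carried by
one sample only, the SNV is deleted and the cluster kept, while the same
variant recurring in several samples removes the cluster. (c) Statistics are
recomputed, and clusters are retained when size ≥ 5 **and** power ≥ 0.05,
both inclusive. (d) The SNVs of every cluster surviving (a)–(b) are restored
per sample.

### Cluster statistics

* **Power** = size / median inter-SNV distance (bp⁻¹). The median is taken
  over *consecutive* gaps after sorting by position; an all-pairs variant is
  available (`gaps = "allpairs"`). The consecutive form is the default
  because consecutive distances are the quantity the rainfall analysis
  plots; nothing in the definition forces one reading, so both ship.
  Degenerate cases: a singleton gets denominator 1; a zero median (duplicate
  pooled positions) is clamped to 1 bp so the filter stays meaningful.
* **Homogeneity** = majority fraction among the cluster's C→T/G→A members,
  in [0.5, 1]: 1 means a fully strand-polar cluster (one exposed strand),
  0.5 an even mix. OTHER-class members are excluded — after deaminase-mode
  filtering at most one can remain, and excluding it keeps the range exact.

## Strand and feature analytics

A C→T call places the deaminated C on the Watson strand, a G→A call on the
Crick strand; combined with the gene's orientation this labels each genic
deamination as *transcribed*- or *non-transcribed*-strand
(`assign_deaminated_strand()`). The 2×2 table of class × gene strand per
feature category gives the phi coefficient; phi > 0 means C→T mutations
preferentially hit genes on the Watson strand, i.e. deamination of the
non-transcribed strand. The p-value uses the 1-df chi-square test without
continuity correction, falling back to Fisher's exact test when any expected
cell is below 5 (the source analyses report phi with a p-value without
naming the test; this pairing is the common default).

Feature categories are assigned with a fixed priority CDS > 5'-UTR > 3'-UTR
> ncRNA > intergenic so every SNV gets exactly one label. Metagene density
profiles count, for each gene, SNVs at gene-relative offsets (mirrored for
Crick-strand genes) in half-open 5 bp bins, and normalize by the *total* SNV
count of the analyzed set — not by the window total — so values are
"fraction of all mutations in this bin". A consequence, accepted
deliberately, is that an SNV upstream of two divergent genes contributes to
both windows. The transcription-start tri-panel restricts to genes with an
annotated 5'-UTR of ≥ 10 bp, maps the UTR panel to percent-of-UTR-length
bins (10%), and drops SNVs overlapping a different gene's body from the
pre-UTR and UTR panels so those panels carry only unambiguous signal.

Sequence context (`context_matrix()`) reverse-complements G→A windows onto
the deaminated C and divides per-offset base frequencies by a background
with GC fraction 0.38 (the yeast genome), renormalizing per offset; at GC =
0.5 the correction is the identity. The half-width defaults to 3 (a 7-mer),
which covers the recognition motifs of the common deaminases; it is
configurable.

## The synthetic world

`simulate_dataset()` generates everything the pipeline consumes, with ground
truth. Defaults, chosen once as a realistic desk-scale version of a heavily
mutagenized yeast genome and not revisited:

* 1 chromosome × 1 Mb at GC 0.38; 300 protein-coding genes (CDS 300–1500 bp,
  5'-UTR 20–200 bp, 3'-UTR 50–200 bp, random strand) plus 10 ncRNAs, placed
  without overlap with random intergenic gaps; 2% of the genome masked, with
  masks kept ≥ 300 bp from gene bodies (repeats are mostly intergenic, and
  the planted TSS-proximal clusters must not be silently mask-filtered).
* log-normal FPKM (meanlog 4, sdlog 1; median ≈ 55, matching the scale of
  the real expression medians).
* 20 planted clusters of 5–15 SNVs within 100–500 bp spans, anchored on
  FPKM-weighted genes with centers uniform in the −100..0 bp window before
  the CDS start; members are placed uniformly on strand-appropriate C sites
  (a C→T needs a reference C, a G→A a reference G), with probability
  p_nt = 0.8 of hitting the non-transcribed strand.
* background 2×10⁻⁴ SNVs per unmasked bp (≈ 200 per Mb, inside the real
  per-genome density range) at deamination-eligible sites, 2% of it
  non-deaminase-like; records spread over 4 clones.
* `sub1_mode` emulates loss of the Sub1 ssDNA-binding factor: half the
  clusters move to a −250..−100 bp promoter window, the strand bias is
  suppressed (p_nt → 0.5), and CDS background is halved.

The generator reproduces the statistical *structure* the analyses assume —
peaked TSS-proximal density, strand coordination, expression coupling — but
not replication timing, chromatin, motif preferences beyond the central C,
or diploid genotype structure. A green synthetic test therefore establishes
that the implementation measures what it claims on data with known truth,
not that the biological effect sizes are realistic.

## Numerical and design choices

* Coordinates are 1-based inclusive internally (VCF/GFF3 convention); BED
  conversion happens only at the file boundary.
* UPGMA ties merge the leftmost pair; flat clusters at the default threshold
  are insensitive to this, which the brute-force oracle suite verifies.
* Threshold comparisons are plain `<=` on double arithmetic; heights are
  means of integer coordinates and the oracle uses the same rule.
* The threshold sweep counts *unrefined* flat clusters, matching the way the
  operating point was chosen.
* Refinement re-clusters members from scratch rather than reusing the global
  subtree, since pooled neighbours can change local tree shape.
* The single-OTHER rescue counts *distinct variants*: one substitution seen
  in several samples is one SNV (recurring ones remove the cluster, as
  recurrence suggests a systematic artifact).

## Known limitations

The border-refinement stage is faithful to its published parameters
(threshold 0.8, depth 2), and that faithfulness has a measurable cost: for a
cluster whose members are placed by anything like a Poisson process, the
merge tree is balanced near the root, balanced links have inconsistency
≈ 1.15 > 0.8 under the standard definition, and the stage fragments the
cluster into caterpillar-shaped runs. The statistic is scale-invariant, so
density does not protect a cluster; in the default synthetic world the full
pipeline recovers only ~7% of planted clusters (precision ~0.5), while the
same pipeline with `refine = FALSE` recovers essentially all of them — and
that contrast is itself asserted in the test suite. On real pooled data the
published method reports many ≥5-SNV clusters, which is consistent with the
surviving fragments being the dense, duplicate-rich cores of larger mutation
showers rather than whole showers. Users who want whole-shower recovery
should run `detect_clusters(..., refine = FALSE)` or raise the inconsistency
threshold above ~1.16 (the depth-2 maximum), which disables splitting
entirely.

Other limitations: the detector assumes single-nucleotide substitutions
(indels are skipped at parse time); chromosome name matching is exact; and
the phi analysis discards positions covered by genes on both strands, so
densely overlapping annotations lose power.
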