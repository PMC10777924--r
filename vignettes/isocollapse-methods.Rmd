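---
title: "Methods: full-length transcriptome collapse, classification and DE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: full-length transcriptome collapse, classification and DE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isocollapse)
```

## Scope and model

The package implements the coordinate-level analysis of a hybrid
(long + short read) transcriptome experiment. Its unit of data is the
*exon chain*: a sorted list of disjoint `[start, end)` intervals on one
chromosome and strand (0-based half-open internally; GTF/BED emit the
standard 1-based dialects at I/O only). Reference isoforms, aligned FLNC
read blocks and collapsed isoforms all share this representation, so the
same junction arithmetic (donors = intron 5′ sides, acceptors = intron 3′
sides, strand-aware) serves every stage.

Nucleotide sequence is deliberately out of scope: hybrid correction and
alignment are upstream tools whose *outputs* — per-read percent identities
and alignment coordinates — are the package's inputs.

## Stage rules

**PID merge.** Each read carries `pid_pre` and `pid_post` (either may be
missing = unmapped in that library). The merged library keeps the higher
PID; ties keep the post-correction version, because short-read-corrected
bases have higher per-base accuracy. Reads mapped in one library only are
merged from that side and reported in the `only_*` categories with the mean
PID of the available side; reads mapped in neither are excluded with a
warning and counted separately. The mapping report classifies the merged
library as unmapped / multiply-best-mapped / low-PID / high-quality over an
*explicit* denominator field, because published four-way tables of this kind
do not always state whether their denominator is the poly(A) total or the
per-library mapped total — making it a report field avoids guessing.

**Same-locus relation.** Two aligned transcripts share a locus iff they have
the same direction, their spans overlap by more than 20 % *of the shorter
span*, and some exon pair overlaps by more than 20 % *of the shorter exon*.
The shorter-feature denominator is a symmetric reading of "20 % overlapping
sequences" and is the common convention when the source of the rule does not
name a denominator. The relation is not transitive, so loci are defined as
its connected components (single-linkage closure) — the only definition that
yields a partition, which downstream accounting (support conservation,
category partitions) requires.

**Collapse and filters.** Within a locus, multi-exon reads with identical
internal junction chains merge into one isoform spanning the widest observed
5′/3′ ends; single-exon reads merge by span containment. Junction equality
is exact (0 bp wobble) by default; long-read aligners can slip a few bases
at junctions, so the simulation keeps junctions exact and a wobble tolerance
is left as future work rather than silently enabled. Redundancy then absorbs
any isoform whose chain is a contiguous 5′-truncated sub-chain of another
(the signature of 5′ RNA degradation; a junction-free remnant must sit
inside the absorber's 3′-terminal exon), *adding* its support to the
absorbing isoform so that the subsequent support-based filter is
order-independent. Finally an isoform is retained iff it has ≥2 FLNC reads,
or every junction of its single-read chain is present in the annotation or
the short-read junction evidence. Filters run redundancy → false-positive;
running them in the other order would discard degraded reads before their
support could rescue the parent isoform.

**Classification.** A multi-exon isoform is *full-length* iff the complete
donor-site set of some annotated isoform (same chromosome/strand) is a
subset of the isoform's donors; this is the strict reading of "covering the
splicing donor sites", and a relaxed any-shared-donor mode is available
(`mode = "any"`) for sensitivity analysis. A locus is a *novel gene* iff its
best same-strand span overlap with an annotated gene is below 20 % of the
shorter span (intergenic or antisense-only). An isoform in a known locus is
a *novel isoform* iff any splice-site coordinate is unannotated. Structural
categories are checked A→G, first match wins:

| category | rule |
|---|---|
| A | junction chain identical to a reference isoform |
| B | proper contiguous sub-chain of a reference chain |
| C | strictly contains a complete reference chain |
| D | shares ≥1 junction, neither sub- nor super-chain |
| E | same-strand exonic overlap, zero shared junctions |
| F | novel locus (intergenic / antisense) |
| G | inside a gene span, no exonic overlap (e.g. intronic) |

A and F/G follow their published definitions; B–E are a deterministic
refinement of the middle ground ("diverse exon and intron arrangements"),
ordered by specificity. Single-exon isoforms have no chains; they are called
A when they reciprocally overlap a single-exon reference isoform by ≥50 %,
otherwise fall through to E/F/G. Length-bin reports use the exonic length of
the longest isoform per locus (`[0,1k) [1k,2k) [2k,3k) [3k,∞)`); genomic
span is the plausible alternative, but exonic length matches the
transcript-length framing of isoform length distributions.

**AS events.** Isoform pairs are compared inside their common genomic span.
Splice sites shared by both chains (same coordinate and donor/acceptor role)
are anchors; each maximal differing segment between anchors (or the common
span edges) is one event. Patterns type the event: an exonic island in one
chain only = ES, a single intron opposite uninterrupted exon = IR, one
differing donor per chain = AD, one differing acceptor = AA, two disjoint
alternative internal exons with shared outer flanks = MEE, anything else =
`complex`. The sixth class exists because published event totals are larger
than the sum of the five named types; `complex` holds the remainder and
percentages are reported over all six. Multi-intron retention inside one
segment is deliberately `complex`, keeping one event per segment and exact
agreement with the brute-force enumerator used in the tests. Differences
touching the transcript termini (degraded 5′ ends, APA 3′ ends) are never AS
events because they are not flanked by anchors on both sides.

**APA.** Poly(A) sites are physically 3′ features, so the package clusters
strand-aware 3′ terminal coordinates of the reads assigned to a gene
(single-linkage, window 24 bp — a common poly(A) microheterogeneity scale),
discards clusters with fewer than 2 supporting reads, and flags a gene as
APA iff ≥2 sites survive. The upstream description of this step names the 5′
end; that is taken as a slip for 3′ and recorded here rather than silently
assumed.

**Fusions.** A chimeric read (two alignment blocks, 5′/3′ in read order)
calls a fusion when each block overlaps a distinct gene by ≥50 % of the
block span; the call is interchromosomal iff the partners sit on different
chromosomes. Intrachromosomal candidates whose partner spans are separated
by <10 kb are dropped as likely read-through artifacts; the guard is
`min_gap` and can be set to 0 (the recovery tests do, because the simulated
intergenic gaps are 5–20 kb).

**Expression and DE.** FPKM is `counts·10⁹ / (length · library size)`; gene
counts are the sum of member transcripts and gene lengths are union-exon
lengths. "Highly expressed" is strictly FPKM > 60; "commonly expressed" in a
tissue means FPKM > 0 in every replicate. The DE test is DESeq2-equivalent
in design, not bit-identical: median-of-ratios size factors (medians taken
on the log scale, matching DESeq2), pooled method-of-moments dispersions
`α̂ = (v − μ)/μ²` shrunk 60 % toward a parametric trend `α = a₀ + a₁/μ`
fitted by least squares, and a Wald test on
`log2((μ_B + 0.5)/(μ_A + 0.5))` with a delta-method standard error;
Benjamini–Hochberg adjustment across rows; calls at |log2FC| > 1 and
adjusted p < 0.05. The 0.5 pseudocount keeps zero-vs-positive rows finite;
all-zero rows get p = 1 and log2FC = 0 by convention. Full empirical-Bayes
dispersion machinery is out of scope — the moment/trend scheme is the
smallest one that keeps 4-vs-4 inference calibrated, and the tests verify
type-I error in [0.03, 0.07] at nominal 0.05 and ≥70 % power with ≤10 %
empirical FDR at planted |log2FC| = 2.

## Synthetic data: what it emulates, and what a green test proves

`simulate_annotation()` lays non-overlapping genes with exon scaffolds
(exons 100–500 bp, introns 300–3000 bp, intergenic gaps 5–20 kb); isoforms
are scaffold-exon subsets that always keep the terminal exons, so a gene's
isoforms always satisfy the same-locus relation. `simulate_flnc()` draws one
phenomenon per read — the truth labels partition the reads:

| phenomenon | construction |
|---|---|
| `full_length` | exact copy of the source chain |
| `degraded_5prime` | drop 0+ 5′ exons, trim into the new 5′ exon (strand-aware) |
| `novel_isoform` | one acceptor shifted 12 bp into its intron; one variant per isoform so novel reads can support each other |
| `novel_gene` | read from a planted intergenic 3-exon model |
| `apa_shifted` | 3′ terminal coordinate moved to a planted site (+200 bp steps) |
| `fusion` | 5′ half of one isoform + 3′ half of another gene's isoform, two blocks |

PID pairs are truncated normals clipped to [50, 100] (defaults mean 99.0
pre, 99.1 post, sd 0.8, half the reads unchanged by correction) with small
unmapped fractions populating the only-pre/only-post categories. Counts are
NB with gamma baselines, per-sample depth factors in [0.7, 1.4], and a
fraction of transcripts multiplied by `2^±lfc` in one tissue; the default
design is 3 tissues × 4 replicates. No degradation-rate measurement exists
to calibrate against, so the default `p_degraded = 0.15` and the other
phenomenon probabilities are package choices exposed as configuration, not
estimates.

The generator is *exact*: junctions never slip, PIDs are independent of the
exon chain, and every read is a coordinate-level edit of an annotated model.
A green recovery test therefore establishes that the rules are implemented
as stated — not that they are robust to alignment wobble, base errors,
internal priming, or expression-dependent coverage, none of which are
modelled. Conversely, the planted-truth tests are strict: with degradation
up to 0.5 the retained chain set must *equal* the source set, fusion recall
must be 1.0 with zero false calls, and detected APA sites must equal the
≥2-read end coordinates.

## Numerical choices

* Percentages print at 2 decimals with round-half-even (`ratio()`); every
  report percentage is recomputed from its own count pair.
* Seeds: one global integer; sub-generators derive child seeds
  deterministically (kept below 2³¹), so stages are reproducible in
  isolation and the whole pipeline is byte-stable for a fixed seed.
* Dispersion moment estimates are floored at 10⁻⁸; trend coefficients are
  clamped non-negative with a median fallback for tiny inputs.
* Ties: post-correction wins PID ties; redundancy absorbs into the candidate
  with most junctions, then most support, then lexicographic id; APA cluster
  representatives are the modal coordinate (smallest on ties).
* Degenerate inputs: empty annotations/loci/reads yield empty, typed
  outputs; zero library sizes, non-positive lengths, invalid thresholds and
  all-zero size-factor references raise errors rather than propagate NaN.

## Limitations

* No base-level simulation or alignment; results say nothing about aligner
  artifacts.
* The B–E category refinement and the `complex` AS class are package
  interpretations where the field's published descriptions are coarse.
* `nb_test()` trades DESeq2's empirical-Bayes shrinkage for a two-parameter
  trend; at very small replicate counts (<3) it will be anti-conservative.
* Single-exon isoform identity (category A) uses a 50 % reciprocal-overlap
  heuristic; there is no junction evidence to do better.
* Published dataset-scale counts (e.g. total isoform or DEG numbers from a
  specific sheep adipose experiment) depend on undeposited raw reads and are
  not reproduction targets; only printed ratio arithmetic and planted-truth
  recovery are.
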