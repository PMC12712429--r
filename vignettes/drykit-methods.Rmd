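---
title: "Methods: k-mer sexing, window statistics, Mapper, CRE enrichment and peptide features"
author: "drykit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-mer sexing, window statistics, Mapper, CRE enrichment and peptide features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drykit)
```

`drykit` packages the analysis layer of a field study of a dioecious
resurrection plant: inferring the sex-chromosome system and localizing
the sex-determining region (SDR) from sexed whole-genome k-mer sets,
describing genome organization with sliding-window statistics,
summarizing a dehydration–rehydration expression time course, building a
Mapper topological graph of samples under a relative-water-content lens,
testing promoter cis-regulatory elements (CREs) for enrichment, and
profiling LEA/ELIP peptide chemistry. This vignette records the models,
the tunable parameters, and the design decisions taken where the
methodology was genuinely open.

## K-mer sexing

K-mers are counted canonically: every A/C/G/T window of length `k`
(default 21) is replaced by the lexicographic minimum of itself and its
reverse complement, making sets strand-independent; windows containing
any other symbol are skipped. `k` must be odd in canonical mode because
an even-length palindrome equals its own reverse complement. Internally
words are 2-bit encoded into doubles (exact for `k <= 26`), which keeps
a 4-Mb diploid genome's set in a sorted numeric vector and makes the
meryl-style algebra (merge-based intersection, union, difference) fast
and deterministic.

Sex-specific sets are defined as the intersection across all samples of
one sex minus the union of the other sex. The intersection-minus-union
reading is deliberately conservative: requiring presence in *every*
male protects against individual-specific variants, and subtracting the
female *union* protects against per-sample dropout in the subtrahend. A
`minuend = "union"` flag provides the permissive alternative, since the
operand order of the original two-step intersect/difference recipe is
ambiguous.

The heterogamety call compares the two set sizes: ratio ≥ τ calls XY,
ratio ≤ 1/τ calls ZW, anything between (or two empty sets) is
undetermined. τ defaults to 2 — observed male:female excesses in real
XY cohorts are around 4, so 2 sits midway between that and the null of
1 while remaining configurable. A zero female-specific count with a
positive male count yields ratio ∞ and an XY call.

Y-mers are localized by exact canonical matching against the assembly's
k-mer stream (a hit at position *p* means window `[p, p + k)`
canonicalizes to a query word). Exact matching replaces permissive
read-mapping deliberately: it is deterministic, oracle-checkable, and at
k = 21 the expected number of chance hits is negligible. Window counts
use 0-based half-open windows starting at 0 and advancing by `step`,
plus one final truncated window when the grid falls short of the
chromosome end. SDR calls take the genome-wide mean window value as
background, flag windows at ≥ `min_fold` × background, and merge runs of
at least `min_run` consecutive flagged windows; calls are ranked by fold
over background. The `sdr_scan()` preset uses nonoverlapping 20-kb
windows: the merged interval's boundary error is on the order of one
window width, so 20-kb windows keep a few-hundred-kb SDR representable
at interval Jaccard ≥ 0.9 while remaining cheap on Mb-scale toy
chromosomes (genome-scale work can pass the 2.5-Mb/100-kb or 250-kb
figure-style geometries instead).

## Genome architecture windows

Feature coverage is fraction-of-bases: the union of the selected
intervals intersected with each window, divided by the actual window
length (the final truncated window is normalized by its own length so
short chromosomes remain representable). Union-not-sum matters when
annotations overlap. Density dispersion is the *sample* (n−1) standard
deviation of coverage across nonoverlapping windows, reported in
percent; population vs sample is not dictated by the quantity's usual
presentation, and the sample form was chosen as the conventional
estimator. Telomeric ends are flagged when ≥ `min_copies` (default 3)
tandem copies of the telomere unit occur wholly within the terminal
`terminal_window` bases (default 1000): the motif itself at the 3' end,
its reverse complement at the 5' end. Both defaults are conventions, not
published values, and are exposed as arguments.

## Hydration bookkeeping and DAT summarization

RWC = (fresh − dry)/(turgid − dry); field samples may mildly exceed 1.
Drying groups come from each plant's minimum RWC: below 0.10
desiccation, 0.10–0.30 severe, above 0.30 mild. Observed cohorts leave a
gap between ~30% and ~60% minimum RWC; the classifier closes it at 0.30
so that it is total, and the thresholds are configurable.

DAT calls use strict gates: Up means log2FC > 2 *and* adjusted p < 0.05,
Down symmetrically. When only raw p-values are supplied, Bonferroni
correction is applied per comparison (m = genes in that comparison); a
`m_scope = "global"` flag switches to genes × comparisons. Nonredundant
phase lists collect genes significant in at least one comparison; a gene
Up at one time point and Down at another stays in both lists with a
bidirectional flag, since collapsing it either way would discard signal.
Venn decompositions and alluvial transition matrices are plain set/count
arithmetic with conservation checks (region counts sum to the union;
transition matrices reproduce the per-timepoint marginals).

The package consumes any per-comparison statistics table, preserving the
study design in which differential testing is done by a dedicated
count-model package. For self-contained testing, `welch_de_stats()`
provides an explicit stand-in: a vectorized Welch t-test on
log2(TPM + 1) per gene per time point against baseline.

## Mapper under an RWC lens

The cover is uniform: interval length L = range/(n − (n − 1)·ω) with
overlap fraction ω, each interval starting L(1 − ω) after the previous,
the last endpoint clamped to the lens maximum; no lens value is covered
by more than ⌈1/(1 − ω)⌉ intervals. Defaults are n = 110 intervals at
ω = 0.90, the published graph geometry for this kind of time course.

The per-interval clusterer — unspecified in the original analyses — is
the classic Mapper recipe: single linkage, then a histogram of the
dendrogram merge heights in `gap_bins = 10` equal bins over
`[0, max(height)]`, cut at the left edge of the first empty bin that
*follows* an occupied one. Two refinements make the heuristic honest on
degenerate inputs: zero merge heights (coincident points) are excluded
from the histogram, because any cutoff merges them and they would
otherwise fake a gap — this also makes the graph invariant under sample
duplication; and requiring the gap to follow an occupied bin prevents a
spurious cut at zero when all heights are large and similar (all
pairwise distances equal thus collapse to one cluster). A
`fallback_epsilon` fixed cut is available. Distances are Euclidean on
per-gene standardized log2(TPM + 1) by default (`transform = "none"`
opts out); preprocessing is a documented choice, not a published one.
Ties are broken by ascending sample id, so graphs are deterministic.

Nodes record members, interval index, mean lens and the majority group
label; edges connect nodes sharing at least one sample, weighted by the
shared count. `pca_scores()` wraps `prcomp` with samples as
observations, returning nonincreasing variance fractions.

## CRE enrichment

Promoters are the `upstream` bases (default 1000) immediately 5' of the
gene start on the plus strand, or the reverse complement of the bases
immediately 3' of the gene end on the minus strand, truncated — never
padded — at contig boundaries, with the truncation flagged. Scanning
treats IUPAC degeneracy as base-class containment and checks both
strands by default (promoter motif databases are strandless in
practice); a flag restricts to the forward strand.

Enrichment fits group (up = 1) ~ presence by binomial IRLS on the
aggregated 2×2 data. For a binary predictor this is saturated, so the
estimate equals the closed-form odds ratio (a·d)/(b·c) with Wald SE
√(1/a + 1/b + 1/c + 1/d) — an identity the tests verify exhaustively
over all tables with cells ≤ 30. Zero cells make the MLE diverge; those
tables get the Haldane–Anscombe +0.5 correction and a separation flag.
Raw p < 0.05 is the significance convention for this analysis;
`adjust = "BH"` appends a Benjamini–Hochberg column for users who want
familywise control. Presence/absence (not occurrence counts) is used,
matching the binary-matrix design.

## Peptide features

GRAVY is the mean Kyte–Doolittle hydropathy; molecular weight sums
average residue masses plus one water (18.015 Da); net charge is the
Henderson–Hasselbalch sum over the N-terminus, K, R, H (positive) and
the C-terminus, D, E, C, Y (negative) with a fixed pKa table, termini
always included and no cystine handling. The disorder call is a
charge–hydropathy score: h_norm − (⟨|q|⟩ + 1.151)/2.785, where h_norm is
the mean normalized hydropathy (KD + 4.5)/9 and ⟨|q|⟩ the mean absolute
net charge per residue at pH 7; strictly negative scores are predicted
disordered. This transparent composition-based proxy stands in for
machine-learned disorder predictors, which are proprietary; it is named
`ch_score` throughout so external per-peptide disorder estimates can be
substituted as a column. Because h_norm is affine in GRAVY, the proxy
reproduces the expected hydropathy–disorder anticorrelation in sign on
synthetic classes; its magnitude on real LEA sets depends on the data
and is not asserted. Charge-at-pH-7 is reported as "charge" (with pI as
a utility), the more informative of the two conventional outputs.

## Synthetic-data generators

The generators define the conditions under which the pipeline is
validated; they are first-class, tested code.

**Sexed genomes.** One X reference chromosome per cohort (plus optional
autosomes); the Y is the X with a contiguous SDR *replaced* by novel
sequence — replacement rather than insertion keeps X and Y the same
length so window coordinates are comparable between haplotypes. Each
haplotype of each diploid individual differs from its reference by
i.i.d. substitutions at `snp_rate` (default 0.004738 per base, the
~47 SNPs/10 kb density of a highly heterozygous outcrosser). Defaults
are 5 males and 5 females and a 700-kb SDR; the validation runs use a
2-Mb chromosome with a 200-kb SDR so that twenty cohorts fit in minutes.
At this SNP rate a 21-mer survives all five male intersections with
probability ≈ 0.905⁵ ≈ 0.61, so ~120k of the ~200k SDR k-mers remain
male-specific — ample signal for both the system call and localization.
Alphabets are uppercase ACGT only; N-handling is exercised by
hand-written fixtures instead.

**Time course.** 12 plants × 13 time points (one baseline, six
dehydration, six rehydration). RWC follows a piecewise-linear decline
from 0.95 to a plant-specific minimum at the last dehydration point,
then linear recovery to baseline over the first two-thirds of the
rehydration points — the simplest shape with the right qualitative
structure; the recovery slope is a free parameter, not a claim about the
plant. Per-plant minima are drawn uniformly within each group's bin
(mild 0.60–0.80, severe 0.12–0.28, desiccation 0.03–0.08), four plants
per group. Module genes move on the log2 scale with amplitude
`effect_size` (default 3, i.e. 8-fold at peak) scaled by each plant's
dehydration progress relative to its own minimum and gated by severity
dependence (shared / severe-only / mild-only); normalizing progress
per plant means every active group reaches full amplitude at its own
minimum, which is what makes mild-only modules detectable in mild
plants. Noise is log-normal multiplicative with log2-scale SD
`noise_dispersion` (default 0.25): the differential testing this feeds
is a mean-difference stand-in, so count-level negative-binomial realism
is unnecessary. Masses are generated so that RWC recomputes exactly.

**Promoters and peptides.** Promoters are uniform ACGT backgrounds with
motifs planted at group-specific frequencies at positions that never
overlap previously planted motifs. Peptides are drawn i.i.d. from
per-class amino-acid composition vectors. The null-calibration design
uses an 8-base concrete motif at equal 0.5 frequencies so that all four
table cells have expectation ≥ 20, the regime where the Wald normal
approximation is accurate; the power design plants a 7-symbol
ABRE-like degenerate motif at (0.8, 0.2).

What the simulations do *not* emulate: sequencing error, read-level
coverage variation, assembly artifacts, linked variation
(recombination), count-level dispersion, motif positional preference,
and real LEA family composition. Passing the recovery tests therefore
demonstrates the correctness and sensitivity of the computations under
their stated assumptions, not performance on raw sequencing data.

## Numerical and degenerate-input conventions

Coordinates are 0-based half-open internally, BED-style on output, and
GFF3 1-based inclusive coordinates are converted on input. K-mer codes
are exact integers in doubles up to k = 26; larger k is refused rather
than silently losing precision. Fold-change and p gates are strict
inequalities. All-zero density tracks yield an empty SDR call list, not
an error. Constant matrices are rejected by PCA; zero-variance features
are dropped from peptide summaries with a warning. Every simulator
restores the caller's RNG state and is byte-identical under a fixed
seed.

## Problem sizes used in the validation suite

Cohort recovery runs twenty seeded cohorts at 2 Mb/200 kb with 21-mers;
oracle equivalence uses 200 random sequences up to 10 kb against naive
string-scanning oracles; window coverage is checked exactly against
per-base bitmaps on 50 random 50-kb fixtures; Mapper invariants run on
100 random matrices; enrichment equivalence enumerates all 810,000
nondegenerate 2×2 tables with cells ≤ 30, with 500 null replicates and
100 power replicates; the end-to-end pipeline uses 2000 genes across 156
samples. These sizes were chosen so the full suite completes in minutes
on a single core while leaving each check statistically meaningful.

## Known limitations

Exact k-mer matching cannot tolerate assembly base errors inside a
window (a deliberate trade against determinism); the SDR caller assumes
a single dominant peak per chromosome and reports maximal runs only; the
Mapper clusterer inherits single linkage's chaining behavior within
intervals; the Wald test is anticonservative for very sparse 2×2 tables
(the separation flag marks the corrected ones); and the disorder proxy
is a composition-level approximation that ignores sequence context.
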