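# drykit

Toolkit for the bespoke computations of resurrection-plant genome and
transcriptome studies. Resurrection plants survive drying to near-zero
water content and recover within hours of rain; profiling them in the
field couples genome architecture questions (sex chromosomes, repeat
organization, putative holocentry) with a dehydration–rehydration
expression time course. `drykit` implements the analysis layer such a
study needs once reads have been assembled, annotated and quantified:

- **K-mer sexing** — meryl-style canonical k-mer set algebra over sexed
  cohorts. With male sets *M₁..Mₘ* and female sets *F₁..Fₙ*, the
  male-specific set is (⋂ᵢ Mᵢ) \ (⋃ⱼ Fⱼ) and symmetrically for females;
  an excess of male-specific 21-mers (ratio ≥ τ, default τ = 2) calls an
  XY system, the reciprocal excess ZW. Y-mers mapped back onto the
  assembly and counted in sliding windows localize the sex-determining
  region (SDR) as maximal runs of windows ≥ `min_fold` times the
  genome-wide background.
- **Genome architecture** — fraction-of-bases gene/repeat coverage in
  sliding windows, the percent standard deviation of density across
  nonoverlapping windows (low values indicate the uniform gene/repeat
  spread of genomes without pericentromeres), and `(TTTAGGG)n` telomere
  end detection in both orientations.
- **Hydration response** — relative water content, RWC = (fresh − dry) /
  (turgid − dry); drying-severity groups from minimum RWC (desiccation
  < 10%, severe 10–30%, mild above); differentially abundant transcripts
  (DATs) gated at |log2FC| > 2 and Bonferroni-adjusted p < 0.05;
  nonredundant up/down lists, three-way Venn decompositions and alluvial
  transition matrices.
- **Expression topology** — a from-scratch Mapper graph over samples:
  RWC is the lens, its range covered by `n` overlapping intervals
  (default 110 intervals, 90% overlap); each interval's samples are
  clustered by single linkage with a first-gap histogram cut; nodes
  sharing samples are joined by weighted edges. A PCA utility
  accompanies it.
- **CRE enrichment** — strand-aware 1-kb promoter extraction from
  GFF3 + FASTA, degenerate IUPAC motif scanning (both strands), and
  per-motif binomial logistic regression of group (up = 1) on motif
  presence. For a binary predictor the fitted odds ratio equals the 2×2
  table estimate (a·d)/(b·c) with Wald SE √(1/a + 1/b + 1/c + 1/d);
  empty cells receive the Haldane–Anscombe +0.5 correction and a
  separation flag.
- **Peptide features** — Kyte–Doolittle GRAVY, average-mass molecular
  weight, Henderson–Hasselbalch net charge, and an Uversky-style
  charge–hydropathy disorder score for LEA/ELIP protein sets, with
  correlation/PCA summaries.
- **Synthetic data** — seeded generators for every input: diploid sexed
  cohorts with a planted Y-specific region, drying time courses with
  severity-gated expression modules, promoter sets with
  group-differential motif frequencies, and composition-biased peptide
  classes. Each generator emits a truth record so planted signal is
  recoverable by independent scans.

## Worked example

```r
library(drykit)

sim  <- simulate_sexed_genomes(n_autosomes = 0, chrom_length = 2e6,
                               sdr_length = 2e5, seed = 11)
sets <- simulate_individual_kmer_sets(sim, k = 21)
sex  <- vapply(sim$individuals, `[[`, character(1), "sex")
sp   <- sex_specific_kmers(sexed_cohort(sets, sex))
classify_heterogamety(sp$male_specific, sp$female_specific)
#> <heterogamety_call> XY (male-specific 122464 : female-specific 0, ratio Inf, tau 2)

scan <- sdr_scan(sp$male_specific, unlist(sim$reference),
                 width = 2e4, step = 2e4)
head(as.data.frame(scan$calls), 1)
#>   chrom start    end mean_window_density fold_over_background n_windows
#> 1  chrY 20000 240000            11133.09             18.18182        11
sim$truth
#> $chrom [1] "chrY";  $start [1] 25992;  $end [1] 225992
```

All 122,464 male-specific 21-mers trace to the planted 200-kb Y region
(its k-mers survive the cohort intersection wherever no substitution
hit a 21-base window in any male), no female-specific k-mers remain, and
the top SDR call overlaps the truth interval at Jaccard 0.91 — the
boundary error is one 20-kb window on each side.

The same end-to-end flow, across all four analysis arms, runs from one
configuration:

```r
res <- run_pipeline(seed = 1)   # or run_pipeline("config.yaml", seed = 1)
str(res$metrics)
#> $ sex_system             : chr "XY"
#> $ sdr_jaccard            : num 0.976
#> $ de_sensitivity         : num 0.951
#> $ de_fdr                 : num 0
#> $ pc1_rwc_abs_cor        : num 0.928
#> $ mapper_samples_covered : logi TRUE
#> $ cre_odds_ratio         : num 4.64
#> $ cre_power              : num 1
#> $ gravy_ch_cor           : num 0.999
#> $ pc1_class_accuracy     : num 1
```

`de_sensitivity` is the fraction of planted expression-module genes
recovered in the correct direction by the DAT summarization;
`pc1_rwc_abs_cor` is the correlation between the first expression
principal component and RWC; `cre_power` is the fraction of 100
replicate promoter sets in which the planted motif is called enriched
(odds ratio > 1, p < 0.05).

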