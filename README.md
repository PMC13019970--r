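# sourcedust

Source-signal tracking for indoor-microbiome seeding interventions.

## The problem

Can a deliberately introduced environmental microbial source — for example
forest soil repeatedly embedded into an entryway rug — be tracked through a
home's airborne dust over months? Longitudinal built-environment amplicon
studies answer this by following a *source signature* through settled-dust
samples collected at increasing distance from the source and comparing each
post-seeding window with the one before it. `sourcedust` implements that
analysis end to end for researchers working with feature (ASV or taxon)
count tables: quality control, compositional distances, ordination,
permutation tests, three source indices, the paired spatiotemporal
statistics, and a fully seeded simulator of the whole study design so every
stage is testable without any sequencing data.

## Core statistics

For a dust sample with relative abundances \(p_i\):

- **SSI (soil source index)** — \( \mathrm{SSI} = \sum_{i \in S} p_i \),
  where \(S\) is the set of the most abundant taxa detected in *every*
  seeding-soil aliquot (prevalence filter first, then rank by mean relative
  abundance across aliquots; 19 taxa for bacteria, 28 for fungi by
  default).
- **HSP (human source proxy)** — the summed relative abundance of five
  human-associated taxa (*Staphylococcus*, *Streptococcus* at genus rank;
  Propionibacteriaceae, Corynebacteriaceae, Enterobacteriaceae at family
  rank), a proxy for occupant-shed bacteria.
- **FaRMI (farm-home resembling microbiota index)** — a logistic-GLM
  probability score \( \mathrm{logit}^{-1}(\beta_0 + \sum_k \beta_k r_k) \)
  over percentile-ranked predictor-taxon abundances \(r_k\) (coefficients
  supplied as a CSV, never hardcoded).
- **Community convergence** — Bray–Curtis distance of each dust sample to
  its home's averaged seeding-soil baseline, plus Aitchison (CLR/Euclidean)
  distance matrices, PCoA, and PERMANOVA (one-factor and marginal
  per-term partial sums of squares, with exhaustive permutation enumeration
  when the permutation set is small).
- **Intervention statistics** — pre/post pairs around each seeding event
  (`pre2w_post2w`, `pre2w_post4w`), Shapiro-gated paired *t* / Wilcoxon
  signed-rank tests per dust stratum, Spearman cross-location correlations,
  and rank-based group comparisons.

The simulator generates the complete study design (5 intervention homes +
1 control, weeks −8…+14, seeding at weeks 0/4/8, five dust strata plus
outdoor) with ground-truth mixing weights per sample: the soil weight
follows \( w_{soil} = A_{home} \cdot att(stratum) \cdot
e^{-\lambda \Delta t} \) and reads are drawn Dirichlet-multinomial.

## Worked example

```r
library(sourcedust)

sim <- simulate_study(simulation_config(), seed = 42)
sim
#> dust_simulation: 468 samples (30 aliquots, 6 blanks), 198 taxa, seed 42

trk <- run_soil_tracking(sim, depth = 2000, seed = 42)
trk$signature
#> source_signature (bacteria): 19 taxa (requested 19)
#>   top: Soilgenus048, Soilgenus049, Soilgenus034, Soilgenus006, Soilgenus036
round(trk$coverage$range, 3)
#>   min   max
#> 0.785 0.867

pairs <- make_pairs(sim$metadata, seeding_design(), "pre2w_post2w")
tab <- paired_by_stratum(trk$ssi, pairs, metric = "SSI")
tab$mean_diff_pct <- round(100 * tab$mean_diff, 2)
tab[, c("stratum", "n_pairs", "mean_diff_pct", "test_used", "p")]
#>        stratum n_pairs mean_diff_pct test_used            p
#> 1 entrance_ABZ      15          1.81         t 0.0003733876
#> 2 entrance_IBZ      15          2.91         t 0.0001136144
#> 3        floor      15          0.82  wilcoxon 0.0007247147
#> 4       LR_ABZ      15          0.94         t 0.0037769637
#> 5       LR_IBZ      15          1.24         t 0.0003553153

round(ssi_recovery_stats(sim, trk)$truth_spearman$rho, 3)
#> [1] 0.917
```

Reading the table: after contaminant removal and rarefaction to 2000
reads, the soil signature captures 78–87% of aliquot reads, and the paired
pre/post comparison shows the soil signal strongest in the entryway infant
breathing zone (mean SSI increase of 2.9 percentage points two weeks after
seeding), decaying monotonically toward the living-room samples and the
floor — the spatial gradient the index is designed to detect. The SSI
tracks the simulator's ground-truth soil mixing weight at Spearman
rho ≈ 0.92.

A small pre-generated study (47 samples, 41 taxa) ships under
`inst/extdata/minihome/` in the exact TSV dialects the loaders consume
(`read_abundance_table()`, `read_taxonomy()`, `read_sample_metadata()`).

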