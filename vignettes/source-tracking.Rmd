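---
title: "Tracking a seeded soil source through indoor dust: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking a seeded soil source through indoor dust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sourcedust)
```

`sourcedust` analyses longitudinal built-environment amplicon surveys in
which an environmental microbial source (here: sieved forest soil embedded
in an entryway rug) is introduced into homes repeatedly, and passive
settled-dust samplers record the airborne community at several locations
and heights over months. This vignette explains the statistical machinery,
the tunable parameters and their defaults, what the simulator does and does
not emulate, and the numerical choices made where the design was open.

## The data model

A study is three tables. The **feature table** is a non-negative matrix of
features (ASVs or rank-aggregated taxa) by samples, tagged with kingdom
(bacteria and fungi are always analysed separately) and mode (counts vs
relative abundances, which many operations deliberately refuse to mix).
The **taxonomy** maps features to six ranks (domain…genus) with explicit
`NA` for unassigned ranks; aggregation to a rank keeps unassigned features
as `"<deepest assigned label>_unclassified"` so per-sample totals are
conserved exactly. The **sample metadata** carries the design: home, sample
type, location, height (IBZ = 30 cm infant breathing zone, ABZ = 150 cm
adult breathing zone), and the collection week. A sample's week is the
*end* of its 2-week passive-collection window, and samples dated at a
seeding week were collected before that week's rug deployment — this
convention drives both the pre/post pairing and the simulator's ground
truth, and getting it wrong by one grid step would silently shift every
paired comparison.

## Quality control

**Contaminant flagging** compares each feature's detection prevalence in
negative-control blanks versus experimental samples and flags features
more prevalent in controls, the signature of reagent contamination. We
score the 2×2 presence/absence table with a one-sided Fisher exact
(hypergeometric) p-value and flag below a threshold (default 0.5). The
widely used prevalence method in this space scores with a chi-squared
statistic; the exact test is a deliberate substitution — it is
direction-explicit, has no small-sample validity issues at typical blank
counts (a dozen blanks), and flags in the same direction. By construction
a feature whose control prevalence does not exceed its sample prevalence
can never be flagged.

**Rarefaction** subsamples each sample without replacement (multivariate
hypergeometric) to a common depth, 2000 reads by default; shallower
samples are dropped and reported. The draw is seeded and mandatory —
any single draw is a valid realisation, but reproducibility requires the
seed to travel with the analysis.

**CLR transform.** Zeros are handled by adding a pseudocount (default 1)
before the centred log-ratio transform. With a pseudocount the transform is
*not* invariant to rescaling a sample's counts — the offset's relative
weight shrinks with depth — which is documented, tested, and one reason
the transform is applied after rarefaction to a common depth.

## Distances, diversity, ordination, PERMANOVA

Bray–Curtis dissimilarity is computed on rarefied counts (equivalently,
relative abundances at equal depth); no pseudocount is ever applied to it.
Aitchison distance is the Euclidean distance between CLR vectors. Shannon
diversity uses the natural log. Chao1 is
\(S_{obs} + F_1^2/(2F_2)\), with the bias-corrected fallback
\(S_{obs} + F_1(F_1-1)/2\) when there are no doubletons (the classic
estimator is undefined there); it requires integer counts. PCoA is
classical metric scaling (Gower double-centering); axes with non-positive
eigenvalues are dropped but the eigenvalues are reported, and each axis's
sign is fixed so its largest-magnitude loading is positive — a
determinism convention, since eigenvectors are sign-ambiguous.

PERMANOVA partitions the total sum of squares of the Gower-centred matrix
and references the pseudo-F against free permutations of sample labels.
The p-value is \((1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})\),
including the identity permutation so p is never zero; when the complete
permutation set is no larger than `n_perm` it is enumerated exhaustively
and the p-value is exact. A degenerate zero-residual partition (perfect
group separation) is treated as \(F = \infty\) rather than left to
floating-point cancellation. Marginal testing computes each term's partial
SS as SS(full) − SS(without the term) against the full-model residual,
shares one permutation stream across terms, and rejects collinear designs
naming the aliased columns. The implementation is tested for exact
agreement of SS, F and R² with `vegan::adonis2` (including `by =
"margin"`), which serves as an independent oracle, and for type-I-error
calibration under simulated nulls.

## Source indices

The **soil source signature** is built from the source aliquots in two
strict stages: a prevalence filter (a taxon absent from even one aliquot
is excluded, regardless of abundance — the point is robustness of the
signature across seeding events), then ranking by unweighted mean relative
abundance across aliquots with a lexicographic tie-break for determinism.
"Most abundant" could also have meant the median or pooled reads; the
unweighted mean was chosen as the simplest estimator that does not let one
deep aliquot dominate. The signature is built from all aliquots jointly
(one list per kingdom), while the per-home *averaged baseline* used for
beta distances lives in the community module. The SSI of a sample is the
summed relative abundance of signature taxa — a sub-compositional sum, so
it is additive over disjoint taxon sets and bounded in [0, 1]. Whether to
score rarefied or unrarefied relative abundances is exposed as a choice;
the pipeline default is rarefied, consistent with the other
rarefaction-based metrics.

The **HSP** resolves a mixed-rank list (two genera, three families)
against the taxonomy; a genus named at genus rank would be excluded from
its family term only if both appeared in the list, which the default list
avoids, so nothing is double-counted. The **FaRMI** percentile-ranks each
predictor taxon's relative abundance *within the set of samples passed in
one call* — the ranking population is an explicit, documented knob, and a
single sample is rejected rather than silently ranked against itself.
Absent predictor taxa contribute zero abundance (and hence tied ranks),
and the published coefficient table is an input file, not package data.

## Pairing and paired tests

For each intervention home × dust stratum × seeding event, the pre sample
is the one whose window ends at the event week and the post sample sits 2
or 4 weeks later; incomplete pairs are dropped with honest n reported per
stratum, and the control home is excluded from pooled testing (it gets a
descriptive report — with one control home there is no power for testing).
With 4-week event spacing the `pre2w_post4w` post sample of one event *is*
the pre sample of the next; this overlap is part of the design and is not
corrected. Differences (post − pre) are screened with Shapiro–Wilk at
α = 0.05 — the design rule said "t-test, or Wilcoxon when not normal"
without naming the test or level, so the gate is explicit and per
metric × stratum cell; normal-looking differences get the paired t,
otherwise the signed-rank test with zeros dropped (the standard
convention) and the exact distribution when the non-zero count is ≤ 25.
All-zero differences return p = 1 by definition. No multiple-testing
correction is applied by default (per-cell raw p-values are reported, as
is conventional for this design's descriptive tables);
`stats::p.adjust` composes trivially if desired.

Spearman correlations (cross-location coherence of metrics, anchored at
the entrance IBZ closest to the rug) use exact permutation p-values for
n ≤ 9 without ties and the t approximation otherwise; pairs are matched
on home × week and the honest pair count is reported.

## The simulator

The generator emulates the study's mixture/decay structure — this is a
modelling choice for testability, not a mechanistic claim. Each dust
sample's expected composition is \(\sum_k w_k P_k\) over four pools (soil,
human, outdoor, home background), with
\(w_{soil} = A_{home}\,att(stratum)\,e^{-\lambda \Delta t}\) where
\(\Delta t\) counts weeks since the most recent seeding *strictly before*
the sample week (samples at a seeding week predate that deployment), and
the background weights rescaled to \(1 - w_{soil}\) preserving their
ratios. Counts are Dirichlet-multinomial (precision c, multinomial as
c → ∞) at lognormal depths. Every sample draws from its own RNG stream
derived by a stable hash of (home, stratum, week) plus the master seed, so
outputs are byte-reproducible and extending the design never perturbs
existing samples.

Defaults, chosen once to land in the qualitative regime the study reports
and then left alone:

| parameter | default | rationale |
|---|---|---|
| homes | 5 intervention + 1 control | study design |
| weeks | −8…+14, step 2; seeding 0/4/8 | study design |
| deposition A | 0.20/0.12/0.10/0.08/0.06 | between-home spread, strongest in home 1; entrance-IBZ paired SSI increases ≈ 2–3 points, per-event peaks up to ~10 |
| attenuation | 1.0/0.8/0.5/0.4/0.2 (entrance-IBZ…floor), 0 outdoor | monotone spatial decay away from the rug |
| λ | 0.3466 / week | signal halves per 2-week window; post4w effects roughly half of post2w |
| background | human 0.5 / outdoor 0.3 / home 0.2 | occupant-dominated indoor air ("swamping") |
| pool overlap | 0 (bacteria-like) | pre-seeding soil-signature levels near zero, as observed for bacterial communities; ~0.5 reproduces the fungi-like regime where signature taxa already circulate via outdoor air and baseline SSI is elevated |
| Dirichlet-multinomial c | 500 | moderate between-sample overdispersion beyond multinomial noise |
| read depth | lognormal(log 8000, 0.25) | comfortably above the 2000-read rarefaction target |
| seasonal drift | slope 0.04/week from week 2 | outdoor pool shifts toward a spring profile, mimicking the season confound |

What the simulator does **not** emulate: resuspension physics, occupant
behaviour, microbial growth or viability, strain-level structure below the
taxon labels, qPCR biomass, and sequencing artefacts other than
compositional noise (no chimeras, no index hopping; contaminants appear
only in blanks). Passing tests on simulated data therefore demonstrate
that the *statistical machinery* recovers the signal its model assumes —
spatial ordering, temporal decay, null behaviour — not that real dust data
meet those assumptions.

## Problem sizes and verification

The test suite verifies closed-form oracles by hand-computed values
(Bray–Curtis, CLR/Aitchison, Chao1 including the F2 = 0 fallback, Shannon,
Spearman, paired t, exact signed-rank, Kruskal–Wallis), cross-checks the
PERMANOVA partition against `vegan::adonis2`, and measures calibration and
recovery by simulation: 500 null data sets (n = 12, 199 permutations) for
type-I error, and 20 replicates of the full default study (~470 samples,
~200 taxa each) for signal recovery — sizes chosen so the whole suite runs
in well under a minute per property while keeping Monte-Carlo error small
against the asserted margins. `scripts/acceptance.R` re-runs the same
computations from a single command-line seed.

## Known limitations

Signature construction assumes the aliquots are sequenced deeply enough
that a truly core soil taxon is detected in every aliquot; at shallow
depths the prevalence filter becomes conservative and the signature
shrinks. The SSI is blind to strain identity: a signature genus arriving
from a different source still counts (the elevated-baseline regime —
overlap > 0 — makes this confounding reproducible). PERMANOVA permutes
labels freely; repeated-measures structure within homes is not respected
(strata are a future knob), so its p-values on longitudinal data are
descriptive. The paired design deliberately reuses the week-4/8 samples in
both comparisons, so the two comparisons are not independent. And the
control arm has a single home: its report is descriptive by construction.
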