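Package: sourcedust
Title: Source-Signal Tracking for Indoor Microbiome Seeding Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for tracking an environmental source signal (e.g. forest
    soil seeded into homes) through longitudinal built-environment amplicon
    surveys. Implements signature-based source indices (soil source index,
    human source proxy, farm-home resembling microbiota index), prevalence
    contaminant flagging, rarefaction, centred log-ratio transforms,
    Bray-Curtis / Aitchison distances, PCoA, PERMANOVA with marginal terms,
    convergence-to-source baselines, paired pre/post intervention statistics,
    and a Dirichlet-multinomial study simulator with per-sample ground-truth
    mixing weights.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
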