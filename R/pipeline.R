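#' Run the source-tracking pipeline on a simulated (or loaded) study
#'
#' The standard analysis path: flag contaminants against the blank
#' controls, drop them, rarefy to a common depth, build the soil source
#' signature from the source aliquots, and score every dust sample's SSI.
#' Returns the intermediate objects so downstream statistics (pairing,
#' correlations, distances) can be composed freely.
#'
#' @param sim a `dust_simulation` from [simulate_study()] (or a compatible
#'   list with `table`, `metadata`, `aliquot_ids`, `blank_ids`).
#' @param depth rarefaction depth (study value 2000).
#' @param seed seed for the rarefaction draw.
#' @param n_taxa signature size; `NULL` for the kingdom default (19
#'   bacteria / 28 fungi).
#' @param contaminant_threshold prevalence-score threshold (default 0.5).
#' @return list with `contaminants` (report), `rarefied` (counts table,
#'   blanks excluded), `signature`, `coverage`, `ssi` (tidy series for
#'   dust samples), `dust_ids`, `aliquot_ids` (those surviving
#'   rarefaction).
#' @export
run_soil_tracking <- function(sim, depth = 2000, seed = 1, n_taxa = NULL,
                              contaminant_threshold = 0.5) {
  tab <- sim$table
  report <- NULL
  if (length(sim$blank_ids)) {
    report <- flag_contaminants_prevalence(tab, sim$blank_ids,
                                           contaminant_threshold)
    tab <- at_samples(tab, setdiff(colnames(tab), sim$blank_ids))
    flagged <- report$feature_id[report$flagged]
    if (length(flagged)) tab <- remove_features(tab, flagged)
  }
  rar <- suppressMessages(rarefy(tab, depth = depth, seed = seed))
  aliq <- intersect(sim$aliquot_ids, colnames(rar))
  if (length(aliq) < 2) stop("fewer than 2 aliquots survived rarefaction")
  sig <- build_source_signature(at_samples(rar, aliq), n_taxa = n_taxa)
  dust <- setdiff(colnames(rar), aliq)
  ssi <- ssi_scores(at_samples(rar, dust), sig)
  list(contaminants = report, rarefied = rar, signature = sig,
       coverage = source_coverage(sig, at_samples(rar, aliq)),
       ssi = ssi, dust_ids = dust, aliquot_ids = aliq)
}

#' Paired SSI table across dust strata for one simulated study
#'
#' Convenience wrapper producing the per-stratum paired pre/post SSI
#' statistics for one comparison, alongside the Spearman correlation of
#' SSI against the generator's ground-truth soil weight over post-seeding
#' dust samples.
#'
#' @param sim a `dust_simulation`.
#' @param tracking result of [run_soil_tracking()] on `sim`.
#' @param comparison pairing comparison (see [make_pairs()]).
#' @param design a [seeding_design()]; defaults to the simulation's
#'   seeding weeks.
#' @return list with `paired` (per-stratum data frame) and
#'   `truth_spearman` (list rho/p/n over post-seeding samples).
#' @export
ssi_recovery_stats <- function(sim, tracking,
                               comparison = "pre2w_post2w",
                               design = NULL) {
  if (is.null(design)) design <- seeding_design(sim$config$seeding_weeks)
  meta <- sim$metadata
  pairs <- make_pairs(meta, design, comparison)
  pairs <- pairs[pairs$pre_id %in% tracking$ssi$sample_id &
                   pairs$post_id %in% tracking$ssi$sample_id, ]
  paired <- paired_by_stratum(tracking$ssi, pairs, metric = "SSI")
  post <- meta$sample_id[!is.na(meta$week) &
                           meta$week > min(sim$config$seeding_weeks) &
                           meta$sample_id %in% tracking$ssi$sample_id &
                           !is.na(dust_stratum(meta))]
  v <- series_values(tracking$ssi)[post]
  w <- sim$truth$w_soil[match(post, sim$truth$sample_id)]
  # a null design (all soil weights zero) has no defined correlation
  sp <- tryCatch(spearman_cor(w, v), error = function(e)
    list(rho = NA_real_, p = NA_real_, n = length(v)))
  list(paired = paired, truth_spearman = sp)
}
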