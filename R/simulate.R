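#' Configuration of the synthetic seeding study
#'
#' Defines the simulated study: a biweekly longitudinal design over several
#' homes (intervention + control), repeated source-seeding events whose
#' signal decays exponentially in time and attenuates with distance from
#' the entryway rug, plus human / outdoor / home background sources (the
#' outdoor pool drifts seasonally) and Dirichlet-multinomial read noise.
#'
#' The defaults reproduce the study design: 5 intervention homes and 1
#' control, weeks -8 to +14 on a 2-week grid, seeding at weeks 0/4/8, five
#' dust strata plus outdoor, and read depths comfortably above the 2000-read
#' rarefaction target. Deposition amplitudes differ by home (strongest
#' first), matching the observed between-home spread of the response.
#'
#' @param n_intervention_homes,n_control_homes home counts.
#' @param weeks sampling grid (even integers); each sample's week is the
#'   end of its 2-week collection window.
#' @param seeding_weeks seeding event weeks.
#' @param attenuation named spatial attenuation factors in [0, 1]; the
#'   names define the sampled strata. Ordered by proximity to the rug.
#' @param richness named taxon counts per source pool.
#' @param pool_overlap fraction of soil-pool taxa shared with the outdoor
#'   pool. The bacteria-like default is 0 (disjoint pools: pre-seeding
#'   soil-signature levels in dust are near zero, as observed for
#'   bacteria); raise to ~0.5 for the fungi-like regime where signature
#'   taxa are already part of the resident mycobiota via outdoor air.
#' @param pool_concentration named Dirichlet concentrations shaping each
#'   pool (small = dominated by few taxa).
#' @param deposition per-intervention-home deposition amplitudes A >= 0
#'   (recycled); control homes always 0.
#' @param decay_rate exponential decay rate lambda per week (default
#'   0.3466: the signal halves every 2-week window).
#' @param background named human/outdoor/home background weights (rescaled
#'   to 1 - w_soil per sample, preserving ratios).
#' @param home_similarity Dirichlet precision tying each home's background
#'   profile to the shared home pool (larger = more similar homes).
#' @param season_start,season_slope outdoor seasonal drift: from
#'   `season_start` the outdoor pool shifts toward a second "spring"
#'   profile at `season_slope` per week (capped at 1).
#' @param depth_meanlog,depth_sdlog lognormal read-depth distribution.
#' @param dm_concentration Dirichlet-multinomial precision c; multinomial
#'   is recovered as c grows.
#' @param n_aliquots_per_event source aliquots sequenced per home and
#'   seeding event.
#' @param n_blanks,blank_depth negative-control blank samples (drawn from a
#'   dedicated contaminant pool).
#' @param kingdom `"bacteria"` or `"fungi"` tag for the emitted tables.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(
    n_intervention_homes = 5, n_control_homes = 1,
    weeks = seq(-8L, 14L, by = 2L),
    seeding_weeks = c(0L, 4L, 8L),
    attenuation = c(entrance_IBZ = 1.0, entrance_ABZ = 0.8, LR_IBZ = 0.5,
                    LR_ABZ = 0.4, floor = 0.2, outdoor = 0),
    richness = c(soil = 60, human = 40, outdoor = 50, home = 40, contaminant = 8),
    pool_overlap = 0,
    pool_concentration = c(soil = 0.5, human = 0.8, outdoor = 0.8,
                           home = 0.8, contaminant = 1),
    deposition = c(0.20, 0.12, 0.10, 0.08, 0.06),
    decay_rate = 0.3466,
    background = c(human = 0.5, outdoor = 0.3, home = 0.2),
    home_similarity = 60,
    season_start = 2, season_slope = 0.04,
    depth_meanlog = log(8000), depth_sdlog = 0.25,
    dm_concentration = 500,
    n_aliquots_per_event = 2,
    n_blanks = 6, blank_depth = 1500,
    kingdom = c("bacteria", "fungi")) {
  kingdom <- match.arg(kingdom)
  if (n_intervention_homes < 1) stop("need >= 1 intervention home")
  if (any(richness < 1)) stop("every pool richness must be >= 1")
  if (any(attenuation < 0 | attenuation > 1)) stop("attenuations must be in [0, 1]")
  if (any(background < 0) || sum(background) <= 0) {
    stop("background weights must be non-negative with positive sum")
  }
  if (any(deposition < 0)) stop("deposition amplitudes must be >= 0")
  if (decay_rate < 0) stop("decay_rate must be >= 0")
  if (any(weeks %% 2 != 0) || any(seeding_weeks %% 2 != 0)) {
    stop("weeks and seeding weeks must lie on the biweekly grid")
  }
  req <- c("soil", "human", "outdoor", "home", "contaminant")
  if (!all(req %in% names(richness)) || !all(req %in% names(pool_concentration))) {
    stop("richness and pool_concentration need entries: ", paste(req, collapse = ", "))
  }
  deposition <- rep_len(deposition, n_intervention_homes)
  structure(list(
    n_intervention_homes = as.integer(n_intervention_homes),
    n_control_homes = as.integer(n_control_homes),
    weeks = as.integer(weeks), seeding_weeks = as.integer(seeding_weeks),
    attenuation = attenuation, richness = richness,
    pool_overlap = pool_overlap, pool_concentration = pool_concentration,
    deposition = deposition, decay_rate = decay_rate,
    background = background / sum(background),
    home_similarity = home_similarity,
    season_start = season_start, season_slope = season_slope,
    depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
    dm_concentration = dm_concentration,
    n_aliquots_per_event = as.integer(n_aliquots_per_event),
    n_blanks = as.integer(n_blanks), blank_depth = as.integer(blank_depth),
    kingdom = kingdom), class = "simulation_config")
}

# stable 31-bit seed from a master seed plus a character key, so each
# sample gets its own stream and adding strata never perturbs others
hash_seed <- function(master, ...) {
  key <- paste(..., sep = "|")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + (master %% 2147483647) * 48271) %% 2147483647)
}

sim_homes <- function(config) {
  c(sprintf("home_%d", seq_len(config$n_intervention_homes)),
    if (config$n_control_homes > 0)
      sprintf("control_%d", seq_len(config$n_control_homes)))
}

deposition_for <- function(config, home) {
  i <- match(home, sprintf("home_%d", seq_len(config$n_intervention_homes)))
  ifelse(is.na(i), 0, config$deposition[i])
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Source pool profiles on a shared taxon axis
#'
#' Draws the soil, human, outdoor (plus a late-season outdoor variant),
#' home-background and contaminant relative-abundance profiles, each from a
#' Dirichlet over its own taxon pool. A configurable fraction of soil taxa
#' is shared with the outdoor pool; at `pool_overlap = 0` the two supports
#' are disjoint. The first human-pool taxa carry the canonical
#' human-associated genus labels so the HSP resolves against the synthetic
#' taxonomy.
#'
#' @param config a [simulation_config()].
#' @param seed integer master seed.
#' @return list with `taxa`, `profiles` (taxa x pools matrix, columns
#'   soil/human/outdoor/outdoor_spring/home/contaminant, each summing
#'   to 1) and `supports` (taxon names per pool).
#' @export
make_source_profiles <- function(config, seed) {
  stopifnot(inherits(config, "simulation_config"))
  rich <- config$richness
  soil_taxa <- sprintf("Soilgenus%03d", seq_len(rich[["soil"]]))
  hsp_named <- c("Staphylococcus", "Streptococcus", "Cutibacterium",
                 "Corynebacterium", "Escherichia")
  nh <- rich[["human"]]
  human_taxa <- c(utils::head(hsp_named, nh),
                  if (nh > length(hsp_named))
                    sprintf("Humangenus%03d", seq_len(nh - length(hsp_named))))
  n_shared <- round(config$pool_overlap * rich[["soil"]])
  shared <- utils::tail(soil_taxa, n_shared)
  n_own <- max(rich[["outdoor"]] - n_shared, 1)
  outdoor_taxa <- c(shared, sprintf("Outdoorgenus%03d", seq_len(n_own)))
  home_taxa <- sprintf("Homegenus%03d", seq_len(rich[["home"]]))
  contam_taxa <- sprintf("Contamgenus%03d", seq_len(rich[["contaminant"]]))
  taxa <- unique(c(soil_taxa, human_taxa, outdoor_taxa, home_taxa, contam_taxa))
  supports <- list(soil = soil_taxa, human = human_taxa, outdoor = outdoor_taxa,
                   outdoor_spring = outdoor_taxa, home = home_taxa,
                   contaminant = contam_taxa)
  conc <- config$pool_concentration
  conc <- c(conc, outdoor_spring = unname(conc[["outdoor"]]))
  set.seed(hash_seed(seed, "profiles"))
  profiles <- matrix(0, nrow = length(taxa), ncol = length(supports),
                     dimnames = list(taxa, names(supports)))
  for (p in names(supports)) {
    sup <- supports[[p]]
    profiles[sup, p] <- rdirichlet1(rep(conc[[p]], length(sup)))
  }
  list(taxa = taxa, profiles = profiles, supports = supports)
}

#' Ground-truth soil mixing weight of a sample
#'
#' \eqn{w_{soil} = A_{home} \cdot att(stratum) \cdot e^{-\lambda \Delta t}}
#' where \eqn{\Delta t} is the time since the most recent seeding event
#' strictly before `week` (samples dated at a seeding week are collected
#' before that week's deployment, so the event does not yet contribute).
#' Zero before the first event and for control homes.
#'
#' @param week sample week (end of collection window).
#' @param stratum stratum label (a name of `config$attenuation`).
#' @param home home label (`"home_i"` or `"control_i"`).
#' @param config a [simulation_config()].
#' @return soil weight in [0, 1].
#' @export
soil_weight <- function(week, stratum, home, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!stratum %in% names(config$attenuation)) {
    stop("unknown stratum '", stratum, "'")
  }
  a <- deposition_for(config, home)
  events <- config$seeding_weeks[config$seeding_weeks < week]
  if (a == 0 || length(events) == 0) return(0)
  dt <- week - max(events)
  a * config$attenuation[[stratum]] * exp(-config$decay_rate * dt)
}

sim_taxonomy <- function(profiles, kingdom) {
  dom <- if (kingdom == "bacteria") "Bacteria" else "Fungi"
  fam_map <- c(Staphylococcus = "Staphylococcaceae",
               Streptococcus = "Streptococcaceae",
               Cutibacterium = "Propionibacteriaceae",
               Corynebacterium = "Corynebacteriaceae",
               Escherichia = "Enterobacteriaceae")
  taxa <- profiles$taxa
  fam <- ifelse(taxa %in% names(fam_map), fam_map[taxa],
                paste0(sub("genus[0-9]+$", "", taxa), "aceae"))
  taxonomy_from_lineages(
    taxa, sprintf("d__%s;f__%s;g__%s", dom, fam, taxa))
}

#' Simulate a complete seeding study
#'
#' Generates counts, metadata, and per-sample ground-truth mixing weights
#' for the full design: for each home x stratum x week the expected
#' composition is \eqn{\sum_k w_k P_k} over the soil / human / outdoor /
#' home pools (soil weight from [soil_weight()], backgrounds rescaled to
#' the remainder; outdoor samples are pure outdoor pool), and reads are
#' drawn Dirichlet-multinomial with precision `dm_concentration` at a
#' lognormal depth. Soil aliquots are drawn from the soil pool for every
#' intervention home and seeding event; blank controls from the
#' contaminant pool. Every sample has its own RNG stream derived from the
#' master seed and its design coordinates, so the output is fully
#' reproducible and insensitive to design extensions.
#'
#' @param config a [simulation_config()].
#' @param seed integer master seed.
#' @return a `dust_simulation` list: `table` (counts
#'   [abundance_table()]), `metadata` ([sample_metadata()]), `truth`
#'   (data frame `sample_id`, `w_soil`, `w_human`, `w_outdoor`, `w_home`),
#'   `aliquot_ids`, `blank_ids`, `taxonomy`, `profiles`, `config`, `seed`.
#' @export
simulate_study <- function(config = simulation_config(), seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  prof <- make_source_profiles(config, seed)
  taxa <- prof$taxa
  homes <- sim_homes(config)
  strata <- names(config$attenuation)
  # per-home background profile: a home-specific Dirichlet wobble around
  # the shared home pool (homes differ, as observed between real homes)
  home_prof <- sapply(homes, function(h) {
    set.seed(hash_seed(seed, "homeprofile", h))
    sup <- prof$supports$home
    out <- numeric(length(taxa)); names(out) <- taxa
    out[sup] <- rdirichlet1(config$home_similarity * prof$profiles[sup, "home"] +
                              1e-6)
    out
  })
  season <- function(week) {
    min(1, max(0, config$season_slope * (week - config$season_start)))
  }
  outdoor_at <- function(week) {
    s <- season(week)
    (1 - s) * prof$profiles[, "outdoor"] + s * prof$profiles[, "outdoor_spring"]
  }
  draw_counts <- function(comp, depth) {
    alpha <- config$dm_concentration * comp
    p <- numeric(length(comp))
    pos <- alpha > 0
    p[pos] <- stats::rgamma(sum(pos), shape = alpha[pos])
    if (sum(p) == 0) p[which.max(comp)] <- 1
    drop(stats::rmultinom(1, size = depth, prob = p / sum(p)))
  }
  rdepth <- function() {
    max(100L, as.integer(round(stats::rlnorm(1, config$depth_meanlog,
                                             config$depth_sdlog))))
  }
  ids <- character(0); cols <- list(); meta <- list(); truth <- list()
  add <- function(id, counts, meta_row, truth_row = NULL) {
    ids[[length(ids) + 1]] <<- id
    cols[[length(cols) + 1]] <<- counts
    meta[[length(meta) + 1]] <<- meta_row
    if (!is.null(truth_row)) truth[[length(truth) + 1]] <<- truth_row
  }
  wtag <- function(w) sprintf("w%s%02d", if (w < 0) "m" else "p", abs(w))
  bg <- config$background
  for (h in homes) {
    is_ctrl <- startsWith(h, "control")
    for (s in strata) {
      for (w in config$weeks) {
        id <- paste(h, s, wtag(w), sep = ".")
        set.seed(hash_seed(seed, h, s, w))
        if (s == "outdoor") {
          ws <- 0
          weights <- c(w_soil = 0, w_human = 0, w_outdoor = 1, w_home = 0)
          comp <- outdoor_at(w)
          meta_row <- data.frame(sample_id = id, home = h,
                                 sample_type = "outdoor", location = "outdoor",
                                 height = "none", week = w,
                                 is_control_home = is_ctrl,
                                 kingdom = config$kingdom)
        } else {
          ws <- soil_weight(w, s, h, config)
          weights <- c(w_soil = ws, w_human = (1 - ws) * bg[["human"]],
                       w_outdoor = (1 - ws) * bg[["outdoor"]],
                       w_home = (1 - ws) * bg[["home"]])
          comp <- ws * prof$profiles[, "soil"] +
            weights[["w_human"]] * prof$profiles[, "human"] +
            weights[["w_outdoor"]] * outdoor_at(w) +
            weights[["w_home"]] * home_prof[, h]
          if (s == "floor") {
            meta_row <- data.frame(sample_id = id, home = h,
                                   sample_type = "floor_dust",
                                   location = "floor", height = "none",
                                   week = w, is_control_home = is_ctrl,
                                   kingdom = config$kingdom)
          } else {
            loc <- if (startsWith(s, "entrance")) "entrance" else "living_room"
            ht <- sub("^.*_", "", s)
            meta_row <- data.frame(sample_id = id, home = h,
                                   sample_type = "settled_dust",
                                   location = loc, height = ht, week = w,
                                   is_control_home = is_ctrl,
                                   kingdom = config$kingdom)
          }
        }
        add(id, draw_counts(comp, rdepth()), meta_row,
            data.frame(sample_id = id, t(weights)))
      }
    }
  }
  aliquot_ids <- character(0)
  for (h in utils::head(homes, config$n_intervention_homes)) {
    for (w in config$seeding_weeks) {
      for (r in seq_len(config$n_aliquots_per_event)) {
        id <- paste(h, "soil", wtag(w), sprintf("r%d", r), sep = ".")
        aliquot_ids <- c(aliquot_ids, id)
        set.seed(hash_seed(seed, h, "soil", w, r))
        add(id, draw_counts(prof$profiles[, "soil"], rdepth()),
            data.frame(sample_id = id, home = h,
                       sample_type = "source_aliquot", location = "source",
                       height = "none", week = w, is_control_home = FALSE,
                       kingdom = config$kingdom))
      }
    }
  }
  blank_ids <- character(0)
  for (b in seq_len(config$n_blanks)) {
    id <- sprintf("blank.%02d", b)
    blank_ids <- c(blank_ids, id)
    set.seed(hash_seed(seed, "blank", b))
    add(id, draw_counts(prof$profiles[, "contaminant"], config$blank_depth),
        data.frame(sample_id = id, home = "lab", sample_type = "control_blank",
                   location = "none", height = "none", week = NA_integer_,
                   is_control_home = FALSE, kingdom = config$kingdom))
  }
  m <- do.call(cbind, cols)
  dimnames(m) <- list(taxa, ids)
  structure(list(
    table = abundance_table(m, kingdom = config$kingdom, mode = "counts"),
    metadata = sample_metadata(do.call(rbind, meta)),
    truth = do.call(rbind, truth),
    aliquot_ids = aliquot_ids, blank_ids = blank_ids,
    taxonomy = sim_taxonomy(prof, config$kingdom),
    profiles = prof, config = config, seed = seed),
    class = "dust_simulation")
}

#' @export
print.dust_simulation <- function(x, ...) {
  cat(sprintf("dust_simulation: %d samples (%d aliquots, %d blanks), %d taxa, seed %d\n",
              ncol(x$table), length(x$aliquot_ids), length(x$blank_ids),
              nrow(x$table), x$seed))
  invisible(x)
}

#' Write a simulation bundle as plain-text fixture files
#'
#' Emits the exact dialects the loaders consume: `counts.tsv`
#' (feature table), `taxonomy.tsv`, `metadata.tsv`, `truth.tsv`, and
#' `aliquots.txt` (one aliquot sample ID per line).
#'
#' @param sim a `dust_simulation` from [simulate_study()].
#' @param out_dir output directory.
#' @param force overwrite an existing non-empty directory.
#' @return invisibly, the named vector of file paths.
#' @export
write_fixture <- function(sim, out_dir, force = FALSE) {
  stopifnot(inherits(sim, "dust_simulation"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    stop("output directory exists and is not empty (use force = TRUE): ", out_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(out_dir, "counts.tsv"),
             taxonomy = file.path(out_dir, "taxonomy.tsv"),
             metadata = file.path(out_dir, "metadata.tsv"),
             truth = file.path(out_dir, "truth.tsv"),
             aliquots = file.path(out_dir, "aliquots.txt"))
  write_abundance_table(sim$table, paths[["counts"]])
  write_taxonomy(sim$taxonomy, paths[["taxonomy"]])
  write_sample_metadata(sim$metadata, paths[["metadata"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(sim$aliquot_ids, paths[["aliquots"]])
  invisible(paths)
}
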