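# shared in-code fixtures for the test suite

toy_matrix <- function(vals, features, samples) {
  matrix(vals, nrow = length(features),
         dimnames = list(features, samples))
}

toy_table <- function(vals, features, samples, kingdom = "bacteria",
                      mode = "counts") {
  abundance_table(toy_matrix(vals, features, samples), kingdom, mode)
}

rand_counts <- function(nf, ns, seed = 1, lambda = 20) {
  set.seed(seed)
  m <- matrix(stats::rpois(nf * ns, lambda), nrow = nf,
              dimnames = list(sprintf("t%02d", seq_len(nf)),
                              sprintf("s%02d", seq_len(ns))))
  abundance_table(m, "bacteria", "counts")
}

# small but complete study config for fast simulation tests
tiny_config <- function(...) {
  args <- list(
    n_intervention_homes = 2, n_control_homes = 1,
    weeks = seq(-4L, 6L, by = 2L), seeding_weeks = c(0L, 4L),
    richness = c(soil = 20, human = 10, outdoor = 15, home = 10,
                 contaminant = 4),
    depth_meanlog = log(3000), n_blanks = 3)
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

# aliquot toy set matching the worked ranking example: candidates A
# (mean 0.30) and C (mean 0.20); B and D each miss one aliquot
ranking_aliquots <- function(kingdom = "bacteria") {
  m <- matrix(c(0.30, 0.50, 0.20, 0.00,
                0.30, 0.00, 0.20, 0.50,
                0.30, 0.45, 0.20, 0.05),
              nrow = 4, dimnames = list(c("A", "B", "C", "D"),
                                        c("q1", "q2", "q3")))
  abundance_table(m, kingdom, "relative")
}

# full-design metadata without running the simulator (for pairing tests)
design_metadata <- function(n_homes = 5, weeks = seq(-8L, 14L, 2L),
                            control = TRUE) {
  strata <- c("entrance_IBZ", "entrance_ABZ", "LR_IBZ", "LR_ABZ", "floor")
  homes <- c(sprintf("home_%d", seq_len(n_homes)), if (control) "control_1")
  g <- expand.grid(home = homes, stratum = strata, week = weeks,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  loc <- ifelse(g$stratum == "floor", "floor",
                ifelse(startsWith(g$stratum, "entrance"), "entrance",
                       "living_room"))
  ht <- ifelse(g$stratum == "floor", "none", sub("^.*_", "", g$stratum))
  sample_metadata(data.frame(
    sample_id = paste(g$home, g$stratum, g$week, sep = "."),
    home = g$home,
    sample_type = ifelse(g$stratum == "floor", "floor_dust", "settled_dust"),
    location = loc, height = ht, week = g$week,
    is_control_home = g$home == "control_1",
    kingdom = "bacteria", stringsAsFactors = FALSE))
}
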