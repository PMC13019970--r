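test_that("source pools respect overlap and are seed-deterministic", {
  cfg0 <- tiny_config(pool_overlap = 0)
  p0 <- make_source_profiles(cfg0, seed = 3)
  expect_length(intersect(p0$supports$soil, p0$supports$outdoor), 0)
  cfg5 <- tiny_config(pool_overlap = 0.5)
  p5 <- make_source_profiles(cfg5, seed = 3)
  expect_equal(length(intersect(p5$supports$soil, p5$supports$outdoor)),
               round(0.5 * 20))
  expect_identical(make_source_profiles(cfg0, seed = 3)$profiles, p0$profiles)
  expect_false(identical(make_source_profiles(cfg0, seed = 4)$profiles,
                         p0$profiles))
  expect_equal(unname(colSums(p0$profiles)), rep(1, 6), tolerance = 1e-12)
})

test_that("profile evenness increases with the Dirichlet concentration", {
  ent <- function(conc, seed) {
    cfg <- tiny_config(pool_concentration = c(soil = conc, human = 1,
                                              outdoor = 1, home = 1,
                                              contaminant = 1))
    p <- make_source_profiles(cfg, seed)$profiles[, "soil"]
    shannon(p[p > 0])
  }
  lo <- vapply(1:8, function(s) ent(0.15, s), numeric(1))
  hi <- vapply(1:8, function(s) ent(8, s), numeric(1))
  expect_gt(mean(hi), mean(lo))
})

test_that("soil weight follows the attenuated exponential decay", {
  cfg <- simulation_config(seeding_weeks = 0L, deposition = 0.1,
                           decay_rate = 0.3466)
  expect_equal(soil_weight(2, "entrance_IBZ", "home_1", cfg), 0.05,
               tolerance = 1e-3)
  expect_equal(soil_weight(4, "entrance_IBZ", "home_1", cfg), 0.025,
               tolerance = 1e-3)
  # samples at or before a seeding week predate that deployment
  expect_equal(soil_weight(0, "entrance_IBZ", "home_1", cfg), 0)
  expect_equal(soil_weight(-2, "entrance_IBZ", "home_1", cfg), 0)
  expect_equal(soil_weight(6, "entrance_IBZ", "control_1", cfg), 0)
  cfg0 <- simulation_config(seeding_weeks = 0L, deposition = 0.1,
                            decay_rate = 0)
  expect_equal(soil_weight(2, "LR_ABZ", "home_1", cfg0),
               soil_weight(14, "LR_ABZ", "home_1", cfg0))
  # spatial attenuation ordering carries over to the weights
  w <- vapply(c("entrance_IBZ", "entrance_ABZ", "LR_IBZ", "LR_ABZ", "floor"),
              function(s) soil_weight(2, s, "home_1", cfg), numeric(1))
  expect_true(all(diff(w) < 0))
  expect_error(soil_weight(2, "attic", "home_1", cfg), "stratum")
})

test_that("simulated studies have coherent truth, metadata and counts", {
  sim <- simulate_study(tiny_config(), seed = 11)
  expect_s3_class(sim$metadata, "sample_metadata")
  tr <- sim$truth
  expect_equal(rowSums(tr[, c("w_soil", "w_human", "w_outdoor", "w_home")]),
               rep(1, nrow(tr)), tolerance = 1e-9)
  md <- sim$metadata[match(tr$sample_id, sim$metadata$sample_id), ]
  expect_true(all(tr$w_soil[md$is_control_home] == 0))
  expect_true(all(tr$w_soil[md$week <= 0] == 0))
  expect_true(all(sim$table[, , drop = FALSE] >= 0))
  expect_true(all(colSums(sim$table) > 0))
  # aliquots and blanks are present and tagged
  expect_true(all(sim$aliquot_ids %in%
                    sim$metadata$sample_id[sim$metadata$sample_type == "source_aliquot"]))
  expect_true(all(sim$blank_ids %in%
                    sim$metadata$sample_id[sim$metadata$sample_type == "control_blank"]))
  # identical seed reproduces everything; different seed does not
  sim2 <- simulate_study(tiny_config(), seed = 11)
  expect_identical(sim$table[, , drop = FALSE], sim2$table[, , drop = FALSE])
  expect_identical(sim$truth, sim2$truth)
  sim3 <- simulate_study(tiny_config(), seed = 12)
  expect_false(identical(sim$table[, , drop = FALSE],
                         sim3$table[, , drop = FALSE]))
})

test_that("read depth scales counts but not expected composition", {
  cfg1 <- tiny_config()
  cfg2 <- tiny_config(depth_meanlog = log(3000) + log(2))
  s1 <- simulate_study(cfg1, seed = 21)
  s2 <- simulate_study(cfg2, seed = 21)
  expect_gt(median(colSums(s2$table)), 1.7 * median(colSums(s1$table)))
  r1 <- rowMeans(sweep(s1$table[, , drop = FALSE], 2, colSums(s1$table), "/"))
  r2 <- rowMeans(sweep(s2$table[, , drop = FALSE], 2, colSums(s2$table), "/"))
  expect_equal(r1, r2, tolerance = 0.02)
})

test_that("fixtures round-trip through the plain-text loaders", {
  sim <- simulate_study(tiny_config(), seed = 2)
  dir <- withr::local_tempdir()
  out <- file.path(dir, "fix")
  paths <- write_fixture(sim, out)
  expect_error(write_fixture(sim, out), "force")
  tab <- read_abundance_table(paths[["counts"]], "bacteria")
  expect_equal(tab[, , drop = FALSE], sim$table[, , drop = FALSE])
  md <- read_sample_metadata(paths[["metadata"]])
  expect_equal(md$sample_id, sim$metadata$sample_id)
  truth <- utils::read.delim(paths[["truth"]])
  expect_equal(rowSums(truth[, -1]), rep(1, nrow(truth)), tolerance = 1e-9)
  tax <- read_taxonomy(paths[["taxonomy"]])
  expect_setequal(tax$feature_id, rownames(sim$table))
  # byte-identical outputs from identical seeds
  p2 <- write_fixture(simulate_study(tiny_config(), seed = 2),
                      file.path(dir, "fix2"))
  expect_identical(unname(tools::md5sum(paths)), unname(tools::md5sum(p2)))
})

test_that("the committed mini fixture loads and matches its truth table", {
  dir <- system.file("extdata", "minihome", package = "sourcedust")
  expect_true(nzchar(dir))
  tab <- read_abundance_table(file.path(dir, "counts.tsv"), "bacteria")
  md <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  truth <- utils::read.delim(file.path(dir, "truth.tsv"))
  expect_lte(nrow(tab), 50)
  expect_lte(ncol(tab), 60)
  expect_true(all(colnames(tab) %in% md$sample_id))
  expect_equal(rowSums(truth[, -1]), rep(1, nrow(truth)), tolerance = 1e-9)
})

test_that("computed SSI tracks the generator's soil signal", {
  sim <- simulate_study(simulation_config(), seed = 31)
  tr <- run_soil_tracking(sim, depth = 2000, seed = 31)
  st <- ssi_recovery_stats(sim, tr, "pre2w_post2w")
  # regression of SSI on truth w_soil recovers the covered soil fraction
  post <- sim$metadata$sample_id[!is.na(sim$metadata$week) &
                                   sim$metadata$week > 0 &
                                   !is.na(dust_stratum(sim$metadata))]
  post <- intersect(post, tr$ssi$sample_id)
  ssi <- tr$ssi$value[match(post, tr$ssi$sample_id)]
  w <- sim$truth$w_soil[match(post, sim$truth$sample_id)]
  slope <- stats::coef(stats::lm(ssi ~ w))[["w"]]
  covg <- mean(tr$coverage$per_aliquot)
  expect_lt(abs(slope - covg) / covg, 0.25)
  expect_gt(st$truth_spearman$rho, 0.85)
  # convergence to the source: post-seeding dust is closer to the soil
  rel_dust <- intersect(tr$dust_ids, sim$metadata$sample_id[
    !is.na(dust_stratum(sim$metadata)) & !sim$metadata$is_control_home])
  dust_tab <- abundance_table(
    sim$table[, rel_dust, drop = FALSE], "bacteria")
  aliq_tab <- abundance_table(
    sim$table[, sim$aliquot_ids, drop = FALSE], "bacteria")
  base <- source_baseline(to_relative(aliq_tab), sim$metadata)
  bd <- beta_to_baseline(to_relative(dust_tab), sim$metadata, base)
  wk <- sim$metadata$week[match(bd$sample_id, sim$metadata$sample_id)]
  expect_lt(mean(bd$distance[wk > 0]), mean(bd$distance[wk <= 0]))
})

test_that("soil-outdoor pool overlap elevates baseline SSI (fungal regime)", {
  base_ssi <- function(overlap, seed) {
    sim <- simulate_study(tiny_config(pool_overlap = overlap,
                                      kingdom = if (overlap > 0) "fungi"
                                      else "bacteria"),
                          seed = seed)
    tr <- run_soil_tracking(sim, depth = 1000, seed = seed, n_taxa = 10)
    pre <- sim$metadata$sample_id[!is.na(sim$metadata$week) &
                                    sim$metadata$week <= 0 &
                                    !is.na(dust_stratum(sim$metadata))]
    mean(tr$ssi$value[tr$ssi$sample_id %in% pre])
  }
  lo <- vapply(1:5, function(s) base_ssi(0, s), numeric(1))
  hi <- vapply(1:5, function(s) base_ssi(0.5, s), numeric(1))
  expect_gt(mean(hi), mean(lo))
})
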