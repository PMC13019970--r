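test_that("Bray-Curtis matches the closed form and its bounds", {
  expect_equal(bray_curtis(c(2, 2, 0), c(1, 1, 2)), 0.5)
  expect_equal(bray_curtis(c(3, 1, 4), c(3, 1, 4)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 5)), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(1:3, 1:2), "axis")
})

test_that("Aitchison distance is the Euclidean metric on CLR vectors", {
  expect_equal(aitchison_distance(c(1, -1), c(-1, 1)), sqrt(8))
  expect_equal(aitchison_distance(c(0.3, -0.3), c(0.3, -0.3)), 0)
  expect_error(aitchison_distance(1:3, 1:2), "length")
  set.seed(21)
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(6); c <- rnorm(6)
    expect_lte(aitchison_distance(a, c),
               aitchison_distance(a, b) + aitchison_distance(b, c) + 1e-12)
  }
})

test_that("distance_matrix is consistent with the pairwise operations", {
  x <- rand_counts(12, 5, seed = 6, lambda = 10)
  db <- as.matrix(distance_matrix(x, "bray_curtis"))
  da <- as.matrix(distance_matrix(x, "aitchison", pseudocount = 1))
  clr <- clr_transform(x, 1)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(db[i, j], bray_curtis(x[, i], x[, j]), tolerance = 1e-12)
    expect_equal(da[i, j], aitchison_distance(clr[, i], clr[, j]),
                 tolerance = 1e-12)
  }
  expect_equal(db, t(db))
  expect_equal(unname(diag(da)), rep(0, 5))
  two <- abundance_table(x[, 1:2], "bacteria")
  expect_equal(as.numeric(distance_matrix(two, "bray_curtis")),
               bray_curtis(x[, 1], x[, 2]))
  expect_error(distance_matrix(abundance_table(x[, 1, drop = FALSE],
                                               "bacteria"), "bray_curtis"),
               ">= 2")
})

test_that("source baselines average each home's aliquots and renormalise", {
  m <- toy_matrix(c(1, 0, 0, 1, 0.5, 0.5), c("a", "b"),
                  c("q1", "q2", "q3"))
  x <- abundance_table(m, "bacteria", "relative")
  meta <- sample_metadata(data.frame(
    sample_id = c("q1", "q2", "q3"), home = c("h1", "h1", "h2"),
    sample_type = "source_aliquot", location = "source", height = "none",
    week = 0L, is_control_home = FALSE, kingdom = "bacteria"))
  b <- source_baseline(x, meta)
  expect_equal(unname(b[, "h1"]), c(0.5, 0.5))
  expect_equal(unname(b[, "h2"]), c(0.5, 0.5))
  expect_equal(unname(colSums(b)), c(1, 1))
  expect_error(source_baseline(x, meta, homes = c("h1", "h9")), "h9")
})

test_that("beta distance to baseline hits the boundary cases", {
  base <- matrix(c(0.5, 0.5, 0), dimnames = list(c("a", "b", "c"), "h1"))
  meta <- sample_metadata(data.frame(
    sample_id = c("d1", "d2"), home = "h1", sample_type = "settled_dust",
    location = "entrance", height = "IBZ", week = 0L,
    is_control_home = FALSE, kingdom = "bacteria"))
  dust <- abundance_table(
    toy_matrix(c(0.5, 0.5, 0, 0, 0, 1), c("a", "b", "c"), c("d1", "d2")),
    "bacteria", "relative")
  r <- beta_to_baseline(dust, meta, base)
  expect_equal(r$distance[r$sample_id == "d1"], 0)
  expect_equal(r$distance[r$sample_id == "d2"], 1)
  meta2 <- meta; meta2$home <- "h9"
  expect_error(beta_to_baseline(dust, sample_metadata(meta2), base), "h9")
})

test_that("Chao1 follows the estimator and its F2 = 0 fallback", {
  expect_equal(chao1(c(5, 3, 1, 1, 2)), 7)      # S + F1^2/(2 F2)
  expect_equal(chao1(c(1, 1)), 3)               # F2 = 0 fallback
  expect_equal(chao1(c(4, 5, 2, 2)), 4)         # no singletons -> S_obs
  expect_error(chao1(c(1.5, 2)), "integer")
  set.seed(14)
  for (i in 1:20) {
    v <- rpois(30, 2)
    if (sum(v) == 0) next
    expect_gte(chao1(v), sum(v > 0))
  }
})

test_that("Shannon diversity uses natural log and is entropy-bounded", {
  expect_equal(shannon(c(7, 0, 0)), 0)
  expect_equal(shannon(rep(2, 4)), log(4))
  expect_error(shannon(c(0, 0)), "all-zero")
  set.seed(15)
  for (i in 1:20) {
    v <- rpois(25, 3)
    if (sum(v) == 0) next
    expect_lte(shannon(v), log(sum(v > 0)) + 1e-12)
    expect_equal(shannon(v), vegan::diversity(v, index = "shannon"),
                 tolerance = 1e-12)
  }
})

test_that("PCoA embeds exact Euclidean configurations and orders eigenvalues", {
  set.seed(33)
  pts <- cbind(rnorm(8), rnorm(8))
  rownames(pts) <- sprintf("s%d", 1:8)
  d <- dist(pts)
  fit <- pcoa(d, k = 2)
  expect_equal(as.matrix(dist(fit$points)), as.matrix(d), tolerance = 1e-9)
  expect_true(all(diff(fit$eigenvalues) <= 1e-9))
  # sign convention: largest-magnitude loading positive
  for (j in 1:2) expect_gt(max(fit$points[, j]), abs(min(fit$points[, j])) - 1e-12)
  # collinear points have a single positive axis
  col3 <- dist(matrix(c(0, 1, 2), ncol = 1))
  expect_warning(f2 <- pcoa(col3, k = 2), "positive")
  expect_equal(ncol(f2$points), 1)
})

test_that("PERMANOVA matches vegan's partitioning and is seed-deterministic", {
  set.seed(99)
  y <- matrix(rnorm(14 * 3), nrow = 14)
  g <- rep(c("A", "B"), each = 7)
  d <- dist(y)
  mine <- permanova(d, g, n_perm = 199, seed = 4)
  ref <- vegan::adonis2(d ~ g, data = data.frame(g = g), permutations = 199)
  expect_equal(mine$F, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$R2, ref$R2[1], tolerance = 1e-10)
  expect_equal(mine$SS, ref$SumOfSqs[1], tolerance = 1e-10)
  expect_identical(permanova(d, g, n_perm = 199, seed = 4)$p, mine$p)
  expect_gte(mine$p, 1 / 200)
  expect_error(permanova(d, rep("A", 14)), "2 groups")
})

test_that("marginal PERMANOVA reproduces adonis2 by-margin partial SS", {
  set.seed(7)
  y <- matrix(rnorm(16 * 4), nrow = 16)
  cov <- data.frame(f = factor(rep(c("u", "v"), 8)),
                    z = rnorm(16))
  d <- dist(y)
  mine <- permanova_marginal(d, cov, n_perm = 99, seed = 2)
  ref <- vegan::adonis2(d ~ f + z, data = cov, by = "margin",
                        permutations = 99)
  expect_equal(mine$SS, ref$SumOfSqs[1:2], tolerance = 1e-10)
  expect_equal(mine$F, ref$F[1:2], tolerance = 1e-10)
  # a single term reduces exactly to the one-factor test
  m1 <- permanova_marginal(d, cov["f"], n_perm = 49, seed = 3)
  m0 <- permanova(d, cov$f, n_perm = 49, seed = 3)
  expect_equal(m1$F, m0$F, tolerance = 1e-12)
  expect_equal(m1$SS, m0$SS, tolerance = 1e-12)
  # duplicated covariate -> rank deficiency named
  expect_error(permanova_marginal(d, data.frame(a = cov$z, b = cov$z)),
               "collinear|aliased")
})
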