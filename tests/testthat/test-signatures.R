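test_that("signature construction enforces prevalence and abundance ranking", {
  # B has the highest mean abundance but misses one aliquot -> excluded
  x <- ranking_aliquots()
  sig <- build_source_signature(x, n_taxa = 2)
  expect_identical(sig$taxa, c("A", "C"))
  expect_false("B" %in% sig$taxa)
  expect_equal(sig$selection_stats$mean_abundance, c(0.30, 0.20))
  expect_error(build_source_signature(x[, 1, drop = FALSE]))
})

test_that("signature size defaults to the kingdom configuration (19/28)", {
  set.seed(42)
  m <- matrix(stats::runif(35 * 3, 0.1, 1), nrow = 35,
              dimnames = list(sprintf("T%02d", 1:35), c("q1", "q2", "q3")))
  bac <- build_source_signature(abundance_table(m, "bacteria"), n_taxa = NULL)
  fun <- build_source_signature(abundance_table(m, "fungi"), n_taxa = NULL)
  expect_length(bac$taxa, 19)
  expect_length(fun$taxa, 28)
  expect_warning(build_source_signature(abundance_table(m, "bacteria"),
                                        n_taxa = 40), "35")
})

test_that("signature construction is invariant to sample and feature order", {
  x <- rand_counts(25, 4, seed = 8, lambda = 5)
  sig <- build_source_signature(x, n_taxa = 10)
  set.seed(1)
  perm <- abundance_table(x[sample(nrow(x)), sample(ncol(x))], "bacteria")
  expect_identical(build_source_signature(perm, n_taxa = 10)$taxa, sig$taxa)
  f <- withr::local_tempfile(fileext = ".json")
  write_signature(sig, f)
  expect_identical(read_signature(f)$taxa, sig$taxa)
})

test_that("signature scores are sub-compositional sums in [0,1]", {
  s <- c(A = 0.10, C = 0.05, D = 0.85)
  expect_equal(signature_score(s, c("A", "C")), 0.15)
  expect_equal(signature_score(s, c("X", "Y")), 0)
  expect_equal(signature_score(s, names(s)), 1)
  # additive over disjoint taxon sets
  x <- to_relative(rand_counts(20, 6, seed = 12))
  s1 <- rownames(x)[1:5]; s2 <- rownames(x)[6:11]
  v1 <- ssi_scores(x, s1)$value
  v2 <- ssi_scores(x, s2)$value
  v12 <- ssi_scores(x, c(s1, s2))$value
  expect_equal(v12, v1 + v2, tolerance = 1e-12)
  expect_true(all(v12 >= 0 & v12 <= 1))
})

test_that("coverage is monotone in signature size", {
  x <- rand_counts(30, 3, seed = 4, lambda = 8)
  sizes <- c(2, 5, 10, 20)
  cov <- vapply(sizes, function(n) {
    sig <- build_source_signature(x, n_taxa = n)
    mean(source_coverage(sig, x)$per_aliquot)
  }, numeric(1))
  expect_true(all(diff(cov) >= 0))
  rng <- source_coverage(build_source_signature(x, n_taxa = 5), x)$range
  expect_lte(rng[["min"]], rng[["max"]])
})

test_that("HSP resolves genus and family terms against the taxonomy", {
  tax <- taxonomy_from_lineages(
    c("a1", "a2", "a3", "a4"),
    c("d__Bacteria;f__Staphylococcaceae;g__Staphylococcus",
      "d__Bacteria;f__Corynebacteriaceae;g__Corynebacterium",
      "d__Bacteria;f__Corynebacteriaceae;g__Lawsonella",
      "d__Bacteria;f__Sphingomonadaceae;g__Sphingomonas"))
  x <- toy_table(c(0.2, 0.06, 0.04, 0.7), c("a1", "a2", "a3", "a4"), "s1",
                 mode = "relative")
  h <- hsp_scores(x, tax)
  expect_equal(h$value, 0.3)  # 0.2 genus + 0.1 family via member genera
  expect_identical(h$index, "HSP")
  none <- toy_table(1, "a4", "s1", mode = "relative")
  expect_equal(hsp_scores(none, tax)$value, 0)
  expect_error(hsp_scores(x, tax, data.frame(label = "X", rank = "order")),
               "rank")
  expect_identical(hsp_default_taxa()$label[1:2],
                   c("Staphylococcus", "Streptococcus"))
})

test_that("FaRMI reproduces the logistic closed forms and is rank-based", {
  x <- toy_table(c(0.1, 0.9, 0.3, 0.7), c("p", "q"), c("s1", "s2"),
                 mode = "relative")
  null_model <- farmi_model(0, c(p = 0, q = 0))
  expect_equal(farmi_scores(x, null_model)$value, c(0.5, 0.5))
  m <- farmi_model(-1, c(p = 2))
  sc <- farmi_scores(x, m)
  # lower-abundance sample: r = 0.5 -> eta = 0 -> 0.5;
  # higher: r = 1 -> eta = 1 -> 1/(1+e^-1)
  expect_equal(sc$value[sc$sample_id == "s1"], 0.5)
  expect_equal(sc$value[sc$sample_id == "s2"], stats::plogis(1),
               tolerance = 1e-6)
  one <- abundance_table(x[, 1, drop = FALSE], "bacteria", "relative")
  expect_error(farmi_scores(one, m), "population")
  # invariance to strictly monotone transforms of a predictor's relative
  # abundances (soaking the change into a non-predictor filler taxon)
  set.seed(3)
  pred <- matrix(runif(4 * 8, 0, 0.2), nrow = 4,
                 dimnames = list(sprintf("pr%d", 1:4), sprintf("s%d", 1:8)))
  rel1 <- rbind(pred, filler = 1 - colSums(pred))
  rel2 <- rbind(pred * c(0.5, 1, 1, 1), filler = NA)
  rel2["filler", ] <- 1 - colSums(rel2[1:4, ])
  mod <- farmi_model(0.2, stats::setNames(stats::rnorm(4), rownames(pred)))
  v1 <- farmi_scores(abundance_table(rel1, "bacteria", "relative"), mod)$value
  v2 <- farmi_scores(abundance_table(rel2, "bacteria", "relative"), mod)$value
  expect_equal(v1, v2)
})

test_that("FaRMI model round-trips through CSV", {
  m <- farmi_model(-0.73, c(Massilia = 1.2, Kocuria = -0.4))
  f <- withr::local_tempfile(fileext = ".csv")
  write_farmi_model(m, f)
  m2 <- read_farmi_model(f)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$coefficients, m$coefficients)
})
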