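complex_medium <- function(id, g_per_l, category = "meat") {
  medium_variant(id, components = tibble::tibble(
    compound_id = paste0("complex-", category), amount = g_per_l,
    unit = "g_per_l", class = "complex", category = category,
    g_per_l = g_per_l))
}

minimal_medium <- function(id) {
  medium_variant(id, components = tibble::tibble(
    compound_id = c("Na+", "Cl-"), amount = 0.01, unit = "mol_per_l",
    class = "defined", category = NA_character_, g_per_l = c(0.23, 0.35)))
}

test_that("richness scores are weighted g/l sums with 5/15 g/l class cutoffs", {
  expect_equal(medium_richness(minimal_medium("m0")),
               tibble::tibble(score = 0, class = "low"))
  expect_equal(medium_richness(complex_medium("m1", 10)),
               tibble::tibble(score = 10, class = "medium"))
  expect_equal(medium_richness(complex_medium("m2", 20)),
               tibble::tibble(score = 20, class = "high"))
  # boundary scores go to the lower class
  expect_equal(medium_richness(complex_medium("m3", 5))$class, "low")
  expect_equal(medium_richness(complex_medium("m4", 15))$class, "medium")
  # category weights rescale the sum
  cfg <- richness_config(weights = c(meat = 0.5))
  expect_equal(medium_richness(complex_medium("m5", 20), cfg)$score, 10)
  # rich defined components count by their gram equivalent
  glucose_med <- medium_variant("m6", components = tibble::tibble(
    compound_id = "glucose", amount = 20 / 180.16, unit = "mol_per_l",
    class = "defined", category = NA_character_, g_per_l = 20))
  expect_equal(medium_richness(glucose_med)$score, 20)
})

test_that("richness is linear in component amounts", {
  withr::local_seed(2)
  for (i in 1:10) {
    g <- runif(1, 0.1, 30)
    s1 <- medium_richness(complex_medium("a", g))$score
    s2 <- medium_richness(complex_medium("a", 2 * g))$score
    expect_equal(s2, 2 * s1)
  }
  # classes are exhaustive and mutually exclusive
  for (score in c(0, 4.99, 5, 5.01, 15, 15.01, 100)) {
    cls <- medium_richness(complex_medium("x", score))$class
    expect_true(cls %in% c("low", "medium", "high"))
  }
})

test_that("organism preference is the argmax of summed class scores", {
  mr <- tibble::tibble(medium_id = c("m1", "m2", "m3"),
                       class = c("low", "high", "low"))
  preds <- tibble::tibble(organism = "org", medium = c("m1", "m2", "m3"),
                          score = c(2, 1, 0.5))
  out <- organism_richness_preference(preds, mr)
  expect_equal(out$preference, "low")       # 2.5 > 1.0
  expect_equal(out$score_low, 2.5)

  all_high <- organism_richness_preference(
    tibble::tibble(organism = "o2", medium = "m2", score = 3), mr)
  expect_equal(all_high$preference, "high")

  none <- organism_richness_preference(
    tibble::tibble(organism = "o3", medium = "m1", score = 0), mr)
  expect_equal(none$preference, "unknown")

  # ties break toward the lower richness class
  tie <- organism_richness_preference(
    tibble::tibble(organism = "o4", medium = c("m1", "m2"), score = c(1, 1)), mr)
  expect_equal(tie$preference, "low")
})

test_that("gold-standard preferences require unanimous documented classes", {
  mr <- tibble::tibble(medium_id = c("l1", "l2", "h1"),
                       class = c("low", "low", "high"))
  db <- growth_db(tibble::tibble(
    organism = c("pure", "pure", "mixed", "mixed", "naked"),
    medium = c("l1", "l2", "l1", "h1", "zz")))
  gold <- gold_standard_preferences(db, mr)
  expect_equal(gold$organism, "pure")
  expect_equal(gold$gold_class, "low")
})

test_that("category enrichment matches the exact rank-sum enumeration", {
  cats <- tibble::tibble(medium_id = c("a", "b", "c", "d", "e"),
                         category = c(rep("polysaccharide", 3), "sugar", "sugar"))
  preds <- tibble::tibble(medium = c("a", "b", "c", "d", "e"),
                          score = c(3, 4, 5, 1, 2))
  out <- category_enrichment(preds, cats, "polysaccharide")
  oracle <- oracle_ranksum_p(c(3, 4, 5), c(1, 2))
  expect_equal(out$statistic, oracle$statistic)
  expect_equal(out$p, oracle$p)
  expect_equal(out$direction, "higher_in_containing")

  # random small untied samples agree with enumeration
  withr::local_seed(17)
  for (i in 1:8) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    scores <- sample(1:50, n1 + n2)
    cats_i <- tibble::tibble(
      medium_id = paste0("m", seq_len(n1 + n2)),
      category = rep(c("yes", "no"), c(n1, n2)))
    preds_i <- tibble::tibble(medium = cats_i$medium_id, score = scores)
    out_i <- category_enrichment(preds_i, cats_i, "yes")
    oracle_i <- oracle_ranksum_p(scores[seq_len(n1)], scores[-seq_len(n1)])
    expect_equal(out_i$p, oracle_i$p, tolerance = 1e-12)
  }
})

test_that("identical score distributions show no enrichment; planted ones do", {
  cats <- tibble::tibble(medium_id = paste0("m", 1:20),
                         category = rep(c("x", "other"), 10))
  same <- tibble::tibble(medium = paste0("m", 1:20), score = rep(1:10, each = 2))
  out_same <- category_enrichment(same, cats, "x")
  expect_gt(out_same$p, 0.5)

  planted <- tibble::tibble(medium = paste0("m", 1:20),
                            score = ifelse(seq_len(20) %% 2 == 1, 10 + 1:20, 1:20))
  out_planted <- category_enrichment(planted, cats, "x")
  expect_lt(out_planted$p, 0.01)
  expect_equal(out_planted$direction, "higher_in_containing")

  expect_error(category_enrichment(same, cats, "absent-category"), "non-empty")
})

test_that("enrichment on synthetic predictions flags the planted carbon source", {
  # imperfect signal, so neighbours also contribute low-scored random media
  # and both category groups are populated among the predictions
  d <- synth_generate(synth_config(signal = 0.8, seed = 21))
  orgs <- d$truth$organisms
  # organisms from clades planted with polysaccharide media
  poly_clades <- unique(orgs$clade[orgs$carbon == "polysaccharide"])[1:2]
  test_orgs <- orgs$organism[orgs$clade %in% poly_clades]
  preds <- predict_media_all(d$db, d$tax, organisms = test_orgs)
  out <- category_enrichment(preds, d$media_categories, "polysaccharide")
  expect_equal(out$direction, "higher_in_containing")
  expect_lt(out$p, 0.05)
})
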