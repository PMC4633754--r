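test_that("collaborative scores follow the cutoff-over-distance weighting", {
  tax <- taxonomy_index(collab_test_tree())
  cfg <- collab_config(distance_cutoff = 0.04)
  db <- growth_db(tibble::tibble(
    organism = c("b", "c", "t01"), medium = c("mX", "mX", "mX")),
    organisms = c("a", "b", "c", "d", paste0("t", sprintf("%02d", 1:96))))

  # b at d = 0.02 contributes 0.04/0.02 = 2; c at the cutoff contributes 1;
  # t01 lies far outside the cutoff
  expect_equal(collab_score("a", "mX", db, tax, cfg), 3)

  # single neighbour exactly at the cutoff
  db1 <- growth_db(tibble::tibble(organism = "c", medium = "mX"),
                   organisms = db_organisms(db))
  expect_equal(collab_score("a", "mX", db1, tax, cfg), 1)

  # no neighbour within the cutoff grows on the medium
  db0 <- growth_db(tibble::tibble(organism = "t01", medium = "mX"),
                   organisms = db_organisms(db))
  expect_equal(collab_score("a", "mX", db0, tax, cfg), 0)

  expect_error(collab_score("ghost", "mX", db, tax, cfg), "ghost")
})

test_that("scores are additive over disjoint neighbour sets and weights bounded", {
  tax <- taxonomy_index(collab_test_tree())
  cfg <- collab_config(distance_cutoff = 0.04)
  orgs <- c("a", "b", "c", "d", paste0("t", sprintf("%02d", 1:96)))
  db_b <- growth_db(tibble::tibble(organism = "b", medium = "mX"), organisms = orgs)
  db_cd <- growth_db(tibble::tibble(organism = c("c", "d"), medium = "mX"),
                     organisms = orgs)
  db_all <- growth_db(tibble::tibble(organism = c("b", "c", "d"), medium = "mX"),
                      organisms = orgs)
  expect_equal(collab_score("a", "mX", db_all, tax, cfg),
               collab_score("a", "mX", db_b, tax, cfg) +
                 collab_score("a", "mX", db_cd, tax, cfg))

  # every neighbour weight lies in [1, cutoff/floor]
  d <- synth_generate(synth_config(n_organisms = 64, clade_size = 8,
                                   signal = 1, seed = 2))
  floor_d <- 1 / d$tax$total_leaves
  preds <- predict_media("org001", d$db, d$tax)
  expect_true(all(preds$score <= preds$neighbour_count * 0.04 / floor_d))
  expect_true(all(preds$score >= preds$neighbour_count))
})

test_that("prediction is leave-one-out honest", {
  d <- synth_generate(synth_config(n_organisms = 64, clade_size = 8,
                                   signal = 0.8, seed = 9))
  org <- "org001"
  with_self <- predict_media(org, d$db, d$tax)
  without <- growth_db(tibble::as_tibble(d$db)[d$db$organism != org, ],
                       organisms = db_organisms(d$db), media = db_media(d$db))
  without_self <- predict_media(org, without, d$tax)
  expect_equal(with_self[, c("medium", "score", "neighbour_count")],
               without_self[, c("medium", "score", "neighbour_count")])
})

test_that("clade-shared media rank first; isolated organisms get nothing", {
  d <- synth_generate(synth_config(n_organisms = 64, clade_size = 8,
                                   signal = 1, seed = 4))
  org <- "org001"
  clade_media <- d$truth$clade_media[["clade01"]]
  preds <- predict_media(org, d$db, d$tax)
  expect_true(preds$medium[1] %in% clade_media)
  expect_true(all(preds$is_known == (preds$medium %in%
                                       d$db$medium[d$db$organism == org])))

  # an organism alone in the tree has no neighbours within the cutoff
  lone_tax <- taxonomy_index(ape::read.tree(text = "((solo,far1),(far2,far3));"))
  lone_db <- growth_db(tibble::tibble(organism = "far1", medium = "m1"),
                       organisms = c("solo", "far1", "far2", "far3"))
  expect_equal(nrow(predict_media("solo", lone_db, lone_tax)), 0)
})

test_that("ecological mode scores with uniform weights under its own cutoff", {
  envs <- environment_table(tibble::tibble(
    organism = c("a", "a", "b", "b", "c"),
    environment = c("e1", "e2", "e1", "e2", "e9")))
  ed <- eco_distance_matrix(envs)
  db <- growth_db(tibble::tibble(organism = c("b", "c"), medium = "mX"))
  s <- collab_score("a", "mX", db, tax = NULL, cfg = collab_config_eco(),
                    eco_dist = ed)
  expect_equal(s, 1)   # only b is within Jaccard distance 0.15, weight 1
})

test_that("the null predictor reproduces popularity weighting", {
  db <- growth_db(tibble::tibble(
    organism = c("u", "u", "v"), medium = c("m1", "m2", "m1")))
  draws <- null_predict(db, 40000, seed = 8)
  # organism u has popularity 2 vs 1: sampled about twice as often
  frac_u <- mean(draws$organism == "u")
  expect_equal(frac_u, 2 / 3, tolerance = 0.03)
  frac_m1 <- mean(draws$medium == "m1")
  expect_equal(frac_m1, 2 / 3, tolerance = 0.03)
  expect_identical(null_predict(db, 100, seed = 3),
                   null_predict(db, 100, seed = 3))

  one <- growth_db(tibble::tibble(organism = "solo", medium = "mOnly"))
  d1 <- null_predict(one, 50, seed = 1)
  expect_true(all(d1$organism == "solo" & d1$medium == "mOnly" & d1$is_known))
  expect_error(null_predict(db, 0), "positive")
})

test_that("partial Spearman removes the controlled variable", {
  withr::local_seed(5)
  x <- rnorm(40)
  y <- x + rnorm(40, sd = 0.3)
  # controlling x against itself leaves nothing
  self <- partial_spearman(y, x, x)
  expect_equal(self$rho, 0, tolerance = 1e-10)
  # y depends on x only through z = x: controlling z kills the association
  z <- x
  part <- partial_spearman(x, y, z)
  expect_lt(abs(part$rho), 0.2)
  # but a genuine direct association survives an unrelated control
  w <- rnorm(40)
  direct <- partial_spearman(x, y, w)
  expect_gt(direct$rho, 0.7)
})

test_that("score-bin evaluation reports TP fractions and correlations", {
  # imperfect signal spreads the score distribution across bins
  d <- synth_generate(synth_config(signal = 0.8, seed = 6))
  orgs <- head(intersect(db_organisms(d$db), d$tax$tips), 60)
  preds <- predict_media_all(d$db, d$tax, organisms = orgs)

  # a predictor that only emits known pairs has TP fraction 1 in every bin
  known <- preds[preds$is_known, ]
  ev_known <- suppressWarnings(evaluate_by_score_bin(known, d$db, n_bins = 5))
  expect_true(all(ev_known$bins$tp_fraction == 1))

  ev <- evaluate_by_score_bin(preds, d$db, n_bins = 6)
  expect_true(all(ev$bins$tp_fraction >= 0 & ev$bins$tp_fraction <= 1))
  expect_equal(sum(ev$bins$n), nrow(preds))
  expect_s3_class(glance(ev), "tbl_df")
  expect_error(evaluate_by_score_bin(preds[0, ], d$db), "No scored")
})

test_that("enrichment against the popularity null detects planted signal", {
  d <- synth_generate(synth_config(signal = 1, seed = 12))
  orgs <- head(intersect(db_organisms(d$db), d$tax$tips), 30)
  preds <- predict_media_all(d$db, d$tax, organisms = orgs)
  en <- enrichment_vs_null(preds, d$db, k = 99, seed = 2, organisms = d$tax$tips)
  expect_lt(en$p_value, 0.05)
  expect_gt(en$enrichment_ratio, 1)
})
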