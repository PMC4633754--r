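# A hand-buildable database with one transitive chain, each medium padded
# to the 3-organism popularity floor.
chain_db <- function() {
  growth_db(tibble::tibble(
    organism = c("A", "B", "x1", "z1",       # m1
                 "B", "C", "x2", "z2",       # m2
                 "C", "y1", "y2"),           # m3
    medium = c(rep("m1", 4), rep("m2", 4), rep("m3", 3))))
}

test_that("the tuple universe matches brute-force enumeration", {
  db <- chain_db()
  mined <- suppressWarnings(mine_patterns(db, n = 10000, seed = 1))
  oracle <- oracle_tuples(db)
  key <- function(x) sort(do.call(paste, as.list(x)))
  expect_equal(key(mined), key(oracle))

  # and on small random databases
  withr::local_seed(23)
  for (i in 1:5) {
    rnd <- growth_db(tibble::tibble(
      organism = sample(paste0("o", 1:8), 30, replace = TRUE),
      medium = sample(paste0("m", 1:5), 30, replace = TRUE)))
    mined <- suppressWarnings(mine_patterns(rnd, n = 1e6, seed = 1,
                                            min_orgs = 2, max_orgs = 100))
    oracle <- oracle_tuples(rnd, min_orgs = 2, max_orgs = 100)
    expect_equal(key(mined), key(oracle))
  }
})

test_that("media outside the popularity window never enter patterns", {
  base <- chain_db()
  crowd <- tibble::tibble(organism = paste0("crowd", 1:101), medium = "mBig")
  joined <- growth_db(dplyr::bind_rows(tibble::as_tibble(base),
                                       crowd,
                                       tibble::tibble(organism = c("A", "B"),
                                                      medium = "mBig")))
  mined <- suppressWarnings(mine_patterns(joined, n = 1e6, seed = 1))
  expect_false("mBig" %in% unlist(mined[, c("m1", "m2", "m3")]))

  empty <- growth_db()
  expect_warning(out <- mine_patterns(empty, n = 10, seed = 1), "No valid")
  expect_equal(nrow(out), 0)
})

test_that("pattern sampling is uniform without replacement and reproducible", {
  pt <- plant_transitivity(0.5, seed = 4)
  a <- mine_patterns(pt$db, n = 200, seed = 9)
  b <- mine_patterns(pt$db, n = 200, seed = 9)
  expect_identical(a, b)
  expect_equal(nrow(a), 200)
  expect_equal(nrow(dplyr::distinct(a)), 200)   # no duplicate tuples
  c_ <- mine_patterns(pt$db, n = 200, seed = 10)
  expect_false(identical(a, c_))
})

test_that("transitivity evaluation counts test and control positives", {
  # saturated relation: every implied pairing is present
  sat <- growth_db(tidyr::expand_grid(organism = paste0("o", 1:6),
                                      medium = paste0("m", 1:4)))
  ev <- evaluate_transitivity(sat, n = 50, seed = 2)
  expect_equal(ev$positives_test, ev$n_tests)

  # chain with (A, m3) absent: no test positives
  ev0 <- suppressWarnings(evaluate_transitivity(chain_db(), n = 20, seed = 2))
  expect_equal(ev0$positives_test, 0)

  expect_error(evaluate_transitivity(sat, n = 0), "positive")
  expect_identical(glance(evaluate_transitivity(sat, n = 30, seed = 5)),
                   glance(evaluate_transitivity(sat, n = 30, seed = 5)))
})

test_that("binomial upper tail matches exhaustive enumeration for n <= 12", {
  expect_equal(binomial_upper_tail(0, 5, 0.3)$p, 1)
  expect_equal(binomial_upper_tail(2, 3, 0.5)$p, 0.5)  # 4 of 8 outcomes
  withr::local_seed(31)
  for (i in 1:12) {
    n <- sample(1:12, 1)
    k <- sample(0:n, 1)
    p <- runif(1, 0.05, 0.95)
    expect_equal(binomial_upper_tail(k, n, p)$p, oracle_binomial_tail(k, n, p),
                 tolerance = 1e-12)
  }
})

test_that("binomial tail is monotone in k and agrees with pbinom in log space", {
  tails <- vapply(0:50, function(k) binomial_upper_tail(k, 50, 0.2)$log10_p, 0)
  expect_true(all(diff(tails) < 0))
  for (k in c(1, 10, 400, 694)) {
    expect_equal(binomial_upper_tail(k, 1000, 0.001)$log10_p,
                 pbinom(k - 1, 1000, 0.001, lower.tail = FALSE, log.p = TRUE) /
                   log(10),
                 tolerance = 1e-6)
  }
  expect_error(binomial_upper_tail(2, 3, 0), "0, 1")
  expect_error(binomial_upper_tail(4, 3, 0.5), "<=")
})

test_that("transitive predictions are deduplicated, annotated and novel", {
  preds <- predict_transitive(chain_db())
  expect_true(any(preds$organism == "A" & preds$medium == "m3"))
  known <- paste(chain_db()$organism, chain_db()$medium)
  expect_false(any(paste(preds$organism, preds$medium) %in% known))
  expect_true(all(preds$witnesses >= 1))

  # two distinct B organisms witness the same implied pair
  db2 <- growth_db(tibble::tibble(
    organism = c("A", "B1", "B2", "x1",
                 "B1", "B2", "C", "x2",
                 "C", "y1", "y2"),
    medium = c(rep("m1", 4), rep("m2", 4), rep("m3", 3))))
  preds2 <- predict_transitive(db2)
  expect_equal(preds2$witnesses[preds2$organism == "A" &
                                  preds2$medium == "m3"], 2)

  # all implied pairs already known -> nothing to predict
  sat <- growth_db(tidyr::expand_grid(organism = paste0("o", 1:6),
                                      medium = paste0("m", 1:4)))
  expect_equal(nrow(predict_transitive(sat)), 0)

  # cross-check witness arithmetic against the enumerated universe
  uni <- oracle_tuples(db2)
  oracle_w <- nrow(uni[uni$A == "A" & uni$m3 == "m3", ])
  expect_equal(preds2$witnesses[preds2$organism == "A" &
                                  preds2$medium == "m3"], oracle_w)
})
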