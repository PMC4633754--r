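#' Configuration for the collaborative filtering scorer
#'
#' The scorer aggregates the documented media of organisms lying within a
#' distance cutoff of the test organism.  On the phylogenetic scale the
#' cutoff defaults to a normalized subtree distance of 0.04 and each
#' neighbour's vote is weighted by cutoff / distance, so a neighbour exactly
#' at the cutoff contributes 1 and closer neighbours contribute more.  On
#' the ecological scale the default cutoff is a Jaccard distance of 0.15
#' with uniform (unweighted) votes.  Because the raw weight cutoff/d is
#' unbounded as d approaches its minimum, distances are floored at
#' `min_distance_floor` (default: the smallest possible subtree distance,
#' 1/total_leaves) so a single near-identical strain cannot dominate the
#' score; every weight therefore lies in \[1, cutoff/floor\].
#'
#' @param distance_cutoff Neighbourhood radius on the distance scale.
#' @param weighting `"cutoff_over_distance"` or `"uniform"`.
#' @param min_distance_floor Positive floor applied to distances before
#'   weighting; `NULL` defers to 1/total_leaves at scoring time.
#' @return A `collab_config`.
#' @export
collab_config <- function(distance_cutoff = 0.04,
                          weighting = c("cutoff_over_distance", "uniform"),
                          min_distance_floor = NULL) {
  weighting <- match.arg(weighting)
  if (distance_cutoff <= 0 || distance_cutoff > 1) {
    abort("`distance_cutoff` must lie in (0, 1].")
  }
  if (!is.null(min_distance_floor) &&
      (min_distance_floor <= 0 || min_distance_floor >= distance_cutoff)) {
    abort("`min_distance_floor` must be positive and below the cutoff.")
  }
  structure(list(distance_cutoff = distance_cutoff, weighting = weighting,
                 min_distance_floor = min_distance_floor),
            class = "collab_config")
}

#' Ecological-mode configuration (Jaccard cutoff 0.15, unweighted)
#' @return A `collab_config`.
#' @export
collab_config_eco <- function() {
  collab_config(distance_cutoff = 0.15, weighting = "uniform",
                min_distance_floor = 1e-9)
}

# distances from test organism to all db organisms usable for scoring
neighbour_distances <- function(test_org, db, tax = NULL, eco_dist = NULL) {
  if (!is.null(tax)) {
    if (!test_org %in% tax$tips) {
      abort(sprintf("Organism '%s' is not in the tree.", test_org))
    }
    pool <- setdiff(intersect(db_organisms(db), tax$tips), test_org)
    d <- tax$dist[test_org, pool]
  } else if (!is.null(eco_dist)) {
    if (!test_org %in% rownames(eco_dist)) {
      abort(sprintf("Organism '%s' is not in the ecological distance matrix.",
                    test_org))
    }
    pool <- setdiff(intersect(db_organisms(db), rownames(eco_dist)), test_org)
    d <- eco_dist[test_org, pool]
  } else {
    abort("Provide `tax` or `eco_dist`.")
  }
  setNames(as.numeric(d), pool)
}

collab_floor <- function(cfg, tax) {
  cfg$min_distance_floor %||%
    (if (!is.null(tax)) 1 / tax$total_leaves else 1e-9)
}

#' Collaborative score of one organism-medium pairing
#'
#' Sum over neighbours o (distance d(test, o) <= cutoff, o != test) that are
#' documented on the medium, of cutoff / max(d, floor) — or of 1 in uniform
#' mode.  The test organism's own pairings are never consulted, so scores
#' for organisms present in the database are honest leave-one-out scores.
#'
#' @param test_org Organism ID (must be in the tree; need not be in `db`).
#' @param medium Medium ID.
#' @param db A [growth_db()].
#' @param tax A [taxonomy_index()] (phylogenetic mode).
#' @param cfg A [collab_config()].
#' @param eco_dist Ecological distance matrix from [eco_distance_matrix()]
#'   (used when `tax` is `NULL`).
#' @return Non-negative score.
#' @export
collab_score <- function(test_org, medium, db, tax = NULL,
                         cfg = collab_config(), eco_dist = NULL) {
  d <- neighbour_distances(test_org, db, tax, eco_dist)
  d <- d[d <= cfg$distance_cutoff]
  if (!length(d)) return(0)
  grown <- db$organism[db$medium == medium]
  d <- d[names(d) %in% grown]
  if (!length(d)) return(0)
  sum(neighbour_weights(d, cfg, collab_floor(cfg, tax)))
}

neighbour_weights <- function(d, cfg, floor) {
  if (cfg$weighting == "uniform") return(rep(1, length(d)))
  cfg$distance_cutoff / pmax(d, floor)
}

#' Rank all media for a test organism
#'
#' Scores every medium that at least one within-cutoff neighbour grows on
#' (all other media score 0 and are omitted).  Ties are broken by medium ID
#' so output order is deterministic.  `is_known` flags pairings already
#' documented for the test organism — these are the leave-one-out true
#' positives, since the scores themselves never use the organism's own rows.
#'
#' @inheritParams collab_score
#' @return Tibble with columns `organism`, `medium`, `score`,
#'   `neighbour_count`, `is_known`, sorted by decreasing score.
#' @export
predict_media <- function(test_org, db, tax = NULL, cfg = collab_config(),
                          eco_dist = NULL) {
  d <- neighbour_distances(test_org, db, tax, eco_dist)
  d <- d[d <= cfg$distance_cutoff]
  own <- db$medium[db$organism == test_org]
  if (!length(d)) {
    return(tibble(organism = character(), medium = character(),
                  score = numeric(), neighbour_count = integer(),
                  is_known = logical()))
  }
  w <- neighbour_weights(d, cfg, collab_floor(cfg, tax))
  rows <- db[db$organism %in% names(d), ]
  rows$weight <- w[rows$organism]
  out <- rows |>
    dplyr::group_by(medium = .data$medium) |>
    dplyr::summarise(score = sum(.data$weight),
                     neighbour_count = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(organism = test_org, is_known = .data$medium %in% own) |>
    dplyr::select("organism", "medium", "score", "neighbour_count",
                  "is_known") |>
    dplyr::arrange(dplyr::desc(.data$score), .data$medium)
  out
}

#' Predict media for many organisms at once
#'
#' @param organisms Organism IDs (default: all database organisms present
#'   in the tree).
#' @inheritParams collab_score
#' @return Row-bound [predict_media()] tibble.
#' @export
predict_media_all <- function(db, tax = NULL, cfg = collab_config(),
                              eco_dist = NULL, organisms = NULL) {
  if (is.null(organisms)) {
    organisms <- if (!is.null(tax)) intersect(db_organisms(db), tax$tips)
                 else intersect(db_organisms(db), rownames(eco_dist))
  }
  dplyr::bind_rows(lapply(organisms, predict_media, db = db, tax = tax,
                          cfg = cfg, eco_dist = eco_dist))
}

#' Popularity-weighted null predictor
#'
#' Pairs organisms with media at random, sampling each side independently
#' with probability proportional to its popularity in the known pairings.
#' This is the reference predictor that any informative recommender must
#' beat: it reproduces the marginal usage statistics of the database while
#' knowing nothing about who is related to whom.
#'
#' @param db A [growth_db()].
#' @param n_predictions Number of pairs to draw.
#' @param seed Integer seed.
#' @param organisms Optional restriction of the organism pool (e.g. the
#'   organisms present in the phylogeny).
#' @return Tibble `organism`, `medium`, `is_known`.
#' @export
null_predict <- function(db, n_predictions, seed = 1, organisms = NULL) {
  stopifnot(is_growth_db(db))
  if (n_predictions <= 0) abort("`n_predictions` must be positive.")
  org_pop <- popularity_table(db, "organism")
  if (!is.null(organisms)) org_pop <- org_pop[org_pop$id %in% organisms, ]
  org_pop <- org_pop[org_pop$popularity > 0, ]
  med_pop <- popularity_table(db, "medium")
  med_pop <- med_pop[med_pop$popularity > 0, ]
  if (!nrow(org_pop) || !nrow(med_pop)) abort("Empty database.")
  local_seed(seed)
  o <- org_pop$id[sample.int(nrow(org_pop), n_predictions, replace = TRUE,
                             prob = org_pop$popularity)]
  m <- med_pop$id[sample.int(nrow(med_pop), n_predictions, replace = TRUE,
                             prob = med_pop$popularity)]
  tibble(organism = o, medium = m,
         is_known = paste(o, m) %in% paste(db$organism, db$medium))
}

#' Partial Spearman correlation
#'
#' Spearman correlation between `x` and `y` after removing the (rank-scale)
#' linear effect of a control variable `z` from both: the Pearson
#' correlation of the residuals of rank(x) ~ rank(z) and rank(y) ~ rank(z),
#' with a t-test on n - 3 degrees of freedom.
#'
#' @param x,y,z Numeric vectors of equal length.
#' @return Tibble with `rho`, `p`, `n`.
#' @export
partial_spearman <- function(x, y, z) {
  keep <- stats::complete.cases(x, y, z)
  x <- rank(x[keep]); y <- rank(y[keep]); z <- rank(z[keep])
  n <- length(x)
  if (n < 4) abort("Partial Spearman needs at least 4 complete observations.")
  rx <- resid(lm(x ~ z))
  ry <- resid(lm(y ~ z))
  # a control identical to x or y leaves numerically-zero residuals
  if (stats::sd(rx) < n * 1e-10 || stats::sd(ry) < n * 1e-10) {
    return(tibble(rho = 0, p = 1, n = n))
  }
  rho <- cor(rx, ry)
  tstat <- rho * sqrt((n - 3) / (1 - rho^2))
  tibble(rho = rho, p = 2 * pt(-abs(tstat), df = n - 3), n = n)
}

#' True-positive fraction by collaborative-score bin
#'
#' Bins predictions by score (logarithmic bins by default, since scores are
#' heavy-tailed) and reports the fraction of predictions per bin that are
#' documented pairings, together with a Spearman correlation of bin score
#' vs true-positive fraction and a partial Spearman controlling for the
#' mean popularity of the predicted media in each bin (media usage
#' frequency itself correlates with score, so the partial correlation shows
#' the score carries signal beyond popularity).
#'
#' @param predictions Tibble from [predict_media_all()] (needs `medium`,
#'   `score`, `is_known`).
#' @param db The [growth_db()] providing ground truth and popularity.
#' @param n_bins Number of score bins.
#' @param log_bins Logarithmic bin edges (default) or linear.
#' @return A `score_bin_summary`: list with `bins` (tibble bin, n,
#'   tp_fraction, mean_score, mean_media_popularity), `rho`, `p`,
#'   `partial_rho`, `partial_p`.
#' @export
evaluate_by_score_bin <- function(predictions, db, n_bins = 10,
                                  log_bins = TRUE) {
  stopifnot(is_growth_db(db))
  pred <- predictions[predictions$score > 0, ]
  if (!nrow(pred)) abort("No scored predictions to evaluate.")
  med_pop <- popularity_table(db, "medium")
  pred$media_popularity <- med_pop$popularity[match(pred$medium, med_pop$id)]

  s <- pred$score
  edges <- if (log_bins) {
    exp(seq(log(min(s)), log(max(s)), length.out = n_bins + 1))
  } else {
    seq(min(s), max(s), length.out = n_bins + 1)
  }
  edges <- unique(edges)
  if (length(edges) < 2) {
    pred$bin <- factor(1)
  } else {
    pred$bin <- cut(s, edges, include.lowest = TRUE)
  }
  bins <- pred |>
    dplyr::group_by(bin = .data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     tp_fraction = mean(.data$is_known),
                     mean_score = mean(.data$score),
                     mean_media_popularity = mean(.data$media_popularity),
                     .groups = "drop")
  if (nrow(bins) < 3) {
    # degenerate score distribution: bins are still reported, but no
    # correlation can be estimated across fewer than 3 points
    warn("Fewer than 3 non-empty score bins; correlations are NA.")
    rho <- p <- partial_rho <- partial_p <- NA_real_
  } else {
    ct <- suppressWarnings(cor.test(bins$mean_score, bins$tp_fraction,
                                    method = "spearman"))
    rho <- unname(ct$estimate); p <- ct$p.value
    part <- partial_spearman(bins$mean_score, bins$tp_fraction,
                             bins$mean_media_popularity)
    partial_rho <- part$rho; partial_p <- part$p
  }
  structure(list(bins = bins, rho = rho, p = p,
                 partial_rho = partial_rho, partial_p = partial_p),
            class = "score_bin_summary")
}

#' @export
print.score_bin_summary <- function(x, ...) {
  cat(sprintf(
    "<score_bin_summary: %d bins; rho = %.3f (p = %s), partial rho = %.3f (p = %s)>\n",
    nrow(x$bins), x$rho, format(x$p, digits = 3),
    x$partial_rho, format(x$partial_p, digits = 3)))
  print(x$bins)
  invisible(x)
}

#' @export
tidy.score_bin_summary <- function(x, ...) x$bins

#' @export
glance.score_bin_summary <- function(x, ...) {
  tibble(rho = x$rho, p = x$p, partial_rho = x$partial_rho,
         partial_p = x$partial_p, n_bins = nrow(x$bins))
}

#' @export
autoplot.score_bin_summary <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$mean_score, y = .data$tp_fraction,
                               size = .data$n)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "collaborative score (bin mean)",
                  y = "true-positive fraction", size = "predictions") +
    ggplot2::theme_minimal()
}

#' Permutation test of predictor enrichment over the popularity null
#'
#' Compares the number of true positives among a predictor's pairings with
#' the distribution obtained from `k` popularity-weighted null prediction
#' sets of matched size.  The empirical p-value is
#' (1 + #\{null TP >= observed TP\}) / (k + 1).
#'
#' @param predictions Tibble with `organism`, `medium`, `is_known`.
#' @param db A [growth_db()].
#' @param k Number of null replicates.
#' @param seed Integer seed.
#' @param organisms Organism pool restriction passed to [null_predict()].
#' @return Tibble with `tp_observed`, `tp_null_mean`, `enrichment_ratio`,
#'   `p_value`, `k`.
#' @export
enrichment_vs_null <- function(predictions, db, k = 199, seed = 1,
                               organisms = NULL) {
  n_pred <- nrow(predictions)
  if (!n_pred) abort("No predictions supplied.")
  tp_obs <- sum(predictions$is_known)
  tp_null <- vapply(seq_len(k), function(i) {
    sum(null_predict(db, n_pred, seed = (seed * 1009 + i) %% 2147483647,
                     organisms = organisms)$is_known)
  }, 0L)
  tibble(tp_observed = tp_obs, tp_null_mean = mean(tp_null),
         enrichment_ratio = tp_obs / max(mean(tp_null), .Machine$double.eps),
         p_value = (1 + sum(tp_null >= tp_obs)) / (k + 1), k = k)
}
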