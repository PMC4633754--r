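#' Transitive growth patterns
#'
#' A transitive pattern is a witness triple over three distinct organisms
#' A, B, C and three distinct media m1, m2, m3 such that A and B both grow
#' on m1, B and C both grow on m2, and C grows on m3.  If sharing of media
#' is a transitive relation, the pattern predicts that A grows on m3.
#' Before mining, media with fewer than 3 or more than 100 organisms are
#' excluded: near-empty media cannot witness sharing and very popular media
#' would make every organism "related".
#'
#' `mine_patterns()` samples exactly `n` patterns uniformly at random,
#' without replacement, from the complete universe of valid tuples.  The
#' universe is enumerated by sparse joins over the co-growth structure
#' (tuples are counted per media triple and only the sampled triples are
#' materialised), which makes exact uniform sampling tractable where naive
#' rejection sampling would practically never accept.
#'
#' @param db A [growth_db()].
#' @param n Number of patterns to sample.
#' @param seed Integer seed; sampling is reproducible bit-for-bit.
#' @param min_orgs,max_orgs Media popularity filter (defaults 3 and 100).
#' @return Tibble with columns `A`, `B`, `C`, `m1`, `m2`, `m3`.  If fewer
#'   than `n` valid tuples exist, all of them are returned with a warning.
#' @export
mine_patterns <- function(db, n = 1000, seed = 1, min_orgs = 3, max_orgs = 100) {
  stopifnot(is_growth_db(db))
  uni <- tuple_universe(db, min_orgs, max_orgs)
  empty <- tibble(A = character(), B = character(), C = character(),
                  m1 = character(), m2 = character(), m3 = character())
  if (!length(uni$triples)) {
    warn("No valid transitive tuples in the database.")
    return(empty)
  }
  total <- sum(vapply(uni$triples, function(t) t$count, 0))
  if (total <= n) {
    if (total < n) {
      warn(sprintf("Only %d valid tuples exist (requested %d); returning all.",
                   total, n))
    }
    return(dplyr::bind_rows(lapply(uni$triples, materialise_triple)))
  }
  local_seed(seed)
  counts <- vapply(uni$triples, function(t) t$count, 0)
  alloc <- hyper_allocate(counts, n)
  picked <- which(alloc > 0)
  dplyr::bind_rows(lapply(picked, function(i) {
    tups <- materialise_triple(uni$triples[[i]])
    tups[sample.int(nrow(tups), alloc[i]), ]
  }))
}

# Media popularity filter + sparse co-growth structure shared by the
# transitivity operations.
tuple_universe <- function(db, min_orgs = 3, max_orgs = 100) {
  pop <- popularity_table(db, "medium")
  keep_media <- pop$id[pop$popularity >= min_orgs & pop$popularity <= max_orgs]
  sub <- db[db$medium %in% keep_media, ]
  media_orgs <- split(sub$organism, sub$medium)
  org_media <- split(sub$medium, sub$organism)

  # sharing sets S_xy for ordered media pairs that co-occur in some organism
  pair_rows <- lapply(org_media[lengths(org_media) >= 2], function(ms) {
    cmb <- combn(sort(ms), 2)
    tibble(x = c(cmb[1, ], cmb[2, ]), y = c(cmb[2, ], cmb[1, ]))
  })
  if (!length(pair_rows)) return(list(triples = list(), media_orgs = media_orgs))
  pairs <- dplyr::bind_rows(pair_rows, .id = "org")
  share <- split(pairs$org, paste(pairs$x, pairs$y, sep = "\r"))
  share <- lapply(share, unique)
  pair_keys <- strsplit(names(share), "\r", fixed = TRUE)
  firsts <- vapply(pair_keys, `[`, "", 1)
  seconds <- vapply(pair_keys, `[`, "", 2)
  by_first <- split(seq_along(share), firsts)

  triples <- list()
  for (i in seq_along(share)) {
    x <- firsts[i]; y <- seconds[i]
    S1 <- share[[i]]
    Ox <- media_orgs[[x]]
    for (j in by_first[[y]] %||% integer()) {
      z <- seconds[j]
      if (z == x || z == y) next
      S2 <- share[[j]]
      cnt <- count_triple(S1, Ox, S2)
      if (cnt > 0) {
        triples[[length(triples) + 1]] <-
          list(x = x, y = y, z = z, S1 = S1, Ox = Ox, S2 = S2, count = cnt)
      }
    }
  }
  # deterministic order regardless of hash internals
  ord <- order(vapply(triples, function(t) paste(t$x, t$y, t$z), ""))
  list(triples = triples[ord], media_orgs = media_orgs)
}

# Number of tuples (B in S1, A in Ox\{B}, C in S2\{A,B}) for one media triple.
count_triple <- function(S1, Ox, S2) {
  s <- length(S2)
  n_A <- length(Ox) - 1L              # B is always in Ox (B grows on x)
  overlap <- length(intersect(S2, Ox))
  sum(vapply(S1, function(B) {
    s_B <- s - (B %in% S2)
    q_B <- overlap - (B %in% S2)      # members of Ox\{B} that sit in S2\{B}
    n_A * s_B - q_B
  }, 0))
}

materialise_triple <- function(t) {
  grid <- expand.grid(B = t$S1, A = t$Ox, C = t$S2,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$A != grid$B & grid$C != grid$A & grid$C != grid$B, ]
  tibble(A = grid$A, B = grid$B, C = grid$C,
         m1 = t$x, m2 = t$y, m3 = t$z)
}

# Exact uniform allocation of n draws (without replacement) across strata
# with the given sizes: sequential hypergeometric draws.
hyper_allocate <- function(counts, n) {
  alloc <- integer(length(counts))
  remaining <- sum(counts)
  for (i in seq_along(counts)) {
    if (n == 0) break
    k <- stats::rhyper(1, counts[i], remaining - counts[i], n)
    alloc[i] <- k
    n <- n - k
    remaining <- remaining - counts[i]
  }
  alloc
}

# set.seed scoped to the calling function, restoring global RNG state.
local_seed <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  withr::defer({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = env)
}

#' Evaluate transitivity of media sharing against a random control
#'
#' For `n` mined patterns, the test counts how often the implied pairing
#' (A, m3) is already documented; the control replaces A with a uniformly
#' random organism X (distinct from A, B, C) and counts (X, m3).  The excess
#' of test positives over the control is scored with an upper-tail binomial
#' probability P(X >= positives_test | n, p), where the null rate defaults
#' to `max(positives_control, 1) / n` — a conservative estimate that never
#' degenerates to zero.
#'
#' @inheritParams mine_patterns
#' @param null_rate Null success probability; default estimates it from the
#'   control as described above.
#' @return A `transitivity_evaluation`: list with `n_tests`,
#'   `positives_test`, `positives_control`, `null_rate`, `binomial_p`,
#'   `log10_p`, `seed`, and the sampled `patterns`.
#' @export
evaluate_transitivity <- function(db, n = 1000, seed = 1, null_rate = NULL,
                                  min_orgs = 3, max_orgs = 100) {
  if (n <= 0) abort("`n` must be positive.")
  patterns <- mine_patterns(db, n, seed, min_orgs, max_orgs)
  if (!nrow(patterns)) abort("No transitive patterns could be mined.")
  n_eff <- nrow(patterns)

  key <- paste(db$organism, db$medium)
  test_pos <- paste(patterns$A, patterns$m3) %in% key

  local_seed(seed + 1L)
  orgs <- db_organisms(db)
  control_pos <- vapply(seq_len(n_eff), function(i) {
    pool <- setdiff(orgs, c(patterns$A[i], patterns$B[i], patterns$C[i]))
    x <- pool[sample.int(length(pool), 1)]
    paste(x, patterns$m3[i]) %in% key
  }, TRUE)

  k_test <- sum(test_pos)
  k_ctrl <- sum(control_pos)
  p0 <- null_rate %||% (max(k_ctrl, 1) / n_eff)
  bt <- binomial_upper_tail(k_test, n_eff, p0)
  structure(list(n_tests = n_eff, positives_test = k_test,
                 positives_control = k_ctrl, null_rate = p0,
                 binomial_p = bt$p, log10_p = bt$log10_p, seed = seed,
                 patterns = patterns),
            class = "transitivity_evaluation")
}

#' @export
print.transitivity_evaluation <- function(x, ...) {
  cat(sprintf(
    "<transitivity_evaluation: %d/%d test positives vs %d/%d control; binomial p = %s (log10 = %.1f)>\n",
    x$positives_test, x$n_tests, x$positives_control, x$n_tests,
    format(x$binomial_p, digits = 3), x$log10_p))
  invisible(x)
}

#' @export
tidy.transitivity_evaluation <- function(x, ...) {
  tibble(quantity = c("positives_test", "positives_control"),
         count = c(x$positives_test, x$positives_control),
         n = x$n_tests,
         fraction = c(x$positives_test, x$positives_control) / x$n_tests)
}

#' @export
glance.transitivity_evaluation <- function(x, ...) {
  tibble(n_tests = x$n_tests, positives_test = x$positives_test,
         positives_control = x$positives_control, null_rate = x$null_rate,
         binomial_p = x$binomial_p, log10_p = x$log10_p, seed = x$seed)
}

#' Upper-tail binomial probability, computed in log space
#'
#' Exact tail sum P(X >= k | n, p) accumulated from log binomial densities
#' with a log-sum-exp reduction, so the log of the tail stays finite far
#' below the smallest positive double (the probability itself is also
#' returned and may underflow to 0 for extreme inputs).
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials.
#' @param p Success probability in (0, 1] (p = 1 gives a tail of 1, the
#'   degenerate saturated case).
#' @return List with `p` (probability, possibly underflowed) and `log10_p`.
#' @examples
#' binomial_upper_tail(2, 3, 0.5)   # 0.5
#' binomial_upper_tail(694, 1000, 0.001)$log10_p
#' @export
binomial_upper_tail <- function(k, n, p) {
  if (!is.finite(p) || p <= 0 || p > 1) abort("`p` must lie in (0, 1].")
  if (k < 0 || k > n || n < 1) abort("Need 0 <= k <= n with n >= 1.")
  if (k == 0) return(list(p = 1, log10_p = 0))
  lp <- dbinom(k:n, n, p, log = TRUE)
  mx <- max(lp)
  log_p <- mx + log(sum(exp(lp - mx)))
  list(p = exp(log_p), log10_p = log_p / log(10))
}

#' Predict new pairings implied by transitivity
#'
#' Every (A, m3) implied by at least one valid transitive pattern and not
#' already documented becomes a prediction, deduplicated at the pair level
#' and annotated with its witness count (the number of distinct patterns
#' implying it).  Witness counts are computed in closed form per media
#' triple, so the full pattern universe never has to be materialised.
#'
#' @inheritParams mine_patterns
#' @return Tibble with columns `organism`, `medium`, `witnesses`, sorted by
#'   decreasing witness count.
#' @export
predict_transitive <- function(db, min_orgs = 3, max_orgs = 100) {
  stopifnot(is_growth_db(db))
  uni <- tuple_universe(db, min_orgs, max_orgs)
  if (!length(uni$triples)) {
    return(tibble(organism = character(), medium = character(),
                  witnesses = integer()))
  }
  per_triple <- lapply(uni$triples, function(t) {
    A <- t$Ox
    s <- length(t$S2)
    n_B <- length(t$S1) - as.integer(A %in% t$S1)
    in_S2 <- as.integer(A %in% t$S2)
    olap <- length(intersect(t$S1, t$S2))
    q <- olap - as.integer(A %in% intersect(t$S1, t$S2))
    w <- n_B * (s - in_S2) - q
    tibble(organism = A, medium = t$z, witnesses = w)[w > 0, ]
  })
  out <- dplyr::bind_rows(per_triple) |>
    dplyr::group_by(.data$organism, .data$medium) |>
    dplyr::summarise(witnesses = sum(.data$witnesses), .groups = "drop")
  known <- paste(db$organism, db$medium)
  out <- out[!paste(out$organism, out$medium) %in% known, ]
  dplyr::arrange(out, dplyr::desc(.data$witnesses), .data$organism, .data$medium)
}
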