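#' Similarity between two compiled media
#'
#' Component identity is taken at the constituent-compound level of the
#' compiled representation, so spelling variants of the same salt can never
#' mismatch; complex components match by their category tag (which is how
#' they are identified after compilation).  Two metrics are supported:
#' `jaccard` (shared components / union) and `component_count` (number of
#' shared components).
#'
#' @param mA,mB `medium_variant` objects, or plain character vectors of
#'   component IDs.
#' @param metric `"jaccard"` or `"component_count"`.
#' @return Similarity value.
#' @export
media_similarity <- function(mA, mB, metric = c("jaccard", "component_count")) {
  metric <- match.arg(metric)
  a <- component_set(mA)
  b <- component_set(mB)
  shared <- length(intersect(a, b))
  if (metric == "component_count") return(shared)
  u <- length(union(a, b))
  if (u == 0) abort("Jaccard similarity of two empty media is undefined.")
  shared / u
}

component_set <- function(x) {
  if (inherits(x, "medium_variant")) return(unique(x$components$compound_id))
  if (is.character(x)) return(unique(x))
  abort("Expected a medium_variant or a character vector of component IDs.")
}

#' Do two organisms match on their media?
#'
#' Three modes, from strictest to loosest interpretation of "sharing" media:
#' `exact` requires at least one identical medium ID; `union` pools the
#' component sets of all media each organism grows on and compares the two
#' pooled sets; `best_match` takes the maximum similarity over all pairs of
#' their media.  The latter two modes compare with [media_similarity()]
#' against a threshold.  For the `component_count` metric only media with at
#' least `min_components` components are compared and thresholds above
#' `min_components` are rejected, since a count threshold larger than a
#' medium's size could never be met even by an identical medium.
#'
#' @param orgA,orgB Organism IDs.
#' @param db A [growth_db()].
#' @param media_components Named list mapping medium ID to a character
#'   vector of component IDs (or a [media_library()]).  Needed for `union`
#'   and `best_match` modes.
#' @param mode `"exact"`, `"union"` or `"best_match"`.
#' @param metric Passed to [media_similarity()].
#' @param threshold Similarity threshold for the partial-match modes.
#' @param min_components Size filter for the `component_count` metric.
#' @return `TRUE`/`FALSE`, or `NA` when an organism has no (eligible) media.
#' @export
pair_match <- function(orgA, orgB, db, media_components = NULL,
                       mode = c("exact", "union", "best_match"),
                       metric = "jaccard", threshold = 0.5,
                       min_components = 15) {
  mode <- match.arg(mode)
  mA <- db$medium[db$organism == orgA]
  mB <- db$medium[db$organism == orgB]
  if (!length(mA) || !length(mB)) return(NA)
  if (mode == "exact") return(length(intersect(mA, mB)) > 0)

  comp_of <- media_component_lookup(media_components)
  if (metric == "component_count") {
    if (threshold > min_components) {
      abort(sprintf("component_count thresholds above %d are not allowed.",
                    min_components))
    }
    keep <- function(ids) ids[vapply(ids, function(m)
      length(comp_of(m)) >= min_components, TRUE)]
    mA <- keep(mA); mB <- keep(mB)
    if (!length(mA) || !length(mB)) return(NA)
  }
  if (mode == "union") {
    a <- unique(unlist(lapply(mA, comp_of)))
    b <- unique(unlist(lapply(mB, comp_of)))
    return(media_similarity(a, b, metric) >= threshold)
  }
  best <- max(vapply(mA, function(x) {
    max(vapply(mB, function(y) {
      media_similarity(comp_of(x), comp_of(y), metric)
    }, 0))
  }, 0))
  best >= threshold
}

media_component_lookup <- function(media_components) {
  if (is.null(media_components)) {
    abort("Partial-match modes need `media_components`.")
  }
  if (inherits(media_components, "media_library")) {
    comps <- split(media_components$components$compound_id,
                   media_components$components$medium_id)
    return(function(m) unique(comps[[m]]) %||% character())
  }
  function(m) unique(media_components[[m]]) %||% character()
}

#' Binned association between organism distance and media sharing
#'
#' The classic sanity check behind neighbour-based media recommendation:
#' bin all organism pairs by phylogenetic (or ecological) distance and, per
#' bin, compute the fraction of pairs sharing at least one medium (or
#' passing a partial-match threshold).  A Spearman correlation over the
#' occupied bins (bin midpoint distance vs sharing fraction) summarises the
#' trend; with real phylogenetic signal the fraction falls with distance, so
#' rho is negative on the distance scale (equivalently, positive against
#' similarity = 1 - distance).
#'
#' Organism pairs where either member has no media cannot share one by
#' construction; they are excluded and their count reported.
#'
#' @param db A [growth_db()].
#' @param tax A [taxonomy_index()], or `NULL` when `envs` is given.
#' @param envs An [environment_table()] for ecological distance (used when
#'   `tax` is `NULL`).
#' @param n_bins Number of bins.
#' @param binning `"equal_width"` on distance, or `"count_balanced"`
#'   (equal-frequency).
#' @param mode,metric,threshold,media_components Passed to [pair_match()].
#' @return A `distance_bin_summary`: list with `bins` (tibble bin_lo,
#'   bin_hi, n_pairs, fraction_sharing), `rho`, `p`, `n_pairs_used`,
#'   `n_pairs_excluded`, `degenerate`.
#' @export
binned_association <- function(db, tax = NULL, envs = NULL, n_bins = 10,
                               binning = c("equal_width", "count_balanced"),
                               mode = "exact", metric = "jaccard",
                               threshold = 0.5, media_components = NULL) {
  binning <- match.arg(binning)
  stopifnot(is_growth_db(db))
  if (is.null(tax) && is.null(envs)) abort("Provide `tax` or `envs`.")

  if (!is.null(tax)) {
    orgs <- intersect(db_organisms(db), tax$tips)
    dmat <- tax$dist[orgs, orgs, drop = FALSE]
  } else {
    orgs <- intersect(db_organisms(db), unique(envs$organism))
    dmat <- eco_distance_matrix(envs, orgs)
  }
  with_media <- orgs[orgs %in% db$organism]
  excluded <- length(orgs) - length(with_media)
  if (length(with_media) < 2) abort("Fewer than two organisms with media.")
  orgs <- with_media
  dmat <- dmat[orgs, orgs, drop = FALSE]

  idx <- which(upper.tri(dmat), arr.ind = TRUE)
  d <- dmat[idx]
  share <- if (mode == "exact") {
    inc <- incidence_matrix(db, organisms = orgs)
    storage.mode(inc) <- "numeric"
    (inc %*% t(inc))[idx] > 0
  } else {
    mapply(function(i, j) pair_match(orgs[i], orgs[j], db, media_components,
                                     mode = mode, metric = metric,
                                     threshold = threshold),
           idx[, 1], idx[, 2])
  }
  keep <- !is.na(share)
  d <- d[keep]; share <- share[keep]

  edges <- if (binning == "equal_width") {
    seq(min(d), max(d), length.out = n_bins + 1)
  } else {
    unique(stats::quantile(d, probs = seq(0, 1, length.out = n_bins + 1)))
  }
  if (length(edges) < 3) abort("All pairs fall into a single bin.")
  bin <- cut(d, edges, include.lowest = TRUE)
  tab <- tibble(
    bin_lo = head(edges, -1), bin_hi = edges[-1],
    n_pairs = as.integer(table(bin)),
    fraction_sharing = as.numeric(tapply(share, bin, mean))
  )
  occ <- tab[tab$n_pairs > 0, ]
  if (nrow(occ) < 2) abort("Fewer than two occupied bins.")

  degenerate <- stats::sd(occ$fraction_sharing) == 0
  if (degenerate) {
    rho <- NA_real_; p <- NA_real_
  } else {
    ct <- suppressWarnings(cor.test((occ$bin_lo + occ$bin_hi) / 2,
                                    occ$fraction_sharing, method = "spearman"))
    rho <- unname(ct$estimate); p <- ct$p.value
  }
  structure(list(bins = tab, rho = rho, p = p,
                 n_pairs_used = length(d), n_pairs_excluded = excluded,
                 degenerate = degenerate),
            class = "distance_bin_summary")
}

#' @export
print.distance_bin_summary <- function(x, ...) {
  cat(sprintf("<distance_bin_summary: %d bins, %d pairs; rho = %s, p = %s%s>\n",
              nrow(x$bins), x$n_pairs_used,
              format(x$rho, digits = 3), format(x$p, digits = 3),
              if (x$degenerate) " (degenerate)" else ""))
  print(x$bins)
  invisible(x)
}

#' @export
tidy.distance_bin_summary <- function(x, ...) x$bins

#' @export
glance.distance_bin_summary <- function(x, ...) {
  tibble(rho = x$rho, p = x$p, n_pairs = x$n_pairs_used,
         n_pairs_excluded = x$n_pairs_excluded, degenerate = x$degenerate)
}

#' Bubble plot of a binned distance-sharing association
#'
#' @param object A `distance_bin_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.distance_bin_summary <- function(object, ...) {
  occ <- object$bins[object$bins$n_pairs > 0, ]
  occ$mid <- (occ$bin_lo + occ$bin_hi) / 2
  ggplot2::ggplot(occ, ggplot2::aes(x = .data$mid, y = .data$fraction_sharing,
                                    size = .data$n_pairs)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "distance (bin midpoint)",
                  y = "fraction of pairs sharing a medium",
                  size = "pairs") +
    ggplot2::theme_minimal()
}
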