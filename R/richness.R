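#' Richness scoring configuration
#'
#' Medium "richness" is a weighted g/l sum over the complex components of a
#' medium (peptone, meat extract, ...) plus a configurable list of rich
#' *defined* components (typically sugars and other bulk carbon sources),
#' capturing the total nutritional carbon on offer.  Scores map to three
#' classes at 5 and 15 g/l; a boundary score goes to the lower class.
#' Category weights default to 1.0 per g/l for every category; they are
#' deliberately a configuration value, not a constant, since the
#' appropriate weighting of e.g. meat- versus plant-derived digests is an
#' empirical judgement.  The defaults here are uniform and should be read
#' as a documented starting point, not a canonical table.
#'
#' @param weights Named numeric vector: complex category -> weight per g/l.
#'   Categories absent from the vector fall back to `default_weight`.
#' @param default_weight Weight for unlisted categories.
#' @param low_cutoff,high_cutoff Class boundaries in g/l (defaults 5, 15).
#' @param rich_defined Character vector of defined constituent IDs whose
#'   g/l also counts toward richness (weight 1).
#' @return A `richness_config`.
#' @export
richness_config <- function(weights = NULL, default_weight = 1,
                            low_cutoff = 5, high_cutoff = 15,
                            rich_defined = c("glucose", "sucrose", "lactose",
                                             "starch", "glycerol", "xylan")) {
  if (low_cutoff <= 0 || high_cutoff <= low_cutoff) {
    abort("Cutoffs must be positive with low_cutoff < high_cutoff.")
  }
  structure(list(weights = weights %||% numeric(),
                 default_weight = default_weight,
                 low_cutoff = low_cutoff, high_cutoff = high_cutoff,
                 rich_defined = rich_defined),
            class = "richness_config")
}

#' Richness score and class of a compiled medium
#'
#' @param medium A `medium_variant` or a components tibble (as produced by
#'   [to_standard_units()]).
#' @param cfg A [richness_config()].
#' @return Tibble with `score` (weighted g/l) and `class`
#'   (`low`/`medium`/`high`).
#' @examples
#' m <- medium_variant("M1", components = tibble::tibble(
#'   compound_id = "complex-meat", amount = 10, unit = "g_per_l",
#'   class = "complex", category = "meat", g_per_l = 10))
#' medium_richness(m)   # 10 g/l -> medium
#' @export
medium_richness <- function(medium, cfg = richness_config()) {
  comps <- if (inherits(medium, "medium_variant")) medium$components else medium
  cx <- comps[comps$class == "complex" & comps$unit == "g_per_l", ]
  w <- vapply(cx$category, function(cat) {
    if (!is.null(cfg$weights) && cat %in% names(cfg$weights)) {
      cfg$weights[[cat]]
    } else cfg$default_weight
  }, 0)
  score <- sum(w * cx$g_per_l)
  rd <- comps[comps$compound_id %in% cfg$rich_defined &
                comps$unit == "mol_per_l" & !is.na(comps$g_per_l), ]
  score <- score + sum(rd$g_per_l)
  tibble(score = score, class = richness_class(score, cfg))
}

richness_class <- function(score, cfg = richness_config()) {
  dplyr::case_when(score <= cfg$low_cutoff ~ "low",
                   score <= cfg$high_cutoff ~ "medium",
                   TRUE ~ "high")
}

#' Richness classes for a whole media library
#'
#' @param library A [media_library()], or a list of `medium_variant`s.
#' @param cfg A [richness_config()].
#' @return Tibble `medium_id`, `score`, `class`.
#' @export
classify_media_richness <- function(library, cfg = richness_config()) {
  variants <- if (inherits(library, "media_library")) library$variants else library
  dplyr::bind_rows(lapply(variants, function(v) {
    dplyr::mutate(medium_richness(v, cfg), medium_id = v$medium_id, .before = 1)
  }))
}

#' Predict an organism's richness preference
#'
#' Sums the collaborative scores of the (salt/oxygen-filtered) predicted
#' media falling in each richness class and picks the class with the
#' highest combined score.  Since the underlying scores are leave-one-out,
#' the preference never uses the organism's own documented pairings.  Ties
#' break toward the lower richness class — the conservative choice when
#' designing a starting medium.
#'
#' @param predictions Filtered prediction tibble for one or more organisms
#'   (columns `organism`, `medium`, `score`).
#' @param media_richness Tibble `medium_id`, `class` (from
#'   [classify_media_richness()]).
#' @return Tibble `organism`, `preference` (`low`/`medium`/`high`, or
#'   `"unknown"` for organisms with no scored predictions), and the three
#'   per-class score sums.
#' @export
organism_richness_preference <- function(predictions, media_richness) {
  cls <- setNames(media_richness$class, media_richness$medium_id)
  lvl <- c("low", "medium", "high")
  predictions |>
    dplyr::mutate(class = unname(cls[.data$medium])) |>
    dplyr::group_by(organism = .data$organism) |>
    dplyr::summarise(
      score_low = sum(.data$score[.data$class %in% "low"]),
      score_medium = sum(.data$score[.data$class %in% "medium"]),
      score_high = sum(.data$score[.data$class %in% "high"]),
      .groups = "drop") |>
    dplyr::mutate(preference = purrr::pmap_chr(
      list(.data$score_low, .data$score_medium, .data$score_high),
      function(lo, me, hi) {
        s <- c(low = lo, medium = me, high = hi)
        if (all(s == 0)) return("unknown")
        lvl[which.max(s[lvl])]        # which.max takes the first (lowest) tie
      })) |>
    dplyr::select("organism", "preference", dplyr::starts_with("score_"))
}

#' Gold-standard richness preferences from documented pairings
#'
#' An organism gets a gold-standard preference only when *all* of its
#' documented media fall in a single richness class; organisms with mixed
#' or no documented classes are omitted (a partial mapping, by design).
#'
#' @param db A [growth_db()].
#' @param media_richness Tibble `medium_id`, `class`.
#' @return Tibble `organism`, `gold_class`.
#' @export
gold_standard_preferences <- function(db, media_richness) {
  cls <- setNames(media_richness$class, media_richness$medium_id)
  db |>
    as_tibble() |>
    dplyr::mutate(class = unname(cls[.data$medium])) |>
    dplyr::filter(!is.na(.data$class)) |>
    dplyr::group_by(organism = .data$organism) |>
    dplyr::summarise(n_classes = dplyr::n_distinct(.data$class),
                     gold_class = .data$class[1], .groups = "drop") |>
    dplyr::filter(.data$n_classes == 1) |>
    dplyr::select("organism", "gold_class")
}

#' Component-category enrichment among predicted media
#'
#' Two-sided Wilcoxon rank-sum test comparing the collaborative scores of
#' predicted media that contain at least one component of the given
#' category against those that lack it.  A positive direction means the
#' containing group scores higher — the signature of a category the
#' organisms need.  The exact null distribution is used for small untied
#' samples and the tie-corrected normal approximation otherwise (the
#' standard [stats::wilcox.test()] behaviour).
#'
#' @param predictions Prediction tibble (`medium`, `score`).
#' @param media_categories Tibble `medium_id`, `category` (long form: one
#'   row per category present in a medium), or a named list medium ID ->
#'   character vector of categories.
#' @param category Category to test.
#' @return Tibble with `category`, `n_containing`, `n_lacking`,
#'   `median_containing`, `median_lacking`, `direction`, `statistic`, `p`.
#' @export
category_enrichment <- function(predictions, media_categories, category) {
  if (is.data.frame(media_categories)) {
    has <- unique(media_categories$medium_id[
      media_categories$category == category])
  } else {
    has <- names(media_categories)[vapply(media_categories, function(x)
      category %in% x, TRUE)]
  }
  contains <- predictions$score[predictions$medium %in% has]
  lacks <- predictions$score[!predictions$medium %in% has]
  if (!length(contains) || !length(lacks)) {
    abort(sprintf("Category '%s': both groups must be non-empty (containing: %d, lacking: %d).",
                  category, length(contains), length(lacks)))
  }
  wt <- suppressWarnings(wilcox.test(contains, lacks, alternative = "two.sided"))
  tibble(category = category,
         n_containing = length(contains), n_lacking = length(lacks),
         median_containing = stats::median(contains),
         median_lacking = stats::median(lacks),
         direction = ifelse(stats::median(contains) >= stats::median(lacks),
                            "higher_in_containing", "higher_in_lacking"),
         statistic = unname(wt$statistic), p = wt$p.value)
}
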