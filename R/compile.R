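#' Resolve a recipe's volume mode (fill or scale)
#'
#' Medium recipes conventionally list the quantities needed to produce one
#' litre, so a recipe without a declared volume is "filled" to 1 l and its
#' amounts read directly as per-litre values.  When a recipe declares a
#' final volume that is genuinely different from 1 l, its composition must
#' instead be *scaled* by 1 l / declared volume.  The general rule here is:
#' fill when no volume is declared or the declared volume is within 1% of
#' 1 l; scale otherwise.  A per-medium override table is authoritative and
#' wins over the rule, mirroring the practice of resolving ambiguous recipes
#' by curation.
#'
#' @param recipe A `raw_recipe`.
#' @param overrides Optional data frame with columns `medium_id`, `mode`
#'   (`"fill"` or `"scale"`).
#' @param unit_map Unit map for interpreting the declared volume.
#' @return List with `mode` and `multiplier` (scale factor to 1 l).
#' @export
resolve_volume <- function(recipe, overrides = NULL,
                           unit_map = default_unit_map()) {
  stopifnot(inherits(recipe, "raw_recipe"))
  mode <- NULL
  if (!is.null(overrides) && nrow(overrides)) {
    hit <- which(overrides$medium_id == recipe$medium_id)
    if (length(hit)) mode <- overrides$mode[hit[1]]
  }
  vol_l <- if (is.null(recipe$declared_volume)) NULL else {
    volume_in_litres(recipe$declared_volume$amount,
                     recipe$declared_volume$unit, unit_map)
  }
  if (is.null(mode)) {
    mode <- if (is.null(vol_l) || abs(vol_l - 1) <= 0.01) "fill" else "scale"
  }
  if (!mode %in% c("fill", "scale")) {
    abort(sprintf("Unknown volume mode '%s' for medium '%s'.", mode, recipe$medium_id))
  }
  if (mode == "fill") {
    return(list(mode = "fill", multiplier = 1))
  }
  if (is.null(vol_l) || vol_l == 0) {
    abort(sprintf("Medium '%s' is in scale mode but has no usable declared volume.",
                  recipe$medium_id))
  }
  list(mode = "scale", multiplier = 1 / vol_l)
}

#' Unpack submedium cross-references into a flat component list
#'
#' Submedia behave like nested parentheses: the per-litre composition of a
#' referenced medium is computed recursively (including that medium's own
#' fill/scale resolution), multiplied by the referenced volume fraction, and
#' merged into the parent.  Volumes of *individual compounds* are converted
#' to grams with the 1 ml = 1 g density convention; volumes of submedia are
#' never converted that way — they remain volume fractions.  Identical
#' compounds contributed at several nesting levels are summed.
#'
#' The top-level recipe's own volume multiplier is *not* applied here; that
#' happens in [compile_medium()], so this function reports amounts per litre
#' of the recipe as written.
#'
#' @param recipe A `raw_recipe` (or a medium ID resolvable in `recipe_set`).
#' @param recipe_set Named list of `raw_recipe`s (from [parse_recipe_set()]).
#' @param overrides Fill/scale override table (see [resolve_volume()]).
#' @param unit_map Unit map.
#' @return Tibble with columns `raw_name`, `amount`, `unit` where `unit` is
#'   one of `g_per_l`, `mol_per_l`, `trace`, `gas_substrate`.
#' @examples
#' rs <- parse_recipe_set(c(
#'   "medium: a", "ref: b @ 10 ml",
#'   "medium: b", "ref: c @ 15 ml",
#'   "medium: c", "X @ 5 ml"))
#' unpack_references(rs[["a"]], rs)   # X contributes 0.00075 g/l
#' @export
unpack_references <- function(recipe, recipe_set = list(), overrides = NULL,
                              unit_map = default_unit_map()) {
  if (is.character(recipe)) recipe <- fetch_recipe(recipe, recipe_set)
  stopifnot(inherits(recipe, "raw_recipe"))
  flat <- unpack_one(recipe, recipe_set, overrides, unit_map,
                     stack = character(), top = TRUE)
  sum_components(flat)
}

fetch_recipe <- function(id, recipe_set) {
  if (!id %in% names(recipe_set)) {
    abort(sprintf("Referenced medium '%s' is not in the recipe set.", id))
  }
  recipe_set[[id]]
}

unpack_one <- function(recipe, recipe_set, overrides, unit_map, stack, top) {
  id <- recipe$medium_id %||% "<anonymous>"
  if (id %in% stack) {
    abort(sprintf("Cyclic medium reference: %s.",
                  paste(c(stack, id), collapse = " -> ")))
  }
  stack <- c(stack, id)

  own <- standardize_lines(recipe$lines, unit_map)
  parts <- list(own)
  for (i in seq_len(nrow(recipe$refs))) {
    sub <- fetch_recipe(recipe$refs$medium_id[i], recipe_set)
    frac <- volume_in_litres(recipe$refs$amount[i], recipe$refs$unit[i], unit_map)
    sub_flat <- unpack_one(sub, recipe_set, overrides, unit_map, stack, top = FALSE)
    sub_flat$amount <- sub_flat$amount * frac
    parts <- c(parts, list(sub_flat))
  }
  flat <- dplyr::bind_rows(parts)
  if (!top) {
    # a submedium's composition is taken per litre of that submedium,
    # so its own fill/scale multiplier applies before dilution
    mult <- resolve_volume(recipe, overrides, unit_map)$multiplier
    flat$amount <- flat$amount * mult
  }
  flat
}

# Ingredient lines -> per-litre amounts in standard units; compound volumes
# become grams via the 1 ml = 1 g rule.
standardize_lines <- function(lines, unit_map) {
  if (!nrow(lines)) {
    return(tibble(raw_name = character(), amount = numeric(), unit = character()))
  }
  out <- lapply(seq_len(nrow(lines)), function(i) {
    s <- standardize_unit(lines$amount[i], lines$unit[i], unit_map)
    if (s$standard == "l_per_l") {       # density 1 g/ml: litres -> grams
      s$amount <- s$amount * 1000
      s$standard <- "g_per_l"
    }
    tibble(raw_name = lines$raw_name[i], amount = s$amount, unit = s$standard)
  })
  dplyr::bind_rows(out)
}

sum_components <- function(flat) {
  if (!nrow(flat)) return(flat)
  flat |>
    dplyr::group_by(.data$raw_name, .data$unit) |>
    dplyr::summarise(amount = if (all(is.na(.data$amount))) NA_real_
                              else sum(.data$amount, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::select("raw_name", "amount", "unit") |>
    dplyr::arrange(.data$raw_name)
}

#' Convert a flat component list to standard concentration entries
#'
#' Defined compounds quantified in grams convert to moles by dividing by the
#' molecular weight *including hydrate waters*; each constituent compound
#' then contributes moles times its molar ratio.  Compounds already in
#' mol/l pass through (times ratios).  Complex components stay in g/l under
#' their category tag.  `trace` and `gas_substrate` entries pass through as
#' flags without a numeric concentration.  Entries resolving to the same
#' constituent are summed.
#'
#' @param entries Tibble `raw_name`, `amount`, `unit` (raw or standard
#'   units; raw units are standardized first).
#' @param compounds A [compound_table()].
#' @param unit_map Unit map.
#' @return Tibble with columns `compound_id`, `amount`, `unit`
#'   (`mol_per_l` / `g_per_l` / `trace` / `gas_substrate`), `class`,
#'   `category`, `g_per_l` (gram-equivalent where computable, else `NA`).
#' @export
to_standard_units <- function(entries, compounds,
                              unit_map = default_unit_map()) {
  stopifnot(inherits(compounds, "compound_table"))
  rows <- lapply(seq_len(nrow(entries)), function(i) {
    s <- standardize_unit(entries$amount[i], entries$unit[i], unit_map)
    if (s$standard == "l_per_l") {
      s$amount <- s$amount * 1000
      s$standard <- "g_per_l"
    }
    rec <- lookup_compound(compounds, entries$raw_name[i])
    convert_entry(rec, s$amount, s$standard)
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(out)
  out |>
    dplyr::group_by(.data$compound_id, .data$unit, .data$class, .data$category) |>
    dplyr::summarise(
      amount = if (all(is.na(.data$amount))) NA_real_ else sum(.data$amount, na.rm = TRUE),
      g_per_l = if (all(is.na(.data$g_per_l))) NA_real_ else sum(.data$g_per_l, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::select("compound_id", "amount", "unit", "class", "category", "g_per_l") |>
    dplyr::arrange(.data$compound_id)
}

convert_entry <- function(rec, amount, standard) {
  if (standard %in% c("trace", "gas_substrate")) {
    return(tibble(compound_id = rec$semi_unique_name, amount = NA_real_,
                  unit = standard, class = rec$compound_class,
                  category = rec$category, g_per_l = NA_real_))
  }
  if (rec$compound_class == "complex") {
    if (standard != "g_per_l") {
      abort(sprintf("Complex component '%s' must be quantified by mass, got %s.",
                    rec$raw_name, standard))
    }
    return(tibble(compound_id = paste0("complex-", rec$category),
                  amount = amount, unit = "g_per_l", class = "complex",
                  category = rec$category, g_per_l = amount))
  }
  # defined / other: convert to moles of each constituent
  moles <- if (standard == "g_per_l") {
    if (is.na(rec$molecular_weight)) {
      abort(sprintf("Compound '%s' is quantified in grams but has no molecular weight.",
                    rec$raw_name))
    }
    amount / rec$molecular_weight
  } else {
    amount
  }
  ids <- split_pipe(rec$constituent_ids)
  ratios <- as.numeric(split_pipe(rec$constituent_ratios))
  mws <- suppressWarnings(as.numeric(split_pipe(rec$constituent_mws)))
  if (length(mws) != length(ids)) mws <- rep(NA_real_, length(ids))
  tibble(compound_id = ids, amount = moles * ratios, unit = "mol_per_l",
         class = rec$compound_class, category = rec$category,
         g_per_l = moles * ratios * mws)
}

#' Compile a recipe into a medium variant
#'
#' End-to-end compilation: unpack submedium references, convert to standard
#' units, apply the recipe's fill/scale volume multiplier, attach pH, and
#' derive `is_defined` (no complex-class components).
#'
#' @param recipe_id Medium ID to compile (must be in `recipe_set`), or a
#'   `raw_recipe` directly.
#' @param recipe_set Named list of `raw_recipe`s.
#' @param compounds A [compound_table()].
#' @param unit_map Unit map.
#' @param overrides Fill/scale override table.
#' @return A `medium_variant`: list with `medium_id`, `name`, `components`
#'   (as in [to_standard_units()]), `ph`, `volume_mode`, `multiplier`,
#'   `is_defined`.
#' @export
compile_medium <- function(recipe_id, recipe_set = list(), compounds,
                           unit_map = default_unit_map(), overrides = NULL) {
  recipe <- if (inherits(recipe_id, "raw_recipe")) recipe_id
            else fetch_recipe(recipe_id, recipe_set)
  flat <- unpack_references(recipe, recipe_set, overrides, unit_map)
  comps <- to_standard_units(flat, compounds, unit_map)
  vol <- resolve_volume(recipe, overrides, unit_map)
  numeric_rows <- !comps$unit %in% c("trace", "gas_substrate")
  comps$amount[numeric_rows] <- comps$amount[numeric_rows] * vol$multiplier
  comps$g_per_l[numeric_rows] <- comps$g_per_l[numeric_rows] * vol$multiplier
  medium_variant(
    medium_id = recipe$medium_id, name = recipe$name %||% recipe$medium_id,
    components = comps, ph = recipe$ph,
    volume_mode = vol$mode, multiplier = vol$multiplier)
}

#' Construct a medium variant
#'
#' The compiled representation of one medium: resolved per-compound molar
#' concentrations (complex components in g/l), pH, volume mode and salt /
#' oxygen annotations.  Normally produced by [compile_medium()] or the
#' synthetic-data generator.
#'
#' @param medium_id,name Identifiers.
#' @param components Component tibble as from [to_standard_units()].
#' @param ph pH in \[0, 14\] or `NULL`.
#' @param volume_mode `"fill"` or `"scale"`.
#' @param multiplier Volume multiplier used.
#' @param oxygen_status `"aerobic"`, `"anaerobic"` or `"unknown"`.
#' @return A `medium_variant`.
#' @export
medium_variant <- function(medium_id, name = medium_id, components,
                           ph = NULL, volume_mode = "fill", multiplier = 1,
                           oxygen_status = "unknown") {
  components <- as_tibble(components)
  structure(list(
    medium_id = medium_id, name = name, components = components, ph = ph,
    volume_mode = volume_mode, multiplier = multiplier,
    is_defined = !any(components$class == "complex"),
    oxygen_status = oxygen_status), class = "medium_variant")
}

#' @export
print.medium_variant <- function(x, ...) {
  cat(sprintf("<medium_variant '%s': %d component(s), %s%s>\n",
              x$medium_id, nrow(x$components),
              if (x$is_defined) "defined" else "complex",
              if (!is.null(x$ph)) sprintf(", pH %.1f", x$ph) else ""))
  invisible(x)
}

#' @export
tidy.medium_variant <- function(x, ...) {
  dplyr::mutate(x$components, medium_id = x$medium_id, .before = 1)
}

#' Compile every recipe of a recipe set
#'
#' @inheritParams compile_medium
#' @param ids Medium IDs to compile (defaults to all).
#' @return A `media_library`: list with `media` (metadata tibble: medium_id,
#'   name, ph, is_defined, volume_mode) and `components` (long tibble of all
#'   compiled components with a `medium_id` column), plus the list of
#'   `medium_variant` objects in `$variants`.
#' @export
compile_media <- function(recipe_set, compounds,
                          unit_map = default_unit_map(), overrides = NULL,
                          ids = names(recipe_set)) {
  variants <- lapply(ids, compile_medium, recipe_set = recipe_set,
                     compounds = compounds, unit_map = unit_map,
                     overrides = overrides)
  names(variants) <- ids
  media_library(variants)
}

#' Bundle medium variants into a library
#'
#' @param variants List of `medium_variant` objects.
#' @return A `media_library`.
#' @export
media_library <- function(variants) {
  meta <- dplyr::bind_rows(lapply(variants, function(v) tibble(
    medium_id = v$medium_id, name = v$name,
    ph = v$ph %||% NA_real_, is_defined = v$is_defined,
    volume_mode = v$volume_mode, oxygen_status = v$oxygen_status)))
  comps <- dplyr::bind_rows(lapply(variants, tidy))
  structure(list(media = meta, components = comps, variants = variants),
            class = "media_library")
}

#' @export
print.media_library <- function(x, ...) {
  cat(sprintf("<media_library: %d media, %d component entries>\n",
              nrow(x$media), nrow(x$components)))
  invisible(x)
}

#' Media-by-compound concentration matrix
#'
#' Wide tibble of molar concentrations (defined constituents) with companion
#' columns for complex components in g/l; trace / gas-substrate flags are
#' encoded as logical columns suffixed `_flag`.
#'
#' @param library A [media_library()].
#' @return Wide tibble, one row per medium.
#' @export
media_component_matrix <- function(library) {
  comps <- library$components
  numeric_part <- comps |>
    dplyr::filter(!.data$unit %in% c("trace", "gas_substrate")) |>
    dplyr::select("medium_id", "compound_id", "amount") |>
    tidyr::pivot_wider(names_from = "compound_id", values_from = "amount",
                       values_fill = 0)
  flag_part <- comps |>
    dplyr::filter(.data$unit %in% c("trace", "gas_substrate")) |>
    dplyr::mutate(compound_id = paste0(.data$compound_id, "_flag"), flag = TRUE) |>
    dplyr::select("medium_id", "compound_id", "flag") |>
    tidyr::pivot_wider(names_from = "compound_id", values_from = "flag",
                       values_fill = FALSE)
  out <- dplyr::left_join(library$media, numeric_part, by = "medium_id")
  if (nrow(flag_part)) out <- dplyr::left_join(out, flag_part, by = "medium_id")
  out
}

#' Write a compiled media library to tab-separated files
#'
#' Writes `media.tsv` (metadata), `components.tsv` (long form) and
#' `matrix.tsv` (wide media-by-compound matrix) under `dir`.
#'
#' @param library A [media_library()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_media_library <- function(library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(library$media, file.path(dir, "media.tsv"), progress = FALSE)
  readr::write_tsv(library$components, file.path(dir, "components.tsv"),
                   progress = FALSE)
  readr::write_tsv(media_component_matrix(library), file.path(dir, "matrix.tsv"),
                   progress = FALSE)
  invisible(dir)
}
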