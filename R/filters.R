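#' Read a media metadata sidecar
#'
#' Tab-separated with `medium_id` and any of `name`, `oxygen_status`
#' (`aerobic`/`anaerobic`/`unknown`), `salt_status` (`salty`/`not_salty`).
#' Oxygen status is an annotation column rather than something inferred
#' from composition, since a compiled component list does not state whether
#' a medium is prepared and incubated anaerobically.
#'
#' @param path File path.
#' @return Tibble of media metadata.
#' @export
read_media_metadata <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!"medium_id" %in% names(tab)) {
    abort("Media metadata needs a medium_id column.")
  }
  tab
}

#' NaCl gram-equivalent of a compiled medium
#'
#' Compiled media carry sodium and chloride as dissociated ions, so the
#' sodium-chloride content is reconstructed as min(mol Na+, mol Cl-) x
#' 58.44 g/mol, plus any complex "sea salts"-category component taken at
#' face g/l value.  This is an approximation: sodium contributed by e.g.
#' sodium sulfate pairs with chloride from e.g. potassium chloride, but for
#' salt classification at a 15 g/l threshold that is the intended reading.
#'
#' @param medium A `medium_variant`, or its components tibble.
#' @param na_id,cl_id Constituent IDs of the sodium and chloride ions.
#' @return Grams of NaCl-equivalent per litre.
#' @export
medium_nacl_g_per_l <- function(medium, na_id = "Na+", cl_id = "Cl-") {
  comps <- if (inherits(medium, "medium_variant")) medium$components else medium
  molar <- comps[comps$unit == "mol_per_l", ]
  na <- sum(molar$amount[molar$compound_id == na_id])
  cl <- sum(molar$amount[molar$compound_id == cl_id])
  sea <- comps[comps$class == "complex" &
                 !is.na(comps$category) & comps$category == "sea-salts", ]
  min(na, cl) * 58.44 + sum(sea$g_per_l, na.rm = TRUE)
}

#' Classify a medium as salty or not
#'
#' A salty medium has at least 15 g/l of NaCl-equivalent or a name
#' containing the word "sea" (case-insensitive) — sea-water media are salty
#' whatever their itemised composition says.
#'
#' @param medium A `medium_variant`.
#' @param threshold_g_per_l Salt threshold (default 15).
#' @return `"salty"` or `"not_salty"`.
#' @export
classify_salt <- function(medium, threshold_g_per_l = 15) {
  stopifnot(inherits(medium, "medium_variant"))
  if (grepl("sea", medium$name %||% "", ignore.case = TRUE) ||
      medium_nacl_g_per_l(medium) >= threshold_g_per_l) "salty" else "not_salty"
}

#' Classify an organism's salt preference from its documented media
#'
#' High-salt if every documented medium is salty, low-salt if none is,
#' unknown when mixed or when the organism has no annotated media.  The
#' positive-only database cannot distinguish "never tested on salt" from
#' "cannot grow on salt", so mixed evidence stays unknown rather than
#' being forced into a class.
#'
#' @param org Organism ID.
#' @param db A [growth_db()].
#' @param media_salt Named character vector medium ID -> "salty"/"not_salty".
#' @return `"high"`, `"low"` or `"unknown"`.
#' @export
classify_salt_organism <- function(org, db, media_salt) {
  st <- media_salt[db$medium[db$organism == org]]
  st <- st[!is.na(st)]
  if (!length(st)) return("unknown")
  if (all(st == "salty")) return("high")
  if (all(st == "not_salty")) return("low")
  "unknown"
}

#' Classify an organism's oxygen preference from its documented media
#'
#' Aerobic if every oxygen-annotated medium it grows on is aerobic,
#' anaerobic if all are anaerobic, facultative when it grows both with and
#' without oxygen, unknown when no documented medium carries an oxygen
#' annotation.
#'
#' @param org Organism ID.
#' @param db A [growth_db()].
#' @param media_oxygen Named character vector medium ID -> "aerobic" /
#'   "anaerobic" (media without annotation may be absent or `"unknown"`).
#' @return `"aerobic"`, `"anaerobic"`, `"facultative"` or `"unknown"`.
#' @export
classify_oxygen <- function(org, db, media_oxygen) {
  ox <- media_oxygen[db$medium[db$organism == org]]
  ox <- ox[!is.na(ox) & ox %in% c("aerobic", "anaerobic")]
  if (!length(ox)) return("unknown")
  if (all(ox == "aerobic")) return("aerobic")
  if (all(ox == "anaerobic")) return("anaerobic")
  "facultative"
}

#' Salt and oxygen profiles for all organisms
#'
#' @param db A [growth_db()].
#' @param media_meta Tibble with `medium_id` and any of `oxygen_status`
#'   (`aerobic`/`anaerobic`/`unknown`) and `salt_status`
#'   (`salty`/`not_salty`).
#' @return Tibble `organism`, `oxygen_class`, `salt_class`.
#' @export
organism_profiles <- function(db, media_meta) {
  ox <- if ("oxygen_status" %in% names(media_meta)) {
    setNames(media_meta$oxygen_status, media_meta$medium_id)
  } else NULL
  sa <- if ("salt_status" %in% names(media_meta)) {
    setNames(media_meta$salt_status, media_meta$medium_id)
  } else NULL
  orgs <- db_organisms(db)
  tibble(
    organism = orgs,
    oxygen_class = vapply(orgs, function(o) {
      if (is.null(ox)) "unknown" else classify_oxygen(o, db, ox)
    }, ""),
    salt_class = vapply(orgs, function(o) {
      if (is.null(sa)) "unknown" else classify_salt_organism(o, db, sa)
    }, "")
  )
}

#' Filter predictions on salt and oxygen compatibility
#'
#' Removes predictions that pair an aerobic organism with an anaerobic
#' medium or vice versa, a high-salt organism with a non-salty medium, or a
#' low-salt organism with a salty medium.  Facultative and unknown classes
#' pass in both directions, as do media without annotation.  Per-filter
#' pass flags are retained so the effect of each filter can be audited.
#'
#' Because an organism's profile is derived from its own documented media,
#' a documented pairing can never contradict the profile it induced, so the
#' filters cannot remove true positives — they only discard incompatible
#' novel predictions.
#'
#' @param predictions Prediction tibble with `organism`, `medium`.
#' @param profiles Tibble from [organism_profiles()].
#' @param media_meta Media metadata (see [organism_profiles()]).
#' @param keep_all Keep filtered rows (flagged) instead of dropping them.
#' @return Predictions with logical columns `passed_oxygen`, `passed_salt`,
#'   `passed_filters`; rows failing a filter are dropped unless
#'   `keep_all = TRUE`.
#' @export
apply_filters <- function(predictions, profiles, media_meta,
                          keep_all = FALSE) {
  ox_class <- setNames(profiles$oxygen_class, profiles$organism)
  sa_class <- setNames(profiles$salt_class, profiles$organism)
  med_ox <- if ("oxygen_status" %in% names(media_meta)) {
    setNames(media_meta$oxygen_status, media_meta$medium_id)
  } else NULL
  med_sa <- if ("salt_status" %in% names(media_meta)) {
    setNames(media_meta$salt_status, media_meta$medium_id)
  } else NULL

  o_org <- unname(ox_class[predictions$organism]) %||% rep("unknown", nrow(predictions))
  o_med <- if (is.null(med_ox)) rep("unknown", nrow(predictions))
           else unname(med_ox[predictions$medium])
  s_org <- unname(sa_class[predictions$organism]) %||% rep("unknown", nrow(predictions))
  s_med <- if (is.null(med_sa)) rep(NA_character_, nrow(predictions))
           else unname(med_sa[predictions$medium])

  passed_oxygen <- !((o_org == "aerobic" & o_med %in% "anaerobic") |
                       (o_org == "anaerobic" & o_med %in% "aerobic"))
  passed_oxygen[is.na(passed_oxygen)] <- TRUE
  passed_salt <- !((s_org == "high" & s_med %in% "not_salty") |
                     (s_org == "low" & s_med %in% "salty"))
  passed_salt[is.na(passed_salt)] <- TRUE

  out <- dplyr::mutate(predictions, passed_oxygen = passed_oxygen,
                       passed_salt = passed_salt,
                       passed_filters = passed_oxygen & passed_salt)
  if (keep_all) out else out[out$passed_filters, ]
}
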