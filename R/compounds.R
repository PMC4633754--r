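#' Compound table: raw ingredient names to constituent compounds
#'
#' Every raw ingredient name that can appear in a recipe maps to a compound
#' record.  Chemically defined compounds decompose into 1-3 constituent
#' compound IDs with integer molar ratios (e.g. calcium chloride dihydrate
#' yields one calcium and two chloride ions), carry the number of hydrate
#' waters and a molecular weight that *includes* those waters, so that a
#' gram amount of the hydrate converts to the correct number of moles.
#' Complex components (peptone, yeast extract, ...) have no constituents and
#' carry a category tag instead; they stay in g/l.  Full dissociation in
#' solution is assumed, as is conventional for medium composition tables.
#'
#' @param table Data frame with columns `raw_name`, `semi_unique_name`,
#'   `constituent_ids` (pipe-separated), `constituent_ratios` (pipe-separated
#'   integers), `n_waters`, `molecular_weight`, `compound_class`
#'   (`defined` / `complex` / `other`) and optional `category` (required for
#'   complex compounds) and `constituent_mws` (pipe-separated g/mol of the
#'   constituents, used to report g/l equivalents).
#' @return Validated tibble of class `compound_table`.
#' @export
compound_table <- function(table) {
  table <- as_tibble(table)
  need <- c("raw_name", "semi_unique_name", "constituent_ids",
            "constituent_ratios", "n_waters", "molecular_weight",
            "compound_class")
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    abort(sprintf("Compound table is missing columns: %s.",
                  paste(missing, collapse = ", ")))
  }
  if (!"category" %in% names(table)) table$category <- NA_character_
  if (!"constituent_mws" %in% names(table)) table$constituent_mws <- NA_character_
  if (anyDuplicated(table$raw_name)) {
    abort("Compound table raw_name values must be unique.")
  }
  bad_class <- setdiff(unique(table$compound_class),
                       c("defined", "complex", "other"))
  if (length(bad_class)) {
    abort(sprintf("Unknown compound_class: %s.", paste(bad_class, collapse = ", ")))
  }
  for (i in seq_len(nrow(table))) {
    row <- table[i, ]
    ids <- split_pipe(row$constituent_ids)
    if (row$compound_class == "complex") {
      if (length(ids)) {
        abort(sprintf("Complex compound '%s' must have no constituents.", row$raw_name))
      }
      if (is.na(row$category)) {
        abort(sprintf("Complex compound '%s' needs a category tag.", row$raw_name))
      }
    } else {
      if (length(ids) < 1 || length(ids) > 3) {
        abort(sprintf("Compound '%s' must list 1-3 constituents.", row$raw_name))
      }
      ratios <- as.numeric(split_pipe(row$constituent_ratios))
      if (length(ratios) != length(ids) || any(is.na(ratios)) ||
          any(ratios <= 0) || any(ratios != round(ratios))) {
        abort(sprintf("Compound '%s' needs positive integer ratios matching its constituents.",
                      row$raw_name))
      }
    }
  }
  if (any(!is.na(table$molecular_weight) & table$molecular_weight <= 0)) {
    abort("Molecular weights must be positive when present.")
  }
  structure(table, class = c("compound_table", class(table)))
}

split_pipe <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character())
  strsplit(x, "|", fixed = TRUE)[[1]]
}

#' Read a compound table from TSV
#'
#' Tab-separated with the columns documented in [compound_table()].
#'
#' @param path File path.
#' @return A [compound_table()].
#' @export
read_compound_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    n_waters = "i", molecular_weight = "d", .default = "c"
  ), progress = FALSE)
  compound_table(tab)
}

lookup_compound <- function(compounds, raw_name) {
  hit <- which(compounds$raw_name == raw_name)
  if (!length(hit)) hit <- which(compounds$semi_unique_name == raw_name)
  if (!length(hit)) {
    abort(sprintf("Compound '%s' is not in the compound table.", raw_name))
  }
  compounds[hit[1], ]
}

#' Default unit map
#'
#' Maps raw recipe units to the five standard units (`g_per_l`, `l_per_l`,
#' `mol_per_l`, `trace`, `gas_substrate`) with a multiplier.  Mass and molar
#' amounts are interpreted per litre of final medium (the per-litre
#' convention of recipe bookkeeping; explicit volumes are handled by the
#' fill/scale resolution).  Percentages are mass/volume: 1% = 10 g/l.  The
#' map is a plain tibble and is user-extensible by row-binding.
#'
#' @return Tibble with columns `unit`, `standard`, `multiplier`.
#' @export
default_unit_map <- function() {
  tribble_units <- list(
    # mass -> g per l
    c("g", "g_per_l", 1), c("mg", "g_per_l", 1e-3), c("ug", "g_per_l", 1e-6),
    c("µg", "g_per_l", 1e-6), c("kg", "g_per_l", 1e3),
    c("ng", "g_per_l", 1e-9),
    c("g/l", "g_per_l", 1), c("mg/l", "g_per_l", 1e-3),
    c("ug/l", "g_per_l", 1e-6), c("µg/l", "g_per_l", 1e-6),
    c("g/ml", "g_per_l", 1e3),
    # percent, mass/volume
    c("%", "g_per_l", 10), c("percent", "g_per_l", 10),
    # volume -> l per l
    c("l", "l_per_l", 1), c("ml", "l_per_l", 1e-3),
    c("ul", "l_per_l", 1e-6), c("µl", "l_per_l", 1e-6),
    c("dl", "l_per_l", 0.1), c("ml/l", "l_per_l", 1e-3),
    # molar amount or concentration -> mol per l
    c("mol", "mol_per_l", 1), c("mmol", "mol_per_l", 1e-3),
    c("umol", "mol_per_l", 1e-6), c("µmol", "mol_per_l", 1e-6),
    c("nmol", "mol_per_l", 1e-9),
    c("m", "mol_per_l", 1), c("mm", "mol_per_l", 1e-3),
    c("um", "mol_per_l", 1e-6), c("µm", "mol_per_l", 1e-6),
    c("nm", "mol_per_l", 1e-9), c("mol/l", "mol_per_l", 1),
    # flags
    c("trace", "trace", 1), c("gas", "gas_substrate", 1),
    c("gas_substrate", "gas_substrate", 1),
    # already-standard passthroughs
    c("g_per_l", "g_per_l", 1), c("l_per_l", "l_per_l", 1),
    c("mol_per_l", "mol_per_l", 1)
  )
  tibble(
    unit = vapply(tribble_units, `[[`, "", 1),
    standard = vapply(tribble_units, `[[`, "", 2),
    multiplier = as.numeric(vapply(tribble_units, `[[`, "", 3))
  )
}

# Standardize an (amount, unit) pair; unit matching is case-insensitive
# except that molarity "M" forms are already lowercased in the map.
standardize_unit <- function(amount, unit, unit_map) {
  i <- match(tolower(unit), unit_map$unit)
  if (is.na(i)) abort(sprintf("Unknown unit '%s'; extend the unit map.", unit))
  std <- unit_map$standard[i]
  list(amount = if (std %in% c("trace", "gas_substrate")) NA_real_
                else amount * unit_map$multiplier[i],
       standard = std)
}

# Convert a volume unit to litres (for declared volumes and submedium refs).
volume_in_litres <- function(amount, unit, unit_map) {
  s <- standardize_unit(amount, unit, unit_map)
  if (s$standard != "l_per_l") {
    abort(sprintf("Expected a volume unit, got '%s'.", unit))
  }
  s$amount
}
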