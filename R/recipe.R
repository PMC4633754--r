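#' Parse a tagged culture-medium recipe
#'
#' Recipes use a small plain-text dialect, one item per line:
#'
#' * `medium: M1` — medium ID (may instead be given via `medium_id`)
#' * `name: Nutrient broth` — human-readable name
#' * `NAME @ AMOUNT UNIT` — ingredient line, e.g. `NaCl @ 58.44 g`;
#'   an optional `/notag/` prefix marks an instruction-free ingredient line
#' * `ref: M2 @ 100 ml` — cross-reference to a submedium by volume
#' * `volume: 0.5 l` — declared final volume (used by scale resolution)
#' * `/ph/ 7.2` — set the medium pH
#' * `/replace/ OLD -> NEW`, `/conc/ NAME @ AMOUNT UNIT`, `/rm/ NAME` —
#'   variant instructions, captured in order but not applied by the parser
#'   (see [expand_variants()])
#'
#' Blank lines and `#` comments are ignored.  The parse is total: any line
#' that fits no form is an error naming the line, never a silent drop.
#'
#' @param text Recipe text (single string or character vector of lines).
#' @param medium_id Medium ID if not given by a `medium:` line.
#' @return A `raw_recipe`: list with `medium_id`, `name`, `lines` (tibble
#'   raw_name/amount/unit), `refs` (tibble medium_id/amount/unit), `ph`,
#'   `declared_volume`, and `instructions` (tibble tag/arg1/arg2/amount/unit,
#'   in source order).
#' @examples
#' r <- parse_recipe("/notag/ CaCl2 x 2 H2O @ 10 mg", medium_id = "M1")
#' r$lines
#' @export
parse_recipe <- function(text, medium_id = NULL) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  rec <- list(medium_id = medium_id, name = NULL,
              lines = tibble(raw_name = character(), amount = numeric(),
                             unit = character()),
              refs = tibble(medium_id = character(), amount = numeric(),
                            unit = character()),
              ph = NULL, declared_volume = NULL,
              instructions = tibble(tag = character(), arg1 = character(),
                                    arg2 = character(), amount = numeric(),
                                    unit = character()))

  for (ln in lines) {
    if (grepl("^medium:", ln)) {
      rec$medium_id <- trimws(sub("^medium:", "", ln))
    } else if (grepl("^name:", ln)) {
      rec$name <- trimws(sub("^name:", "", ln))
    } else if (grepl("^volume:", ln)) {
      av <- parse_amount_unit(trimws(sub("^volume:", "", ln)), ln)
      rec$declared_volume <- list(amount = av$amount, unit = av$unit)
    } else if (grepl("^ref:", ln)) {
      body <- trimws(sub("^ref:", "", ln))
      parts <- strsplit(body, "@", fixed = TRUE)[[1]]
      if (length(parts) != 2) abort(sprintf("Malformed reference line: '%s'.", ln))
      av <- parse_amount_unit(trimws(parts[2]), ln)
      rec$refs <- dplyr::bind_rows(rec$refs, tibble(
        medium_id = trimws(parts[1]), amount = av$amount, unit = av$unit))
    } else if (grepl("^/ph/", ln)) {
      val <- suppressWarnings(as.numeric(trimws(sub("^/ph/", "", ln))))
      if (is.na(val) || val < 0 || val > 14) {
        abort(sprintf("Malformed pH line: '%s'.", ln))
      }
      rec$ph <- val
    } else if (grepl("^/replace/", ln)) {
      body <- trimws(sub("^/replace/", "", ln))
      parts <- strsplit(body, "->", fixed = TRUE)[[1]]
      if (length(parts) != 2) abort(sprintf("Malformed /replace/ line: '%s'.", ln))
      rec$instructions <- dplyr::bind_rows(rec$instructions, tibble(
        tag = "replace", arg1 = trimws(parts[1]), arg2 = trimws(parts[2]),
        amount = NA_real_, unit = NA_character_))
    } else if (grepl("^/conc/", ln)) {
      body <- trimws(sub("^/conc/", "", ln))
      ing <- parse_ingredient(body, ln)
      rec$instructions <- dplyr::bind_rows(rec$instructions, tibble(
        tag = "conc", arg1 = ing$raw_name, arg2 = NA_character_,
        amount = ing$amount, unit = ing$unit))
    } else if (grepl("^/rm/", ln)) {
      rec$instructions <- dplyr::bind_rows(rec$instructions, tibble(
        tag = "rm", arg1 = trimws(sub("^/rm/", "", ln)), arg2 = NA_character_,
        amount = NA_real_, unit = NA_character_))
    } else if (grepl("^/notag/", ln)) {
      ing <- parse_ingredient(trimws(sub("^/notag/", "", ln)), ln)
      rec$lines <- dplyr::bind_rows(rec$lines, ing)
    } else if (grepl("^/", ln)) {
      abort(sprintf("Unknown tag in line: '%s'.", ln))
    } else {
      rec$lines <- dplyr::bind_rows(rec$lines, parse_ingredient(ln, ln))
    }
  }
  structure(rec, class = "raw_recipe")
}

parse_ingredient <- function(body, ln) {
  parts <- strsplit(body, "@", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    abort(sprintf("Malformed ingredient line (expected 'name @ amount unit'): '%s'.", ln))
  }
  av <- parse_amount_unit(trimws(parts[2]), ln)
  tibble(raw_name = trimws(parts[1]), amount = av$amount, unit = av$unit)
}

parse_amount_unit <- function(s, ln) {
  toks <- strsplit(s, "[[:space:]]+")[[1]]
  if (length(toks) != 2) {
    abort(sprintf("Malformed amount in line: '%s' (expected 'amount unit').", ln))
  }
  amount <- suppressWarnings(as.numeric(toks[1]))
  if (is.na(amount) || amount < 0) {
    abort(sprintf("Malformed amount '%s' in line: '%s'.", toks[1], ln))
  }
  list(amount = amount, unit = toks[2])
}

#' @export
print.raw_recipe <- function(x, ...) {
  cat(sprintf("<raw_recipe '%s': %d ingredient line(s), %d reference(s)%s>\n",
              x$medium_id %||% "?", nrow(x$lines), nrow(x$refs),
              if (!is.null(x$ph)) sprintf(", pH %.1f", x$ph) else ""))
  invisible(x)
}

#' Parse a file of recipes into a recipe set
#'
#' Recipes are separated by `medium:` lines; everything up to the next
#' `medium:` line belongs to the current recipe.
#'
#' @param text Full text, or a file path via `file`.
#' @param file Optional path read with [readLines()].
#' @return Named list of `raw_recipe`s keyed by medium ID.
#' @export
parse_recipe_set <- function(text = NULL, file = NULL) {
  if (!is.null(file)) text <- readLines(file, warn = FALSE)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  starts <- grep("^\\s*medium:", lines)
  if (!length(starts)) abort("No 'medium:' lines found in recipe set.")
  ends <- c(starts[-1] - 1, length(lines))
  recs <- lapply(seq_along(starts), function(i) {
    parse_recipe(lines[starts[i]:ends[i]])
  })
  ids <- vapply(recs, function(r) r$medium_id, "")
  if (anyDuplicated(ids)) abort("Duplicate medium IDs in recipe set.")
  setNames(recs, ids)
}

#' Variant instructions and edits
#'
#' A variant instruction is an ordered list of edits applied to a base
#' recipe to derive a strain-specific medium variant: replace one compound
#' with another, change a concentration, remove or add a compound, or set
#' the pH.  Variants receive the base medium ID suffixed with `.` and a
#' 1-based counter.
#'
#' @param ... Edits built with `edit_replace()`, `edit_set_concentration()`,
#'   `edit_remove()`, `edit_add()`, `edit_set_ph()`.
#' @param label Optional variant label (defaults to the counter).
#' @return A `variant_instruction`.
#' @export
variant_instruction <- function(..., label = NULL) {
  edits <- list(...)
  structure(list(edits = edits, label = label), class = "variant_instruction")
}

#' @rdname variant_instruction
#' @param old,new,name Compound raw names.
#' @export
edit_replace <- function(old, new) list(op = "replace", old = old, new = new)

#' @rdname variant_instruction
#' @param amount,unit Amount and raw unit.
#' @export
edit_set_concentration <- function(name, amount, unit) {
  list(op = "conc", name = name, amount = amount, unit = unit)
}

#' @rdname variant_instruction
#' @export
edit_remove <- function(name) list(op = "rm", name = name)

#' @rdname variant_instruction
#' @export
edit_add <- function(name, amount, unit) {
  list(op = "add", name = name, amount = amount, unit = unit)
}

#' @rdname variant_instruction
#' @param value pH value.
#' @export
edit_set_ph <- function(value) list(op = "ph", value = value)

#' Expand a base recipe into medium variants
#'
#' Returns the unmodified base followed by one variant per instruction.
#' Edits apply in order; `replace`/`rm`/`conc` referencing a compound absent
#' from the recipe at that point is an error naming the compound, so silent
#' no-op edits cannot slip through.
#'
#' @param base A `raw_recipe`.
#' @param instructions List of [variant_instruction()]s.
#' @return List of `raw_recipe`s; variant IDs are `baseID.1`, `baseID.2`, ...
#' @export
expand_variants <- function(base, instructions = list()) {
  stopifnot(inherits(base, "raw_recipe"))
  out <- list(base)
  for (i in seq_along(instructions)) {
    ins <- instructions[[i]]
    stopifnot(inherits(ins, "variant_instruction"))
    var <- base
    suffix <- ins$label %||% as.character(i)
    var$medium_id <- paste0(base$medium_id, ".", suffix)
    for (ed in ins$edits) {
      var <- apply_edit(var, ed)
    }
    out <- c(out, list(var))
  }
  out
}

apply_edit <- function(rec, ed) {
  find_line <- function(name) {
    j <- which(rec$lines$raw_name == name)
    if (!length(j)) {
      abort(sprintf("Edit refers to compound '%s' absent from medium '%s'.",
                    name, rec$medium_id))
    }
    j
  }
  switch(ed$op,
    replace = {
      rec$lines$raw_name[find_line(ed$old)] <- ed$new
      rec
    },
    conc = {
      j <- find_line(ed$name)
      rec$lines$amount[j] <- ed$amount
      rec$lines$unit[j] <- ed$unit
      rec
    },
    rm = {
      rec$lines <- rec$lines[-find_line(ed$name), ]
      rec
    },
    add = {
      rec$lines <- dplyr::bind_rows(rec$lines, tibble(
        raw_name = ed$name, amount = ed$amount, unit = ed$unit))
      rec
    },
    ph = {
      rec$ph <- ed$value
      rec
    },
    abort(sprintf("Unknown edit op '%s'.", ed$op))
  )
}
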