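#' Positive-only organism-by-media growth database
#'
#' A growth database records which organisms are documented to grow on which
#' media.  It is strictly positive-only: the absence of a pairing carries no
#' evidence of non-growth.  The database is stored as a tibble of pairings
#' (one row per organism-medium pair) together with the full registers of
#' known organisms and media, so that an organism or medium with no pairings
#' is still a legal entity with popularity zero.
#'
#' @param pairings A data frame with columns `organism` and `medium`
#'   (character).  Duplicate rows are collapsed.
#' @param organisms Character vector of registered organism IDs.  Defaults to
#'   the organisms appearing in `pairings`.
#' @param media Character vector of registered medium IDs.  Defaults to the
#'   media appearing in `pairings`.
#' @return A `growth_db`: a tibble of pairings with `organisms` and `media`
#'   registers stored as attributes.
#' @examples
#' db <- growth_db(tibble::tibble(
#'   organism = c("orgA", "orgA", "orgB"),
#'   medium   = c("m1", "m2", "m1")
#' ))
#' popularity(db, "m1")
#' @export
growth_db <- function(pairings = NULL, organisms = NULL, media = NULL) {
  if (is.null(pairings)) {
    pairings <- tibble(organism = character(), medium = character())
  }
  pairings <- as_tibble(pairings)
  if (!all(c("organism", "medium") %in% names(pairings))) {
    abort("`pairings` needs columns `organism` and `medium`.")
  }
  pairings <- dplyr::distinct(pairings[, c("organism", "medium")])
  pairings$organism <- as.character(pairings$organism)
  pairings$medium <- as.character(pairings$medium)
  organisms <- sort(unique(c(as.character(organisms %||% character()),
                             pairings$organism)))
  media <- sort(unique(c(as.character(media %||% character()),
                         pairings$medium)))
  structure(pairings,
            organisms = organisms, media = media,
            class = c("growth_db", class(pairings)))
}

#' @export
print.growth_db <- function(x, ...) {
  cat(sprintf("<growth_db: %d pairings, %d organisms, %d media>\n",
              nrow(x), length(attr(x, "organisms")), length(attr(x, "media"))))
  NextMethod()
}

#' Registered organisms / media of a growth database
#' @param db A [growth_db()].
#' @return Character vector of IDs.
#' @export
db_organisms <- function(db) attr(db, "organisms")

#' @rdname db_organisms
#' @export
db_media <- function(db) attr(db, "media")

is_growth_db <- function(x) inherits(x, "growth_db")

#' Add a pairing to a growth database
#'
#' Idempotent: adding an existing pairing leaves the database unchanged.
#' Both entities must already be registered; this catches typos early rather
#' than silently growing the registers.
#'
#' @param db A [growth_db()].
#' @param organism,medium Single IDs.
#' @return The updated `growth_db`.
#' @export
add_pairing <- function(db, organism, medium) {
  stopifnot(is_growth_db(db))
  if (!organism %in% db_organisms(db)) {
    abort(sprintf("Unknown organism ID: '%s'.", organism))
  }
  if (!medium %in% db_media(db)) {
    abort(sprintf("Unknown medium ID: '%s'.", medium))
  }
  if (any(db$organism == organism & db$medium == medium)) return(db)
  out <- dplyr::bind_rows(as_tibble(db),
                          tibble(organism = organism, medium = medium))
  growth_db(out, organisms = db_organisms(db), media = db_media(db))
}

#' Popularity of an organism or medium
#'
#' Popularity counts the pairings touching an entity: for a medium, how many
#' organisms are documented on it; for an organism, how many media it is
#' documented on.  The popularity-weighted null predictor ([null_predict()])
#' samples entities proportional to these counts.
#'
#' @param db A [growth_db()].
#' @param entity A single registered organism or medium ID.
#' @return Non-negative integer count.
#' @export
popularity <- function(db, entity) {
  stopifnot(is_growth_db(db))
  if (entity %in% db_organisms(db)) return(sum(db$organism == entity))
  if (entity %in% db_media(db)) return(sum(db$medium == entity))
  abort(sprintf("Unknown entity ID: '%s'.", entity))
}

#' Popularity table for all registered organisms or media
#'
#' @param db A [growth_db()].
#' @param what `"organism"` or `"medium"`.
#' @return Tibble with columns `id`, `popularity` (zero rows included).
#' @export
popularity_table <- function(db, what = c("medium", "organism")) {
  what <- match.arg(what)
  ids <- if (what == "medium") db_media(db) else db_organisms(db)
  counts <- table(factor(db[[what]], levels = ids))
  tibble(id = ids, popularity = as.integer(counts))
}

#' Read / write a growth database as tab-separated text
#'
#' The on-disk format is a two-column TSV `organism_id`, `medium_id` with a
#' header, UTF-8.  The round trip is lossless for the pairing relation;
#' entities without pairings are not representable in the file and should be
#' re-registered on read if needed.
#'
#' @param path File path.
#' @return `read_growth_db()` returns a [growth_db()];
#'   `write_growth_db()` returns `path` invisibly.
#' @export
read_growth_db <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("organism_id", "medium_id") %in% names(tab))) {
    abort("Growth database file needs columns organism_id, medium_id.")
  }
  growth_db(tibble(organism = tab$organism_id, medium = tab$medium_id))
}

#' @rdname read_growth_db
#' @param db A [growth_db()].
#' @export
write_growth_db <- function(db, path) {
  stopifnot(is_growth_db(db))
  readr::write_tsv(tibble(organism_id = db$organism, medium_id = db$medium),
                   path, progress = FALSE)
  invisible(path)
}

#' Organism-by-media incidence matrix
#'
#' @param db A [growth_db()].
#' @param organisms,media Optional ID vectors fixing row/column order.
#' @return Logical matrix, organisms in rows.
#' @keywords internal
incidence_matrix <- function(db, organisms = db_organisms(db),
                             media = db_media(db)) {
  m <- matrix(FALSE, length(organisms), length(media),
              dimnames = list(organisms, media))
  keep <- db$organism %in% organisms & db$medium %in% media
  m[cbind(db$organism[keep], db$medium[keep])] <- TRUE
  m
}
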