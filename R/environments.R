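#' Organism-environment co-occurrence table
#'
#' Ecological similarity between two organisms is the Jaccard index of the
#' environments they are observed to grow in: shared environments divided by
#' the union.  The table is long format, one row per (organism, environment)
#' observation.
#'
#' @param table Data frame with columns `organism`, `environment`.
#' @return A tibble of class `environment_table`.
#' @export
environment_table <- function(table) {
  table <- as_tibble(table)
  if (!all(c("organism", "environment") %in% names(table))) {
    abort("Environment table needs columns `organism` and `environment`.")
  }
  out <- dplyr::distinct(table[, c("organism", "environment")])
  out$organism <- as.character(out$organism)
  out$environment <- as.character(out$environment)
  structure(out, class = c("environment_table", class(out)))
}

#' Read an environment table from TSV
#'
#' Long-format `organism_id`, `environment_id` with header.
#'
#' @param path File path.
#' @return An [environment_table()].
#' @export
read_environments <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("organism_id", "environment_id") %in% names(tab))) {
    abort("Environment file needs columns organism_id, environment_id.")
  }
  environment_table(tibble(organism = tab$organism_id,
                           environment = tab$environment_id))
}

#' Ecological similarity (co-growth Jaccard index)
#'
#' @param envs An [environment_table()].
#' @param a,b Organism IDs.
#' @return Jaccard index in \[0, 1\].  Two organisms with no recorded
#'   environments at all have an undefined similarity and raise an error
#'   rather than silently scoring 0.
#' @export
eco_similarity <- function(envs, a, b) {
  stopifnot(inherits(envs, "environment_table"))
  ea <- envs$environment[envs$organism == a]
  eb <- envs$environment[envs$organism == b]
  u <- union(ea, eb)
  if (!length(u)) {
    abort(sprintf("Organisms '%s' and '%s' have no recorded environments; Jaccard similarity is undefined.",
                  a, b))
  }
  length(intersect(ea, eb)) / length(u)
}

#' Pairwise ecological distance matrix (1 - Jaccard similarity)
#'
#' @param envs An [environment_table()].
#' @param organisms Organism IDs to include (all must have at least one
#'   recorded environment).
#' @return Symmetric matrix of Jaccard distances.
#' @export
eco_distance_matrix <- function(envs, organisms = unique(envs$organism)) {
  inc <- table(factor(envs$organism, levels = organisms),
               factor(envs$environment)) > 0
  storage.mode(inc) <- "numeric"
  if (any(rowSums(inc) == 0)) {
    abort("Every organism needs at least one recorded environment.")
  }
  shared <- inc %*% t(inc)
  sizes <- rowSums(inc)
  un <- outer(sizes, sizes, "+") - shared
  d <- 1 - shared / un
  dimnames(d) <- list(organisms, organisms)
  d
}
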