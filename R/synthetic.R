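#' Configuration for the synthetic benchmark generator
#'
#' The generator emulates the statistical structure that neighbour-based
#' media recommendation assumes: organisms sit on a taxonomy, clades of
#' related organisms prefer particular media, and the observed growth
#' database is a sparse positive-only sample of those preferences.  The
#' phylogenetic signal `s` is the probability that any one documented
#' pairing is drawn from the organism's clade-level media preferences
#' rather than uniformly from all media; `s = 1` gives perfectly
#' clade-structured data and `s = 0` makes pairing incidence independent of
#' the tree.
#'
#' Defaults: 256 organisms on a balanced binary tree with preference-bearing
#' clades of 8 (so the whole clade sits within a 0.04 subtree distance:
#' 8/256 = 0.031), 3 preferred media per clade (96 media), 3 documented
#' pairings per organism (sparse, like real strain catalogues where
#' organisms rarely list more than a handful of media), signal 0.8 (strong
#' but imperfect clade structure), 30% anaerobic and 20% high-salt clades,
#' and a 40/35/25 low/medium/high richness mix.
#'
#' @param n_organisms Number of organisms (power of 2).
#' @param clade_size Organisms per preference clade (power of 2, divides
#'   `n_organisms`).
#' @param media_per_clade Preferred media per clade.
#' @param pairings_per_organism Documented pairings drawn per organism.
#' @param signal Phylogenetic signal s in \[0, 1\].
#' @param frac_anaerobic Fraction of anaerobic clades (and hence media).
#' @param frac_salty Fraction of high-salt clades.
#' @param richness_mix Named probabilities for clade richness classes.
#' @param seed Integer seed; generation is reproducible bit-for-bit.
#' @return A `synth_config`.
#' @export
synth_config <- function(n_organisms = 256, clade_size = 8,
                         media_per_clade = 3, pairings_per_organism = 3,
                         signal = 0.8, frac_anaerobic = 0.3,
                         frac_salty = 0.2,
                         richness_mix = c(low = 0.4, medium = 0.35,
                                          high = 0.25),
                         seed = 1) {
  if (signal < 0 || signal > 1) abort("`signal` must lie in [0, 1].")
  if (frac_anaerobic < 0 || frac_anaerobic > 1 ||
      frac_salty < 0 || frac_salty > 1) {
    abort("Fractions must lie in [0, 1].")
  }
  if (n_organisms < 4 || bitwAnd(n_organisms, n_organisms - 1L) != 0) {
    abort("`n_organisms` must be a power of 2 (>= 4).")
  }
  if (clade_size < 2 || n_organisms %% clade_size != 0 ||
      bitwAnd(clade_size, clade_size - 1L) != 0) {
    abort("`clade_size` must be a power of 2 dividing `n_organisms`.")
  }
  if (media_per_clade < 1 || pairings_per_organism < 1) {
    abort("Need at least one medium per clade and one pairing per organism.")
  }
  if (abs(sum(richness_mix) - 1) > 1e-8 ||
      !all(c("low", "medium", "high") %in% names(richness_mix))) {
    abort("`richness_mix` needs probabilities for low/medium/high summing to 1.")
  }
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic taxonomy, media library and growth database
#'
#' See [synth_config()] for the generative model.  Media compositions are
#' simple but honest: dissociated Na+/Cl- at either high-salt (20 g/l
#' NaCl-equivalent) or low-salt (2 g/l) levels, a complex digest at a g/l
#' level matching the planted richness class (2 / 10 / 20 g/l), and a
#' carbon source (a polysaccharide for half the clades, a sugar otherwise),
#' so that salt classification, richness scoring and category enrichment
#' all operate on the same compiled representation they would see on real
#' compiled media.  Organism salt/oxygen classes are planted per clade and
#' all of a clade's preferred media match them, so at full signal the
#' derived organism profiles agree with the planted ones by construction.
#'
#' @param cfg A [synth_config()].
#' @return A `synth_data` list: `tax` ([taxonomy_index()]), `db`
#'   ([growth_db()]), `library` ([media_library()]), `media` (metadata
#'   tibble with `medium_id`, `name`, `oxygen_status`, `salt_status`,
#'   `richness_class`, `clade`), `media_categories` (long tibble
#'   `medium_id`, `category`), `envs` ([environment_table()]) and `truth`
#'   (ground-truth ledger: planted organism classes, clade assignments and
#'   clade media preferences — sufficient to compute exact expected values
#'   for every recovery test).
#' @export
synth_generate <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  local_seed(cfg$seed)

  tree <- balanced_taxonomy(cfg$n_organisms)
  tax <- taxonomy_index(tree)
  orgs <- tax$tips
  n_clades <- cfg$n_organisms / cfg$clade_size
  clade_of <- rep(sprintf("clade%02d", seq_len(n_clades)),
                  each = cfg$clade_size)

  clades <- tibble(
    clade = sprintf("clade%02d", seq_len(n_clades)),
    oxygen_class = ifelse(runif(n_clades) < cfg$frac_anaerobic,
                          "anaerobic", "aerobic"),
    salt_class = ifelse(runif(n_clades) < cfg$frac_salty, "high", "low"),
    richness_class = sample(names(cfg$richness_mix), n_clades, replace = TRUE,
                            prob = cfg$richness_mix),
    carbon = sample(c("polysaccharide", "sugar"), n_clades, replace = TRUE)
  )

  media_rows <- list()
  variants <- list()
  cat_rows <- list()
  complex_g <- c(low = 2, medium = 10, high = 20)
  for (i in seq_len(n_clades)) {
    for (j in seq_len(cfg$media_per_clade)) {
      mid <- sprintf("m%03d", (i - 1) * cfg$media_per_clade + j)
      salty <- clades$salt_class[i] == "high"
      nacl_g <- if (salty) 20 else 2
      carbon_id <- if (clades$carbon[i] == "polysaccharide") "xylan" else "glucose"
      carbon_mw <- if (carbon_id == "xylan") 600 else 180.16
      comps <- tibble(
        compound_id = c("Na+", "Cl-", "complex-meat", carbon_id),
        amount = c(nacl_g / 58.44, nacl_g / 58.44,
                   complex_g[[clades$richness_class[i]]], 2 / carbon_mw),
        unit = c("mol_per_l", "mol_per_l", "g_per_l", "mol_per_l"),
        class = c("defined", "defined", "complex", "defined"),
        category = c(NA, NA, "meat", NA),
        g_per_l = c(nacl_g / 58.44 * 22.99, nacl_g / 58.44 * 35.45,
                    complex_g[[clades$richness_class[i]]], 2)
      )
      v <- medium_variant(mid, name = paste("synthetic medium", mid),
                          components = comps, ph = 7,
                          oxygen_status = clades$oxygen_class[i])
      variants[[mid]] <- v
      media_rows[[mid]] <- tibble(
        medium_id = mid, name = v$name,
        oxygen_status = clades$oxygen_class[i],
        salt_status = classify_salt(v),
        richness_class = clades$richness_class[i],
        clade = clades$clade[i])
      cat_rows[[mid]] <- tibble(
        medium_id = mid,
        category = c("common-ion", "complex-meat", clades$carbon[i]))
    }
  }
  media <- dplyr::bind_rows(media_rows)
  media_categories <- dplyr::bind_rows(cat_rows)
  pref <- split(media$medium_id, media$clade)

  # planted pairings: per organism, each documented slot comes from the
  # clade preference set with probability s, else uniform over all media
  all_media <- media$medium_id
  pair_rows <- lapply(seq_along(orgs), function(k) {
    clade_media <- pref[[clade_of[k]]]
    n_clade <- stats::rbinom(1, cfg$pairings_per_organism, cfg$signal)
    picks <- c(
      sample(clade_media, min(n_clade, length(clade_media))),
      if (cfg$pairings_per_organism - n_clade > 0)
        sample(all_media, cfg$pairings_per_organism - n_clade)
    )
    tibble(organism = orgs[k], medium = unique(picks))
  })
  db <- growth_db(dplyr::bind_rows(pair_rows), organisms = orgs,
                  media = all_media)

  envs <- environment_table(dplyr::bind_rows(
    tibble(organism = orgs,
           environment = paste0("env_", clade_of)),
    tibble(organism = orgs,
           environment = sample(paste0("global_env", 1:5),
                                length(orgs), replace = TRUE))[
                                  runif(length(orgs)) < 0.3, ]))

  truth <- list(
    organisms = tibble(organism = orgs, clade = clade_of) |>
      dplyr::left_join(clades, by = "clade"),
    clades = clades,
    clade_media = pref,
    config = cfg)

  structure(list(tax = tax, db = db, library = media_library(variants),
                 media = media, media_categories = media_categories,
                 envs = envs, truth = truth),
            class = "synth_data")
}

#' @export
print.synth_data <- function(x, ...) {
  cat(sprintf("<synth_data: %d organisms, %d media, %d pairings, signal %.2f, seed %d>\n",
              x$tax$total_leaves, nrow(x$media), nrow(x$db),
              x$truth$config$signal, x$truth$config$seed))
  invisible(x)
}

#' Growth database with a planted transitive fraction
#'
#' Builds a database in which a known fraction `f` of all valid transitive
#' tuples (see [mine_patterns()]) carry a documented (A, m3) pairing.  Two
#' group archetypes over three media each are mixed: "clique" groups, where
#' all nine organisms grow on all three media so every tuple mined inside
#' the group is transitive-positive, and "chain" groups (A-organisms on m1
#' only, B on m1+m2, C on m2+m3) where no mined tuple can be positive.
#' The number of groups of each kind is chosen so the positive-tuple
#' fraction of the mixture matches `f`; because tuple counts per archetype
#' are measured by enumeration, the realized fraction (recorded in the
#' returned truth ledger) is exact, not an approximation.
#'
#' @param f Target fraction of transitive-positive tuples, in \[0, 1\].
#' @param seed Integer seed (used only for ID shuffling; the construction
#'   is deterministic).
#' @param min_tuples Lower bound on the total tuple universe, so that
#'   mining e.g. 1,000 patterns stays a small sample of it.
#' @param min_groups Lower bound on the total number of groups, so that the
#'   organism pool is large enough for random controls to be rare events.
#' @return List with `db` ([growth_db()]) and `truth` (target and realized
#'   f, group counts, tuple counts).
#' @export
plant_transitivity <- function(f, seed = 1, min_tuples = 2000,
                               min_groups = 8) {
  if (f < 0 || f > 1) abort("`f` must lie in [0, 1].")

  one_group_db <- function(kind, tag) {
    a <- paste0(tag, "_A", 1:3); b <- paste0(tag, "_B", 1:3)
    c_ <- paste0(tag, "_C", 1:3)
    m <- paste0(tag, "_m", 1:3)
    rows <- if (kind == "clique") {
      expand.grid(organism = c(a, b, c_), medium = m,
                  stringsAsFactors = FALSE)
    } else {
      dplyr::bind_rows(
        tibble(organism = rep(a, 1), medium = m[1]),
        tibble(organism = rep(b, 2), medium = rep(m[1:2], each = 3)),
        tibble(organism = rep(c_, 2), medium = rep(m[2:3], each = 3)))
    }
    as_tibble(rows)
  }
  tuple_count <- function(kind) {
    db1 <- growth_db(one_group_db(kind, "p"))
    sum(vapply(tuple_universe(db1)$triples, function(t) t$count, 0))
  }
  C <- tuple_count("clique")   # positives per clique group
  D <- tuple_count("chain")    # negatives per chain group

  # smallest mixture matching f with at least min_tuples tuples
  best <- NULL
  for (gp in 0:40) {
    gn_exact <- if (f == 0) NA else gp * C * (1 - f) / (D * f)
    gn_cands <- unique(pmax(0, c(floor(gn_exact), ceiling(gn_exact),
                                 if (f == 0) ceiling(max(min_tuples / D,
                                                         min_groups)))))
    gn_cands <- gn_cands[is.finite(gn_cands)]
    for (gn in gn_cands) {
      tot <- gp * C + gn * D
      if (tot < min_tuples || gp + gn < min_groups) next
      realized <- gp * C / tot
      err <- abs(realized - f)
      if (is.null(best) || err < best$err - 1e-12 ||
          (err < best$err + 1e-12 && gp + gn < best$gp + best$gn)) {
        best <- list(gp = gp, gn = gn, err = err, realized = realized)
      }
    }
    if (f == 0) break
  }
  if (is.null(best)) abort("No feasible group mixture found; lower `min_tuples`.")

  local_seed(seed)
  parts <- c(
    lapply(seq_len(best$gp), function(i) one_group_db("clique", sprintf("q%03d", i))),
    lapply(seq_len(best$gn), function(i) one_group_db("chain", sprintf("n%03d", i))))
  db <- growth_db(dplyr::bind_rows(parts))
  list(db = db,
       truth = list(f_target = f, f_realized = best$realized,
                    n_clique_groups = best$gp, n_chain_groups = best$gn,
                    tuples_per_clique = C, tuples_per_chain = D,
                    total_tuples = best$gp * C + best$gn * D))
}

#' Write all synthetic artifacts to a directory
#'
#' Writes the tree (Newick), growth TSV, environment TSV, media metadata
#' TSV and compiled media files, so the full pipeline can be exercised from
#' files exactly as with external data.
#'
#' @param data A `synth_data` from [synth_generate()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_synth_data <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(data$tax$tree, file.path(dir, "tree.nwk"))
  write_growth_db(data$db, file.path(dir, "growth.tsv"))
  readr::write_tsv(tibble(organism_id = data$envs$organism,
                          environment_id = data$envs$environment),
                   file.path(dir, "environments.tsv"), progress = FALSE)
  readr::write_tsv(data$media, file.path(dir, "media_metadata.tsv"),
                   progress = FALSE)
  readr::write_tsv(data$media_categories, file.path(dir, "media_categories.tsv"),
                   progress = FALSE)
  write_media_library(data$library, file.path(dir, "compiled"))
  invisible(dir)
}
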