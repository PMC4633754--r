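# Shared fixtures and independent oracles, all built in code.

tiny_compounds <- function() {
  compound_table(tibble::tibble(
    raw_name = c("NaCl", "CaCl2 x 2 H2O", "glucose", "peptone",
                 "yeast extract", "sea salts", "vitamin mix", "H2"),
    semi_unique_name = c("sodium chloride", "calcium chloride",
                         "glucose", "rich-peptone", "rich-yeast-extract",
                         "rich-sea-salts", "trace-vitamins", "hydrogen"),
    constituent_ids = c("Na+|Cl-", "Ca2+|Cl-", "glucose", "", "", "",
                        "vitamins", "H2"),
    constituent_ratios = c("1|1", "1|2", "1", "", "", "", "1", "1"),
    n_waters = c(0L, 2L, 0L, 0L, 0L, 0L, 0L, 0L),
    # MWs include hydrate waters (CaCl2.2H2O = 110.98 + 2*18.015)
    molecular_weight = c(58.44, 147.01, 180.16, NA, NA, NA, NA, 2.016),
    compound_class = c("defined", "defined", "defined", "complex",
                       "complex", "complex", "other", "defined"),
    category = c(NA, NA, NA, "meat", "microbial", "sea-salts", NA, NA),
    constituent_mws = c("22.99|35.45", "40.08|35.45", "180.16", "", "", "",
                        "", "2.016")
  ))
}

# Brute-force subtree-distance oracle: explicit ancestor-path LCA
# enumeration, independent of the mrca-matrix implementation.
oracle_phylo_distance <- function(tree, a, b) {
  n_tip <- length(tree$tip.label)
  parent <- integer(n_tip + tree$Nnode)
  for (i in seq_len(nrow(tree$edge))) parent[tree$edge[i, 2]] <- tree$edge[i, 1]
  ancestors <- function(node) {
    path <- node
    while (parent[node] != 0) {
      node <- parent[node]
      path <- c(path, node)
    }
    path
  }
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  common <- intersect(ancestors(ia), ancestors(ib))
  lca <- common[1]                       # paths are tip -> root, so first hit
  tips_below <- function(node) {
    if (node <= n_tip) return(1L)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    sum(vapply(kids, tips_below, 1L))
  }
  tips_below(lca) / n_tip
}

# Brute-force transitive-tuple oracle: full loop over all ordered media
# triples and organism triples.
oracle_tuples <- function(db, min_orgs = 3, max_orgs = 100) {
  pop <- popularity_table(db, "medium")
  media <- pop$id[pop$popularity >= min_orgs & pop$popularity <= max_orgs]
  key <- paste(db$organism, db$medium)
  on <- function(o, m) paste(o, m) %in% key
  orgs <- db_organisms(db)
  out <- list()
  for (m1 in media) for (m2 in setdiff(media, m1))
    for (m3 in setdiff(media, c(m1, m2)))
      for (B in orgs) {
        if (!(on(B, m1) && on(B, m2))) next
        for (A in setdiff(orgs, B)) {
          if (!on(A, m1)) next
          for (C in setdiff(orgs, c(A, B))) {
            if (on(C, m2) && on(C, m3)) {
              out[[length(out) + 1]] <- c(A = A, B = B, C = C,
                                          m1 = m1, m2 = m2, m3 = m3)
            }
          }
        }
      }
  if (!length(out)) {
    return(tibble::tibble(A = character(), B = character(), C = character(),
                          m1 = character(), m2 = character(), m3 = character()))
  }
  tibble::as_tibble(do.call(rbind, out))
}

# Exhaustive binomial upper-tail oracle for small n: enumerate all 2^n
# outcome vectors.
oracle_binomial_tail <- function(k, n, p) {
  outcomes <- expand.grid(rep(list(c(0, 1)), n))
  probs <- apply(outcomes, 1, function(x) prod(ifelse(x == 1, p, 1 - p)))
  sum(probs[rowSums(outcomes) >= k])
}

# Exact two-sided rank-sum oracle: enumerate all group-label assignments.
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  combined <- c(x, y)
  r <- rank(combined)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U of x
  idx <- utils::combn(n1 + n2, n1)
  w_all <- apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  pl <- mean(w_all <= w_obs)
  pu <- mean(w_all >= w_obs)
  list(statistic = w_obs, p = min(1, 2 * min(pl, pu)))
}

# A 100-leaf tree where org "a" has neighbours at exact subtree distances
# 0.02 (b) and 0.04 (c, d): (((a,b),(c,d)), 96 further leaves).
collab_test_tree <- function() {
  rest <- paste0("t", sprintf("%02d", 1:96))
  fold <- function(labels) {
    if (length(labels) == 1) return(labels)
    half <- ceiling(length(labels) / 2)
    paste0("(", fold(labels[seq_len(half)]), ",",
           fold(labels[-seq_len(half)]), ")")
  }
  ape::read.tree(text = paste0("((((a,b),(c,d)),", fold(rest), "));"))
}
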