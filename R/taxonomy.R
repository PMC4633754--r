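#' Taxonomy index over a rooted tree of organisms
#'
#' Wraps an `ape::phylo` tree whose tips are organism IDs, precomputing the
#' leaf count beneath every node and the matrix of pairwise normalized
#' subtree distances.  The subtree distance between two organisms is the
#' number of leaves beneath their lowest common ancestor divided by the total
#' number of leaves in the tree, so it lies in (0, 1]: identical organisms
#' score 1/total_leaves and organisms whose only common ancestor is the root
#' score 1.  Phylogenetic similarity is defined as 1 - distance.
#'
#' Branch lengths are ignored throughout: the distance is purely topological,
#' which makes it robust to trees assembled from taxonomies rather than
#' molecular data.
#'
#' @param tree An `ape::phylo` object, or a path to a Newick file, or a
#'   two-column parent-child data frame (columns `parent`, `child`; leaves
#'   are children that never appear as parents).
#' @return A `taxonomy_index` with elements `tree`, `tips`, `total_leaves`
#'   and the full pairwise distance matrix `dist`.
#' @examples
#' tr <- ape::read.tree(text = "((a,b),(c,d));")
#' tax <- taxonomy_index(tr)
#' phylo_distance(tax, "a", "b")   # 2/4
#' phylo_distance(tax, "a", "c")   # 1
#' @export
taxonomy_index <- function(tree) {
  if (is.character(tree) && length(tree) == 1) {
    tree <- ape::read.tree(tree)
  } else if (is.data.frame(tree)) {
    tree <- tree_from_edges(tree)
  }
  if (!inherits(tree, "phylo")) abort("`tree` must be a phylo object.")
  if (anyDuplicated(tree$tip.label)) abort("Tree tip labels must be unique.")
  n <- length(tree$tip.label)
  mrca <- ape::mrca(tree)                       # tip x tip node numbers
  leafcount <- node_leaf_counts(tree)           # indexed by node number
  d <- matrix(leafcount[mrca], n, n,
              dimnames = list(tree$tip.label, tree$tip.label)) / n
  diag(d) <- 1 / n
  structure(list(tree = tree, tips = tree$tip.label,
                 total_leaves = n, dist = d),
            class = "taxonomy_index")
}

#' @export
print.taxonomy_index <- function(x, ...) {
  cat(sprintf("<taxonomy_index: %d leaves>\n", x$total_leaves))
  invisible(x)
}

# Leaf count beneath every node (tips count 1), vector indexed by node id.
node_leaf_counts <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  counts <- c(rep(1L, n_tip), rep(0L, n_node - n_tip))
  # postorder guarantees children are summed before their parent
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(edges))) {
    counts[edges[i, 1]] <- counts[edges[i, 1]] + counts[edges[i, 2]]
  }
  counts
}

# Build a phylo from a parent-child table via Newick text.
tree_from_edges <- function(edges) {
  if (!all(c("parent", "child") %in% names(edges))) {
    abort("Parent-child table needs columns `parent` and `child`.")
  }
  parent <- as.character(edges$parent)
  child <- as.character(edges$child)
  roots <- setdiff(parent, child)
  if (length(roots) != 1) {
    abort(sprintf("Expected exactly one root, found: %s.",
                  paste(roots, collapse = ", ")))
  }
  kids <- split(child, factor(parent, levels = unique(parent)))
  build <- function(node, seen = character()) {
    if (node %in% seen) abort(sprintf("Cycle at node '%s'.", node))
    ch <- kids[[node]]
    if (is.null(ch) || !length(ch)) return(node)
    paste0("(", paste(vapply(ch, build, "", seen = c(seen, node)),
                      collapse = ","), ")")
  }
  ape::read.tree(text = paste0(build(roots), ";"))
}

#' Normalized phylogenetic subtree distance
#'
#' @param tax A [taxonomy_index()].
#' @param a,b Organism IDs (vectorized, recycled).
#' @return Numeric distances in (0, 1].
#' @export
phylo_distance <- function(tax, a, b) {
  stopifnot(inherits(tax, "taxonomy_index"))
  missing <- setdiff(unique(c(a, b)), tax$tips)
  if (length(missing)) {
    abort(sprintf("Organism(s) not in tree: %s.",
                  paste(missing, collapse = ", ")))
  }
  tax$dist[cbind(a, b)]
}

#' Organisms shared between a growth database and a taxonomy
#'
#' Organisms present in the database but absent from the tree are retained in
#' the database but excluded from phylogeny-based operations; this helper
#' reports the usable set and warns about the excluded ones.
#'
#' @param db A [growth_db()].
#' @param tax A [taxonomy_index()].
#' @return Character vector of organism IDs present in both.
#' @export
phylo_organisms <- function(db, tax) {
  orgs <- db_organisms(db)
  out <- intersect(orgs, tax$tips)
  dropped <- setdiff(orgs, tax$tips)
  if (length(dropped)) {
    warn(sprintf(
      "%d organism(s) absent from the tree are excluded from phylogeny-based operations (e.g. '%s').",
      length(dropped), dropped[1]))
  }
  out
}

#' Balanced binary taxonomy over n organisms
#'
#' Convenience constructor used by the synthetic-data generator: a balanced
#' binary tree with tips `org001 ...`.  `n` must be a power of two.
#'
#' @param n Number of organisms (power of 2).
#' @param prefix Tip label prefix.
#' @return An `ape::phylo`.
#' @export
balanced_taxonomy <- function(n, prefix = "org") {
  if (n < 2 || bitwAnd(n, n - 1L) != 0) abort("`n` must be a power of 2 (>= 2).")
  labels <- sprintf("%s%03d", prefix, seq_len(n))
  build <- function(idx) {
    if (length(idx) == 1) return(labels[idx])
    half <- length(idx) / 2
    paste0("(", build(idx[seq_len(half)]), ",",
           build(idx[-seq_len(half)]), ")")
  }
  ape::read.tree(text = paste0(build(seq_len(n)), ";"))
}
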