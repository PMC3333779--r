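#' Patristic distance matrix of a tree
#'
#' Pairwise path lengths between leaves through their most recent common
#' ancestor (sum of branch lengths along the connecting path), computed with
#' [ape::cophenetic.phylo()].
#'
#' @param tree An \pkg{ape} `phylo` object (see [read_newick_tree()]).
#' @return A symmetric matrix of leaf-to-leaf distances.
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    warnf("tree has no branch lengths; using unit lengths")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  stats::cophenetic(tree)
}

#' Patristic distance between two leaves
#'
#' @param tree An \pkg{ape} `phylo` object.
#' @param a,b Leaf labels.
#' @return Non-negative path length between `a` and `b`.
#' @export
pairwise_tree_distance <- function(tree, a, b) {
  d <- patristic_distances(tree)
  for (leaf in c(a, b)) {
    if (!leaf %in% rownames(d)) stopf("leaf '%s' not in tree", leaf)
  }
  unname(d[a, b])
}

#' Correlation between pairwise bias difference and phylogenetic distance
#'
#' For every unordered pair of organisms present in both the profile table
#' and the tree, computes the absolute difference in the chosen bias measure
#' (default CAI_ave) and the patristic distance, and correlates the two over
#' all pairs. Absence of correlation indicates that the extent of codon
#' usage bias is not explained by phylogenetic relatedness.
#'
#' @param profiles A genome profile table.
#' @param tree An \pkg{ape} `phylo` object.
#' @param measure Profile column to difference (default `"cai_ave"`).
#' @return A list: `correlation` (a `correlation_result`) and `pairs`, a data
#'   frame with one row per pair (`org_a`, `org_b`, `delta` = absolute
#'   measure difference, `distance` = patristic distance), suitable for a
#'   scatter plot.
#' @export
bias_distance_correlation <- function(profiles, tree, measure = "cai_ave") {
  stopifnot(is.data.frame(profiles), inherits(tree, "phylo"))
  shared <- intersect(profiles$organism_id, tree$tip.label)
  if (length(shared) < 3L) {
    stopf("need at least 3 organisms shared between profiles and tree (have %d)",
          length(shared))
  }
  vals <- setNames(profiles[[measure]][match(shared, profiles$organism_id)],
                   shared)
  d <- patristic_distances(tree)[shared, shared]
  idx <- utils::combn(length(shared), 2L)
  pairs <- data.frame(
    org_a = shared[idx[1L, ]],
    org_b = shared[idx[2L, ]],
    delta = abs(vals[idx[1L, ]] - vals[idx[2L, ]]),
    distance = d[cbind(idx[1L, ], idx[2L, ])],
    stringsAsFactors = FALSE
  )
  rownames(pairs) <- NULL
  if (stats::var(pairs$delta) == 0) {
    stopf("degenerate x: all organisms have identical %s", measure)
  }
  list(correlation = pearson_correlation(pairs$delta, pairs$distance),
       pairs = pairs)
}

#' Select a phylogenetically remote subset of leaves
#'
#' Greedy maximin selection: starts from the most distant leaf pair and
#' repeatedly adds the leaf whose minimum patristic distance to the current
#' selection is largest, stopping at `n` leaves or when no remaining leaf is
#' at least `min_dist` from every selected leaf. Used to build redundancy-
#' reduced organism subsets for robustness analyses.
#'
#' @param tree An \pkg{ape} `phylo` object.
#' @param n Maximum subset size.
#' @param min_dist Minimum acceptable distance to the selected set.
#' @return Character vector of selected leaf labels.
#' @export
select_remote_taxa <- function(tree, n, min_dist = 0) {
  stopifnot(inherits(tree, "phylo"), n >= 2L)
  d <- patristic_distances(tree)
  leaves <- rownames(d)
  start <- which(d == max(d), arr.ind = TRUE)[1L, ]
  sel <- leaves[start]
  while (length(sel) < n) {
    rest <- setdiff(leaves, sel)
    if (length(rest) == 0L) break
    min_to_sel <- apply(d[rest, sel, drop = FALSE], 1L, min)
    best <- which.max(min_to_sel)
    if (min_to_sel[best] < min_dist) break
    sel <- c(sel, rest[best])
  }
  sel
}
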