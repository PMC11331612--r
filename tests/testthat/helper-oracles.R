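# Independent brute-force oracles used to validate the fast implementations.

# Tip-index sets of every node's clade, from the edge matrix alone.
tip_sets_from_edges <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  sets <- vector("list", n_all)
  for (i in seq_len(n_tip)) sets[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    sets[[p]] <- sort(c(sets[[p]], sets[[ch]]))
  }
  sets
}

# Exhaustive maximal-valid-clade partition: enumerate every clade, keep those
# whose max pairwise leaf distance is within the threshold, select the ones
# with no valid proper ancestor.  Returns a canonical set-of-leaf-sets.
oracle_max_clade <- function(tree, threshold, tol = 1e-12) {
  n_tip <- length(tree$tip.label)
  d <- ape::cophenetic.phylo(tree)[tree$tip.label, tree$tip.label]
  sets <- tip_sets_from_edges(tree)
  valid <- vapply(sets, function(s) {
    if (length(s) < 2) TRUE
    else max(d[tree$tip.label[s], tree$tip.label[s]]) <= threshold + tol
  }, logical(1))
  parent <- rep(NA_integer_, length(sets))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  has_valid_ancestor <- vapply(seq_along(sets), function(v) {
    p <- parent[v]
    while (!is.na(p)) {
      if (valid[p]) return(TRUE)
      p <- parent[p]
    }
    FALSE
  }, logical(1))
  keep <- which(valid & !has_valid_ancestor)
  canonical_sets(lapply(keep, function(v) tree$tip.label[sets[[v]]]))
}

canonical_sets <- function(sets) {
  sets <- lapply(sets, sort)
  unname(sort(vapply(sets, paste, "", collapse = "|")))
}

partition_sets <- function(partition) {
  canonical_sets(split(names(partition$assignment), partition$assignment))
}

# Root-path-intersection MRCA oracle, using only the hierarchy's raw parent
# links (not the package's LCA walk).
oracle_mrca <- function(h, names) {
  paths <- lapply(names, function(nm) {
    i <- unname(h$index[mtgrouper::hg_core(nm)])
    path <- integer(0)
    while (!is.na(i)) {
      path <- c(i, path)  # root first
      i <- h$parent[i]
    }
    path
  })
  common <- Reduce(intersect, paths)
  # deepest common node = last on the root-first path present in all
  h$labels[common[length(common)]]
}

# One finer partition refines one coarser one: every fine cluster lies inside
# a single coarse cluster.
refines <- function(fine, coarse) {
  all(tapply(coarse$assignment[names(fine$assignment)], fine$assignment,
             function(v) length(unique(v)) == 1L))
}
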