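# Rooted weighted tree model: Newick I/O, leaf path distances, and the
# max-clade partition — the algorithm-based grouping at the heart of the
# package.  A max-clade partition at threshold t cuts the tree into the
# highest clades whose maximum within-clade leaf-to-leaf path distance does
# not exceed t; every leaf belongs to exactly one such clade.

# Absolute slack for threshold comparisons, guarding accumulated
# floating-point summation noise on branch-length sums.
.DIST_TOL <- 1e-12

#' Read a Newick tree
#'
#' Thin wrapper around [ape::read.tree()] that validates the result for use
#' here: unique leaf labels, no negative branch lengths.  Surrounding quotes
#' on labels are stripped.  Square-bracket comments are not supported by the
#' underlying reader and should be removed upstream.
#'
#' @param text A Newick string (semicolon-terminated) or a file path.
#' @return A rooted `phylo` object.
#' @export
read_newick <- function(text) {
  tr <- if (grepl(";[[:space:]]*$", text) && !file.exists(text))
    ape::read.tree(text = text) else ape::read.tree(file = text)
  if (is.null(tr))
    stop_mtg("could not parse Newick input", class = "mtg_error_newick")
  unquote <- function(x) sub("^'(.*)'$", "\\1", x)
  tr$tip.label <- unquote(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- unquote(tr$node.label)
  if (anyDuplicated(tr$tip.label))
    stop_mtg("duplicate leaf label '%s'",
             tr$tip.label[anyDuplicated(tr$tip.label)],
             class = "mtg_error_newick")
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop_mtg("negative branch length in Newick input",
             class = "mtg_error_newick")
  tr
}

#' Write a tree as Newick
#'
#' @param tree A `phylo` object.
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @param digits Printed precision for branch lengths.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

check_weighted_rooted <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree))
    stop_mtg("tree must be rooted (root it, e.g. on an outgroup such as the RSRS, before clustering)",
             class = "mtg_error_tree")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop_mtg("tree must have branch lengths on all edges",
             class = "mtg_error_tree")
  if (any(tree$edge.length < 0))
    stop_mtg("negative branch lengths are not allowed", class = "mtg_error_tree")
  invisible(tree)
}

#' Leaf pairwise path-distance matrix
#'
#' Sum of branch lengths along the unique path between every pair of leaves,
#' in the units of the branch lengths (typically substitutions/site).
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @return A symmetric numeric matrix with zero diagonal, rows/columns in
#'   `tree$tip.label` order.
#' @export
leaf_distance_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop_mtg("tree must have branch lengths on all edges",
             class = "mtg_error_tree")
  if (any(tree$edge.length < 0))
    stop_mtg("negative branch lengths are not allowed", class = "mtg_error_tree")
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label, drop = FALSE]
}

# Per-node subtree summaries needed by the max-clade criterion: for every
# node, the max leaf depth below it and the subtree's leaf-pair diameter.
# One postorder sweep over the edge matrix; no recursion.
clade_diameters <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  down <- numeric(n_all)          # max root-ward distance to a leaf below
  diam <- numeric(n_all)          # max over child subtree diameters
  best1 <- rep(-Inf, n_all)       # two largest child depths (child dist + edge)
  best2 <- rep(-Inf, n_all)
  finalize <- function(v) {
    if (v > n_tip && best2[v] > -Inf) max(diam[v], best1[v] + best2[v])
    else diam[v]
  }
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]; len <- po$edge.length[e]
    diam[ch] <- finalize(ch)               # child subtree complete by postorder
    d <- down[ch] + len
    diam[p] <- max(diam[p], diam[ch])
    down[p] <- max(down[p], d)
    if (d > best1[p]) { best2[p] <- best1[p]; best1[p] <- d }
    else if (d > best2[p]) best2[p] <- d
  }
  root <- n_tip + 1L
  diam[root] <- finalize(root)
  list(diameter = diam, max_depth = down)
}

#' Max-clade partition of tree leaves
#'
#' Partitions the leaves of a rooted weighted tree into maximal clades whose
#' maximum within-clade pairwise path distance is at most `threshold`
#' (inclusive, with an absolute tolerance of 1e-12).  Every leaf receives a
#' cluster id, singletons included; for every emitted non-root clade the
#' parent clade violates the threshold, so the partition is unique.
#'
#' The algorithm is linear in the number of edges: a postorder sweep computes
#' each clade's leaf-pair diameter (the two deepest leaf paths through
#' distinct children), then a top-down pass emits a cluster at every highest
#' valid clade.  Cluster ids are assigned in ascending order of each
#' cluster's smallest tip index, so identical inputs always yield identical
#' ids.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param threshold Non-negative distance threshold, in branch-length units.
#' @return An object of class `"clade_partition"`: list with `threshold`,
#'   `assignment` (named integer vector, leaf label -> cluster id, ids dense
#'   from 1) and `n_clusters`.
#' @examples
#' tr <- read_newick("(((A:1,B:1):1,(C:1,D:1):1):2,(E:1,F:3):2);")
#' max_clade_partition(tr, 4)$assignment
#' @export
max_clade_partition <- function(tree, threshold) {
  check_weighted_rooted(tree)
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0)
    stop_mtg("threshold must be a single non-negative number",
             class = "mtg_error_threshold")
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  cd <- clade_diameters(tree)
  valid <- cd$diameter <= threshold + .DIST_TOL

  # Top-down over the cladewise edge order: a node inside an emitted cluster
  # is covered; otherwise emit it if its clade is valid, else descend.
  covered <- logical(n_tip + tree$Nnode)
  emitted <- integer(0)
  if (valid[root]) {
    emitted <- root
    covered[root] <- TRUE
  }
  cw <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(cw$edge))) {
    p <- cw$edge[e, 1]; ch <- cw$edge[e, 2]
    if (covered[p]) {
      covered[ch] <- TRUE
    } else if (valid[ch]) {
      covered[ch] <- TRUE
      emitted <- c(emitted, ch)
    }
  }
  tipsets <- lapply(emitted, function(v) {
    if (v <= n_tip) v else phangorn::Descendants(tree, v, type = "tips")[[1]]
  })
  ord <- order(vapply(tipsets, min, numeric(1)))
  assignment <- integer(n_tip)
  for (k in seq_along(ord)) assignment[tipsets[[ord[k]]]] <- k
  names(assignment) <- tree$tip.label
  structure(list(threshold = threshold, assignment = assignment,
                 n_clusters = length(emitted)),
            class = "clade_partition")
}

#' @export
print.clade_partition <- function(x, ...) {
  cat(sprintf("<clade_partition> threshold %g: %d leaves in %d clusters\n",
              x$threshold, length(x$assignment), x$n_clusters))
  invisible(x)
}

#' Max-clade partitions over a decreasing threshold ladder
#'
#' Runs [max_clade_partition()] at each threshold of a strictly decreasing
#' ladder.  By monotonicity of the max-clade constraint, each partition
#' refines all coarser ones and cluster counts are non-decreasing as the
#' threshold decreases.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param thresholds Strictly decreasing numeric vector, all `>= 0`.
#' @return A named list of `clade_partition` objects (names = thresholds).
#' @export
threshold_sweep <- function(tree, thresholds) {
  if (length(thresholds) == 0L || any(thresholds < 0) ||
      any(diff(thresholds) >= 0))
    stop_mtg("thresholds must be a strictly decreasing ladder of non-negative values",
             class = "mtg_error_threshold")
  out <- lapply(thresholds, function(t) max_clade_partition(tree, t))
  names(out) <- format(thresholds, trim = TRUE, scientific = FALSE)
  out
}

#' Write a cluster partition as TSV with a JSON run manifest
#'
#' @param partition A `clade_partition`.
#' @param path Output TSV path (`sample_id<TAB>cluster_id`); a JSON manifest
#'   with the threshold and cluster count is written beside it as
#'   `<path>.json`.
#' @param tree_file Optional path of the source tree, recorded (with its md5)
#'   in the manifest.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path, tree_file = NULL) {
  df <- data.frame(sample_id = names(partition$assignment),
                   cluster_id = unname(partition$assignment))
  write_tsv_strict(df, path)
  meta <- list(threshold = partition$threshold,
               n_clusters = partition$n_clusters,
               n_leaves = length(partition$assignment))
  if (!is.null(tree_file))
    meta$tree <- list(file = tree_file,
                      md5 = unname(tools::md5sum(tree_file)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
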