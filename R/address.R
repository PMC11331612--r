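# mtHg-addresses: hierarchical cluster addresses over a decreasing threshold
# ladder, plus MRCA-haplogroup naming of grouping levels (macro/meso/micro).
#
# An address is the ordered list of a sample's max-clade cluster ids across
# the ladder, rendered as numbers joined with "." (e.g. 2.2.4.4.4.5.5.5.5).
# Because finer partitions refine coarser ones, equal components at one
# position imply equality at all coarser positions (prefix consistency), and
# a ladder ending at 0 gives identical addresses exactly to identical
# haplotypes (zero tree distance).

#' Default threshold ladder
#'
#' Nine strictly decreasing thresholds from 0.008 down to 0 (in
#' substitutions/site), the illustrative ladder used throughout the package.
#'
#' @return Numeric vector of length 9.
#' @export
default_ladder <- function() c(0.008, 0.007, 0.006, 0.005, 0.004, 0.003,
                               0.002, 0.001, 0)

check_ladder <- function(ladder) {
  if (length(ladder) == 0L || any(ladder < 0) || any(diff(ladder) >= 0))
    stop_mtg("ladder must be strictly decreasing with all values >= 0",
             class = "mtg_error_ladder")
  invisible(ladder)
}

#' Assign mtHg-addresses across a threshold ladder
#'
#' Computes a max-clade partition at every ladder threshold and stacks the
#' per-level cluster ids into one dotted address per leaf.  Cluster ids are
#' per level (the same number may recur across levels).
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param ladder Strictly decreasing non-negative thresholds; defaults to
#'   [default_ladder()].
#' @return A data frame with `sample_id`, one integer column `tc_<threshold>`
#'   per ladder level, and `mthg_address` (components joined with ".").  The
#'   ladder is attached as attribute `"ladder"`.
#' @export
assign_addresses <- function(tree, ladder = default_ladder()) {
  check_ladder(ladder)
  parts <- threshold_sweep(tree, ladder)
  comp <- vapply(parts, function(p) p$assignment[tree$tip.label],
                 integer(length(tree$tip.label)))
  comp <- matrix(comp, nrow = length(tree$tip.label),
                 dimnames = list(NULL, paste0("tc_", names(parts))))
  out <- data.frame(sample_id = tree$tip.label, comp,
                    mthg_address = apply(comp, 1, paste, collapse = "."),
                    check.names = FALSE)
  attr(out, "ladder") <- ladder
  out
}

parse_address <- function(a) {
  if (is.character(a)) as.integer(strsplit(a, ".", fixed = TRUE)[[1]])
  else as.integer(a)
}

#' Finest threshold at which two addresses agree
#'
#' Compares two mtHg-addresses built on the same ladder and returns the
#' smallest (finest) ladder threshold at which the two samples still fall in
#' the same cluster, i.e. the threshold at the end of their longest shared
#' address prefix.  Returns `NA` when the addresses already differ at the
#' coarsest level.
#'
#' @param a,b Addresses: dotted strings (`"2.2.4.4.4.5.5.5.5"`) or integer
#'   vectors of per-level cluster ids.
#' @param ladder The decreasing threshold ladder the addresses were built on.
#' @return A single threshold value, or `NA_real_`.
#' @examples
#' finest_shared_threshold("2.2.4.4.4.5.5.5.5", "2.2.4.4.6.6.6.6.6")  # 0.005
#' @export
finest_shared_threshold <- function(a, b, ladder = default_ladder()) {
  check_ladder(ladder)
  a <- parse_address(a); b <- parse_address(b)
  if (length(a) != length(b) || length(a) != length(ladder))
    stop_mtg("addresses and ladder must all have the same length (got %d, %d, %d)",
             length(a), length(b), length(ladder), class = "mtg_error_ladder")
  eq <- a == b
  k <- if (all(eq)) length(eq) else which(!eq)[1] - 1L
  if (k == 0L) NA_real_ else ladder[k]
}

#' Name the clusters of one partition by MRCA haplogroup
#'
#' Each cluster is named by the MRCA haplogroup (in `hierarchy`) of the
#' haplogroups of its member leaves.  A cluster whose members all carry the
#' same haplogroup is named by that haplogroup directly, without a hierarchy
#' lookup.
#'
#' @param partition A `clade_partition`.
#' @param leaf_haplogroups Named character vector, leaf label -> haplogroup.
#' @param hierarchy An `hg_hierarchy`.
#' @return A named character vector: cluster id -> haplogroup name.
#' @export
name_level <- function(partition, leaf_haplogroups, hierarchy) {
  leaves <- names(partition$assignment)
  missing <- setdiff(leaves, names(leaf_haplogroups))
  if (length(missing))
    stop_mtg("no haplogroup given for leaf '%s'", missing[1],
             class = "mtg_error_lookup")
  ids <- sort(unique(partition$assignment))
  nm <- vapply(ids, function(k) {
    hgs <- unique(leaf_haplogroups[leaves[partition$assignment == k]])
    if (length(hgs) == 1L) unname(hgs) else hg_mrca(hierarchy, hgs)
  }, character(1))
  stats::setNames(nm, ids)
}

#' Per-sample table with named grouping levels and mtHg-address
#'
#' Combines addresses over `ladder` with MRCA-haplogroup naming at the
#' configured macro/meso/micro thresholds into one table per sample, in the
#' spirit of an augmented haplogroup-caller output.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param leaf_haplogroups Named character vector, leaf label -> haplogroup.
#' @param hierarchy An `hg_hierarchy` resolving all (modifier-stripped)
#'   haplogroups.
#' @param ladder Strictly decreasing thresholds; defaults to
#'   [default_ladder()].
#' @param levels Named numeric vector with entries `macro`, `meso`, `micro`;
#'   each value must be a ladder threshold and macro >= meso >= micro.  The
#'   defaults (0.006/0.005/0.004) are illustrative, not a standard.
#' @return A data frame with columns `sample_id`, `haplogroup`, `micro_hg`,
#'   `meso_hg`, `macro_hg`, `mthg_address`.
#' @export
designate_levels <- function(tree, leaf_haplogroups, hierarchy,
                             ladder = default_ladder(),
                             levels = c(macro = 0.006, meso = 0.005,
                                        micro = 0.004)) {
  check_ladder(ladder)
  need <- c("macro", "meso", "micro")
  if (!all(need %in% names(levels)))
    stop_mtg("levels must name macro, meso and micro thresholds",
             class = "mtg_error_config")
  levels <- levels[need]
  if (!(levels["macro"] >= levels["meso"] && levels["meso"] >= levels["micro"]))
    stop_mtg("level thresholds must satisfy macro >= meso >= micro",
             class = "mtg_error_config")
  if (!all(levels %in% ladder))
    stop_mtg("level threshold %g is not on the ladder",
             levels[!(levels %in% ladder)][1], class = "mtg_error_config")
  addr <- assign_addresses(tree, ladder)
  parts <- threshold_sweep(tree, ladder)
  level_name <- function(t) {
    p <- parts[[match(t, ladder)]]
    nm <- name_level(p, leaf_haplogroups, hierarchy)
    unname(nm[as.character(p$assignment[tree$tip.label])])
  }
  data.frame(
    sample_id = tree$tip.label,
    haplogroup = unname(leaf_haplogroups[tree$tip.label]),
    micro_hg = level_name(levels["micro"]),
    meso_hg = level_name(levels["meso"]),
    macro_hg = level_name(levels["macro"]),
    mthg_address = addr$mthg_address
  )
}
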