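# Haplogroup hierarchy: a rooted, node-labelled tree of haplogroup names,
# supporting MRCA-haplogroup lookup.  Read from a two-column child/parent TSV
# or from a Newick string with internal node labels.

new_hg_hierarchy <- function(labels, parent) {
  stopifnot(length(labels) == length(parent))
  if (anyDuplicated(labels))
    stop_mtg("duplicate haplogroup name in hierarchy: '%s'",
             labels[anyDuplicated(labels)], class = "mtg_error_hierarchy")
  root <- which(is.na(parent))
  if (length(root) != 1L)
    stop_mtg("hierarchy must have exactly one root (found %d)", length(root),
             class = "mtg_error_hierarchy")
  # depth by walking up; also detects cycles
  n <- length(labels)
  depth <- rep(NA_integer_, n)
  depth[root] <- 0L
  for (i in seq_len(n)) {
    if (!is.na(depth[i])) next
    path <- i
    j <- i
    while (is.na(depth[j])) {
      j <- parent[j]
      if (is.na(j) || j %in% path)
        stop_mtg("hierarchy is cyclic or disconnected at '%s'", labels[i],
                 class = "mtg_error_hierarchy")
      path <- c(path, j)
    }
    d <- depth[j]
    for (k in rev(path[-length(path)])) {
      d <- d + 1L
      depth[k] <- d
    }
  }
  structure(list(labels = labels, parent = parent, depth = depth,
                 root = root, index = stats::setNames(seq_len(n), labels)),
            class = "hg_hierarchy")
}

#' Read a haplogroup hierarchy
#'
#' Reads a rooted, uniquely node-labelled haplogroup hierarchy either from a
#' two-column tab-separated file with header `child<TAB>parent` (the root is
#' any name appearing only as a parent) or from a Newick file/string whose
#' internal nodes are labelled with haplogroup names.
#'
#' @param path Path to a TSV or Newick file, or a Newick string ending in ";".
#' @param format `"auto"` (default; Newick when the content ends in ";"),
#'   `"tsv"` or `"newick"`.
#' @return An object of class `"hg_hierarchy"`.
#' @export
read_hg_hierarchy <- function(path, format = c("auto", "tsv", "newick")) {
  format <- match.arg(format)
  txt <- if (grepl(";[[:space:]]*$", path) && !file.exists(path)) path
         else paste(readLines(path, warn = FALSE), collapse = "\n")
  is_newick <- switch(format, newick = TRUE, tsv = FALSE,
                      auto = grepl(";[[:space:]]*$", txt))
  if (is_newick) return(as_hg_hierarchy(read_newick(txt)))
  df <- utils::read.delim(text = txt, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  if (!all(c("child", "parent") %in% names(df)))
    stop_mtg("hierarchy TSV needs 'child' and 'parent' columns",
             class = "mtg_error_hierarchy")
  hg_hierarchy_from_edges(df$child, df$parent)
}

#' Build a haplogroup hierarchy from child/parent name pairs
#'
#' @param child,parent Character vectors of equal length; each row states that
#'   `child` is nested within `parent`.  The single name occurring only as a
#'   parent becomes the root.
#' @return An object of class `"hg_hierarchy"`.
#' @export
hg_hierarchy_from_edges <- function(child, parent) {
  if (anyDuplicated(child))
    stop_mtg("haplogroup '%s' listed with two parents",
             child[anyDuplicated(child)], class = "mtg_error_hierarchy")
  labels <- unique(c(parent, child))
  par_idx <- rep(NA_integer_, length(labels))
  par_idx[match(child, labels)] <- match(parent, labels)
  new_hg_hierarchy(labels, par_idx)
}

#' Convert a labelled phylogeny to a haplogroup hierarchy
#'
#' @param tree A rooted `phylo` object whose tips and internal nodes all carry
#'   haplogroup names (`node.label` required).
#' @return An object of class `"hg_hierarchy"`.
#' @export
as_hg_hierarchy <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label)))
    stop_mtg("hierarchy Newick must label every internal node",
             class = "mtg_error_hierarchy")
  labels <- c(tree$tip.label, tree$node.label)
  parent <- rep(NA_integer_, length(labels))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  new_hg_hierarchy(labels, parent)
}

#' @export
print.hg_hierarchy <- function(x, ...) {
  cat(sprintf("<hg_hierarchy> %d haplogroups, root '%s', max depth %d\n",
              length(x$labels), x$labels[x$root], max(x$depth)))
  invisible(x)
}

#' The packaged schematic human mtDNA haplogroup hierarchy
#'
#' A compact, hand-curated hierarchy following the schematic structure of the
#' human mtDNA phylogeny (PhyloTree-style): mt-MRCA splits into L0 and
#' L1'2'3'4'5'6; all non-L haplogroups nest within L3 via M and N; R carries
#' R0/HV, JT, U and B, etc.  It is a teaching/testing fixture, not a full
#' reference phylogeny.
#'
#' @return An object of class `"hg_hierarchy"`.
#' @export
schematic_hierarchy <- function() {
  read_hg_hierarchy(system.file("extdata", "hg_hierarchy_schematic.tsv",
                                package = "mtgrouper"), format = "tsv")
}

hg_node <- function(h, name) {
  core <- hg_core(name)
  i <- h$index[core]
  if (is.na(i))
    stop_mtg("haplogroup '%s' not found in hierarchy", core,
             class = "mtg_error_lookup")
  unname(i)
}

#' Ancestors of a haplogroup in a hierarchy
#'
#' @param h An `hg_hierarchy`.
#' @param name A haplogroup label (modifier-stripped before lookup).
#' @return Character vector of ancestor names from the name itself up to the
#'   root (ancestor-or-self path).
#' @export
hg_ancestors <- function(h, name) {
  i <- hg_node(h, name)
  out <- character(0)
  while (!is.na(i)) {
    out <- c(out, h$labels[i])
    i <- h$parent[i]
  }
  out
}

#' MRCA haplogroup of a set of names
#'
#' Returns the label of the lowest hierarchy node that is an ancestor-or-self
#' of every given haplogroup name.  Names are modifier-stripped before lookup
#' (so `"D5a2a1+@16172"` resolves as `D5a2a1`); apostrophe-merged names are
#' matched verbatim.
#'
#' @param h An `hg_hierarchy`.
#' @param names Character vector (or list) of haplogroup labels; non-empty.
#' @return A single haplogroup name.
#' @examples
#' h <- schematic_hierarchy()
#' hg_mrca(h, c("B4a1a1b", "J2b1a"))  # "R"
#' @export
hg_mrca <- function(h, names) {
  names <- unique(as.character(names))
  if (length(names) == 0L)
    stop_mtg("hg_mrca needs at least one name", class = "mtg_error_lookup")
  idx <- vapply(names, function(nm) hg_node(h, nm), integer(1))
  a <- idx[1]
  for (b in idx[-1]) {
    # classic two-pointer LCA on parent links using depths
    while (h$depth[a] > h$depth[b]) a <- h$parent[a]
    while (h$depth[b] > h$depth[a]) b <- h$parent[b]
    while (a != b) { a <- h$parent[a]; b <- h$parent[b] }
  }
  h$labels[a]
}
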