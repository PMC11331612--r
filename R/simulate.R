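# Seeded generators for trees, haplogroup labels + hierarchies, population
# assignments and alignments.  Every generator records its ground truth so
# tests can use the generator's own bookkeeping as the oracle.  All
# randomness flows from the `seed` argument; identical seeds give identical
# output.

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Simulate a rooted weighted tree with a fixed diameter
#'
#' Draws a random topology (Yule birth process or Kingman coalescent) and
#' rescales all branch lengths so the maximum leaf-pair path distance equals
#' `target_diameter`, putting the tree on the same scale as the threshold
#' ladders used for clustering.
#'
#' @param n_leaves Number of leaves (`>= 2`).
#' @param model `"yule"` (default) or `"kingman"`.
#' @param target_diameter Desired leaf-pair diameter (> 0), in
#'   substitutions/site.
#' @param seed Integer seed; identical seeds give byte-identical trees.
#' @return A rooted `phylo` with tips `S001`, `S002`, ...
#' @export
simulate_tree <- function(n_leaves, model = c("yule", "kingman"),
                          target_diameter = 0.01, seed = 1) {
  model <- match.arg(model)
  if (n_leaves < 2L || target_diameter <= 0)
    stop_mtg("need n_leaves >= 2 and target_diameter > 0",
             class = "mtg_error_sim")
  set.seed(seed)
  tr <- if (model == "yule") ape::rphylo(n_leaves, birth = 1, death = 0)
        else ape::rcoal(n_leaves)
  tr$tip.label <- sprintf("S%03d", seq_len(n_leaves))
  D <- max(ape::cophenetic.phylo(tr))
  tr$edge.length <- tr$edge.length * (target_diameter / D)
  tr
}

# Extend a strict-grammar clade name by one level: capital letter at depth 1,
# then digit blocks and single lowercase letters in alternation.
extend_name <- function(parent_name, rank, depth) {
  if (depth == 1L) {
    if (rank > 26L) stop_mtg("more than 26 root children unsupported",
                             class = "mtg_error_sim")
    LETTERS[rank]
  } else if (depth %% 2L == 0L) {
    paste0(parent_name, rank)
  } else {
    if (rank > 26L) stop_mtg("more than 26 children unsupported",
                             class = "mtg_error_sim")
    paste0(parent_name, letters[rank])
  }
}

#' Label tree leaves with nomenclature-consistent haplogroup names
#'
#' Builds a nested haplogroup hierarchy mirroring the tree topology down to
#' `hierarchy_depth` levels below the root ("mt-MRCA"), with names following
#' the strict cladistic grammar (capital letter, then alternating digit
#' blocks and lowercase letters).  Each leaf is labelled with the name of its
#' deepest named ancestor, so leaves within one tree clade carry
#' hierarchically related names.  Naming irregularities can be injected at
#' given per-leaf rates, with full bookkeeping: apostrophe merges create a
#' sibling-level composite name that is inserted into the hierarchy (so it
#' still resolves), and `+@<pos>` mutation suffixes resolve via modifier
#' stripping.
#'
#' @param tree A `phylo` object.
#' @param hierarchy_depth Number of named levels below the root (default 4).
#' @param irregularity_rates Named list/vector with per-leaf injection
#'   probabilities `apostrophe` and `symbols` (defaults 0).
#' @param seed Integer seed.
#' @return A list: `haplogroups` (named character vector leaf -> name),
#'   `hierarchy` (`hg_hierarchy` resolving every emitted name),
#'   `injections` (data frame `leaf`, `base`, `haplogroup`,
#'   `injected_apostrophe`, `injected_symbols`).
#' @export
label_haplogroups <- function(tree, hierarchy_depth = 4,
                              irregularity_rates = list(apostrophe = 0,
                                                        symbols = 0),
                              seed = 1) {
  stopifnot(inherits(tree, "phylo"))
  rate_apo <- irregularity_rates$apostrophe %||% 0
  rate_sym <- irregularity_rates$symbols %||% 0
  if (rate_apo < 0 || rate_apo > 1 || rate_sym < 0 || rate_sym > 1)
    stop_mtg("irregularity rates must be in [0, 1]", class = "mtg_error_sim")
  set.seed(seed)
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  root <- n_tip + 1L
  cw <- ape::reorder.phylo(tree, "cladewise")
  depth <- integer(n_all); depth[root] <- 0L
  nm <- character(n_all); nm[root] <- "mt-MRCA"
  child_count <- integer(n_all)
  parent_name <- character(0)  # child name -> parent name, grown below
  child_name <- character(0)
  for (e in seq_len(nrow(cw$edge))) {
    p <- cw$edge[e, 1]; ch <- cw$edge[e, 2]
    depth[ch] <- depth[p] + 1L
    if (depth[ch] <= hierarchy_depth) {
      child_count[p] <- child_count[p] + 1L
      nm[ch] <- extend_name(nm[p], child_count[p], depth[ch])
      child_name <- c(child_name, nm[ch])
      parent_name <- c(parent_name, nm[p])
    } else {
      nm[ch] <- nm[p]  # inherits the deepest named ancestor
    }
  }
  hgs <- stats::setNames(nm[seq_len(n_tip)], tree$tip.label)
  base <- hgs

  # irregularity injection with bookkeeping
  inj_apo <- stats::runif(n_tip) < rate_apo
  inj_sym <- stats::runif(n_tip) < rate_sym
  succ_token <- function(x) {
    if (grepl("[0-9]+$", x)) {
      as.character(as.integer(sub("^.*?([0-9]+)$", "\\1", x)) + 1L)
    } else {
      last <- substr(x, nchar(x), nchar(x))
      idx <- match(tolower(last), letters) %% 26L + 1L  # z wraps to a
      if (last %in% LETTERS) LETTERS[idx] else letters[idx]
    }
  }
  for (i in which(inj_apo)) {
    x <- base[i]
    merged <- paste0(x, "'", succ_token(x))
    if (!merged %in% child_name) {
      # sibling-level composite name, attached under x's parent so it
      # resolves in the hierarchy
      par <- if (x %in% child_name) parent_name[match(x, child_name)]
             else "mt-MRCA"
      child_name <- c(child_name, merged)
      parent_name <- c(parent_name, par)
    }
    hgs[i] <- merged
  }
  for (i in which(inj_sym))
    hgs[i] <- paste0(hgs[i], "+@", sample(16569L, 1L))

  keep <- !duplicated(child_name)
  list(
    haplogroups = hgs,
    hierarchy = hg_hierarchy_from_edges(child_name[keep], parent_name[keep]),
    injections = data.frame(
      leaf = tree$tip.label, base = unname(base), haplogroup = unname(hgs),
      injected_apostrophe = inj_apo, injected_symbols = inj_sym)
  )
}

#' Assign population labels with distinct group-frequency profiles
#'
#' Draws, for each population, a Dirichlet frequency profile over the
#' distinct leaf groups, then samples each leaf's population with probability
#' proportional to its group's frequency in that population.  Large
#' `concentration` values give near-uniform profiles (and hence near-uniform
#' population assignments); small values give strongly differentiated
#' populations.
#'
#' @param leaf_groups Named character vector, leaf -> group label (e.g. an SC
#'   grouping of simulated haplogroups).
#' @param n_pops Number of populations (`>= 1`); labelled `P1`, `P2`, ...
#' @param concentration Symmetric Dirichlet concentration parameter (> 0).
#' @param seed Integer seed.
#' @return A list: `population` (named vector leaf -> population), `freq`
#'   (true Dirichlet profiles, populations x groups, rows sum to 1),
#'   `cond` (P(population | group) matrix actually used for sampling).
#' @export
assign_populations <- function(leaf_groups, n_pops = 7, concentration = 1,
                               seed = 1) {
  if (n_pops < 1L || concentration <= 0)
    stop_mtg("need n_pops >= 1 and concentration > 0", class = "mtg_error_sim")
  set.seed(seed)
  groups <- sort(unique(as.character(leaf_groups)))
  pops <- paste0("P", seq_len(n_pops))
  F <- rdirichlet(n_pops, rep(concentration, length(groups)))
  dimnames(F) <- list(pops, groups)
  cond <- sweep(F, 2, colSums(F), `/`)
  pop <- vapply(as.character(leaf_groups), function(g)
    sample(pops, 1L, prob = cond[, g]), character(1))
  names(pop) <- names(leaf_groups)
  list(population = pop, freq = F, cond = cond)
}

#' Simulate an alignment along a tree (equal-rates substitution model)
#'
#' Evolves sequences from a uniform-random root down every branch under the
#' one-parameter equal-exchange model: on a branch of length `b` each site
#' substitutes with probability `3/4 (1 - exp(-4 b rate / 3))`, choosing
#' uniformly among the three other bases.  No indels are simulated, so the
#' leaf sequences are emitted aligned.
#'
#' @param tree A rooted `phylo` with branch lengths (substitutions/site).
#' @param n_sites Number of sites (`>= 1`).
#' @param rate Rate multiplier applied to branch lengths (> 0).
#' @param seed Integer seed.
#' @return An MSA character matrix (see [as_msa()]), rows = tree leaves.
#' @export
simulate_msa <- function(tree, n_sites = 1000, rate = 1, seed = 1) {
  check_weighted_rooted(tree)
  if (n_sites < 1L || rate <= 0)
    stop_mtg("need n_sites >= 1 and rate > 0", class = "mtg_error_sim")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  root <- n_tip + 1L
  seqs <- matrix(0L, n_all, n_sites)
  seqs[root, ] <- sample.int(4L, n_sites, replace = TRUE)
  cw <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(cw$edge))) {
    p <- cw$edge[e, 1]; ch <- cw$edge[e, 2]
    prob <- 0.75 * (1 - exp(-4 * cw$edge.length[e] * rate / 3))
    s <- seqs[p, ]
    mut <- which(stats::runif(n_sites) < prob)
    if (length(mut))
      s[mut] <- (s[mut] + sample.int(3L, length(mut), replace = TRUE) - 1L) %%
        4L + 1L
    seqs[ch, ] <- s
  }
  m <- matrix(bases[seqs[seq_len(n_tip), , drop = FALSE]], n_tip, n_sites)
  rownames(m) <- tree$tip.label
  as_msa(m)
}

#' Simulate a complete, internally consistent fixture bundle
#'
#' One call producing a tree, a haplogroup hierarchy with leaf labels,
#' population assignments and an alignment that all refer to the same
#' samples, emulating the inputs of a population mtDNA survey (by default: 7
#' populations, 100 leaves, tree diameter 0.01 so thresholds 0.001-0.008 are
#' meaningful).  Sub-generators are seeded deterministically from `seed`.
#'
#' @param n_leaves,n_pops,n_sites,diameter,rate,hierarchy_depth,
#'   irregularity_rates,concentration Passed to the individual generators.
#' @param seed Master integer seed.
#' @return A list of class `"fixture_bundle"`: `tree`, `haplogroups`,
#'   `hierarchy`, `population`, `msa`, `truth` (generator bookkeeping:
#'   injections, population frequency profiles), `params`.
#' @export
simulate_bundle <- function(n_leaves = 100, n_pops = 7, n_sites = 1000,
                            diameter = 0.01, rate = 1, hierarchy_depth = 4,
                            irregularity_rates = list(apostrophe = 0,
                                                      symbols = 0),
                            concentration = 1, seed = 1) {
  tree <- simulate_tree(n_leaves, "yule", diameter, seed = seed)
  lab <- label_haplogroups(tree, hierarchy_depth, irregularity_rates,
                           seed = seed + 1L)
  pops <- assign_populations(
    stats::setNames(group_sc(unname(lab$haplogroups)), names(lab$haplogroups)),
    n_pops, concentration, seed = seed + 2L)
  msa <- simulate_msa(tree, n_sites, rate, seed = seed + 3L)
  structure(list(
    tree = tree,
    haplogroups = lab$haplogroups,
    hierarchy = lab$hierarchy,
    population = pops$population,
    msa = msa,
    truth = list(injections = lab$injections, pop_freq = pops$freq,
                 pop_cond = pops$cond),
    params = list(n_leaves = n_leaves, n_pops = n_pops, n_sites = n_sites,
                  diameter = diameter, rate = rate,
                  hierarchy_depth = hierarchy_depth,
                  irregularity_rates = irregularity_rates,
                  concentration = concentration, seed = seed)
  ), class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("<fixture_bundle> %d leaves, %d populations, %d sites (seed %d)\n",
              length(x$tree$tip.label), length(unique(x$population)),
              ncol(x$msa), x$params$seed))
  invisible(x)
}
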