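# Seeded generators: trees, haplogroup labels, populations, alignments.

test_that("simulated trees hit the target diameter and reproduce by seed", {
  cherry <- simulate_tree(2, target_diameter = 0.004, seed = 1)
  expect_equal(max(leaf_distance_matrix(cherry)), 0.004, tolerance = 1e-12)

  t1 <- simulate_tree(50, seed = 99)
  t2 <- simulate_tree(50, seed = 99)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_false(identical(write_newick(t1),
                         write_newick(simulate_tree(50, seed = 100))))

  big <- simulate_tree(100, target_diameter = 0.01, seed = 4)
  expect_lt(abs(max(leaf_distance_matrix(big)) - 0.01), 1e-9)
  expect_error(simulate_tree(1), "n_leaves")
})

test_that("generated haplogroup labels are strict and clade-consistent", {
  tr <- simulate_tree(80, seed = 31)
  lab <- label_haplogroups(tr, seed = 31)
  tab <- parse_hg_names(unname(lab$haplogroups))
  expect_true(all(tab$strict_cladistic))

  # every emitted name resolves in the emitted hierarchy
  for (nm in unique(lab$haplogroups))
    expect_no_error(hg_mrca(lab$hierarchy, nm))

  # clade consistency: the MRCA haplogroup of any clade's leaves is an
  # ancestor-or-self of each member's haplogroup
  sets <- tip_sets_from_edges(tr)
  internal <- seq(length(tr$tip.label) + 1L, length.out = tr$Nnode)
  for (v in sample(internal, 20)) {
    members <- lab$haplogroups[tr$tip.label[sets[[v]]]]
    anc <- hg_mrca(lab$hierarchy, unique(members))
    for (m in unique(members))
      expect_true(anc %in% hg_ancestors(lab$hierarchy, m))
  }
})

test_that("irregularity injections are bookkept and recovered exactly", {
  tr <- simulate_tree(200, seed = 37)
  lab <- label_haplogroups(tr, irregularity_rates = list(apostrophe = 0.1,
                                                         symbols = 0.15),
                           seed = 37)
  s <- classify_hg_names(unname(lab$haplogroups))
  expect_identical(unname(s$counts["has_apostrophe"]),
                   sum(lab$injections$injected_apostrophe))
  expect_identical(unname(s$counts["has_symbols"]),
                   sum(lab$injections$injected_symbols))
  # strict + at-least-one-flag partitions the generated names
  expect_identical(unname(s$counts["strict_cladistic"] +
                            s$counts["any_irregular"]), s$total)
  # injected names still resolve (apostrophe verbatim, symbols via stripping)
  for (nm in unique(lab$haplogroups))
    expect_no_error(hg_mrca(lab$hierarchy, nm))
})

test_that("population assignment honours the Dirichlet profiles", {
  groups <- setNames(rep(c("A", "B", "C"), length.out = 30),
                     sprintf("S%03d", 1:30))
  one <- assign_populations(groups, n_pops = 1, seed = 5)
  expect_identical(unique(unname(one$population)), "P1")

  # high concentration: near-uniform assignment probabilities
  many <- setNames(rep(c("A", "B"), 1000), sprintf("S%04d", 1:2000))
  ap <- assign_populations(many, n_pops = 4, concentration = 1000, seed = 6)
  emp <- table(ap$population) / 2000
  se <- sqrt(0.25 * 0.75 / 2000)
  expect_true(all(abs(emp - 0.25) <= 3 * se))
  expect_equal(unname(rowSums(ap$freq)), rep(1, 4), tolerance = 1e-12)

  r1 <- assign_populations(groups, n_pops = 3, seed = 7)
  r2 <- assign_populations(groups, n_pops = 3, seed = 7)
  expect_identical(r1, r2)
})

test_that("sequence simulation follows the substitution model", {
  tr <- simulate_tree(4, target_diameter = 0.01, seed = 8)
  frozen <- simulate_msa(tr, n_sites = 50, seed = 8)
  expect_identical(simulate_msa(tr, n_sites = 50, seed = 8), frozen)
  expect_identical(rownames(frozen), tr$tip.label)

  # vanishing rate: all sequences identical
  cold <- simulate_msa(tr, n_sites = 100, rate = 1e-12, seed = 9)
  expect_identical(length(unique(apply(cold, 1, paste, collapse = ""))), 1L)

  # cherry closed form: expected p-distance (3/4)(1 - exp(-4 l / 3))
  l <- 0.02
  cherry <- read_newick(sprintf("(A:%g,B:%g);", l / 2, l / 2))
  msa <- simulate_msa(cherry, n_sites = 10000, seed = 10)
  p <- pairwise_differences(msa, "p")["A", "B"]
  q <- 0.75 * (1 - exp(-4 * l / 3))
  expect_lt(abs(p - q), 3 * sqrt(q * (1 - q) / 10000))
})

test_that("fixture bundles are internally consistent and seed-stable", {
  b <- simulate_bundle(n_leaves = 25, n_sites = 60, seed = 41,
                       irregularity_rates = list(apostrophe = 0.05,
                                                 symbols = 0.1))
  expect_identical(sort(names(b$haplogroups)), sort(b$tree$tip.label))
  expect_identical(sort(names(b$population)), sort(b$tree$tip.label))
  expect_identical(sort(rownames(b$msa)), sort(b$tree$tip.label))
  # full pipeline runs without error on a bundle
  expect_no_error(parse_hg_names(unname(b$haplogroups)))
  expect_no_error(designate_levels(b$tree, b$haplogroups, b$hierarchy))
  expect_no_error(pairwise_differences(b$msa))

  b2 <- simulate_bundle(n_leaves = 25, n_sites = 60, seed = 41,
                        irregularity_rates = list(apostrophe = 0.05,
                                                  symbols = 0.1))
  expect_identical(write_newick(b$tree), write_newick(b2$tree))
  expect_identical(b$haplogroups, b2$haplogroups)
  expect_identical(b$population, b2$population)
  expect_identical(unclass(b$msa)[, ], unclass(b2$msa)[, ])
})
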