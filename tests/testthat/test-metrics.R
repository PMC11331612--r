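# Grouping-scheme diagnostics: frequency tables, CA, MDS, within-group
# distances, representative reduction.

test_that("frequency tables count and normalise per population", {
  ct <- frequency_table(c("P1", "P1", "P2", "P2"), c("X", "Y", "X", "Y"))
  expect_identical(unname(ct$counts), matrix(1L, 2, 2))
  expect_true(all(ct$freq == 0.5))
  expect_identical(ct$n, 4L)

  one <- frequency_table(rep("P1", 6), c("X", "X", "X", "Y", "Y", "Z"))
  expect_identical(dim(one$counts), c(1L, 3L))
  expect_equal(unname(one$freq["P1", ]), c(3, 2, 1) / 6)
  expect_lt(abs(sum(one$freq) - 1), 1e-12)

  expect_error(frequency_table(c("P1"), c("X", "Y")), "same length")
  expect_error(frequency_table(c("P1", NA), c("X", "Y")), "missing")
})

test_that("empirical frequencies recover generator probabilities within 3 SE", {
  F <- rbind(P1 = c(0.5, 0.3, 0.2), P2 = c(0.1, 0.6, 0.3))
  colnames(F) <- c("g1", "g2", "g3")
  set.seed(101)
  n_per <- 500
  pops <- rep(rownames(F), each = n_per)
  grp <- unlist(lapply(rownames(F), function(p)
    sample(colnames(F), n_per, replace = TRUE, prob = F[p, ])))
  ct <- frequency_table(pops, grp)
  se <- sqrt(F * (1 - F) / n_per)
  expect_true(all(abs(ct$freq[rownames(F), colnames(F)] - F) <= 3 * se))
})

test_that("CA total inertia equals chi-square over n", {
  # maximal association: 3x3 diagonal table, chi2 = 60, n = 30, inertia 2
  d3 <- diag(10, 3)
  ca <- correspondence_analysis(d3)
  expect_equal(ca$total_inertia, 2, tolerance = 1e-10)

  # independence: outer-product table has zero inertia and no dimensions
  op <- outer(c(2, 3, 5), c(1, 4, 2, 3))
  ca0 <- correspondence_analysis(op)
  expect_equal(ca0$total_inertia, 0, tolerance = 1e-12)
  expect_identical(length(ca0$singular_values), 0L)

  set.seed(7)
  for (i in 1:10) {
    x <- matrix(rpois(20, 8), 4, 5)
    x[1, 1] <- x[1, 1] + 10  # guarantee association
    ca <- correspondence_analysis(x)
    chi2 <- suppressWarnings(chisq.test(x)$statistic)
    expect_equal(ca$total_inertia, unname(chi2) / sum(x), tolerance = 1e-10)
  }
})

test_that("CA is scale-invariant and permutation-equivariant", {
  set.seed(8)
  x <- matrix(rpois(12, 6) + 1, 3, 4)
  a <- correspondence_analysis(x)
  b <- correspondence_analysis(x * 7)       # counts vs scaled counts
  expect_equal(a$row_coords, b$row_coords, tolerance = 1e-10)
  perm <- correspondence_analysis(x[c(2, 1, 3), ])
  expect_equal(sort(perm$inertia), sort(a$inertia), tolerance = 1e-10)
})

test_that("CA coordinates match the reference implementation up to sign", {
  skip_if_not_installed("MASS")
  set.seed(9)
  x <- matrix(rpois(20, 10) + 1, 4, 5)
  ca <- correspondence_analysis(x)
  ref <- MASS::corresp(x, nf = 2)
  for (k in 1:2) {
    ours <- ca$row_coords[, k]
    theirs <- ref$rscore[, k] * ref$cor[k]   # principal coordinates
    expect_lt(min(max(abs(ours - theirs)), max(abs(ours + theirs))), 1e-8)
  }
})

test_that("CA prunes empty rows/columns and rejects degenerate input", {
  x <- rbind(c(3, 0, 2), c(0, 0, 0), c(1, 0, 4))
  expect_message(ca <- correspondence_analysis(x), "pruning")
  expect_identical(dim(ca$row_coords)[1], 2L)
  expect_error(suppressMessages(correspondence_analysis(rbind(c(1, 1)))),
               "at least 2")
  expect_error(correspondence_analysis(matrix(-1, 2, 2)), "non-negative")
})

test_that("classical MDS reproduces Euclidean configurations", {
  # collinear points on a line, k = 1
  d <- rbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0))
  m <- classical_mds(d, k = 1)
  expect_equal(as.matrix(dist(m$points)), unname(d), tolerance = 1e-9,
               ignore_attr = TRUE)

  set.seed(10)
  pts <- matrix(rnorm(20), 10, 2)
  d2 <- as.matrix(dist(pts))
  m2 <- classical_mds(d2, k = 2)
  expect_lt(max(abs(as.matrix(dist(m2$points)) - d2)), 1e-9)
  expect_true(all(diff(m2$eigenvalues) <= 1e-9))

  # agreement with the standard implementation up to axis sign
  ref <- cmdscale(d2, k = 2)
  for (k in 1:2)
    expect_lt(min(max(abs(m2$points[, k] - ref[, k])),
                  max(abs(m2$points[, k] + ref[, k]))), 1e-8)
})

test_that("MDS reports negative eigenvalues of non-Euclidean tree metrics", {
  tr <- simulate_tree(12, seed = 21, target_diameter = 1)
  d <- leaf_distance_matrix(tr)
  m <- classical_mds(d, k = 2)
  expect_true(any(m$eigenvalues < 0))
  expect_identical(ncol(m$points), 2L)
  expect_warning(classical_mds(rbind(c(0, 1), c(1, 0)), k = 5), "truncated")
  expect_error(classical_mds(rbind(c(0, 1), c(2, 0))), "symmetric")
})

test_that("within-group summaries cover pairs, singletons and the clade bound", {
  d <- matrix(c(0, 0.004, 0.004, 0), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  w <- within_group_distances(d, c(a = "g1", b = "g1"))
  expect_equal(w$summary$mean_dist, 0.004)
  expect_equal(w$summary$max_dist, 0.004)
  expect_identical(w$summary$n_pairs, 1L)

  w2 <- within_group_distances(d, c(a = "g1", b = "g2"))
  expect_identical(w2$summary$n_pairs, c(0L, 0L))
  expect_true(all(is.na(w2$summary$mean_dist)))

  expect_error(within_group_distances(d, c(zz = "g1")), "zz")

  tr <- simulate_tree(30, seed = 25, target_diameter = 0.01)
  dt <- leaf_distance_matrix(tr)
  p <- max_clade_partition(tr, 0.003)
  w3 <- within_group_distances(dt, p$assignment)
  expect_true(all(w3$summary$max_dist <= 0.003 + 1e-12, na.rm = TRUE))
})

test_that("representative reduction keeps one sample per label tuple", {
  gt <- data.frame(sample_id = c("s3", "s1", "s2", "s4"),
                   sc = c("L", "L", "L", "B"),
                   tc = c(1, 1, 2, 2))
  r <- representative_reduction(gt, c("sc", "tc"))
  expect_identical(sort(r$representatives), c("s1", "s2", "s4"))
  expect_identical(nrow(r$reduced), 3L)

  allsame <- data.frame(sample_id = c("b", "a"), sc = c("L", "L"))
  expect_identical(representative_reduction(allsame, "sc")$representatives, "a")

  alldiff <- data.frame(sample_id = letters[1:4], sc = LETTERS[1:4])
  expect_identical(length(representative_reduction(alldiff, "sc")$representatives),
                   4L)
  expect_error(representative_reduction(gt, "nope"), "unknown scheme")

  # fixture check: set size equals the independently counted tuple classes
  b <- simulate_bundle(n_leaves = 50, n_sites = 10, seed = 29)
  sw <- threshold_sweep(b$tree, c(0.006, 0.003))
  gt2 <- data.frame(sample_id = names(b$haplogroups),
                    sc = group_sc(unname(b$haplogroups)),
                    tc6 = unname(sw[[1]]$assignment[names(b$haplogroups)]),
                    tc3 = unname(sw[[2]]$assignment[names(b$haplogroups)]))
  r2 <- representative_reduction(gt2, c("sc", "tc6", "tc3"))
  expect_identical(length(r2$representatives),
                   nrow(unique(gt2[c("sc", "tc6", "tc3")])))
})
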