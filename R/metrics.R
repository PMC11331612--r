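# Diagnostics for comparing grouping schemes: population-by-group frequency
# tables, correspondence analysis (CA), classical multidimensional scaling
# (MDS), within-group pairwise-distance summaries, and the minimal
# representative-set reduction used to draw a reduced phylogeny.

#' Population-by-group contingency table and relative frequencies
#'
#' @param populations Character vector of population labels, one per sample.
#' @param groups Character vector of group labels (same length/order).
#' @return A list of class `"contingency_table"`: `counts` (populations x
#'   groups integer matrix), `freq` (rows rescaled to sum to 1), `n`.
#' @export
frequency_table <- function(populations, groups) {
  if (length(populations) != length(groups))
    stop_mtg("populations and groups must have the same length",
             class = "mtg_error_table")
  if (anyNA(populations) || anyNA(groups))
    stop_mtg("missing population or group label", class = "mtg_error_table")
  counts <- unclass(table(population = populations, group = groups))
  freq <- counts / rowSums(counts)
  structure(list(counts = counts, freq = freq, n = sum(counts)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %d populations x %d groups, n = %d\n",
              nrow(x$counts), ncol(x$counts), x$n))
  print(x$counts)
  invisible(x)
}

#' Correspondence analysis of a contingency table
#'
#' Standard CA by singular value decomposition of the matrix of standardized
#' residuals: with correspondence matrix `P = X/n`, row masses `r` and column
#' masses `c`, `S = diag(r)^-1/2 (P - r c') diag(c)^-1/2` is decomposed as
#' `S = U D V'`; principal coordinates are the mass-rescaled singular vectors
#' scaled by the singular values.  The total inertia (sum of squared
#' singular values) equals the Pearson chi-square statistic of the table
#' divided by `n`.  CA is scale-invariant, so counts and relative frequencies
#' give identical coordinates.  Axis signs are arbitrary.
#'
#' All-zero rows and columns are pruned (with a message) before the
#' decomposition, since masses must be positive.
#'
#' @param x A counts matrix (non-negative), or a `"contingency_table"` from
#'   [frequency_table()].
#' @return A list of class `"ca_result"`: `row_coords`, `col_coords`
#'   (principal coordinates, dimensions with non-negligible singular value),
#'   `singular_values`, `inertia` (per dimension), `inertia_pct`,
#'   `total_inertia`, `row_mass`, `col_mass`.
#' @export
correspondence_analysis <- function(x) {
  if (inherits(x, "contingency_table")) x <- x$counts
  x <- as.matrix(x)
  if (any(x < 0) || sum(x) <= 0)
    stop_mtg("CA needs a non-negative table with positive total",
             class = "mtg_error_ca")
  keep_r <- rowSums(x) > 0
  keep_c <- colSums(x) > 0
  if (!all(keep_r) || !all(keep_c)) {
    message(sprintf("correspondence_analysis: pruning %d all-zero row(s) and %d all-zero column(s)",
                    sum(!keep_r), sum(!keep_c)))
    x <- x[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop_mtg("CA needs at least 2 non-empty rows and 2 non-empty columns",
             class = "mtg_error_ca")
  n <- sum(x)
  P <- x / n
  r <- rowSums(P)
  cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
  sv <- svd(S)
  kmax <- min(nrow(x), ncol(x)) - 1L
  d <- sv$d[seq_len(kmax)]
  k <- sum(d > 1e-10)
  principal <- function(vec, mass, labels) {
    m <- matrix(NA_real_, nrow = length(mass), ncol = k)
    rownames(m) <- labels
    if (k > 0) {
      colnames(m) <- paste0("Dim", seq_len(k))
      m[] <- sweep(vec[, seq_len(k), drop = FALSE] / sqrt(mass), 2,
                   d[seq_len(k)], `*`)
    }
    m
  }
  row_coords <- principal(sv$u, r, rownames(x))
  col_coords <- principal(sv$v, cc, colnames(x))
  inertia <- d^2
  structure(list(
    row_coords = row_coords, col_coords = col_coords,
    singular_values = d[seq_len(k)],
    inertia = inertia[seq_len(k)],
    inertia_pct = if (sum(inertia) > 0) 100 * inertia[seq_len(k)] / sum(inertia)
                  else numeric(0),
    total_inertia = sum(inertia),
    row_mass = r, col_mass = cc
  ), class = "ca_result")
}

#' @export
print.ca_result <- function(x, ...) {
  cat(sprintf("<ca_result> total inertia %.6g over %d dimension(s)\n",
              x$total_inertia, length(x$singular_values)))
  if (length(x$inertia))
    cat("  inertia:", paste(sprintf("%.4g (%.1f%%)", x$inertia, x$inertia_pct),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix, `B = -1/2 J D^2 J`, and embeds
#' the samples with the top-`k` non-negative eigenpairs of `B`.  When the
#' distances are Euclidean-embeddable in at most `k` dimensions the embedding
#' reproduces them exactly (up to rigid motion).  Negative eigenvalues
#' (common for tree metrics, which are additive but generally not Euclidean)
#' are reported in `eigenvalues` and never used for coordinates; if fewer
#' than `k` positive eigenvalues exist, `k` is truncated with a warning.
#'
#' @param d Symmetric distance matrix (or `dist`) with zero diagonal.
#' @param k Number of requested dimensions.
#' @return A list of class `"mds_result"`: `points` (n x k' coordinate
#'   matrix), `eigenvalues` (all n, sorted decreasing), `k` (retained
#'   dimensions).
#' @export
classical_mds <- function(d, k = 2) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8 ||
      max(abs(diag(d))) > 1e-8)
    stop_mtg("d must be a symmetric distance matrix with zero diagonal",
             class = "mtg_error_mds")
  n <- nrow(d)
  D2 <- d^2
  # double centering without forming J explicitly
  rm_ <- rowMeans(D2); gm <- mean(D2)
  B <- -0.5 * (D2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-12
  pos <- which(e$values > tol)
  kk <- min(k, length(pos))
  if (kk < k)
    warning(sprintf("only %d positive eigenvalue(s); k truncated from %d to %d",
                    length(pos), k, kk))
  pts <- if (kk > 0)
    e$vectors[, pos[seq_len(kk)], drop = FALSE] %*%
      diag(sqrt(e$values[pos[seq_len(kk)]]), kk)
  else matrix(numeric(0), n, 0)
  rownames(pts) <- rownames(d)
  if (kk > 0) colnames(pts) <- paste0("Dim", seq_len(kk))
  structure(list(points = pts, eigenvalues = e$values, k = kk),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat(sprintf("<mds_result> %d samples in %d dimension(s); %d negative eigenvalue(s)\n",
              nrow(x$points), x$k, sum(x$eigenvalues < 0)))
  invisible(x)
}

#' Within-group pairwise distance summaries
#'
#' Collects, per group, the pairwise distances between its members (unordered
#' pairs), the raw material of the within-group violin plots.  When the
#' groups come from a max-clade partition computed on the same tree metric,
#' every within-group distance is bounded by that partition's threshold.
#'
#' @param d Symmetric distance matrix covering all samples.
#' @param groups Named character/integer vector, sample id -> group label.
#' @return A list of class `"within_group_summary"`: `summary` data frame
#'   (`group`, `n`, `n_pairs`, `mean_dist`, `max_dist`; `NA` summaries for
#'   singletons) and `distances`, a named list of per-group distance vectors.
#' @export
within_group_distances <- function(d, groups) {
  d <- as.matrix(d)
  ids <- names(groups)
  if (is.null(ids))
    stop_mtg("groups must be named by sample id", class = "mtg_error_table")
  missing <- setdiff(ids, rownames(d))
  if (length(missing))
    stop_mtg("sample '%s' is missing from the distance matrix", missing[1],
             class = "mtg_error_table")
  lv <- sort(unique(as.character(groups)))
  dist_list <- lapply(lv, function(g) {
    members <- ids[as.character(groups) == g]
    if (length(members) < 2L) return(numeric(0))
    sub <- d[members, members, drop = FALSE]
    sub[upper.tri(sub)]
  })
  names(dist_list) <- lv
  sizes <- vapply(lv, function(g) sum(as.character(groups) == g), integer(1))
  structure(list(
    summary = data.frame(
      group = lv, n = sizes, n_pairs = lengths(dist_list),
      mean_dist = vapply(dist_list, function(v)
        if (length(v)) mean(v) else NA_real_, numeric(1)),
      max_dist = vapply(dist_list, function(v)
        if (length(v)) max(v) else NA_real_, numeric(1)),
      row.names = NULL),
    distances = dist_list
  ), class = "within_group_summary")
}

#' Minimal representative sample set over grouping schemes
#'
#' Identifies a minimal set of samples capturing all distinct combinations of
#' group labels across the given schemes (one representative per distinct
#' label tuple, the lexicographically smallest sample id), as used to draw a
#' reduced phylogeny.
#'
#' @param gt Data frame with a `sample_id` column and one column per scheme.
#' @param schemes Character vector of column names to combine.
#' @return A list: `representatives` (character vector of sample ids),
#'   `reduced` (the corresponding rows of `gt`), `tuple` (the tuple label of
#'   every sample, named by sample id).
#' @export
representative_reduction <- function(gt, schemes) {
  if (!"sample_id" %in% names(gt))
    stop_mtg("gt must have a sample_id column", class = "mtg_error_table")
  bad <- setdiff(schemes, names(gt))
  if (length(bad))
    stop_mtg("unknown scheme column '%s'", bad[1], class = "mtg_error_table")
  tuple <- do.call(paste, c(gt[schemes], sep = "\r"))
  reps <- vapply(split(as.character(gt$sample_id), tuple),
                 function(v) sort(v)[1], character(1))
  reps <- unname(sort(reps))
  list(representatives = reps,
       reduced = gt[match(reps, gt$sample_id), , drop = FALSE],
       tuple = stats::setNames(tuple, gt$sample_id))
}
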