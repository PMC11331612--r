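# Aligned mtDNA sequences: FASTA I/O, coordinate masking of
# alignment-hostile regions (poly-C tracts), and pairwise distances with
# pairwise deletion of gaps/ambiguities.
#
# An MSA is held as an uppercase character matrix, one row per sample, with
# an optional designated reference row (e.g. the rCRS) carried as the
# "reference" attribute for reference-space coordinate masking.

#' Read an aligned FASTA into an MSA matrix
#'
#' @param path FASTA file (wrapped or single-line); all sequences must have
#'   equal length.
#' @param reference Optional id of the reference row (e.g. the rCRS entry);
#'   stored as attribute `"reference"`.
#' @return Uppercase character matrix over `{A,C,G,T,N,-,...}` with sample
#'   ids as row names.
#' @export
read_msa <- function(path, reference = NULL) {
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L)
    stop_mtg("no sequences in FASTA '%s'", path, class = "mtg_error_msa")
  chr <- lapply(as.character(dna), toupper)
  lens <- lengths(chr)
  if (length(unique(lens)) != 1L)
    stop_mtg("sequences are not aligned: lengths %s", paste(unique(lens),
             collapse = ", "), class = "mtg_error_msa")
  m <- do.call(rbind, chr)
  rownames(m) <- names(dna)
  as_msa(m, reference)
}

#' Construct an MSA matrix
#'
#' @param m Character matrix (rows = samples, named) or named character
#'   vector of equal-length strings.
#' @param reference Optional reference row id.
#' @return Uppercase character matrix with attribute `"reference"`.
#' @export
as_msa <- function(m, reference = NULL) {
  if (is.character(m) && is.null(dim(m))) {
    if (is.null(names(m)))
      stop_mtg("sequences must be named", class = "mtg_error_msa")
    if (length(unique(nchar(m))) != 1L)
      stop_mtg("sequences are not aligned", class = "mtg_error_msa")
    nm <- names(m)
    m <- do.call(rbind, strsplit(toupper(m), ""))
    rownames(m) <- nm
  }
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop_mtg("MSA rows must have unique names", class = "mtg_error_msa")
  m[] <- toupper(m)
  if (!is.null(reference) && !reference %in% rownames(m))
    stop_mtg("reference row '%s' not present in MSA", reference,
             class = "mtg_error_msa")
  attr(m, "reference") <- reference
  m
}

#' Write an MSA matrix as FASTA
#'
#' @param msa Character matrix as returned by [read_msa()]/[as_msa()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(msa))) {
    writeLines(paste0(">", rownames(msa)[i]), con)
    writeLines(paste(msa[i, ], collapse = ""), con)
  }
  invisible(path)
}

#' Default mtDNA mask: the poly-C regions
#'
#' The two poly-cytosine tracts around positions 303-315 and 16183-16194
#' (rCRS coordinates, 1-based inclusive) that are known to interfere with
#' multiple sequence alignment and are removed before distance computation.
#'
#' @return A two-column integer matrix of `start`,`end` ranges.
#' @export
default_mask <- function() {
  cbind(start = c(303L, 16183L), end = c(315L, 16194L))
}

normalize_ranges <- function(ranges) {
  ranges <- matrix(as.integer(ranges), ncol = 2,
                   dimnames = list(NULL, c("start", "end")))
  if (nrow(ranges) == 0L) return(ranges)
  if (any(ranges[, 1] < 1L) || any(ranges[, 2] < ranges[, 1]))
    stop_mtg("mask ranges must satisfy 1 <= start <= end",
             class = "mtg_error_mask")
  ranges <- ranges[order(ranges[, 1]), , drop = FALSE]
  # merge overlapping/adjacent ranges
  out <- ranges[1, , drop = FALSE]
  for (i in seq_len(nrow(ranges))[-1]) {
    if (ranges[i, 1] <= out[nrow(out), 2] + 1L)
      out[nrow(out), 2] <- max(out[nrow(out), 2], ranges[i, 2])
    else out <- rbind(out, ranges[i, , drop = FALSE])
  }
  out
}

#' Mask alignment positions
#'
#' Removes from every row the alignment columns falling in the given 1-based
#' inclusive coordinate ranges.  With `space = "reference"` coordinates are
#' counted over the non-gap characters of the designated reference row;
#' alignment columns where the reference has a gap (insertions relative to
#' the reference) inherit the coordinate of the last preceding reference
#' base, so insertions inside a masked range are masked with it.  With
#' `space = "alignment"` the ranges index alignment columns directly.
#'
#' @param msa Character matrix from [read_msa()]/[as_msa()].
#' @param ranges Two-column matrix of `start`,`end` pairs; defaults to
#'   [default_mask()].  Overlapping ranges are merged.
#' @param space `"reference"` (default) or `"alignment"`.
#' @return The masked MSA matrix (same class and attributes).
#' @export
mask_positions <- function(msa, ranges = default_mask(),
                           space = c("reference", "alignment")) {
  space <- match.arg(space)
  ranges <- normalize_ranges(ranges)
  if (nrow(ranges) == 0L) return(msa)
  L <- ncol(msa)
  if (space == "alignment") {
    coord <- seq_len(L)
    ref_len <- L
  } else {
    # original reference coordinates survive masking (attribute "ref_coord"),
    # so masking twice with the same spec equals masking once
    coord <- attr(msa, "ref_coord")
    ref_len <- attr(msa, "ref_len")
    if (is.null(coord)) {
      ref_id <- attr(msa, "reference")
      if (is.null(ref_id))
        stop_mtg("reference-space masking needs a designated reference row (see as_msa())",
                 class = "mtg_error_mask")
      coord <- cumsum(msa[ref_id, ] != "-")
      ref_len <- max(coord)
    }
  }
  if (any(ranges[, 1] > ref_len))
    stop_mtg("mask range starting at %d lies beyond the reference length %d",
             ranges[ranges[, 1] > ref_len, 1][1], ref_len,
             class = "mtg_error_mask")
  drop <- rep(FALSE, L)
  for (i in seq_len(nrow(ranges)))
    drop <- drop | (coord >= ranges[i, 1] & coord <= ranges[i, 2])
  if (all(drop))
    warning("mask removes every alignment column; returning a zero-length MSA")
  out <- msa[, !drop, drop = FALSE]
  attr(out, "reference") <- attr(msa, "reference")
  if (space == "reference") {
    attr(out, "ref_coord") <- coord[!drop]
    attr(out, "ref_len") <- ref_len
  }
  out
}

#' Pairwise sequence differences with pairwise deletion
#'
#' For each pair of rows, alignment sites where either sequence is a gap
#' (`-`) or not an unambiguous base (`A`,`C`,`G`,`T`) are excluded, and the
#' distance is the mismatch count (`mode = "count"`) or its proportion of the
#' compared sites (`mode = "p"`, the p-distance).  Ambiguity codes are
#' treated as missing (`N`), i.e. excluded pairwise.
#'
#' @param msa Character matrix from [read_msa()]/[as_msa()].
#' @param mode `"p"` (default) or `"count"`.
#' @return Symmetric numeric matrix with zero diagonal, rows/columns named by
#'   sample id.  A pair with zero comparable sites is an error.
#' @export
pairwise_differences <- function(msa, mode = c("p", "count")) {
  mode <- match.arg(mode)
  n <- nrow(msa)
  if (n == 0L) stop_mtg("empty MSA", class = "mtg_error_msa")
  good <- msa %in% c("A", "C", "G", "T")
  dim(good) <- dim(msa)
  d <- matrix(0, n, n, dimnames = list(rownames(msa), rownames(msa)))
  for (i in seq_len(n)) {
    if (i == n) break
    for (j in seq((i + 1), n)) {
      ok <- good[i, ] & good[j, ]
      m <- sum(ok)
      if (m == 0L)
        stop_mtg("sequences '%s' and '%s' share no comparable sites",
                 rownames(msa)[i], rownames(msa)[j],
                 class = "mtg_error_distance")
      diff <- sum(msa[i, ok] != msa[j, ok])
      d[i, j] <- d[j, i] <- if (mode == "count") diff else diff / m
    }
  }
  d
}
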