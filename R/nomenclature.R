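# Haplogroup nomenclature: parsing, irregularity classification, and
# nomenclature-based groupings (SC, SCL, custom prefix maps).
#
# The cladistic notation assumes a haplogroup name starts with a capital
# letter followed by digit blocks and single lowercase letters in alternation
# (e.g. C1d1).  Historically accumulated exceptions are flagged rather than
# rejected: two consecutive uppercase letters (nested-clade shorthand such as
# JT), two consecutive lowercase letters (H3ag1), mutation-modifier symbols
# *()@+" (D5a2a1+@16172), and apostrophe merges of sibling clades (M9a'b).

# Strict cladistic grammar on the core name: one uppercase letter, then
# optionally a digit block followed by alternating lowercase-letter/digit-block
# pairs, optionally ending on a single lowercase letter.
.HG_STRICT_RE <- "^[A-Z]([0-9]+([a-z][0-9]+)*[a-z]?)?$"

# Modifier symbols that start a trailing mutation annotation; the core clade
# name is everything before the first of them.
.HG_MODIFIER_RE <- "[+@*].*$"

.HG_SYMBOL_RE <- '[*()@+"]'

#' Parse a haplogroup name
#'
#' Parses a single haplogroup label under the cladistic notation, stripping a
#' trailing mutation modifier (anything from the first of `+`, `@`, `*`) to
#' obtain the core clade name, and flags naming irregularities.
#'
#' Leading/trailing whitespace is trimmed and internal whitespace and
#' digit-group commas are removed before parsing (labels are sometimes printed
#' as `"D5a2a1 + @16,172"`).  Names are case-sensitive.
#'
#' @param raw A single haplogroup label, e.g. `"L0d2c1a1"` or `"M9a'b"`.
#' @return An object of class `"hg_name"`: a list with elements `raw`
#'   (cleaned verbatim label), `core` (modifier-stripped clade name),
#'   `first_letter`, `l_prefix` (`"L"` plus first digit when the core starts
#'   with `L<digit>`, otherwise `NA`), and logical flags
#'   `consecutive_upper`, `consecutive_lower`, `has_symbols`,
#'   `has_apostrophe`, `strict_cladistic`.  `strict_cladistic` is `TRUE` only
#'   when the core matches the grammar and no irregularity flag is set.
#' @examples
#' parse_hg_name("C1d1")$strict_cladistic      # TRUE
#' parse_hg_name("H3ag1")$consecutive_lower    # TRUE
#' parse_hg_name("D5a2a1+@16172")$core         # "D5a2a1"
#' @export
parse_hg_name <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw))
    stop_mtg("haplogroup name must be a single character string",
             class = "mtg_error_parse")
  x <- gsub("[[:space:]]+", "", trimws(raw))
  x <- gsub(",", "", x, fixed = TRUE)
  if (!nzchar(x))
    stop_mtg("empty haplogroup name", class = "mtg_error_parse")
  if (!grepl("^[A-Z]", x))
    stop_mtg("haplogroup name '%s' does not start with an uppercase letter", x,
             class = "mtg_error_parse")
  core <- sub(.HG_MODIFIER_RE, "", x)
  flags <- list(
    consecutive_upper = grepl("[A-Z]{2}", core),
    consecutive_lower = grepl("[a-z]{2}", core),
    has_symbols       = grepl(.HG_SYMBOL_RE, x),
    has_apostrophe    = grepl("'", core, fixed = TRUE)
  )
  strict <- grepl(.HG_STRICT_RE, core) && !any(unlist(flags))
  first <- substr(core, 1L, 1L)
  l_prefix <- if (first == "L" && grepl("^L[0-9]", core))
    substr(core, 1L, 2L) else NA_character_
  structure(
    c(list(raw = x, core = core, first_letter = first, l_prefix = l_prefix),
      flags, list(strict_cladistic = strict)),
    class = "hg_name")
}

#' @export
print.hg_name <- function(x, ...) {
  flg <- c("consecutive_upper", "consecutive_lower", "has_symbols",
           "has_apostrophe")
  on <- flg[vapply(x[flg], isTRUE, logical(1))]
  cat(sprintf("<hg_name> %s (core %s)%s\n", x$raw, x$core,
              if (x$strict_cladistic) " [strict]"
              else paste0(" [", paste(on, collapse = ", "), "]")))
  invisible(x)
}

# Strip the trailing mutation modifier from a raw label (vectorised).
#' Core clade name of a haplogroup label
#'
#' Cleans whitespace/commas and strips the trailing mutation modifier
#' (from the first `+`, `@`, or `*`), returning the core clade name used for
#' grouping and hierarchy lookup.
#'
#' @param x Character vector of haplogroup labels.
#' @return Character vector of core names.
#' @export
hg_core <- function(x) {
  x <- gsub(",", "", gsub("[[:space:]]+", "", trimws(x)), fixed = TRUE)
  sub(.HG_MODIFIER_RE, "", x)
}

#' Parse many haplogroup names into a data frame
#'
#' @param x Character vector of haplogroup labels.
#' @return A data frame with one row per label and columns `raw`, `core`,
#'   `first_letter`, `l_prefix`, the four irregularity flags and
#'   `strict_cladistic`.
#' @export
parse_hg_names <- function(x) {
  if (length(x) == 0L)
    stop_mtg("no haplogroup names supplied", class = "mtg_error_parse")
  rows <- lapply(seq_along(x), function(i) {
    p <- tryCatch(parse_hg_name(x[[i]]), mtg_error_parse = function(e)
      stop_mtg("name %d ('%s'): %s", i, as.character(x[[i]]),
               conditionMessage(e), class = "mtg_error_parse"))
    as.data.frame(unclass(p), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarise naming irregularities over a set of haplogroup labels
#'
#' Counts, over all parsed names, how many carry each irregularity flag and
#' how many follow the strict cladistic grammar.  Percentages are rounded
#' half-up to one decimal, the precision at which such statistics are usually
#' reported.
#'
#' @param names Character vector of haplogroup labels (non-empty).
#' @return A list of class `"hg_name_summary"` with `total`, a `counts` named
#'   integer vector (`consecutive_upper`, `consecutive_lower`, `has_symbols`,
#'   `has_apostrophe`, `any_irregular`, `strict_cladistic`) and `percent`, the
#'   matching percentages.
#' @export
classify_hg_names <- function(names) {
  tab <- parse_hg_names(names)
  flg <- c("consecutive_upper", "consecutive_lower", "has_symbols",
           "has_apostrophe")
  counts <- vapply(tab[flg], sum, integer(1))
  counts <- c(counts,
              any_irregular = sum(rowSums(tab[flg]) > 0),
              strict_cladistic = sum(tab$strict_cladistic))
  total <- nrow(tab)
  structure(list(
    total = total,
    counts = counts,
    percent = round_half_up(100 * counts / total, 1)
  ), class = "hg_name_summary")
}

#' @export
print.hg_name_summary <- function(x, ...) {
  cat(sprintf("Haplogroup name classification over %d names\n", x$total))
  for (k in names(x$counts))
    cat(sprintf("  %-18s %6d  (%.1f%%)\n", k, x$counts[[k]], x$percent[[k]]))
  invisible(x)
}

#' Single Character (SC) grouping
#'
#' Groups a haplogroup by the first letter of its name, e.g. `C1b13c1` and
#' `C4a1a3a1` both map to `C`.  Note that for names starting with `L` this
#' lumps the phylogenetically deepest human mtDNA lineages into one
#' non-monophyletic group.
#'
#' @param x Character vector of haplogroup labels, or a single `hg_name`.
#' @return Character vector of SC group labels.
#' @export
group_sc <- function(x) {
  if (inherits(x, "hg_name")) return(x$first_letter)
  substr(hg_ok(x)$core, 1L, 1L)
}

#' Single Character and L-with-one-digit (SCL) grouping
#'
#' Same as [group_sc()] except that names starting with `L` are grouped by
#' their first letter plus first digit (`L0d2c1a1` and `L0k1a1c` map to `L0`),
#' which better reflects the depth of the African portion of the mtDNA
#' phylogeny.  A bare `"L"` is an error: no haplogroup L exists, only L0-L7.
#'
#' @inheritParams group_sc
#' @return Character vector of SCL group labels.
#' @export
group_scl <- function(x) {
  tab <- if (inherits(x, "hg_name"))
    as.data.frame(unclass(x), stringsAsFactors = FALSE) else hg_ok(x)
  out <- tab$first_letter
  isL <- tab$first_letter == "L"
  bad <- isL & is.na(tab$l_prefix)
  if (any(bad))
    stop_mtg(
      "cannot SCL-group '%s': a name starting with L must be followed by a digit (there is no haplogroup L)",
      tab$core[which(bad)[1]], class = "mtg_error_group")
  out[isL] <- tab$l_prefix[isL]
  out
}

hg_ok <- function(x) parse_hg_names(as.character(x))

#' Custom prefix-map grouping
#'
#' Groups each haplogroup by the longest key of `cluster_map` that is a prefix
#' of its core name; supports caller-defined top-level cluster schemes such as
#' the 33-cluster convention of recent haplogroup callers (where e.g. `HV` is
#' its own category distinct from `H`).
#'
#' @param x Character vector of haplogroup labels.
#' @param cluster_map Named character vector or list: `prefix -> group label`.
#' @param default Optional fallback label for names matching no prefix; when
#'   `NULL` (default) an unmatched name is an error.
#' @return Character vector of group labels.
#' @examples
#' group_custom(c("HV1a", "H1c"), c(HV = "HV", H = "H"))  # "HV" "H"
#' @export
group_custom <- function(x, cluster_map, default = NULL) {
  if (length(cluster_map) == 0L)
    stop_mtg("cluster_map must be non-empty", class = "mtg_error_group")
  keys <- names(cluster_map)
  if (is.null(keys) || any(!nzchar(keys)))
    stop_mtg("cluster_map must have non-empty names (the prefixes)",
             class = "mtg_error_group")
  keys <- keys[order(nchar(keys), decreasing = TRUE)]  # longest prefix wins
  cores <- hg_ok(x)$core
  vapply(cores, function(core) {
    hit <- keys[startsWith(core, keys)]
    if (length(hit)) as.character(cluster_map[[hit[1]]])
    else if (!is.null(default)) as.character(default)
    else stop_mtg("haplogroup '%s' matches no prefix in cluster_map and no default was given",
                  core, class = "mtg_error_group")
  }, character(1), USE.NAMES = FALSE)
}
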