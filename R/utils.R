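# Internal helpers shared across modules.

# Round half away from zero (printed-precision convention for percentages).
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mtg <- function(fmt, ..., class = "mtg_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "mtg_error")))
}

# Read a TSV with a header row; tab-separated, "." decimal, UTF-8.
read_tsv_strict <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}

write_tsv_strict <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
}
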