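# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Validate a character vector of nucleotide sequences. Returns invisibly the
# uppercased sequences; N (or any non-ACGT character) is rejected.
check_dna <- function(x, length = NULL, what = "sequence") {
  x <- toupper(x)
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf(
      "invalid %s at position %d: '%s' (only A/C/G/T allowed)",
      what, which(bad)[1], x[which(bad)[1]]
    ), call. = FALSE)
  }
  if (!is.null(length)) {
    wrong <- nchar(x) != length
    if (any(wrong)) {
      stop(sprintf(
        "%s at position %d has length %d, expected %d",
        what, which(wrong)[1], nchar(x[which(wrong)[1]]), length
      ), call. = FALSE)
    }
  }
  invisible(x)
}

# Run code under a fixed seed without disturbing the caller's RNG stream;
# a NULL seed leaves the current stream untouched.
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# Column presence check with a friendly error.
check_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Drop package subclasses so derived tables print/behave as plain tibbles.
as_plain_tibble <- function(x) {
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}
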