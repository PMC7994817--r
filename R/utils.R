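# Internal helpers shared across modules.

# Deterministic polynomial hash of a non-negative integer vector into
# [0, 2^31 - 2]. Horner scheme mod the Mersenne prime 2^31 - 1; all
# intermediates stay below 2^53 so double arithmetic is exact.
hash_ints <- function(v) {
  p <- 2147483647
  h <- 17
  for (x in v) {
    h <- (h * 31 + (x %% p)) %% p
  }
  h
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Median absolute deviation without consistency scaling.
raw_mad <- function(x) median(abs(x - median(x)))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Split a semicolon-separated tag field into a trimmed character vector.
split_tags <- function(x) {
  out <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  out[nzchar(out)]
}
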