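# Shared fixtures for the test suite. Everything is generated in code.

# construct a CountFingerprint from a named count vector
make_fp <- function(counts, radius = 2L) {
  structure(as.integer(counts), names = names(counts),
            radius = as.integer(radius),
            class = "CountFingerprint")
}

make_bits <- function(bits, radius = 3L) {
  structure(as.logical(bits), radius = as.integer(radius),
            class = "BitFingerprint")
}

# write a small annotated SMILES CSV and return its path
write_toy_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  df <- as.data.frame(rows, stringsAsFactors = FALSE)
  names(df) <- c("id", "smiles", "class", "subclass", "fragments", "role")
  write.csv(df, path, row.names = FALSE)
  path
}

toy_rows <- function() {
  rbind(
    c("a1", "CCO",       "A", "A-1", "f1;f2", "pnp"),
    c("a2", "CCCO",      "A", "A-1", "f1;f2", "pnp"),
    c("b1", "c1ccccc1",  "B", "B-1", "f3;f2", "pnp")
  )
}

# a deterministic profile matrix with given dimensions
toy_profiles <- function(n, F, seed = 42, induction = NULL) {
  set.seed(seed)
  values <- matrix(rnorm(n * F), n, F,
                   dimnames = list(sprintf("cpd%02d@10", seq_len(n)),
                                   sprintf("f_%04d", seq_len(F))))
  meta <- data.frame(
    compound_id = sprintf("cpd%02d", seq_len(n)),
    concentration_uM = 10,
    n_replicates = 1L,
    induction = induction %||% rep(25, n),
    stringsAsFactors = FALSE
  )
  rownames(meta) <- rownames(values)
  structure(list(meta = meta, values = values, z_star = 3),
            class = "cpa_profiles")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent Pearson correlation written out as raw sums (oracle)
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}
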