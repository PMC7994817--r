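#' Pairwise similarity matrix of a compound collection
#'
#' Computes all pairwise Tanimoto similarities between the parsed compounds
#' of a collection, using either count (ECFC-style) or bit (ECFP-style)
#' circular fingerprints.
#'
#' @param set a [compound_set()].
#' @param kind `"count"` or `"bit"`.
#' @param radius environment radius; defaults to 2 for count and 3 for bit
#'   fingerprints.
#' @param nbits bit-fingerprint length (ignored for `kind = "count"`).
#' @return An object of class `SimilarityMatrix`: a symmetric numeric matrix
#'   with unit diagonal, row/column names set to compound ids, and attribute
#'   `kind`.
#' @export
similarity_matrix <- function(set, kind = c("count", "bit"),
                              radius = NULL, nbits = 1024L) {
  stopifnot(inherits(set, "CompoundSet"))
  kind <- match.arg(kind)
  if (is.null(radius)) radius <- if (kind == "count") 2L else 3L
  ids <- set$compounds$id
  if (length(ids) < 2L) stopf("need at least 2 compounds")

  fps <- lapply(set$mols[ids], function(m) {
    if (kind == "count") count_fingerprint(m, radius = radius)
    else bit_fingerprint(m, radius = radius, nbits = nbits)
  })
  n <- length(ids)
  sim <- diag(1, n)
  dimnames(sim) <- list(ids, ids)
  tan <- if (kind == "count") tanimoto_count else tanimoto_bit
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- tan(fps[[i]], fps[[j]])
      sim[i, j] <- s
      sim[j, i] <- s
    }
  }
  structure(sim, kind = kind, radius = radius, class = c("SimilarityMatrix",
                                                         "matrix", "array"))
}

#' Intra- and inter-subclass similarity medians
#'
#' Summarizes the chemical homogeneity of the collection's subclasses: the
#' pooled median over all unordered within-subclass compound pairs
#' (self-pairs excluded), the pooled median over all cross-subclass pairs,
#' and per-subclass medians. Subclasses with a single member contribute no
#' within-pairs and are reported with a warning.
#'
#' The pooled intra median is the median of the union of within-subclass
#' pairs, not the median of per-subclass medians; per-subclass medians are
#' returned as well so either aggregation is recoverable.
#'
#' @param set a [compound_set()].
#' @param kind,radius,nbits passed to [similarity_matrix()].
#' @return An object of class `ClassSimilaritySummary`: a list with
#'   `intra_median`, `inter_median`, `per_subclass` (named vector),
#'   `n_intra_pairs`, `n_inter_pairs`, and the long-format `pairs`
#'   data.frame (`id_a`, `id_b`, `subclass_a`, `subclass_b`, `similarity`).
#' @export
class_similarity_summary <- function(set, kind = c("count", "bit"),
                                     radius = NULL, nbits = 1024L) {
  kind <- match.arg(kind)
  sim <- similarity_matrix(set, kind = kind, radius = radius, nbits = nbits)
  df <- set$compounds
  sub <- setNames(df$subclass_label, df$id)
  ids <- rownames(sim)
  n <- length(ids)

  pairs <- list()
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      k <- k + 1L
      pairs[[k]] <- data.frame(
        id_a = ids[i], id_b = ids[j],
        subclass_a = sub[[ids[i]]], subclass_b = sub[[ids[j]]],
        similarity = sim[i, j], stringsAsFactors = FALSE
      )
    }
  }
  pairs <- do.call(rbind, pairs)

  intra <- pairs[pairs$subclass_a == pairs$subclass_b, , drop = FALSE]
  inter <- pairs[pairs$subclass_a != pairs$subclass_b, , drop = FALSE]

  singletons <- names(which(table(df$subclass_label) == 1L))
  if (length(singletons)) {
    warnf("subclass(es) with a single member omitted from intra median: %s",
          paste(singletons, collapse = ", "))
  }

  per_sub <- tapply(intra$similarity, intra$subclass_a, median)

  structure(
    list(
      intra_median = if (nrow(intra)) median(intra$similarity) else NA_real_,
      inter_median = if (nrow(inter)) median(inter$similarity) else NA_real_,
      per_subclass = per_sub,
      n_intra_pairs = nrow(intra),
      n_inter_pairs = nrow(inter),
      pairs = pairs
    ),
    class = "ClassSimilaritySummary"
  )
}

#' @export
print.ClassSimilaritySummary <- function(x, ...) {
  cat(sprintf("Subclass similarity: intra median %.3f (%d pairs), inter median %.3f (%d pairs)\n",
              x$intra_median, x$n_intra_pairs, x$inter_median, x$n_inter_pairs))
  invisible(x)
}

#' Write the long-format pair similarity table
#'
#' @param summary a [class_similarity_summary()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pair_csv <- function(summary, path) {
  stopifnot(inherits(summary, "ClassSimilaritySummary"))
  write.csv(summary$pairs, path, row.names = FALSE)
  invisible(path)
}
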