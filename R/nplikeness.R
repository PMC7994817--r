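#' Train a natural-product-likeness scorer
#'
#' Learns per-fragment contributions from a natural-product reference set
#' and a synthetic reference set. Fragments are the atom-centered circular
#' environments of [count_fingerprint()] (radius 2 by default). Each
#' fragment's contribution is the log-ratio of its relative occurrence
#' frequency in the two sets, with add-one (Laplace) smoothing over the
#' joint fragment vocabulary:
#'
#' `contribution(k) = log( (c_np(k)+1)/(T_np+V) / ((c_syn(k)+1)/(T_syn+V)) )`
#'
#' where `c` are occurrence counts, `T` total occurrences per set and `V`
#' the vocabulary size. Fragments seen only in the NP set get positive
#' contributions, fragments equally frequent in both get contributions near
#' zero. Training is deterministic for fixed reference sets.
#'
#' @param np_refs,synth_refs [compound_set()] reference collections
#'   (both non-empty).
#' @param radius fragment environment radius; default 2.
#' @return An object of class `FragmentScoreTable`: list with
#'   `contributions` (named numeric), `radius` and training set sizes.
#' @export
train_np_likeness <- function(np_refs, synth_refs, radius = 2L) {
  stopifnot(inherits(np_refs, "CompoundSet"),
            inherits(synth_refs, "CompoundSet"))
  if (length(np_refs) == 0L || length(synth_refs) == 0L) {
    stopf("both reference sets must be non-empty")
  }
  tally <- function(set) {
    counts <- new.env(parent = emptyenv())
    for (m in set$mols) {
      fp <- count_fingerprint(m, radius = radius)
      for (k in names(fp)) {
        assign(k, (if (exists(k, counts)) get(k, counts) else 0L) + fp[[k]],
               envir = counts)
      }
    }
    cc <- as.list(counts)
    setNames(as.numeric(unlist(cc)), names(cc))
  }
  c_np <- tally(np_refs)
  c_syn <- tally(synth_refs)
  vocab <- sort(union(names(c_np), names(c_syn)))
  v_np <- setNames(numeric(length(vocab)), vocab)
  v_syn <- v_np
  v_np[names(c_np)] <- c_np
  v_syn[names(c_syn)] <- c_syn
  V <- length(vocab)
  f_np <- (v_np + 1) / (sum(v_np) + V)
  f_syn <- (v_syn + 1) / (sum(v_syn) + V)
  structure(
    list(
      contributions = log(f_np / f_syn),
      radius = as.integer(radius),
      n_np = length(np_refs),
      n_synth = length(synth_refs),
      totals = c(np = sum(v_np), synth = sum(v_syn), vocabulary = V)
    ),
    class = "FragmentScoreTable"
  )
}

#' Score the natural-product likeness of a molecule
#'
#' Sums the trained contributions over the molecule's atom-centered
#' fragments (occurrence-weighted), normalizes by heavy-atom count, and
#' clips the result to `[-5, 5]`. Fragments absent from the training
#' vocabulary contribute zero. Positive scores indicate NP-like
#' connectivity, negative scores synthetic-like connectivity.
#'
#' @param mol a single SDF molecule (e.g. from a [compound_set()]'s `mols`).
#' @param table a [train_np_likeness()] result.
#' @return numeric score in `[-5, 5]`.
#' @export
np_likeness_score <- function(mol, table) {
  stopifnot(inherits(table, "FragmentScoreTable"))
  g <- if (is.list(mol) && !is.null(mol$elements)) mol else mol_graph(mol)
  fp <- count_fingerprint(g, radius = table$radius)
  if (length(fp) == 0L) stopf("molecule has no scorable fragments")
  contrib <- table$contributions[names(fp)]
  contrib[is.na(contrib)] <- 0
  score <- sum(contrib * as.numeric(fp)) / g$n
  max(-5, min(5, score))
}
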