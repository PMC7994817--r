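#' Circular count fingerprints
#'
#' Computes an atom-centered circular (Morgan-style) count fingerprint of a
#' molecule. Every heavy atom contributes one hashed environment identifier
#' per radius from 0 up to `radius`; identifiers are counted, so the result
#' is a sparse map from identifier to occurrence count (an ECFC-style count
#' fingerprint; the collection analysis uses radius 2, i.e. ECFC4-like).
#'
#' The hashing scheme is fixed and documented for reproducibility: the
#' radius-0 invariant of an atom is the tuple (atomic number, heavy-atom
#' degree, total bond order, implicit hydrogen count, ring-membership flag)
#' hashed with a polynomial hash modulo 2^31-1; at each iteration an atom's
#' identifier is rehashed together with the sorted list of (bond order,
#' neighbor identifier) pairs. Sorting makes the result invariant to input
#' atom ordering. An atom stops emitting new identifiers once its
#' environment no longer grows (e.g. a single-atom molecule emits exactly
#' one identifier at radius 0).
#'
#' This scheme is deterministic across sessions but is not bit-compatible
#' with other toolkits' circular fingerprints.
#'
#' @param mol a single SDF molecule (e.g. one element of the `mols` list of
#'   a [compound_set()]).
#' @param radius maximum environment radius (non-negative integer);
#'   default 2.
#' @return An object of class `CountFingerprint`: a named integer vector of
#'   counts (names are identifier strings) with attribute `radius`.
#' @export
count_fingerprint <- function(mol, radius = 2L) {
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0) {
    stopf("radius must be a non-negative integer")
  }
  radius <- as.integer(radius)
  g <- if (is.list(mol) && !is.null(mol$elements)) mol else mol_graph(mol)

  z <- .atomic_number[g$elements]
  z[is.na(z)] <- 0L
  ids <- vapply(seq_len(g$n), function(i) {
    hash_ints(c(z[i], g$degree[i], round(g$bond_sum[i] * 10),
                g$nH[i], as.integer(g$ring_atoms[i])))
  }, numeric(1))

  emitted <- ids
  active <- rep(TRUE, g$n)

  if (radius > 0L && nrow(g$bonds) > 0L) {
    # neighbor lists: for atom i, (bond order, other atom)
    nb <- lapply(seq_len(g$n), function(i) {
      ks <- g$adj[[i]]
      if (!length(ks)) return(NULL)
      other <- ifelse(g$bonds$a[ks] == i, g$bonds$b[ks], g$bonds$a[ks])
      cbind(order = g$bonds$order[ks], atom = other)
    })
    # atoms within distance r, for environment-growth dedup
    env_size <- vapply(seq_len(g$n), function(i) 1L, integer(1))
    envs <- lapply(seq_len(g$n), function(i) i)

    for (r in seq_len(radius)) {
      new_ids <- ids
      for (i in seq_len(g$n)) {
        if (!active[i]) next
        m <- nb[[i]]
        if (is.null(m)) { active[i] <- FALSE; next }
        pairs <- cbind(m[, "order"], ids[m[, "atom"]])
        ord <- order(pairs[, 1], pairs[, 2])
        new_ids[i] <- hash_ints(c(r, ids[i], t(pairs[ord, , drop = FALSE])))
      }
      # grow environments; deactivate atoms whose environment is saturated
      new_envs <- envs
      for (i in seq_len(g$n)) {
        if (!active[i]) next
        m <- nb[[i]]
        grown <- unique(unlist(c(envs[i], lapply(envs[[i]], function(a) {
          ma <- nb[[a]]
          if (is.null(ma)) integer(0) else ma[, "atom"]
        }))))
        new_envs[[i]] <- grown
        if (length(grown) == length(envs[[i]])) {
          active[i] <- FALSE
        } else {
          emitted <- c(emitted, new_ids[i])
        }
      }
      envs <- new_envs
      ids <- new_ids
      if (!any(active)) break
    }
  }

  counts <- table(format(emitted, scientific = FALSE, trim = TRUE))
  fp <- setNames(as.integer(counts), names(counts))
  structure(fp, radius = radius, class = "CountFingerprint")
}

#' Circular bit fingerprints
#'
#' Folds the hashed environment identifiers of [count_fingerprint()] into a
#' fixed-length bit vector (default 1024 bits, radius 3: an ECFP6-style bit
#' fingerprint).
#'
#' @param mol a single SDF molecule.
#' @param radius environment radius; default 3.
#' @param nbits fingerprint length; default 1024.
#' @return An object of class `BitFingerprint`: a logical vector of length
#'   `nbits` with attribute `radius`.
#' @export
bit_fingerprint <- function(mol, radius = 3L, nbits = 1024L) {
  fp <- count_fingerprint(mol, radius = radius)
  keys <- as.numeric(names(fp))
  bits <- logical(nbits)
  bits[(keys %% nbits) + 1L] <- TRUE
  structure(bits, radius = as.integer(radius), class = "BitFingerprint")
}

#' Tanimoto similarity of count fingerprints
#'
#' The count generalization of the Tanimoto coefficient:
#' `sum_k min(a_k, b_k) / sum_k max(a_k, b_k)` over the union of keys.
#'
#' @param a,b [count_fingerprint()] objects computed at the same radius.
#' @return similarity in \[0, 1\].
#' @export
tanimoto_count <- function(a, b) {
  if (!identical(attr(a, "radius"), attr(b, "radius"))) {
    stopf("fingerprints have different radii (%s vs %s)",
          attr(a, "radius"), attr(b, "radius"))
  }
  if (length(a) == 0L && length(b) == 0L) {
    stopf("Tanimoto similarity undefined for two empty fingerprints")
  }
  keys <- union(names(a), names(b))
  av <- setNames(numeric(length(keys)), keys)
  bv <- av
  av[names(a)] <- a
  bv[names(b)] <- b
  sum(pmin(av, bv)) / sum(pmax(av, bv))
}

#' Tanimoto similarity of bit fingerprints
#'
#' `|a AND b| / |a OR b|` for equal-length bit vectors.
#'
#' @param a,b [bit_fingerprint()] objects of the same length.
#' @return similarity in \[0, 1\].
#' @export
tanimoto_bit <- function(a, b) {
  if (length(a) != length(b)) stopf("bit fingerprints differ in length")
  u <- sum(a | b)
  if (u == 0L) stopf("Tanimoto similarity undefined for two empty fingerprints")
  sum(a & b) / u
}
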