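#' Select one profile per compound by induction window
#'
#' For each compound, chooses the concentration whose induction lies inside
#' the window (default 20-40%). When several concentrations qualify, the
#' one closest to the window midpoint wins; exact ties go to the lower
#' concentration (prefer the weaker perturbation at equal information).
#' Compounds with no qualifying concentration are excluded and listed.
#'
#' @param profiles a [profiles_from_plates()] object.
#' @param window induction window `c(lo, hi)` in percent.
#' @return A `cpa_profiles` subset with one row per selected compound and
#'   attribute `excluded`: a data.frame of compounds with no concentration
#'   in the window and their best induction.
#' @export
select_profiles <- function(profiles, window = c(20, 40)) {
  stopifnot(inherits(profiles, "cpa_profiles"))
  if (length(window) != 2L || window[1] >= window[2]) {
    stopf("window must be c(lo, hi) with lo < hi")
  }
  meta <- profiles$meta
  mid <- mean(window)
  chosen <- integer(0)
  excluded <- list()
  for (cid in unique(meta$compound_id)) {
    rows <- which(meta$compound_id == cid)
    ok <- rows[meta$induction[rows] >= window[1] &
               meta$induction[rows] <= window[2]]
    if (!length(ok)) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        compound_id = cid,
        best_induction = meta$induction[rows][
          which.min(abs(meta$induction[rows] - mid))],
        stringsAsFactors = FALSE
      )
      next
    }
    dist <- abs(meta$induction[ok] - mid)
    best <- ok[order(dist, meta$concentration_uM[ok])][1]
    chosen <- c(chosen, best)
  }
  if (!length(chosen)) {
    stopf("no compound has a concentration inside the induction window [%g, %g]; %d compounds excluded",
          window[1], window[2], length(excluded))
  }
  out <- subset_profiles(profiles, chosen)
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(compound_id = character(0), best_induction = numeric(0))
  attr(out, "window") <- window
  out
}

#' PCA of phenotypic profiles
#'
#' Condenses selected profiles into `k` (default 3) principal components of
#' the standardized feature matrix, and reports the absolute Pearson
#' correlation between PC1 scores and induction. A wide induction range
#' makes PC1 track overall activity strength rather than phenotype, which is
#' why profile selection narrows the induction window first; this
#' diagnostic quantifies that artifact.
#'
#' @param profiles a `cpa_profiles` object.
#' @param k number of components (default 3).
#' @return An object of class `ProfilePCAResult`: list with `scores`,
#'   `explained_variance`, `pc1_induction_r` and `meta` (copied from the
#'   input).
#' @export
profile_pca <- function(profiles, k = 3L) {
  stopifnot(inherits(profiles, "cpa_profiles"))
  n <- nrow(profiles$values)
  if (n < k + 1L) stopf("need at least k + 1 = %d profiles, have %d", k + 1L, n)
  x <- profiles$values
  sds <- apply(x, 2, sd)
  x <- x[, sds > 0, drop = FALSE]
  p <- prcomp(x, center = TRUE, scale. = TRUE)
  k <- min(k, ncol(p$x))
  evf <- p$sdev^2 / sum(p$sdev^2)
  r <- if (sd(profiles$meta$induction) == 0) NA_real_ else
    abs(cor(p$x[, 1], profiles$meta$induction))
  structure(
    list(scores = p$x[, seq_len(k), drop = FALSE],
         explained_variance = evf[seq_len(k)],
         pc1_induction_r = r,
         meta = profiles$meta),
    class = "ProfilePCAResult"
  )
}

#' Cluster separation of labelled profiles in PCA space
#'
#' Operationalizes "the classes form clusters in the PCA plot" as the mean
#' silhouette width of the subclass labels on the 3-D component scores
#' (Euclidean distances). Labels with a single member are excluded with a
#' warning. The `clustered` flag is `score >= cutoff` (default 0.25).
#'
#' @param scores a [profile_pca()] result or a numeric score matrix.
#' @param labels subclass label per profile.
#' @param cutoff silhouette cutoff for the `clustered` flag.
#' @return An object of class `ClusterSeparation`: list with `score`
#'   (overall mean silhouette in \[-1, 1\]), `per_label`, `clustered`,
#'   `cutoff` and `labels_used`.
#' @export
cluster_separation <- function(scores, labels, cutoff = 0.25) {
  x <- if (inherits(scores, "ProfilePCAResult")) scores$scores else
    as.matrix(scores)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  tab <- table(labels)
  singletons <- names(tab)[tab < 2L]
  if (length(singletons)) {
    warnf("label(s) with a single member excluded: %s",
          paste(singletons, collapse = ", "))
    keep <- !(labels %in% singletons)
    x <- x[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  if (length(unique(labels)) < 2L) {
    stopf("cluster separation needs at least 2 labels with >= 2 members")
  }
  f <- factor(labels)
  sil <- cluster::silhouette(as.integer(f), stats::dist(x))
  per_label <- tapply(sil[, "sil_width"], labels, mean)
  score <- mean(sil[, "sil_width"])
  structure(
    list(score = score, per_label = per_label,
         clustered = score >= cutoff, cutoff = cutoff,
         labels_used = levels(f)),
    class = "ClusterSeparation"
  )
}

#' Classify a shared fragment as dominating or non-dominating
#'
#' Given the selected profiles of all subclasses sharing a fragment,
#' computes (i) the cross-subclass MBP -- the median over per-subclass-pair
#' MBPs, so large subclasses do not dominate (the pooled-pairs aggregation
#' is also returned) -- and (ii) whether the subclasses form clusters in
#' 3-component PCA space ([cluster_separation()]).
#'
#' Decision rule: a low cross-subclass MBP (`< threshold`, default 75%)
#' and/or class-based clustering means combination-specific profiles, i.e.
#' the fragment is **non-dominating**; a high MBP without clustering means
#' the shared fragment dictates the phenotype, i.e. **dominating**. When
#' the MBP falls within `band` points of the threshold (default 1) and the
#' two signals conflict, the call is **maybe_non_dominating**.
#'
#' @param profiles a `cpa_profiles` object of selected profiles (e.g. from
#'   [select_profiles()]).
#' @param subclass subclass label per profile row.
#' @param fragment the fragment tag under evaluation (bookkeeping only).
#' @param threshold biosimilarity threshold in percent (default 75).
#' @param band half-width of the conflict band around the threshold.
#' @param silhouette_cutoff passed to [cluster_separation()].
#' @return An object of class `DominanceCall`: list with `fragment`,
#'   `classification` (one of `"dominating"`, `"maybe_non_dominating"`,
#'   `"non_dominating"`), `mbp`, `mbp_pooled`, `pair_mbps`, `clustered`,
#'   `silhouette`, `subclasses` and the thresholds used.
#' @export
classify_fragment_dominance <- function(profiles, subclass, fragment = NA,
                                        threshold = 75, band = 1,
                                        silhouette_cutoff = 0.25) {
  stopifnot(inherits(profiles, "cpa_profiles"))
  subclass <- as.character(subclass)
  stopifnot(nrow(profiles$meta) == length(subclass))
  subs <- unique(subclass)
  if (length(subs) < 2L) {
    stopf("fragment dominance needs >= 2 subclasses sharing the fragment")
  }

  pair_mbps <- list()
  for (i in seq_along(subs)[-length(subs)]) {
    for (j in (i + 1L):length(subs)) {
      A <- subset_profiles(profiles, subclass == subs[i])
      B <- subset_profiles(profiles, subclass == subs[j])
      pair_mbps[[length(pair_mbps) + 1L]] <- data.frame(
        subclass_a = subs[i], subclass_b = subs[j],
        mbp = mbp(cross_similarity(A, B), mode = "between"),
        stringsAsFactors = FALSE
      )
    }
  }
  pair_mbps <- do.call(rbind, pair_mbps)
  frag_mbp <- median(pair_mbps$mbp)

  # pooled alternative: all cross-subclass cells at once
  pooled <- unlist(lapply(seq_len(nrow(pair_mbps)), function(k) {
    A <- subset_profiles(profiles, subclass == pair_mbps$subclass_a[k])
    B <- subset_profiles(profiles, subclass == pair_mbps$subclass_b[k])
    as.vector(unclass(cross_similarity(A, B)))
  }))
  mbp_pooled <- median(pooled)

  pca <- profile_pca(profiles, k = 3L)
  sep <- cluster_separation(pca, subclass, cutoff = silhouette_cutoff)

  call <- dominance_rule(frag_mbp, sep$clustered, threshold, band)

  structure(
    list(fragment = fragment, classification = call,
         mbp = frag_mbp, mbp_pooled = mbp_pooled, pair_mbps = pair_mbps,
         clustered = sep$clustered, silhouette = sep$score,
         subclasses = subs, threshold = threshold, band = band,
         silhouette_cutoff = silhouette_cutoff,
         window = attr(profiles, "window")),
    class = "DominanceCall"
  )
}

# The codified dominance rule, exposed for testing: evidence in, label out.
dominance_rule <- function(mbp_value, clustered, threshold = 75, band = 1) {
  mbp_low <- mbp_value < threshold
  conflict <- mbp_low == !clustered  # the two signals disagree
  if (abs(mbp_value - threshold) <= band && conflict) {
    "maybe_non_dominating"
  } else if (mbp_low || clustered) {
    "non_dominating"
  } else {
    "dominating"
  }
}

#' @export
print.DominanceCall <- function(x, ...) {
  cat(sprintf("Fragment '%s': %s (MBP %.1f%%, silhouette %.2f%s)\n",
              x$fragment, x$classification, x$mbp, x$silhouette,
              if (x$clustered) ", clustered" else ""))
  invisible(x)
}

#' Evaluate a predictively designed compound class
#'
#' Compares a new class's selected profiles against reference classes
#' grouped by shared fragment: for each reference group the average MBP is
#' the arithmetic mean of the new-class-vs-subclass MBPs. The verdict is
#' `"unique"` when every average MBP falls below the biosimilarity
#' threshold (expected for a class built from non-dominating fragments) and
#' `"redundant"` naming the matching fragment groups otherwise (expected
#' when a dominating fragment is reused).
#'
#' @param new_profiles `cpa_profiles` of the new class.
#' @param reference_groups named list (one element per reference fragment);
#'   each element is a named list of `cpa_profiles`, one per subclass
#'   containing that fragment.
#' @param threshold biosimilarity threshold (default 75%).
#' @return An object of class `PredictionReport`: list with `average_mbp`
#'   (named vector, one per reference fragment), `per_subclass` (data.frame
#'   fragment/subclass/mbp), `verdict` and `redundant_with`.
#' @export
evaluate_predicted_class <- function(new_profiles, reference_groups,
                                     threshold = 75) {
  stopifnot(inherits(new_profiles, "cpa_profiles"))
  if (!length(reference_groups) || is.null(names(reference_groups))) {
    stopf("reference_groups must be a non-empty named list")
  }
  per <- list()
  avg <- setNames(numeric(length(reference_groups)), names(reference_groups))
  for (frag in names(reference_groups)) {
    group <- reference_groups[[frag]]
    if (!length(group)) stopf("reference group '%s' is empty", frag)
    mbps <- vapply(group, function(ref) {
      mbp(cross_similarity(new_profiles, ref), mode = "between")
    }, numeric(1))
    avg[frag] <- mean(mbps)
    per[[frag]] <- data.frame(
      fragment = frag,
      subclass = if (is.null(names(group))) as.character(seq_along(group)) else
        names(group),
      mbp = unname(mbps), stringsAsFactors = FALSE
    )
  }
  redundant <- names(avg)[avg >= threshold]
  structure(
    list(average_mbp = avg,
         per_subclass = do.call(rbind, unname(per)),
         verdict = if (length(redundant)) "redundant" else "unique",
         redundant_with = redundant,
         threshold = threshold),
    class = "PredictionReport"
  )
}

#' @export
print.PredictionReport <- function(x, ...) {
  cat(sprintf("Predicted-class evaluation: %s%s\n", x$verdict,
              if (length(x$redundant_with))
                paste0(" (with ", paste(x$redundant_with, collapse = ", "), ")")
              else ""))
  for (f in names(x$average_mbp)) {
    cat(sprintf("  vs %s: average MBP %.1f%%\n", f, x$average_mbp[[f]]))
  }
  invisible(x)
}
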