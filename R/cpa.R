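#' Well-level plate data
#'
#' Container for one plate of a cell-painting experiment: a well table
#' (well id, treatment compound or DMSO control flag, concentration) and the
#' raw feature matrix. Control wells carry `compound_id == "DMSO"`.
#'
#' @param plate plate identifier.
#' @param wells data.frame with columns `well`, `compound_id`,
#'   `concentration_uM`.
#' @param features numeric matrix, one row per well; columns are the
#'   morphological features (all wells must share the same feature set).
#' @return An object of class `PlateData`.
#' @export
plate_data <- function(plate, wells, features) {
  features <- as.matrix(features)
  stopifnot(nrow(wells) == nrow(features))
  need <- c("well", "compound_id", "concentration_uM")
  missing_cols <- setdiff(need, names(wells))
  if (length(missing_cols)) {
    stopf("wells table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (is.null(colnames(features))) {
    colnames(features) <- sprintf("f_%04d", seq_len(ncol(features)))
  }
  structure(list(plate = as.character(plate), wells = wells,
                 features = features),
            class = "PlateData")
}

#' @export
print.PlateData <- function(x, ...) {
  cat(sprintf("PlateData %s: %d wells (%d DMSO), %d features\n",
              x$plate, nrow(x$wells), sum(x$wells$compound_id == "DMSO"),
              ncol(x$features)))
  invisible(x)
}

#' Read well-level plate CSV
#'
#' Reads the well-level dialect `plate, well, compound_id,
#' concentration_uM, <feature columns...>` and splits it into one
#' [plate_data()] object per plate.
#'
#' @param path CSV file.
#' @return named list of `PlateData`.
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("plate", "well", "compound_id", "concentration_uM")
  missing_cols <- setdiff(meta_cols, names(df))
  if (length(missing_cols)) {
    stopf("plate CSV lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  feat_cols <- setdiff(names(df), meta_cols)
  if (!length(feat_cols)) stopf("plate CSV has no feature columns")
  out <- lapply(split(df, df$plate), function(d) {
    plate_data(d$plate[1], d[, c("well", "compound_id", "concentration_uM")],
               as.matrix(d[, feat_cols, drop = FALSE]))
  })
  out[order(names(out))]
}

#' Write plates to the well-level CSV dialect
#'
#' @param plates a `PlateData` or list of them.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(plates, path) {
  if (inherits(plates, "PlateData")) plates <- list(plates)
  rows <- lapply(plates, function(p) {
    cbind(data.frame(plate = p$plate, p$wells, stringsAsFactors = FALSE),
          as.data.frame(p$features))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Robust z-normalization of a plate against its DMSO controls
#'
#' Per feature and per plate: `z = (x - median_DMSO) / (1.4826 * MAD_DMSO)`
#' where the MAD is the raw median absolute deviation of the plate's DMSO
#' control wells. Features whose control MAD is zero are flagged and their
#' z-scores set to 0 (no information about spread).
#'
#' @param p a [plate_data()].
#' @param min_dmso minimum number of control wells required (default 8).
#' @return A `PlateData` whose `features` are robust z-scores, with
#'   attribute `flagged` naming any zero-MAD features.
#' @export
normalize_plate <- function(p, min_dmso = 8L) {
  stopifnot(inherits(p, "PlateData"))
  ctrl <- p$wells$compound_id == "DMSO"
  if (sum(ctrl) < min_dmso) {
    stopf("plate %s has %d DMSO wells; %d required", p$plate, sum(ctrl),
          min_dmso)
  }
  D <- p$features[ctrl, , drop = FALSE]
  med <- apply(D, 2, median)
  scale <- 1.4826 * apply(D, 2, raw_mad)
  flagged <- colnames(p$features)[scale == 0]
  scale[scale == 0] <- Inf  # z -> 0 for flagged features
  z <- sweep(sweep(p$features, 2, med), 2, scale, "/")
  out <- plate_data(p$plate, p$wells, z)
  attr(out, "flagged") <- flagged
  out
}

#' Median-aggregate replicate wells
#'
#' Collapses the replicate z-score vectors of one compound/concentration
#' into a single profile by the per-feature median.
#'
#' @param zmat numeric matrix, one row per replicate well.
#' @return list with `values` (named numeric vector) and `n_replicates`.
#' @export
aggregate_replicates <- function(zmat) {
  zmat <- rbind(zmat)
  if (nrow(zmat) < 1L) stopf("at least one replicate required")
  list(values = apply(zmat, 2, median), n_replicates = nrow(zmat))
}

#' Induction percentage of a profile
#'
#' The percentage of features significantly changed relative to the DMSO
#' control: `100 * #(|z| >= z_star) / F`.
#'
#' @param z normalized profile vector.
#' @param z_star significance threshold on the robust z-score (default 3).
#' @return induction percent in \[0, 100\].
#' @export
induction <- function(z, z_star = 3) {
  if (length(z) == 0L) stopf("empty profile")
  100 * mean(abs(z) >= z_star)
}

#' Biosimilarity of two profiles
#'
#' Derived from the correlation distance `d = 1 - r` between the two full
#' feature vectors (Pearson): `biosimilarity = 100 * (1 - d) = 100 * r`,
#' clipped at 0 so percentages lie in \[0, 100\]. Identical profiles give
#' 100; anti-correlated profiles clip to 0.
#'
#' @param a,b numeric feature vectors of equal length.
#' @return biosimilarity percent in \[0, 100\].
#' @export
biosimilarity <- function(a, b) {
  if (length(a) != length(b)) stopf("profiles differ in length")
  if (sd(a) == 0 || sd(b) == 0) stopf("zero-variance profile")
  100 * max(0, cor(a, b))
}

#' Collections of aggregated profiles
#'
#' Builds compound/concentration profiles from normalized plates: replicate
#' wells (same compound and concentration across plates) are
#' median-aggregated, and each profile's induction is computed.
#'
#' @param plates list of [normalize_plate()] outputs.
#' @param z_star induction significance threshold.
#' @return An object of class `cpa_profiles`: list with `meta` (data.frame:
#'   `compound_id`, `concentration_uM`, `n_replicates`, `induction`) and
#'   `values` (profile x feature matrix, rows aligned with `meta`).
#' @export
profiles_from_plates <- function(plates, z_star = 3) {
  if (inherits(plates, "PlateData")) plates <- list(plates)
  rows <- do.call(rbind, lapply(plates, function(p) {
    data.frame(compound_id = p$wells$compound_id,
               concentration_uM = p$wells$concentration_uM,
               stringsAsFactors = FALSE)
  }))
  zmat <- do.call(rbind, lapply(plates, function(p) p$features))
  treated <- rows$compound_id != "DMSO"
  rows <- rows[treated, , drop = FALSE]
  zmat <- zmat[treated, , drop = FALSE]
  key <- paste(rows$compound_id, rows$concentration_uM, sep = "@")
  keys <- unique(key)
  meta <- list()
  values <- matrix(NA_real_, length(keys), ncol(zmat),
                   dimnames = list(keys, colnames(zmat)))
  for (i in seq_along(keys)) {
    sel <- key == keys[i]
    agg <- aggregate_replicates(zmat[sel, , drop = FALSE])
    values[i, ] <- agg$values
    meta[[i]] <- data.frame(
      compound_id = rows$compound_id[sel][1],
      concentration_uM = rows$concentration_uM[sel][1],
      n_replicates = agg$n_replicates,
      induction = induction(agg$values, z_star),
      stringsAsFactors = FALSE
    )
  }
  meta <- do.call(rbind, meta)
  rownames(meta) <- keys
  structure(list(meta = meta, values = values, z_star = z_star),
            class = "cpa_profiles")
}

#' @export
print.cpa_profiles <- function(x, ...) {
  cat(sprintf("cpa_profiles: %d profiles, %d features, induction %.1f-%.1f%%\n",
              nrow(x$meta), ncol(x$values), min(x$meta$induction),
              max(x$meta$induction)))
  invisible(x)
}

# subset a cpa_profiles by row index or rowname
subset_profiles <- function(profiles, idx) {
  structure(list(meta = profiles$meta[idx, , drop = FALSE],
                 values = profiles$values[idx, , drop = FALSE],
                 z_star = profiles$z_star),
            class = "cpa_profiles")
}

#' Cross-similarity matrix between two profile sets
#'
#' All pairwise biosimilarities between the rows of two profile sets.
#'
#' @param setA,setB `cpa_profiles` objects (or numeric matrices with row
#'   names).
#' @return A `BiosimilarityMatrix`: numeric matrix of percentages with the
#'   profile ids as dimnames and attribute `same_set` when A and B are the
#'   same set of ids.
#' @export
cross_similarity <- function(setA, setB = setA) {
  A <- if (inherits(setA, "cpa_profiles")) setA$values else as.matrix(setA)
  B <- if (inherits(setB, "cpa_profiles")) setB$values else as.matrix(setB)
  if (nrow(A) == 0L || nrow(B) == 0L) stopf("empty profile set")
  m <- matrix(NA_real_, nrow(A), nrow(B),
              dimnames = list(rownames(A), rownames(B)))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      m[i, j] <- biosimilarity(A[i, ], B[j, ])
    }
  }
  same <- identical(rownames(A), rownames(B)) && nrow(A) == nrow(B)
  structure(m, same_set = same, class = c("BiosimilarityMatrix",
                                          "matrix", "array"))
}

#' Median biosimilarity percentage (MBP)
#'
#' The summary statistic of a cross-similarity comparison. In `"within"`
#' mode (a square self-comparison) the median is taken over the
#' off-diagonal cells, excluding self-pairs; in `"between"` mode over all
#' cells.
#'
#' @param m a [cross_similarity()] matrix.
#' @param mode `"within"` or `"between"`.
#' @return MBP percent.
#' @export
mbp <- function(m, mode = c("between", "within")) {
  mode <- match.arg(mode)
  m <- unclass(m)
  if (mode == "within") {
    if (nrow(m) != ncol(m)) stopf("within-mode MBP requires a square matrix")
    vals <- m[upper.tri(m)]
  } else {
    vals <- as.vector(m)
  }
  if (!length(vals)) stopf("no eligible cells for MBP")
  median(vals)
}
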