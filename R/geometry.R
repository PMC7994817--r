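#' Generate a 3D conformer
#'
#' Embeds a molecule in 3D using OpenBabel's rule-based builder followed by
#' force-field cleanup (the `gen3D` operation). The builder is
#' deterministic, so repeated calls yield identical coordinates; the `seed`
#' and `n_conformers` arguments are validated and recorded as provenance.
#'
#' @param smiles a single SMILES string (or an `AnnotatedCompound` row's
#'   `smiles` value).
#' @param n_conformers requested conformer count (must be >= 1); recorded in
#'   provenance.
#' @param seed integer seed recorded in provenance.
#' @return An object of class `Geometry`: list with `coords` (n x 3 matrix,
#'   Angstrom), `elements`, `masses` (amu), and `provenance`.
#' @export
embed_conformer <- function(smiles, n_conformers = 10L, seed = 1L) {
  if (!is_string(smiles)) stopf("smiles must be a single string")
  if (!is.numeric(n_conformers) || n_conformers < 1) {
    stopf("n_conformers must be >= 1")
  }
  txt <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "SDF", paste0(smiles, "\n"),
      options = data.frame(names = "gen3D", args = "")
    )),
    error = function(e) ""
  )
  if (!nzchar(txt)) stopf("3D embedding failed for '%s'", smiles)
  sdfset <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(textConnection(txt)))
  ab <- ChemmineR::atomblock(sdfset[[1]])
  coords <- unname(ab[, 1:3, drop = FALSE])
  elements <- sub("_.*$", "", rownames(ab))
  if (nrow(coords) < 1L || !all(is.finite(coords))) {
    stopf("3D embedding produced invalid coordinates for '%s'", smiles)
  }
  geometry(coords, elements,
           provenance = list(method = "openbabel gen3D",
                             n_conformers = as.integer(n_conformers),
                             seed = as.integer(seed)))
}

#' Construct a Geometry from coordinates
#'
#' @param coords numeric n x 3 matrix of coordinates (Angstrom).
#' @param elements character vector of element symbols (used to look up
#'   standard atomic masses), or `NULL` to use `masses`.
#' @param masses numeric vector of atomic masses (amu); overrides the
#'   element lookup when given.
#' @param provenance free-form list recorded with the geometry.
#' @return A `Geometry` object.
#' @export
geometry <- function(coords, elements = NULL, masses = NULL,
                     provenance = list()) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stopf("coords must be an n x 3 matrix")
  if (nrow(coords) < 1L) stopf("geometry needs at least one atom")
  if (!all(is.finite(coords))) stopf("coordinates must be finite")
  if (is.null(masses)) {
    if (is.null(elements)) stopf("either elements or masses must be given")
    masses <- .atomic_mass[elements]
    if (anyNA(masses)) {
      stopf("no mass for element(s): %s",
            paste(unique(elements[is.na(masses)]), collapse = ", "))
    }
  }
  if (length(masses) != nrow(coords)) stopf("one mass per atom required")
  structure(list(coords = coords, elements = elements,
                 masses = unname(masses), provenance = provenance),
            class = "Geometry")
}

#' Principal moments of inertia
#'
#' Eigenvalues of the (by default mass-weighted) inertia tensor about the
#' center of mass, sorted ascending. The three moments satisfy
#' `0 <= I1 <= I2 <= I3` and the inertia "triangle" inequality
#' `I3 <= I1 + I2`.
#'
#' @param g a [geometry()] (at least two atoms, not all coincident).
#' @param mass_weighted if `FALSE`, unit masses are used instead of atomic
#'   masses (both conventions appear in shape analyses; mass-weighted is the
#'   default).
#' @return An object of class `PrincipalMoments`: numeric vector
#'   `c(I1, I2, I3)` in amu Angstrom^2.
#' @export
principal_moments <- function(g, mass_weighted = TRUE) {
  stopifnot(inherits(g, "Geometry"))
  x <- g$coords
  if (nrow(x) < 2L) stopf("principal moments need at least 2 atoms")
  m <- if (mass_weighted) g$masses else rep(1, nrow(x))
  com <- colSums(x * m) / sum(m)
  x <- sweep(x, 2, com)
  if (max(abs(x)) < 1e-12) stopf("all atoms coincident")
  # inertia tensor I = sum_i m_i (|r|^2 E - r r^T)
  r2 <- rowSums(x^2)
  I <- diag(sum(m * r2), 3) - crossprod(x * sqrt(m))
  ev <- sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
  ev <- pmax(ev, 0)
  structure(ev, class = "PrincipalMoments")
}

#' Normalized principal moment ratios
#'
#' Maps principal moments to the rod-disk-sphere shape triangle:
#' `npr1 = I1/I3`, `npr2 = I2/I3`. A rod lies at (0, 1), a disk at
#' (0.5, 0.5), a sphere at (1, 1); every molecule satisfies
#' `npr1 + npr2 >= 1`.
#'
#' @param pm a [principal_moments()] result.
#' @return named numeric vector `c(npr1 = , npr2 = )`.
#' @export
npr <- function(pm) {
  stopifnot(inherits(pm, "PrincipalMoments"))
  if (pm[3] <= 0) stopf("largest principal moment is zero")
  c(npr1 = pm[[1]] / pm[[3]], npr2 = pm[[2]] / pm[[3]])
}
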