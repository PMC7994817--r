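# Rotatable bonds: single, acyclic bonds between two non-terminal heavy
# atoms (the simple rotor definition; amide bonds are not excluded).
count_rotatable_bonds <- function(g) {
  if (nrow(g$bonds) == 0L) return(0L)
  rot <- g$bonds$order == 1L & !g$ring_bonds &
    g$degree[g$bonds$a] > 1L & g$degree[g$bonds$b] > 1L
  sum(rot)
}

# Bridgehead atoms: for every pair of SSSR rings sharing at least two
# bonds (a bridged, not merely fused, system), the shared-path endpoints --
# atoms of the intersection carrying >= 3 ring bonds.
count_bridgeheads <- function(sdf, g = mol_graph(sdf)) {
  rr <- sssr_rings(sdf, g)
  rings <- rr$rings
  if (length(rings) < 2L) return(0L)
  ring_bond_sets <- lapply(rings, function(atoms) {
    m <- length(atoms)
    paste(pmin(atoms, atoms[c(2:m, 1)]), pmax(atoms, atoms[c(2:m, 1)]))
  })
  n_ring_bonds <- integer(g$n)
  for (k in which(g$ring_bonds)) {
    n_ring_bonds[g$bonds$a[k]] <- n_ring_bonds[g$bonds$a[k]] + 1L
    n_ring_bonds[g$bonds$b[k]] <- n_ring_bonds[g$bonds$b[k]] + 1L
  }
  bridge <- logical(g$n)
  for (i in seq_along(rings)[-length(rings)]) {
    for (j in (i + 1L):length(rings)) {
      if (length(intersect(ring_bond_sets[[i]], ring_bond_sets[[j]])) >= 2L) {
        shared <- intersect(rings[[i]], rings[[j]])
        bridge[shared[n_ring_bonds[shared] >= 3L]] <- TRUE
      }
    }
  }
  sum(bridge)
}

# Fraction of sp3 carbons among all carbons (0 when the molecule has no
# carbon atoms).
fraction_sp3 <- function(g) {
  carbons <- which(g$elements == "C")
  if (!length(carbons)) return(0)
  sp3 <- vapply(carbons, function(i) {
    ks <- g$adj[[i]]
    length(ks) == 0L || all(g$bonds$order[ks] == 1L)
  }, logical(1))
  mean(sp3)
}

#' The 17-descriptor vector of a molecule
#'
#' Computes the seventeen molecular descriptors used for the collection
#' PCA: number of heavy atoms, molecular weight, number of rings, aromatic
#' rings, aliphatic rings, hydrogen-bond donors, hydrogen-bond acceptors,
#' SLogP, topological polar surface area, rotatable bonds, oxygen count,
#' nitrogen count, halogen count, bridgehead atoms, fraction sp3, Lipinski
#' rule-of-five violations (MW > 500, logP > 5, HBD > 5, N+O > 10) and
#' Veber violations (rotatable bonds > 10, TPSA > 140).
#'
#' logP and TPSA come from OpenBabel's standard atom-contribution models
#' (Wildman-Crippen-type SLogP and Ertl TPSA); the remaining counts are
#' derived from the connection table.
#'
#' @param smiles single SMILES string.
#' @return named numeric vector of length 17.
#' @export
descriptors17 <- function(smiles) {
  sdfset <- ChemmineR::smiles2sdf(setNames(smiles, "d"))
  props <- ChemmineR::propOB(sdfset)
  g <- mol_graph(sdfset[[1]])
  rr <- sssr_rings(sdfset[[1]], g)

  mw <- props$MW[1]
  logp <- props$logP[1]
  tpsa <- props$TPSA[1]
  hbd <- props$HBD[1]
  hba <- props$HBA1[1]
  rotb <- count_rotatable_bonds(g)
  n_o <- sum(g$elements == "O")
  n_n <- sum(g$elements == "N")
  lipinski <- sum(mw > 500, logp > 5, hbd > 5, (n_o + n_n) > 10)
  veber <- sum(rotb > 10, tpsa > 140)

  c(
    heavy_atoms = g$n,
    molecular_weight = mw,
    rings = n_rings(g),
    aromatic_rings = sum(rr$aromatic),
    aliphatic_rings = length(rr$aromatic) - sum(rr$aromatic),
    hbd = hbd,
    hba = hba,
    slogp = logp,
    tpsa = tpsa,
    rotatable_bonds = rotb,
    o_count = n_o,
    n_count = n_n,
    halogen_count = sum(g$elements %in% c("F", "Cl", "Br", "I")),
    bridgehead_atoms = count_bridgeheads(sdfset[[1]], g),
    fraction_sp3 = fraction_sp3(g),
    lipinski_violations = lipinski,
    veber_violations = veber
  )
}

#' Principal component analysis of descriptor vectors
#'
#' Standardizes the descriptor matrix (zero mean, unit variance per
#' column), drops constant columns with a warning, and decomposes with
#' [stats::prcomp()].
#'
#' @param x numeric matrix (items x descriptors), e.g. rows of
#'   [descriptors17()].
#' @param k number of components to keep.
#' @return An object of class `PCAResult`: list with `scores` (items x k),
#'   `loadings` (descriptors x k), `explained_variance` (fractions, length
#'   k) and `dropped` (names of constant columns).
#' @export
descriptor_pca <- function(x, k = 2L) {
  x <- as.matrix(x)
  if (nrow(x) < k + 1L) stopf("need at least k + 1 = %d items", k + 1L)
  sds <- apply(x, 2, sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    warnf("dropping constant descriptor column(s): %s",
          paste(dropped, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) < 1L) stopf("no non-constant descriptors left")
  k <- min(k, ncol(x))
  p <- prcomp(x, center = TRUE, scale. = TRUE)
  evf <- p$sdev^2 / sum(p$sdev^2)
  structure(
    list(
      scores = p$x[, seq_len(k), drop = FALSE],
      loadings = p$rotation[, seq_len(k), drop = FALSE],
      explained_variance = evf[seq_len(k)],
      dropped = dropped
    ),
    class = "PCAResult"
  )
}
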