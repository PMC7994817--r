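# Internal molecular-graph model built from ChemmineR SDF records.
#
# The chemistry modules need a light connection-table view of each molecule:
# elements, bond orders, implicit hydrogen counts, and ring membership.
# Structures are parsed and canonicalized by OpenBabel (via ChemmineOB);
# this file only re-expresses the resulting SDF as plain vectors/matrices.

# Default valences used for implicit-hydrogen assignment. Hypervalent cases
# (sulfones, phosphates) fall out naturally through the max(0, .) floor.
# Formal charges are not modelled; see the methods vignette for scope.
.default_valence <- c(
  B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1, Se = 2, As = 3, H = 1
)

.atomic_number <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
  Cl = 17, Se = 34, Br = 35, I = 53, As = 33
)

# Standard atomic weights (amu), 2021 IUPAC abridged values.
.atomic_mass <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Se = 78.971,
  Br = 79.904, I = 126.904, As = 74.922
)

# Build the internal graph for one molecule.
# sdf: a ChemmineR SDF object (single molecule). Returns a list with
# elements, implicit H counts, a bond table, adjacency lists, and ring flags.
mol_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  n <- length(elements)
  if (n < 1L) stopf("molecule has no atoms")

  if (is.null(bb) || length(bb) == 0L || is.null(dim(bb)) ||
      nrow(bb) == 0L || ncol(bb) < 3L) {
    bonds <- data.frame(a = integer(0), b = integer(0), order = integer(0))
  } else {
    bonds <- data.frame(
      a = as.integer(bb[, 1]), b = as.integer(bb[, 2]),
      order = as.integer(bb[, 3])
    )
  }

  # drop explicit hydrogens: heavy-atom graph with implicit H counts
  heavy <- which(elements != "H")
  idx_map <- match(seq_len(n), heavy)  # old -> new index (NA for H)
  nH_explicit <- integer(length(heavy))
  keep <- logical(nrow(bonds))
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a[k]; b <- bonds$b[k]
    ha <- elements[a] != "H"; hb <- elements[b] != "H"
    if (ha && hb) {
      keep[k] <- TRUE
    } else if (ha && !hb) {
      nH_explicit[idx_map[a]] <- nH_explicit[idx_map[a]] + 1L
    } else if (!ha && hb) {
      nH_explicit[idx_map[b]] <- nH_explicit[idx_map[b]] + 1L
    }
  }
  bonds <- bonds[keep, , drop = FALSE]
  bonds$a <- idx_map[bonds$a]
  bonds$b <- idx_map[bonds$b]
  elements <- elements[heavy]
  n <- length(elements)

  bond_sum <- numeric(n)
  degree <- integer(n)
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a[k]; b <- bonds$b[k]; o <- bonds$order[k]
    bond_sum[a] <- bond_sum[a] + o
    bond_sum[b] <- bond_sum[b] + o
    degree[a] <- degree[a] + 1L
    degree[b] <- degree[b] + 1L
    adj[[a]] <- c(adj[[a]], k)
    adj[[b]] <- c(adj[[b]], k)
  }

  val <- .default_valence[elements]
  val[is.na(val)] <- 0
  nH <- pmax(0L, as.integer(val - bond_sum - nH_explicit)) + nH_explicit

  # ring membership through biconnected components (any component with more
  # edges than a single bridge is a cycle)
  ring_atoms <- logical(n)
  ring_bonds <- logical(nrow(bonds))
  if (nrow(bonds) > 0L) {
    g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("a", "b")]),
                                     directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    bc <- igraph::biconnected_components(g)
    for (comp in bc$component_edges) {
      if (length(comp) > 1L) {
        ring_bonds[as.integer(comp)] <- TRUE
      }
    }
    ring_atoms[unique(c(bonds$a[ring_bonds], bonds$b[ring_bonds]))] <- TRUE
  }

  list(
    elements = elements, n = n, bonds = bonds, adj = adj,
    degree = degree, bond_sum = bond_sum, nH = nH,
    ring_atoms = ring_atoms, ring_bonds = ring_bonds
  )
}

# Number of rings in the sense of the cyclomatic number (SSSR size).
n_rings <- function(g) {
  if (nrow(g$bonds) == 0L) return(0L)
  ig <- igraph::graph_from_edgelist(as.matrix(g$bonds[, c("a", "b")]),
                                    directed = FALSE)
  if (igraph::vcount(ig) < g$n) ig <- igraph::add_vertices(ig, g$n - igraph::vcount(ig))
  ncomp <- igraph::components(ig)$no
  as.integer(nrow(g$bonds) - g$n + ncomp)
}

# Smallest set of smallest rings: ChemmineR enumerates rings; we keep a
# GF(2)-independent subset of ascending size, up to the cyclomatic number.
# Returns list(rings = list of atom-index vectors, aromatic = logical).
sssr_rings <- function(sdf, g = mol_graph(sdf)) {
  target <- n_rings(g)
  if (target == 0L) return(list(rings = list(), aromatic = logical(0)))
  rr <- ChemmineR::rings(sdf, type = "all", arom = TRUE)
  ring_names <- rr$RINGS
  arom <- rr$AROMATIC
  # ring atoms are given as e.g. "C_3"; positions index the full atom block
  # (which equals the heavy-atom graph when no explicit H are present)
  ab_names <- rownames(ChemmineR::atomblock(sdf))
  heavy_names <- ab_names[sub("_.*$", "", ab_names) != "H"]
  to_idx <- function(at) match(at, heavy_names)

  sizes <- vapply(ring_names, length, integer(1))
  ord <- order(sizes)
  bond_key <- paste(pmin(g$bonds$a, g$bonds$b), pmax(g$bonds$a, g$bonds$b))

  ring_vec <- function(atoms) {
    # incidence vector over bonds for the ring cycle
    m <- length(atoms)
    a <- atoms
    b <- atoms[c(2:m, 1)]
    keys <- paste(pmin(a, b), pmax(a, b))
    v <- logical(nrow(g$bonds))
    v[match(keys, bond_key)] <- TRUE
    v
  }

  basis <- list()
  chosen <- integer(0)
  for (i in ord) {
    atoms <- to_idx(ring_names[[i]])
    if (anyNA(atoms)) next
    v <- ring_vec(atoms)
    # GF(2) elimination against current basis
    w <- v
    for (bvec in basis) {
      piv <- which(bvec)[1]
      if (w[piv]) w <- xor(w, bvec)
    }
    if (any(w)) {
      basis[[length(basis) + 1L]] <- w
      chosen <- c(chosen, i)
      if (length(chosen) == target) break
    }
  }
  list(
    rings = lapply(ring_names[chosen], to_idx),
    aromatic = unname(arom[chosen])
  )
}

# Canonicalize a vector of SMILES via OpenBabel. Returns a character vector
# with NA for strings that do not parse.
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n"))),
      error = function(e) ""
    )
    out <- strsplit(out, "[\t\n ]")[[1]][1]
    if (is.na(out) || !nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

# Parse SMILES into a ChemmineR SDFset (2D, no coordinates needed).
# Invalid entries yield NULL slots.
smiles_to_sdf <- function(smiles, ids = names(smiles)) {
  out <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    sdf <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(smiles[i])),
      error = function(e) NULL
    )
    if (!is.null(sdf) && length(sdf) == 1L &&
        nrow(ChemmineR::atomblock(sdf[[1]])) > 0L) {
      out[[i]] <- sdf[[1]]
    }
  }
  names(out) <- ids
  out
}
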