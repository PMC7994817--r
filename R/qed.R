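#' Published desirability parameters for QED
#'
#' The asymmetric-double-sigmoid (ADS) parameter sets fitted for the eight
#' physicochemical properties of the quantitative estimate of drug-likeness
#' (QED): molecular weight (MW), calculated logP (ALOGP), hydrogen-bond
#' acceptors (HBA) and donors (HBD), polar surface area (PSA), rotatable
#' bonds (ROTB), aromatic rings (AROM) and structural alerts (ALERTS).
#' Each row holds the ADS coefficients `a..f` and the normalization maximum
#' `dmax`.
#'
#' @return data.frame with one row per property.
#' @export
qed_params <- function() {
  data.frame(
    property = c("MW", "ALOGP", "HBA", "HBD", "PSA", "ROTB", "AROM", "ALERTS"),
    a = c(2.817065973, 3.172690585, 2.948620388, 1.618662227, 1.876861559,
          0.01, 3.21778897, 0.01),
    b = c(392.5754953, 137.8624751, 160.4605972, 1010.051101, 125.2232657,
          272.4121427, 957.7374108, 1199.094025),
    c = c(290.7489764, 2.534937431, 3.615294657, 0.985094388, 62.90773554,
          2.55837997, 2.274627939, -0.09002883),
    d = c(2.419764353, 4.581497897, 4.435986202, 1e-09, 87.83366614,
          1.565547684, 1e-09, 1e-09),
    e = c(49.22325677, 0.822739154, 0.290141953, 0.713820843, 12.01999824,
          1.271567166, 1.317690384, 0.185904477),
    f = c(65.37051707, 0.576295591, 1.300669958, 0.920922555, 28.51324732,
          2.758063707, 0.375760881, 0.875193782),
    dmax = c(104.9805561, 131.3186604, 148.7763046, 258.1632616, 104.5686167,
             105.4420403, 312.337261, 417.725314),
    stringsAsFactors = FALSE
  )
}

# asymmetric double sigmoid desirability, normalized to its maximum
ads <- function(x, p) {
  raw <- p$a + p$b /
    (1 + exp(-(x - p$c + p$d / 2) / p$e)) *
    (1 - 1 / (1 + exp(-(x - p$c - p$d / 2) / p$f)))
  raw / p$dmax
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' Maps the eight QED properties through their ADS desirability functions
#' and aggregates them as the exponential of the weighted mean of log
#' desirabilities (a weighted geometric mean). Desirabilities are floored at
#' `1e-6` before taking logs. With unit weights (the default, the
#' "unweighted" QED variant) and all desirabilities equal to `d`, the score
#' is `d`.
#'
#' @param properties named numeric vector or list with elements `MW`,
#'   `ALOGP`, `HBA`, `HBD`, `PSA`, `ROTB`, `AROM`, `ALERTS`.
#' @param weights named numeric vector of non-negative per-property weights;
#'   default all 1.
#' @param params ADS parameter table as returned by [qed_params()].
#' @return QED score in (0, 1].
#' @export
qed <- function(properties, weights = NULL, params = qed_params()) {
  need <- params$property
  properties <- unlist(properties)
  missing_p <- setdiff(need, names(properties))
  if (length(missing_p)) {
    stopf("missing QED propert%s: %s",
          if (length(missing_p) > 1) "ies" else "y",
          paste(missing_p, collapse = ", "))
  }
  if (is.null(weights)) weights <- setNames(rep(1, length(need)), need)
  w <- weights[need]
  if (anyNA(w) || any(w < 0) || sum(w) <= 0) {
    stopf("weights must be non-negative, named after the 8 properties")
  }
  d <- vapply(seq_along(need), function(i) {
    ads(properties[[need[i]]], params[i, ])
  }, numeric(1))
  d <- pmax(d, 1e-6)
  exp(sum(w * log(d)) / sum(w))
}

# Compact structural-alert SMARTS set used for the ALERTS property.
# A curated list of classic reactive/promiscuous motifs; users may supply
# their own SMARTS. Each matching pattern contributes one alert.
.alert_smarts <- c(
  nitro            = "[N+](=O)[O-]",
  nitro_neutral    = "N(=O)=O",
  aldehyde         = "[CX3H1]=O",
  acyl_halide      = "C(=O)[F,Cl,Br,I]",
  anhydride        = "C(=O)OC(=O)",
  peroxide         = "[OX2][OX2]",
  thiol            = "[SX2H]",
  azo              = "N=N",
  azide            = "N=[N+]=[N-]",
  isocyanate       = "N=C=O",
  michael_acceptor = "C=CC(=O)[C,O]",
  alkyl_halide     = "[CX4][Br,I]",
  hydrazine        = "[NX3][NX3]",
  imine            = "[CX3]=[NX2][!O]",
  quaternary_n     = "[N+X4]",
  phosphorus       = "[P]"
)

#' Compute the eight QED properties of a molecule
#'
#' MW, logP, HBA, HBD and TPSA come from OpenBabel's descriptor models;
#' rotatable bonds, aromatic ring count and structural alerts are computed
#' from the connection table (alerts by SMARTS matching against a compact,
#' user-extensible alert list).
#'
#' @param smiles single SMILES string.
#' @param alerts character vector of alert SMARTS patterns; each pattern
#'   with at least one match counts one alert.
#' @return named numeric vector with the 8 QED properties.
#' @export
qed_properties <- function(smiles, alerts = .alert_smarts) {
  sdfset <- ChemmineR::smiles2sdf(setNames(smiles, "q"))
  props <- ChemmineR::propOB(sdfset)
  g <- mol_graph(sdfset[[1]])
  rr <- sssr_rings(sdfset[[1]], g)
  n_alerts <- 0L
  for (sm in alerts) {
    hit <- tryCatch(
      suppressWarnings(ChemmineR::smartsSearchOB(sdfset, sm)),
      error = function(e) 0L
    )
    if (any(hit > 0)) n_alerts <- n_alerts + 1L
  }
  c(
    MW = props$MW[1],
    ALOGP = props$logP[1],
    HBA = props$HBA1[1],
    HBD = props$HBD[1],
    PSA = props$TPSA[1],
    ROTB = count_rotatable_bonds(g),
    AROM = sum(rr$aromatic),
    ALERTS = n_alerts
  )
}
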