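#' Configuration for synthetic cell-painting assays
#'
#' Describes a generative model for synthetic plates with known ground
#' truth. Each fragment has a signature vector drawn once from a seeded
#' standard normal (scaled by `scale`, optionally sparsified) and a
#' dominance weight `weight`; each subclass is a fragment combination with a
#' pair-interaction signature scaled by `gamma`. The true mean profile of a
#' compound in subclass `s` with fragments (f1, f2) is
#'
#' `mu = potency * (w_f1 s_f1 + w_f2 s_f2 + gamma s_pair) + jitter`
#'
#' where the per-compound jitter is a low-rank combination of
#' `jitter_rank` shared variability directions (coefficient SD
#' `jitter_sd`), emulating the correlated biological variability of real
#' morphological profiles. A well's raw value is
#' `baseline + mu * conc_mult + N(0, noise_sd)`; DMSO control wells are
#' `baseline + N(0, noise_sd)`. All unassigned wells of each plate are DMSO
#' controls.
#'
#' @param F feature count (default 579).
#' @param fragments named list; each element a list with `scale`
#'   (signature SD), `weight` (dominance weight), and optional `sparsity`
#'   (fraction of nonzero signature features, default 1).
#' @param subclasses named list; each element a list with `fragments`
#'   (character vector of 1 or 2 fragment tags), `n` (compound count),
#'   optional `gamma` (pair-interaction scale, default 0), `jitter_sd`
#'   (default 0.5), `potency` (length-2 range of per-compound signal
#'   multipliers, spread linearly over the subclass, default `c(1, 1)`),
#'   and `class_label` (defaults to the subclass name).
#' @param concentrations treatment concentrations in uM.
#' @param conc_mult named per-concentration signal multipliers (default 1
#'   at every concentration).
#' @param replicates replicate plate sets (default 3).
#' @param wells_per_plate plate capacity (default 384).
#' @param min_dmso minimum DMSO wells per plate (default 8).
#' @param noise_sd well-level Gaussian noise SD (default 1).
#' @param baseline_sd SD of the per-feature baseline drawn once (default 1).
#' @param jitter_rank number of shared jitter directions (default 8).
#' @param z_star induction significance threshold used for expected
#'   inductions (default 3).
#' @param planted optional named character vector of planted per-fragment
#'   dominance labels (ground-truth bookkeeping).
#' @param seed RNG seed; a fixed seed makes [simulate_assay()] output
#'   byte-identical.
#' @return An object of class `SimConfig` (a validated list).
#' @export
sim_config <- function(F = 579L, fragments, subclasses,
                       concentrations = 10, conc_mult = NULL,
                       replicates = 3L, wells_per_plate = 384L,
                       min_dmso = 8L, noise_sd = 1, baseline_sd = 1,
                       jitter_rank = 8L, z_star = 3, planted = NULL,
                       seed = 1L) {
  if (F < 2L) stopf("F must be >= 2")
  if (replicates < 1L) stopf("replicates must be >= 1")
  if (noise_sd <= 0) stopf("noise_sd must be positive")
  stopifnot(is.list(fragments), length(fragments) > 0,
            !is.null(names(fragments)))
  stopifnot(is.list(subclasses), length(subclasses) > 0,
            !is.null(names(subclasses)))
  for (fn in names(fragments)) {
    fr <- fragments[[fn]]
    fragments[[fn]]$sparsity <- fr$sparsity %||% 1
    if ((fr$weight %||% 1) < 0) stopf("fragment weights must be >= 0")
  }
  for (sn in names(subclasses)) {
    sc <- subclasses[[sn]]
    if (!all(sc$fragments %in% names(fragments))) {
      stopf("subclass '%s' references unknown fragment(s)", sn)
    }
    if (!(length(sc$fragments) %in% c(1L, 2L))) {
      stopf("subclass '%s' must combine 1 or 2 fragments", sn)
    }
    subclasses[[sn]]$gamma <- sc$gamma %||% 0
    subclasses[[sn]]$jitter_sd <- sc$jitter_sd %||% 0.5
    subclasses[[sn]]$potency <- sc$potency %||% c(1, 1)
    subclasses[[sn]]$class_label <- sc$class_label %||% sn
  }
  if (is.null(conc_mult)) {
    conc_mult <- setNames(rep(1, length(concentrations)),
                          as.character(concentrations))
  }
  structure(
    list(F = as.integer(F), fragments = fragments, subclasses = subclasses,
         concentrations = concentrations, conc_mult = conc_mult,
         replicates = as.integer(replicates),
         wells_per_plate = as.integer(wells_per_plate),
         min_dmso = as.integer(min_dmso), noise_sd = noise_sd,
         baseline_sd = baseline_sd, jitter_rank = as.integer(jitter_rank),
         z_star = z_star, planted = planted, seed = as.integer(seed)),
    class = "SimConfig"
  )
}

#' Simulate a synthetic cell-painting assay
#'
#' Draws fragment and pair signatures, compound mean profiles and plates of
#' well-level raw feature values according to a [sim_config()], together
#' with the ground truth (true mean profiles, expected single-well
#' inductions under the robust-z null, planted dominance labels).
#'
#' Each replicate is laid out on as many plates as needed, with the
#' compound-to-well assignment rotated between replicates (shifted
#' layouts); all remaining wells are DMSO controls.
#'
#' @param cfg a [sim_config()].
#' @return list with `plates` (list of [plate_data()]), `truth` (class
#'   `GroundTruth`) and `annotations` (data.frame compound_id, class_label,
#'   subclass_label, fragments).
#' @export
simulate_assay <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  F <- cfg$F
  baseline <- rnorm(F, sd = cfg$baseline_sd)

  signatures <- lapply(cfg$fragments, function(fr) {
    s <- rnorm(F) * (fr$scale %||% 1)
    mask <- runif(F) < (fr$sparsity %||% 1)
    s * mask
  })
  pair_signatures <- lapply(cfg$subclasses, function(sc) {
    s <- rnorm(F)  # drawn for every subclass to keep the stream aligned
    if (length(sc$fragments) == 2L && sc$gamma != 0) s else numeric(F)
  })
  V <- matrix(rnorm(cfg$jitter_rank * F), cfg$jitter_rank, F)

  # compound mean profiles
  ann <- list()
  mu <- list()
  for (sn in names(cfg$subclasses)) {
    sc <- cfg$subclasses[[sn]]
    w_sum <- Reduce(`+`, lapply(sc$fragments, function(fn) {
      (cfg$fragments[[fn]]$weight %||% 1) * signatures[[fn]]
    }))
    base_sig <- w_sum + sc$gamma * pair_signatures[[sn]]
    potency <- if (sc$n == 1L) mean(sc$potency) else
      seq(sc$potency[1], sc$potency[2], length.out = sc$n)
    coef <- matrix(rnorm(sc$n * cfg$jitter_rank, sd = sc$jitter_sd),
                   sc$n, cfg$jitter_rank)
    for (i in seq_len(sc$n)) {
      cid <- sprintf("%s_%02d", sn, i)
      mu[[cid]] <- potency[i] * base_sig + as.vector(coef[i, ] %*% V)
      ann[[cid]] <- data.frame(
        compound_id = cid, class_label = sc$class_label,
        subclass_label = sn,
        fragments = paste(sc$fragments, collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  }
  mu <- do.call(rbind, mu)
  ann <- do.call(rbind, ann)
  n_cpd <- nrow(mu)

  # expected single-well induction per compound x concentration
  expected <- list()
  for (conc in cfg$concentrations) {
    mult <- cfg$conc_mult[[as.character(conc)]] %||% 1
    lam <- mu * mult / cfg$noise_sd
    e <- 100 * rowMeans(pnorm(-cfg$z_star - lam) + pnorm(-cfg$z_star + lam))
    expected[[length(expected) + 1L]] <- data.frame(
      compound_id = rownames(mu), concentration_uM = conc,
      expected_induction = unname(e), stringsAsFactors = FALSE
    )
  }
  expected <- do.call(rbind, expected)

  # plate layout
  treatments <- expand.grid(
    compound_id = rownames(mu), concentration_uM = cfg$concentrations,
    stringsAsFactors = FALSE
  )
  capacity <- cfg$wells_per_plate - cfg$min_dmso
  if (capacity < 1L) stopf("plate layout leaves no treatment wells")
  n_treat <- nrow(treatments)
  n_plates <- ceiling(n_treat / capacity)

  plates <- list()
  for (rep_i in seq_len(cfg$replicates)) {
    shift <- (rep_i - 1L) * 5L %% n_treat
    ord <- ((seq_len(n_treat) - 1L + shift) %% n_treat) + 1L
    tre <- treatments[ord, , drop = FALSE]
    for (p_i in seq_len(n_plates)) {
      lo <- (p_i - 1L) * capacity + 1L
      hi <- min(p_i * capacity, n_treat)
      tp <- tre[lo:hi, , drop = FALSE]
      n_dmso <- cfg$wells_per_plate - nrow(tp)
      wells <- data.frame(
        well = sprintf("W%03d", seq_len(nrow(tp) + n_dmso)),
        compound_id = c(tp$compound_id, rep("DMSO", n_dmso)),
        concentration_uM = c(tp$concentration_uM, rep(0, n_dmso)),
        stringsAsFactors = FALSE
      )
      feat <- matrix(rnorm(nrow(wells) * F, sd = cfg$noise_sd),
                     nrow(wells), F)
      feat <- sweep(feat, 2, baseline, "+")
      for (k in seq_len(nrow(tp))) {
        mult <- cfg$conc_mult[[as.character(tp$concentration_uM[k])]] %||% 1
        feat[k, ] <- feat[k, ] + mu[tp$compound_id[k], ] * mult
      }
      colnames(feat) <- sprintf("f_%04d", seq_len(F))
      plates[[length(plates) + 1L]] <-
        plate_data(sprintf("R%d_P%d", rep_i, p_i), wells, feat)
    }
  }

  truth <- structure(
    list(baseline = baseline, signatures = signatures,
         pair_signatures = pair_signatures, jitter_directions = V,
         mu = mu, expected_induction = expected,
         dominance = cfg$planted),
    class = "GroundTruth"
  )
  list(plates = plates, truth = truth, annotations = ann, config = cfg)
}

#' Preset simulation scenarios
#'
#' Named [sim_config()]s with planted ground truth, calibrated from the
#' generator's variance model (see the methods vignette):
#'
#' * `dominating_fragment`: two subclasses share a heavily weighted
#'   fragment (weight 4 vs 0.3 partners, small interaction) -- high
#'   cross-subclass MBP, no class clustering in PCA.
#' * `combination_driven`: weak fragment weights, strong pair interactions
#'   -- combination-specific profiles, low cross-subclass MBP and clear
#'   clustering (non-dominating shared fragment).
#' * `inactive_np`: a zero-signature fragment whose own profile is
#'   inactive (< 5% induction) while its combination products are strongly
#'   active, emulating an inactive guiding natural product.
#' * `wide_induction`: one compound series spanning roughly 5-70%
#'   induction through a potency gradient, for the PC1-induction
#'   diagnostic.
#' * `pure_null`: 200 compounds with zero signatures on single-replicate
#'   384-well plates, for null calibration of the induction statistic.
#'
#' @param seed base seed stored in each config.
#' @return named list of `SimConfig` objects.
#' @export
preset_scenarios <- function(seed = 1L) {
  list(
    dominating_fragment = sim_config(
      F = 579L,
      fragments = list(
        dom = list(scale = 1, weight = 4),
        pA  = list(scale = 1, weight = 0.3),
        pB  = list(scale = 1, weight = 0.3)
      ),
      subclasses = list(
        `DOM-A` = list(fragments = c("dom", "pA"), n = 8, gamma = 0.3,
                       jitter_sd = 0.5),
        `DOM-B` = list(fragments = c("dom", "pB"), n = 8, gamma = 0.3,
                       jitter_sd = 0.5)
      ),
      wells_per_plate = 96L, jitter_rank = 8L, noise_sd = 1,
      planted = c(dom = "dominating"), seed = seed
    ),
    combination_driven = sim_config(
      F = 579L,
      fragments = list(
        f1 = list(scale = 1, weight = 0.5),
        f2 = list(scale = 1, weight = 0.5),
        f3 = list(scale = 1, weight = 0.5)
      ),
      subclasses = list(
        `F12` = list(fragments = c("f1", "f2"), n = 8, gamma = 4,
                     jitter_sd = 0.5),
        `F13` = list(fragments = c("f1", "f3"), n = 8, gamma = 4,
                     jitter_sd = 0.5)
      ),
      wells_per_plate = 96L, jitter_rank = 8L, noise_sd = 1,
      planted = c(f1 = "non_dominating"), seed = seed
    ),
    inactive_np = sim_config(
      F = 579L,
      fragments = list(
        sino = list(scale = 0, weight = 1),
        chrA = list(scale = 1, weight = 0.3),
        indA = list(scale = 1, weight = 0.3)
      ),
      subclasses = list(
        `SM`   = list(fragments = "sino", n = 1, jitter_sd = 0),
        `SM-C` = list(fragments = c("sino", "chrA"), n = 6, gamma = 4,
                      jitter_sd = 0.5),
        `SM-I` = list(fragments = c("sino", "indA"), n = 6, gamma = 4,
                      jitter_sd = 0.5)
      ),
      wells_per_plate = 96L, jitter_rank = 8L, noise_sd = 1,
      planted = c(sino = "dominating"), seed = seed
    ),
    wide_induction = sim_config(
      F = 579L,
      fragments = list(core = list(scale = 1, weight = 1)),
      subclasses = list(
        `WIDE` = list(fragments = "core", n = 250, jitter_sd = 0.75,
                      potency = c(0.8, 7.5))
      ),
      wells_per_plate = 384L, jitter_rank = 4L, noise_sd = 1,
      seed = seed
    ),
    pure_null = sim_config(
      F = 579L,
      fragments = list(nullfrag = list(scale = 0, weight = 0)),
      subclasses = list(
        `NULL` = list(fragments = "nullfrag", n = 200, jitter_sd = 0)
      ),
      replicates = 1L, wells_per_plate = 384L, min_dmso = 284L,
      jitter_rank = 2L, noise_sd = 1, seed = seed
    )
  )
}

#' Deterministic toy compound collection
#'
#' A small annotated collection of valid toy molecules covering all roles
#' (PNPs with two fragment tags, guiding NPs, small fragments, a predicted
#' class), three classes with two subclasses each. Intended for exercising
#' the chemical modules without external downloads; the structures are
#' synthetic stand-ins, not the deposited collection.
#'
#' @return a [compound_set()].
#' @export
toy_compound_set <- function() {
  rows <- rbind(
    # class PYR-F: pyridine + furan, two subclasses (regioisomer families)
    c("pf_a1", "c1ccncc1Cc1ccco1",        "PYR-F", "PYR-F-a", "pyridine;furan", "pnp"),
    c("pf_a2", "Cc1ccncc1Cc1ccco1",       "PYR-F", "PYR-F-a", "pyridine;furan", "pnp"),
    c("pf_a3", "c1ccncc1CCc1ccco1",       "PYR-F", "PYR-F-a", "pyridine;furan", "pnp"),
    c("pf_b1", "c1ccncc1-c1ccco1",        "PYR-F", "PYR-F-b", "pyridine;furan", "pnp"),
    c("pf_b2", "Cc1ccc(-c2ccco2)nc1",     "PYR-F", "PYR-F-b", "pyridine;furan", "pnp"),
    c("pf_b3", "c1ccc(-c2ccco2)cn1",      "PYR-F", "PYR-F-b", "pyridine;furan", "pnp"),
    # class PYR-C: pyridine + cyclohexane
    c("pc_a1", "c1ccncc1C1CCCCC1",        "PYR-C", "PYR-C-a", "pyridine;cyclohexane", "pnp"),
    c("pc_a2", "Cc1ccncc1C1CCCCC1",       "PYR-C", "PYR-C-a", "pyridine;cyclohexane", "pnp"),
    c("pc_a3", "c1ccncc1CC1CCCCC1",       "PYR-C", "PYR-C-a", "pyridine;cyclohexane", "pnp"),
    c("pc_b1", "OC1CCCCC1c1ccncc1",       "PYR-C", "PYR-C-b", "pyridine;cyclohexane", "pnp"),
    c("pc_b2", "OC1CCCCC1Cc1ccncc1",      "PYR-C", "PYR-C-b", "pyridine;cyclohexane", "pnp"),
    # class BEN-F: benzene + furan
    c("bf_a1", "c1ccccc1Cc1ccco1",        "BEN-F", "BEN-F-a", "benzene;furan", "pnp"),
    c("bf_a2", "Cc1ccccc1Cc1ccco1",       "BEN-F", "BEN-F-a", "benzene;furan", "pnp"),
    c("bf_b1", "c1ccccc1-c1ccco1",        "BEN-F", "BEN-F-b", "benzene;furan", "pnp"),
    c("bf_b2", "Cc1ccc(-c2ccco2)cc1",     "BEN-F", "BEN-F-b", "benzene;furan", "pnp"),
    # guiding NPs and small fragments
    c("np_pyr", "c1ccncc1",               "NP",    "NP-pyr",  "pyridine", "guiding_np"),
    c("np_ben", "c1ccccc1",               "NP",    "NP-ben",  "benzene",  "guiding_np"),
    c("fr_fur", "c1ccoc1",                "FRAG",  "FR-fur",  "furan",    "small_fragment"),
    c("fr_chx", "C1CCCCC1",               "FRAG",  "FR-chx",  "cyclohexane", "small_fragment"),
    # predicted class: benzene + cyclohexane
    c("bc_p1", "c1ccccc1C1CCCCC1",        "BEN-C", "BEN-C-p", "benzene;cyclohexane", "predicted_class"),
    c("bc_p2", "Cc1ccccc1C1CCCCC1",       "BEN-C", "BEN-C-p", "benzene;cyclohexane", "predicted_class")
  )
  df <- as.data.frame(rows, stringsAsFactors = FALSE)
  names(df) <- c("id", "smiles", "class_label", "subclass_label",
                 "fragments", "role")
  compound_set(df, provenance = "toy_compound_set()")
}
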