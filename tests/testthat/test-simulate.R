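small_cfg <- function(seed = 1, ...) {
  sim_config(
    F = 60L,
    fragments = list(fa = list(scale = 1, weight = 1),
                     fb = list(scale = 1, weight = 0)),
    subclasses = list(S1 = list(fragments = c("fa", "fb"), n = 3,
                                jitter_sd = 0)),
    replicates = 2L, wells_per_plate = 24L, jitter_rank = 2L,
    noise_sd = 1, seed = seed, ...
  )
}

test_that("a fixed seed reproduces the assay byte-for-byte", {
  s1 <- simulate_assay(small_cfg(seed = 5))
  s2 <- simulate_assay(small_cfg(seed = 5))
  expect_identical(s1$plates, s2$plates)
  expect_identical(s1$truth$mu, s2$truth$mu)
  s3 <- simulate_assay(small_cfg(seed = 6))
  expect_false(identical(s1$plates, s3$plates))
})

test_that("the noise-free limit yields near-perfect within-fragment biosimilarity", {
  cfg <- sim_config(
    F = 120L,
    fragments = list(fa = list(scale = 1, weight = 1),
                     fb = list(scale = 1, weight = 0)),
    subclasses = list(S1 = list(fragments = c("fa", "fb"), n = 4,
                                jitter_sd = 0)),
    replicates = 1L, wells_per_plate = 48L, jitter_rank = 2L,
    noise_sd = 1e-6, seed = 3
  )
  sim <- simulate_assay(cfg)
  # compounds share the same mean profile exactly; correlate raw wells
  treated <- sim$plates[[1]]$wells$compound_id != "DMSO"
  vals <- sim$plates[[1]]$features[treated, ]
  for (i in 1:3) {
    expect_gt(biosimilarity(vals[i, ], vals[i + 1, ]), 99.9)
  }
})

test_that("zero-signal compounds have the analytic null expected induction", {
  cfg <- sim_config(
    F = 579L,
    fragments = list(fz = list(scale = 0, weight = 0)),
    subclasses = list(S0 = list(fragments = "fz", n = 2, jitter_sd = 0)),
    replicates = 1L, wells_per_plate = 24L, jitter_rank = 2L, seed = 2
  )
  sim <- simulate_assay(cfg)
  expect_equal(sim$truth$expected_induction$expected_induction,
               rep(100 * 2 * pnorm(-3), 2), tolerance = 1e-12)
})

test_that("expected induction is monotone in the potency multiplier", {
  cfg <- sim_config(
    F = 200L,
    fragments = list(fa = list(scale = 1, weight = 1)),
    subclasses = list(S = list(fragments = "fa", n = 10, jitter_sd = 0,
                               potency = c(0.5, 6))),
    replicates = 1L, wells_per_plate = 24L, jitter_rank = 2L, seed = 4
  )
  tr <- simulate_assay(cfg)$truth
  e <- tr$expected_induction$expected_induction
  expect_true(all(diff(e) > 0))
})

test_that("realized per-well induction matches ground truth at high replication", {
  cfg <- sim_config(
    F = 100L,
    fragments = list(fa = list(scale = 1, weight = 2)),
    subclasses = list(S = list(fragments = "fa", n = 2, jitter_sd = 0.3,
                               potency = c(1, 2))),
    replicates = 200L, wells_per_plate = 96L, jitter_rank = 2L, seed = 9
  )
  sim <- simulate_assay(cfg)
  norm <- lapply(sim$plates, normalize_plate)
  # per-well (single replicate) induction, averaged over 200 replicates
  for (cid in rownames(sim$truth$mu)) {
    wells <- unlist(lapply(norm, function(p) {
      sel <- p$wells$compound_id == cid
      if (any(sel)) apply(p$features[sel, , drop = FALSE], 1, induction)
    }))
    expected <- sim$truth$expected_induction$expected_induction[
      sim$truth$expected_induction$compound_id == cid]
    # 100 features x 200 wells of Bernoulli mixtures; allow 3 x MC sd plus
    # the small finite-control normalization bias
    expect_equal(mean(wells), expected, tolerance = 0.08 * expected + 1)
  }
})

test_that("presets cover the documented scenarios with consistent structure", {
  presets <- preset_scenarios(seed = 2)
  expect_setequal(names(presets),
                  c("dominating_fragment", "combination_driven",
                    "inactive_np", "wide_induction", "pure_null"))
  for (p in presets) expect_s3_class(p, "SimConfig")
  expect_equal(presets$dominating_fragment$planted[["dom"]], "dominating")
  expect_equal(presets$combination_driven$planted[["f1"]], "non_dominating")
})

test_that("the inactive-NP scenario separates fragment and PNP activity", {
  sim <- simulate_assay(preset_scenarios(seed = 13)$inactive_np)
  prof <- profiles_from_plates(lapply(sim$plates, normalize_plate))
  ind <- setNames(prof$meta$induction, prof$meta$compound_id)
  expect_lt(ind[["SM_01"]], 5)
  pnps <- grep("^SM-", names(ind), value = TRUE)
  expect_true(all(ind[pnps] > 20))
})

test_that("invalid layouts and configs are rejected", {
  expect_error(sim_config(F = 1L,
                          fragments = list(a = list(scale = 1, weight = 1)),
                          subclasses = list(S = list(fragments = "a", n = 1))),
               "F must")
  expect_error(small_cfg(min_dmso = 30L) |> simulate_assay(),
               "no treatment wells")
  expect_error(sim_config(F = 10L,
                          fragments = list(a = list(scale = 1, weight = 1)),
                          subclasses = list(S = list(fragments = "zz", n = 1))),
               "unknown fragment")
})

test_that("the toy compound collection is valid, rich and deterministic", {
  set1 <- toy_compound_set()
  set2 <- toy_compound_set()
  expect_identical(set1$compounds, set2$compounds)
  expect_equal(nrow(validate_collection(set1)), 0L)
  expect_gte(length(set1), 20L)
  # every PNP class has at least 2 subclasses
  pnp <- set1$compounds[set1$compounds$role == "pnp", ]
  per_class <- tapply(pnp$subclass_label, pnp$class_label,
                      function(x) length(unique(x)))
  expect_true(all(per_class >= 2))
  expect_setequal(unique(set1$compounds$role),
                  c("pnp", "guiding_np", "small_fragment", "predicted_class"))
})
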