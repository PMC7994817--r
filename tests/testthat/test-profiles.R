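profiles_with_inductions <- function(spec, F = 40, seed = 8) {
  # spec: data.frame(compound_id, concentration_uM, induction)
  set.seed(seed)
  values <- matrix(rnorm(nrow(spec) * F), nrow(spec), F)
  rn <- paste0(spec$compound_id, "@", spec$concentration_uM)
  dimnames(values) <- list(rn, sprintf("f_%04d", seq_len(F)))
  meta <- data.frame(spec, n_replicates = 3L, stringsAsFactors = FALSE)
  meta <- meta[, c("compound_id", "concentration_uM", "n_replicates",
                   "induction")]
  rownames(meta) <- rn
  structure(list(meta = meta, values = values, z_star = 3),
            class = "cpa_profiles")
}

test_that("profile selection applies the window and its tie-breaks", {
  spec <- rbind(
    data.frame(compound_id = "a", concentration_uM = c(1, 10, 50),
               induction = c(12, 25, 60)),
    data.frame(compound_id = "b", concentration_uM = 10, induction = 17),
    data.frame(compound_id = "c", concentration_uM = c(3, 30),
               induction = c(22, 38))
  )
  prof <- profiles_with_inductions(spec)
  sel <- select_profiles(prof, window = c(20, 40))
  expect_equal(sel$meta$compound_id, c("a", "c"))
  expect_equal(sel$meta$induction, c(25, 22))  # 22 and 38 tie; lower conc wins
  excl <- attr(sel, "excluded")
  expect_equal(excl$compound_id, "b")
  expect_equal(excl$best_induction, 17)

  # idempotence: selecting from the selection changes nothing
  sel2 <- select_profiles(sel, window = c(20, 40))
  expect_equal(sel2$meta, sel$meta)

  expect_error(select_profiles(prof, window = c(40, 20)), "lo < hi")
  expect_error(select_profiles(
    profiles_with_inductions(
      data.frame(compound_id = "z", concentration_uM = 10, induction = 90)),
    window = c(20, 40)), "no compound")
})

subset_profiles_for_test <- function(p, idx) pnpcpa:::subset_profiles(p, idx)

test_that("profile PCA reports variance order and the PC1-induction diagnostic", {
  # profiles spanning a single signal direction with magnitude = induction
  set.seed(12)
  F <- 60
  sig <- rnorm(F)
  mag <- seq(1, 10, length.out = 8)
  values <- outer(mag, sig) + matrix(rnorm(8 * F, sd = 0.05), 8, F)
  prof <- profiles_with_inductions(
    data.frame(compound_id = letters[1:8], concentration_uM = 10,
               induction = mag * 7))
  prof$values <- values
  p <- profile_pca(prof, k = 3)
  expect_gt(p$explained_variance[1], 0.9)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_gt(p$pc1_induction_r, 0.95)
  expect_error(profile_pca(subset_profiles_for_test(prof, 1:3), k = 3),
               "at least")
})

test_that("duplicated profiles receive identical scores", {
  prof <- profiles_with_inductions(
    data.frame(compound_id = letters[1:5], concentration_uM = 10,
               induction = 25))
  dup <- prof
  dup$values <- rbind(prof$values, prof$values[1, , drop = FALSE])
  dup$meta <- rbind(prof$meta, prof$meta[1, ])
  rownames(dup$values)[6] <- rownames(dup$meta)[6] <- "dup@10"
  p <- profile_pca(dup, k = 3)
  expect_equal(unname(p$scores[1, ]), unname(p$scores[6, ]), tolerance = 1e-10)
})

test_that("cluster separation distinguishes blobs from label noise", {
  set.seed(31)
  blob1 <- matrix(rnorm(60, sd = 0.2), 20, 3)
  blob2 <- sweep(matrix(rnorm(60, sd = 0.2), 20, 3), 2, c(10, 0, 0), "+")
  sep <- cluster_separation(rbind(blob1, blob2), rep(c("A", "B"), each = 20))
  expect_gt(sep$score, 0.9)
  expect_true(sep$clustered)

  # random labels on one blob: no separation
  sep0 <- cluster_separation(blob1, rep(c("A", "B"), 10))
  expect_lt(abs(sep0$score), 0.2)
  expect_false(sep0$clustered)

  expect_warning(
    sep1 <- cluster_separation(rbind(blob1, blob2[1, , drop = FALSE]),
                               c(rep(c("A", "B"), 10), "C")),
    "single member")
  expect_false("C" %in% sep1$labels_used)
  expect_error(cluster_separation(blob1, rep("A", 20)), "2 labels")
})

test_that("the dominance rule reproduces its defining evidence table", {
  expect_equal(pnpcpa:::dominance_rule(86, clustered = FALSE), "dominating")
  expect_equal(pnpcpa:::dominance_rule(45, clustered = TRUE), "non_dominating")
  expect_equal(pnpcpa:::dominance_rule(75, clustered = TRUE),
               "maybe_non_dominating")
  expect_equal(pnpcpa:::dominance_rule(74.5, clustered = FALSE),
               "maybe_non_dominating")
  expect_equal(pnpcpa:::dominance_rule(71, clustered = FALSE),
               "non_dominating")
  expect_equal(pnpcpa:::dominance_rule(80, clustered = TRUE),
               "non_dominating")
  expect_equal(pnpcpa:::dominance_rule(71, clustered = TRUE),
               "non_dominating")
})

test_that("dominance classification recovers planted scenarios and is invariant", {
  presets <- preset_scenarios(seed = 17)
  sim <- simulate_assay(presets$dominating_fragment)
  prof <- profiles_from_plates(lapply(sim$plates, normalize_plate))
  ann <- sim$annotations
  sub <- ann$subclass_label[match(prof$meta$compound_id, ann$compound_id)]
  call <- classify_fragment_dominance(prof, sub, fragment = "dom")
  expect_equal(call$classification, "dominating")
  expect_gt(call$mbp, 75)
  expect_false(call$clustered)

  # invariance to profile ordering and to subclass renaming
  perm <- sample(nrow(prof$meta))
  prof_p <- pnpcpa:::subset_profiles(prof, perm)
  sub_renamed <- setNames(c("S1", "S2"), unique(sub))[sub][perm]
  call_p <- classify_fragment_dominance(prof_p, sub_renamed, fragment = "dom")
  expect_equal(call_p$classification, call$classification)
  expect_equal(call_p$mbp, call$mbp)

  sim2 <- simulate_assay(presets$combination_driven)
  prof2 <- profiles_from_plates(lapply(sim2$plates, normalize_plate))
  ann2 <- sim2$annotations
  sub2 <- ann2$subclass_label[match(prof2$meta$compound_id, ann2$compound_id)]
  call2 <- classify_fragment_dominance(prof2, sub2, fragment = "f1")
  expect_equal(call2$classification, "non_dominating")
  expect_lt(call2$mbp, 75)

  expect_error(classify_fragment_dominance(prof, rep("only", nrow(prof$meta))),
               "2 subclasses")
})

test_that("predicted-class evaluation issues the expected verdicts", {
  set.seed(41)
  F <- 50
  sigA <- rnorm(F); sigB <- rnorm(F)
  mk <- function(sig, n, seed) {
    set.seed(seed)
    p <- toy_profiles(n, F, seed = seed)
    p$values <- outer(rep(4, n), sig) + matrix(rnorm(n * F, sd = 0.6), n, F)
    rownames(p$values) <- rownames(p$meta)
    p
  }
  new_cls <- mk(sigA, 4, 1)
  same_group <- list(grpA1 = mk(sigA, 5, 2), grpA2 = mk(sigA, 5, 3))
  diff_group <- list(grpB1 = mk(sigB, 5, 4))

  rep1 <- evaluate_predicted_class(new_cls, list(fragA = same_group))
  expect_equal(rep1$verdict, "redundant")
  expect_equal(rep1$redundant_with, "fragA")
  expect_gt(rep1$average_mbp[["fragA"]], 75)

  rep2 <- evaluate_predicted_class(new_cls, list(fragB = diff_group))
  expect_equal(rep2$verdict, "unique")
  expect_lt(rep2$average_mbp[["fragB"]], 75)

  # a class of identical profiles compared to itself is maximally redundant
  clone <- new_cls
  clone$values <- clone$values[rep(1, 4), ]
  rownames(clone$values) <- rownames(clone$meta)
  rep3 <- evaluate_predicted_class(clone, list(self = list(s = clone)))
  expect_equal(rep3$average_mbp[["self"]], 100)

  expect_error(evaluate_predicted_class(new_cls, list()), "named list")
  expect_error(evaluate_predicted_class(new_cls, list(empty = list())),
               "empty")
})
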