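make_plate <- function(values, compound_ids, plate = "P1") {
  n <- nrow(values)
  wells <- data.frame(
    well = sprintf("W%03d", seq_len(n)),
    compound_id = compound_ids,
    concentration_uM = ifelse(compound_ids == "DMSO", 0, 10),
    stringsAsFactors = FALSE
  )
  plate_data(plate, wells, values)
}

test_that("robust z-normalization is exact against its defining formula", {
  set.seed(3)
  dmso <- matrix(rnorm(16 * 4, mean = 5, sd = 2), 16, 4)
  med <- apply(dmso, 2, median)
  madv <- apply(dmso, 2, function(v) median(abs(v - median(v))))
  treat <- rbind(med,                      # exactly at the control median
                 med + 1.4826 * madv,      # exactly one robust SD above
                 med - 2 * 1.4826 * madv)
  p <- make_plate(rbind(treat, dmso), c("c1", "c2", "c3", rep("DMSO", 16)))
  z <- normalize_plate(p)$features
  expect_equal(unname(z[1, ]), rep(0, 4))
  expect_equal(unname(z[2, ]), rep(1, 4))
  expect_equal(unname(z[3, ]), rep(-2, 4))
})

test_that("zero-MAD features are flagged and zeroed; low control counts fail", {
  vals <- cbind(rep(1, 12), rnorm(12))
  p <- make_plate(vals, c("c1", rep("DMSO", 11)))
  norm <- normalize_plate(p)
  expect_equal(attr(norm, "flagged"), "f_0001")
  expect_equal(unname(norm$features[, 1]), rep(0, 12))

  p2 <- make_plate(matrix(rnorm(8), 4, 2), c("c1", rep("DMSO", 3)))
  expect_error(normalize_plate(p2), "DMSO")
})

test_that("replicate aggregation is the per-feature median, order-invariant", {
  z <- rbind(c(1, 5), c(2, 6), c(9, 7))
  agg <- aggregate_replicates(z)
  expect_equal(unname(agg$values), c(2, 6))
  expect_equal(agg$n_replicates, 3L)
  expect_equal(aggregate_replicates(z[c(3, 1, 2), ])$values, agg$values)
  single <- aggregate_replicates(z[1, , drop = FALSE])
  expect_equal(unname(single$values), c(1, 5))
})

test_that("induction counts significant features as a percentage", {
  expect_equal(induction(rep(0.5, 100)), 0)
  z <- c(rep(4, 58), rep(0, 521))
  expect_equal(round(induction(z), 2), 10.02)
  expect_equal(induction(c(-3, 3, 0, 0)), 50)  # |z| >= z* is two-sided
  expect_equal(induction(rep(10, 5)), 100)
  expect_error(induction(numeric(0)), "empty")
})

test_that("biosimilarity equals clipped Pearson correlation times 100", {
  a <- c(0.2, -1.5, 3.1, 0.4, -0.9, 2.2)
  b <- c(0.1, -0.8, 2.5, 1.0, -1.2, 1.9)
  expect_equal(biosimilarity(a, b), 100 * pearson_oracle(a, b))
  expect_equal(biosimilarity(a, a), 100)
  expect_equal(biosimilarity(a, -a), 0)
  # Pearson scale/shift invariance
  expect_equal(biosimilarity(a, 2 * a + 5), 100)
  expect_error(biosimilarity(a, b[1:3]), "length")
  expect_error(biosimilarity(rep(1, 6), b), "variance")
})

test_that("cross-similarity matches the exhaustive loop oracle", {
  prof <- toy_profiles(5, 30, seed = 9)
  m <- cross_similarity(prof)
  expect_equal(dim(m), c(5L, 5L))
  expect_equal(unname(diag(m)), rep(100, 5))
  expect_equal(unclass(m), t(unclass(m)), ignore_attr = TRUE)

  A <- toy_profiles(2, 30, seed = 1)
  B <- toy_profiles(3, 30, seed = 2)
  mab <- cross_similarity(A, B)
  expect_equal(dim(mab), c(2L, 3L))
  for (i in 1:2) {
    for (j in 1:3) {
      expect_equal(mab[i, j],
                   100 * max(0, pearson_oracle(A$values[i, ], B$values[j, ])))
    }
  }
})

test_that("MBP takes the correct median in both modes", {
  m <- matrix(c(100, 42, 42, 100), 2, 2)
  class(m) <- c("BiosimilarityMatrix", "matrix", "array")
  expect_equal(mbp(m, "within"), 42)

  mb <- matrix(c(80, 60, 90), 1, 3)
  expect_equal(mbp(mb, "between"), 80)
  expect_error(mbp(mb, "within"), "square")

  # invariant under simultaneous row/column permutation
  prof <- toy_profiles(6, 25, seed = 4)
  m6 <- cross_similarity(prof)
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(mbp(m6[perm, perm], "within"), mbp(m6, "within"))
})

test_that("profiles_from_plates aggregates replicates across plates", {
  set.seed(21)
  F <- 10
  base <- matrix(rnorm(20 * F), 20, F)
  plates <- lapply(1:3, function(r) {
    vals <- rbind(matrix(rnorm(2 * F, sd = 0.1) + 5, 2, F), base)
    make_plate(vals, c("cpdA", "cpdB", rep("DMSO", 20)), plate = paste0("P", r))
  })
  prof <- profiles_from_plates(lapply(plates, normalize_plate))
  expect_equal(nrow(prof$meta), 2L)
  expect_equal(prof$meta$n_replicates, c(3L, 3L))
  expect_true(all(prof$meta$induction > 50))  # strong planted shift
  # aggregation oracle: per-feature median of the three replicate z-rows
  z1 <- normalize_plate(plates[[1]])$features[1, ]
  z2 <- normalize_plate(plates[[2]])$features[1, ]
  z3 <- normalize_plate(plates[[3]])$features[1, ]
  expect_equal(unname(prof$values["cpdA@10", ]),
               unname(apply(rbind(z1, z2, z3), 2, median)))
})

test_that("plate CSV round-trips through the well-level dialect", {
  set.seed(2)
  p1 <- make_plate(matrix(rnorm(24), 12, 2), c("c1", "c2", rep("DMSO", 10)),
                   plate = "A")
  p2 <- make_plate(matrix(rnorm(24), 12, 2), c("c1", "c2", rep("DMSO", 10)),
                   plate = "B")
  path <- tempfile(fileext = ".csv")
  write_plate_csv(list(p1, p2), path)
  back <- read_plate_csv(path)
  expect_length(back, 2L)
  expect_equal(back[["A"]]$features, p1$features, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back[["B"]]$wells$compound_id, p2$wells$compound_id)
})
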