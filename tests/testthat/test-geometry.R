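# closed-form eigenvalues of a symmetric 3x3 matrix (trigonometric method),
# used as an oracle independent of the package's eigen solve
eig3_oracle <- function(A) {
  p1 <- A[1, 2]^2 + A[1, 3]^2 + A[2, 3]^2
  if (p1 == 0) return(sort(diag(A)))
  q <- sum(diag(A)) / 3
  p2 <- sum((diag(A) - q)^2) + 2 * p1
  p <- sqrt(p2 / 6)
  B <- (A - q * diag(3)) / p
  r <- det(B) / 2
  r <- max(-1, min(1, r))
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  sort(c(e1, 3 * q - e1 - e3, e3))
}

# inertia tensor written out element-wise (independent of the implementation)
inertia_oracle <- function(x, m) {
  com <- colSums(x * m) / sum(m)
  x <- sweep(x, 2, com)
  I <- matrix(0, 3, 3)
  I[1, 1] <- sum(m * (x[, 2]^2 + x[, 3]^2))
  I[2, 2] <- sum(m * (x[, 1]^2 + x[, 3]^2))
  I[3, 3] <- sum(m * (x[, 1]^2 + x[, 2]^2))
  I[1, 2] <- I[2, 1] <- -sum(m * x[, 1] * x[, 2])
  I[1, 3] <- I[3, 1] <- -sum(m * x[, 1] * x[, 3])
  I[2, 3] <- I[3, 2] <- -sum(m * x[, 2] * x[, 3])
  I
}

test_that("limiting geometries land on the shape-triangle corners", {
  # rod: equal masses on a line -> I1 ~ 0, NPR (0, 1)
  rod <- geometry(cbind(seq(-2, 2, length.out = 5), 0, 0), masses = rep(1, 5))
  pm <- principal_moments(rod)
  expect_equal(pm[[1]], 0, tolerance = 1e-12)
  expect_equal(unname(npr(pm)), c(0, 1), tolerance = 1e-6)

  # disk: planar equilateral triangle -> I3 = I1 + I2, NPR (0.5, 0.5)
  tri <- geometry(rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0),
                        c(-0.5, -sqrt(3) / 2, 0)), masses = rep(1, 3))
  pmt <- principal_moments(tri)
  expect_equal(pmt[[3]], pmt[[1]] + pmt[[2]], tolerance = 1e-10)
  expect_equal(unname(npr(pmt)), c(0.5, 0.5), tolerance = 1e-6)

  # sphere-like: regular tetrahedron -> NPR (1, 1)
  tet <- geometry(rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                        c(-1, -1, 1)), masses = rep(1, 4))
  expect_equal(unname(npr(principal_moments(tet))), c(1, 1), tolerance = 1e-6)
})

test_that("principal moments match the closed-form eigenvalue oracle", {
  set.seed(7)
  for (rep_i in 1:5) {
    x <- matrix(rnorm(15), 5, 3)
    m <- runif(5, 1, 20)
    g <- geometry(x, masses = m)
    pm <- principal_moments(g)
    expect_equal(as.numeric(pm), eig3_oracle(inertia_oracle(x, m)),
                 tolerance = 1e-9)
  }
})

test_that("principal moments are invariant under rigid motions", {
  set.seed(11)
  x <- matrix(rnorm(24), 8, 3)
  m <- runif(8, 1, 16)
  pm0 <- as.numeric(principal_moments(geometry(x, masses = m)))
  for (rep_i in 1:5) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    xr <- x %*% Q + matrix(rnorm(3), 8, 3, byrow = TRUE) * 10
    pm1 <- as.numeric(principal_moments(geometry(xr, masses = m)))
    expect_equal(pm1, pm0, tolerance = 1e-8)
  }
})

test_that("degenerate geometries are rejected", {
  expect_error(principal_moments(geometry(rbind(c(0, 0, 0)), masses = 1)),
               "2 atoms")
  expect_error(
    principal_moments(geometry(rbind(c(1, 1, 1), c(1, 1, 1)),
                               masses = c(1, 1))), "coincident")
  pm_rod <- structure(c(0, 0, 0), class = "PrincipalMoments")
  expect_error(npr(pm_rod), "zero")
  expect_error(geometry(rbind(c(Inf, 0, 0)), masses = 1), "finite")
})

test_that("conformer embedding is deterministic and respects geometry", {
  g1 <- embed_conformer("c1ccccc1", n_conformers = 10, seed = 1)
  g2 <- embed_conformer("c1ccccc1", n_conformers = 10, seed = 1)
  expect_identical(g1$coords, g2$coords)
  expect_error(embed_conformer("c1ccccc1", n_conformers = 0), "n_conformers")

  # rigid planar aromatic: disk-like, I3 ~ I1 + I2
  pm <- principal_moments(g1)
  expect_equal(pm[[3]], pm[[1]] + pm[[2]], tolerance = 1e-2 * pm[[3]])
})

test_that("every embedded molecule falls inside the NPR triangle", {
  set <- toy_compound_set()
  smiles <- set$compounds$smiles[seq(1, 21, by = 3)]
  for (smi in smiles) {
    pm <- principal_moments(embed_conformer(smi))
    expect_true(pm[[3]] <= pm[[1]] + pm[[2]] + 1e-8 * pm[[3]])
    co <- npr(pm)
    expect_true(co[1] >= 0 && co[1] <= co[2] && co[2] <= 1)
    expect_true(co[1] + co[2] >= 1 - 1e-8)
  }
})

test_that("unit-mass and mass-weighted conventions are both available", {
  x <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 2, 0))
  g <- geometry(x, elements = c("C", "O", "N"))
  pm_m <- principal_moments(g, mass_weighted = TRUE)
  pm_u <- principal_moments(g, mass_weighted = FALSE)
  expect_false(isTRUE(all.equal(as.numeric(pm_m), as.numeric(pm_u))))
  expect_equal(as.numeric(pm_u),
               eig3_oracle(inertia_oracle(x, rep(1, 3))), tolerance = 1e-9)
})
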