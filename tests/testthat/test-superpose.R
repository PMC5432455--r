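test_that("kabsch on identical point sets is the identity transform", {
  set.seed(1)
  P <- matrix(rnorm(12), 4, 3)
  fit <- kabsch(P, P)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit$translation, c(0, 0, 0), tolerance = 1e-9)
})

test_that("kabsch recovers a constructed rotation and translation", {
  set.seed(2)
  P <- matrix(rnorm(30), 10, 3)
  theta <- pi / 2
  R_true <- rbind(c(cos(theta), -sin(theta), 0),
                  c(sin(theta), cos(theta), 0),
                  c(0, 0, 1))
  t_true <- c(1, 2, 3)
  Q <- sweep(P %*% R_true, 2, t_true, "+")
  fit <- kabsch(P, Q)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation, R_true, tolerance = 1e-9)
  expect_equal(fit$translation, t_true, tolerance = 1e-9)
  expect_equal(apply_transform(P, fit), Q, tolerance = 1e-9)
})

test_that("mirror images yield a proper rotation and non-zero rmsd", {
  # chiral 4-point set; reflection would fit exactly but is not allowed
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  Q <- P
  Q[, 1] <- -Q[, 1]
  fit <- kabsch(P, Q)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_gt(fit$rmsd, 0.1)
  # brute force over many proper rotations: none beats the kabsch rmsd
  set.seed(3)
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  brute <- replicate(500, {
    R <- random_proper_rotation()
    sqrt(mean(rowSums((Pc %*% R - Qc)^2)))
  })
  expect_true(all(brute >= fit$rmsd - 1e-9))
})

test_that("kabsch rmsd dominates random rigid transforms and is symmetric", {
  set.seed(4)
  for (rep in 1:5) {
    P <- matrix(rnorm(21), 7, 3)
    Q <- matrix(rnorm(21), 7, 3)
    fit <- kabsch(P, Q)
    Pc <- sweep(P, 2, colMeans(P))
    Qc <- sweep(Q, 2, colMeans(Q))
    rand <- replicate(200, {
      R <- random_proper_rotation()
      sqrt(mean(rowSums((Pc %*% R - Qc)^2)))
    })
    expect_true(all(rand >= fit$rmsd - 1e-9))
    expect_equal(kabsch(Q, P)$rmsd, fit$rmsd, tolerance = 1e-9)
  }
})

test_that("kabsch input contracts are enforced", {
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "3 points")
  expect_error(kabsch(matrix(0, 4, 3), matrix(0, 5, 3)), "same number")
})

test_that("kabsch agrees with an independent superposition implementation", {
  skip_if_not_installed("bio3d")
  set.seed(5)
  P <- matrix(rnorm(30), 10, 3)
  Q <- P %*% random_proper_rotation() + matrix(rnorm(30, sd = 0.2), 10, 3)
  ours <- kabsch(P, Q)$rmsd
  moved <- bio3d::fit.xyz(fixed = as.vector(t(Q)),
                          mobile = matrix(as.vector(t(P)), nrow = 1),
                          fixed.inds = 1:30, mobile.inds = 1:30)
  m <- matrix(moved, ncol = 3, byrow = TRUE)
  ref <- sqrt(mean(rowSums((m - Q)^2)))
  expect_equal(ours, ref, tolerance = 1e-6)
})

test_that("rmsd series is zero for identical or rigidly moved frames", {
  set.seed(6)
  base <- matrix(rnorm(30), 10, 3)
  topo <- ca_chain(base)
  ens <- toy_ensemble(topo, list(base, base, base))
  expect_equal(rmsd_series(ens)$values, c(0, 0, 0), tolerance = 1e-12)
  rigid <- lapply(1:4, function(k) {
    sweep(base %*% random_proper_rotation(), 2, runif(3, -9, 9), "+")
  })
  rs <- rmsd_series(toy_ensemble(topo, c(list(base), rigid)))
  expect_equal(rs$values, rep(0, 5), tolerance = 1e-9)
})

test_that("a hand-derived symmetric displacement gives rmsd d/2", {
  # 4 CA atoms: two on the x-axis, two on the y-axis; raising the y-axis
  # pair by d shifts the centroid by d/2 and, by symmetry, leaves the
  # optimal rotation at identity, so every atom ends |d/2| from the
  # reference: RMSD = sqrt(4 (d/2)^2 / 4) = d/2.
  r <- 5
  d <- 1.2
  base <- rbind(c(r, 0, 0), c(-r, 0, 0), c(0, r, 0), c(0, -r, 0))
  moved <- base
  moved[3:4, 3] <- d
  topo <- ca_chain(base)
  rs <- rmsd_series(toy_ensemble(topo, list(base, moved)))
  expect_equal(rs$values[2], d / 2, tolerance = 1e-9)
})

test_that("rmsd series is invariant to a global rigid motion of all frames", {
  set.seed(7)
  base <- matrix(rnorm(30), 10, 3)
  topo <- ca_chain(base)
  frames <- lapply(1:6, function(k) base + matrix(rnorm(30, sd = 0.4), 10, 3))
  rs1 <- rmsd_series(toy_ensemble(topo, frames))$values
  R <- random_proper_rotation()
  shift <- c(4, -2, 9)
  moved <- lapply(frames, function(f) sweep(f %*% R, 2, shift, "+"))
  rs2 <- rmsd_series(toy_ensemble(topo, moved))$values
  expect_equal(rs1, rs2, tolerance = 1e-9)
})

test_that("stability verdicts follow the post-equilibration means", {
  a <- structure(list(values = rep(2, 100), times = 0:99),
                 class = "xf_rmsd_series")
  b <- structure(list(values = rep(1, 100), times = 0:99),
                 class = "xf_rmsd_series")
  expect_equal(compare_stability(a, b)$verdict, "b_more_stable")
  expect_equal(compare_stability(a, a)$verdict, "indistinguishable")
  # 1.00 vs 1.02 at the default 5% tolerance: indistinguishable
  c1 <- structure(list(values = rep(1.00, 50)), class = "xf_rmsd_series")
  c2 <- structure(list(values = rep(1.02, 50)), class = "xf_rmsd_series")
  expect_equal(compare_stability(c1, c2)$verdict, "indistinguishable")
  expect_error(compare_stability(a, b, equilibration_start = 101), "beyond")
})

test_that("the pointwise-dominance flag enforces strict dominance", {
  va <- c(rep(2, 50), rep(2, 50))
  vb <- c(rep(1, 50), c(rep(1, 49), 3))  # one excursion above a
  strict <- compare_stability(va, vb, pointwise = TRUE)
  expect_equal(strict$verdict, "indistinguishable")
  relaxed <- compare_stability(va, vb, pointwise = FALSE)
  expect_equal(relaxed$verdict, "b_more_stable")
})
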