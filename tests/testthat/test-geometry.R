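rot_z <- function(th) matrix(c(cos(th), sin(th), 0,
                               -sin(th), cos(th), 0, 0, 0, 1), 3, 3)

test_that("least-squares plane recovers a flat cloud and its frame", {
  set.seed(1)
  flat <- cbind(runif(200, -5, 5), runif(200, -5, 5), 0)
  pl <- fit_plane(flat)
  expect_equal(abs(pl$axes[, 3]), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(pl$eigenvalues[3], 0, tolerance = 1e-12)
  expect_true(all(diff(pl$eigenvalues) <= 1e-9))
  # orthonormal axes
  expect_equal(crossprod(pl$axes), diag(3), tolerance = 1e-9)
  # equivariance: rotating the input rotates the normal identically
  R <- rot_z(0.8) %*% matrix(c(1, 0, 0, 0, cos(0.5), sin(0.5),
                               0, -sin(0.5), cos(0.5)), 3, 3)
  pl2 <- fit_plane(flat %*% t(R))
  expect_equal(abs(sum(pl2$axes[, 3] * (R %*% pl$axes[, 3]))), 1,
               tolerance = 1e-9)
  expect_error(fit_plane(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))),
               "collinear")
})

test_that("plane eigenvalues equal the covariance eigendecomposition", {
  set.seed(2)
  cloud <- matrix(rnorm(600), 200, 3) %*% diag(c(3, 1.5, 0.4))
  pl <- fit_plane(cloud)
  C <- crossprod(sweep(cloud, 2, colMeans(cloud))) / nrow(cloud)
  expect_equal(pl$eigenvalues, sort(eigen(C)$values, decreasing = TRUE),
               tolerance = 1e-9)
})

test_that("planarity matches closed forms and the noise expectation", {
  set.seed(3)
  flat <- cbind(runif(100, -5, 5), runif(100, -5, 5), 0)
  expect_equal(planarity(flat), 0, tolerance = 1e-9)
  # each xy position split into +1/-1 off-plane pair: optimal plane stays
  # at z = 0 and the rms is exactly 1
  alt <- rbind(cbind(flat[, 1:2], 1), cbind(flat[, 1:2], -1))
  expect_equal(planarity(alt), 1.0, tolerance = 1e-6)
  # Gaussian out-of-plane noise sd 0.5 -> planarity 0.5
  noisy <- cbind(runif(2000, -10, 10), runif(2000, -10, 10),
                 rnorm(2000, 0, 0.5))
  expect_equal(planarity(noisy), 0.5, tolerance = 0.03 / 0.5)
})

test_that("eccentricity is 1 for a disc, ~0 for a line, 0.5 for a 2:1 ellipse", {
  set.seed(4)
  th <- runif(4000, 0, 2 * pi); r <- sqrt(runif(4000))
  disc <- cbind(r * cos(th), r * sin(th), 0)
  expect_equal(eccentricity(disc), 1.0, tolerance = 0.05)
  line <- cbind(seq(-5, 5, length.out = 100), rnorm(100, 0, 1e-4), 0)
  expect_lt(eccentricity(line), 0.01)
  ellipse <- cbind(2 * r * cos(th), r * sin(th), rnorm(4000, 0, 0.01))
  expect_equal(eccentricity(ellipse), 0.50, tolerance = 0.03 / 0.50)
})

test_that("planarity and eccentricity are rigid-motion invariant", {
  set.seed(5)
  cloud <- matrix(rnorm(300), 100, 3) %*% diag(c(4, 2, 0.6))
  R <- rot_z(1.1)
  moved <- sweep(cloud %*% t(R), 2, c(10, -4, 7), "+")
  expect_equal(planarity(moved), planarity(cloud), tolerance = 1e-9)
  expect_equal(eccentricity(moved), eccentricity(cloud), tolerance = 1e-9)
})

test_that("gap volume of a two-plate toy approximates the analytic slab", {
  d <- 6
  A <- make_structure(plate_xyz(0, extent = 24, spacing = 1.5), chain = "A")
  B <- make_structure(plate_xyz(d, extent = 24, spacing = 1.5), chain = "B")
  cx <- bind_structures(A, B)
  gv <- gap_volume(cx, partner_selection("A", "B"), grid_spacing = 0.5)
  slab <- 24 * 24 * (d - 2 * 1.70)   # patch area x free gap height
  expect_equal(gv$gap_volume, slab, tolerance = 0.15)
})

test_that("gap volume converges under grid refinement on a toy complex", {
  toy <- build_toy_complex(toy_spec("class_I_helix_groove", seed = 7))
  idef <- define_interface(toy$pp, toy$selection, n_points = 240L)
  g1 <- gap_volume(toy$pp, toy$selection, idef, grid_spacing = 1.0)
  g05 <- gap_volume(toy$pp, toy$selection, idef, grid_spacing = 0.5)
  expect_lt(abs(g05$gap_volume - g1$gap_volume) / g1$gap_volume, 0.10)
  expect_gt(g1$gap_volume, 0)
  # gap index = gap volume / total two-side delta-ASA
  expect_equal(g1$gap_index,
               g1$gap_volume / (idef$delta_asa_side_a +
                                idef$delta_asa_side_b),
               tolerance = 1e-9)
})

test_that("gap index is undefined for a zero interface", {
  A <- make_structure(plate_xyz(0, 6, 3), chain = "A")
  B <- make_structure(plate_xyz(60, 6, 3), chain = "B")
  cx <- bind_structures(A, B)
  expect_error(gap_volume(cx, partner_selection("A", "B")),
               "zero interface")
})

test_that("Kabsch superposition recovers identity, known rotations and noise", {
  set.seed(6)
  A <- matrix(rnorm(300), 100, 3)
  sp0 <- superpose(A, A)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-9)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(det(sp0$rotation), 1, tolerance = 1e-12)

  R <- rot_z(0.7)
  B <- sweep(A %*% t(R), 2, c(3, -2, 5), "+")
  sp <- superpose(A, B)
  expect_equal(sp$rmsd, 0, tolerance = 1e-9)
  expect_equal(sp$rotation, R, tolerance = 1e-9)

  noisy <- B + matrix(rnorm(600, 0, 0.3), 200, 3)[1:100, ]
  spn <- superpose(noisy, B)
  expect_equal(spn$rmsd, 0.3 * sqrt(3), tolerance = 0.05 / 0.52)
  expect_error(superpose(A[1:2, ], B[1:2, ]), "at least 3")
})

test_that("Kabsch fit beats random rigid transforms (optimality)", {
  set.seed(8)
  A <- matrix(rnorm(150), 50, 3)
  B <- A + matrix(rnorm(150, 0, 0.5), 50, 3)
  best <- superpose(A, B)$rmsd
  for (k in 1:20) {
    th <- runif(3, -pi, pi)
    R <- rot_z(th[1]) %*%
      matrix(c(1, 0, 0, 0, cos(th[2]), sin(th[2]),
               0, -sin(th[2]), cos(th[2])), 3, 3)
    tr <- rnorm(3, 0, 1)
    rmsd_k <- sqrt(mean(rowSums((sweep(A %*% t(R), 2, tr, "+") - B)^2)))
    expect_gte(rmsd_k, best - 1e-9)
  }
})

test_that("CA superposition pairs residues by identity", {
  toy <- build_toy_complex(toy_spec("class_I_strand", seed = 9))
  sp <- superpose_ca(toy$unbound, toy$pp, chains = "A")
  expect_gt(sp$n_pairs, 10)
  expect_gt(sp$rmsd, 0.2)   # seeded jitter, sd 0.4 A
  expect_lt(sp$rmsd, 1.5)
  sp_self <- superpose_ca(toy$pp, toy$pp, chains = "A")
  expect_equal(sp_self$rmsd, 0, tolerance = 1e-9)
})
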