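test_that("voxel volume matches the analytic sphere and is additive", {
  single <- make_mol("C", c(0, 0, 0))             # Bondi C radius 1.70
  v <- compute_vdw_volume(single, resolution = 0.1)
  expect_equal(v$total, 4 / 3 * pi * 1.7^3, tolerance = 0.02)
  expect_equal(v$polar, 0)

  two_apart <- make_mol(c("C", "C"), c(0, 0, 0, 10, 0, 0))
  v2 <- compute_vdw_volume(two_apart, resolution = 0.1)
  expect_equal(v2$total, 2 * v$total, tolerance = 0.01)

  coincident <- make_mol(c("C", "C"), c(0, 0, 0, 0, 0, 0))
  v1 <- compute_vdw_volume(coincident, resolution = 0.1)
  expect_equal(v1$total, v$total, tolerance = 1e-12)

  expect_error(compute_vdw_volume(single, resolution = 2.0), "coarser")
  expect_error(compute_vdw_volume(single, resolution = 0), "positive")
})

test_that("polar volume partitions the union and ties go to the lower atom index", {
  # one O fully overlapping one C of equal radius: O listed first wins ties
  m <- make_mol(c("O", "C"), c(0, 0, 0, 0.5, 0, 0))
  v <- compute_vdw_volume(m, resolution = 0.1)
  expect_gt(v$polar, 0)
  expect_lte(v$polar, v$total)
  # all-polar molecule: polar equals total exactly
  allp <- make_mol(c("O", "N"), c(0, 0, 0, 1.2, 0, 0))
  vp <- compute_vdw_volume(allp, resolution = 0.1)
  expect_identical(vp$polar, vp$total)
})

test_that("fpv is the polar fraction with exact endpoints", {
  expect_equal(compute_fpv(100, 0), 0)
  expect_equal(compute_fpv(100, 100), 1)
  expect_equal(compute_fpv(100, 29.4), 0.294)
  expect_error(compute_fpv(0, 0), "positive")
  expect_error(compute_fpv(100, 120), "polar volume")
})

test_that("box axes: analytic cases and rigid-motion invariance", {
  single <- make_mol("C", c(0, 0, 0))
  b <- compute_box_axes(single)
  expect_equal(c(b$S, b$M, b$L), rep(3.4, 3), tolerance = 1e-6)

  pair <- make_mol(c("H", "H"), c(0, 0, 0, 3, 0, 0))  # radius 1.2
  # use unit radii via direct search to match the hand-computed 2 x 2 x 5 box
  bb <- coformr:::min_box_search(matrix(c(0, 0, 0, 3, 0, 0), 2, byrow = TRUE),
                                 radii = c(1, 1))
  expect_equal(c(bb$S, bb$M, bb$L), c(2, 2, 5), tolerance = 1e-4)
  expect_equal(crossprod(bb$rotation), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)

  # rigid motion leaves box edges (and ratios) unchanged
  set.seed(21)
  coords <- matrix(rnorm(18, sd = 1.5), 6, 3)
  radii <- runif(6, 1.2, 1.8)
  b1 <- coformr:::min_box_search(coords, radii)
  R <- coformr:::euler_zyz(0.7, 0.4, 1.1)
  b2 <- coformr:::min_box_search(sweep(coords %*% t(R), 2, c(3, -2, 5), "+"),
                                 radii)
  expect_equal(b1$volume, b2$volume, tolerance = 0.01)
  expect_equal(c(b1$S, b1$M, b1$L), c(b2$S, b2$M, b2$L), tolerance = 0.02)
})

test_that("box search matches a brute-force 2-degree rotation grid oracle", {
  set.seed(7)
  for (k in 1:3) {
    n <- sample(3:8, 1)
    coords <- matrix(rnorm(n * 3, sd = 2), n, 3)
    radii <- runif(n, 1.1, 1.9)
    mine <- coformr:::min_box_search(coords, radii)$volume
    oracle <- brute_box_volume(coords, radii)
    expect_lte(mine, oracle * 1.01)    # never worse than the grid oracle + 1%
    expect_gte(mine, oracle * 0.97)    # nor implausibly below it (both bound
                                       # the same true minimum from above)
  }
})

test_that("dipole moment: hand conversion, translation invariance, charge warning", {
  dip <- make_mol(c("C", "C"), c(0, 0, 0, 1, 0, 0), charges = c(0.5, -0.5))
  expect_equal(compute_dipole(dip), 0.5 * 4.80321, tolerance = 1e-9)

  zero <- make_mol(c("C", "C"), c(0, 0, 0, 1, 0, 0), charges = c(0, 0))
  expect_equal(compute_dipole(zero), 0)

  shifted <- mol_coords(dip) + matrix(rep(c(5, -3, 2), each = 2), 2)
  expect_equal(compute_dipole(dip, coords = shifted), compute_dipole(dip))

  ion <- make_mol("N", c(0, 0, 0), charges = 1, formal = 1L)
  expect_warning(compute_dipole(ion), "origin-dependent")
})

test_that("volume is invariant under rigid motion and monotone under atom addition", {
  m <- fixture_mol("CC(=O)Nc1ccc(O)cc1", "acetaminophen")
  v0 <- compute_vdw_volume(m)$total
  R <- coformr:::euler_zyz(1.0, 0.8, 0.3)
  vr <- compute_vdw_volume(m, coords = mol_coords(m) %*% t(R) + 2)$total
  expect_equal(vr, v0, tolerance = 0.02)

  sub <- make_mol(c("C", "C"), c(0, 0, 0, 1.5, 0, 0))
  sup <- make_mol(c("C", "C", "O"), c(0, 0, 0, 1.5, 0, 0, 3.0, 0, 0))
  expect_gt(compute_vdw_volume(sup, resolution = 0.15)$total,
            compute_vdw_volume(sub, resolution = 0.15)$total)
})

test_that("descriptor vectors behave on reference shapes and are deterministic", {
  w <- fixture_mol("O", "water")
  dw <- descriptor_vector(w)
  expect_gt(dw$fpv, 0.3)
  expect_gt(dw$s_over_l, 0.7)   # near-spherical

  oct <- fixture_mol("CCCCCCCC", "octane")
  expect_lt(descriptor_vector(oct)$s_over_l, 0.5)  # elongated
  expect_equal(descriptor_vector(oct)$fpv, 0)

  d1 <- descriptor_vector(w)
  d2 <- descriptor_vector(w, coords = mol_coords(w))
  expect_identical(d1, d2)

  # atom-count FPV variant
  d_ac <- descriptor_vector(w, fpv_mode = "atom_count")
  expect_equal(d_ac$fpv, 1)     # water's only heavy atom is polar
})
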