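# seeded generators: determinism, ground truth, degenerate limits

test_that("all generators are byte-identical under a fixed seed", {
  g1 <- gen_coating_volume(region = c(8, 8), jitter = 0.1, seed = 21)
  g2 <- gen_coating_volume(region = c(8, 8), jitter = 0.1, seed = 21)
  expect_identical(g1$volume$occ, g2$volume$occ)
  p1 <- gen_pore_image(n_pores = 25, size_px = 450, seed = 5)
  p2 <- gen_pore_image(n_pores = 25, size_px = 450, seed = 5)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$truth, p2$truth)
  c1 <- gen_capsule_section(seed = 8)
  c2 <- gen_capsule_section(seed = 8)
  expect_identical(c1$mask, c2$mask)
  # different seed, different realisation
  p3 <- gen_pore_image(n_pores = 25, size_px = 450, seed = 6)
  expect_false(identical(p1$image, p3$image))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(gen_pore_image(n_pores = 10, size_px = 300, seed = 3))
  after <- rnorm(1)
  expect_identical(before, after)
})

test_that("coating volume bounding box is the region plus loop margin", {
  g <- gen_coating_volume(region = c(10, 10), seed = 1)
  v <- g$volume
  ext_lo <- v$origin[1:2]
  ext_hi <- v$origin[1:2] + dim(v$occ)[1:2] * v$voxel
  margin <- 3.5 / 2 + 0.1 + 2 * 0.05
  expect_equal(ext_lo, c(-margin, -margin), tolerance = 0.06)
  expect_true(all(ext_hi >= 10 + margin - 0.06))
})

test_that("a six-layer coating stacks two three-layer coatings", {
  # with zero jitter and no inter-layer penetration the upper replicate is
  # the lower one shifted by exactly three filament diameters
  s3 <- coating_spec(n_layers = 3)
  s6 <- coating_spec(n_layers = 6)
  g3 <- gen_coating_volume(s3, region = c(8, 8), seed = 1, penetration = 0)
  g6 <- gen_coating_volume(s6, region = c(8, 8), seed = 1, penetration = 0)
  n3 <- length(g3$curves)
  expect_length(g6$curves, 2 * n3)
  for (k in seq_len(n3)) {
    lo <- g6$curves[[k]]$coords
    hi <- g6$curves[[k + n3]]$coords
    expect_equal(hi[, 1:2], lo[, 1:2])
    expect_equal(unique(round(hi[, 3] - lo[, 3], 9)), 3 * 0.2)
  }
  # voxel grids agree after shifting by 3 * 0.2 / 0.05 = 12 slices
  d6 <- dim(g6$volume$occ)
  occ3 <- voxelize_filaments(g3$curves, voxel = 0.05,
                             bbox = rbind(g6$volume$origin,
                                          g6$volume$origin + d6 * 0.05))$occ
  shifted <- array(FALSE, d6)
  shifted[, , 13:d6[3]] <- occ3[, , 1:(d6[3] - 12)]
  expect_identical(g6$volume$occ, occ3 | shifted)
})

test_that("pore truth tables match the requested distribution", {
  g <- gen_pore_image(n_pores = 50, size_px = 650, seed = 2)
  expect_equal(nrow(g$truth), 50)
  expect_equal(g$truth$area_um2, pi * (g$truth$diameter_um / 2)^2,
               tolerance = 1e-9)
  # degenerate lognormal: all diameters equal the median
  g0 <- gen_pore_image(n_pores = 12, sigma_log = 0, size_px = 300, seed = 2)
  expect_equal(unique(g0$truth$diameter_um), 4.1)
  expect_error(gen_pore_image(n_pores = 5000, size_px = 300, seed = 1),
               "density")
})

test_that("capsule sections honour their stated geometry", {
  flat <- gen_capsule_section(thickness_mean = 120, seed = 3)
  expect_equal(flat$truth_mean, 120)
  # parallel band: every column of the mask has the same thickness
  runs <- apply(flat$mask, 1, sum)
  expect_lte(diff(range(runs[10:(length(runs) - 10)])), 1)
  expect_warning(
    gen_capsule_section(thickness_mean = 500, waviness = 60,
                        wavelength_um = 400, seed = 1),
    "curvature")
})

test_that("flared mandrel profiles are smooth and symmetric", {
  flat <- gen_flared_mandrel(base_radius = 8, flare_radius = 8)
  expect_equal(unique(flat$radius), 8)
  md <- gen_flared_mandrel(base_radius = 8, flare_radius = 14,
                           flare_center = 30, flare_width = 24, length = 60)
  expect_equal(max(md$radius), 14, tolerance = 1e-9)
  expect_equal(md$radius[md$z == 30], 14)
  # monotone blend on each side of the flare
  left <- md$radius[md$z >= 18 & md$z <= 30]
  right <- md$radius[md$z >= 30 & md$z <= 42]
  expect_true(all(diff(left) >= -1e-12))
  expect_true(all(diff(right) <= 1e-12))
  # symmetry about the flare centre
  r1 <- approx(md$z, md$radius, xout = 30 - (0:40) * 0.25)$y
  r2 <- approx(md$z, md$radius, xout = 30 + (0:40) * 0.25)$y
  expect_equal(r1, r2, tolerance = 1e-9)
})
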