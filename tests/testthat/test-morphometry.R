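# curvature, MIP/void analysis, height maps, window/level, particles

test_that("quadric-fit curvature matches closed forms", {
  # cylinder r = 0.1 mm (filament scale): H = 1/(2r) = 5
  cf <- surface_curvature(cylinder_mesh(0.1, 1))
  expect_true(abs(median(cf$H) / 5 - 1) < 0.10)
  # sphere R = 1: H = 1
  cs <- surface_curvature(sphere_mesh(1))
  expect_true(abs(median(cs$H) - 1) < 0.05)
  # plane: H = 0
  cp <- surface_curvature(plane_mesh())
  expect_true(max(abs(cp$H)) < 0.05)
  q <- curvature_quantiles(cs)
  expect_length(q$quartiles, 3)
  expect_length(q$ventiles, 19)
  expect_true(all(cf$kmin <= cf$kmax))
})

test_that("curvature of a levelset-extracted sphere matches 1/R", {
  sv <- sphere_volume(1, 0.04)
  m <- mesh_from_volume(sv)
  cf <- surface_curvature(m, ring = 4, sample = 1500)
  expect_true(abs(median(cf$H) - 1) < 0.05)
})

test_that("maximum intensity projection collapses columns", {
  occ <- array(FALSE, c(6, 6, 4)); occ[2, 3, 2] <- TRUE
  mp <- max_intensity_projection(voxel_volume(occ, 0.1))
  expect_equal(sum(mp$mask), 1)
  expect_true(mp$mask[2, 3])
  # idempotent over z: full column projects like a single voxel
  occ2 <- occ; occ2[2, 3, ] <- TRUE
  expect_identical(max_intensity_projection(voxel_volume(occ2, 0.1))$mask,
                   mp$mask)
})

test_that("projected filament fraction grows with layer count", {
  g1 <- gen_coating_volume(coating_spec(n_layers = 1), region = c(12, 12),
                           seed = 1)
  g3 <- gen_coating_volume(region = c(12, 12), seed = 1)
  f1 <- mean(max_intensity_projection(g1$volume)$mask)
  f3 <- mean(max_intensity_projection(g3$volume)$mask)
  expect_gt(f3, f1)
})

test_that("void analysis is exact on constructed rectangular holes", {
  img <- matrix(TRUE, 60, 60)             # 0.1 mm pixels: 6 x 6 mm block
  img[11:20, 11:20] <- FALSE              # 10x10 px = 1.0 mm^2
  img[35:44, 31:35] <- FALSE              # 10x5  px = 0.5 mm^2
  vs <- analyze_voids(img, 0.1)
  expect_equal(vs$count, 2)
  expect_equal(sort(vs$areas), c(0.5, 1.0))
  expect_equal(vs$mean_area, 0.75)
  # solid block: no interior voids
  solid <- matrix(FALSE, 40, 40); solid[10:30, 10:30] <- TRUE
  expect_equal(analyze_voids(solid, 0.1)$count, 0)
  expect_error(analyze_voids(matrix(TRUE, 5, 5), 0.1), "both filament")
})

test_that("height map reports the topmost occupied voxel per column", {
  # one flat layer of 0.2 mm filaments
  cv <- filament_curve(cbind(seq(0, 5, 0.05), 2.5, 0.1), radius = 0.1)
  v <- voxelize_filaments(cv, voxel = 0.05,
                          bbox = rbind(c(-0.5, 0, 0), c(5.5, 5, 0.5)))
  hm <- compute_height_map(v)
  expect_true(abs(hm$max - 0.2) <= 0.05 + 1e-9)
  expect_true(all(is.na(hm$heights) | hm$heights > 0))
  # empty columns excluded from the mean
  expect_gte(hm$mean, hm$min)
})

test_that("window/level is the documented linear ramp", {
  W <- 88; L <- 141
  img <- matrix(c(L, L - W / 2, L + W / 2, 0, 255), 1)
  out <- window_level(img, W, L)
  expect_equal(out[1, 1], 127.5)
  expect_equal(out[1, 2], 0)
  expect_equal(out[1, 3], 255)
  expect_equal(out[1, 4], 0)
  expect_equal(out[1, 5], 255)
  expect_error(window_level(img, 88, 300), "L must be")
})

test_that("particle filter keeps disks, rejects slivers and dust", {
  px <- 0.25
  img <- matrix(FALSE, 200, 200)
  # digital disk r = 2 um (8 px): near-circular, survives
  xs <- matrix(rep(1:200, 200), 200); ys <- t(xs)
  img[(xs - 50)^2 + (ys - 50)^2 <= 8^2] <- TRUE
  # bar 0.5 x 30 um (2 x 120 px): circularity ~0.05, rejected
  img[120:121, 40:159] <- TRUE
  # dust below 0.38 um^2 (5 px = 0.3125 um^2), rejected
  img[180, 100:104] <- TRUE
  ps <- analyze_particles(img, px)
  expect_equal(ps$count, 1)
  expect_true(abs(ps$areas[1] - pi * 2^2) / (pi * 2^2) < 0.05)
  expect_gte(ps$circularity[1], 0.9)
  # the disk's equivalent diameter is recovered
  expect_equal(ps$diameters[1], 4, tolerance = 0.05)
})

test_that("sub-threshold particles never change surviving statistics", {
  g <- gen_pore_image(n_pores = 30, size_px = 520, seed = 11)
  base <- analyze_pore_image(g$image, g$pixel_um)
  img2 <- g$image
  # sprinkle sub-area dust (1-2 px each, far below 0.38 um^2)
  set.seed(1)
  for (k in 1:30) {
    i <- sample(5:515, 1); j <- sample(5:515, 1)
    if (all(img2[i + (-2:2), j + (-2:2)] > 150)) img2[i, j] <- 60
  }
  with_dust <- analyze_pore_image(img2, g$pixel_um)
  expect_equal(with_dust$count, base$count)
  expect_equal(sort(with_dust$diameters), sort(base$diameters))
})

test_that("pore summaries aggregate per-ROI medians", {
  mk <- function(d) structure(list(median_diameter = median(d),
                                   count_per_area = 0.01),
                              class = "pore_stats")
  s <- summarize_pores(list(mk(c(1, 2, 3)), mk(c(2, 2, 2)), mk(c(3, 3, 3))))
  expect_equal(s$per_roi_median, c(2, 2, 3))
  expect_equal(s$median_of_medians, 2)
  s2 <- summarize_pores(list(mk(c(1, 2, 3)), mk(c(1, 2, 3))))
  expect_equal(s2$sd_of_medians, 0)
  expect_error(summarize_pores(list()), "at least one")
})

test_that("pipeline recovers generator medians without bias", {
  for (m in c(2, 4.1, 8)) {
    px <- if (m > 6) 0.5 else 0.25
    g <- gen_pore_image(median_um = m, pixel_um = px, seed = 207)
    ps <- analyze_pore_image(g$image, g$pixel_um)
    expect_true(abs(ps$median_diameter / median(g$truth$diameter_um) - 1) < 0.02,
                label = sprintf("median recovery at %g um", m))
  }
})

test_that("the full morphometry pipeline is deterministic", {
  g1 <- gen_coating_volume(region = c(10, 10), seed = 7)
  g2 <- gen_coating_volume(region = c(10, 10), seed = 7)
  expect_identical(g1$volume$occ, g2$volume$occ)
  v1 <- analyze_voids(max_intensity_projection(g1$volume)$mask, 0.05)
  v2 <- analyze_voids(max_intensity_projection(g2$volume)$mask, 0.05)
  expect_identical(v1$areas, v2$areas)
})
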