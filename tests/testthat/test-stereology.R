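# orthogonal-intercept thickness, point counting, vessel metrics, areas

test_that("thickness is exact on a parallel band at any grid orientation", {
  mask <- matrix(FALSE, 200, 160)
  mask[, 16:115] <- TRUE                       # band y in [30, 230] um
  interface <- cbind(x = seq(5, 195, by = 1), y = 30)
  for (ang in c(0, 17, 45, 80)) {
    th <- orthogonal_intercept_thickness(interface, mask,
                                         grid_config(23, angle = ang), 2)
    expect_equal(th$mean, 200, tolerance = 1e-6,
                 label = sprintf("band thickness at grid angle %g", ang))
  }
  expect_error(
    orthogonal_intercept_thickness(interface, mask, grid_config(1e6), 2),
    "finer grid")
})

test_that("thickness recovery on tortuous synthetic capsules is within 10%", {
  errs <- vapply(1:20, function(i) {
    tm <- 50 + (i - 1) * (450 / 19)            # true means 50-500 um
    g <- gen_capsule_section(thickness_mean = tm, thickness_sd = tm / 5,
                             waviness = 25, wavelength_um = 1600,
                             seed = 9000 + i)
    est <- orthogonal_intercept_thickness(g$interface, g$mask,
                                          grid_config(150), g$pixel_um)
    abs(est$mean / g$truth_mean - 1)
  }, numeric(1))
  expect_lt(mean(errs), 0.10)
})

test_that("halving the grid spacing does not shift the estimate", {
  g <- gen_capsule_section(thickness_mean = 150, thickness_sd = 30,
                           waviness = 25, wavelength_um = 1600, seed = 44)
  e1 <- orthogonal_intercept_thickness(g$interface, g$mask, grid_config(150),
                                       g$pixel_um)
  e2 <- orthogonal_intercept_thickness(g$interface, g$mask, grid_config(75),
                                       g$pixel_um)
  expect_true(abs(e2$mean / e1$mean - 1) < 0.08)  # sampling noise only
})

test_that("harmonic-mean correction is available but off by default", {
  mask <- matrix(FALSE, 100, 100); mask[, 11:60] <- TRUE
  interface <- cbind(x = seq(5, 95, 1), y = 20)
  est <- orthogonal_intercept_thickness(interface, mask, grid_config(17), 2,
                                        correction = TRUE)
  expect_equal(est$true_thickness, (8 / (3 * pi)) * est$mean,
               tolerance = 1e-9)  # constant intercepts: harmonic = arithmetic
  est0 <- orthogonal_intercept_thickness(interface, mask, grid_config(17), 2)
  expect_null(est0$true_thickness)
})

test_that("point counting converges to the area fraction", {
  tgt <- matrix(FALSE, 300, 300); tgt[1:150, ] <- TRUE
  ref <- matrix(TRUE, 300, 300)
  f <- point_count_volume_fraction(tgt, ref, grid_config(7), 1)
  expect_equal(as.numeric(f), 0.5, tolerance = 0.02)
  expect_equal(as.numeric(point_count_volume_fraction(ref, ref,
                                                      grid_config(11), 1)), 1)
  empty <- matrix(FALSE, 300, 300)
  expect_equal(as.numeric(point_count_volume_fraction(empty, ref,
                                                      grid_config(11), 1)), 0)
  expect_error(point_count_volume_fraction(tgt, empty, grid_config(11), 1),
               "empty")
  # SE of the estimate shrinks roughly as 1/sqrt(n points)
  fr <- vapply(c(40, 10), function(sp) {
    f <- point_count_volume_fraction(tgt, ref, grid_config(sp, offset = c(3, 5)), 1)
    abs(as.numeric(f) - 0.5)
  }, numeric(1))
  expect_true(fr[2] <= fr[1] + 0.02)
})

test_that("vessel metrics follow the stereological identities", {
  v <- vessel_metrics(20, 0.1)
  expect_equal(v$N_A, 200)
  expect_equal(v$Lv, 400)
  expect_equal(v$radial_diffusion_um, 1000 / sqrt(pi * 400), tolerance = 1e-9)
  expect_equal(round(v$radial_diffusion_um, 1), 28.2)
  z <- vessel_metrics(0, 0.1)
  expect_equal(z$Lv, 0)
  expect_true(is.na(z$radial_diffusion_um))
  m <- vessel_metrics(8, 0.1, mature = rep(TRUE, 8))
  expect_equal(m$maturity_ratio, 1)
  vv <- vessel_metrics(4, 0.5, profile_areas = c(0.01, 0.02, 0.03, 0.04))
  expect_equal(vv$Vv, 0.2)
})

test_that("polygon areas use the shoelace formula with scale", {
  expect_equal(region_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 1)
  expect_equal(region_area(rbind(c(0, 0), c(3, 0), c(3, 4))), 6)
  # orientation invariance
  expect_equal(region_area(rbind(c(0, 1), c(1, 1), c(1, 0), c(0, 0))), 1)
  # pixel scale
  expect_equal(region_area(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
                           pixel_size = 0.1), 1)
  expect_error(region_area(rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))),
               "self-intersecting")
  expect_error(region_area(rbind(c(0, 0), c(1, 1))), "3 vertices")
})
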