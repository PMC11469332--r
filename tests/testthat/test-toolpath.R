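# planar, height-map and mandrel planning

test_that("planar rows span the region at the layer spacing", {
  tp <- plan_planar_coating(c(21, 21), coating_spec(n_layers = 1, angles = 0))
  expect_equal(nrow(tp$points) / 2, 7)  # rows on both edges, 3.5 mm apart
  expect_warning(plan_planar_coating(c(2, 2), coating_spec(n_layers = 1)),
                 "single row")
})

test_that("default layer cycle is 0/45/135 and six layers replicate it", {
  expect_equal(coating_spec()$layers$angle, c(0, 45, 135))
  expect_equal(coating_spec(n_layers = 6)$layers$angle,
               c(0, 45, 135, 0, 45, 135))
  p6 <- plan_planar_coating(c(21, 21), coating_spec(n_layers = 6))$points
  for (k in 0:2) {
    a <- p6[p6$layer == k, c("x", "y")]
    b <- p6[p6$layer == k + 3, c("x", "y")]
    expect_equal(unname(as.matrix(a)), unname(as.matrix(b)))
    expect_equal(unique(round(p6$z[p6$layer == k + 3] -
                                p6$z[p6$layer == k], 9)), 0.6)
  }
})

test_that("planner output is deterministic", {
  g1 <- write_gcode(plan_planar_coating(c(20, 20)))
  g2 <- write_gcode(plan_planar_coating(c(20, 20)))
  expect_identical(g1, g2)
})

test_that("height-map coating follows the surface at constant standoff", {
  # degenerate flat map equals the planar plan at z = standoff
  hm <- heightmap_surface(matrix(0, 51, 51), pitch = 1)
  tpf <- plan_heightmap_coating(hm, coating_spec(n_layers = 1, angles = 0))
  expect_equal(unique(round(tpf$points$z, 9)), 6)  # h(A = 3.5) = 6 mm
  # hemispherical cap: per-point clearance equals the standoff
  xs <- 0:50
  hemi <- outer(xs, xs, function(x, y) {
    r2 <- 20^2 - (x - 25)^2 - (y - 25)^2
    ifelse(r2 > 0, sqrt(pmax(r2, 0)), 0)
  })
  hs <- heightmap_surface(hemi, pitch = 1)
  tph <- plan_heightmap_coating(hs, coating_spec(n_layers = 1, angles = 0),
                                sample_step = 0.5)
  clr <- tph$points$z - surface_height(hs, tph$points$x, tph$points$y)
  expect_equal(min(clr), 6, tolerance = 1e-9)
  expect_equal(max(clr), 6, tolerance = 1e-9)
  # spray raster keeps the atomizer standoff everywhere
  tsp <- plan_heightmap_coating(hs, standoff = 85, mode = "spray")
  expect_equal(unique(tsp$points$standoff), 85)
  expect_equal(unique(tsp$points$z - surface_height(hs, tsp$points$x,
                                                    tsp$points$y)), 85)
  expect_error(surface_height(hs, -5, 10), "outside")
})

test_that("mandrel layers emit the configured helical line counts", {
  md <- gen_flared_mandrel()
  tm <- suppressWarnings(plan_mandrel_coating(md, n_lines = c(34, 21, 13)))
  expect_equal(tm$meta$n_lines, c(34, 21, 13))
  for (li in 0:2) {
    pl <- tm$points[tm$points$layer == li, ]
    expect_equal(diff(range(pl$a)) / 360, c(34, 21, 13)[li + 1],
                 tolerance = 1e-6)
  }
})

test_that("mandrel rotation keeps the substrate surface speed constant", {
  # constant radius: omega = v / rho everywhere
  mc <- mandrel_profile(c(0, 40), c(10, 10))
  tc <- suppressWarnings(plan_mandrel_coating(mc, n_lines = 34,
                                              surface_speed = 1000))
  pc <- tc$points
  rc <- mandrel_radius(mc, pc$z)
  rbar <- 0.5 * (rc[-1] + rc[-length(rc)])
  dth <- diff(pc$a) * pi / 180
  ds <- sqrt((rbar * dth)^2 + diff(pc$z)^2)
  omega <- dth / (ds / 1000)
  expect_true(all(abs(omega - 1000 / 10) < 1))
  # flared mandrel: omega * rho constant within 1%
  md <- gen_flared_mandrel()
  tm <- suppressWarnings(plan_mandrel_coating(md, n_lines = 34,
                                              surface_speed = 1000))
  pl <- tm$points[tm$points$layer == 0, ]
  rho <- mandrel_radius(md, pl$z)
  rbar <- 0.5 * (rho[-1] + rho[-length(rho)])
  dth <- diff(pl$a) * pi / 180
  ds <- sqrt((rbar * dth)^2 + diff(pl$z)^2)
  speed <- ds / (ds / pl$feed[-1])       # by construction
  omega_rho <- (dth / (ds / pl$feed[-1])) * rbar
  expect_true((max(omega_rho) - min(omega_rho)) / mean(omega_rho) < 0.01)
  expect_true(all(abs(speed - 1000) < 1e-9))
})

test_that("mandrel standoff inverts the amplitude law for the line gap", {
  # neighbour gap 3.5 mm -> the A(6) = 3.5 anchor gives standoff 6
  mc <- mandrel_profile(c(0, 35), c(10, 10))
  tc <- plan_mandrel_coating(mc, n_lines = 10, surface_speed = 1000)
  expect_equal(unique(round(tc$points$standoff, 9)), 6)
})

test_that("embossing is additive, bounded and commutative", {
  base <- heightmap_surface(matrix(0, 30, 30), 1)
  expect_equal(emboss_feature(base, matrix(0, 5, 5), c(10, 10))$heights,
               base$heights)
  e <- emboss_feature(base, matrix(1, 5, 5), c(10, 10))
  expect_equal(sum(e$heights == 1), 25)
  expect_equal(sum(e$heights), 25)
  f1 <- matrix(1, 4, 4); f2 <- matrix(2, 3, 3)
  ab <- emboss_feature(emboss_feature(base, f1, c(2, 2)), f2, c(20, 20))
  ba <- emboss_feature(emboss_feature(base, f2, c(20, 20)), f1, c(2, 2))
  expect_equal(ab$heights, ba$heights)
  expect_error(emboss_feature(base, matrix(1, 5, 5), c(28, 28)), "outside")
})
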