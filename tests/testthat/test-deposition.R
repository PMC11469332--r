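# drape, voxelization, levelset meshing

test_that("vertical drape reproduces substrate heights exactly", {
  xy <- cbind(seq(0, 10, 0.5), 2 + sin(seq(0, 10, 0.5)))
  cv <- filament_curve(xy, radius = 0.1)
  d0 <- drape_on_surface(cv, plane_surface(0))
  expect_equal(unname(d0$coords[, 1:2]), unname(xy))
  expect_equal(unique(d0$coords[, 3]), 0)
  d2 <- drape_on_surface(cv, plane_surface(2), layer_z = 0.3)
  expect_equal(unique(d2$coords[, 3]), 2.3)
  # sampled sinusoidal surface: vertex heights equal surface heights
  xs <- 0:12
  hm <- heightmap_surface(outer(xs, xs, function(x, y) 0.5 * sin(x)), 1)
  ds <- drape_on_surface(cv, hm)
  expect_equal(ds$coords[, 3], surface_height(hm, xy[, 1], xy[, 2]))
})

test_that("voxelized straight filament recovers the cylinder volume", {
  cv <- filament_curve(cbind(seq(0, 10, 0.05), 0, 0), radius = 0.1)
  v <- voxelize_filaments(cv, voxel = 0.02)
  vol <- sum(v$occ) * v$voxel^3
  expect_true(abs(vol / (pi * 0.1^2 * 10) - 1) < 0.05)
})

test_that("voxelization is an idempotent, order-invariant union", {
  c1 <- filament_curve(cbind(seq(0, 5, 0.1), 0, 0), radius = 0.1)
  c2 <- filament_curve(cbind(0, seq(0, 5, 0.1), 0), radius = 0.1)
  bb <- rbind(c(-0.5, -0.5, -0.5), c(5.5, 5.5, 0.5))
  v1 <- voxelize_filaments(list(c1, c2), voxel = 0.05, bbox = bb)
  v2 <- voxelize_filaments(list(c2, c1, c1), voxel = 0.05, bbox = bb)
  expect_identical(v1$occ, v2$occ)
  # duplicated curve adds nothing
  v3 <- voxelize_filaments(list(c1, c1), voxel = 0.05, bbox = bb)
  v4 <- voxelize_filaments(c1, voxel = 0.05, bbox = bb)
  expect_identical(v3$occ, v4$occ)
})

test_that("voxelization guards resolution and empty input", {
  cv <- filament_curve(cbind(seq(0, 5, 0.1), 0, 0), radius = 0.1)
  expect_error(voxelize_filaments(cv, voxel = 0.2), "voxel")
  expect_error(voxelize_filaments(list()), "no filament curves")
})

test_that("levelset mesh area converges on closed-form solids", {
  # sphere R = 1 at 0.02 mm voxels: area within 3% of 4 pi
  sv <- sphere_volume(1, 0.02)
  m <- mesh_from_volume(sv)
  expect_true(abs(mesh_area(m) / (4 * pi) - 1) < 0.03)
  expect_true(abs(mesh_volume(m) / (4 * pi / 3) - 1) < 0.03)
  # cube side 1: area within 5% of 6
  h <- 0.02; n <- ceiling(1.4 / h)
  cs <- (seq_len(n) - 0.5) * h - 0.7
  gx <- array(cs, c(n, n, n)); gy <- aperm(gx, c(2, 1, 3))
  gz <- aperm(gx, c(3, 2, 1))
  cub <- voxel_volume(pmax(abs(gx), pmax(abs(gy), abs(gz))) <= 0.5, h,
                      rep(-0.7, 3))
  expect_true(abs(mesh_area(mesh_from_volume(cub)) / 6 - 1) < 0.05)
})

test_that("a single voxel meshes to a small closed positive solid", {
  occ <- array(FALSE, c(5, 5, 5)); occ[3, 3, 3] <- TRUE
  m <- mesh_from_volume(voxel_volume(occ, 0.1), smooth_passes = 0)
  expect_gt(nrow(m$vertices), 0)
  expect_gt(mesh_volume(m), 0)
  # every undirected edge is shared by exactly two faces (watertight)
  ed <- rbind(m$faces[, 1:2], m$faces[, 2:3], m$faces[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  expect_true(all(table(key) == 2))
  expect_error(mesh_from_volume(voxel_volume(array(FALSE, c(3, 3, 3)), 0.1)),
               "no occupied")
})

test_that("mesh and volume round trip with high Dice overlap", {
  cv <- filament_curve(cbind(seq(0, 5, 0.05), 0, 0), radius = 0.5)
  v <- voxelize_filaments(cv, voxel = 0.1)  # voxel = r/5
  m <- mesh_from_volume(v)
  v2 <- mesh_to_volume(m, like = v)
  expect_gte(dice_overlap(v, v2), 0.97)
})

test_that("the default three-layer coating stays within the height bound", {
  g <- gen_coating_volume(region = c(12, 12), seed = 3)
  hm <- compute_height_map(g$volume)
  expect_lte(hm$max, 1.3)
  expect_gte(hm$max, hm$mean)
  expect_gte(hm$mean, hm$min)
})

test_that("voxel volumes survive the TIFF stack round trip", {
  g <- gen_coating_volume(region = c(6, 6), seed = 2)
  path <- tempfile(fileext = ".tiff")
  write_voxel_tiff(g$volume, path)
  v2 <- read_voxel_tiff(path)
  expect_identical(v2$occ, g$volume$occ)
  expect_equal(v2$voxel, g$volume$voxel)
  expect_equal(v2$origin, g$volume$origin)
  unlink(c(path, paste0(path, ".json")))
})

test_that("meshes export to STL and OBJ", {
  m <- sphere_mesh(1, n = 8)
  stl <- tempfile(fileext = ".stl"); obj <- tempfile(fileext = ".obj")
  write_stl(m, stl); write_obj(m, obj)
  expect_true(grepl("^solid", readLines(stl, n = 1)))
  ol <- readLines(obj)
  expect_equal(sum(grepl("^v ", ol)), nrow(m$vertices))
  expect_equal(sum(grepl("^f ", ol)), nrow(m$faces))
  unlink(c(stl, obj))
})
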