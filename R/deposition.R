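# Deposition simulator: drape loop centerlines onto substrates, sweep rigid
# filament tubes into a binary voxel volume, and extract a levelset
# isosurface mesh (signed Euclidean distance transform + marching
# tetrahedra) -- the in-silico analogue of a segmented micro-CT scan.

#' Drape a planar filament curve onto a substrate
#'
#' Vertical projection (3-axis z-follow): the x/y coordinates are kept and
#' each vertex's z is set to the substrate height at that point plus
#' `layer_z`. Surfaces are assumed single-valued (non-intersecting
#' manifolds), so the drape is well defined.
#'
#' @param curve A planar [filament_curve()].
#' @param surface A substrate surface ([plane_surface()] or
#'   [heightmap_surface()]).
#' @param layer_z Additional height offset (mm), e.g. the layer stacking
#'   increment plus the filament radius.
#' @return A 3D [filament_curve()].
#' @export
drape_on_surface <- function(curve, surface, layer_z = 0) {
  stopifnot(inherits(curve, "filament_curve"))
  xy <- curve$coords[, 1:2, drop = FALSE]
  z <- surface_height(surface, xy[, 1], xy[, 2]) + layer_z
  filament_curve(cbind(xy, z = z), radius = curve$radius, layer = curve$layer)
}

#' Binary voxel volume
#'
#' Isotropic occupancy grid standing in for segmented micro-CT image data
#' (0 = background, 1 = coating). Voxel `[i, j, k]` has its center at
#' `origin + (c(i, j, k) - 0.5) * voxel`.
#'
#' @param occ Logical 3D array.
#' @param voxel Isotropic voxel size (mm).
#' @param origin Grid corner (mm).
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(occ, voxel, origin = c(0, 0, 0)) {
  stopifnot(is.array(occ), length(dim(occ)) == 3)
  check_positive(voxel, "voxel")
  structure(list(occ = occ, voxel = voxel, origin = origin),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("<voxel_volume> ", paste(dim(x$occ), collapse = " x "),
      " voxels @ ", x$voxel, " mm, ", sum(x$occ), " occupied\n", sep = "")
  invisible(x)
}

#' Voxelize filament curves
#'
#' A voxel is occupied iff its center lies within the filament radius of any
#' centerline segment (rigid-tube sweep; contacting filaments are unioned).
#' The voxel size must not exceed half the smallest filament radius, so a
#' tube cross-section is always resolved.
#'
#' @param curves A [filament_curve()] or list of them (3D coordinates).
#' @param voxel Voxel size (mm); default 0.05.
#' @param bbox Optional 2x3 matrix (rows: min, max) fixing the grid extent;
#'   default the curve bounds padded by the radius plus two voxels.
#' @return A [voxel_volume()].
#' @export
voxelize_filaments <- function(curves, voxel = 0.05, bbox = NULL) {
  if (inherits(curves, "filament_curve")) curves <- list(curves)
  if (length(curves) == 0) stop_invalid("no filament curves supplied")
  rmin <- min(vapply(curves, function(cv) cv$radius, numeric(1)))
  if (voxel > rmin / 2 + 1e-12)
    stop_invalid("voxel size ", voxel, " mm too coarse for filament radius ",
                 rmin, " mm; use voxel <= ", format(rmin / 2))
  segs <- do.call(rbind, lapply(curves, function(cv) {
    P <- cv$coords
    if (ncol(P) == 2) P <- cbind(P, 0)
    n <- nrow(P)
    if (n < 2) return(NULL)
    cbind(P[-n, 1], P[-n, 2], P[-n, 3], P[-1, 1], P[-1, 2], P[-1, 3], cv$radius)
  }))
  if (is.null(segs) || nrow(segs) == 0) stop_invalid("curves contain no segments")
  if (is.null(bbox)) {
    pad <- max(vapply(curves, function(cv) cv$radius, numeric(1))) + 2 * voxel
    lo <- pmin(apply(segs[, 1:3, drop = FALSE], 2, min),
               apply(segs[, 4:6, drop = FALSE], 2, min)) - pad
    hi <- pmax(apply(segs[, 1:3, drop = FALSE], 2, max),
               apply(segs[, 4:6, drop = FALSE], 2, max)) + pad
  } else {
    lo <- bbox[1, ]; hi <- bbox[2, ]
  }
  dims <- pmax(as.integer(ceiling((hi - lo) / voxel)), 1L)
  occ <- cpp_voxelize(segs, lo, voxel, dims)
  occ <- array(occ, dims)
  if (!any(occ)) stop_invalid("deposition produced no occupied voxels")
  voxel_volume(occ, voxel, lo)
}

#' Triangle mesh
#'
#' @param vertices Numeric n x 3 matrix (mm).
#' @param faces Integer m x 3 matrix of 1-based vertex indices, oriented
#'   with outward normals.
#' @return An object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces) {
  structure(list(vertices = vertices, faces = faces), class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat("<trimesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces\n", sep = "")
  invisible(x)
}

# separable 3-tap binomial smoothing of a 3D array (replicated edges)
smooth_field3 <- function(a) {
  n <- dim(a)
  for (d in 1:3) {
    perm <- switch(d, c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))
    b <- aperm(a, perm)
    nb <- dim(b)
    bm <- matrix(b, nb[1])
    sm <- 0.25 * bm[c(1, seq_len(nb[1] - 1)), , drop = FALSE] + 0.5 * bm +
      0.25 * bm[c(seq_len(nb[1] - 1) + 1, nb[1]), , drop = FALSE]
    a <- aperm(array(sm, nb), order(perm))
  }
  a
}

#' Levelset isosurface mesh from a binary volume
#'
#' Computes the signed Euclidean distance transform of the binary
#' segmentation (negative inside the structure), optionally smooths the
#' field with a small binomial kernel to suppress half-voxel quantization
#' ripple, and extracts the zero isosurface with marching tetrahedra. The
#' volume is padded with background so closed components yield watertight
#' meshes with outward-oriented faces.
#'
#' @param vol A non-empty [voxel_volume()].
#' @param smooth_passes Binomial smoothing passes on the signed field
#'   (default 1; 0 disables).
#' @return A [trimesh()].
#' @export
mesh_from_volume <- function(vol, smooth_passes = 1) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (!any(vol$occ)) stop_invalid("volume has no occupied voxels")
  pad <- 2L
  d0 <- dim(vol$occ)
  dims <- d0 + 2L * pad
  occ <- array(FALSE, dims)
  occ[pad + seq_len(d0[1]), pad + seq_len(d0[2]), pad + seq_len(d0[3])] <- vol$occ
  din <- cpp_edt_sq(as.logical(occ), dims)   # 0 inside the structure
  dout <- cpp_edt_sq(as.logical(!occ), dims) # 0 in the background
  # signed distance: negative inside, positive outside
  fld <- array((sqrt(din) - sqrt(dout)) * vol$voxel, dims)
  if (smooth_passes > 0)
    for (i in seq_len(smooth_passes)) fld <- smooth_field3(fld)
  origin <- vol$origin - pad * vol$voxel
  m <- cpp_march_tets(as.numeric(fld), dims, origin, vol$voxel)
  if (nrow(m$vertices) == 0) stop_invalid("isosurface extraction produced no mesh")
  trimesh(m$vertices, m$faces)
}

#' Mesh surface area
#' @param mesh A [trimesh()].
#' @return Total area (mm^2).
#' @export
mesh_area <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Enclosed mesh volume
#' @param mesh A watertight, outward-oriented [trimesh()].
#' @return Signed enclosed volume (mm^3); positive for outward orientation.
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  cc <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - cc[, 2] * b[, 3]) -
      b[, 1] * (a[, 2] * cc[, 3] - cc[, 2] * a[, 3]) +
      cc[, 1] * (a[, 2] * b[, 3] - b[, 2] * a[, 3])) / 6
}

#' Resample a mesh onto a voxel grid
#'
#' Voxelizes a closed mesh by z-column ray parity: a voxel is occupied iff
#' its center lies inside the surface. Used for round-trip validation of
#' the levelset meshing.
#'
#' @param mesh A closed [trimesh()].
#' @param voxel Voxel size (mm); ignored when `like` is given.
#' @param like Optional [voxel_volume()] whose grid (origin, size, dims) is
#'   reused, for voxel-wise comparison.
#' @return A [voxel_volume()].
#' @export
mesh_to_volume <- function(mesh, voxel = 0.05, like = NULL) {
  stopifnot(inherits(mesh, "trimesh"))
  if (!is.null(like)) {
    origin <- like$origin; voxel <- like$voxel; dims <- dim(like$occ)
  } else {
    lo <- apply(mesh$vertices, 2, min) - 2 * voxel
    hi <- apply(mesh$vertices, 2, max) + 2 * voxel
    origin <- lo
    dims <- pmax(as.integer(ceiling((hi - lo) / voxel)), 1L)
  }
  occ <- cpp_mesh_to_grid(mesh$vertices, mesh$faces, origin, voxel, dims)
  voxel_volume(array(occ, dims), voxel, origin)
}

#' Dice overlap of two voxel volumes on the same grid
#' @param a,b [voxel_volume()] objects with identical grids.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_overlap <- function(a, b) {
  stopifnot(identical(dim(a$occ), dim(b$occ)))
  2 * sum(a$occ & b$occ) / (sum(a$occ) + sum(b$occ))
}
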