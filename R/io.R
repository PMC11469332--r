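# File formats: voxel volumes as multi-page TIFF stacks with a JSON sidecar
# (voxel size, origin), 8-bit images as PNG/TIFF, meshes as ASCII STL/OBJ,
# mandrel profiles and calibration tables as CSV.

#' Read and write voxel volumes as TIFF stacks
#'
#' The occupancy grid is stored as one TIFF page per z slice (0/1 values);
#' grid geometry goes to `<path>.json`.
#'
#' @param vol A [voxel_volume()].
#' @param path Output TIFF path.
#' @return `write_voxel_tiff`: the path, invisibly. `read_voxel_tiff`: a
#'   [voxel_volume()].
#' @export
write_voxel_tiff <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  d <- dim(vol$occ)
  pages <- lapply(seq_len(d[3]), function(k) {
    # TIFF pages are [row, col]; store rows = y, cols = x
    t(matrix(as.numeric(vol$occ[, , k]), d[1], d[2]))
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  jsonlite::write_json(list(voxel = vol$voxel, origin = vol$origin, dims = d),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_voxel_tiff
#' @export
read_voxel_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- as.integer(meta$dims)
  occ <- array(FALSE, d)
  for (k in seq_len(d[3])) occ[, , k] <- t(pages[[k]]) > 0.5
  voxel_volume(occ, meta$voxel, meta$origin)
}

#' Read and write 8-bit grayscale images
#'
#' Images are numeric matrices in `[0, 255]` indexed `[ix, iy]` with pixel
#' centers at `(index - 0.5) * pixel size`; PNG files are transposed from
#' their row-major layout on read/write.
#'
#' @param img Numeric matrix in `[0, 255]` (write) .
#' @param path PNG file path.
#' @return `read_image_png`: a numeric matrix in `[0, 255]`.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(t(pmin(pmax(img / 255, 0), 1)), path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  t(m) * 255
}

#' Write a mesh as ASCII STL
#' @param mesh A [trimesh()].
#' @param path Output path.
#' @param name Solid name.
#' @return The path, invisibly.
#' @export
write_stl <- function(mesh, path, name = "ropecoil") {
  V <- mesh$vertices; F <- mesh$faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- n / pmax(sqrt(rowSums(n^2)), 1e-30)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", name), con)
  for (i in seq_len(nrow(F))) {
    writeLines(c(
      sprintf("facet normal %g %g %g", n[i, 1], n[i, 2], n[i, 3]),
      "  outer loop",
      sprintf("    vertex %g %g %g", V[F[i, 1:3], 1], V[F[i, 1:3], 2],
              V[F[i, 1:3], 3]),
      "  endloop", "endfacet"), con)
  }
  writeLines(paste("endsolid", name), con)
  invisible(path)
}

#' Write a mesh as Wavefront OBJ
#' @inheritParams write_stl
#' @return The path, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %g %g %g", mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' Read and write mandrel radius profiles as CSV
#'
#' @param mandrel A [mandrel_profile()].
#' @param path CSV path (columns `z_mm`, `radius_mm`).
#' @return `read_mandrel_csv`: a [mandrel_profile()].
#' @export
write_mandrel_csv <- function(mandrel, path) {
  write.csv(data.frame(z_mm = mandrel$z, radius_mm = mandrel$radius),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mandrel_csv
#' @export
read_mandrel_csv <- function(path) {
  d <- read.csv(path)
  mandrel_profile(d$z_mm, d$radius_mm)
}
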