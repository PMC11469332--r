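# Macro/micro pore quantification: mesh principal curvature by local
# quadric fitting, maximum-intensity-projection 2D void analysis, coating
# height maps, and SEM-style window/level + particle analysis.

#' Principal curvatures of a mesh surface
#'
#' Estimates per-vertex principal curvatures by fitting a quadric height
#' function over an n-ring vertex neighbourhood in the local tangent frame
#' (normal from area-weighted face normals), then taking the eigenvalues of
#' the shape operator. Mean curvature is reported as the mean of the
#' minimum and maximum curvature; with outward-oriented faces a convex
#' surface (sphere of radius R) has H = 1/R.
#'
#' @param mesh A [trimesh()] with outward-oriented faces.
#' @param ring Neighbourhood ring order (default 2; larger rings smooth
#'   the sub-voxel ripple of meshes extracted from voxel data).
#' @param sample Optional number of randomly sampled vertices to evaluate
#'   (default all); sampling uses a fixed internal seed so results are
#'   reproducible.
#' @return An object of class `curvature_field`: data frame with columns
#'   `kmin`, `kmax`, `H` (1/mm) per vertex; attribute `skipped` counts
#'   vertices with insufficient neighbourhoods.
#' @export
surface_curvature <- function(mesh, ring = 2, sample = NULL) {
  stopifnot(inherits(mesh, "trimesh"))
  V <- mesh$vertices; F <- mesh$faces
  nv <- nrow(V)
  # vertex normals (area-weighted face normals)
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  vn <- matrix(0, nv, 3)
  for (c in 1:3) {
    for (d in 1:3) {
      acc <- rowsum(fn[, d], F[, c])
      vn[as.integer(rownames(acc)), d] <- vn[as.integer(rownames(acc)), d] + acc
    }
  }
  vn <- vn / pmax(sqrt(rowSums(vn^2)), 1e-30)
  # 1-ring adjacency, indexed by vertex
  ed <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  ed <- rbind(ed, ed[, 2:1])
  adj <- split(ed[, 2], factor(ed[, 1], levels = seq_len(nv)))
  adj <- lapply(adj, unique)
  nbhd <- function(v) {
    nb <- adj[[v]]
    if (ring >= 2) {
      for (r in seq_len(ring - 1)) {
        nb <- unique(c(nb, unlist(adj[nb], use.names = FALSE)))
      }
    }
    nb[nb != v]
  }
  kmin <- kmax <- rep(NA_real_, nv)
  skipped <- 0L
  have <- which(lengths(adj) > 0)
  if (!is.null(sample) && sample < length(have))
    have <- sort(with_seed(20831L, base::sample(have, sample)))
  for (v in have) {
    nb <- nbhd(v)
    if (length(nb) < 5) { skipped <- skipped + 1L; next }
    n <- vn[v, ]
    t1 <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    t1 <- t1 - sum(t1 * n) * n
    t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(n[2] * t1[3] - n[3] * t1[2],
            n[3] * t1[1] - n[1] * t1[3],
            n[1] * t1[2] - n[2] * t1[1])
    P <- sweep(V[nb, , drop = FALSE], 2, V[v, ])
    u <- P %*% t1; w <- P %*% t2; q <- P %*% n
    X <- cbind(u^2, u * w, w^2, u, w)
    fit <- tryCatch(qr.coef(qr(X), q), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit)) { skipped <- skipped + 1L; next }
    a <- fit[1]; b <- fit[2]; cc <- fit[3]; d <- fit[4]; e <- fit[5]
    # shape operator: S = -G^{-1} B with first/second fundamental forms
    gden <- sqrt(1 + d^2 + e^2)
    B <- matrix(c(2 * a, b, b, 2 * cc), 2) / gden
    G <- matrix(c(1 + d^2, d * e, d * e, 1 + e^2), 2)
    S <- -solve(G, B)
    k <- sort(Re(eigen(S, only.values = TRUE)$values))
    kmin[v] <- k[1]; kmax[v] <- k[2]
  }
  ok <- !is.na(kmin)
  out <- data.frame(vertex = which(ok), kmin = kmin[ok], kmax = kmax[ok],
                    H = (kmin[ok] + kmax[ok]) / 2)
  structure(out, class = c("curvature_field", "data.frame"),
            skipped = skipped + (nv - length(have)))
}

#' Quantile summary of a curvature field
#'
#' Quartiles, deciles and ventiles of the per-vertex mean curvature,
#' matching the per-sample distribution summaries used for repeatability
#' assessment.
#'
#' @param cf A `curvature_field`.
#' @return A list with `quartiles`, `deciles`, `ventiles`, `median_H`.
#' @export
curvature_quantiles <- function(cf) {
  c(quantile_summary(cf$H), list(median_H = median(cf$H)))
}

#' Maximum intensity projection of a voxel volume
#'
#' Collapses the volume along z: a pixel is set iff any voxel in its column
#' is occupied, producing the single binary 2D image used for void
#' analysis of thin coatings.
#'
#' @param vol A [voxel_volume()].
#' @return A list with `mask` (logical matrix `[ix, iy]`) and `pixel_size`
#'   (mm).
#' @export
max_intensity_projection <- function(vol) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (!any(vol$occ)) stop_invalid("volume has no occupied voxels")
  mask <- rowSums(vol$occ, dims = 2) > 0
  list(mask = mask, pixel_size = vol$voxel)
}

#' 2D void analysis
#'
#' Voids are connected clusters of background pixels within the coating
#' footprint of a binary image (filament = TRUE). Background components
#' touching the image border are excluded by default, restricting voids to
#' the interior of the coating; set `exclude_border = FALSE` to count open
#' background as void.
#'
#' @param img Logical matrix, TRUE = filament.
#' @param pixel_size Pixel edge length (mm).
#' @param exclude_border Drop border-connected background (default TRUE).
#' @param connectivity 8 (default) or 4.
#' @return An object of class `void_stats`: list with `areas` (mm^2),
#'   `mean_area`, `sd_area`, `count` and `quantiles`.
#' @export
analyze_voids <- function(img, pixel_size, exclude_border = TRUE,
                          connectivity = 8) {
  img <- as.matrix(img)
  if (!any(img) || all(img))
    stop_invalid("image must contain both filament and background pixels")
  bg <- !img
  lab <- array(cpp_label2d(as.logical(bg), dim(img), as.integer(connectivity)),
               dim(img))
  if (exclude_border) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    lab[lab %in% border] <- 0L
  }
  counts <- tabulate(lab[lab > 0L])
  counts <- counts[counts > 0]
  areas <- counts * pixel_size^2
  structure(list(areas = areas,
                 mean_area = if (length(areas)) mean(areas) else NA_real_,
                 sd_area = if (length(areas) > 1) sd(areas) else NA_real_,
                 count = length(areas),
                 quantiles = if (length(areas)) quantile_summary(areas) else NULL),
            class = "void_stats")
}

#' Coating height map from a voxel volume
#'
#' Per-pixel height of the topmost occupied voxel above the substrate
#' plane, with mean/max/min summaries over occupied columns only.
#'
#' @param vol A [voxel_volume()].
#' @param substrate_z Height of the substrate plane (mm, default 0).
#' @return An object of class `height_map_result`: list with `heights`
#'   (matrix, NA for empty columns), `mean`, `max`, `min` (mm).
#' @export
compute_height_map <- function(vol, substrate_z = 0) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (!any(vol$occ)) stop_invalid("volume has no occupied voxels")
  d <- dim(vol$occ)
  # topmost occupied slice per column: max over k of k * occ
  top <- array(0L, d[1:2])
  for (k in seq_len(d[3])) {
    sl <- vol$occ[, , k]
    top[sl] <- k
  }
  h <- ifelse(top > 0L, vol$origin[3] + top * vol$voxel - substrate_z, NA_real_)
  occd <- h[!is.na(h)]
  structure(list(heights = h, mean = mean(occd), max = max(occd),
                 min = min(occd)),
            class = "height_map_result")
}

#' Window/level contrast adjustment
#'
#' Linear display ramp used to prepare SEM micrographs for thresholding:
#' grey values at or below `L - W/2` map to 0, at or above `L + W/2` to
#' 255, linear in between. The defaults (W = 88, L = 141) are the settings
#' used for micropore segmentation.
#'
#' @param img Numeric matrix of 8-bit grey values (0-255).
#' @param W Window width in grey levels (default 88).
#' @param L Window centre level (default 141).
#' @return Matrix of remapped grey values in `[0, 255]`.
#' @export
window_level <- function(img, W = 88, L = 141) {
  check_positive(W, "W")
  if (L < 0 || L > 255) stop_invalid("L must be in [0, 255]")
  pmin(pmax((img - (L - W / 2)) / W * 255, 0), 255)
}

#' Binarize a window/levelled image at mid-grey
#'
#' Pores image dark: pixels below the ramp midpoint (127.5) are pore
#' candidates.
#'
#' @param img Numeric matrix in `[0, 255]`.
#' @return Logical matrix, TRUE = pore.
#' @export
binarize_midgrey <- function(img) {
  img < 127.5
}

#' Particle filter configuration
#'
#' Window/level and particle-analysis acceptance settings for micropore
#' quantification: particles below the minimum area or outside the
#' circularity band (`4 pi A / P^2`) are rejected. Defaults match the
#' published segmentation recipe (W = 88, L = 141, area >= 0.38 um^2,
#' circularity 0.10-1.00).
#'
#' @param window,level Window/level in grey values.
#' @param min_area Minimum particle area (um^2).
#' @param circularity Length-2 acceptance band.
#' @return An object of class `particle_filter_config`.
#' @export
particle_filter_config <- function(window = 88, level = 141,
                                   min_area = 0.38,
                                   circularity = c(0.10, 1.00)) {
  if (any(circularity < 0 | circularity > 1) || circularity[1] > circularity[2])
    stop_invalid("circularity bounds must satisfy 0 <= lo <= hi <= 1")
  structure(list(window = window, level = level, min_area = min_area,
                 circularity = circularity),
            class = "particle_filter_config")
}

#' Particle (micropore) analysis of a binary image
#'
#' Labels 8-connected particles, measures area and boundary-chain perimeter
#' (Vossepoel-Smeulders corrected chain code:
#' `P = 0.980 Ne + 1.406 No - 0.091 Nc`), computes circularity
#' `C = 4 pi A / P^2` (capped at 1), and keeps particles passing the area
#' and circularity filters. Equivalent diameters are `2 sqrt(A / pi)`.
#'
#' @param mask Logical matrix, TRUE = particle (pore).
#' @param pixel_size Pixel edge length (um).
#' @param config A [particle_filter_config()].
#' @param roi Optional logical region-of-interest mask; particles are
#'   clipped to it and the per-area density uses the ROI area.
#' @return An object of class `pore_stats`: list with per-particle `areas`
#'   (um^2), `diameters` (um), `circularity`, the `median_diameter`,
#'   `quantiles` (50/90/95%), `span` (max - min diameter), `count`,
#'   `roi_area_um2` and `count_per_area` (um^-2).
#' @export
analyze_particles <- function(mask, pixel_size, config = particle_filter_config(),
                              roi = NULL) {
  mask <- as.matrix(mask)
  if (!is.null(roi)) {
    if (!any(roi)) stop_invalid("ROI mask is empty")
    mask <- mask & roi
    roi_area <- sum(roi) * pixel_size^2
  } else {
    roi_area <- length(mask) * pixel_size^2
  }
  lab <- array(cpp_label2d(as.logical(mask), dim(mask), 8L), dim(mask))
  nlab <- max(lab)
  if (nlab == 0L) {
    return(structure(list(areas = numeric(), diameters = numeric(),
                          circularity = numeric(), median_diameter = NA_real_,
                          quantiles = c(`50%` = NA_real_, `90%` = NA_real_,
                                        `95%` = NA_real_),
                          span = NA_real_, count = 0L,
                          roi_area_um2 = roi_area, count_per_area = 0),
                     class = "pore_stats"))
  }
  px_areas <- tabulate(lab[lab > 0L], nbins = nlab)
  per_px <- cpp_region_perimeters(lab, dim(mask), nlab)
  areas <- px_areas * pixel_size^2
  per <- per_px * pixel_size
  circ <- pmin(4 * pi * areas / per^2, 1)
  keep <- areas >= config$min_area &
    circ >= config$circularity[1] & circ <= config$circularity[2]
  areas <- areas[keep]; circ <- circ[keep]
  d <- 2 * sqrt(areas / pi)
  qs <- if (length(d)) quantile(d, c(0.5, 0.9, 0.95)) else
    c(`50%` = NA_real_, `90%` = NA_real_, `95%` = NA_real_)
  structure(list(areas = areas, diameters = d, circularity = circ,
                 median_diameter = if (length(d)) median(d) else NA_real_,
                 quantiles = qs,
                 span = if (length(d)) max(d) - min(d) else NA_real_,
                 count = length(d), roi_area_um2 = roi_area,
                 count_per_area = length(d) / roi_area),
            class = "pore_stats")
}

#' Grayscale micropore pipeline
#'
#' Convenience wrapper: window/level an 8-bit SEM-style image, binarize at
#' mid-grey, and run [analyze_particles()].
#'
#' @param img Numeric matrix of grey values (0-255).
#' @param pixel_size Pixel edge length (um).
#' @param config A [particle_filter_config()].
#' @param roi Optional ROI mask.
#' @return A `pore_stats` object.
#' @export
analyze_pore_image <- function(img, pixel_size,
                               config = particle_filter_config(), roi = NULL) {
  wl <- window_level(img, config$window, config$level)
  analyze_particles(binarize_midgrey(wl), pixel_size, config, roi)
}

#' Cross-sample pore summary
#'
#' Aggregates `pore_stats` across regions of interest: per-ROI median
#' equivalent diameters, the median and standard deviation of those
#' medians, and the mean pores-per-area.
#'
#' @param stats_list List of `pore_stats`.
#' @return A list with `per_roi_median`, `median_of_medians`,
#'   `sd_of_medians`, `mean_count_per_area`, `n_roi`.
#' @export
summarize_pores <- function(stats_list) {
  if (inherits(stats_list, "pore_stats")) stats_list <- list(stats_list)
  if (length(stats_list) < 1) stop_invalid("need at least one ROI")
  med <- vapply(stats_list, function(s) s$median_diameter, numeric(1))
  cpa <- vapply(stats_list, function(s) s$count_per_area, numeric(1))
  list(per_roi_median = med,
       median_of_medians = median(med),
       sd_of_medians = if (length(med) > 1) sd(med) else 0,
       mean_count_per_area = mean(cpa),
       n_roi = length(stats_list))
}
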