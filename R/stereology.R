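# Stereological quantification of peri-implant tissue: orthogonal-intercept
# capsule thickness, point-count volume fractions, vessel metrics, and
# polygonal area measurement.

#' Stereological test grid
#'
#' A square grid of test lines (both orientations) superimposed on a
#' section image.
#'
#' @param spacing Line spacing (um).
#' @param offset Grid origin offset `c(x, y)` (um).
#' @param angle Grid orientation (deg, default 0).
#' @return An object of class `grid_config`.
#' @export
grid_config <- function(spacing, offset = c(0, 0), angle = 0) {
  check_positive(spacing, "spacing")
  structure(list(spacing = spacing, offset = offset, angle = angle),
            class = "grid_config")
}

# sample a logical mask (pixel centers at (i - 0.5) * px) with bilinear
# interpolation; >= 0.5 counts as inside
mask_inside <- function(mask, x, y, px) {
  bilinear_px(mask * 1, x, y, px) >= 0.5
}

# intersections of a polyline with the family of lines {p . m = off_k}
polyline_line_hits <- function(P, m, offs) {
  s <- P %*% m
  hits <- list()
  for (off in offs) {
    d <- s - off
    # transversal crossings only; a segment lying exactly in the test line
    # is a tangency and yields no intercept
    cross <- which((d[-length(d)] <= 0 & d[-1] > 0) |
                   (d[-length(d)] >= 0 & d[-1] < 0))
    for (i in cross) {
      t <- d[i] / (d[i] - d[i + 1])
      hits[[length(hits) + 1L]] <-
        c(i = i, x = unname(P[i, 1] + t * (P[i + 1, 1] - P[i, 1])),
          y = unname(P[i, 2] + t * (P[i + 1, 2] - P[i, 2])))
    }
  }
  if (length(hits)) do.call(rbind, hits) else NULL
}

# unit tangent at interface vertex i from a 5-point window
tangent5 <- function(P, i) {
  n <- nrow(P)
  a <- max(1L, i - 2L); b <- min(n, i + 2L)
  t <- P[b, ] - P[a, ]
  t / sqrt(sum(t^2))
}

#' Orthogonal-intercept capsule thickness
#'
#' At every intersection of the tissue-device interface with a test line of
#' the stereological grid, a chord is drawn orthogonal to the local
#' interface tangent (5-point window) from the interface to the far edge of
#' the capsule mask, and its length is measured; the estimate is the
#' arithmetic mean of the intercepts. The classical true-thickness
#' correction for orthogonal intercepts (`8/(3 pi)` times the harmonic
#' mean) is available via `correction = TRUE` but is off by default, the
#' arithmetic mean being the conventional report.
#'
#' Exit points are located to sub-pixel precision by bisecting the bilinear
#' interpolation of the mask across the 0.5 level.
#'
#' @param interface n x 2 matrix: interface polyline (um), in the image
#'   frame (pixel centers at `(index - 0.5) * pixel_size`).
#' @param mask Logical capsule mask, `[ix, iy]`.
#' @param grid A [grid_config()].
#' @param pixel_size Pixel edge (um).
#' @param correction Also report the harmonic-mean true thickness.
#' @param max_chord Abort a chord beyond this length (um); default the
#'   image diagonal.
#' @return An object of class `thickness_estimate`: list with `intercepts`
#'   (um), `mean`, `count`, `skipped`, and optionally `true_thickness`.
#' @export
orthogonal_intercept_thickness <- function(interface, mask, grid, pixel_size,
                                           correction = FALSE,
                                           max_chord = NULL) {
  interface <- as.matrix(interface)
  mask <- as.matrix(mask)
  if (!any(mask)) stop_invalid("capsule mask is empty")
  if (is.null(max_chord))
    max_chord <- sqrt(sum((dim(mask) * pixel_size)^2))
  th <- grid$angle * pi / 180
  dirs <- list(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  bb <- apply(interface, 2, range)
  hits <- NULL
  for (u in dirs) {
    m <- c(-u[2], u[1])  # line normal
    s0 <- sum(grid$offset * m)
    pr <- rbind(bb[, 1], bb[, 2], c(bb[1, 1], bb[2, 2]),
                c(bb[2, 1], bb[1, 2])) %*% m
    ks <- seq(floor((min(pr) - s0) / grid$spacing),
              ceiling((max(pr) - s0) / grid$spacing))
    offs <- s0 + ks * grid$spacing
    h <- polyline_line_hits(interface, m, offs)
    if (!is.null(h)) hits <- rbind(hits, h)
  }
  if (is.null(hits))
    stop_invalid("no interface/test-line intersections; use a finer grid")
  step <- pixel_size / 4
  intercepts <- numeric(0)
  skipped <- 0L
  for (r in seq_len(nrow(hits))) {
    q <- hits[r, c("x", "y")]
    tg <- tangent5(interface, hits[r, "i"])
    nrm <- c(-tg[2], tg[1])
    probe <- 0.75 * pixel_size
    in_p <- mask_inside(mask, q[1] + probe * nrm[1], q[2] + probe * nrm[2],
                        pixel_size)
    in_m <- mask_inside(mask, q[1] - probe * nrm[1], q[2] - probe * nrm[2],
                        pixel_size)
    if (in_p == in_m) { skipped <- skipped + 1L; next }
    if (in_m) nrm <- -nrm
    # march until the chord exits the capsule (vectorised sampling)
    ts <- seq(step, max_chord, by = step)
    inside <- mask_inside(mask, q[1] + ts * nrm[1], q[2] + ts * nrm[2],
                          pixel_size)
    # the rasterized band may start within the first pixel; enter the
    # capsule first (within one pixel of the interface), then find the exit
    first_in <- which(inside)[1]
    if (is.na(first_in) || ts[first_in] > 1.5 * pixel_size) {
      skipped <- skipped + 1L; next
    }
    rel_out <- which(!inside[-seq_len(first_in)])[1]
    if (is.na(rel_out)) { skipped <- skipped + 1L; next }
    first_out <- first_in + rel_out
    t_out <- ts[first_out]
    t_in <- ts[first_out - 1]
    f <- function(tt) bilinear_px(mask * 1, q[1] + tt * nrm[1],
                                  q[2] + tt * nrm[2], pixel_size) - 0.5
    lo <- t_in; hi <- t_out
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      if (f(mid) >= 0) lo <- mid else hi <- mid
    }
    intercepts <- c(intercepts, (lo + hi) / 2)
  }
  if (!length(intercepts))
    stop_invalid("no measurable intercepts; use a finer grid")
  out <- list(intercepts = intercepts, mean = mean(intercepts),
              count = length(intercepts), skipped = skipped)
  if (correction)
    out$true_thickness <- (8 / (3 * pi)) * 1 / mean(1 / intercepts)
  structure(out, class = "thickness_estimate")
}

#' Point-count volume fraction
#'
#' Superimposes the grid's point lattice on the section and reports the
#' fraction of points falling on the target phase among points falling on
#' the reference phase; by the Delesse/point-counting principle this
#' converges to the areal (and volume) fraction as the spacing shrinks.
#'
#' @param target Logical mask of the phase of interest, `[ix, iy]`.
#' @param reference Logical reference-phase mask (same grid).
#' @param grid A [grid_config()]; spacing in um.
#' @param pixel_size Pixel edge (um).
#' @return Estimated fraction in `[0, 1]`, with attributes `points_target`
#'   and `points_reference`.
#' @export
point_count_volume_fraction <- function(target, reference, grid, pixel_size) {
  target <- as.matrix(target); reference <- as.matrix(reference)
  if (!any(reference)) stop_invalid("reference mask is empty")
  th <- grid$angle * pi / 180
  u <- c(cos(th), sin(th)); v <- c(-sin(th), cos(th))
  ext <- dim(reference) * pixel_size
  kmax <- ceiling(sqrt(sum(ext^2)) / grid$spacing)
  ks <- (-kmax):kmax
  gx <- grid$offset[1] + outer(ks * grid$spacing * u[1], ks * grid$spacing * v[1], "+")
  gy <- grid$offset[2] + outer(ks * grid$spacing * u[2], ks * grid$spacing * v[2], "+")
  ix <- round(gx / pixel_size + 0.5); iy <- round(gy / pixel_size + 0.5)
  ok <- ix >= 1 & iy >= 1 & ix <= nrow(reference) & iy <= ncol(reference)
  idx <- cbind(ix[ok], iy[ok])
  on_ref <- reference[idx]
  n_ref <- sum(on_ref)
  if (n_ref == 0) stop_invalid("no grid points fall on the reference mask")
  n_tar <- sum(target[idx] & on_ref)
  structure(n_tar / n_ref, points_target = n_tar, points_reference = n_ref)
}

#' Vessel metrics from profile counts
#'
#' Standard stereological identities for vessel profiles counted on a
#' section: profiles per area `N_A = n / A`, length density `Lv = 2 N_A`
#' (isotropic-section estimator), radial diffusion distance
#' `r = 1 / sqrt(pi Lv)`, volume fraction from summed profile areas, and
#' the maturity ratio of flagged (e.g. alpha-SMA positive) profiles.
#'
#' @param n_profiles Number of vessel profiles counted.
#' @param reference_area Reference section area (mm^2).
#' @param profile_areas Optional vessel profile areas (mm^2) for the volume
#'   fraction.
#' @param mature Optional logical vector (length `n_profiles`) flagging
#'   mature vessels.
#' @return An object of class `vessel_metrics`: list with `N_A` (mm^-2),
#'   `Lv` (mm^-2), `radial_diffusion_um`, `Vv`, `maturity_ratio`.
#' @export
vessel_metrics <- function(n_profiles, reference_area, profile_areas = NULL,
                           mature = NULL) {
  check_positive(reference_area, "reference_area")
  if (n_profiles < 0) stop_invalid("n_profiles must be >= 0")
  N_A <- n_profiles / reference_area
  Lv <- 2 * N_A
  rdd <- if (Lv > 0) 1000 / sqrt(pi * Lv) else NA_real_
  Vv <- if (!is.null(profile_areas)) sum(profile_areas) / reference_area
        else NA_real_
  ratio <- if (!is.null(mature) && n_profiles > 0) sum(mature) / n_profiles
           else NA_real_
  structure(list(N_A = N_A, Lv = Lv, radial_diffusion_um = rdd,
                 Vv = Vv, maturity_ratio = ratio),
            class = "vessel_metrics")
}

#' Polygonal region area
#'
#' Shoelace area of a simple polygon delineated on a section image,
#' expressed in mm^2.
#'
#' @param vertices n x 2 matrix of polygon vertices (pixel units or mm).
#' @param pixel_size Scale (mm per unit); default 1.
#' @return Area (mm^2), independent of vertex orientation.
#' @export
region_area <- function(vertices, pixel_size = 1) {
  P <- as.matrix(vertices)
  if (nrow(P) < 3) stop_invalid("polygon needs at least 3 vertices")
  ring <- rbind(P, P[1, ])
  si <- cpp_self_intersections(ring[, 1], ring[, 2])
  if (nrow(si) > 0) {
    # the closing edge is adjacent to the first edge; ignore that contact
    n <- nrow(P)
    real <- si[!(si[, 1] == 1 & si[, 2] == n), , drop = FALSE]
    if (nrow(real) > 0) stop_invalid("polygon is self-intersecting")
  }
  x <- P[, 1]; y <- P[, 2]
  a <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  a * pixel_size^2
}
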