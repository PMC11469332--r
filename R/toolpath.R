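# Toolpath planning over planes, scanned height-map surfaces and rotary
# mandrels, plus the coating layer specification.

#' Substrate surfaces
#'
#' Three substrate descriptions are supported: an infinite plane at height
#' `z0`; a single-valued height-map surface sampled on a regular grid (the
#' digital form of a laser surface scan), with grid nodes at
#' `origin + (index - 1) * pitch`; and a rotary mandrel described by its
#' radius profile along the axis.
#'
#' @param z0 Plane height (mm).
#' @return A substrate object (`plane_surface`, `heightmap_surface` or
#'   `mandrel_profile`).
#' @export
plane_surface <- function(z0 = 0) {
  structure(list(z0 = z0), class = c("plane_surface", "substrate_surface"))
}

#' @rdname plane_surface
#' @param heights Matrix of surface heights (mm), indexed `[ix, iy]`.
#' @param pitch Grid pitch (mm per pixel).
#' @param origin Grid origin `c(x, y)` (mm) of node `[1, 1]`.
#' @export
heightmap_surface <- function(heights, pitch, origin = c(0, 0)) {
  heights <- as.matrix(heights)
  if (!all(is.finite(heights))) stop_invalid("heights must be finite")
  check_positive(pitch, "pitch")
  structure(list(heights = heights, pitch = pitch, origin = origin),
            class = c("heightmap_surface", "substrate_surface"))
}

#' @rdname plane_surface
#' @param z Axial sample positions (mm), strictly increasing.
#' @param radius Radii at `z` (mm), all positive.
#' @export
mandrel_profile <- function(z, radius) {
  if (any(diff(z) <= 0)) stop_invalid("z must be strictly increasing")
  if (any(radius <= 0)) stop_invalid("all radii must be > 0")
  structure(list(z = z, radius = radius),
            class = c("mandrel_profile", "substrate_surface"))
}

#' Surface height lookup
#'
#' Bilinear height of a substrate at planar positions; errors for points
#' outside a height-map grid.
#'
#' @param surface A substrate surface.
#' @param x,y Query coordinates (mm).
#' @return Heights (mm).
#' @export
surface_height <- function(surface, x, y) {
  UseMethod("surface_height")
}

#' @export
surface_height.plane_surface <- function(surface, x, y) {
  rep(surface$z0, length(x))
}

#' @export
surface_height.heightmap_surface <- function(surface, x, y) {
  hm <- surface$heights
  u <- (x - surface$origin[1]) / surface$pitch
  v <- (y - surface$origin[2]) / surface$pitch
  if (any(u < -1e-9 | v < -1e-9 |
          u > nrow(hm) - 1 + 1e-9 | v > ncol(hm) - 1 + 1e-9))
    stop_invalid("query point outside height-map grid")
  u <- pmin(pmax(u, 0), nrow(hm) - 1)
  v <- pmin(pmax(v, 0), ncol(hm) - 1)
  i0 <- pmin(floor(u), nrow(hm) - 2); j0 <- pmin(floor(v), ncol(hm) - 2)
  fu <- u - i0; fv <- v - j0
  hm[cbind(i0 + 1, j0 + 1)] * (1 - fu) * (1 - fv) +
    hm[cbind(i0 + 2, j0 + 1)] * fu * (1 - fv) +
    hm[cbind(i0 + 1, j0 + 2)] * (1 - fu) * fv +
    hm[cbind(i0 + 2, j0 + 2)] * fu * fv
}

#' Mandrel radius lookup
#'
#' @param mandrel A [mandrel_profile()].
#' @param z Axial positions (mm).
#' @return Interpolated radii (mm).
#' @export
mandrel_radius <- function(mandrel, z) {
  approx(mandrel$z, mandrel$radius, xout = z, rule = 2)$y
}

#' Coating layer specification
#'
#' An ordered list of LRC layers, each with a deposition angle, loop
#' amplitude, overlap frequency and row spacing. The default three-layer
#' coating deposits rows along the machine X axis, then at 45 and 135
#' degrees; a six-layer coating replicates that sequence twice. Row spacing
#' defaults to the amplitude so that adjacent loop rows touch.
#'
#' @param n_layers Number of layers (default 3).
#' @param angles Layer angles (deg), recycled over the default cycle
#'   `c(0, 45, 135)`.
#' @param amplitude Loop amplitude per layer (mm), recycled.
#' @param frequency Loop frequency per layer, recycled.
#' @param spacing Row spacing (mm), default equal to the amplitude.
#' @param filament_d Filament diameter (mm).
#' @return An object of class `coating_spec` with a `layers` data frame.
#' @examples
#' coating_spec()            # standard three-layer 0/45/135 coating
#' coating_spec(n_layers = 6) # twice-replicated sequence
#' @export
coating_spec <- function(n_layers = 3, angles = c(0, 45, 135),
                         amplitude = 3.5, frequency = 1,
                         spacing = NULL, filament_d = 0.2) {
  if (n_layers < 1) stop_invalid("layer count must be >= 1")
  angles <- rep_len(angles, n_layers)
  amplitude <- rep_len(amplitude, n_layers)
  frequency <- rep_len(frequency, n_layers)
  spacing <- if (is.null(spacing)) amplitude else rep_len(spacing, n_layers)
  if (any(spacing <= 0)) stop_invalid("spacing must be > 0")
  structure(list(layers = data.frame(angle = angles, amplitude = amplitude,
                                     frequency = frequency, spacing = spacing),
                 filament_d = filament_d),
            class = "coating_spec")
}

new_toolpath <- function(points, substrate = "plane", meta = list()) {
  structure(list(points = points, substrate = substrate, meta = meta),
            class = "toolpath")
}

#' @export
print.toolpath <- function(x, ...) {
  cat("<toolpath> ", nrow(x$points), " points, ",
      length(unique(x$points$layer)), " layer(s), substrate: ",
      x$substrate, "\n", sep = "")
  invisible(x)
}

# offsets of parallel rows across a span [smin, smax]
row_offsets <- function(smin, smax, spacing, convention = c("edge", "half")) {
  convention <- match.arg(convention)
  span <- smax - smin
  if (spacing > span) {
    warning("row spacing exceeds region span: emitting a single row")
    return(mean(c(smin, smax)))
  }
  if (convention == "edge") seq(smin, smax, by = spacing)
  else seq(smin + spacing / 2, smax, by = spacing)
}

# clip the line {base + t*dir} to an axis-aligned rectangle; NULL if outside
clip_line_rect <- function(base, dir, rect) {
  tmin <- -Inf; tmax <- Inf
  for (d in 1:2) {
    if (abs(dir[d]) < 1e-12) {
      if (base[d] < rect[1, d] - 1e-9 || base[d] > rect[2, d] + 1e-9) return(NULL)
    } else {
      t1 <- (rect[1, d] - base[d]) / dir[d]
      t2 <- (rect[2, d] - base[d]) / dir[d]
      tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
    }
  }
  if (tmin > tmax) return(NULL)
  rbind(base + tmin * dir, base + tmax * dir)
}

#' Plan a planar multi-layer LRC coating
#'
#' Lays out parallel nozzle rows for each coating layer at the layer angle,
#' clipped to a rectangular region, in serpentine order. The nozzle standoff
#' per layer is obtained by inverting the amplitude-height law for the layer
#' amplitude; the commanded flow follows the frequency law so the deposited
#' loops have the requested overlap. Layer `k` is raised by
#' `k * layer_dz` (default one filament diameter).
#'
#' @param region Either `c(width, height)` (mm, origin at 0) or
#'   `c(xmin, xmax, ymin, ymax)`.
#' @param spec A [coating_spec()].
#' @param model An [amplitude_model()].
#' @param params A [print_params()]; supplies the feed velocity and nozzle.
#' @param layer_dz Vertical increment per layer (mm); default the filament
#'   diameter.
#' @param convention Row placement: `"edge"` (rows on both region edges,
#'   default) or `"half"` (first row at half spacing).
#' @return A `toolpath` object; `$points` has columns x, y, z, a, standoff,
#'   feed, flow, layer.
#' @export
plan_planar_coating <- function(region, spec = coating_spec(),
                                model = amplitude_model(),
                                params = print_params(140, feed_V = 600),
                                layer_dz = NULL,
                                convention = c("edge", "half")) {
  convention <- match.arg(convention)
  rect <- parse_region(region)
  if (any(rect[2, ] <= rect[1, ])) stop_invalid("region is degenerate")
  if (is.null(layer_dz)) layer_dz <- spec$filament_d
  pts <- list()
  for (li in seq_len(nrow(spec$layers))) {
    lay <- spec$layers[li, ]
    rows <- plan_layer_rows(rect, lay$angle, lay$spacing, convention)
    h <- height_for_amplitude(lay$amplitude, model)
    flow <- 2.2 * lay$frequency * params$feed_V * pi * (params$nozzle_d / 2)^2
    z <- (li - 1) * layer_dz + h
    for (ri in seq_along(rows)) {
      ends <- rows[[ri]]
      if (ri %% 2 == 0) ends <- ends[2:1, , drop = FALSE]
      pts[[length(pts) + 1L]] <- data.frame(
        x = ends[, 1], y = ends[, 2], z = z, a = NA_real_,
        standoff = h, feed = params$feed_V, flow = flow, layer = li - 1L)
    }
  }
  new_toolpath(do.call(rbind, pts), substrate = "plane",
               meta = list(region = rect, spec = spec,
                           convention = convention, layer_dz = layer_dz))
}

parse_region <- function(region) {
  if (length(region) == 2) rbind(c(0, 0), region)
  else if (length(region) == 4) rbind(region[c(1, 3)], region[c(2, 4)])
  else stop_invalid("region must have length 2 or 4")
}

plan_layer_rows <- function(rect, angle, spacing, convention) {
  th <- angle * pi / 180
  dir <- c(cos(th), sin(th))
  nrm <- c(-sin(th), cos(th))
  corners <- rbind(c(rect[1, 1], rect[1, 2]), c(rect[2, 1], rect[1, 2]),
                   c(rect[1, 1], rect[2, 2]), c(rect[2, 1], rect[2, 2]))
  s <- corners %*% nrm
  offs <- row_offsets(min(s), max(s), spacing, convention)
  rows <- lapply(offs, function(o) clip_line_rect(o * nrm, dir, rect))
  rows[!vapply(rows, is.null, logical(1))]
}

#' Plan a coating or spray pass over a scanned surface
#'
#' Projects the planar layer pattern vertically onto a height-map surface
#' (3-axis z-follow): at every sampled point the nozzle z equals the local
#' surface height plus the standoff. In `"loop"` mode the LRC layer rows
#' are draped; in `"spray"` mode a serpentine raster is emitted at the spray
#' standoff (85 mm for the atomizing nozzle).
#'
#' @param surface A [heightmap_surface()].
#' @param spec A [coating_spec()] (loop mode).
#' @param standoff Nozzle standoff (mm): defaults to the amplitude-law
#'   height in loop mode; required in spray mode (e.g. 85).
#' @param mode `"loop"` or `"spray"`.
#' @param region Planar region to coat; default the full grid extent.
#' @param sample_step Along-row sampling step (mm) for the z-follow.
#' @param spray_spacing Raster spacing in spray mode (mm).
#' @param model,params,layer_dz,convention As in [plan_planar_coating()].
#' @return A `toolpath` object.
#' @export
plan_heightmap_coating <- function(surface, spec = coating_spec(),
                                   standoff = NULL,
                                   mode = c("loop", "spray"),
                                   region = NULL, sample_step = NULL,
                                   spray_spacing = 2,
                                   model = amplitude_model(),
                                   params = print_params(140, feed_V = 600),
                                   layer_dz = NULL,
                                   convention = c("edge", "half")) {
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  stopifnot(inherits(surface, "heightmap_surface"))
  if (is.null(region)) {
    region <- c(surface$origin[1],
                surface$origin[1] + (nrow(surface$heights) - 1) * surface$pitch,
                surface$origin[2],
                surface$origin[2] + (ncol(surface$heights) - 1) * surface$pitch)
  }
  rect <- parse_region(region)
  if (is.null(sample_step)) sample_step <- max(surface$pitch, 0.5)
  if (mode == "spray") {
    if (is.null(standoff)) stop_invalid("spray mode requires a standoff (mm)")
    offs <- row_offsets(rect[1, 2], rect[2, 2], spray_spacing, "edge")
    pts <- list()
    for (ri in seq_along(offs)) {
      xs <- seq(rect[1, 1], rect[2, 1], by = sample_step)
      if (tail(xs, 1) < rect[2, 1]) xs <- c(xs, rect[2, 1])
      if (ri %% 2 == 0) xs <- rev(xs)
      ys <- rep(offs[ri], length(xs))
      zs <- surface_height(surface, xs, ys) + standoff
      pts[[ri]] <- data.frame(x = xs, y = ys, z = zs, a = NA_real_,
                              standoff = standoff, feed = params$feed_V,
                              flow = params$flow_Q, layer = 0L)
    }
    return(new_toolpath(do.call(rbind, pts), substrate = "heightmap",
                        meta = list(mode = "spray", spray_spacing = spray_spacing)))
  }
  if (is.null(layer_dz)) layer_dz <- spec$filament_d
  pts <- list()
  for (li in seq_len(nrow(spec$layers))) {
    lay <- spec$layers[li, ]
    h <- if (is.null(standoff)) height_for_amplitude(lay$amplitude, model) else standoff
    flow <- 2.2 * lay$frequency * params$feed_V * pi * (params$nozzle_d / 2)^2
    rows <- plan_layer_rows(rect, lay$angle, lay$spacing, convention)
    for (ri in seq_along(rows)) {
      ends <- rows[[ri]]
      if (ri %% 2 == 0) ends <- ends[2:1, , drop = FALSE]
      len <- sqrt(sum((ends[2, ] - ends[1, ])^2))
      nstep <- max(2L, ceiling(len / sample_step) + 1L)
      tt <- seq(0, 1, length.out = nstep)
      xs <- ends[1, 1] + tt * (ends[2, 1] - ends[1, 1])
      ys <- ends[1, 2] + tt * (ends[2, 2] - ends[1, 2])
      zs <- surface_height(surface, xs, ys) + (li - 1) * layer_dz + h
      pts[[length(pts) + 1L]] <- data.frame(
        x = xs, y = ys, z = zs, a = NA_real_, standoff = h,
        feed = params$feed_V, flow = flow, layer = li - 1L)
    }
  }
  new_toolpath(do.call(rbind, pts), substrate = "heightmap",
               meta = list(mode = "loop", spec = spec))
}

#' Plan a helical mandrel coating with constant linear velocity
#'
#' Each layer is printed as a continuous helix of `n_lines` turns along the
#' mandrel axis. The rotational rate at every axial position is set so that
#' the substrate surface moves under the nozzle at a constant linear
#' velocity (CLV): `omega(z) = v / rho(z)`. The nozzle standoff at each
#' point is computed by measuring the meridional gap to the neighbouring
#' helical line and inverting the amplitude law so that printed loop rows
#' touch; amplitudes outside the calibrated model range are clamped with a
#' warning.
#'
#' @param mandrel A [mandrel_profile()].
#' @param n_lines Integer vector: helical line count per layer (e.g.
#'   `c(34, 21, 13)` inner to outer).
#' @param surface_speed Target substrate surface speed (mm/min).
#' @param model An [amplitude_model()].
#' @param params A [print_params()].
#' @param samples_per_turn Angular sampling of the helix.
#' @param layer_dz Radial increment per layer (mm); default filament
#'   diameter.
#' @return A `toolpath`; points carry axial `z`, rotary angle `a` (deg),
#'   radial nozzle position `x = rho(z) + standoff + layer offset`, and
#'   `feed` equal to the commanded surface speed. `$meta$n_lines` records
#'   the per-layer line counts.
#' @export
plan_mandrel_coating <- function(mandrel, n_lines, surface_speed = 1000,
                                 model = amplitude_model(),
                                 params = print_params(140, feed_V = 600),
                                 samples_per_turn = 72, layer_dz = 0.2) {
  stopifnot(inherits(mandrel, "mandrel_profile"))
  zr <- range(mandrel$z)
  length_z <- diff(zr)
  pts <- list()
  a_rng <- amplitude_from_height(model$height_range, model)
  for (li in seq_along(n_lines)) {
    turns <- n_lines[li]
    pitch <- length_z / turns
    nstep <- max(2L, turns * samples_per_turn)
    th <- seq(0, 2 * pi * turns, length.out = nstep)
    z <- zr[1] + length_z * th / (2 * pi * turns)
    rho <- mandrel_radius(mandrel, z)
    # meridional slope d rho / d z via central differences
    slope <- c(diff(rho[1:2]) / diff(z[1:2]),
               (rho[-(1:2)] - rho[1:(length(rho) - 2)]) /
                 (z[-(1:2)] - z[1:(length(z) - 2)]),
               diff(rho[(length(rho) - 1):length(rho)]) /
                 diff(z[(length(z) - 1):length(z)]))
    gap <- pitch * sqrt(1 + slope^2)
    a_req <- pmin(pmax(gap, a_rng[1]), a_rng[2])
    if (any(gap < a_rng[1] - 1e-9 | gap > a_rng[2] + 1e-9))
      warning("required amplitude outside calibrated model range; clamped")
    h <- height_for_amplitude(a_req, model)
    flow <- 2.2 * 1 * surface_speed * pi * (params$nozzle_d / 2)^2
    pts[[li]] <- data.frame(
      x = rho + h + (li - 1) * layer_dz, y = 0, z = z,
      a = th * 180 / pi, standoff = h,
      feed = surface_speed, flow = flow, layer = li - 1L)
  }
  new_toolpath(do.call(rbind, pts), substrate = "mandrel",
               meta = list(n_lines = n_lines, surface_speed = surface_speed))
}

#' Emboss a feature onto a height-map surface
#'
#' Adds a feature height map (e.g. a nipple/areola analog) onto a base
#' surface at a given position. The operation is additive: heights inside
#' the feature footprint are raised by the feature height, everything else
#' is unchanged, so disjoint features commute.
#'
#' @param surface A [heightmap_surface()].
#' @param feature Height matrix (mm) at the same pitch as `surface`.
#' @param position `c(x, y)` (mm) of the feature's `[1, 1]` node on the
#'   surface; snapped to the nearest grid node.
#' @return The modified [heightmap_surface()].
#' @export
emboss_feature <- function(surface, feature, position = c(0, 0)) {
  stopifnot(inherits(surface, "heightmap_surface"))
  feature <- as.matrix(feature)
  i0 <- round((position[1] - surface$origin[1]) / surface$pitch) + 1L
  j0 <- round((position[2] - surface$origin[2]) / surface$pitch) + 1L
  i1 <- i0 + nrow(feature) - 1L
  j1 <- j0 + ncol(feature) - 1L
  if (i0 < 1 || j0 < 1 || i1 > nrow(surface$heights) || j1 > ncol(surface$heights))
    stop_invalid("feature footprint falls outside the surface grid")
  surface$heights[i0:i1, j0:j1] <- surface$heights[i0:i1, j0:j1] + feature
  surface
}
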