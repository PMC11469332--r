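# Seeded synthetic-data generators: simulated LRC coating volumes,
# SEM-like micropore fields, capsule sections and flared mandrel profiles,
# each carrying its ground truth so downstream estimators can be validated
# against known answers.

#' Simulate a deposited LRC coating volume
#'
#' Plans the layer rows of a coating over a planar region, generates the
#' steady-coil trochoid centerline of every row (optionally with lateral
#' row-position jitter mimicking deposition variability), drapes the
#' layers with the configured stacking increment, and voxelizes the
#' filament tubes -- producing the in-silico analogue of a segmented
#' micro-CT scan together with its ground-truth centerlines.
#'
#' Layer `k`'s centerline plane sits at `r + k (d_f - penetration r)` above
#' the substrate, where `r` is the filament radius and `d_f` the filament
#' diameter: consecutive layers interpenetrate by a fraction of the radius
#' to mimic contact fusion.
#'
#' @param spec A [coating_spec()].
#' @param params A [print_params()].
#' @param region Planar region (mm), as in [plan_planar_coating()].
#' @param jitter Row lateral jitter standard deviation (mm, default 0).
#' @param voxel Voxel size (mm, default 0.05).
#' @param seed RNG seed.
#' @param penetration Inter-layer penetration as a fraction of the
#'   filament radius (default 0.25).
#' @param model,convention Passed to the planner.
#' @return A list with `volume` ([voxel_volume()], substrate plane at
#'   z = 0), `curves` (list of 3D [filament_curve()]), and `region`.
#' @export
gen_coating_volume <- function(spec = coating_spec(),
                               params = print_params(140, feed_V = 600),
                               region = c(20, 20), jitter = 0, voxel = 0.05,
                               seed = 1, penetration = 0.25,
                               model = amplitude_model(),
                               convention = "edge") {
  rect <- parse_region(region)
  r_fil <- spec$filament_d / 2
  dz_layer <- spec$filament_d - penetration * r_fil
  curves <- with_seed(seed, {
    out <- list()
    for (li in seq_len(nrow(spec$layers))) {
      lay <- spec$layers[li, ]
      lspec <- loop_spec(lay$amplitude, frequency = lay$frequency,
                         filament_d = spec$filament_d)
      rows <- plan_layer_rows(rect, lay$angle, lay$spacing, convention)
      z_c <- r_fil + (li - 1) * dz_layer
      for (ends in rows) {
        d <- ends[2, ] - ends[1, ]
        len <- sqrt(sum(d^2))
        if (len < 2 * lay$amplitude) next
        d <- d / len
        nrm <- c(-d[2], d[1])
        off <- if (jitter > 0) rnorm(1, 0, jitter) else 0
        cv <- generate_loop_centerline(lspec, params, path_length = len)
        xy <- cv$coords
        pts <- cbind(ends[1, 1] + xy[, 1] * d[1] + (xy[, 2] + off) * nrm[1],
                     ends[1, 2] + xy[, 1] * d[2] + (xy[, 2] + off) * nrm[2],
                     z_c)
        out[[length(out) + 1L]] <- filament_curve(pts, radius = r_fil,
                                                  layer = li - 1L)
      }
    }
    out
  })
  if (!length(curves)) stop_invalid("region too small for the requested loops")
  amax <- max(spec$layers$amplitude)
  lo <- c(rect[1, ] - amax / 2 - r_fil - 2 * voxel, 0)
  hi <- c(rect[2, ] + amax / 2 + r_fil + 2 * voxel,
          r_fil + (nrow(spec$layers) - 1) * dz_layer + r_fil + 2 * voxel)
  vol <- voxelize_filaments(curves, voxel = voxel, bbox = rbind(lo, hi))
  list(volume = vol, curves = curves, region = rect)
}

# low-frequency noise field: coarse Gaussian grid, bilinear upsampling
smooth_noise <- function(nx, ny, cells = 8, sd = 1) {
  g <- matrix(rnorm((cells + 2)^2, 0, sd), cells + 2)
  cell_px <- max(nx, ny) / cells
  xs <- (seq_len(nx) - 0.5) + cell_px   # one-cell pad avoids edge falloff
  ys <- (seq_len(ny) - 0.5) + cell_px
  outer(xs, ys, function(x, y) bilinear_px(g, x, y, cell_px))
}

#' Generate an SEM-like micropore image with ground truth
#'
#' Dark elliptical pores on a bright, softly textured background. Pore
#' equivalent diameters are lognormal with the given median; ellipse aspect
#' ratios are drawn in `[1, 2]` so most, but not all, pores pass the
#' circularity filter. Defaults are calibrated to the sprayed-membrane
#' micropore population (median 4.1 um).
#'
#' @param n_pores Number of pores (default 120, typical of a 200x
#'   SEM region of interest).
#' @param median_um Median equivalent diameter (um, default 4.1).
#' @param sigma_log Lognormal sdlog of diameters (default 0.3).
#' @param size_px Image side (pixels, default 900, i.e. a 225 um field).
#' @param pixel_um Pixel size (um, default 0.25).
#' @param aspect_range Ellipse aspect ratio range.
#' @param bg,fg Background/pore grey values.
#' @param noise_sd Background texture amplitude (grey values).
#' @param seed RNG seed.
#' @param max_cover Maximum allowed pore area fraction (overlap guard).
#' @return A list with `image` (grey matrix `[ix, iy]`, 0-255), `truth`
#'   (data frame: x, y, diameter_um, area_um2), `pixel_um`.
#' @export
gen_pore_image <- function(n_pores = 120, median_um = 4.1, sigma_log = 0.3,
                           size_px = 900, pixel_um = 0.25,
                           aspect_range = c(1, 2), bg = 200, fg = 60,
                           noise_sd = 6, seed = 1, max_cover = 0.05) {
  with_seed(seed, {
    d <- median_um * exp(rnorm(n_pores, 0, sigma_log))
    q <- runif(n_pores, aspect_range[1], aspect_range[2])
    ang <- runif(n_pores, 0, pi)
    a <- d / 2 * sqrt(q)   # semi-axes (um); area pi a b = pi (d/2)^2
    b <- d / 2 / sqrt(q)
    ext_um <- size_px * pixel_um
    cover <- sum(pi * a * b) / ext_um^2
    if (cover > max_cover)
      stop_invalid("pore density too high (cover ", round(cover, 3),
                   "); reduce n_pores or enlarge the image")
    # place pores without mutual overlap (rejection sampling) so the truth
    # table maps one-to-one onto measurable particles
    marg <- max(a) + 2 * pixel_um
    cx <- cy <- numeric(n_pores)
    for (p in seq_len(n_pores)) {
      placed <- FALSE
      for (try in 1:400) {
        px0 <- runif(1, marg, ext_um - marg)
        py0 <- runif(1, marg, ext_um - marg)
        if (p == 1 || all(sqrt((cx[seq_len(p - 1)] - px0)^2 +
                               (cy[seq_len(p - 1)] - py0)^2) >
                          a[seq_len(p - 1)] + a[p] + 2 * pixel_um)) {
          cx[p] <- px0; cy[p] <- py0; placed <- TRUE; break
        }
      }
      if (!placed)
        stop_invalid("could not place pores without overlap; reduce density")
    }
    img <- bg + smooth_noise(size_px, size_px, cells = 8, sd = noise_sd)
    for (p in seq_len(n_pores)) {
      ir <- ceiling((cx[p] - a[p]) / pixel_um):ceiling((cx[p] + a[p]) / pixel_um)
      jr <- ceiling((cy[p] - a[p]) / pixel_um):ceiling((cy[p] + a[p]) / pixel_um)
      ir <- ir[ir >= 1 & ir <= size_px]; jr <- jr[jr >= 1 & jr <= size_px]
      px <- (rep(ir, length(jr)) - 0.5) * pixel_um - cx[p]
      py <- (rep(jr, each = length(ir)) - 0.5) * pixel_um - cy[p]
      u <- px * cos(ang[p]) + py * sin(ang[p])
      w <- -px * sin(ang[p]) + py * cos(ang[p])
      ins <- (u / a[p])^2 + (w / b[p])^2 <= 1
      if (any(ins))
        img[cbind(rep(ir, length(jr))[ins], rep(jr, each = length(ir))[ins])] <- fg
    }
    img <- pmin(pmax(img, 0), 255)
    list(image = img,
         truth = data.frame(x = cx, y = cy, diameter_um = d,
                            area_um2 = pi * a * b),
         pixel_um = pixel_um)
  })
}

#' Generate a synthetic capsule section with known mean thickness
#'
#' A fibrous-capsule band of spatially varying thickness around a wavy
#' tissue-device interface: the interface is a smooth sinusoid mixture, the
#' local thickness field a smooth positive function with the requested mean
#' and variation, and the capsule mask is the region swept between the
#' interface and its normal offset by the local thickness. The true mean
#' thickness (average of the local thickness field along the interface) is
#' returned for estimator validation.
#'
#' @param thickness_mean Mean capsule thickness (um).
#' @param thickness_sd Amplitude of the spatial thickness variation (um).
#' @param waviness Interface waviness amplitude (um); 0 gives a straight
#'   interface and a parallel band.
#' @param width_um Section width (um).
#' @param pixel_um Mask pixel size (um).
#' @param wavelength_um Interface/thickness variation wavelength (um).
#' @param seed RNG seed.
#' @return A list with `interface` (polyline, um), `mask` (logical,
#'   `[ix, iy]`), `truth_mean` (um), `pixel_um`.
#' @export
gen_capsule_section <- function(thickness_mean = 150, thickness_sd = 0,
                                waviness = 0, width_um = 2000, pixel_um = 2,
                                wavelength_um = 600, seed = 1) {
  check_positive(thickness_mean, "thickness_mean")
  # the normal offset is only a valid band while the interface curvature
  # radius exceeds the local thickness; warn when the band would fold
  kmax <- waviness * ((2 * pi / wavelength_um)^2 +
                        0.4 * (2.3 * 2 * pi / wavelength_um)^2)
  if (kmax * (thickness_mean + 1.5 * thickness_sd) > 0.8)
    warning("interface curvature too high for the requested thickness; ",
            "the capsule band folds and the stored truth mean is unreliable ",
            "(increase wavelength_um or reduce waviness)")
  with_seed(seed, {
    ph <- runif(4, 0, 2 * pi)
    xs <- seq(0, width_um, by = pixel_um / 2)
    y0 <- 2.5 * waviness + 40
    yi <- y0 + if (waviness > 0)
      waviness * (sin(2 * pi * xs / wavelength_um + ph[1]) +
                  0.4 * sin(2 * pi * 2.3 * xs / wavelength_um + ph[2]))
      else rep(0, length(xs))
    tfield <- thickness_mean + if (thickness_sd > 0)
      thickness_sd * (sin(2 * pi * xs / (1.7 * wavelength_um) + ph[3]) +
                      0.5 * sin(2 * pi * 3.1 * xs / (1.7 * wavelength_um) + ph[4]))
      else rep(0, length(xs))
    tfield <- pmax(tfield, thickness_mean / 5)
    # unit normal of the interface (pointing into the capsule, +y side)
    dy <- c(diff(yi) / diff(xs), 0)
    dy[length(dy)] <- dy[length(dy) - 1]
    nx <- -dy / sqrt(1 + dy^2)
    ny <- 1 / sqrt(1 + dy^2)
    xo <- xs + tfield * nx
    yo <- yi + tfield * ny
    poly <- rbind(cbind(xs, yi), cbind(rev(xo), rev(yo)))
    npx <- ceiling(width_um / pixel_um)
    npy <- ceiling((max(yo) + 40) / pixel_um)
    mask <- matrix(FALSE, npx, npy)
    ex1 <- poly[, 1]; ey1 <- poly[, 2]
    ex2 <- c(ex1[-1], ex1[1]); ey2 <- c(ey1[-1], ey1[1])
    for (iy in seq_len(npy)) {
      yl <- (iy - 0.5) * pixel_um
      sel <- (ey1 <= yl & ey2 > yl) | (ey2 <= yl & ey1 > yl)
      if (!any(sel)) next
      xc <- sort(ex1[sel] + (yl - ey1[sel]) / (ey2[sel] - ey1[sel]) *
                   (ex2[sel] - ex1[sel]))
      for (p in seq_len(length(xc) %/% 2)) {
        i0 <- max(ceiling(xc[2 * p - 1] / pixel_um + 0.5), 1L)
        i1 <- min(floor(xc[2 * p] / pixel_um + 0.5), npx)
        if (i1 >= i0) mask[i0:i1, iy] <- TRUE
      }
    }
    keep <- seq(1, length(xs), by = 2)
    list(interface = cbind(x = xs[keep], y = yi[keep]),
         mask = mask, truth_mean = mean(tfield), pixel_um = pixel_um)
  })
}

#' Generate a flared mandrel radius profile
#'
#' Constant base radius with a C1-smooth raised-cosine flare, mimicking a
#' non-uniform-circumference tubular substrate.
#'
#' @param base_radius Base radius (mm).
#' @param flare_radius Peak radius at the flare centre (mm).
#' @param flare_center Axial position of the flare centre (mm).
#' @param flare_width Full width of the flare (mm).
#' @param length Mandrel length (mm).
#' @param dz Axial sampling step (mm).
#' @return A [mandrel_profile()].
#' @export
gen_flared_mandrel <- function(base_radius = 8, flare_radius = 14,
                               flare_center = 30, flare_width = 24,
                               length = 60, dz = 0.25) {
  check_positive(base_radius, "base_radius")
  check_positive(flare_radius, "flare_radius")
  z <- seq(0, length, by = dz)
  bump <- ifelse(abs(z - flare_center) < flare_width / 2,
                 0.5 * (1 + cos(2 * pi * (z - flare_center) / flare_width)),
                 0)
  mandrel_profile(z, base_radius + (flare_radius - base_radius) * bump)
}
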