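# Parametric model of the liquid rope-coil (LRC) effect: flow calibration,
# buckling-regime classification, loop frequency and amplitude laws, and
# trochoid centerline generation for the steady-coil regime.

#' Print parameter set
#'
#' Bundles the extrusion state of a direct-ink-writing print head: volumetric
#' flow, nozzle inner diameter, print-head (feed) velocity and nozzle standoff
#' height. The default nozzle diameter corresponds to a 27-gauge conical tip
#' (200 um inner diameter).
#'
#' @param flow_Q Volumetric flow rate (uL/min).
#' @param nozzle_d Nozzle inner diameter (mm). Default 0.2.
#' @param feed_V Print-head velocity (mm/min).
#' @param height_h Nozzle standoff above the substrate (mm).
#' @return An object of class `print_params`.
#' @examples
#' print_params(flow_Q = 140, feed_V = 600, height_h = 6)
#' @export
print_params <- function(flow_Q, nozzle_d = 0.2, feed_V, height_h = 6) {
  check_positive(nozzle_d, "nozzle_d")
  check_positive(feed_V, "feed_V")
  check_positive(height_h, "height_h")
  if (!is.numeric(flow_Q) || length(flow_Q) != 1L || !is.finite(flow_Q) || flow_Q < 0)
    stop_invalid("flow_Q must be a single non-negative finite number")
  structure(list(flow_Q = flow_Q, nozzle_d = nozzle_d,
                 feed_V = feed_V, height_h = height_h),
            class = "print_params")
}

#' Flow calibration table
#'
#' Maps commanded volumetric flow (uL/min) to the effective extruded filament
#' length rate (mm/min). With no table the identity calibration is used, i.e.
#' the filament is an incompressible cylinder of the nozzle diameter:
#' `L = Q / (pi (d/2)^2)`. A measured table captures the nonlinearity of real
#' extrusion at high flow; it is interpolated piecewise linearly through the
#' origin.
#'
#' @param table Optional data frame with columns `commanded_Q_uL_min` and
#'   `L_mm_min`. Must be monotone non-decreasing in both columns.
#' @param extrapolate One of `"error"` (default) or `"linear"`: behaviour for
#'   flows outside the table range.
#' @return An object of class `flow_calibration`.
#' @export
flow_calibration <- function(table = NULL, extrapolate = c("error", "linear")) {
  extrapolate <- match.arg(extrapolate)
  if (!is.null(table)) {
    if (!all(c("commanded_Q_uL_min", "L_mm_min") %in% names(table)))
      stop_invalid("calibration table needs columns commanded_Q_uL_min, L_mm_min")
    table <- table[order(table$commanded_Q_uL_min), , drop = FALSE]
    if (any(diff(table$L_mm_min) < 0))
      stop_invalid("calibration: L must be monotone non-decreasing in Q")
    if (table$commanded_Q_uL_min[1] > 0) {
      table <- rbind(data.frame(commanded_Q_uL_min = 0, L_mm_min = 0), table)
    } else if (table$L_mm_min[table$commanded_Q_uL_min == 0] != 0) {
      stop_invalid("calibration: L(0) must be 0")
    }
  }
  structure(list(table = table, extrapolate = extrapolate),
            class = "flow_calibration")
}

#' Read a flow calibration table from CSV
#'
#' @param path CSV file with columns `commanded_Q_uL_min`, `L_mm_min`.
#' @param ... Passed to [flow_calibration()].
#' @return A `flow_calibration` object.
#' @export
read_flow_calibration <- function(path, ...) {
  flow_calibration(read.csv(path), ...)
}

#' Effective filament length rate
#'
#' Converts a commanded volumetric flow into the length of filament extruded
#' per unit time. Under the identity calibration this is the cylinder
#' relation `L = Q / (pi (d/2)^2)`; with a measured calibration table the
#' value is interpolated, capturing the nonlinearity of volumetric extrusion
#' at higher flow rates.
#'
#' @param params A [print_params()] object.
#' @param cal A [flow_calibration()] object; default identity.
#' @return Filament length rate L (mm/min).
#' @examples
#' effective_filament_rate(print_params(140, feed_V = 600)) # ~4456.3 mm/min
#' @export
effective_filament_rate <- function(params, cal = flow_calibration()) {
  stopifnot(inherits(params, "print_params"), inherits(cal, "flow_calibration"))
  Q <- params$flow_Q
  if (Q < 0) stop_invalid("flow_Q must be non-negative")
  if (is.null(cal$table))
    return(Q / (pi * (params$nozzle_d / 2)^2))
  tb <- cal$table
  rng <- range(tb$commanded_Q_uL_min)
  if (Q > rng[2] && cal$extrapolate == "error")
    stop_invalid("flow ", Q, " uL/min outside calibration range [",
                 rng[1], ", ", rng[2], "]")
  approx(tb$commanded_Q_uL_min, tb$L_mm_min, xout = Q, rule = 2,
         method = "linear")$y +
    if (Q > rng[2] && cal$extrapolate == "linear") {
      n <- nrow(tb)
      slope <- (tb$L_mm_min[n] - tb$L_mm_min[n - 1]) /
        (tb$commanded_Q_uL_min[n] - tb$commanded_Q_uL_min[n - 1])
      (Q - rng[2]) * slope
    } else 0
}

#' Regime thresholds
#'
#' Ordered boundaries on the dimensionless ratio `rho = L / V` (filament
#' length rate over print-head velocity) separating the buckling regimes of a
#' viscous thread deposited on a moving substrate. The steady-coil onset at
#' `rho = 2.2` is the measured value for the silicone ink; the lower
#' boundaries (straight-to-meander, meander-to-alternating) are approximate
#' and configurable.
#'
#' @param meander Onset of meandering (default 1.0, approximate).
#' @param alternating Onset of alternating loops (default 1.6, approximate).
#' @param steady Onset of steady coiling (default 2.2).
#' @return An object of class `regime_thresholds`.
#' @export
regime_thresholds <- function(meander = 1.0, alternating = 1.6, steady = 2.2) {
  b <- c(meander = meander, alternating = alternating, steady = steady)
  if (any(diff(b) <= 0) || any(b <= 0))
    stop_invalid("regime boundaries must be strictly increasing and positive")
  structure(as.list(b), class = "regime_thresholds")
}

#' Classify the deposition regime
#'
#' The loop regime is a monotone step function of `rho = L / V`: STRAIGHT
#' below the meander onset, then MEANDER, ALTERNATING_LOOPS, and STEADY_COIL
#' at and above `rho = 2.2`. In the steady-coil regime further flow increase
#' does not change loop shape, only overlap (frequency).
#'
#' @param L Filament length rate (mm/min); vectorised.
#' @param V Print-head velocity (mm/min).
#' @param thresholds A [regime_thresholds()] object.
#' @return Character vector of regime labels.
#' @examples
#' classify_regime(c(600, 1400, 2200), 1000)
#' @export
classify_regime <- function(L, V, thresholds = regime_thresholds()) {
  if (!is.numeric(V) || any(V <= 0)) stop_invalid("feed velocity V must be > 0")
  if (any(L < 0)) stop_invalid("filament rate L must be >= 0")
  rho <- L / V
  # boundary membership: the approximate lower boundaries close the lower
  # regime (rho = 1.0 still lays a straight line); the measured steady-coil
  # onset belongs to the coil (rho = 2.2 is already coiling)
  ifelse(rho >= thresholds$steady, "STEADY_COIL",
         ifelse(rho <= thresholds$meander, "STRAIGHT",
                ifelse(rho <= thresholds$alternating, "MEANDER",
                       "ALTERNATING_LOOPS")))
}

#' Loop overlap frequency
#'
#' In the steady-coil regime, increasing flow increases loop overlap, termed
#' frequency: F = 1 at the coiling onset (`rho = 2.2`), 2 when loops are
#' doubly overlapped, 0.5 for a sparse coil. The default law is
#' `F = (L/V) / onset` with the onset divisor calibratable.
#'
#' @param L Filament length rate (mm/min).
#' @param V Print-head velocity (mm/min).
#' @param onset Coiling onset ratio (default 2.2).
#' @return Dimensionless frequency, strictly increasing in `L`, decreasing
#'   in `V`.
#' @export
loop_frequency <- function(L, V, onset = 2.2) {
  if (!is.numeric(V) || any(V <= 0)) stop_invalid("feed velocity V must be > 0")
  (L / V) / onset
}

#' Amplitude-height calibration
#'
#' Loop amplitude grows near-linearly with nozzle standoff height:
#' `A(h) = a h + b`. The default calibration is anchored at the standard
#' coating setting, A(6 mm) = 3.5 mm, with slope 0.45 mm/mm, valid over the
#' calibrated deposition heights 3-9 mm.
#'
#' @param slope Amplitude gain a (mm per mm of standoff), must be > 0.
#' @param intercept Intercept b (mm).
#' @param height_range Calibrated standoff range (mm).
#' @return An object of class `amplitude_model`.
#' @export
amplitude_model <- function(slope = 0.45, intercept = 3.5 - 0.45 * 6,
                            height_range = c(3, 9)) {
  check_positive(slope, "slope")
  structure(list(slope = slope, intercept = intercept,
                 height_range = height_range),
            class = "amplitude_model")
}

#' Loop amplitude from nozzle height
#'
#' @param h Nozzle standoff (mm); warns outside the calibrated range.
#' @param model An [amplitude_model()].
#' @return Amplitude A (mm).
#' @examples
#' amplitude_from_height(6) # 3.5 mm at the standard coating setting
#' @export
amplitude_from_height <- function(h, model = amplitude_model()) {
  if (any(h <= 0)) stop_invalid("height must be > 0")
  if (any(h < model$height_range[1] | h > model$height_range[2]))
    warning("height outside calibrated range [",
            model$height_range[1], ", ", model$height_range[2], "] mm")
  model$slope * h + model$intercept
}

#' Nozzle height needed for a target amplitude
#'
#' Exact inverse of the linear amplitude law.
#'
#' @param A Target loop amplitude (mm).
#' @param model An [amplitude_model()].
#' @return Standoff height h (mm).
#' @export
height_for_amplitude <- function(A, model = amplitude_model()) {
  if (any(A <= model$intercept))
    stop_invalid("requested amplitude ", format(min(A)),
                 " mm is at or below the model intercept (non-physical)")
  (A - model$intercept) / model$slope
}

# along-travel extent of the closed lobe of the translated-coiling trochoid
# x(phi) = p phi/(2 pi) + R sin(phi), y(phi) = R cos(phi)
trochoid_lobe_width <- function(p, R) {
  phi1 <- acos(-p / (2 * pi * R))
  2 * R * sin(phi1) - p * (1 - phi1 / pi)
}

# advance-per-period p that realises the requested lobe width at radius R
trochoid_advance_for_width <- function(R, width) {
  if (width <= 0 || width >= 2 * R)
    stop_invalid("lobe width must lie in (0, amplitude)")
  uniroot(function(p) trochoid_lobe_width(p, R) - width,
          interval = c(1e-9, 2 * pi * R * (1 - 1e-9)), tol = 1e-12)$root
}

# arc length of one trochoid period
trochoid_period_arclen <- function(p, R) {
  stats::integrate(function(phi)
    sqrt((p / (2 * pi) + R * cos(phi))^2 + (R * sin(phi))^2),
    0, 2 * pi, rel.tol = 1e-10)$value
}

# ratio between the along-travel loop width and the amplitude at frequency 1
# (the standard coating calibration: width 2.2 mm at amplitude 3.5 mm)
WIDTH_RATIO <- 2.2 / 3.5

#' Loop geometry specification
#'
#' Describes the loop geometry deposited in a given regime: amplitude (the
#' transverse peak-to-peak extent), width (the along-travel extent of a
#' single loop at frequency 1; defaults to the standard calibration ratio
#' `2.2/3.5` of the amplitude), overlap frequency, and the filament diameter
#' after extrusion (equal to the nozzle inner diameter for this ink).
#'
#' @param amplitude Loop amplitude A (mm).
#' @param frequency Loop overlap frequency (dimensionless, default 1).
#' @param width Single-loop along-travel width at frequency 1 (mm); default
#'   `amplitude * 2.2 / 3.5`.
#' @param filament_d Filament diameter (mm), default 0.2.
#' @param regime Regime label, default `"STEADY_COIL"`.
#' @return An object of class `loop_spec`.
#' @examples
#' loop_spec(3.5) # the standard coating loop: width 2.2 mm
#' @export
loop_spec <- function(amplitude, frequency = 1, width = NULL,
                      filament_d = 0.2, regime = "STEADY_COIL") {
  check_positive(amplitude, "amplitude")
  check_positive(frequency, "frequency")
  check_positive(filament_d, "filament_d")
  if (is.null(width)) width <- amplitude * WIDTH_RATIO
  if (width <= 0 || width >= amplitude)
    stop_invalid("width must lie in (0, amplitude) for a steady coil")
  structure(list(amplitude = amplitude, width = width, frequency = frequency,
                 filament_d = filament_d, regime = regime),
            class = "loop_spec")
}

#' Filament curve
#'
#' A polyline centerline of a deposited filament, planar (2 columns) or
#' draped in 3D (3 columns), with its tube radius.
#'
#' @param coords Numeric matrix of vertex coordinates (mm), 2 or 3 columns.
#' @param radius Filament radius (mm).
#' @param layer Integer layer index (0-based).
#' @return An object of class `filament_curve`.
#' @export
filament_curve <- function(coords, radius, layer = 0L) {
  coords <- as.matrix(coords)
  if (!ncol(coords) %in% c(2L, 3L)) stop_invalid("coords must have 2 or 3 columns")
  check_positive(radius, "radius")
  structure(list(coords = coords, radius = radius, layer = as.integer(layer)),
            class = "filament_curve")
}

#' Generate a steady-coil loop centerline
#'
#' Produces the planar centerline of a translated-coiling trochoid
#' `c(t) = (V t + R sin(2 pi f_c t), R cos(2 pi f_c t))` with `R = A/2`.
#' The coil rate `f_c` follows from the print-head velocity and the
#' advance-per-period, which is calibrated numerically so that the closed
#' lobe of a frequency-1 loop has the specified along-travel width (default
#' calibration: 2.2 mm at A = 3.5 mm); higher frequency divides the advance.
#' The arc length deposited per unit time then defines the effective
#' filament rate of the curve (attribute `filament_rate`), which the flow
#' controller must supply for mass conservation.
#'
#' For non-steady regimes an approximate non-looping curve is emitted
#' (straight line, or a sinusoidal meander) and flagged with attribute
#' `approximate`.
#'
#' @param spec A [loop_spec()].
#' @param params A [print_params()] providing the feed velocity.
#' @param path_length Along-travel length to cover (mm); must exceed one
#'   loop period.
#' @param points_per_period Sampling density of the polyline.
#' @return A [filament_curve()] with attributes `advance` (mm/period),
#'   `coil_rate` (periods/min), `filament_rate` (mm/min) and
#'   `required_flow` (uL/min).
#' @examples
#' cv <- generate_loop_centerline(loop_spec(3.5), path_length = 30)
#' attr(cv, "advance") # ~2.834 mm per loop at F = 1
#' @export
generate_loop_centerline <- function(spec, params = print_params(140, feed_V = 600),
                                     path_length, points_per_period = 160) {
  stopifnot(inherits(spec, "loop_spec"), inherits(params, "print_params"))
  check_positive(path_length, "path_length")
  R <- spec$amplitude / 2
  r_fil <- spec$filament_d / 2
  V <- params$feed_V
  if (spec$regime != "STEADY_COIL") {
    warning("non-steady regime '", spec$regime,
            "': emitting an approximate non-looping curve")
    x <- seq(0, path_length, length.out = 200)
    y <- if (spec$regime == "STRAIGHT") rep(0, length(x))
         else R * sin(2 * pi * x / max(spec$width, 1e-6))
    cv <- filament_curve(cbind(x = x, y = y), radius = r_fil)
    attr(cv, "approximate") <- TRUE
    return(cv)
  }
  p1 <- trochoid_advance_for_width(R, spec$width)
  p <- p1 / spec$frequency
  f_c <- V / p                       # periods per minute
  n_per <- path_length / p
  if (n_per <= 1)
    stop_invalid("path_length must exceed one loop period (", format(p), " mm)")
  phi <- seq(0, 2 * pi * n_per, length.out = max(2L, ceiling(n_per * points_per_period)))
  x <- p * phi / (2 * pi) + R * sin(phi)
  y <- R * cos(phi)
  cv <- filament_curve(cbind(x = x, y = y), radius = r_fil)
  s_per <- trochoid_period_arclen(p, R)
  attr(cv, "advance") <- p
  attr(cv, "coil_rate") <- f_c
  attr(cv, "filament_rate") <- s_per * f_c
  attr(cv, "required_flow") <- s_per * f_c * pi * (params$nozzle_d / 2)^2
  cv
}

#' Measure loop metrics from a centerline
#'
#' Recovers the loop geometry from an observed planar centerline: amplitude
#' as the transverse peak-to-peak extent, width as the along-travel extent
#' of a detected closed lobe (bounded by a self-intersection of the curve),
#' and frequency from the advance between successive lobes relative to the
#' calibrated frequency-1 advance. This inverts [generate_loop_centerline()]
#' to within sampling error.
#'
#' @param curve A planar [filament_curve()] containing at least two loops,
#'   or any polyline (non-looping curves yield `regime = "NON_COILING"`
#'   with undefined width).
#' @return A [loop_spec()]-like list with measured `amplitude`, `width`,
#'   `frequency`, `regime` and `n_loops`.
#' @export
measure_loop_metrics <- function(curve) {
  stopifnot(inherits(curve, "filament_curve"))
  xy <- curve$coords
  x <- xy[, 1]; y <- xy[, 2]
  amp <- diff(range(y))
  si <- cpp_self_intersections(x, y)
  if (nrow(si) == 0) {
    return(list(amplitude = amp, width = NA_real_, frequency = NA_real_,
                regime = "NON_COILING", n_loops = 0L))
  }
  # samples per period from transverse zero crossings
  ym <- mean(range(y))
  cross <- sum(diff(sign(y - ym)) != 0)
  period_samples <- 2 * length(y) / max(cross, 1L)
  # a lobe pinch joins two segments strictly less than one period apart;
  # crossings between neighbouring loops are always more than one period
  # apart, so one period separates the two families at any overlap
  pinch <- si[(si[, 2] - si[, 1]) < period_samples, , drop = FALSE]
  if (nrow(pinch) == 0) {
    return(list(amplitude = amp, width = NA_real_, frequency = NA_real_,
                regime = "NON_COILING", n_loops = 0L))
  }
  widths <- vapply(seq_len(nrow(pinch)), function(k) {
    i <- pinch[k, 1]; j <- pinch[k, 2]
    seg <- x[i:(j + 1)]
    max(seg) - min(seg)
  }, numeric(1))
  px <- sort(pinch[, 3])
  adv <- if (length(px) > 1) median(diff(px)) else NA_real_
  freq <- if (is.na(adv) || adv <= 0) NA_real_ else {
    p1 <- trochoid_advance_for_width(amp / 2, amp * WIDTH_RATIO)
    p1 / adv
  }
  list(amplitude = amp, width = median(widths), frequency = freq,
       regime = "STEADY_COIL", n_loops = nrow(pinch))
}
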