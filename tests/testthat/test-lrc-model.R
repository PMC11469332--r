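# coiling model: flow calibration, regime law, amplitude law, trochoid
# generation and metric recovery

test_that("effective filament rate follows the cylinder relation and tables", {
  # closed form: L = Q / (pi (d/2)^2) = 140 / (pi * 0.1^2)
  p <- print_params(flow_Q = 140, feed_V = 600)
  expect_equal(effective_filament_rate(p), 140 / (pi * 0.1^2), tolerance = 1e-10)
  expect_equal(round(effective_filament_rate(p), 1), 4456.3)
  # no flow, no filament
  expect_equal(effective_filament_rate(print_params(0, feed_V = 600)), 0)
  # piecewise-linear calibration table: midpoint interpolation
  cal <- flow_calibration(data.frame(commanded_Q_uL_min = c(140, 260),
                                     L_mm_min = c(4000, 6000)))
  expect_equal(effective_filament_rate(print_params(200, feed_V = 600), cal),
               5000)
  # out-of-range flow errors under the default policy
  expect_error(effective_filament_rate(print_params(300, feed_V = 600), cal),
               "calibration range")
  expect_error(flow_calibration(data.frame(commanded_Q_uL_min = c(0, 100),
                                           L_mm_min = c(10, 5))),
               "monotone")
  expect_error(print_params(flow_Q = -5, feed_V = 600), "non-negative")
})

test_that("regime classification is a monotone step function with onset 2.2", {
  V <- 1000
  rho <- c(0.5, 1.0, 1.3, 1.6, 2.0, 2.2, 5, 10)
  labs <- classify_regime(rho * V, V)
  expect_equal(labs, c("STRAIGHT", "STRAIGHT", "MEANDER", "MEANDER",
                       "ALTERNATING_LOOPS", "STEADY_COIL", "STEADY_COIL",
                       "STEADY_COIL"))
  # monotone: label index never decreases as rho grows
  order_idx <- match(labs, c("STRAIGHT", "MEANDER", "ALTERNATING_LOOPS",
                             "STEADY_COIL"))
  expect_true(all(diff(order_idx) >= 0))
  expect_error(classify_regime(1000, 0), "V must be > 0")
})

test_that("loop frequency is the onset-normalised ratio", {
  expect_equal(loop_frequency(2.2 * 500, 500), 1)
  expect_equal(loop_frequency(4.4 * 500, 500), 2)
  expect_equal(loop_frequency(1.1 * 500, 500), 0.5)
  # strictly increasing in L, decreasing in V
  expect_true(loop_frequency(2000, 500) > loop_frequency(1500, 500))
  expect_true(loop_frequency(2000, 700) < loop_frequency(2000, 500))
})

test_that("amplitude law is anchored at A(6) = 3.5 and inverts exactly", {
  expect_equal(amplitude_from_height(6), 3.5)
  h <- 4.2
  expect_equal(height_for_amplitude(amplitude_from_height(h)), h,
               tolerance = 1e-12)
  m <- amplitude_model(slope = 0.5, intercept = 0.5)
  expect_equal(amplitude_from_height(3, m), 2.0)
  expect_error(height_for_amplitude(0.5), "non-physical")
  expect_warning(amplitude_from_height(12), "outside calibrated range")
})

test_that("steady-coil centerline has the calibrated geometry", {
  cv <- generate_loop_centerline(loop_spec(3.5), path_length = 30)
  xy <- cv$coords
  # transverse extent is the amplitude by construction
  expect_equal(diff(range(xy[, 2])), 3.5, tolerance = 1e-3)
  m <- measure_loop_metrics(cv)
  # single-loop along-travel width at the standard setting
  expect_equal(m$width, 2.2, tolerance = 0.01)
  expect_error(generate_loop_centerline(loop_spec(3.5), path_length = 1),
               "one loop period")
})

test_that("arc-length conservation holds across the steady-coil range", {
  # the filament rate is a per-period average, so measure whole periods
  for (A in c(1, 3.5, 5)) for (F in c(0.5, 1.5, 3)) {
    spec <- loop_spec(A, frequency = F)
    scout <- generate_loop_centerline(spec, path_length = max(15, 10 * A))
    p <- attr(scout, "advance")
    n_per <- 12
    cv <- generate_loop_centerline(spec, path_length = n_per * p)
    xy <- cv$coords
    arclen <- sum(sqrt(rowSums(diff(xy)^2)))
    rate <- arclen / (n_per / attr(cv, "coil_rate"))
    expect_true(abs(rate / attr(cv, "filament_rate") - 1) < 0.01,
                label = sprintf("arc conservation at A=%g F=%g", A, F))
  }
})

test_that("measured loop metrics invert the generator within 2%", {
  for (A in c(0.8, 2, 3.5, 5)) for (F in c(0.5, 1, 2, 3)) {
    cv <- generate_loop_centerline(loop_spec(A, frequency = F),
                                   path_length = max(20, 12 * A))
    m <- measure_loop_metrics(cv)
    expect_true(abs(m$amplitude / A - 1) < 0.02,
                label = sprintf("amplitude recovery A=%g F=%g", A, F))
    expect_true(abs(m$frequency / F - 1) < 0.02,
                label = sprintf("frequency recovery A=%g F=%g", A, F))
  }
})

test_that("non-coiling curves are flagged and degenerate input handled", {
  straight <- filament_curve(cbind(seq(0, 10, 0.1), 0), radius = 0.1)
  m <- measure_loop_metrics(straight)
  expect_equal(m$regime, "NON_COILING")
  expect_true(is.na(m$width))
  expect_warning(
    generate_loop_centerline(loop_spec(3.5, regime = "MEANDER"),
                             path_length = 20),
    "non-steady")
})
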