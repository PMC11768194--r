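ctrl <- reference_mixolab_params("control")

test_that("smooth_envelope matches closed forms", {
  tt <- seq(0, 10, by = 1 / 60)
  # constant torque: all three envelopes equal the constant
  cv <- new_torque_curve(tt, rep(1.2, length(tt)), rep(30, length(tt)))
  env <- smooth_envelope(cv, 30)
  expect_identical(env$upper, rep(1.2, length(tt)))
  expect_identical(env$lower, rep(1.2, length(tt)))
  expect_equal(env$mid, rep(1.2, length(tt)))  # cumsum rounding allowed
  # sinusoid of peak-to-peak A around mean m, window >= one period
  A <- 0.08; m <- 1
  cv <- new_torque_curve(tt, m + A / 2 * sin(2 * pi * tt / 0.5),
                         rep(30, length(tt)))
  env <- smooth_envelope(cv, 30)
  inner <- tt > 0.5 & tt < 9.5
  expect_lt(max(abs(env$upper[inner] - env$lower[inner] - A)), A * 0.02)
  expect_lt(max(abs(env$mid[inner] - m)), 0.002)
  expect_true(all(env$upper >= env$mid & env$mid >= env$lower))
  # monotone ramp: mid within half a window's rise of the ramp
  cv <- new_torque_curve(tt, 0.1 * tt, rep(30, length(tt)))
  env <- smooth_envelope(cv, 30)
  expect_lt(max(abs(env$mid - 0.1 * tt)), 0.1 * 0.25 + 1e-9)
  expect_error(smooth_envelope(cv, 11 * 60), "shorter than the record")
})

test_that("noiseless control-row curve round-trips within tolerance", {
  ex <- extract_parameters(generate_torque_curve(ctrl, noise_sd = 0))
  expect_lt(abs(ex$c1 - 1.10), 0.01)
  expect_lt(abs(ex$c2 - 0.52), 0.01)
  expect_lt(abs(ex$c3 - 1.61), 0.01)
  expect_lt(abs(ex$c4 - 1.29), 0.01)
  expect_lt(abs(ex$c5 - 1.89), 0.01)
  expect_lt(abs(ex$stability - 6.97), 0.1)
  expect_lt(abs(ex$gelling_mid - 66.0), 0.5)
  expect_lt(abs(ex$t_hydr - 3.63), 0.1)
  expect_lt(abs(ex$t1 - 7.08), 0.1)
  expect_lt(abs(ex$t3 - 21.7), 0.1)
  expect_lt(abs(ex$amplitude - 0.073), 0.01)
  expect_equal(ex$water_absorption, 62.8)
  # slopes carry the Table-style signs
  expect_lt(ex$slope_alpha, 0)
  expect_gt(ex$slope_beta, 0)
})

test_that("flat zero-torque records degrade to absent/zero features", {
  tt <- seq(0, 45, by = 1 / 6)
  temp <- approx(c(0, 8, 38, 41, 45), c(30, 30, 90, 90, 74), xout = tt)$y
  cv <- new_torque_curve(tt, rep(0, length(tt)), temp)
  ex <- extract_parameters(cv)
  expect_equal(ex$c1, 0)
  expect_true(is.na(ex$t_hydr))
  expect_equal(ex$stability, 0)
  expect_equal(ex$amplitude, 0)
  expect_true(is.na(ex$gelling_mid))
})

test_that("missing heating phase yields a partial result, not an error", {
  tt <- seq(0, 10, by = 1 / 6)
  cv <- new_torque_curve(tt, 1 + 0.1 * sin(tt), rep(30, length(tt)))
  ex <- extract_parameters(cv)
  expect_false(is.na(ex$c1))
  expect_true(is.na(ex$c2) && is.na(ex$c3) && is.na(ex$c5) &&
                is.na(ex$gelling_mid))
})

test_that("noiseless round-trip holds across random parameter vectors", {
  ps <- random_mixolab_params(12, seed = 202)
  for (p in ps) {
    ex <- extract_parameters(generate_torque_curve(p, noise_sd = 0))
    for (nm in c("c1", "c2", "c3", "c4", "c5", "amplitude")) {
      expect_lt(abs(ex[[nm]] - p[[nm]]), 0.01)
    }
    for (nm in c("t_hydr", "t1", "t3", "stability")) {
      expect_lt(abs(ex[[nm]] - p[[nm]]), 0.1)
    }
    expect_lt(abs(ex$gelling_mid - p$gelling_mid), 0.5)
    # ordering invariants of the extracted vector
    expect_lte(ex$c2, ex$c1)
    expect_lte(ex$c2, ex$c3)
    expect_lt(ex$t1, ex$t3)
    # gelling mid-point lies on the heating ramp below the peak
    expect_gt(ex$gelling_mid, 30)
    expect_lt(ex$gelling_mid,
              approx(generate_torque_curve(p)$time,
                     generate_torque_curve(p)$temperature, xout = ex$t3)$y)
  }
})

test_that("raising C3 never decreases the extracted slope_beta", {
  base <- random_mixolab_params(1, seed = 77)[[1]]
  base$c4 <- min(base$c4, 1.4)
  betas <- sapply(c(1.55, 1.65, 1.75, 1.85), function(c3) {
    p <- base
    p$c3 <- c3
    p <- do.call(mixolab_params, unclass(p)[names(formals(mixolab_params))])
    extract_parameters(generate_torque_curve(p, noise_sd = 0))$slope_beta
  })
  expect_true(all(diff(betas) >= 0))
})

test_that("extraction_config validates its tolerances", {
  expect_error(extraction_config(stability_tolerance = 1.2),
               "stability_tolerance")
  expect_error(extraction_config(hydration_fraction = 0), "hydration_fraction")
})
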