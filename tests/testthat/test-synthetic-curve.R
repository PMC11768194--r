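ctrl <- reference_mixolab_params("control")

test_that("protocol and parameter preconditions are enforced by name", {
  expect_error(mixolab_params(t_hydr = 1, t1 = 5, c1 = 1, stability = 6,
                              c2 = 1.2, c3 = 1.6, t3 = 21, gelling_mid = 66,
                              c4 = 1.2, c5 = 1.8),
               "C2 > C1", class = "crumblab_bad_params")
  # degenerate request with T1 = 0 violates the anchor ordering
  expect_error(mixolab_params(t_hydr = 1, t1 = 0, c1 = 1, stability = 6,
                              c2 = 0.5, c3 = 1.6, t3 = 21, gelling_mid = 66,
                              c4 = 1.2, c5 = 1.8),
               "T_hydr >= T1", class = "crumblab_bad_params")
  p <- ctrl; p$t1 <- 9  # outside the 8-min mixing phase
  expect_error(generate_torque_curve(do.call(mixolab_params,
                                             unclass(p)[names(formals(mixolab_params))])),
               "mixing phase", class = "crumblab_bad_params")
  expect_error(chopin_protocol(total_minutes = 30, hold_minutes_at_start = 10,
                               heat_rate = 2),
               "does not fit")
})

test_that("noiseless curve hits its anchors: C5 at the end, C1 as mixing max", {
  cv <- generate_torque_curve(ctrl, noise_sd = 0)
  expect_lt(abs(cv$torque[length(cv$torque)] - ctrl$c5), 1e-9)
  # without the oscillation the mixing-phase maximum is C1 = 1.10 Nm
  cv0 <- generate_torque_curve(ctrl, noise_sd = 0, oscillation_amplitude = 0)
  mix <- cv0$time <= chopin_protocol()$hold_minutes_at_start
  expect_lt(abs(max(cv0$torque[mix]) - 1.10), 1e-4)
  # temperature column follows the protocol: starts at 30, peaks at 90
  expect_equal(cv$temperature[1], 30)
  expect_equal(max(cv$temperature), 90)
  expect_equal(max(cv$time), 45)
})

test_that("generator is bit-stable under a seed and responsive to noise", {
  a <- generate_torque_curve(ctrl, noise_sd = 0.01, seed = 5)
  b <- generate_torque_curve(ctrl, noise_sd = 0.01, seed = 5)
  expect_identical(a$torque, b$torque)
  c <- generate_torque_curve(ctrl, noise_sd = 0.01, seed = 6)
  expect_false(identical(a$torque, c$torque))
})

test_that("torque curves are valid containers", {
  expect_error(new_torque_curve(c(0, 1, 1), c(1, 1, 1), c(30, 30, 30)),
               "time not increasing")
  expect_error(new_torque_curve(c(0, 1), c(1, -1), c(30, 30)),
               "non-negative")
  cv <- generate_torque_curve(ctrl)
  df <- as.data.frame(cv)
  expect_named(df, c("time_min", "torque_nm", "temp_c"))
})

test_that("colour readings generator: zero noise, Monte Carlo mean, determinism", {
  means <- list(a = lab_color(80, 1, 10), b = lab_color(85, 2, 12))
  r0 <- generate_color_readings(means, sd = 0, n_replicates = 3, seed = 1)
  expect_true(all(r0$L[r0$group == "a"] == 80))
  expect_true(all(r0$b[r0$group == "b"] == 12))
  # grand mean of (reading - group mean) within 3 SE of zero per channel
  big <- setNames(replicate(10000, lab_color(50, 0, 0), simplify = FALSE),
                  paste0("g", 1:10000))
  rr <- generate_color_readings(big, sd = 0.5, n_replicates = 3, seed = 2)
  se3 <- 3 * 0.5 / sqrt(nrow(rr))
  expect_lt(abs(mean(rr$L) - 50), se3)
  expect_lt(abs(mean(rr$a)), se3)
  expect_lt(abs(mean(rr$b)), se3)
  expect_identical(generate_color_readings(means, 0.4, 3, seed = 9),
                   generate_color_readings(means, 0.4, 3, seed = 9))
  expect_error(generate_color_readings(means, sd = -1), "negative sd")
})

test_that("the infeasible printed row is rejected, all others build", {
  tab <- reference_mixolab_params()
  expect_identical(nrow(tab), 10L)
  expect_error(reference_mixolab_params("cavendish_5"), "T_hydr >= T1")
  for (s in setdiff(tab$sample, "cavendish_5")) {
    expect_s3_class(reference_mixolab_params(s), "mixolab_params")
  }
})
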