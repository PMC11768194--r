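## Phenomenological MixoLab curve synthesis: a torque trace is built as a
## monotone piecewise-cubic interpolation through the anchor points that
## the feature extractor is defined on (C1 at T1, C2 minimum, C3 maximum
## at T3, C4 hold minimum, C5 final), plus a fast mixing-phase
## oscillation (dough elasticity) and optional Gaussian noise. No dough
## physics is simulated.

## shared conventions between generator and extractor
.STABILITY_TOL <- 0.11   # stability band: torque >= (1 - tol) * C1
.HYDRATION_FRAC <- 0.5   # T_hydr: first crossing of this fraction of C1
.OSC_PERIOD_MIN <- 0.5   # mixing-phase oscillation period (min)

#' Chopin+ style mixing/heating protocol
#'
#' Temperature program of a Chopin+ MixoLab run: constant-temperature
#' kneading, a linear heating ramp, a hold at peak temperature, and a
#' final cooling segment. Defaults follow the standard settings (80 rpm,
#' 30 degC start, 2 degC/min heating, 45 min total).
#'
#' @param mix_speed_rpm kneading speed (metadata only).
#' @param start_temp mixer temperature during kneading, degC.
#' @param hold_minutes_at_start kneading (constant temperature) phase
#'   length, min.
#' @param heat_rate heating rate, degC/min (> 0).
#' @param peak_temp peak temperature, degC.
#' @param hold_minutes_at_peak hold length at peak temperature, min.
#' @param cool_rate cooling rate after the hold, degC/min.
#' @param total_minutes total analysis time, min.
#' @param sampling_interval sampling interval, seconds.
#' @return an object of class `chopin_protocol`.
#' @export
chopin_protocol <- function(mix_speed_rpm = 80, start_temp = 30,
                            hold_minutes_at_start = 8, heat_rate = 2,
                            peak_temp = 90, hold_minutes_at_peak = 3,
                            cool_rate = 4, total_minutes = 45,
                            sampling_interval = 1) {
  check_number(heat_rate, "heat_rate", min = 1e-9)
  check_number(total_minutes, "total_minutes", min = 1e-9)
  check_number(start_temp, "start_temp")
  check_number(peak_temp, "peak_temp", min = start_temp + 1e-9)
  check_number(hold_minutes_at_start, "hold_minutes_at_start", min = 0)
  check_number(hold_minutes_at_peak, "hold_minutes_at_peak", min = 0)
  check_number(cool_rate, "cool_rate", min = 0)
  check_number(sampling_interval, "sampling_interval", min = 1e-3)
  p <- structure(list(
    mix_speed_rpm = mix_speed_rpm, start_temp = start_temp,
    hold_minutes_at_start = hold_minutes_at_start, heat_rate = heat_rate,
    peak_temp = peak_temp, hold_minutes_at_peak = hold_minutes_at_peak,
    cool_rate = cool_rate, total_minutes = total_minutes,
    sampling_interval = sampling_interval
  ), class = "chopin_protocol")
  ph <- protocol_phases(p)
  if (ph$hold_end >= total_minutes) {
    abort("protocol does not fit: kneading + ramp + peak hold exceeds total_minutes",
          "crumblab_bad_arg")
  }
  p
}

protocol_phases <- function(protocol) {
  t_h <- protocol$hold_minutes_at_start
  ramp_end <- t_h + (protocol$peak_temp - protocol$start_temp) / protocol$heat_rate
  list(heat_onset = t_h, ramp_end = ramp_end,
       hold_end = ramp_end + protocol$hold_minutes_at_peak)
}

#' MixoLab parameter vector
#'
#' The 14 dough-rheology features read off a Chopin+ MixoLab curve:
#' hydration time `t_hydr` (min), development time `t1` (min), peak
#' mixing consistency `c1` (Nm), `water_absorption` (%, instrument dosing
#' metadata, not derivable from the trace), oscillation `amplitude`
#' (peak-to-peak, Nm), `stability` (min above the tolerance band),
#' `slope_alpha` (protein weakening rate, Nm/min), protein-weakening
#' minimum `c2` (Nm), `slope_beta` (gelatinization rate, Nm/min),
#' gelatinization peak `c3` (Nm) at time `t3` (min), `gelling_mid`
#' (degC, temperature at which the C2 -> C3 torque rise is half
#' complete), hot-gel minimum `c4` (Nm) and final cooled torque `c5`
#' (Nm).
#'
#' @param t_hydr,t1,c1,water_absorption,amplitude,stability,slope_alpha
#'   see description.
#' @param c2,slope_beta,c3,t3,gelling_mid,c4,c5 see description.
#' @return an object of class `mixolab_params` (a named list).
#' @export
mixolab_params <- function(t_hydr, t1, c1, water_absorption = NA_real_,
                           amplitude = 0, stability, slope_alpha = NA_real_,
                           c2, slope_beta = NA_real_, c3, t3, gelling_mid,
                           c4, c5) {
  p <- list(t_hydr = t_hydr, t1 = t1, c1 = c1,
            water_absorption = water_absorption, amplitude = amplitude,
            stability = stability, slope_alpha = slope_alpha, c2 = c2,
            slope_beta = slope_beta, c3 = c3, t3 = t3,
            gelling_mid = gelling_mid, c4 = c4, c5 = c5)
  for (nm in c("t_hydr", "t1", "c1", "amplitude", "stability", "c2", "c3",
               "t3", "gelling_mid", "c4", "c5")) {
    check_number(p[[nm]], nm, min = 0)
  }
  if (p$c2 > p$c1) abort("inconsistent parameters: C2 > C1", "crumblab_bad_params")
  if (p$c2 >= p$c3) abort("inconsistent parameters: C2 >= C3", "crumblab_bad_params")
  if (p$t1 >= p$t3) abort("inconsistent parameters: T1 >= T3", "crumblab_bad_params")
  if (p$t_hydr >= p$t1) {
    abort("inconsistent parameters: T_hydr >= T1", "crumblab_bad_params")
  }
  structure(p, class = "mixolab_params")
}

#' Reference parameter vectors for wheat/green-banana flour doughs
#'
#' Reads the bundled table of mean MixoLab parameter vectors (control
#' wheat bread plus 5/10/15% green banana flour substitutions of three
#' cultivars) that ships with the package as plain CSV. These printed
#' instrument means are used as generator inputs in examples and tests.
#'
#' @param sample optional sample label (e.g. `"control"`); when given,
#'   returns a single [mixolab_params()] object instead of the table.
#' @return a data.frame, or a `mixolab_params` object when `sample` is
#'   given.
#' @export
reference_mixolab_params <- function(sample = NULL) {
  path <- system.file("extdata", "mixolab_reference_parameters.csv",
                      package = "crumblab", mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (is.null(sample)) return(tab)
  row <- tab[tab$sample == sample, , drop = FALSE]
  if (nrow(row) != 1L) {
    abort(paste0("unknown reference sample: ", sample), "crumblab_bad_arg")
  }
  mixolab_params(
    t_hydr = row$t_hydr, t1 = row$t1, c1 = row$c1,
    water_absorption = row$water_absorption, amplitude = row$amplitude,
    stability = row$stability, slope_alpha = row$slope_alpha, c2 = row$c2,
    slope_beta = row$slope_beta, c3 = row$c3, t3 = row$t3,
    gelling_mid = row$gelling_mid, c4 = row$c4, c5 = row$c5
  )
}

## anchor layout shared by the generator (and mirrored by tests); times in
## minutes. The stability window [t_up, t_dn] straddles T1 and may extend
## into early heating (as on the instrument); C2 sits partway down the
## weakening limb, and the (C2+C3)/2 crossing time t_mid carries the
## gelling mid-point temperature anchor.
curve_anchors <- function(params, protocol,
                          stability_tolerance = .STABILITY_TOL,
                          hydration_fraction = .HYDRATION_FRAC) {
  p <- params
  ph <- protocol_phases(protocol)
  if (hydration_fraction >= 1 - stability_tolerance) {
    abort("hydration_fraction must lie below the stability band",
          "crumblab_bad_params")
  }
  band <- (1 - stability_tolerance) * p$c1
  if (p$c2 >= band) {
    abort("inconsistent parameters: C2 must lie below the stability band (1 - tol) * C1",
          "crumblab_bad_params")
  }
  if (p$c4 > p$c3) abort("inconsistent parameters: C4 > C3", "crumblab_bad_params")
  if (p$c4 > p$c5) abort("inconsistent parameters: C4 > C5", "crumblab_bad_params")
  if (p$t1 >= ph$heat_onset) {
    abort("inconsistent parameters: T1 must fall inside the mixing phase",
          "crumblab_bad_params")
  }
  t_up <- p$t1 - 0.2 * p$stability
  t_dn <- t_up + p$stability
  if (t_up <= p$t_hydr) {
    abort("inconsistent parameters: stability window opens before T_hydr (T_hydr < T1 - 0.2 * stability required)",
          "crumblab_bad_params")
  }
  if (t_dn >= p$t3) {
    abort("inconsistent parameters: stability window must close before T3",
          "crumblab_bad_params")
  }
  t_c2 <- t_dn + 0.35 * (p$t3 - t_dn)
  if (t_c2 <= ph$heat_onset) {
    abort("inconsistent parameters: C2 time must fall after heating onset (T1 < time of C2 < T3)",
          "crumblab_bad_params")
  }
  if (p$t3 >= ph$ramp_end) {
    abort("inconsistent parameters: T3 must fall on the heating ramp",
          "crumblab_bad_params")
  }
  if (p$gelling_mid <= protocol$start_temp || p$gelling_mid >= protocol$peak_temp) {
    abort("inconsistent parameters: gelling mid-point must lie between start and peak temperature",
          "crumblab_bad_params")
  }
  t_mid <- (t_c2 + p$t3) / 2
  c0 <- 0.2 * hydration_fraction * p$c1
  ## shoulder anchors just after the T1 and T3 peaks keep the local shape
  ## roughly symmetric, so the smoothed argmax does not drift onto a flat
  ## plateau (the instrument's own curves fall visibly after each peak)
  t1s <- p$t1 + min(1.2, 0.3 * (t_dn - p$t1))
  s_left1 <- (p$c1 - band) / (p$t1 - t_up)
  c1s <- p$c1 - min(s_left1 * (t1s - p$t1), 0.6 * (p$c1 - band))
  ## approach anchor so the stability band is always crossed at a clear
  ## downward slope (a near-flat tangent there would make the measured
  ## stability hypersensitive to small torque errors)
  t_dna <- if (t_dn - 0.75 > t1s) t_dn - 0.75 else (t1s + t_dn) / 2
  c_dna <- band + 0.035 * p$c1
  t_c4 <- (ph$ramp_end + ph$hold_end) / 2
  t3s <- p$t3 + min(1, 0.3 * (t_c4 - p$t3))
  s_left3 <- (p$c3 - p$c2) / 2 / (p$t3 - t_mid)
  c3s <- p$c3 - min(s_left3 * (t3s - p$t3), 0.75 * (p$c3 - p$c4))
  list(
    torque_t = c(0, p$t_hydr, t_up, p$t1, t1s, t_dna, t_dn, t_c2, t_mid,
                 p$t3, t3s, t_c4, protocol$total_minutes),
    torque_y = c(c0, hydration_fraction * p$c1, band, p$c1, c1s, c_dna,
                 band, p$c2, (p$c2 + p$c3) / 2, p$c3, c3s, p$c4, p$c5),
    temp_t = c(0, ph$heat_onset, t_mid, ph$ramp_end, ph$hold_end,
               protocol$total_minutes),
    temp_y = c(protocol$start_temp, protocol$start_temp, p$gelling_mid,
               protocol$peak_temp, protocol$peak_temp,
               protocol$peak_temp -
                 protocol$cool_rate * (protocol$total_minutes - ph$hold_end)),
    t_up = t_up, t_dn = t_dn, t_c2 = t_c2, t_mid = t_mid
  )
}

#' Generate a synthetic MixoLab torque curve
#'
#' Inverts the feature definitions used by [extract_parameters()]: the
#' returned curve passes through the torque anchors implied by `params`
#' (C1 at T1, C2 minimum during early heating, C3 at T3, C4 minimum in
#' the peak-temperature hold, C5 at the final sample), connected by
#' monotone piecewise-cubic segments. A zero-mean sinusoidal oscillation
#' of peak-to-peak amplitude `oscillation_amplitude` is superimposed
#' during the mixing phase (tapered out just before heating onset), and
#' the smoothed trace stays above `(1 - stability_tolerance) * C1` for
#' exactly `stability` minutes around T1.
#'
#' The recorded dough temperature follows the protocol schedule but is
#' warped through one anchor so that it crosses `gelling_mid` exactly
#' where the torque crosses `(C2 + C3) / 2` (the dough temperature lags
#' the mixer program, so printed gelling mid-points sit above the nominal
#' 2 degC/min schedule).
#'
#' @param params a [mixolab_params()] vector.
#' @param protocol a [chopin_protocol()].
#' @param oscillation_amplitude peak-to-peak mixing oscillation, Nm;
#'   defaults to `params$amplitude`.
#' @param noise_sd additive Gaussian noise SD, Nm.
#' @param seed integer seed (noise only; the noiseless curve is fully
#'   determined by its inputs).
#' @param stability_tolerance,hydration_fraction conventions shared with
#'   the extractor; keep defaults unless you change both sides.
#' @return a [new_torque_curve()] object.
#' @export
generate_torque_curve <- function(params, protocol = chopin_protocol(),
                                  oscillation_amplitude = params$amplitude,
                                  noise_sd = 0, seed = 1L,
                                  stability_tolerance = .STABILITY_TOL,
                                  hydration_fraction = .HYDRATION_FRAC) {
  stopifnot(inherits(params, "mixolab_params"),
            inherits(protocol, "chopin_protocol"))
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(oscillation_amplitude, "oscillation_amplitude", min = 0)
  an <- curve_anchors(params, protocol, stability_tolerance,
                      hydration_fraction)
  tt <- seq(0, protocol$total_minutes, by = protocol$sampling_interval / 60)
  base <- pchip_fun(an$torque_t, an$torque_y)(tt)

  if (oscillation_amplitude > 0) {
    t_h <- protocol_phases(protocol)$heat_onset
    taper <- ifelse(tt >= t_h, 0,
                    ifelse(tt <= t_h - 0.5, 1,
                           0.5 * (1 + cos(pi * (tt - (t_h - 0.5)) / 0.5))))
    base <- base + taper * (oscillation_amplitude / 2) *
      sin(2 * pi * tt / .OSC_PERIOD_MIN)
  }
  if (noise_sd > 0) {
    base <- base + with_seed(seed, rnorm(length(tt), 0, noise_sd))
  }
  temp <- approx(an$temp_t, an$temp_y, xout = tt)$y
  new_torque_curve(time = tt, torque = pmax(base, 0), temperature = temp,
                   water_absorption = params$water_absorption,
                   protocol = protocol)
}

#' Torque curve container
#'
#' @param time sampling times, minutes, strictly increasing.
#' @param torque torque, Nm, non-negative.
#' @param temperature dough temperature, degC.
#' @param water_absorption instrument water dosing, % (metadata).
#' @param protocol the [chopin_protocol()] used, or `NULL`.
#' @return an object of class `torque_curve`.
#' @export
new_torque_curve <- function(time, torque, temperature,
                             water_absorption = NA_real_, protocol = NULL) {
  n <- length(time)
  if (n < 2L || length(torque) != n || length(temperature) != n) {
    abort("time, torque and temperature must have equal length >= 2",
          "crumblab_bad_arg")
  }
  if (any(!is.finite(time)) || any(diff(time) <= 0)) {
    abort("time not increasing", "crumblab_bad_arg")
  }
  if (any(!is.finite(torque)) || any(torque < 0)) {
    abort("torque must be finite and non-negative", "crumblab_bad_arg")
  }
  structure(list(time = as.numeric(time), torque = as.numeric(torque),
                 temperature = as.numeric(temperature),
                 water_absorption = water_absorption, protocol = protocol),
            class = "torque_curve")
}

#' @export
as.data.frame.torque_curve <- function(x, ...) {
  data.frame(time_min = x$time, torque_nm = x$torque, temp_c = x$temperature)
}

#' @export
print.torque_curve <- function(x, ...) {
  cat(sprintf("<torque_curve> %d samples, %.1f-%.1f min, torque %.3f-%.3f Nm, temp %.1f-%.1f degC\n",
              length(x$time), min(x$time), max(x$time), min(x$torque),
              max(x$torque), min(x$temperature), max(x$temperature)))
  invisible(x)
}
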