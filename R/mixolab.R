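## MixoLab curve parameterization: phase detection from the temperature
## column, envelope smoothing of the oscillating torque trace, and
## extraction of the 14-value parameter vector (T_hydr, T1, C1, water
## absorption, amplitude, stability, slope-alpha, C2, slope-beta, C3, T3,
## gelling mid-point, C4, C5).

#' Extraction configuration
#'
#' Conventions used by [extract_parameters()]. Defaults are shared with
#' [generate_torque_curve()] so that generated curves round-trip.
#'
#' @param smoothing_window envelope window, seconds. Must cover at least
#'   one oscillation period of the mixer (30 s on a Chopin+ at 80 rpm
#'   with the default generator period).
#' @param presmooth_window light running-mean denoising window, seconds,
#'   applied before the envelopes.
#' @param stability_tolerance stability band half-depth as a fraction of
#'   C1; the band is `torque >= (1 - tol) * C1` (0.11 = Chopin
#'   convention).
#' @param hydration_fraction fraction of C1 whose first crossing defines
#'   T_hydr (a convention; the instrument manuals do not define T_hydr
#'   operationally).
#' @param temp_tolerance degC tolerance for phase detection on the
#'   temperature column.
#' @return an object of class `extraction_config`.
#' @export
extraction_config <- function(smoothing_window = 30, presmooth_window = 7,
                              stability_tolerance = .STABILITY_TOL,
                              hydration_fraction = .HYDRATION_FRAC,
                              temp_tolerance = 0.5) {
  check_number(smoothing_window, "smoothing_window", min = 1e-9)
  check_number(presmooth_window, "presmooth_window", min = 0)
  check_number(stability_tolerance, "stability_tolerance", min = 1e-9, max = 1 - 1e-9)
  check_number(hydration_fraction, "hydration_fraction", min = 1e-9, max = 1 - 1e-9)
  check_number(temp_tolerance, "temp_tolerance", min = 1e-9)
  structure(list(smoothing_window = smoothing_window,
                 presmooth_window = presmooth_window,
                 stability_tolerance = stability_tolerance,
                 hydration_fraction = hydration_fraction,
                 temp_tolerance = temp_tolerance),
            class = "extraction_config")
}

## centered running mean with partial windows at the edges
running_mean <- function(y, k) {
  if (k <= 1L) return(y)
  n <- length(y)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

running_extreme <- function(y, k, fun) {
  n <- length(y)
  half <- (k - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    fun(y[max(1L, i - half):min(n, i + half)])
  }, 0)
}

#' Rolling envelopes of a torque trace
#'
#' Rolling maximum / mean / minimum over a time window. The mid envelope
#' is the smoothed consistency curve on which all torque landmarks are
#' read; upper minus lower brackets the mixing oscillation.
#'
#' @param curve a [new_torque_curve()].
#' @param window window length in seconds; must be shorter than the
#'   record.
#' @return list with numeric vectors `upper`, `mid`, `lower` (pointwise
#'   `upper >= mid >= lower`).
#' @export
smooth_envelope <- function(curve, window = 30) {
  stopifnot(inherits(curve, "torque_curve"))
  dt <- stats::median(diff(curve$time)) * 60  # seconds
  k <- max(1L, 2L * floor(window / dt / 2) + 1L)  # odd sample count
  if (k >= length(curve$time)) {
    abort("smoothing window must be shorter than the record",
          "crumblab_bad_arg")
  }
  list(upper = running_extreme(curve$torque, k, max),
       mid = running_mean(curve$torque, k),
       lower = running_extreme(curve$torque, k, min))
}

## Local-polynomial refinement of a discrete extremum of the smoothed
## trace. A cubic is fitted around the sample extremum; its vertex and
## value are then corrected for the first-order bias of the box
## smoothing: the smoothed curve is E[f(t+X)] ~ f(t) + f''(t) v/2 with v
## the smoothing-window variance, which depresses peaks by f'' v / 2 and
## shifts the vertex by f''' v / (2 f''). Falls back to the raw sample
## when the fit is degenerate or the vertex leaves the window.
refine_extremum <- function(t, y, i, var_smooth = 0, halfwidth = 0.35) {
  sel <- which(t >= t[i] - halfwidth & t <= t[i] + halfwidth)
  if (length(sel) < 7L) return(list(t = t[i], value = y[i]))
  x <- t[sel] - t[i]
  fit <- lm(y[sel] ~ x + I(x^2) + I(x^3))
  cf <- coef(fit)
  if (any(!is.finite(cf)) || cf[[3L]] == 0) {
    return(list(t = t[i], value = y[i]))
  }
  ## vertex of the fitted cubic nearest the sample extremum
  disc <- (2 * cf[[3L]])^2 - 4 * (3 * cf[[4L]]) * cf[[2L]]
  v0 <- if (cf[[4L]] == 0 || disc < 0) {
    -cf[[2L]] / (2 * cf[[3L]])
  } else {
    r <- c((-2 * cf[[3L]] + sqrt(disc)) / (2 * 3 * cf[[4L]]),
           (-2 * cf[[3L]] - sqrt(disc)) / (2 * 3 * cf[[4L]]))
    r[which.min(abs(r))]
  }
  if (!is.finite(v0) || abs(v0) > halfwidth) {
    return(list(t = t[i], value = y[i]))
  }
  f2 <- 2 * cf[[3L]] + 6 * cf[[4L]] * v0   # y'' at the vertex
  f3 <- 6 * cf[[4L]]                       # y'''
  shift <- if (f2 != 0) var_smooth / 2 * f3 / f2 else 0
  if (!is.finite(shift) || abs(shift) > halfwidth) shift <- 0
  t_hat <- t[i] + v0 + shift
  val <- cf[[1L]] + cf[[2L]] * v0 + cf[[3L]] * v0^2 + cf[[4L]] * v0^3 -
    var_smooth / 2 * f2
  list(t = t_hat, value = val)
}

## Plain quadratic sub-sample vertex (no bias correction): preferred for
## the T1 time, where the mixing oscillation residue makes the cubic's
## third-derivative estimate unreliable.
refine_vertex <- function(t, y, i, halfwidth = 0.35) {
  sel <- which(t >= t[i] - halfwidth & t <= t[i] + halfwidth)
  if (length(sel) < 5L) return(t[i])
  x <- t[sel] - t[i]
  cf <- coef(lm(y[sel] ~ x + I(x^2)))
  if (any(!is.finite(cf)) || cf[[3L]] == 0) return(t[i])
  v <- -cf[[2L]] / (2 * cf[[3L]])
  if (abs(v) > halfwidth) t[i] else t[i] + v
}

## Level-crossing refinement with the same smoothing-bias correction: a
## local quadratic is fitted around the bracketing samples and solved at
## the bias-adjusted level L + a * v (a = fitted curvature/2 coefficient).
refine_crossing <- function(t, y, i_before, level, var_smooth = 0,
                            halfwidth = 0.5) {
  t0 <- crossing_time(t, y, i_before, level)
  sel <- which(t >= t0 - halfwidth & t <= t0 + halfwidth)
  if (length(sel) < 7L) return(t0)
  x <- t[sel] - t0
  cf <- coef(lm(y[sel] ~ x + I(x^2)))
  if (any(!is.finite(cf))) return(t0)
  a <- cf[[3L]]; b <- cf[[2L]]; c0 <- cf[[1L]] - (level + a * var_smooth)
  disc <- b^2 - 4 * a * c0
  root <- if (a == 0 || disc < 0) {
    if (b != 0) -c0 / b else NA_real_
  } else {
    r <- c((-b + sqrt(disc)) / (2 * a), (-b - sqrt(disc)) / (2 * a))
    r[which.min(abs(r))]
  }
  if (!is.finite(root) || abs(root) > halfwidth) t0 else t0 + root
}

ls_slope <- function(t, y, from, to) {
  sel <- t >= from & t <= to
  if (sum(sel) < 2L) return(NA_real_)
  unname(coef(lm(y[sel] ~ t[sel]))[2L])
}

## detect protocol phases from the recorded temperature column
detect_phases <- function(curve, tol) {
  temp <- curve$temperature; tt <- curve$time
  start_temp <- temp[1L]
  rising <- which(temp > start_temp + tol)
  if (length(rising) == 0L) {
    return(list(heat_onset = NA_real_, hold_start = NA_real_,
                hold_end = NA_real_, has_cooling = FALSE))
  }
  i_on <- max(rising[1L] - 1L, 1L)
  peak <- max(temp)
  at_peak <- which(temp >= peak - tol)
  hold_start <- tt[at_peak[1L]]
  hold_end <- tt[at_peak[length(at_peak)]]
  list(heat_onset = tt[i_on], hold_start = hold_start, hold_end = hold_end,
       has_cooling = at_peak[length(at_peak)] < length(tt))
}

#' Extract the MixoLab parameter vector from a torque curve
#'
#' Reads all torque landmarks off the mid (rolling mean) envelope of the
#' lightly denoised trace, with protocol phases detected from the
#' temperature column:
#'
#' * `c1` = mid-envelope maximum during the constant-temperature mixing
#'   phase, at time `t1` (parabolic sub-sample refinement);
#' * `t_hydr` = first crossing of `hydration_fraction * c1`;
#' * `stability` = length of the contiguous interval around `t1` where
#'   the mid envelope stays at or above `(1 - stability_tolerance) * c1`
#'   (the window may extend into early heating, as on the instrument);
#' * `amplitude` = peak-to-peak mixing oscillation at `t1`, estimated
#'   from the RMS of the raw-minus-mid residual just before `t1` with the
#'   noise floor (measured on the oscillation-free cooling segment)
#'   subtracted;
#' * `c2` = mid-envelope minimum on the heating ramp; `slope_alpha` =
#'   least-squares slope from heating onset to `t(c2)`;
#' * `c3` = mid-envelope maximum on the ramp after `c2`, at `t3`;
#'   `slope_beta` = least-squares slope from `t(c2)` to `t3`;
#' * `gelling_mid` = recorded temperature at the first crossing of torque
#'   level `(c2 + c3) / 2` between `t(c2)` and `t3`;
#' * `c4` = mid-envelope minimum during the peak-temperature hold;
#' * `c5` = local linear fit of the raw torque over the final window,
#'   evaluated at the last sample.
#'
#' Missing phases yield `NA` for the fields that need them (a record with
#' no temperature rise reports only the mixing-phase features). Water
#' absorption is instrument dosing metadata and is passed through from
#' the curve, never computed.
#'
#' @param curve a [new_torque_curve()].
#' @param config an [extraction_config()].
#' @return a list of class `mixolab_extraction` with the 14 parameter
#'   fields of [mixolab_params()] plus the conventions used.
#' @export
extract_parameters <- function(curve, config = extraction_config()) {
  stopifnot(inherits(curve, "torque_curve"))
  tt <- curve$time
  dt_s <- stats::median(diff(tt)) * 60
  kp <- max(1L, 2L * floor(config$presmooth_window / dt_s / 2) + 1L)
  pre <- running_mean(curve$torque, kp)
  pre_curve <- new_torque_curve(tt, pmax(pre, 0), curve$temperature,
                                curve$water_absorption, curve$protocol)
  env <- smooth_envelope(pre_curve, config$smoothing_window)
  mid <- env$mid
  ph <- detect_phases(curve, config$temp_tolerance)
  ## variance (min^2) of the combined box filters, for bias correction
  ke <- max(1L, 2L * floor(config$smoothing_window / dt_s / 2) + 1L)
  v_sm <- ((ke^2 - 1) + (kp^2 - 1)) / 12 * (dt_s / 60)^2

  out <- list(t_hydr = NA_real_, t1 = NA_real_, c1 = NA_real_,
              water_absorption = curve$water_absorption,
              amplitude = NA_real_, stability = NA_real_,
              slope_alpha = NA_real_, c2 = NA_real_, slope_beta = NA_real_,
              c3 = NA_real_, t3 = NA_real_, gelling_mid = NA_real_,
              c4 = NA_real_, c5 = NA_real_)

  mix_end <- if (is.na(ph$heat_onset)) tt[length(tt)] else ph$heat_onset
  im <- which(tt <= mix_end)
  i1 <- im[which.max(mid[im])]
  r1 <- refine_extremum(tt, mid, i1, v_sm)
  out$c1 <- r1$value
  out$t1 <- refine_vertex(tt, mid, i1)

  if (out$c1 > 0) {
    ## T_hydr: first crossing of hydration_fraction * C1
    level <- config$hydration_fraction * out$c1
    ih <- first_at_or_above(mid, level)
    if (!is.na(ih)) {
      out$t_hydr <- if (ih == 1L) tt[1L] else
        refine_crossing(tt, mid, ih - 1L, level, v_sm)
    }
    ## stability: contiguous band interval around the peak
    band <- (1 - config$stability_tolerance) * out$c1
    lo <- i1
    while (lo > 1L && mid[lo - 1L] >= band) lo <- lo - 1L
    hi <- i1
    while (hi < length(mid) && mid[hi + 1L] >= band) hi <- hi + 1L
    t_up <- if (lo == 1L) tt[1L] else
      refine_crossing(tt, mid, lo - 1L, band, v_sm)
    t_dn <- if (hi == length(mid)) tt[hi] else
      refine_crossing(tt, mid, hi, band, v_sm)
    out$stability <- t_dn - t_up
  } else {
    out$stability <- 0
    out$amplitude <- 0
  }

  ## noise floor from the cooling segment (no mixing oscillation there)
  resid <- curve$torque - mid
  noise_var <- 0
  if (!is.na(ph$hold_end) && ph$has_cooling) {
    cool <- which(tt > ph$hold_end)
    if (length(cool) > 20L) {
      noise_var <- (sd(diff(curve$torque[cool])) / sqrt(2))^2
    }
  }
  if (out$c1 > 0) {
    win <- which(tt >= max(tt[1L], out$t1 - 1) & tt <= out$t1)
    if (length(win) >= 10L) {
      ms <- mean(resid[win]^2)
      out$amplitude <- 2 * sqrt(2) * sqrt(max(0, ms - noise_var))
    }
  }

  if (!is.na(ph$heat_onset)) {
    ir <- which(tt >= ph$heat_onset & tt <= ph$hold_start)
    i2 <- ir[which.min(mid[ir])]
    r2 <- refine_extremum(tt, mid, i2, v_sm)
    out$c2 <- r2$value
    t_c2 <- r2$t
    out$slope_alpha <- ls_slope(tt, mid, ph$heat_onset, t_c2)
    ig <- ir[ir >= i2]
    i3 <- ig[which.max(mid[ig])]
    r3 <- refine_extremum(tt, mid, i3, v_sm)
    out$c3 <- r3$value
    out$t3 <- r3$t
    out$slope_beta <- ls_slope(tt, mid, t_c2, out$t3)
    ## gelling mid-point: temperature at the (C2+C3)/2 torque crossing
    level <- (out$c2 + out$c3) / 2
    seg <- i2:i3
    ic <- first_at_or_above(mid[seg], level)
    if (!is.na(ic) && length(seg) > 1L && out$c3 > out$c2) {
      j <- seg[ic]
      t_x <- if (j == seg[1L]) tt[j] else
        refine_crossing(tt, mid, j - 1L, level, v_sm)
      out$gelling_mid <- approx(tt, curve$temperature, xout = t_x)$y
    }
    ih <- which(tt >= ph$hold_start & tt <= ph$hold_end)
    if (length(ih) > 0L) {
      i4 <- ih[which.min(mid[ih])]
      out$c4 <- refine_extremum(tt, mid, i4, v_sm)$value
    }
    if (ph$has_cooling) {
      iw <- which(tt >= tt[length(tt)] - config$smoothing_window / 60)
      fit <- lm(curve$torque[iw] ~ tt[iw])
      out$c5 <- unname(coef(fit)[1L] + coef(fit)[2L] * tt[length(tt)])
    }
  }

  structure(c(out, list(stability_tolerance = config$stability_tolerance,
                        hydration_fraction = config$hydration_fraction)),
            class = "mixolab_extraction")
}

#' @export
print.mixolab_extraction <- function(x, ...) {
  fmt <- function(v, d = 3) ifelse(is.na(v), "NA", formatC(v, digits = d, format = "f"))
  cat("<mixolab_extraction>\n",
      sprintf("  T_hydr %s min | T1 %s min | C1 %s Nm | WA %s%%\n",
              fmt(x$t_hydr, 2), fmt(x$t1, 2), fmt(x$c1), fmt(x$water_absorption, 1)),
      sprintf("  amplitude %s Nm | stability %s min (tol %.2f C1) | slope-a %s Nm/min\n",
              fmt(x$amplitude), fmt(x$stability, 2), x$stability_tolerance,
              fmt(x$slope_alpha)),
      sprintf("  C2 %s | slope-b %s | C3 %s @ %s min | gelling mid %s degC\n",
              fmt(x$c2), fmt(x$slope_beta), fmt(x$c3), fmt(x$t3, 2),
              fmt(x$gelling_mid, 1)),
      sprintf("  C4 %s | C5 %s Nm  (T_hydr convention: first crossing of %.2f C1)\n",
              fmt(x$c4), fmt(x$c5), x$hydration_fraction), sep = "")
  invisible(x)
}

#' Random feasible MixoLab parameter vectors
#'
#' Draws parameter vectors uniformly from realistic instrument ranges
#' (consistent with wheat/banana composite doughs) that satisfy every
#' generator precondition. Used for round-trip recovery testing.
#'
#' @param n number of vectors.
#' @param seed integer seed.
#' @return a list of [mixolab_params()] objects.
#' @export
random_mixolab_params <- function(n = 1L, seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      c1 <- runif(1, 0.9, 1.3)
      stability <- runif(1, 5, 8)
      t1 <- runif(1, 4.5, 7.5)
      t_up <- t1 - 0.2 * stability
      t_hydr <- runif(1, 0.8, t_up - 0.8)
      c2 <- runif(1, 0.35, 0.6)
      c3 <- runif(1, 1.5, 1.9)
      c4 <- runif(1, 1.1, c3 - 0.05)
      mixolab_params(
        t_hydr = t_hydr, t1 = t1, c1 = c1,
        water_absorption = runif(1, 60, 68),
        amplitude = runif(1, 0.06, 0.12), stability = stability,
        c2 = c2, c3 = c3, t3 = runif(1, 20, 23),
        gelling_mid = runif(1, 60, 72), c4 = c4,
        c5 = c4 + runif(1, 0.3, 0.9)
      )
    })
  })
}
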