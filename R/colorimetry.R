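## CIELAB colorimetry: replicate averaging, total colour difference
## (Delta E, CIE76) with the five perceptual bands, CIEDE2000 as an
## optional variant, and substitution-level trend fitting.

#' CIELAB colour
#'
#' @param L lightness, 0--100.
#' @param a green (-) / red (+) axis.
#' @param b blue (-) / yellow (+) axis.
#' @return an object of class `lab_color` (named numeric vector).
#' @export
lab_color <- function(L, a, b) {
  check_number(L, "L", min = 0, max = 100)
  check_number(a, "a")
  check_number(b, "b")
  structure(c(L = L, a = a, b = b), class = "lab_color")
}

as_lab <- function(x) {
  if (inherits(x, "lab_color")) return(unclass(x))
  if (is.numeric(x) && length(x) == 3L) {
    return(c(L = unname(x[1L]), a = unname(x[2L]), b = unname(x[3L])))
  }
  abort("expected a lab_color or numeric L/a/b triplet", "crumblab_bad_arg")
}

#' Average replicate colour readings
#'
#' Channel-wise arithmetic mean of CIELAB readings, as used when several
#' sensor readings per measurement group are averaged before reporting.
#'
#' @param readings a list of [lab_color()]s / numeric triplets, or a
#'   data.frame with columns `L`, `a`, `b`.
#' @return a [lab_color()].
#' @export
average_readings <- function(readings) {
  if (is.data.frame(readings)) {
    if (nrow(readings) == 0L) abort("no readings to average", "crumblab_bad_arg")
    return(lab_color(mean(readings$L), mean(readings$a), mean(readings$b)))
  }
  if (length(readings) == 0L) abort("no readings to average", "crumblab_bad_arg")
  m <- colMeans(do.call(rbind, lapply(readings, as_lab)))
  lab_color(m[["L"]], m[["a"]], m[["b"]])
}

## five perceptual bands, half-open on the left boundary: a value on a
## boundary belongs to the upper band
.DELTA_E_BANDS <- data.frame(
  lower = c(0, 1, 2, 3.5, 5),
  upper = c(1, 2, 3.5, 5, Inf),
  label = c("imperceptible", "slight", "noticeable", "substantial", "distinct"),
  stringsAsFactors = FALSE
)

#' Classify a total colour difference into perceptual bands
#'
#' Bands: `[0, 1)` imperceptible to the human eye, `[1, 2)` slight
#' (visible to trained observers), `[2, 3.5)` noticeable even for
#' unexperienced observers, `[3.5, 5)` substantial, and `[5, Inf)`
#' distinctly different colours. Boundary values belong to the upper
#' band.
#'
#' @param value Delta E value(s), >= 0 (vectorised).
#' @return character vector of band labels.
#' @export
classify_delta_e <- function(value) {
  if (any(!is.finite(value)) || any(value < 0)) {
    abort("Delta E must be finite and non-negative", "crumblab_bad_arg")
  }
  idx <- findInterval(value, .DELTA_E_BANDS$lower)  # boundary -> upper band
  .DELTA_E_BANDS$label[idx]
}

#' Total colour difference between two CIELAB colours
#'
#' Computes Delta E and its perceptual band. The primary formula is
#' CIE76, the Euclidean distance
#' \deqn{\Delta E = \sqrt{\Delta L^{*2} + \Delta a^{*2} + \Delta b^{*2}},}
#' which is symmetric in its arguments. CIEDE2000 is available behind
#' `method = "ciede2000"` but is never the default.
#'
#' @param reference,sample [lab_color()]s (conventionally the reference
#'   is the 0%-substitution control of the same material).
#' @param method `"cie76"` (default) or `"ciede2000"`.
#' @return a list of class `delta_e_result` with `delta_e`, `band_label`
#'   and `method`.
#' @export
delta_e <- function(reference, sample, method = c("cie76", "ciede2000")) {
  method <- match.arg(method)
  r <- as_lab(reference); s <- as_lab(sample)
  de <- if (method == "cie76") {
    sqrt(sum((r - s)^2))
  } else {
    ciede2000(r, s)
  }
  structure(list(delta_e = de, band_label = classify_delta_e(de),
                 method = method),
            class = "delta_e_result")
}

#' @export
print.delta_e_result <- function(x, ...) {
  cat(sprintf("Delta E (%s) = %.4g [%s]\n", x$method, x$delta_e, x$band_label))
  invisible(x)
}

## CIEDE2000 (Sharma, Wu & Dalal 2005 formulation); optional variant only
ciede2000 <- function(r, s, kL = 1, kC = 1, kH = 1) {
  C1 <- sqrt(r[["a"]]^2 + r[["b"]]^2)
  C2 <- sqrt(s[["a"]]^2 + s[["b"]]^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * r[["a"]]; a2p <- (1 + G) * s[["a"]]
  C1p <- sqrt(a1p^2 + r[["b"]]^2); C2p <- sqrt(a2p^2 + s[["b"]]^2)
  h1p <- if (C1p == 0) 0 else (atan2(r[["b"]], a1p) * 180 / pi) %% 360
  h2p <- if (C2p == 0) 0 else (atan2(s[["b"]], a2p) * 180 / pi) %% 360
  dLp <- s[["L"]] - r[["L"]]
  dCp <- C2p - C1p
  dhp <- if (C1p * C2p == 0) 0 else {
    d <- h2p - h1p
    if (d > 180) d - 360 else if (d < -180) d + 360 else d
  }
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp * pi / 360)
  Lbp <- (r[["L"]] + s[["L"]]) / 2
  Cbp <- (C1p + C2p) / 2
  hbp <- if (C1p * C2p == 0) h1p + h2p else {
    d <- abs(h1p - h2p); su <- h1p + h2p
    if (d <= 180) su / 2 else if (su < 360) (su + 360) / 2 else (su - 360) / 2
  }
  Tt <- 1 - 0.17 * cos((hbp - 30) * pi / 180) + 0.24 * cos(2 * hbp * pi / 180) +
    0.32 * cos((3 * hbp + 6) * pi / 180) - 0.20 * cos((4 * hbp - 63) * pi / 180)
  dTheta <- 30 * exp(-(((hbp - 275) / 25)^2))
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * Tt
  RT <- -sin(2 * dTheta * pi / 180) * RC
  sqrt((dLp / (kL * SL))^2 + (dCp / (kC * SC))^2 + (dHp / (kH * SH))^2 +
         RT * (dCp / (kC * SC)) * (dHp / (kH * SH)))
}

#' Fit a linear trend of a colour channel against substitution level
#'
#' Ordinary least squares of per-level responses (e.g. mean L*) on the
#' substitution percentage, with the Pearson correlation and the standard
#' error of the slope. When the responses have zero variance the slope is
#' 0 and `pearson_r` is defined as 0 by convention.
#'
#' @param levels substitution levels (%), at least 3 distinct values.
#' @param responses channel values, one per level.
#' @return a list of class `trend_fit` with `slope`, `intercept`,
#'   `pearson_r`, `slope_se` and `fitted` (per-level fitted values).
#' @export
fit_color_trend <- function(levels, responses) {
  if (length(levels) != length(responses)) {
    abort("levels and responses must have equal length", "crumblab_bad_arg")
  }
  if (length(unique(levels)) < 3L) {
    abort("need >= 3 distinct substitution levels", "crumblab_bad_arg")
  }
  if (var(levels) == 0) abort("zero variance in levels", "crumblab_bad_arg")
  if (var(responses) == 0) {
    return(structure(list(slope = 0, intercept = responses[1L], pearson_r = 0,
                          slope_se = 0, fitted = responses),
                     class = "trend_fit"))
  }
  fit <- lm(responses ~ levels)
  ## summary.lm warns on exactly collinear data; the zero SE is correct
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 pearson_r = unname(cor(levels, responses)),
                 slope_se = unname(sm$coefficients[2L, 2L]),
                 fitted = unname(fitted(fit))),
            class = "trend_fit")
}

#' Generate replicate CIELAB readings around group means
#'
#' Per group, draws `n_replicates` Gaussian readings per channel around
#' the group mean -- a stand-in for repeated colour-sensor readings of the
#' same sample.
#'
#' @param group_means named list of [lab_color()]s (names are group
#'   labels).
#' @param sd per-channel Gaussian SD (single value or length-3 `L`,`a`,`b`).
#' @param n_replicates readings per group, >= 1.
#' @param seed integer seed; same seed gives an identical table.
#' @return data.frame with columns `group`, `replicate`, `L`, `a`, `b`.
#' @export
generate_color_readings <- function(group_means, sd = 0.5, n_replicates = 3L,
                                    seed = 1L) {
  if (length(group_means) == 0L) abort("no groups", "crumblab_bad_arg")
  if (is.null(names(group_means)) || any(names(group_means) == "")) {
    abort("group_means must be a named list", "crumblab_bad_arg")
  }
  if (any(sd < 0)) abort("negative sd rejected", "crumblab_bad_arg")
  check_number(n_replicates, "n_replicates", min = 1)
  sd <- rep_len(sd, 3L)
  with_seed(seed, {
    rows <- lapply(names(group_means), function(g) {
      m <- as_lab(group_means[[g]])
      data.frame(
        group = g, replicate = seq_len(n_replicates),
        L = m[["L"]] + rnorm(n_replicates, 0, sd[1L]),
        a = m[["a"]] + rnorm(n_replicates, 0, sd[2L]),
        b = m[["b"]] + rnorm(n_replicates, 0, sd[3L]),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}
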