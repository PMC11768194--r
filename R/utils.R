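## internal helpers shared across modules

abort <- function(msg, class) {
  stop(structure(
    class = c(class, "crumblab_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is_number(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]",
                  name, format(min), format(max)), "crumblab_bad_arg")
  }
  x
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE", name), "crumblab_bad_arg")
  }
  x
}

## linear interpolation of the crossing time where y passes `level`
## between samples i and i+1 (assumes y[i], y[i+1] bracket the level)
crossing_time <- function(t, y, i, level) {
  if (y[i + 1L] == y[i]) return(t[i])
  t[i] + (level - y[i]) * (t[i + 1L] - t[i]) / (y[i + 1L] - y[i])
}

## first index where x >= level, NA if never
first_at_or_above <- function(x, level) {
  i <- which(x >= level)
  if (length(i) == 0L) NA_integer_ else i[1L]
}

## Shape-preserving piecewise-cubic Hermite interpolant (PCHIP,
## Fritsch-Carlson slopes). Unlike splinefun(method = "monoH.FC") it sets
## the derivative to zero at interior local extrema, so the interpolant
## never overshoots an anchor: monotone on every interval between
## adjacent anchors. Returns a function of xout.
pchip_fun <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 2L, length(y) == n, all(diff(x) > 0))
  h <- diff(x)
  d <- diff(y) / h
  m <- numeric(n)
  if (n == 2L) {
    m[] <- d
  } else {
    for (i in 2:(n - 1L)) {
      if (d[i - 1L] * d[i] <= 0) {
        m[i] <- 0
      } else {
        w1 <- 2 * h[i] + h[i - 1L]
        w2 <- h[i] + 2 * h[i - 1L]
        m[i] <- (w1 + w2) / (w1 / d[i - 1L] + w2 / d[i])
      }
    }
    edge <- function(h1, h2, d1, d2) {
      mm <- ((2 * h1 + h2) * d1 - h1 * d2) / (h1 + h2)
      if (sign(mm) != sign(d1)) 0
      else if (sign(d1) != sign(d2) && abs(mm) > 3 * abs(d1)) 3 * d1
      else mm
    }
    m[1L] <- edge(h[1L], h[2L], d[1L], d[2L])
    m[n] <- edge(h[n - 1L], h[n - 2L], d[n - 1L], d[n - 2L])
  }
  function(xout) {
    i <- findInterval(xout, x, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), n - 1L)
    t <- (xout - x[i]) / h[i]
    h00 <- (1 + 2 * t) * (1 - t)^2
    h10 <- t * (1 - t)^2
    h01 <- t^2 * (3 - 2 * t)
    h11 <- t^2 * (t - 1)
    h00 * y[i] + h10 * h[i] * m[i] + h01 * y[i + 1L] + h11 * h[i] * m[i + 1L]
  }
}
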