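## Boolean-model crumb scenes: random non-overlapping darker disks (air
## cells) inside an elliptical "slice" on a pure-white background, with
## known per-pore ground truth. Emulates a background-removed photograph
## of a bread slice on a white matte surface.

#' Specification of a synthetic crumb scene
#'
#' Describes a ground-truthed synthetic bread-slice image: an elliptical
#' slice of matrix (crumb) intensity on a white background, with
#' `n_pores` darker disks whose radii follow a lognormal distribution.
#'
#' @param image_width,image_height image size in pixels.
#' @param slice_shape semi-axes of the slice ellipse, in pixels, as
#'   `c(rx, ry)` (columns, rows); the ellipse is centred in the image.
#' @param n_pores number of air cells to place.
#' @param pore_radius_median,pore_radius_sigma lognormal radius
#'   distribution: median in pixels and log-scale sigma.
#' @param allow_overlap may disks overlap? When `FALSE`, placement
#'   enforces centre distance >= r_i + r_j + `min_separation`.
#' @param min_separation extra clearance (px) between non-overlapping
#'   disks so that rasterized pores are never 8-adjacent.
#' @param matrix_intensity,pore_intensity grey levels (0--255) of crumb
#'   matrix and pores; pores must be darker.
#' @param noise_sd additive Gaussian noise SD in grey levels (applied
#'   inside the slice only; the removed background stays pure white).
#' @param illumination_gradient maximum fractional shading across the
#'   image width (0 = flat illumination).
#' @param seed integer seed; the same spec (including seed) always
#'   produces a bit-identical scene.
#' @return an object of class `crumb_scene_spec`.
#' @export
crumb_scene_spec <- function(image_width = 640L, image_height = 480L,
                             slice_shape = c(300, 220), n_pores = 40L,
                             pore_radius_median = 8, pore_radius_sigma = 0.4,
                             allow_overlap = FALSE, min_separation = 3,
                             matrix_intensity = 200, pore_intensity = 120,
                             noise_sd = 5, illumination_gradient = 0,
                             seed = 1L) {
  check_number(image_width, "image_width", min = 8)
  check_number(image_height, "image_height", min = 8)
  if (length(slice_shape) != 2L || any(slice_shape <= 0)) {
    abort("`slice_shape` must be two positive semi-axes (px)",
          "crumblab_bad_arg")
  }
  check_number(n_pores, "n_pores", min = 0)
  check_number(pore_radius_median, "pore_radius_median", min = 1e-6)
  check_number(pore_radius_sigma, "pore_radius_sigma", min = 0)
  check_flag(allow_overlap, "allow_overlap")
  check_number(min_separation, "min_separation", min = 0)
  check_number(matrix_intensity, "matrix_intensity", min = 0, max = 255)
  check_number(pore_intensity, "pore_intensity", min = 0, max = 255)
  if (pore_intensity >= matrix_intensity) {
    abort("pores must be darker than the matrix (pore_intensity < matrix_intensity)",
          "crumblab_bad_arg")
  }
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(illumination_gradient, "illumination_gradient", min = 0, max = 0.99)
  check_number(seed, "seed")
  structure(list(
    image_width = as.integer(image_width),
    image_height = as.integer(image_height),
    slice_shape = as.numeric(slice_shape), n_pores = as.integer(n_pores),
    pore_radius_median = pore_radius_median,
    pore_radius_sigma = pore_radius_sigma,
    allow_overlap = allow_overlap, min_separation = min_separation,
    matrix_intensity = matrix_intensity, pore_intensity = pore_intensity,
    noise_sd = noise_sd, illumination_gradient = illumination_gradient,
    seed = as.integer(seed)
  ), class = "crumb_scene_spec")
}

## evaluate code with a private, restored RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

ellipse_mask <- function(h, w, rx, ry) {
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  col <- matrix(seq_len(w), h, w, byrow = TRUE)
  row <- matrix(seq_len(h), h, w)
  ((col - cx) / rx)^2 + ((row - cy) / ry)^2 <= 1
}

#' Generate a synthetic crumb image with ground truth
#'
#' Places disks by rejection sampling inside the slice ellipse, rasterizes
#' them darker than the matrix, then applies an optional linear
#' illumination gradient and additive Gaussian noise (clipped to 0--255)
#' inside the slice. The background outside the slice stays pure white
#' (255), emulating background removal. Ground truth is derived from the
#' noise-free label mask.
#'
#' @param spec a [crumb_scene_spec()].
#' @return a list with components
#'   * `image`: a [new_crumb_image()] (pixels + slice mask),
#'   * `truth`: class `crumb_ground_truth` with `label_mask` (integer
#'     matrix, 0 = matrix/background), `region_table` (data.frame:
#'     `region_id`, `area`, `centroid_row`, `centroid_col`, `radius`) and
#'     `n_pores`.
#' @export
generate_crumb_image <- function(spec) {
  stopifnot(inherits(spec, "crumb_scene_spec"))
  h <- spec$image_height; w <- spec$image_width
  rx <- spec$slice_shape[1L]; ry <- spec$slice_shape[2L]
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  mask <- ellipse_mask(h, w, rx, ry)

  pores <- with_seed(spec$seed, {
    n <- spec$n_pores
    px <- numeric(n); py <- numeric(n); pr <- numeric(n)
    placed <- 0L
    attempts <- 0L
    max_attempts <- 1000L * max(n, 1L)
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        abort("scene too crowded: pore placement failed", "crumblab_crowded")
      }
      x <- runif(1, 1, w); y <- runif(1, 1, h)
      if (((x - cx) / rx)^2 + ((y - cy) / ry)^2 > 1) next
      r <- exp(rnorm(1, log(spec$pore_radius_median), spec$pore_radius_sigma))
      if (!spec$allow_overlap && placed > 0L) {
        i <- seq_len(placed)
        if (any(sqrt((px[i] - x)^2 + (py[i] - y)^2) <=
                pr[i] + r + spec$min_separation)) next
      }
      placed <- placed + 1L
      px[placed] <- x; py[placed] <- y; pr[placed] <- r
    }
    noise <- if (spec$noise_sd > 0) rnorm(sum(mask), 0, spec$noise_sd) else NULL
    list(x = px, y = py, r = pr, noise = noise)
  })

  labels <- matrix(0L, h, w)
  for (k in seq_len(spec$n_pores)) {
    x0 <- pores$x[k]; y0 <- pores$y[k]; r <- pores$r[k]
    rows <- max(1L, floor(y0 - r)):min(h, ceiling(y0 + r))
    cols <- max(1L, floor(x0 - r)):min(w, ceiling(x0 + r))
    sub_r <- matrix(rows, length(rows), length(cols))
    sub_c <- matrix(cols, length(rows), length(cols), byrow = TRUE)
    inside <- (sub_c - x0)^2 + (sub_r - y0)^2 <= r^2
    idx <- cbind(sub_r[inside], sub_c[inside])
    labels[idx] <- k
  }
  labels[!mask] <- 0L  # background removal clips pores at the slice edge

  img <- matrix(255, h, w)
  img[mask] <- spec$matrix_intensity
  img[labels > 0L] <- spec$pore_intensity
  if (spec$illumination_gradient > 0) {
    shade <- 1 - spec$illumination_gradient *
      (matrix(seq_len(w), h, w, byrow = TRUE) - 1) / (w - 1)
    img[mask] <- img[mask] * shade[mask]
  }
  if (!is.null(pores$noise)) img[mask] <- img[mask] + pores$noise
  img <- round(pmin(pmax(img, 0), 255))

  ids <- sort(unique(labels[labels > 0L]))
  region_table <- if (length(ids) == 0L) {
    data.frame(region_id = integer(), area = integer(),
               centroid_row = numeric(), centroid_col = numeric(),
               radius = numeric())
  } else {
    area <- tabulate(labels, nbins = spec$n_pores)[ids]
    idx <- which(labels > 0L, arr.ind = TRUE)
    lab <- labels[labels > 0L]
    data.frame(
      region_id = ids,
      area = area,
      centroid_row = as.numeric(tapply(idx[, 1L], lab, mean)[as.character(ids)]),
      centroid_col = as.numeric(tapply(idx[, 2L], lab, mean)[as.character(ids)]),
      center_row = pores$y[ids],
      center_col = pores$x[ids],
      radius = pores$r[ids]
    )
  }

  list(
    image = new_crumb_image(img, mask),
    truth = structure(list(label_mask = labels, region_table = region_table,
                           n_pores = length(ids)),
                      class = "crumb_ground_truth")
  )
}
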