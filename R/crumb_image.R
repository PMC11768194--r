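## Crumb cell structure analysis: background masking, Otsu (between-class
## variance) pore/matrix segmentation inside the slice mask, connected
## component labelling, region properties, size-class counting and an
## area-coded colourmap rendering.

#' Crumb image container
#'
#' @param pixels numeric matrix of grey intensities 0--255.
#' @param slice_mask logical matrix of the same size; `TRUE` marks bread
#'   slice pixels, `FALSE` removed background.
#' @param scale optional pixels-per-mm calibration.
#' @return an object of class `crumb_image`.
#' @export
new_crumb_image <- function(pixels, slice_mask = NULL, scale = NULL) {
  if (!is.matrix(pixels)) abort("pixels must be a matrix", "crumblab_bad_arg")
  if (is.null(slice_mask)) slice_mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  if (!is.logical(slice_mask) || !identical(dim(pixels), dim(slice_mask))) {
    abort("slice_mask must be a logical matrix matching pixels",
          "crumblab_bad_arg")
  }
  structure(list(pixels = pixels, slice_mask = slice_mask, scale = scale),
            class = "crumb_image")
}

#' @export
print.crumb_image <- function(x, ...) {
  cat(sprintf("<crumb_image> %d x %d px, slice = %d px (%.1f%%)\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$slice_mask),
              100 * mean(x$slice_mask)))
  invisible(x)
}

## ITU-R BT.601 luminance
rgb_to_grey <- function(img) {
  0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
}

## separable box filter (partial windows at the borders)
box_smooth <- function(m, k = 3L) {
  if (k <= 1L) return(m)
  run <- function(v) {
    n <- length(v)
    half <- (k - 1L) %/% 2L
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  m <- apply(m, 2L, run)
  t(apply(m, 1L, run))
}

#' Load a bread-slice image and derive its slice mask
#'
#' Reads an image (or accepts an in-memory array) and separates the bread
#' slice from the removed background. RGB input is converted to grey by
#' standard luminance weights.
#'
#' @param image a file path accepted by [read_image()], or a numeric
#'   matrix / `H x W x C` array on the 0--255 scale.
#' @param background_mode one of `"white_threshold"` (background is the
#'   near-white fill left by background removal; slice = intensity <
#'   `white_cutoff`), `"alpha"` (slice = alpha > 0; input must carry an
#'   alpha channel) or `"none"` (whole frame is slice).
#' @param white_cutoff intensity cutoff for `"white_threshold"` mode.
#' @param scale optional pixels-per-mm.
#' @return a [new_crumb_image()] object.
#' @export
load_slice <- function(image,
                       background_mode = c("white_threshold", "alpha", "none"),
                       white_cutoff = 250, scale = NULL) {
  background_mode <- match.arg(background_mode)
  img <- if (is.character(image)) read_image(image) else image
  alpha <- NULL
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3L]
    if (nc == 4L) { alpha <- img[, , 4L]; img <- img[, , 1:3] }
    if (nc == 2L) { alpha <- img[, , 2L]; img <- img[, , 1L] }
    if (!is.matrix(img)) img <- rgb_to_grey(img)
  }
  if (!is.matrix(img)) abort("unsupported image shape", "crumblab_bad_arg")
  mask <- switch(background_mode,
    white_threshold = img < white_cutoff,
    alpha = {
      if (is.null(alpha)) abort("alpha mode requires an alpha channel",
                                "crumblab_bad_arg")
      alpha > 0
    },
    none = matrix(TRUE, nrow(img), ncol(img))
  )
  if (!any(mask)) abort("empty slice", "crumblab_empty_slice")
  new_crumb_image(img, mask, scale = scale)
}

#' Otsu threshold of a set of intensities
#'
#' Global threshold by between-class variance maximization over a 256-bin
#' histogram (the "statistical image segmentation" of the texture
#' analyzer). Returns the grey level `t` such that foreground = intensity
#' `<= t`; ties resolved toward the lowest level.
#'
#' @param values numeric intensities, 0--255.
#' @return threshold level, or `NA` (with a `"no contrast"` warning) when
#'   the input has a single intensity.
#' @export
otsu_threshold <- function(values) {
  v <- round(values)
  if (length(unique(v)) < 2L) {
    warning("no contrast: single intensity value, threshold undefined",
            call. = FALSE)
    return(NA_real_)
  }
  counts <- tabulate(v + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  omega <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[256L]
  valid <- omega > 0 & omega < 1
  sigma_b <- rep(-Inf, 256L)
  sigma_b[valid] <- (mu_t * omega[valid] - mu[valid])^2 /
    (omega[valid] * (1 - omega[valid]))
  levels[which.max(sigma_b)]
}

## 2-means (Lloyd) split on intensities; alternative to Otsu
kmeans2_threshold <- function(values) {
  v <- as.numeric(values)
  if (length(unique(round(v))) < 2L) {
    warning("no contrast: single intensity value, threshold undefined",
            call. = FALSE)
    return(NA_real_)
  }
  c1 <- min(v); c2 <- max(v)
  for (i in 1:100) {
    cut <- (c1 + c2) / 2
    lo <- v <= cut
    n1 <- mean(v[lo]); n2 <- mean(v[!lo])
    if (isTRUE(all.equal(c(n1, n2), c(c1, c2)))) break
    c1 <- n1; c2 <- n2
  }
  floor((c1 + c2) / 2)
}

#' Size-class and segmentation configuration
#'
#' Area bands for the small/medium/large pore counts and the labelling
#' settings. The band boundaries are explicit configuration (they are
#' resolution-dependent and reported with every output), never hidden
#' constants.
#'
#' @param small_max exclusive upper area bound (px^2) of "small" pores.
#' @param medium_max exclusive upper area bound (px^2) of "medium" pores.
#' @param min_area noise floor: regions below this area are discarded.
#' @param connectivity pixel connectivity, 4 or 8.
#' @param method threshold method, `"otsu"` or `"kmeans"`.
#' @return an object of class `size_class_config`.
#' @export
size_class_config <- function(small_max = 100, medium_max = 1000,
                              min_area = 2, connectivity = 8,
                              method = c("otsu", "kmeans")) {
  method <- match.arg(method)
  check_number(min_area, "min_area", min = 1e-9)
  check_number(small_max, "small_max")
  check_number(medium_max, "medium_max")
  if (!(min_area <= small_max && small_max < medium_max)) {
    abort("size classes require 0 < min_area <= small_max < medium_max",
          "crumblab_bad_arg")
  }
  if (!connectivity %in% c(4, 8)) {
    abort("connectivity must be 4 or 8", "crumblab_bad_arg")
  }
  structure(list(small_max = small_max, medium_max = medium_max,
                 min_area = min_area, connectivity = connectivity,
                 method = method),
            class = "size_class_config")
}

#' Label connected foreground components
#'
#' Connected-component labelling of a logical matrix at 4- or
#' 8-connectivity, built on a pixel-adjacency graph. Labels are compact
#' (1..n) and assigned in column-major order of each component's first
#' pixel, so the result is deterministic.
#'
#' @param fg logical matrix (TRUE = foreground).
#' @param connectivity 4 or 8.
#' @return integer matrix of labels, 0 = background.
#' @export
label_components <- function(fg, connectivity = 8) {
  h <- nrow(fg); w <- ncol(fg)
  labels <- matrix(0L, h, w)
  idx <- which(fg)
  if (length(idx) == 0L) return(labels)
  vid <- matrix(0L, h, w)
  vid[idx] <- seq_along(idx)
  rr <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  edge_to <- function(dr, dc) {
    ok <- rr + dr >= 1L & rr + dr <= h & cc + dc >= 1L & cc + dc <= w
    nb <- idx[ok] + dr + dc * h
    keep <- fg[nb]
    cbind(vid[idx[ok][keep]], vid[nb[keep]])
  }
  edges <- rbind(edge_to(1L, 0L), edge_to(0L, 1L))
  if (connectivity == 8) {
    edges <- rbind(edges, edge_to(1L, 1L), edge_to(-1L, 1L))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  ## renumber so labels follow column-major first-pixel order
  labels[idx] <- match(comp, unique(comp))
  labels
}

#' Segment pores in a crumb image
#'
#' Computes a global Otsu threshold from the within-mask intensity
#' histogram, marks in-mask pixels darker than (or equal to) the
#' threshold as pore, labels connected components at the configured
#' connectivity, discards components smaller than `min_area`, and
#' re-compacts the labels.
#'
#' The threshold is computed on a lightly denoised (3 x 3 box) copy of
#' the image but applied to the raw pixels: denoising keeps the
#' between-class criterion from splitting the matrix noise when pores
#' occupy a small fraction of the slice, while raw-pixel classification
#' preserves exact pore boundaries on clean images.
#'
#' @param image a [new_crumb_image()] / [load_slice()] result.
#' @param config a [size_class_config()].
#' @return integer label matrix (0 = matrix/background). A slice with no
#'   contrast yields zero regions (with a warning), not an error.
#' @export
segment_pores <- function(image, config = size_class_config()) {
  stopifnot(inherits(image, "crumb_image"))
  if (!any(image$slice_mask)) abort("empty slice mask", "crumblab_empty_slice")
  vals <- box_smooth(image$pixels)[image$slice_mask]
  thr <- if (config$method == "otsu") otsu_threshold(vals) else kmeans2_threshold(vals)
  h <- nrow(image$pixels)
  if (is.na(thr)) return(matrix(0L, h, ncol(image$pixels)))
  fg <- image$slice_mask & image$pixels <= thr
  labels <- label_components(fg, config$connectivity)
  if (max(labels) == 0L) return(labels)
  areas <- tabulate(labels)
  keep <- which(areas >= config$min_area)
  remap <- integer(length(areas))
  remap[keep] <- seq_along(keep)
  labels[labels > 0L] <- remap[labels[labels > 0L]]
  labels
}

#' Extract per-region properties from a label map
#'
#' @param labels integer label matrix (from [segment_pores()]).
#' @param image optional [new_crumb_image()] supplying a px-per-mm scale.
#' @return data.frame with one row per region: `region_id`, `area` (px^2;
#'   plus `area_mm2` when a scale is available), `centroid_row`,
#'   `centroid_col`, `bbox_*` and `touches_border` (of the image frame).
#' @export
extract_regions <- function(labels, image = NULL) {
  n <- max(labels)
  if (n == 0L) {
    out <- data.frame(region_id = integer(), area = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      bbox_min_row = integer(), bbox_min_col = integer(),
                      bbox_max_row = integer(), bbox_max_col = integer(),
                      touches_border = logical())
    return(out)
  }
  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[labels > 0L]
  f <- factor(lab, levels = seq_len(n))
  rows <- split(idx[, 1L], f)
  cols <- split(idx[, 2L], f)
  out <- data.frame(
    region_id = seq_len(n),
    area = as.integer(lengths(rows)),
    centroid_row = vapply(rows, mean, 0),
    centroid_col = vapply(cols, mean, 0),
    bbox_min_row = vapply(rows, min, 0L),
    bbox_min_col = vapply(cols, min, 0L),
    bbox_max_row = vapply(rows, max, 0L),
    bbox_max_col = vapply(cols, max, 0L)
  )
  out$touches_border <- out$bbox_min_row == 1L | out$bbox_min_col == 1L |
    out$bbox_max_row == nrow(labels) | out$bbox_max_col == ncol(labels)
  if (!is.null(image) && !is.null(image$scale)) {
    out$area_mm2 <- out$area / image$scale^2
  }
  rownames(out) <- NULL
  out
}

#' Count pores by size class and compute density parameters
#'
#' Partitions retained regions into area bands
#' `[min_area, small_max)`, `[small_max, medium_max)` and
#' `[medium_max, Inf)` and reports the density-description parameters:
#' porosity (pore area / slice area), mean pore area and pore density per
#' 10^4 slice pixels.
#'
#' @param regions region table from [extract_regions()].
#' @param slice_area slice area in px^2 (> 0), e.g.
#'   `sum(image$slice_mask)`.
#' @param config a [size_class_config()].
#' @return a list of class `pore_statistics`: `n_small`, `n_medium`,
#'   `n_large`, `n_total`, `porosity`, `mean_pore_area`, `pore_density`,
#'   and the band boundaries used.
#' @export
classify_sizes <- function(regions, slice_area, config = size_class_config()) {
  check_number(slice_area, "slice_area", min = 1e-9)
  a <- regions$area
  a <- a[a >= config$min_area]  # no-op for segment_pores output
  n_small <- sum(a < config$small_max)
  n_medium <- sum(a >= config$small_max & a < config$medium_max)
  n_large <- sum(a >= config$medium_max)
  structure(list(
    n_small = n_small, n_medium = n_medium, n_large = n_large,
    n_total = length(a),
    porosity = sum(a) / slice_area,
    mean_pore_area = if (length(a) == 0L) 0 else mean(a),
    pore_density = 1e4 * length(a) / slice_area,
    small_max = config$small_max, medium_max = config$medium_max,
    min_area = config$min_area
  ), class = "pore_statistics")
}

#' @export
print.pore_statistics <- function(x, ...) {
  cat(sprintf(
    "<pore_statistics> total %d (small %d / medium %d / large %d), porosity %.3f, mean area %.1f px^2, density %.2f per 10^4 px^2\n  bands: small < %g <= medium < %g <= large (min_area %g)\n",
    x$n_total, x$n_small, x$n_medium, x$n_large, x$porosity,
    x$mean_pore_area, x$pore_density, x$small_max, x$medium_max, x$min_area))
  invisible(x)
}

#' Render a label map with regions colour-coded by area
#'
#' Maps each region's area through a per-image normalization (smallest
#' area -> first colormap entry, largest -> last), so the same area can
#' receive different colours on images with different area ranges. All
#' regions of equal area (degenerate range) get the midpoint colour.
#' Matrix and background are rendered neutral.
#'
#' @param labels label matrix from [segment_pores()].
#' @param regions matching region table from [extract_regions()].
#' @param palette function `n -> n colours`, default
#'   [viridisLite::viridis].
#' @param matrix_col,background_col neutral fill colours.
#' @return an `H x W x 3` numeric array, 0--255.
#' @export
render_colourmap <- function(labels, regions,
                             palette = viridisLite::viridis,
                             matrix_col = "grey85", background_col = "white") {
  n_col <- 256L
  pal <- t(col2rgb(palette(n_col)))
  base <- t(col2rgb(c(matrix_col, background_col)))
  h <- nrow(labels); w <- ncol(labels)
  out <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3) out[, , ch] <- base[1L, ch]
  if (nrow(regions) > 0L) {
    rng <- range(regions$area)
    pos <- if (rng[1L] == rng[2L]) {
      rep((n_col + 1L) %/% 2L, nrow(regions))
    } else {
      1L + as.integer(round((n_col - 1L) *
                              (regions$area - rng[1L]) / (rng[2L] - rng[1L])))
    }
    colour_of <- matrix(pal[pos, , drop = FALSE], ncol = 3L)
    in_region <- labels > 0L
    lab <- labels[in_region]
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[in_region] <- colour_of[lab, ch]
      out[, , ch] <- plane
    }
  }
  out
}

#' One-call crumb analysis
#'
#' Convenience wrapper: segment, extract regions and classify sizes.
#'
#' @inheritParams segment_pores
#' @return list with `labels`, `regions` and `stats`
#'   (a `pore_statistics`).
#' @export
analyze_crumb <- function(image, config = size_class_config()) {
  labels <- segment_pores(image, config)
  regions <- extract_regions(labels, image)
  stats <- classify_sizes(regions, sum(image$slice_mask), config)
  list(labels = labels, regions = regions, stats = stats)
}
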