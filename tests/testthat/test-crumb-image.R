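test_that("load_slice handles white-threshold, alpha and degenerate input", {
  # fully white image has no slice
  white <- matrix(255, 20, 20)
  expect_error(load_slice(white, "white_threshold"), "empty slice",
               class = "crumblab_empty_slice")
  # generated scene: recovered mask equals the generator's ellipse exactly
  sc <- generate_crumb_image(crumb_scene_spec(n_pores = 5, noise_sd = 5,
                                              seed = 3))
  img <- load_slice(sc$image$pixels, "white_threshold")
  expect_identical(img$slice_mask, sc$image$slice_mask)
  # alpha passthrough
  rgba <- array(128, dim = c(10, 12, 4))
  rgba[, , 4] <- 0
  rgba[3:6, 4:9, 4] <- 255
  img2 <- load_slice(rgba, "alpha")
  expect_identical(img2$slice_mask, rgba[, , 4] > 0)
  # none mode takes the whole frame
  expect_true(all(load_slice(white, "none")$slice_mask))
})

test_that("label_components agrees with a flood-fill oracle at both connectivities", {
  # two disks touching at one diagonal pixel pair
  fg <- matrix(FALSE, 6, 6)
  fg[2, 2] <- TRUE; fg[2, 3] <- TRUE; fg[3, 2] <- TRUE
  fg[4, 4] <- TRUE; fg[4, 5] <- TRUE; fg[5, 4] <- TRUE
  fg[3, 3] <- TRUE  # diagonal bridge pixel pair (3,3)-(4,4)
  expect_identical(max(label_components(fg, 8)), 1L)
  expect_identical(max(label_components(fg, 4)), 2L)
  # property: random masks match the reference flood fill
  set.seed(11)
  for (i in 1:8) {
    m <- matrix(runif(30 * 25) < 0.35, 30, 25)
    for (conn in c(4, 8)) {
      got <- label_components(m, conn)
      ref <- flood_fill_labels(m, conn)
      expect_identical(max(got), max(ref))
      # same partition (labels may be permuted): 1-to-1 label mapping
      expect_true(all(tapply(got[m], ref[m],
                             function(x) length(unique(x))) == 1L))
      expect_true(all(tapply(ref[m], got[m],
                             function(x) length(unique(x))) == 1L))
    }
  }
})

test_that("noiseless segmentation recovers the ground truth exactly", {
  sc <- generate_crumb_image(crumb_scene_spec(n_pores = 10, noise_sd = 0,
                                              seed = 21))
  lab <- segment_pores(sc$image)
  expect_identical(max(lab), 10L)
  expect_identical(lab > 0L, sc$truth$label_mask > 0L)
  reg <- extract_regions(lab)
  key <- function(d) paste(d$area, round(d$centroid_row, 6),
                           round(d$centroid_col, 6))
  expect_setequal(key(reg), key(sc$truth$region_table))
})

test_that("no contrast and no pores are handled as zero regions", {
  flat <- new_crumb_image(matrix(180, 30, 30))
  expect_warning(lab <- segment_pores(flat), "no contrast")
  expect_identical(max(lab), 0L)
  expect_identical(nrow(extract_regions(lab)), 0L)
})

test_that("extract_regions reports hand-computable properties", {
  lab <- matrix(0L, 8, 8)
  lab[1:3, 1:3] <- 1L
  reg <- extract_regions(lab)
  expect_identical(reg$area, 9L)
  expect_equal(reg$centroid_row, 2)
  expect_equal(reg$centroid_col, 2)
  expect_true(reg$touches_border)
  expect_identical(nrow(extract_regions(matrix(0L, 4, 4))), 0L)
})

test_that("classify_sizes bands, partition identity and config validation", {
  reg <- data.frame(area = c(5, 50, 500, 5000))
  st <- classify_sizes(reg, slice_area = 1e5,
                       size_class_config(small_max = 100, medium_max = 1000,
                                         min_area = 2))
  expect_identical(c(st$n_small, st$n_medium, st$n_large, st$n_total),
                   c(2L, 1L, 1L, 4L))
  expect_equal(st$porosity, 5555 / 1e5)
  st0 <- classify_sizes(data.frame(area = numeric()), 100)
  expect_equal(c(st0$n_total, st0$mean_pore_area), c(0, 0))
  expect_equal(st0$porosity, 0)
  # partition identity on random areas
  set.seed(2)
  for (i in 1:20) {
    st <- classify_sizes(data.frame(area = round(runif(40, 2, 3000))), 1e5)
    expect_identical(st$n_small + st$n_medium + st$n_large, st$n_total)
  }
  expect_error(size_class_config(small_max = 100, medium_max = 50),
               "min_area <= small_max < medium_max")
})

test_that("porosity is invariant to 90-degree rotations and mirroring", {
  sc <- generate_crumb_image(crumb_scene_spec(n_pores = 20, noise_sd = 5,
                                              seed = 31))
  por <- function(px, mask) {
    analyze_crumb(new_crumb_image(px, mask))$stats$porosity
  }
  rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  p0 <- por(sc$image$pixels, sc$image$slice_mask)
  expect_equal(por(rot90(sc$image$pixels), rot90(sc$image$slice_mask)), p0)
  mir <- function(m) m[, ncol(m):1, drop = FALSE]
  expect_equal(por(mir(sc$image$pixels), mir(sc$image$slice_mask)), p0)
})

test_that("raising min_area never increases the total pore count", {
  sc <- generate_crumb_image(crumb_scene_spec(n_pores = 40, noise_sd = 9,
                                              seed = 41))
  totals <- sapply(c(2, 5, 20, 60, 120), function(ma) {
    cfg <- size_class_config(min_area = ma, small_max = 150)
    analyze_crumb(sc$image, cfg)$stats$n_total
  })
  expect_true(all(diff(totals) <= 0))
})

test_that("otsu and 2-means agree on a clean bimodal scene", {
  sc <- generate_crumb_image(crumb_scene_spec(n_pores = 12, noise_sd = 2,
                                              seed = 5))
  lab_o <- segment_pores(sc$image, size_class_config(method = "otsu"))
  lab_k <- segment_pores(sc$image, size_class_config(method = "kmeans"))
  expect_identical(lab_o > 0L, lab_k > 0L)
})

test_that("colourmap renders area-coded colours with per-image normalization", {
  mk <- function(areas) {
    lab <- matrix(0L, 12, sum(areas) + 10)
    col0 <- 1L
    for (i in seq_along(areas)) {
      lab[1, col0:(col0 + areas[i] - 1L)] <- i
      col0 <- col0 + areas[i] + 2L
    }
    list(labels = lab, regions = extract_regions(lab))
  }
  # equal areas: all regions take the same (midpoint) colour
  eq <- mk(c(20, 20))
  img <- render_colourmap(eq$labels, eq$regions)
  c1 <- img[1, 1, ]; c2 <- img[1, 23, ]
  expect_identical(c1, c2)
  # per-image normalization: a region of area 20 gets different colours
  # in images whose area ranges differ
  a <- mk(c(10, 20)); b <- mk(c(20, 40))
  col_a <- render_colourmap(a$labels, a$regions)[1, 12, ]
  col_b <- render_colourmap(b$labels, b$regions)[1, 1, ]
  expect_false(identical(col_a, col_b))
  # zero regions: neutral image
  none <- render_colourmap(matrix(0L, 5, 5), extract_regions(matrix(0L, 5, 5)))
  expect_identical(dim(none), c(5L, 5L, 3L))
  expect_true(all(none[, , 1] == none[1, 1, 1]))
  # deterministic
  expect_identical(render_colourmap(a$labels, a$regions),
                   render_colourmap(a$labels, a$regions))
})
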