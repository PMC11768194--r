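test_that("average_readings is the channel-wise mean", {
  r <- lab_color(80, 1, 10)
  expect_equal(unclass(average_readings(list(r, r, r))), unclass(r))
  m <- average_readings(list(lab_color(80, 0, 0), lab_color(82, 0, 0),
                             lab_color(84, 0, 0)))
  expect_equal(m[["L"]], 82)
  # brute-force oracle over random triplets
  set.seed(4)
  for (i in 1:200) {
    xs <- replicate(3, lab_color(runif(1, 0, 100), runif(1, -20, 20),
                                 runif(1, -20, 20)), simplify = FALSE)
    got <- average_readings(xs)
    brute <- (unclass(xs[[1]]) + unclass(xs[[2]]) + unclass(xs[[3]])) / 3
    expect_lt(max(abs(unclass(got) - brute)), 1e-12)
  }
  expect_error(average_readings(list()), "no readings")
})

test_that("delta_e matches the Euclidean formula and is a metric", {
  x <- lab_color(80, 1, 10)
  expect_equal(delta_e(x, x)$delta_e, 0)
  expect_identical(delta_e(x, x)$band_label, "imperceptible")
  # 3-4-5 identity
  expect_equal(delta_e(lab_color(50, 0, 0), lab_color(53, 0, 4))$delta_e, 5)
  set.seed(8)
  for (i in 1:1000) {
    a <- c(runif(1, 0, 100), runif(2, -30, 30))
    b <- c(runif(1, 0, 100), runif(2, -30, 30))
    brute <- sqrt(sum((a - b)^2))
    expect_lt(abs(delta_e(a, b)$delta_e - brute), 1e-12)
    expect_equal(delta_e(a, b)$delta_e, delta_e(b, a)$delta_e)  # symmetry
  }
  # triangle inequality over random triples
  for (i in 1:200) {
    p <- replicate(3, c(runif(1, 0, 100), runif(2, -30, 30)),
                   simplify = FALSE)
    expect_lte(delta_e(p[[1]], p[[3]])$delta_e,
               delta_e(p[[1]], p[[2]])$delta_e +
                 delta_e(p[[2]], p[[3]])$delta_e + 1e-12)
  }
})

test_that("ciede2000 variant is available but never default", {
  a <- lab_color(50, 2.6772, -79.7751)
  b <- lab_color(50, 0, -82.7485)
  # Sharma et al. reference pair #1: Delta E00 = 2.0425
  expect_lt(abs(delta_e(a, b, method = "ciede2000")$delta_e - 2.0425), 1e-4)
  expect_identical(delta_e(a, b)$method, "cie76")
})

test_that("classification bands partition [0, Inf) with printed boundaries", {
  expect_identical(classify_delta_e(0), "imperceptible")
  expect_identical(classify_delta_e(8.4), "distinct")
  # boundaries belong to the upper band
  expect_identical(classify_delta_e(c(1, 2, 3.5, 5)),
                   c("slight", "noticeable", "substantial", "distinct"))
  grid <- seq(0, 10, by = 0.005)
  lab <- classify_delta_e(grid)
  expect_true(all(lab %in% c("imperceptible", "slight", "noticeable",
                             "substantial", "distinct")))
  expect_identical(length(lab), length(grid))  # total, single-valued cover
  # band membership is consistent with the interval table
  expect_true(all(lab[grid < 1] == "imperceptible"))
  expect_true(all(lab[grid >= 1 & grid < 2] == "slight"))
  expect_true(all(lab[grid >= 2 & grid < 3.5] == "noticeable"))
  expect_true(all(lab[grid >= 3.5 & grid < 5] == "substantial"))
  expect_true(all(lab[grid >= 5] == "distinct"))
  expect_error(classify_delta_e(-0.1), "non-negative")
})

test_that("fit_color_trend recovers slopes and handles degeneracy", {
  lv <- c(0, 5, 10, 15, 20, 25, 30)
  fit <- fit_color_trend(lv, 2 * lv + 1)
  expect_equal(fit$pearson_r, 1)
  expect_equal(fit$slope, 2)
  expect_lt(max(abs(fit$fitted - (2 * lv + 1))), 1e-12)
  # simulation recovery: mean slope within 3 SE of the truth
  set.seed(12)
  slopes <- replicate(500, fit_color_trend(lv, 2 * lv + rnorm(7, 0, 0.1))$slope)
  expect_lt(abs(mean(slopes) - 2), 3 * sd(slopes) / sqrt(500))
  # constant responses: slope 0, r defined as 0
  flat <- fit_color_trend(lv, rep(3, 7))
  expect_identical(c(flat$slope, flat$pearson_r), c(0, 0))
  expect_error(fit_color_trend(c(0, 5), c(1, 2)), "3 distinct")
  expect_error(fit_color_trend(rep(1, 4), 1:4), "3 distinct")
})
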