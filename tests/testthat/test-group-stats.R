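test_that("group_data validates its invariants", {
  expect_error(group_data("a", 1), "2 groups")
  expect_error(group_data(c("a", "a", "b"), c(1, 2, 3)), "2 replicates")
  expect_error(group_data(c("a", "a", "b", "b"), c(1, NA, 3, 4)), "finite")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(14)
  for (i in 1:10) {
    y <- rnorm(12) + rep(c(0, runif(1, 0, 2)), each = 6)
    g <- rep(c("a", "b"), each = 6)
    av <- one_way_anova(group_data(g, y))
    tt <- t.test(y ~ g, var.equal = TRUE)
    expect_lt(abs(av$f - tt$statistic^2), 1e-9)
    expect_lt(abs(av$p - tt$p.value), 1e-12)
  }
})

test_that("ANOVA is invariant to shifts and scaling", {
  set.seed(15)
  gd <- random_group_data(4)
  f0 <- one_way_anova(gd)$f
  shifted <- group_data(gd$group, gd$value + 100)
  scaled <- group_data(gd$group, gd$value * 7)
  expect_equal(one_way_anova(shifted)$f, f0)
  expect_equal(one_way_anova(scaled)$f, f0)
})

test_that("degenerate inputs warn and take the documented path", {
  g <- rep(c("a", "b", "c"), each = 3)
  expect_warning(res <- one_way_anova(group_data(g, rep(5, 9))), "degenerate")
  expect_equal(res$p, 1)
  expect_warning(res2 <- one_way_anova(group_data(g, rep(c(1, 2, 3), each = 3))),
                 "degenerate")
  expect_equal(res2$p, 0)
  expect_warning(tk <- tukey_letters(group_data(g, rep(5, 9))), "degenerate")
  expect_true(all(tk$letters == "a"))
})

test_that("Tukey matches base TukeyHSD and separates a far group", {
  set.seed(16)
  y <- rnorm(12); g <- rep(letters[1:4], each = 3)
  tk <- tukey_letters(group_data(g, y))
  ref <- TukeyHSD(stats::aov(y ~ g))$g
  expect_lt(max(abs(sort(tk$pairs$p_adj) - sort(ref[, "p adj"]))), 1e-10)
  # two-group Tukey equals the unadjusted two-sample comparison
  y2 <- rnorm(8) + rep(c(0, 1), each = 4); g2 <- rep(c("a", "b"), each = 4)
  tk2 <- tukey_letters(group_data(g2, y2))
  expect_lt(abs(tk2$pairs$p_adj - t.test(y2 ~ g2, var.equal = TRUE)$p.value),
            1e-7)
  # far group shares no letter with the near pair
  set.seed(17)
  yf <- c(rnorm(3, 0, 0.01), rnorm(3, 0.01, 0.01), rnorm(3, 100, 0.01))
  gf <- rep(c("lo1", "lo2", "hi"), each = 3)
  tkf <- tukey_letters(group_data(gf, yf))
  expect_false(share_letter(tkf$letters[["hi"]], tkf$letters[["lo1"]]))
  expect_false(share_letter(tkf$letters[["hi"]], tkf$letters[["lo2"]]))
  expect_true(share_letter(tkf$letters[["lo1"]], tkf$letters[["lo2"]]))
  # "a" goes to the highest mean
  expect_identical(unname(tkf$letters[["hi"]]), "a")
})

test_that("letters are consistent with the pairwise p matrix (iff)", {
  set.seed(18)
  for (i in 1:60) {
    gd <- random_group_data(sample(3:6, 1), n = sample(2:4, 1),
                            mean_spread = runif(1, 0, 4))
    tk <- tukey_letters(gd)
    for (r in seq_len(nrow(tk$pairs))) {
      expect_identical(share_letter(tk$letters[[tk$pairs$group1[r]]],
                                    tk$letters[[tk$pairs$group2[r]]]),
                       tk$pairs$p_adj[r] >= tk$alpha)
    }
  }
})

test_that("lettered_table formats the usual mean +/- SD column", {
  gd <- group_data(rep(c("a", "b"), each = 3), c(1, 1.1, 0.9, 5, 5.2, 4.8))
  lt <- lettered_table(gd, digits = 2)
  expect_identical(lt$group, c("a", "b"))
  expect_match(lt$mean_sd[1], "^1\\.00 ± 0\\.10 [a-z]+$")
  expect_false(share_letter(lt$letters[1], lt$letters[2]))
})
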