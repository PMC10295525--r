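test_that("bilinear interpolation matches the hand formula", {
  z <- matrix(c(1, 3, 2, 8), 2, 2)  # corners (x1,y1)=1,(x2,y1)=3,(x1,y2)=2,(x2,y2)=8
  bl <- heatwind:::.bilinear
  # node values are returned exactly
  expect_equal(bl(c(0, 1), c(0, 1), z, c(0, 1, 0, 1), c(0, 0, 1, 1)),
               c(1, 3, 2, 8))
  # interior point against the direct formula
  wx <- 0.3; wy <- 0.7
  expected <- 1 * (1 - wx) * (1 - wy) + 3 * wx * (1 - wy) +
    2 * (1 - wx) * wy + 8 * wx * wy
  expect_equal(bl(c(0, 1), c(0, 1), z, wx, wy), expected)
  # outside the axes or next to an NA node: NA
  expect_true(is.na(bl(c(0, 1), c(0, 1), z, 1.5, 0.5)))
  z[2, 2] <- NA
  expect_true(is.na(bl(c(0, 1), c(0, 1), z, 0.5, 0.5)))
})

test_that("effect pairs interpolate both fields at the conditions", {
  s <- canonical_surface("hr")
  f <- canonical_field()
  conds <- data.frame(ta_C = c(30, 40, 45, 60), pa_kPa = c(1, 2, 4, 1))
  expect_warning(pr <- pair_effects(conds, s, f), "dropped")
  expect_lte(nrow(pr), nrow(conds))
  expect_true(all(is.finite(pr$delta_utci) & is.finite(pr$delta_physio)))
  # a condition on a grid node reproduces the node value of the field
  g <- f$grid
  node <- suppressWarnings(
    pair_effects(data.frame(ta_C = 40, pa_kPa = 2), s, f))
  expect_equal(node$delta_utci,
               f$delta[match(40, g$ta_axis), match(2, g$pa_axis)])
})

test_that("Spearman correlation handles monotone, antitone and tied data", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_correlation(x, exp(x))$r_s, 1)
  expect_equal(spearman_correlation(x, -x^3)$r_s, -1)
  # mid-rank ties: against the independent base implementation
  y <- c(2, 2, 1, 5, 4)
  ours <- spearman_correlation(x, y)
  expect_equal(ours$r_s, unname(stats::cor(x, y, method = "spearman")))
  ref <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(ours$r_s, unname(ref$estimate))
  expect_error(spearman_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearman_correlation(1:2, 2:3), "3")
})

test_that("heating classification counts and metrics are exact", {
  # 9 TP, 1 FN, 6 TN, 4 FP
  pairs <- data.frame(
    delta_physio = c(rep(1, 9), 1, rep(-1, 6), rep(-1, 4)),
    delta_utci = c(rep(1, 9), -1, rep(-1, 6), rep(1, 4)))
  m <- heating_classification(pairs)
  expect_equal(m[c("TP", "FN", "TN", "FP")], list(TP = 9L, FN = 1L,
                                                  TN = 6L, FP = 4L))
  expect_equal(m$sensitivity, 0.90)
  expect_equal(m$specificity, 0.60)
  expect_equal(m$accuracy, 0.75)
  # perfect sign agreement
  p2 <- data.frame(delta_physio = c(-1, 2, -3, 4), delta_utci = c(-2, 1, -1, 3))
  m2 <- heating_classification(p2)
  expect_equal(c(m2$sensitivity, m2$specificity, m2$accuracy), c(1, 1, 1))
  # all-negative predictions with mixed truth: zero sensitivity
  p3 <- data.frame(delta_physio = c(1, -1), delta_utci = c(-1, -1))
  expect_equal(heating_classification(p3)$sensitivity, 0)
  # exact zero is non-heating for both truth and prediction
  p4 <- data.frame(delta_physio = c(0, 1), delta_utci = c(0, 1))
  m4 <- heating_classification(p4)
  expect_equal(m4$TN, 1L)
  expect_equal(m4$TP, 1L)
  # undefined sensitivity without positive truth cases
  p5 <- data.frame(delta_physio = c(-1, -2), delta_utci = c(1, -1))
  expect_true(is.na(heating_classification(p5)$sensitivity))
})

test_that("metrics are invariant under strictly monotone transforms", {
  set.seed(4)
  pairs <- data.frame(delta_utci = stats::rnorm(40),
                      delta_physio = stats::rnorm(40))
  r0 <- spearman_correlation(pairs$delta_utci, pairs$delta_physio)$r_s
  m0 <- heating_classification(pairs)
  tr <- function(v) sign(v) * abs(v)^3 * 2  # strictly monotone, sign-preserving
  pairs2 <- data.frame(delta_utci = tr(pairs$delta_utci),
                       delta_physio = tr(pairs$delta_physio))
  expect_equal(spearman_correlation(pairs2$delta_utci,
                                    pairs2$delta_physio)$r_s, r0)
  expect_equal(heating_classification(pairs2), m0)
})

test_that("canonical pipeline shows the expected UTCI-physiology agreement", {
  f <- canonical_field()
  tr <- canonical_trials()
  surfaces <- list(hr = canonical_surface("hr"),
                   tre = canonical_surface("tre"),
                   tsk = canonical_surface("tsk"),
                   sr = canonical_surface("sr"))
  cmp <- suppressWarnings(compare_effects(tr, surfaces, f))
  rs <- vapply(cmp, function(x) x$spearman$r_s, numeric(1))
  # positive rank correlation for all four responses
  expect_true(all(rs > 0))
  # closest agreement for the responses wind acts on directly: skin
  # temperature and sweat rate as a group outrank heart rate and core
  # temperature
  expect_gt(mean(rs[c("tsk", "sr")]), mean(rs[c("hr", "tre")]))
  acc <- vapply(cmp, function(x) x$classification$accuracy, numeric(1))
  expect_true(all(acc > 0.5))
})
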