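test_that("dice matches its defining arithmetic and properties", {
  a <- disc_fixture(32, c(16, 16), 8)
  expect_equal(dice(a, a), 1)
  b <- matrix(0, 32, 32); b[1:2, 1:2] <- 1
  expect_equal(dice(a, b), 0)
  # |A|=|B|=100, intersection 50
  s <- matrix(0, 20, 20); s[1:10, 1:10] <- 1
  g <- matrix(0, 20, 20); g[1:10, 6:15] <- 1
  expect_equal(dice(s, g), 0.5)
  expect_error(dice(matrix(0, 4, 4), matrix(0, 4, 4)), "both masks are empty")
  expect_error(dice(a, matrix(0, 16, 16)), "identical dimensions")
  # symmetry and range on random pairs
  set.seed(42)
  for (i in 1:20) {
    m1 <- matrix(rbinom(16 * 16, 1, 0.4), 16, 16)
    m2 <- matrix(rbinom(16 * 16, 1, 0.4), 16, 16)
    if (sum(m1) + sum(m2) == 0) next
    d <- dice(m1, m2)
    expect_identical(d, dice(m2, m1))
    expect_true(d >= 0 && d <= 1)
  }
})

test_that("mask_to_contour traces the half-level boundary at sub-pixel accuracy", {
  # n x n filled block: the 0.5-level contour runs half a pixel outside the
  # pixel centers with cut corners, perimeter within 5% of 4n
  sq <- matrix(0, 20, 20); sq[6:15, 6:15] <- 1
  cn <- mask_to_contour(sq)
  expect_lt(abs(contour_perimeter(cn) - 40) / 40, 0.05)
  # disc radius 20: enclosed (shoelace) area within 2% of pi r^2
  dm <- disc_fixture(64, c(32.5, 32.5), 20)
  cd <- mask_to_contour(dm)
  expect_lt(abs(contour_area(cd) - pi * 400) / (pi * 400), 0.02)
  # rasterizing the contour recovers the mask almost exactly
  expect_gte(dice(rasterize_contour(cd, c(64, 64)), dm), 0.98)
  # error cases
  expect_error(mask_to_contour(matrix(0, 8, 8)), "empty")
  two <- matrix(0, 16, 16); two[2:4, 2:4] <- 1; two[10:12, 10:12] <- 1
  expect_error(mask_to_contour(two), "2 connected components")
})

test_that("contour files round-trip through the x-y text format", {
  cn <- mask_to_contour(disc_fixture(32, c(16, 16), 8), spacing = 1.367)
  path <- tempfile(fileext = ".txt")
  on.exit(unlink(path))
  write_contour(cn, path)
  back <- read_contour(path, spacing = 1.367)
  expect_equal(back$x, cn$x, tolerance = 1e-4)
  expect_equal(back$y, cn$y, tolerance = 1e-4)
  expect_lt(apd(cn, back), 1e-3)
})

test_that("apd matches geometry on concentric circles and is well-behaved", {
  circle <- function(r, spacing = 1, n = 360) {
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    lv_contour(32 + r * cos(th), 32 + r * sin(th), spacing)
  }
  a <- circle(10); b <- circle(12)
  expect_equal(apd(a, a), 0)
  d <- apd(a, b)
  expect_lt(abs(d - 2), 0.1)                       # analytic ring distance
  expect_lt(abs(d - oracle_apd(a, b)), 0.02)       # dense brute-force oracle
  # contours extracted from rasterized discs agree with the same oracle
  am <- mask_to_contour(disc_fixture(64, c(32.5, 32.5), 10), spacing = 1)
  bm <- mask_to_contour(disc_fixture(64, c(32.5, 32.5), 12), spacing = 1)
  expect_lt(abs(apd(am, bm) - oracle_apd(am, bm)), 0.02)
  # spacing linearity: scaling the pixel size scales APD exactly
  expect_equal(apd(circle(10, 1.5), circle(12, 1.5)), 1.5 * d)
  expect_error(apd(a, circle(12, 1.5)), "different pixel spacings")
  # symmetry and translation invariance
  expect_identical(apd(a, b), apd(b, a))
  shift <- function(cn) { cn$x <- cn$x + 3.2; cn$y <- cn$y - 1.7; cn }
  expect_equal(apd(shift(a), shift(b)), d, tolerance = 1e-12)
})

test_that("the good-contour rule is strict at 5 mm", {
  expect_true(classify_good(4.85))
  expect_false(classify_good(6.25))
  expect_false(classify_good(5))
  expect_false(classify_good(NA))
  expect_error(classify_good(-1), "negative")
})

test_that("evaluate_case bookkeeping matches the PGC arithmetic", {
  gt <- disc_fixture(48, c(24, 24), 8)
  good_pred <- disc_fixture(48, c(24, 24), 8.5)
  bad_pred <- disc_fixture(48, c(38, 38), 8)   # ~20 px away: APD >> 5 mm
  # 12 good + 1 bad of 13 slices
  cm13 <- evaluate_case(c(rep(list(good_pred), 12), list(bad_pred)),
                        rep(list(gt), 13), spacing = 1)
  expect_equal(round(cm13$pgc_percent, 2), 92.31)
  expect_equal(cm13$pgc_percent, 100 * 12 / 13)
  expect_equal(cm13$n_good, 12)
  # 17 good + 1 empty prediction of 18: an undetected structure is not good
  cm18 <- evaluate_case(c(rep(list(good_pred), 17), list(gt * 0)),
                        rep(list(gt), 18), spacing = 1)
  expect_equal(round(cm18$pgc_percent, 2), 94.44)
  expect_equal(cm18$pgc_percent, 100 * 17 / 18)
  expect_true(is.na(cm18$slices$apd_mm[18]))
  # only good slices enter the DM/APD means
  expect_equal(cm13$mean_dm_of_good, mean(cm13$slices$dm[cm13$slices$good]))
  # perfect prediction
  cm <- evaluate_case(rep(list(gt), 3), rep(list(gt), 3), spacing = 1)
  expect_equal(cm$pgc_percent, 100)
  expect_equal(cm$mean_dm_of_good, 1)
  expect_equal(cm$mean_apd_of_good, 0)
  expect_error(evaluate_case(list(gt), rep(list(gt), 2), 1), "differ in length")
})

test_that("good slices always satisfy the APD threshold on random evaluations", {
  set.seed(99)
  gt <- disc_fixture(48, c(24, 24), 9)
  preds <- lapply(1:10, function(i)
    disc_fixture(48, c(24 + sample(-12:12, 1), 24 + sample(-12:12, 1)), 9))
  cm <- evaluate_case(preds, rep(list(gt), 10), spacing = 1)
  expect_true(all(cm$slices$apd_mm[cm$slices$good] < 5))
  expect_equal(cm$pgc_percent, 100 * cm$n_good / cm$n_slices)
})

test_that("cohort summaries use sample statistics", {
  gt <- disc_fixture(48, c(24, 24), 8)
  one_case <- function(pgc_bad) {
    preds <- rep(list(gt), 10)
    if (pgc_bad > 0) preds[seq_len(pgc_bad)] <- list(gt * 0)
    evaluate_case(preds, rep(list(gt), 10), spacing = 1)
  }
  single <- summarize_cases(list(one_case(0)))
  expect_equal(single["mean", "pgc_percent"], 100)
  expect_equal(single["sd", "pgc_percent"], 0)
  two <- summarize_cases(list(one_case(0), one_case(0)))
  expect_equal(two["mean", "pgc_percent"], 100)
  expect_equal(two["sd", "pgc_percent"], 0)
  # hand-listed PGC triple {90, 95, 100}: brute-force sample SD oracle
  triple <- list(one_case(1), one_case(0), one_case(0))
  pgcs <- vapply(triple, `[[`, numeric(1), "pgc_percent")
  sm <- summarize_cases(triple)
  expect_equal(sm["mean", "pgc_percent"], mean(pgcs))
  expect_equal(sm["sd", "pgc_percent"],
               sqrt(sum((pgcs - mean(pgcs))^2) / (length(pgcs) - 1)))
  expect_error(summarize_cases(list()), "no cases")
})
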