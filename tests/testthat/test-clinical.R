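test_that("slab-summation volumes follow their defining arithmetic", {
  sl <- matrix(0, 40, 40); sl[1:25, 1:40] <- 1   # 1000 px
  stack <- rep(list(sl), 3)
  expect_equal(volume_ml(stack, 1, 8), 24)        # 3 x 1000 x 8 mm3 = 24 ml
  expect_equal(volume_ml(list(), 1, 8), 0)
  expect_equal(volume_ml(stack, 1, 16), 2 * volume_ml(stack, 1, 8))
  # additive over disjoint subsets; linear in each spacing factor
  expect_equal(volume_ml(stack, 1, 8),
               volume_ml(stack[1:2], 1, 8) + volume_ml(stack[3], 1, 8))
  expect_equal(volume_ml(stack, c(2, 1), 8), 2 * volume_ml(stack, 1, 8))
  expect_equal(volume_ml(stack, 1.367, 8), 1.367^2 * volume_ml(stack, 1, 8))
  # gap adds to the slab height
  expect_equal(volume_ml(stack, 1, 8, gap_mm = 2), 30)
  expect_error(volume_ml(stack, -1, 8), "positive")
})

test_that("LVM and EF formulas are exact with guarded degenerate inputs", {
  expect_equal(lvm_g(150, 100), 52.5)
  expect_equal(lvm_g(100, 100), 0)
  expect_error(lvm_g(90, 100), "enclose")
  expect_equal(ef_percent(100, 40), 60)
  expect_equal(ef_percent(100, 100), 0)
  expect_error(ef_percent(0, 10), "positive")
})

test_that("phantom mask volumes agree with the analytic annulus formula", {
  cfg <- phantom_config(image_size = 96, endo_radius_px = c(14, 14),
                        wall_thickness_px = c(6, 6), center_jitter_px = 0,
                        apex_taper = 1, noise_sd = 0, n_slices = 5)
  case <- generate_case(cfg, seed = 1)
  ed <- resunetlv:::case_slices(case, "ED")
  v_endo <- volume_ml(lapply(ed, `[[`, "endo_mask"),
                      cfg$pixel_spacing_mm, cfg$slice_thickness_mm)
  v_epi <- volume_ml(lapply(ed, `[[`, "epi_mask"),
                     cfg$pixel_spacing_mm, cfg$slice_thickness_mm)
  an_endo <- 5 * pi * 14^2 * cfg$pixel_spacing_mm^2 * cfg$slice_thickness_mm / 1000
  an_epi <- 5 * pi * 20^2 * cfg$pixel_spacing_mm^2 * cfg$slice_thickness_mm / 1000
  expect_lt(abs(v_endo - an_endo) / an_endo, 0.03)
  expect_lt(abs(v_epi - an_epi) / an_epi, 0.03)
  # LVM from the generated masks vs the analytic annulus, within rasterization
  lvm_mask <- lvm_g(v_epi, v_endo)
  lvm_analytic <- (an_epi - an_endo) * 1.05
  expect_lt(abs(lvm_mask - lvm_analytic) / lvm_analytic, 0.03)
})

test_that("agreement statistics match a direct-formula oracle", {
  # perfect agreement
  x <- c(10, 12, 14, 15, 18, 20)
  ag <- agreement(x, x)
  expect_equal(ag$bias, 0)
  expect_equal(c(ag$lower_limit, ag$upper_limit), c(0, 0))
  expect_equal(ag$r_squared, 1)
  expect_equal(ag$slope, 1)
  expect_equal(ag$n_outside, 0)
  # constant offset: bias 5, zero-width limits, perfect regression
  ag5 <- agreement(x + 5, x)
  expect_equal(ag5$bias, 5)
  expect_equal(ag5$sd_diff, 0)
  expect_equal(ag5$r_squared, 1)
  expect_true(is.na(ag5$p_bias))
  # hand-listed 6-pair table against brute-force formulas
  auto <- c(101.2, 95.4, 120.9, 88.1, 130.5, 104.0)
  manual <- c(99.0, 97.5, 118.2, 90.0, 126.8, 101.5)
  ag6 <- agreement(auto, manual)
  d <- auto - manual
  m <- mean(d); s <- sqrt(sum((d - m)^2) / (length(d) - 1))
  expect_equal(ag6$bias, m)
  expect_equal(ag6$sd_diff, s)
  expect_equal(ag6$lower_limit, m - 1.96 * s)
  expect_equal(ag6$upper_limit, m + 1.96 * s)
  tt <- m / (s / sqrt(6))
  expect_equal(ag6$p_bias, 2 * pt(-abs(tt), df = 5))
  b1 <- sum((manual - mean(manual)) * (auto - mean(auto))) /
    sum((manual - mean(manual))^2)
  expect_equal(ag6$slope, b1)
  expect_equal(ag6$intercept, mean(auto) - b1 * mean(manual))
  expect_equal(ag6$r_squared, cor(auto, manual)^2)
  expect_equal(ag6$n_outside, sum(d < m - 1.96 * s | d > m + 1.96 * s))
  # antisymmetry of bias, invariance of R^2
  swap <- agreement(manual, auto)
  expect_equal(swap$bias, -ag6$bias)
  expect_equal(swap$r_squared, ag6$r_squared)
  expect_error(agreement(1:2, 1:2), "at least 3")
  expect_error(agreement(1:4, 1:3), "length")
})

test_that("clinical_indices wires volumes into LVM and EF", {
  endo <- matrix(0, 20, 20); endo[1:10, 1:10] <- 1     # 100 px
  epi <- matrix(0, 20, 20); epi[1:15, 1:10] <- 1       # 150 px
  ci <- clinical_indices(endo_ed = list(endo), endo_es = list(endo * 0),
                         epi_ed = list(epi), pixel_spacing_mm = 1,
                         slice_thickness_mm = 10)
  expect_equal(ci$v_end_ed_ml, 1)
  expect_equal(ci$v_epi_ed_ml, 1.5)
  expect_equal(ci$lvm_g, 0.5 * 1.05)
  expect_equal(ci$ef_percent, 100)
})
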