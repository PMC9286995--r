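test_that("noiseless slice geometry is exact", {
  cfg <- tiny_phantom(noise_sd = 0)
  sl <- generate_slice(cfg, center = c(32, 32), endo_radius_px = 10, wall_px = 4)
  expect_equal(sum(sl$endo_mask), sum(disc_fixture(64, c(32, 32), 10)))
  # noiseless pool intensity is exact inside the endo mask
  expect_true(all(sl$image[sl$endo_mask == 1] == cfg$intensity_pool))
  expect_true(all(sl$image[sl$epi_mask == 1 & sl$endo_mask == 0] ==
                    cfg$intensity_myo))
})

test_that("ES phase scales the endocardial radius multiplicatively", {
  cfg <- tiny_phantom(noise_sd = 0, es_scale = 0.7)
  sl <- generate_slice(cfg, c(32, 32), 10, 4, phase = "ES")
  expect_equal(sl$endo_radius_px, 7)
  # epicardial radius is phase-independent (the wall thickens at ES)
  expect_equal(sl$epi_radius_px, 14)
})

test_that("endo mask is strictly inside the epi mask for any seed", {
  cfg <- tiny_phantom(wobble_amp_px = 0.6)
  for (s in 1:5) {
    case <- generate_case(cfg, seed = s)
    for (sl in case$slices) {
      expect_true(all(sl$epi_mask[sl$endo_mask == 1] == 1))   # containment
      expect_equal(resunetlv:::n_components(sl$endo_mask), 1)
      expect_equal(dice(sl$endo_mask, sl$endo_mask), 1)
    }
  }
})

test_that("slice geometry exceeding the frame is rejected", {
  cfg <- tiny_phantom()
  expect_error(generate_slice(cfg, c(5, 5), 10, 4), "exceeds image bounds")
})

test_that("cases are seeded deterministically with the expected structure", {
  cfg <- tiny_phantom(n_slices = 8)
  a <- generate_case(cfg, seed = 3)
  b <- generate_case(cfg, seed = 3)
  expect_identical(a, b)
  expect_length(a$slices, 16)  # 8 slices x 2 phases
  expect_setequal(vapply(a$slices, `[[`, character(1), "phase"), c("ED", "ES"))
  # base-to-apex taper applies cumulatively and never increases
  expect_equal(a$endo_radii_px,
               a$base_endo_radius_px * cfg$apex_taper^(0:7))
  expect_true(all(diff(a$endo_radii_px) < 0))
})

test_that("three cumulative taper steps at 0.9 shrink radius 10 to 7.29", {
  cfg <- phantom_config(image_size = 64, endo_radius_px = c(10, 10),
                        wall_thickness_px = c(4, 4), apex_taper = 0.9,
                        center_jitter_px = 0, n_slices = 4)
  case <- generate_case(cfg, seed = 1)
  expect_equal(case$endo_radii_px[4], 10 * 0.9^3)  # = 7.29
})

test_that("a taper driving the radius below 1 px truncates with a warning", {
  cfg <- phantom_config(image_size = 64, endo_radius_px = c(3, 3),
                        wall_thickness_px = c(2, 2), apex_taper = 0.5,
                        n_slices = 8, center_jitter_px = 0)
  expect_warning(case <- generate_case(cfg, seed = 1), "truncated")
  expect_lt(length(case$endo_radii_px), 8)
  expect_true(all(case$endo_radii_px * cfg$es_scale >= 1))
})

test_that("config invariants are enforced", {
  expect_error(phantom_config(es_scale = 1.2), "es_scale")
  expect_error(phantom_config(intensity_pool = 0.3, intensity_myo = 0.5),
               "brighter")
  expect_error(phantom_config(endo_radius_px = c(60, 80), image_size = 128),
               "image_size/2")
})

test_that("written datasets round-trip and are byte-stable across runs", {
  cfg <- tiny_phantom(n_slices = 3)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  m1 <- generate_dataset(cfg, n_cases = 2, seed = 5, out_dir = d1, overwrite = TRUE)
  m2 <- generate_dataset(cfg, n_cases = 2, seed = 5, out_dir = d2, overwrite = TRUE)
  expect_equal(nrow(m1), 2 * 3 * 2)  # cases x slices x phases
  expect_identical(m1$true_center_row, m2$true_center_row)
  # re-read mask equals the in-memory mask
  case <- generate_case(cfg, seed = 5 + 1)
  endo <- read_slice_stack(file.path(d1, m1$endo_path[m1$phase == "ED"][1]))
  expect_equal(endo[[1]], case$slices[[1]]$endo_mask, ignore_attr = TRUE)
  # byte-identical files across the two runs (seeded determinism)
  f1 <- file.path(d1, "manifest.csv"); f2 <- file.path(d2, "manifest.csv")
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readBin(file.path(d1, m1$image_path[1]), "raw", 1e6),
                   readBin(file.path(d2, m1$image_path[1]), "raw", 1e6))
  # distinct case seeds produce distinct center jitters
  expect_true(length(unique(m1$true_center_row)) > 1)
  # existing manifest is protected
  expect_error(generate_dataset(cfg, 1, seed = 5, out_dir = d1), "overwrite")
})
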