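test_that("forward pass preserves resolution and normalizes class scores", {
  for (preset in c("improved", "resunet_skip", "resunet")) {
    cfg <- resunet_preset(preset, input_size = 16, n_levels = 2,
                          base_channels = 4, seed = 3)
    model <- build_resunet(cfg)
    img <- matrix(rnorm(16 * 16), 16, 16)
    pred <- predict(model, img)
    expect_equal(dim(pred$prob_map), c(16, 16, 2))
    expect_equal(dim(pred$mask), c(16, 16))
    sums <- apply(pred$prob_map, c(1, 2), sum)
    expect_lt(max(abs(sums - 1)), 1e-5)
  }
})

test_that("input shape mismatches are reported with both shapes", {
  model <- build_resunet(tiny_arch())
  expect_error(predict(model, matrix(0, 8, 8)), "model input is 16x16")
  expect_error(arch_config(input_size = 100, n_levels = 3), "divisible")
  expect_error(arch_config(base_channels = 3,
                           conv_type = "depthwise_separable"), "even")
})

test_that("dsconv block builds the two half-channel maps with fewer weights", {
  w <- init_dsconv(16, 32)
  expect_equal(dim(w$W1), c(9 * 16, 16))   # S1: standard 3x3, c2/2 channels
  expect_equal(dim(w$wd), c(9, 16))        # S2: depthwise 3x3 of S1
  expect_equal(length(w$W1) + length(w$wd), 2448)   # vs 9*16*32 = 4608 plain
  expect_lt(length(w$W1) + length(w$wd), 9 * 16 * 32)
  x <- array(rnorm(8 * 8 * 16), c(8, 8, 16))
  y <- dsconv_block(x, w)
  expect_equal(dim(y), c(8, 8, 32))
  expect_error(init_dsconv(16, 7), "even")
  # output channel count equals c2 for a sweep of even widths
  for (c2 in c(2, 4, 8, 16, 32, 64)) {
    xs <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
    expect_equal(dim(dsconv_block(xs, init_dsconv(3, c2)))[3], c2)
  }
})

test_that("residual units preserve spatial size and honour the skip modes", {
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  for (ss in c("both", "additive", "none")) {
    w <- init_residual_unit(4, 6, "standard", ss)
    y <- residual_unit(x, w)
    expect_equal(dim(y), c(8, 8, 6))
  }
  # with all residual-branch weights zeroed and matching channels, the unit
  # reduces to ReLU of the identity path (batch norm of the zero branch is
  # exactly zero)
  w0 <- init_residual_unit(4, 4, "standard", "both")
  for (nm in names(w0))
    if (!grepl("gamma", nm)) w0[[nm]][] <- 0
  w0 <- structure(w0, cin = 4, cout = 4, conv_type = "standard",
                  short_skip = "both", stats = attr(w0, "stats"))
  for (nm in names(w0)) if (grepl("gamma", nm)) w0[[nm]][] <- 1
  y0 <- residual_unit(x, w0)
  expect_equal(y0, pmax(x, 0))
  # short_skip = "none" is a plain two-conv block: no projection weights exist
  wn <- init_residual_unit(4, 6, "standard", "none")
  expect_false(any(grepl("proj", names(wn))))
})

test_that("param_count is structural and counts exact weights", {
  expect_equal(param_count(list(W = matrix(0, 9, 8))), 72)  # 3x3 conv, 1->8
  model <- build_resunet(tiny_arch())
  n1 <- param_count(model)
  model$params <- lapply(model$params, function(a) a * 7 + 1)
  expect_identical(param_count(model), n1)   # invariant to weight values
})

test_that("the separable network always has fewer parameters than its twin", {
  for (levels in 2:3) for (base in c(4, 8)) {
    imp <- build_resunet(arch_config(input_size = 32, n_levels = levels,
                                     base_channels = base,
                                     conv_type = "depthwise_separable"))
    std <- build_resunet(arch_config(input_size = 32, n_levels = levels,
                                     base_channels = base,
                                     conv_type = "standard"))
    expect_lt(param_count(imp), param_count(std))
  }
})

test_that("toggling the medium skip changes exactly the predicted weights", {
  L <- 2; B <- 4; M <- 2; in_ch <- 1   # M != B so no projection appears/vanishes
  with_med <- build_resunet(arch_config(input_size = 16, n_levels = L,
                                        base_channels = B, use_medium_skip = TRUE,
                                        medium_channels = M,
                                        conv_type = "standard"))
  without <- build_resunet(arch_config(input_size = 16, n_levels = L,
                                       base_channels = B, use_medium_skip = FALSE,
                                       conv_type = "standard"))
  # closed-form oracle: the per-level 1x1 kernels plus the first/second conv
  # and projection widening of every unit whose input gains M channels
  couts <- B * 2^(1:L)               # units 2..L and the transition unit
  med_params <- L * (in_ch * M + M)
  widen <- sum(9 * M * couts + 9 * M * couts + M * couts)
  expect_equal(param_count(with_med) - param_count(without),
               med_params + widen)
})

test_that("degenerate uniform scores give an empty mask (background ties)", {
  model <- build_resunet(tiny_arch())
  model$params$head.W[] <- 0
  model$params$head.b[] <- 0
  pred <- predict(model, matrix(rnorm(16 * 16), 16, 16))
  expect_true(all(pred$prob_map == 0.5))
  expect_equal(sum(pred$mask), 0)
})

test_that("prediction post-processing keeps the largest component", {
  m <- matrix(0, 10, 10); m[2:4, 2:4] <- 1; m[8:9, 8:9] <- 1
  kept <- resunetlv:::largest_component(m)
  expect_equal(sum(kept), 9)
  expect_true(all(kept[2:4, 2:4] == 1))
})

test_that("analytic gradients match finite differences through the network", {
  # a wiring bug corrupts whole parameter blocks; isolated coordinate
  # mismatches only occur at ReLU/max-pool kinks, so require a large majority
  frac1 <- gradcheck_fraction(arch_config(input_size = 8, n_levels = 2,
                                          base_channels = 2, seed = 3))
  expect_gte(frac1, 0.85)
  frac2 <- gradcheck_fraction(arch_config(input_size = 8, n_levels = 2,
                                          base_channels = 2, seed = 5,
                                          conv_type = "standard",
                                          short_skip = "additive",
                                          downsample = "strided"))
  expect_gte(frac2, 0.85)
})
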