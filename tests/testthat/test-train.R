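test_that("the linear learning-rate schedule hits its anchor points", {
  tc <- train_config()
  expect_equal(lr_schedule(0, tc), 0.001)
  expect_equal(lr_schedule(120, tc), 0.0001)
  expect_equal(lr_schedule(60, tc), 0.00055)      # linear midpoint
  expect_equal(lr_schedule(121, tc), 0.0001)      # constant plateau
  expect_equal(lr_schedule(150, tc), 0.0001)
  # strictly linear before the end epoch
  eps <- lr_schedule(0:120, tc)
  expect_equal(diff(eps), rep((0.0001 - 0.001) / 120, 120))
  expect_error(lr_schedule(-1, tc), ">= 0")
})

test_that("train_config validates its invariants", {
  expect_error(train_config(lr_initial = 1e-4, lr_final = 1e-3), "lr_final")
  expect_error(train_config(lr_end_epoch = 200, n_epochs = 150), "exceed")
  expect_error(train_config(batch_size = 0), "batch_size")
})

overfit_pairs <- function(n = 4) {
  cfg <- phantom_config(image_size = 16, endo_radius_px = c(4, 5),
                        wall_thickness_px = c(2, 2), center_jitter_px = 1,
                        n_slices = 2, noise_sd = 0.02)
  case <- generate_case(cfg, seed = 21)
  lapply(case$slices[seq_len(n)], function(sl)
    list(image = sl$image, mask = sl$endo_mask))
}

test_that("one epoch of bookkeeping produces one consistent history record", {
  pairs <- overfit_pairs(4)
  model <- build_resunet(arch_config(input_size = 16, n_levels = 2,
                                     base_channels = 4, seed = 7))
  fit <- fit_resunet(model, pairs, config = train_config(n_epochs = 1,
                                                         batch_size = 4,
                                                         lr_end_epoch = 1))
  expect_equal(nrow(fit$history), 1)
  expect_equal(fit$history$epoch, 0)
  expect_equal(fit$history$lr, 0.001)
  expect_s3_class(fit, "resunet_fit")
})

test_that("training is deterministic for a fixed seed", {
  pairs <- overfit_pairs(4)
  run <- function() {
    model <- build_resunet(arch_config(input_size = 16, n_levels = 2,
                                       base_channels = 4, seed = 7))
    fit_resunet(model, pairs, config = train_config(n_epochs = 3, batch_size = 2,
                                                    lr_end_epoch = 3, seed = 5))
  }
  a <- run(); b <- run()
  expect_identical(a$history$loss, b$history$loss)
  expect_identical(a$model$params, b$model$params)
})

test_that("the recorded learning-rate trajectory equals the schedule exactly", {
  pairs <- overfit_pairs(2)
  tc <- train_config(n_epochs = 6, batch_size = 2, lr_end_epoch = 4)
  model <- build_resunet(arch_config(input_size = 16, n_levels = 2,
                                     base_channels = 4, seed = 7))
  fit <- fit_resunet(model, pairs, config = tc)
  expect_identical(fit$history$lr, lr_schedule(0:5, tc))
  expect_identical(fit$history$epoch, 0:5)
})

test_that("gradients flow through all skip types: a 4-slice set is overfit", {
  pairs <- overfit_pairs(4)
  model <- build_resunet(arch_config(input_size = 16, n_levels = 2,
                                     base_channels = 4, seed = 7))
  # constant learning rate: the decay schedule is irrelevant to this
  # gradient-flow sanity check
  fit <- fit_resunet(model, pairs,
                     config = train_config(n_epochs = 200, batch_size = 4,
                                           lr_final = 0.001, lr_end_epoch = 200))
  expect_lt(min(fit$history$loss), 0.05)
  # and the fitted masks match the targets
  pred <- predict(fit$model, pairs[[1]]$image)
  expect_gte(dice(pred$mask, pairs[[1]]$mask), 0.9)
})

test_that("the best-validation checkpoint is retained", {
  pairs <- overfit_pairs(4)
  model <- build_resunet(arch_config(input_size = 16, n_levels = 2,
                                     base_channels = 4, seed = 7))
  fit <- fit_resunet(model, pairs, val_set = pairs,
                     config = train_config(n_epochs = 8, batch_size = 4,
                                           lr_end_epoch = 8))
  expect_equal(max(fit$history$val_dice), fit$history$val_dice[fit$best_epoch + 1])
  expect_equal(resunetlv:::validate_dice(fit$model, pairs),
               max(fit$history$val_dice))
})

test_that("checkpoints round-trip through the text format", {
  pairs <- overfit_pairs(2)
  model <- build_resunet(arch_config(input_size = 16, n_levels = 2,
                                     base_channels = 4, seed = 7,
                                     conv_type = "standard"))
  fit <- fit_resunet(model, pairs, config = train_config(n_epochs = 2,
                                                         batch_size = 2,
                                                         lr_end_epoch = 2))
  path <- tempfile(fileext = ".ckpt")
  on.exit(unlink(path))
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  expect_equal(back$config, fit$model$config)
  expect_equal(back$params, fit$model$params, tolerance = 1e-14)
  img <- pairs[[1]]$image
  expect_equal(predict(back, img)$prob_map, predict(fit$model, img)$prob_map,
               tolerance = 1e-12)
})

test_that("empty or malformed training sets are rejected", {
  model <- build_resunet(arch_config(input_size = 16, n_levels = 2,
                                     base_channels = 4))
  expect_error(fit_resunet(model, list()), "empty")
  bad <- list(list(image = matrix(0, 16, 16), mask = matrix(0.5, 16, 16)))
  expect_error(fit_resunet(model, bad), "binary")
  wrong <- list(list(image = matrix(0, 8, 8), mask = matrix(0, 8, 8)))
  expect_error(fit_resunet(model, wrong), "input size")
})
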