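#' Training configuration
#'
#' Hyperparameters of the training loop. The learning rate is adjusted
#' dynamically and linearly from `lr_initial` at epoch 0 to `lr_final` at
#' epoch `lr_end_epoch`, then held constant (see [lr_schedule()]).
#'
#' @param lr_initial,lr_final,lr_end_epoch Linear learning-rate schedule:
#'   defaults 0.001 to 0.0001 at epoch 120.
#' @param n_epochs Total epochs (default 150, past the schedule plateau).
#' @param batch_size Mini-batch size.
#' @param loss `"cross_entropy"` (pixel-wise, default), `"dice"` (soft dice on
#'   the foreground channel) or `"combined"`.
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param seed Seed for shuffling (weight init is seeded by the
#'   [arch_config()]).
#' @param target Which structure the model is being trained for; bookkeeping
#'   only (endocardium and epicardium are segmented by two separately trained
#'   binary models).
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr_initial = 0.001, lr_final = 0.0001,
                         lr_end_epoch = 120, n_epochs = 150, batch_size = 8,
                         loss = c("cross_entropy", "dice", "combined"),
                         optimizer = c("adam", "sgd"), seed = 1L,
                         target = c("endo", "epi")) {
  loss <- match.arg(loss); optimizer <- match.arg(optimizer)
  target <- match.arg(target)
  if (!(lr_final > 0 && lr_final <= lr_initial))
    stop("need 0 < lr_final <= lr_initial", call. = FALSE)
  if (lr_end_epoch > n_epochs)
    stop("lr_end_epoch (", lr_end_epoch, ") must not exceed n_epochs (",
         n_epochs, ")", call. = FALSE)
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  structure(list(lr_initial = lr_initial, lr_final = lr_final,
                 lr_end_epoch = lr_end_epoch, n_epochs = as.integer(n_epochs),
                 batch_size = as.integer(batch_size), loss = loss,
                 optimizer = optimizer, seed = as.integer(seed),
                 target = target),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Linear interpolation from `lr_initial` (epoch 0) to `lr_final` (epoch
#' `lr_end_epoch`), constant at `lr_final` afterwards.
#'
#' @param epoch Epoch index, 0-based (vectorized).
#' @param config A [train_config()].
#' @return Learning rate(s).
#' @examples
#' lr_schedule(c(0, 60, 120, 150), train_config())
#' @export
lr_schedule <- function(epoch, config = train_config()) {
  if (any(epoch < 0)) stop("epoch must be >= 0", call. = FALSE)
  frac <- pmin(epoch, config$lr_end_epoch) / config$lr_end_epoch
  config$lr_initial + (config$lr_final - config$lr_initial) * frac
}

flatten_params <- function(P) unlist(P, use.names = FALSE)

relist_params <- function(theta, template) {
  pos <- 0L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    v <- theta[pos + seq_len(n)]
    dim(v) <- dim(template[[nm]])
    template[[nm]] <- v
    pos <- pos + n
  }
  template
}

# mean foreground dice of a model over a list of (image, mask) pairs
validate_dice <- function(model, pairs) {
  preds <- predict(model, lapply(pairs, `[[`, "image"))
  if (length(pairs) == 1) preds <- list(preds)
  mean(mapply(function(pd, pr) {
    if (sum(pd$mask) + sum(pr$mask) == 0) 1 else dice(pd$mask, as_mask(pr$mask))
  }, preds, pairs))
}

#' Train a network
#'
#' Mini-batch training with the linear learning-rate schedule, Adam (or plain
#' SGD), per-epoch training loss and validation dice tracking, and retention
#' of the best-validation-dice parameters. Deterministic for a fixed seed.
#'
#' @param model A [build_resunet()] model.
#' @param train_set List of `list(image, mask)` pairs; images must match the
#'   model input size, masks must be binary.
#' @param val_set Optional validation pairs; when given, the returned model
#'   carries the weights of the best validation epoch.
#' @param config A [train_config()].
#' @param verbose Print one line per epoch?
#' @return Object of class `resunet_fit`: list with `model` (trained
#'   `resunet`), `history` (data frame: epoch, lr, loss, val_dice, seconds),
#'   `best_epoch`, `train_config`.
#' @export
fit_resunet <- function(model, train_set, val_set = NULL,
                        config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "resunet"), inherits(config, "train_config"))
  if (length(train_set) == 0) stop("empty training set", call. = FALSE)
  sz <- model$config$input_size
  for (pr in train_set) {
    if (!identical(dim(pr$image), c(sz, sz)) && !identical(dim(pr$image)[1:2], c(sz, sz)))
      stop("training image does not match model input size ", sz, call. = FALSE)
    stop_if_not_mask(pr$mask, "training mask")
  }
  n <- length(train_set)
  X <- array(0, c(sz, sz, n, 1))
  Tg <- array(1, c(sz, sz, n))
  for (i in seq_len(n)) {
    X[, , i, 1] <- train_set[[i]]$image
    Tg[, , i] <- as_mask(train_set[[i]]$mask) + 1  # classes 1 = bg, 2 = structure
  }
  P <- model$params
  theta <- flatten_params(P)
  stats_cur <- model$bn_stats
  adam_m <- adam_v <- numeric(length(theta))
  tstep <- 0L
  hist <- vector("list", config$n_epochs)
  best <- list(dice = -Inf, theta = theta, stats = stats_cur, epoch = NA_integer_)
  cur <- model
  with_seed(config$seed, {
    for (epoch in 0:(config$n_epochs - 1)) {
      t0 <- proc.time()[3]
      lr <- lr_schedule(epoch, config)
      ord <- sample.int(n)
      losses <- c()
      for (b in seq(1, n, by = config$batch_size)) {
        idx <- ord[b:min(b + config$batch_size - 1, n)]
        S <- new.env(parent = emptyenv())
        S$cache <- list(); S$stats <- stats_cur
        cur$params <- P
        fw <- resunet_forward(cur, X[, , idx, , drop = FALSE], training = TRUE, S = S)
        ls <- seg_loss(fw$probs, Tg[, , idx, drop = FALSE], config$loss)
        if (!is.finite(ls$value))
          stop(sprintf("training aborted: non-finite loss at epoch %d (lr = %g)",
                       epoch, lr), call. = FALSE)
        losses <- c(losses, ls$value)
        stats_cur <- S$stats
        gr <- resunet_backward(cur, S, ls$dlogits)
        g <- unlist(gr, use.names = FALSE)
        tstep <- tstep + 1L
        if (config$optimizer == "adam") {
          adam_m <- 0.9 * adam_m + 0.1 * g
          adam_v <- 0.999 * adam_v + 0.001 * g * g
          mhat <- adam_m / (1 - 0.9^tstep)
          vhat <- adam_v / (1 - 0.999^tstep)
          theta <- theta - lr * mhat / (sqrt(vhat) + 1e-8)
        } else {
          theta <- theta - lr * g
        }
        P <- relist_params(theta, P)
      }
      cur$params <- P
      cur$bn_stats <- stats_cur
      vd <- if (!is.null(val_set)) validate_dice(cur, val_set) else NA_real_
      secs <- proc.time()[3] - t0
      hist[[epoch + 1]] <- data.frame(epoch = epoch, lr = lr,
                                      loss = mean(losses), val_dice = vd,
                                      seconds = secs)
      if (verbose)
        message(sprintf("epoch %3d  lr %.6f  loss %.5f  val dice %s  (%.1fs)",
                        epoch, lr, mean(losses),
                        ifelse(is.na(vd), "-", sprintf("%.4f", vd)), secs))
      if (!is.na(vd) && vd > best$dice)
        best <- list(dice = vd, theta = theta, stats = stats_cur, epoch = epoch)
    }
  })
  history <- do.call(rbind, hist)
  rownames(history) <- NULL
  if (!is.null(val_set) && is.finite(best$dice)) {
    cur$params <- relist_params(best$theta, model$params)
    cur$bn_stats <- best$stats
    best_epoch <- best$epoch
  } else best_epoch <- config$n_epochs - 1L
  structure(list(model = cur, history = history, best_epoch = best_epoch,
                 train_config = config),
            class = "resunet_fit")
}

#' @export
print.resunet_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<resunet_fit> %d epochs (%s loss, %s), final loss %.4f\n",
              nrow(h), x$train_config$loss, x$train_config$optimizer,
              h$loss[nrow(h)]))
  if (!all(is.na(h$val_dice)))
    cat(sprintf("  best val dice %.4f at epoch %d\n",
                max(h$val_dice, na.rm = TRUE), x$best_epoch))
  print(x$model)
  invisible(x)
}

#' @export
summary.resunet_fit <- function(object, ...) {
  h <- object$history
  out <- list(n_epochs = nrow(h), final_loss = h$loss[nrow(h)],
              best_epoch = object$best_epoch,
              best_val_dice = if (all(is.na(h$val_dice))) NA_real_
                              else max(h$val_dice, na.rm = TRUE),
              mean_epoch_seconds = mean(h$seconds),
              param_count = param_count(object$model),
              history = h)
  class(out) <- "summary.resunet_fit"
  out
}

#' @export
print.summary.resunet_fit <- function(x, ...) {
  cat(sprintf("Training: %d epochs, final loss %.4f, best val dice %s (epoch %s)\n",
              x$n_epochs, x$final_loss,
              ifelse(is.na(x$best_val_dice), "-", sprintf("%.4f", x$best_val_dice)),
              x$best_epoch))
  cat(sprintf("Parameters: %d; mean epoch time %.2f s\n",
              x$param_count, x$mean_epoch_seconds))
  invisible(x)
}

#' @export
plot.resunet_fit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, if (all(is.na(h$val_dice))) 1 else 2))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", ...)
  if (!all(is.na(h$val_dice)))
    graphics::plot(h$epoch, h$val_dice, type = "l", xlab = "epoch",
                   ylab = "validation dice", ...)
  invisible(x)
}

#' @export
predict.resunet_fit <- function(object, image, ...) predict(object$model, image, ...)

#' @export
coef.resunet_fit <- function(object, ...) object$model$params

## ---- checkpoint I/O (self-describing text format) -------------------------

#' Save and load a model checkpoint
#'
#' Text checkpoint: the architecture configuration as key-value lines followed
#' by every weight array (and batch-norm running moments), so a checkpoint is
#' self-describing and portable.
#'
#' @param model A `resunet` or `resunet_fit`.
#' @param path File path.
#' @return `load_checkpoint()` returns a `resunet`.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "resunet_fit")) model <- model$model
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- model$config
  writeLines("# resunet checkpoint v1", con)
  for (nm in names(cfg))
    writeLines(sprintf("@config %s %s", nm, as.character(cfg[[nm]])), con)
  dump_arrays <- function(lst, tag) {
    for (nm in names(lst)) {
      a <- lst[[nm]]
      writeLines(sprintf("@%s %s %s", tag, nm,
                         paste(dim(a) %||% length(a), collapse = "x")), con)
      writeLines(paste(format(as.vector(a), digits = 17), collapse = " "), con)
    }
  }
  dump_arrays(model$params, "param")
  dump_arrays(model$bn_stats, "stat")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  lines <- readLines(path)
  cfg_lines <- grep("^@config ", lines, value = TRUE)
  cfg <- list()
  for (l in cfg_lines) {
    parts <- strsplit(sub("^@config ", "", l), " ")[[1]]
    cfg[[parts[1]]] <- parts[2]
  }
  ac <- arch_config(
    input_size = as.integer(cfg$input_size), in_channels = as.integer(cfg$in_channels),
    n_classes = as.integer(cfg$n_classes), n_levels = as.integer(cfg$n_levels),
    base_channels = as.integer(cfg$base_channels),
    use_medium_skip = as.logical(cfg$use_medium_skip),
    short_skip = cfg$short_skip, conv_type = cfg$conv_type,
    downsample = cfg$downsample, medium_channels = as.integer(cfg$medium_channels),
    seed = as.integer(cfg$seed))
  model <- build_resunet(ac)
  idx <- grep("^@(param|stat) ", lines)
  for (i in idx) {
    parts <- strsplit(lines[i], " ")[[1]]
    nm <- parts[2]
    dims <- as.integer(strsplit(parts[3], "x")[[1]])
    vals <- as.numeric(strsplit(trimws(lines[i + 1]), " +")[[1]])
    if (length(dims) > 1) dim(vals) <- dims
    if (parts[1] == "@param") model$params[[nm]] <- vals
    else model$bn_stats[[nm]] <- vals
  }
  model
}
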