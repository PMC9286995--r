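p_ <- function(...) paste(..., sep = ".")

#' Architecture configuration for the improved residual U-Net
#'
#' Declarative description of the network: a contracting path of residual
#' units with 2x downsampling per level, a transition residual unit at the
#' bottom, an expanding path of 2x2 up-convolutions with long skip
#' concatenations from the matching contracting level, and a 1x1 convolution
#' + SoftMax head at the input resolution. Three architectural switches
#' reproduce the ablation ladder:
#'
#' * `use_medium_skip` — at each contracting step the raw model input,
#'   reduced by a per-level strided 1x1 convolution, is concatenated with the
#'   downsampled features.
#' * `short_skip` — skip wiring inside each residual unit: `"both"` keeps the
#'   additive identity skip (1x1 projection when channel counts differ) *and*
#'   the concatenative skip of the unit input into the second convolution
#'   block; `"additive"` keeps only the identity skip (a plain residual
#'   unit); `"none"` is a plain two-convolution block.
#' * `conv_type` — `"depthwise_separable"` builds each 3x3 convolution block
#'   as half the output channels from a standard 3x3 convolution (S1) and the
#'   other half from a per-channel 3x3 convolution of S1 (S2), concatenated;
#'   `"standard"` uses a full 3x3 convolution. The separable form has strictly
#'   fewer weights.
#'
#' @param input_size Input side length in px; must be divisible by
#'   `2^n_levels`.
#' @param in_channels Input channels (1 for grayscale MR).
#' @param n_classes Output classes (2: background, structure).
#' @param n_levels Number of downsampling steps.
#' @param base_channels Channels of the first level (doubled per level); must
#'   be even for the depthwise-separable convolution.
#' @param use_medium_skip,short_skip,conv_type See above.
#' @param downsample `"pooling"` (2x2 max pool) or `"strided"` (learned 2x2
#'   stride-2 convolution).
#' @param medium_channels Channels produced by each medium-skip 1x1
#'   convolution (default `base_channels`).
#' @param seed Weight-initialisation seed.
#' @return Object of class `arch_config`.
#' @seealso [build_resunet()], [resunet_preset()]
#' @export
arch_config <- function(input_size = 128, in_channels = 1, n_classes = 2,
                        n_levels = 4, base_channels = 32,
                        use_medium_skip = TRUE,
                        short_skip = c("both", "additive", "none"),
                        conv_type = c("depthwise_separable", "standard"),
                        downsample = c("pooling", "strided"),
                        medium_channels = base_channels,
                        seed = 1L) {
  short_skip <- match.arg(short_skip)
  conv_type <- match.arg(conv_type)
  downsample <- match.arg(downsample)
  if (input_size %% 2^n_levels != 0)
    stop("input_size (", input_size, ") must be divisible by 2^n_levels (",
         2^n_levels, ")", call. = FALSE)
  if (conv_type == "depthwise_separable" && base_channels %% 2 != 0)
    stop("base_channels must be even for depthwise-separable convolutions",
         call. = FALSE)
  structure(list(input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 n_levels = as.integer(n_levels),
                 base_channels = as.integer(base_channels),
                 use_medium_skip = isTRUE(use_medium_skip),
                 short_skip = short_skip, conv_type = conv_type,
                 downsample = downsample,
                 medium_channels = as.integer(medium_channels),
                 seed = as.integer(seed)),
            class = "arch_config")
}

#' Ablation presets of the architecture
#'
#' `"resunet"` is the plain residual U-Net baseline (additive short skip only,
#' no medium skip, standard convolutions); `"resunet_skip"` adds the medium
#' and concatenative short skips; `"improved"` additionally replaces standard
#' convolutions with the depthwise-separable block.
#'
#' @param variant One of `"resunet"`, `"resunet_skip"`, `"improved"`.
#' @param ... Passed to [arch_config()] (sizes, seed, ...).
#' @return An `arch_config`.
#' @export
resunet_preset <- function(variant = c("improved", "resunet_skip", "resunet"), ...) {
  variant <- match.arg(variant)
  switch(variant,
    resunet = arch_config(use_medium_skip = FALSE, short_skip = "additive",
                          conv_type = "standard", ...),
    resunet_skip = arch_config(use_medium_skip = TRUE, short_skip = "both",
                               conv_type = "standard", ...),
    improved = arch_config(use_medium_skip = TRUE, short_skip = "both",
                           conv_type = "depthwise_separable", ...))
}

#' @export
print.arch_config <- function(x, ...) {
  cat(sprintf("<arch_config> %dx%dx%d -> %d classes, %d levels, base %d ch\n",
              x$input_size, x$input_size, x$in_channels, x$n_classes,
              x$n_levels, x$base_channels))
  cat(sprintf("  conv %s, short skip %s, medium skip %s, downsample %s, seed %d\n",
              x$conv_type, x$short_skip, x$use_medium_skip, x$downsample, x$seed))
  invisible(x)
}

## ---- parameter initialisation (seeded He-style) ---------------------------

he_mat <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)

init_cb <- function(id, c1, c2, type) {
  P <- list()
  if (type == "standard") {
    P[[p_(id, "W")]] <- he_mat(9 * c1, c2, 9 * c1)
    P[[p_(id, "b")]] <- numeric(c2)
  } else {
    if (c2 %% 2 != 0)
      stop("depthwise-separable block needs an even output channel count, got ",
           c2, call. = FALSE)
    h <- c2 %/% 2
    P[[p_(id, "W1")]] <- he_mat(9 * c1, h, 9 * c1)
    P[[p_(id, "b1")]] <- numeric(h)
    P[[p_(id, "wd")]] <- he_mat(9, h, 9)
  }
  P[[p_(id, "gamma")]] <- rep(1, c2)
  P[[p_(id, "beta")]] <- numeric(c2)
  attr(P, "stats") <- stats::setNames(list(numeric(c2), rep(1, c2)),
                                      c(p_(id, "mean"), p_(id, "var")))
  P
}

init_unit <- function(uid, cin, cout, type, short) {
  P1 <- init_cb(p_(uid, "cb1"), cin, cout, type)
  cin2 <- if (short == "both") cin + cout else cout
  P2 <- init_cb(p_(uid, "cb2"), cin2, cout, type)
  P <- c(P1, P2)
  st <- c(attr(P1, "stats"), attr(P2, "stats"))
  if (short != "none" && cin != cout) {
    P[[p_(uid, "proj", "W")]] <- he_mat(cin, cout, cin)
    P[[p_(uid, "proj", "b")]] <- numeric(cout)
  }
  attr(P, "stats") <- st
  P
}

# channel bookkeeping shared by init / forward / backward
resunet_plan <- function(cfg) {
  L <- cfg$n_levels; B <- cfg$base_channels
  med <- if (cfg$use_medium_skip) cfg$medium_channels else 0L
  cout <- B * 2^(0:(L - 1))
  cin <- c(cfg$in_channels, cout[-L] + med)
  list(L = L, B = B, med = med, down_cin = cin, down_cout = cout,
       trans_cin = cout[L] + med, trans_cout = B * 2^L,
       up_cout = cout,             # level j expanding output channels
       up_prev = c(cout[-1], B * 2^L))  # channels entering upconv at level j
}

#' Build the network
#'
#' Allocates and seeds all trainable parameters of the architecture described
#' by an [arch_config()]. The result is an untrained model; train it with
#' [fit_resunet()] and apply it with [predict()].
#'
#' @param config An `arch_config`.
#' @return Object of class `resunet`: list with `config`, `params` (named
#'   flat list of weight arrays) and `bn_stats` (batch-norm running moments).
#' @export
build_resunet <- function(config) {
  stopifnot(inherits(config, "arch_config"))
  plan <- resunet_plan(config)
  with_seed(config$seed, {
    P <- list(); st <- list()
    add <- function(Pi) {
      st <<- c(st, attr(Pi, "stats"))
      attr(Pi, "stats") <- NULL
      P <<- c(P, Pi)
    }
    for (i in seq_len(plan$L)) {
      add(init_unit(p_("down", i), plan$down_cin[i], plan$down_cout[i],
                    config$conv_type, config$short_skip))
      if (config$downsample == "strided") {
        P[[p_("pool", i, "W")]] <- array(stats::rnorm(
          plan$down_cout[i] * plan$down_cout[i] * 4, 0,
          sqrt(2 / (4 * plan$down_cout[i]))),
          c(plan$down_cout[i], plan$down_cout[i], 4))
        P[[p_("pool", i, "b")]] <- numeric(plan$down_cout[i])
      }
      if (plan$med > 0) {
        P[[p_("med", i, "W")]] <- he_mat(config$in_channels, plan$med,
                                         config$in_channels)
        P[[p_("med", i, "b")]] <- numeric(plan$med)
      }
    }
    add(init_unit("trans", plan$trans_cin, plan$trans_cout,
                  config$conv_type, config$short_skip))
    for (j in seq_len(plan$L)) {
      P[[p_("up", j, "W")]] <- array(stats::rnorm(
        plan$up_prev[j] * plan$up_cout[j] * 4, 0, sqrt(2 / plan$up_prev[j])),
        c(plan$up_prev[j], plan$up_cout[j], 4))
      P[[p_("up", j, "b")]] <- numeric(plan$up_cout[j])
      add(init_unit(p_("upu", j), 2 * plan$up_cout[j], plan$up_cout[j],
                    config$conv_type, config$short_skip))
    }
    P[["head.W"]] <- he_mat(plan$B, config$n_classes, plan$B)
    P[["head.b"]] <- numeric(config$n_classes)
    structure(list(config = config, params = P, bn_stats = st),
              class = "resunet")
  })
}

#' Number of trainable parameters
#'
#' Exact count of trainable weights (convolution kernels, biases, batch-norm
#' scale/shift). Invariant to the weight values; batch-norm running moments
#' are not trainable and are not counted.
#'
#' @param model A `resunet`, `resunet_fit`, or a named list of weight arrays
#'   (e.g. from [init_dsconv()]).
#' @return Integer count.
#' @export
param_count <- function(model) UseMethod("param_count")

#' @export
param_count.resunet <- function(model) sum(lengths(model$params))

#' @export
param_count.resunet_fit <- function(model) param_count(model$model)

#' @export
param_count.default <- function(model) sum(lengths(model))

#' @export
print.resunet <- function(x, ...) {
  cat(sprintf("<resunet> %s conv, short skip %s, medium skip %s\n",
              x$config$conv_type, x$config$short_skip, x$config$use_medium_skip))
  cat(sprintf("  input %dx%dx%d, %d levels, base %d ch, %d classes, %d parameters\n",
              x$config$input_size, x$config$input_size, x$config$in_channels,
              x$config$n_levels, x$config$base_channels, x$config$n_classes,
              param_count(x)))
  invisible(x)
}

#' @export
coef.resunet <- function(object, ...) object$params

## ---- forward / backward ---------------------------------------------------

cb_fwd <- function(x, P, S, id, type, relu, training) {
  if (type == "standard") {
    cv <- conv3_fwd(x, P[[p_(id, "W")]], P[[p_(id, "b")]])
    z <- cv$y; conv_cache <- cv$cache
  } else {
    c1 <- conv3_fwd(x, P[[p_(id, "W1")]], P[[p_(id, "b1")]])
    dw <- dwconv3_fwd(c1$y, P[[p_(id, "wd")]])
    z <- concat_ch(c1$y, dw$y)
    conv_cache <- list(c1 = c1$cache, dw = dw$cache)
  }
  bn <- bn_fwd(z, P[[p_(id, "gamma")]], P[[p_(id, "beta")]], training,
               S$stats[[p_(id, "mean")]], S$stats[[p_(id, "var")]])
  if (training) {
    S$stats[[p_(id, "mean")]] <- bn$run_mean
    S$stats[[p_(id, "var")]] <- bn$run_var
  }
  if (relu) {
    rl <- relu_fwd(bn$y); y <- rl$y; relu_cache <- rl$cache
  } else { y <- bn$y; relu_cache <- NULL }
  if (training)
    S$cache[[id]] <- list(conv = conv_cache, bn = bn$cache, relu = relu_cache)
  y
}

cb_bwd <- function(dy, P, S, G, id, type, relu) {
  cc <- S$cache[[id]]
  if (relu) dy <- relu_bwd(dy, cc$relu)
  bnb <- bn_bwd(dy, cc$bn, P[[p_(id, "gamma")]])
  assign(p_(id, "gamma"), bnb$dgamma, envir = G)
  assign(p_(id, "beta"), bnb$dbeta, envir = G)
  dz <- bnb$dx
  if (type == "standard") {
    cb <- conv3_bwd(dz, cc$conv, P[[p_(id, "W")]])
    assign(p_(id, "W"), cb$dW, envir = G)
    assign(p_(id, "b"), cb$db, envir = G)
    cb$dx
  } else {
    h <- ncol(P[[p_(id, "W1")]])
    sp <- split_ch(dz, h)
    dwb <- dwconv3_bwd(sp[[2]], cc$conv$dw, P[[p_(id, "wd")]])
    assign(p_(id, "wd"), dwb$dw, envir = G)
    c1b <- conv3_bwd(sp[[1]] + dwb$dx, cc$conv$c1, P[[p_(id, "W1")]])
    assign(p_(id, "W1"), c1b$dW, envir = G)
    assign(p_(id, "b1"), c1b$db, envir = G)
    c1b$dx
  }
}

unit_fwd <- function(x, P, S, uid, cin, cout, type, short, training) {
  f1 <- cb_fwd(x, P, S, p_(uid, "cb1"), type, relu = TRUE, training)
  g <- if (short == "both") concat_ch(x, f1) else f1
  h <- cb_fwd(g, P, S, p_(uid, "cb2"), type, relu = FALSE, training)
  has_proj <- short != "none" && cin != cout
  if (short != "none") {
    idp <- if (has_proj)
      conv1_fwd(x, P[[p_(uid, "proj", "W")]], P[[p_(uid, "proj", "b")]])$y
    else x
    pre <- h + idp
  } else pre <- h
  rl <- relu_fwd(pre)
  if (training)
    S$cache[[uid]] <- list(relu = rl$cache, x = if (has_proj) x else NULL,
                           cin = cin, short = short, has_proj = has_proj)
  rl$y
}

unit_bwd <- function(dy, P, S, G, uid, type) {
  cc <- S$cache[[uid]]
  dpre <- relu_bwd(dy, cc$relu)
  dx_extra <- NULL
  if (cc$short != "none") {
    if (cc$has_proj) {
      pb <- conv1_bwd(dpre, cc$x, P[[p_(uid, "proj", "W")]])
      assign(p_(uid, "proj", "W"), pb$dW, envir = G)
      assign(p_(uid, "proj", "b"), pb$db, envir = G)
      dx_extra <- pb$dx
    } else dx_extra <- dpre
  }
  dg <- cb_bwd(dpre, P, S, G, p_(uid, "cb2"), type, relu = FALSE)
  if (cc$short == "both") {
    sp <- split_ch(dg, cc$cin)
    df1 <- sp[[2]]
    dx_extra <- if (is.null(dx_extra)) sp[[1]] else dx_extra + sp[[1]]
  } else df1 <- dg
  dx <- cb_bwd(df1, P, S, G, p_(uid, "cb1"), type, relu = TRUE)
  if (!is.null(dx_extra)) dx <- dx + dx_extra
  dx
}

resunet_forward <- function(model, x, training = FALSE, S = NULL) {
  cfg <- model$config; P <- model$params
  plan <- resunet_plan(cfg)
  x <- as_feat(x)
  d <- dim(x)
  if (d[1] != cfg$input_size || d[2] != cfg$input_size || d[4] != cfg$in_channels)
    stop(sprintf("input shape (%d, %d, %d channels) does not match model input (%d, %d, %d channels)",
                 d[1], d[2], d[4], cfg$input_size, cfg$input_size,
                 cfg$in_channels), call. = FALSE)
  if (is.null(S)) { S <- new.env(parent = emptyenv()); S$cache <- list() }
  S$stats <- S$stats %||% model$bn_stats
  ct <- cfg$conv_type; ss <- cfg$short_skip
  f <- vector("list", plan$L)
  cur <- x
  for (i in seq_len(plan$L)) {
    cur <- unit_fwd(cur, P, S, p_("down", i), plan$down_cin[i],
                    plan$down_cout[i], ct, ss, training)
    f[[i]] <- cur
    if (cfg$downsample == "pooling") {
      mp <- maxpool2_fwd(cur)
      pooled <- mp$y
      if (training) S$cache[[p_("pool", i)]] <- mp$cache
    } else {
      Wp <- P[[p_("pool", i, "W")]]
      dc <- downconv2_fwd(cur, lapply(1:4, function(k) Wp[, , k]),
                          P[[p_("pool", i, "b")]])
      pooled <- dc$y
      if (training) S$cache[[p_("pool", i)]] <- cur
    }
    if (plan$med > 0) {
      mi <- conv1_fwd(x, P[[p_("med", i, "W")]], P[[p_("med", i, "b")]],
                      stride = 2L^i)
      if (training) S$cache[[p_("med", i)]] <- mi$cache
      cur <- concat_ch(pooled, mi$y)
    } else cur <- pooled
  }
  cur <- unit_fwd(cur, P, S, "trans", plan$trans_cin, plan$trans_cout, ct, ss,
                  training)
  for (j in rev(seq_len(plan$L))) {
    Wu <- P[[p_("up", j, "W")]]
    uc <- upconv2_fwd(cur, lapply(1:4, function(k) Wu[, , k]),
                      P[[p_("up", j, "b")]])
    if (training) S$cache[[p_("up", j)]] <- cur
    cat_ <- concat_ch(uc$y, f[[j]])
    cur <- unit_fwd(cat_, P, S, p_("upu", j), 2 * plan$up_cout[j],
                    plan$up_cout[j], ct, ss, training)
  }
  hd <- conv1_fwd(cur, P[["head.W"]], P[["head.b"]])
  if (training) S$cache[["head"]] <- hd$cache
  list(logits = hd$y, probs = softmax_ch(hd$y), S = S)
}

resunet_backward <- function(model, S, dlogits) {
  cfg <- model$config; P <- model$params
  plan <- resunet_plan(cfg)
  ct <- cfg$conv_type
  G <- new.env(parent = emptyenv())
  hb <- conv1_bwd(dlogits, S$cache[["head"]], P[["head.W"]])
  assign("head.W", hb$dW, envir = G); assign("head.b", hb$db, envir = G)
  dcur <- hb$dx
  df_long <- vector("list", plan$L)
  for (j in seq_len(plan$L)) {
    dcat <- unit_bwd(dcur, P, S, G, p_("upu", j), ct)
    sp <- split_ch(dcat, plan$up_cout[j])
    df_long[[j]] <- sp[[2]]
    Wu <- P[[p_("up", j, "W")]]
    ub <- upconv2_bwd(sp[[1]], S$cache[[p_("up", j)]],
                      lapply(1:4, function(k) Wu[, , k]))
    assign(p_("up", j, "W"), simplify2array(ub$dWs), envir = G)
    assign(p_("up", j, "b"), ub$db, envir = G)
    dcur <- ub$dx
  }
  dcur <- unit_bwd(dcur, P, S, G, "trans", ct)
  for (i in rev(seq_len(plan$L))) {
    if (plan$med > 0) {
      sp <- split_ch(dcur, plan$down_cout[i])
      dpooled <- sp[[1]]
      mb <- conv1_bwd(sp[[2]], S$cache[[p_("med", i)]],
                      P[[p_("med", i, "W")]], need_dx = FALSE)
      assign(p_("med", i, "W"), mb$dW, envir = G)
      assign(p_("med", i, "b"), mb$db, envir = G)
    } else dpooled <- dcur
    if (cfg$downsample == "pooling") {
      dunit <- maxpool2_bwd(dpooled, S$cache[[p_("pool", i)]])
    } else {
      Wp <- P[[p_("pool", i, "W")]]
      pb <- downconv2_bwd(dpooled, S$cache[[p_("pool", i)]],
                          lapply(1:4, function(k) Wp[, , k]))
      assign(p_("pool", i, "W"), simplify2array(pb$dWs), envir = G)
      assign(p_("pool", i, "b"), pb$db, envir = G)
      dunit <- pb$dx
    }
    dunit <- dunit + df_long[[i]]
    dcur <- unit_bwd(dunit, P, S, G, p_("down", i), ct)
  }
  # return gradients aligned with the parameter list order
  lapply(stats::setNames(names(P), names(P)), function(nm) get(nm, envir = G))
}

## ---- prediction ------------------------------------------------------------

#' Segment an image with a (trained) network
#'
#' Runs the forward pass in inference mode and converts per-pixel class
#' scores to a binary mask: argmax over classes with ties broken toward the
#' background, then (optionally) retaining only the largest connected
#' component, since the left ventricle is a single structure.
#'
#' @param object A `resunet` (or `resunet_fit`).
#' @param image Matrix matching the model's input size, or a list of such
#'   matrices (processed as one batch).
#' @param keep_largest Keep only the largest connected component of the
#'   foreground mask?
#' @param ... Unused.
#' @return For a single image, a list with `prob_map` (H x W x n_classes,
#'   per-pixel scores summing to 1) and `mask` (binary matrix). For a list of
#'   images, a list of such lists.
#' @export
predict.resunet <- function(object, image, keep_largest = TRUE, ...) {
  single <- !is.list(image)
  imgs <- if (single) list(image) else image
  sz <- object$config$input_size
  N <- length(imgs)
  x <- array(0, c(sz, sz, N, object$config$in_channels))
  for (n in seq_len(N)) {
    d <- dim(imgs[[n]])
    if (d[1] != sz || d[2] != sz)
      stop(sprintf("image %d is %dx%d but the model input is %dx%d (crop or resize first)",
                   n, d[1], d[2], sz, sz), call. = FALSE)
    x[, , n, ] <- imgs[[n]]
  }
  out <- resunet_forward(object, x, training = FALSE)
  K <- dim(out$probs)[4]
  one <- function(n) {
    pr <- out$probs[, , n, ]
    dim(pr) <- c(sz, sz, K)
    pm <- matrix(pr, sz * sz, K)
    cls <- max.col(pm, ties.method = "first")  # ties -> background (class 1)
    mask <- matrix(as.numeric(if (K > 2) cls > 1 else cls == K), sz, sz)
    if (keep_largest) mask <- largest_component(mask)
    list(prob_map = pr, mask = mask)
  }
  if (single) one(1) else lapply(seq_len(N), one)
}

## ---- standalone block operations (ablation/unit tests) --------------------

#' Initialise and apply a depthwise-separable convolution block
#'
#' The block maps m x n x c1 features to m x n x c2: a standard 3x3
#' convolution produces the first c2/2 channels (S1), a per-channel 3x3
#' convolution of S1 produces the other c2/2 (S2), the concatenation is
#' followed by batch normalization and ReLU. `init_dsconv()` allocates its
#' weights (`W1`, `b1`, `wd`, `gamma`, `beta`); `dsconv_block()` runs it.
#'
#' @param c1,c2 Input/output channel counts; `c2` must be even.
#' @param seed Seed for the weight draw.
#' @param x Input features: H x W x c1 array (or H x W x c1 x N).
#' @param weights An `init_dsconv()` result.
#' @return `dsconv_block()` returns the output feature array (same leading
#'   dimensions, c2 channels).
#' @export
init_dsconv <- function(c1, c2, seed = 1L) {
  if (c2 %% 2 != 0)
    stop("depthwise-separable block needs an even output channel count, got ",
         c2, call. = FALSE)
  with_seed(seed, {
    P <- init_cb("ds", c1, c2, "depthwise_separable")
    attr(P, "stats") <- NULL
    names(P) <- sub("^ds\\.", "", names(P))
    P
  })
}

#' @rdname init_dsconv
#' @export
dsconv_block <- function(x, weights) {
  x <- as_feat(x)
  c1v <- conv3_fwd(x, weights$W1, weights$b1)
  dw <- dwconv3_fwd(c1v$y, weights$wd)
  z <- concat_ch(c1v$y, dw$y)
  h <- ncol(weights$W1)
  bn <- bn_fwd(z, weights$gamma, weights$beta, training = TRUE,
               run_mean = numeric(2 * h), run_var = rep(1, 2 * h))
  y <- relu_fwd(bn$y)$y
  drop_batch_dim(y)
}

# (H, W, 1, C) -> (H, W, C) for single-sample convenience wrappers
drop_batch_dim <- function(y) {
  d <- dim(y)
  if (d[3] == 1) dim(y) <- c(d[1], d[2], d[4])
  y
}

#' Initialise and apply a standalone residual unit
#'
#' A residual unit is two 3x3 convolution blocks (each followed by batch
#' normalization; ReLU after the first block and after the additive join) with
#' up to two short skip connections: an additive identity skip from unit input
#' to output (1x1 projection when channel counts differ) and a concatenative
#' skip of the unit input into the second block's input.
#'
#' @param cin,cout Channel counts.
#' @param conv_type `"standard"` or `"depthwise_separable"`.
#' @param short_skip `"both"`, `"additive"` or `"none"` (plain two-conv block).
#' @param seed Weight seed.
#' @param x Input features, H x W x cin (or with a batch dimension).
#' @param weights An `init_residual_unit()` result.
#' @return `residual_unit()` returns the output features (spatial size
#'   preserved, `cout` channels).
#' @export
init_residual_unit <- function(cin, cout, conv_type = "standard",
                               short_skip = "both", seed = 1L) {
  with_seed(seed, {
    P <- init_unit("u", cin, cout, conv_type, short_skip)
    st <- attr(P, "stats"); attr(P, "stats") <- NULL
    structure(P, cin = cin, cout = cout, conv_type = conv_type,
              short_skip = short_skip, stats = st)
  })
}

#' @rdname init_residual_unit
#' @export
residual_unit <- function(x, weights) {
  x <- as_feat(x)
  S <- new.env(parent = emptyenv())
  S$cache <- list()
  S$stats <- attr(weights, "stats")
  y <- unit_fwd(x, weights, S, "u", attr(weights, "cin"), attr(weights, "cout"),
                attr(weights, "conv_type"), attr(weights, "short_skip"),
                training = TRUE)
  drop_batch_dim(y)
}
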