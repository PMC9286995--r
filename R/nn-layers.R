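# Low-level network layers. Feature tensors are arrays (H, W, N, C) —
# channel-last, so the (H*W*N, C) matrix form needed for BLAS is a free
# `dim<-` reinterpretation, channel concatenation is a plain cbind, and every
# spatial operation (padded 3x3 shifts, stride-2 sampling) is a row
# gather/scatter on that matrix with a memoized index vector. All
# convolutions are shifted matrix multiplications; every layer has a matching
# backward pass, validated by finite-difference gradient checks in the test
# suite.

# free matrix view (H,W,N,C) <-> (H*W*N, C)
fm <- function(x) { d <- dim(x); dim(x) <- c(d[1] * d[2] * d[3], d[4]); x }
fa <- function(m, d) { dim(m) <- d; m }

# normalize to (H, W, N=1, C): a matrix is one single-channel image, a 3D
# array is one multi-channel feature map (H, W, C)
as_feat <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2) dim(x) <- c(dim(x), 1, 1)
  else if (length(d) == 3) dim(x) <- c(d[1], d[2], 1, d[3])
  x
}

## --- memoized row-index vectors --------------------------------------------

.idx_cache <- new.env(parent = emptyenv())

# flat row index of (i, j, n) in (H, W, N) order, with out-of-frame positions
# pointing at the sentinel row H*W*N + 1 (kept at zero)
shift_idx <- function(H, W, N, di, dj) {
  key <- paste("s", H, W, N, di, dj)
  got <- .idx_cache[[key]]
  if (!is.null(got)) return(got)
  i <- rep_len(seq_len(H), H * W)
  j <- rep(seq_len(W), each = H)
  si <- i + di; sj <- j + dj
  ok <- si >= 1L & si <= H & sj >= 1L & sj <= W
  base <- ifelse(ok, si + (sj - 1L) * H, NA_integer_)
  idx <- as.integer(outer(base, (seq_len(N) - 1L) * H * W, "+"))
  idx[is.na(idx)] <- H * W * N + 1L
  .idx_cache[[key]] <- idx
  idx
}

# rows of the full-resolution matrix sampled at stride 2 with offset (oi, oj)
stride2_idx <- function(H, W, N, oi, oj) {
  key <- paste("p", H, W, N, oi, oj)
  got <- .idx_cache[[key]]
  if (!is.null(got)) return(got)
  i <- seq(1L, H, by = 2L) + oi
  j <- seq(1L, W, by = 2L) + oj
  base <- outer(i, (j - 1L) * H, "+")
  idx <- as.integer(outer(as.integer(base), (seq_len(N) - 1L) * H * W, "+"))
  .idx_cache[[key]] <- idx
  idx
}

CONV_DI <- rep(-1:1, each = 3)
CONV_DJ <- rep(-1:1, times = 3)
POOL_OI <- rep(0:1, each = 2)
POOL_OJ <- rep(0:1, times = 2)

# (H*W*N, 9*C) column blocks, offsets di (outer) / dj (inner) over -1..1;
# the gather runs in compiled code (src/im2col.cpp)
im2col3 <- function(x) {
  d <- dim(x)
  im2col3_cpp(x, d[1], d[2], d[3], d[4])
}

# transpose-and-flip a (9*Cin x Cout) conv kernel into the (9*Cout x Cin)
# kernel of the adjoint convolution: block j of the result is t(block 10-j)
flip_w3 <- function(W, Cin) {
  Cout <- ncol(W)
  W2 <- matrix(0, 9 * Cout, Cin)
  for (j in 1:9) {
    k <- 10 - j
    W2[((j - 1) * Cout + 1):(j * Cout), ] <-
      t(W[((k - 1) * Cin + 1):(k * Cin), , drop = FALSE])
  }
  W2
}

add_bias <- function(ym, b) {
  add_bias_inplace(ym, b)   # ym is always a fresh GEMM result, never shared
  ym
}

## --- 3x3 convolution (same padding), W: (9*Cin x Cout) matrix -------------

conv3_fwd <- function(x, W, b) {
  d <- dim(x)
  X9 <- im2col3(x)
  y <- add_bias(X9 %*% W, b)
  list(y = fa(y, c(d[1], d[2], d[3], ncol(W))), cache = list(X9 = X9, d = d))
}

conv3_bwd <- function(dy, cache, W, need_dx = TRUE) {
  dym <- fm(dy)
  dW <- crossprod(cache$X9, dym)
  db <- colSums(dym)
  dx <- NULL
  if (need_dx) {
    d <- cache$d
    Cin <- d[4]
    dx <- fa(im2col3(dy) %*% flip_w3(W, Cin), d)
  }
  list(dx = dx, dW = dW, db = db)
}

## --- 3x3 depthwise (per-channel) convolution, w: (9 x C) ------------------

# fused compiled kernels: no im2col matrix is materialized for the
# depthwise convolution, its adjoint, or its weight gradient
dwconv3_fwd <- function(x, w) {
  d <- dim(x)
  y <- dwconv3_direct_cpp(x, d[1], d[2], d[3], d[4], w, FALSE)
  list(y = fa(y, d), cache = list(x = x, d = d))
}

dwconv3_bwd <- function(dy, cache, w) {
  d <- cache$d
  dw <- dwgrad3_direct_cpp(cache$x, d[1], d[2], d[3], d[4], dy)
  dx <- fa(dwconv3_direct_cpp(dy, d[1], d[2], d[3], d[4], w, TRUE), d)
  list(dx = dx, dw = dw)
}

## --- 1x1 convolution, optional input stride (no padding) ------------------

conv1_fwd <- function(x, W, b, stride = 1L) {
  d <- dim(x)
  if (stride > 1) {
    keep <- as.vector(outer(outer(seq(1L, d[1], by = stride),
                                  (seq(1L, d[2], by = stride) - 1L) * d[1], "+"),
                            (seq_len(d[3]) - 1L) * d[1] * d[2], "+"))
    x <- fa(fm(x)[keep, , drop = FALSE],
            c(length(seq(1L, d[1], by = stride)),
              length(seq(1L, d[2], by = stride)), d[3], d[4]))
    d <- dim(x)
  }
  y <- add_bias(fm(x) %*% W, b)
  list(y = fa(y, c(d[1], d[2], d[3], ncol(W))), cache = x)
}

# dx only needed for stride 1 (the strided use feeds from the raw model
# input, which needs no gradient)
conv1_bwd <- function(dy, x_sub, W, need_dx = TRUE) {
  d <- dim(x_sub)
  dym <- fm(dy)
  dW <- crossprod(fm(x_sub), dym)
  db <- colSums(dym)
  dx <- if (need_dx) fa(dym %*% t(W), d) else NULL
  list(dx = dx, dW = dW, db = db)
}

## --- batch normalization (per channel over batch x space) -----------------

BN_EPS <- 1e-5

bn_fwd <- function(x, gamma, beta, training, run_mean, run_var, momentum = 0.9) {
  d <- dim(x)
  m <- fm(x)
  if (training) {
    mv <- col_mean_var_cpp(m)
    mu <- mv$mean; v <- mv$var
    new_mean <- momentum * run_mean + (1 - momentum) * mu
    new_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean; v <- run_var
    new_mean <- run_mean; new_var <- run_var
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  core <- bn_core_cpp(m, mu, invstd, gamma, beta)
  list(y = fa(core$y, d),
       cache = list(xhat = core$xhat, invstd = invstd, d = d,
                    training = training),
       run_mean = new_mean, run_var = new_var)
}

bn_bwd <- function(dy, cache, gamma) {
  out <- bn_bwd_cpp(fm(dy), cache$xhat, gamma, cache$invstd, cache$training)
  list(dx = fa(out$dx, cache$d), dgamma = out$dgamma, dbeta = out$dbeta)
}

## --- ReLU ------------------------------------------------------------------

relu_fwd <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_bwd <- function(dy, cache) dy * cache

## --- 2x2 max pooling, stride 2 ---------------------------------------------

pool_idx <- function(d) lapply(1:4, function(k)
  stride2_idx(d[1], d[2], d[3], POOL_OI[k], POOL_OJ[k]))

maxpool2_fwd <- function(x) {
  d <- dim(x)
  M <- fm(x)
  px <- pool_idx(d)
  cand <- lapply(px, function(i) M[i, , drop = FALSE])
  y <- pmax(cand[[1]], cand[[2]], cand[[3]], cand[[4]])
  # deterministic tie-break: first candidate wins
  w1 <- cand[[1]] == y
  w2 <- (cand[[2]] == y) & !w1
  w3 <- (cand[[3]] == y) & !(w1 | w2)
  w4 <- !(w1 | w2 | w3)
  list(y = fa(y, c(d[1] %/% 2, d[2] %/% 2, d[3], d[4])),
       cache = list(w = list(w1, w2, w3, w4), d = d))
}

maxpool2_bwd <- function(dy, cache) {
  d <- cache$d
  dym <- fm(dy)
  dxm <- matrix(0, d[1] * d[2] * d[3], d[4])
  px <- pool_idx(d)
  for (k in 1:4) dxm[px[[k]], ] <- dym * cache$w[[k]]
  fa(dxm, d)
}

## --- 2x2 strided convolution (learned downsampling), Ws: list of 4 --------

downconv2_fwd <- function(x, Ws, b) {
  d <- dim(x)
  M <- fm(x)
  px <- pool_idx(d)
  y <- matrix(0, length(px[[1]]), ncol(Ws[[1]]))
  for (k in 1:4) y <- y + M[px[[k]], , drop = FALSE] %*% Ws[[k]]
  y <- add_bias(y, b)
  list(y = fa(y, c(d[1] %/% 2, d[2] %/% 2, d[3], ncol(Ws[[1]]))), cache = x)
}

downconv2_bwd <- function(dy, x, Ws) {
  d <- dim(x)
  M <- fm(x)
  px <- pool_idx(d)
  dym <- fm(dy)
  dxm <- matrix(0, nrow(M), d[4])
  dWs <- vector("list", 4)
  for (k in 1:4) {
    xs <- M[px[[k]], , drop = FALSE]
    dWs[[k]] <- crossprod(xs, dym)
    dxm[px[[k]], ] <- dym %*% t(Ws[[k]])   # offsets address disjoint rows
  }
  list(dx = fa(dxm, d), dWs = dWs, db = colSums(dym))
}

## --- 2x2 transposed convolution, stride 2 (up-convolution) ----------------

upconv2_fwd <- function(x, Ws, b) {
  d <- dim(x)
  xm <- fm(x)
  Cout <- ncol(Ws[[1]])
  d_out <- c(2 * d[1], 2 * d[2], d[3], Cout)
  ym <- matrix(0, 4 * d[1] * d[2] * d[3], Cout)
  px <- pool_idx(d_out)
  for (k in 1:4) ym[px[[k]], ] <- xm %*% Ws[[k]]
  list(y = fa(add_bias(ym, b), d_out), cache = x)
}

upconv2_bwd <- function(dy, x, Ws) {
  d <- dim(x)
  xm <- fm(x)
  dym <- fm(dy)
  px <- pool_idx(dim(dy))
  dWs <- vector("list", 4)
  dxm <- matrix(0, nrow(xm), ncol(xm))
  db <- 0
  for (k in 1:4) {
    dyk <- dym[px[[k]], , drop = FALSE]
    dWs[[k]] <- crossprod(xm, dyk)
    dxm <- dxm + dyk %*% t(Ws[[k]])
    db <- db + colSums(dyk)
  }
  list(dx = fa(dxm, d), dWs = dWs, db = db)
}

## --- channel concat / split (channel-last: a cbind) ------------------------

concat_ch <- function(x1, x2) {
  d1 <- dim(x1); d2 <- dim(x2)
  fa(cbind(fm(x1), fm(x2)), c(d1[1], d1[2], d1[3], d1[4] + d2[4]))
}

split_ch <- function(dy, c1) {
  d <- dim(dy)
  m <- fm(dy)
  list(fa(m[, seq_len(c1), drop = FALSE], c(d[1], d[2], d[3], c1)),
       fa(m[, (c1 + 1):d[4], drop = FALSE], c(d[1], d[2], d[3], d[4] - c1)))
}

## --- softmax head and losses -----------------------------------------------

softmax_ch <- function(logits) {
  d <- dim(logits)
  m <- fm(logits)
  mx <- m[, 1]
  for (k in 2:ncol(m)) mx <- pmax(mx, m[, k])
  e <- exp(m - mx)
  fa(e / rowSums(e), d)
}

# target: (H, W, N) array of class indices 1..K (binary: 1 = background,
# 2 = structure). Returns loss value and gradient w.r.t. logits.
seg_loss <- function(probs, target, loss = c("cross_entropy", "dice", "combined")) {
  loss <- match.arg(loss)
  d <- dim(probs)
  n_pix <- d[1] * d[2] * d[3]
  pm <- fm(probs)
  tgt <- as.integer(as.vector(target))
  idx <- cbind(seq_len(n_pix), tgt)
  onehot <- matrix(0, n_pix, d[4]); onehot[idx] <- 1
  ce <- -mean(log(pmax(pm[idx], 1e-12)))
  eps <- 1
  p1 <- pm[, d[4]]; t1 <- onehot[, d[4]]
  num <- 2 * sum(p1 * t1) + eps
  den <- sum(p1) + sum(t1) + eps
  dsc <- 1 - num / den
  value <- switch(loss, cross_entropy = ce, dice = dsc, combined = ce + dsc)
  if (loss == "cross_entropy") {
    dlogits <- (pm - onehot) / n_pix
  } else {
    # d(dice loss)/dp1, then through the softmax jacobian
    g <- matrix(0, n_pix, d[4])
    g[, d[4]] <- -(2 * t1 * den - num) / den^2
    dl_dsc <- pm * (g - rowSums(g * pm))
    dlogits <- if (loss == "dice") dl_dsc else (pm - onehot) / n_pix + dl_dsc
  }
  list(value = value, dice_value = 1 - dsc, ce_value = ce,
       dlogits = fa(dlogits, d))
}
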