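# shared in-code fixtures: everything is generated, nothing read from disk

# a binary disc mask under the package's half-open pixel-center rule
disc_fixture <- function(size, center, radius) {
  r <- matrix(seq_len(size), size, size) - center[1]
  cc <- matrix(seq_len(size), size, size, byrow = TRUE) - center[2]
  (r^2 + cc^2 < radius^2) * 1
}

# small, fast phantom geometry used across tests
tiny_phantom <- function(n_slices = 4, ...) {
  phantom_config(image_size = 64, endo_radius_px = c(7, 11),
                 wall_thickness_px = c(3, 5), center_jitter_px = 4,
                 n_slices = n_slices, ...)
}

tiny_arch <- function(...) {
  arch_config(input_size = 16, n_levels = 2, base_channels = 4, seed = 7, ...)
}

# independent brute-force APD oracle: average over vertices of the distance to
# a densely resampled version of the other polyline (point-to-point at 20k
# samples approximates point-to-segment), symmetrized; in mm
oracle_apd <- function(ca, cb, n_dense = 20000) {
  sp <- ca$spacing
  densify <- function(cn) {
    x <- c(cn$x, cn$x[1]) * sp[2]; y <- c(cn$y, cn$y[1]) * sp[1]
    seg <- sqrt(diff(x)^2 + diff(y)^2)
    tt <- cumsum(c(0, seg)); tot <- tt[length(tt)]
    s <- seq(0, tot, length.out = n_dense)
    cbind(approx(tt, x, xout = s)$y, approx(tt, y, xout = s)$y)
  }
  da <- densify(ca); db <- densify(cb)
  pa <- cbind(ca$x * sp[2], ca$y * sp[1])
  pb <- cbind(cb$x * sp[2], cb$y * sp[1])
  mind <- function(P, D) {
    vapply(seq_len(nrow(P)), function(i)
      sqrt(min((D[, 1] - P[i, 1])^2 + (D[, 2] - P[i, 2])^2)), numeric(1))
  }
  (mean(mind(pa, db)) + mean(mind(pb, da))) / 2
}

# finite-difference gradient audit of a built network: returns the fraction of
# sampled coordinates whose analytic gradient matches central differences.
# Parameters are jittered away from the zero-init symmetry so the loss is
# differentiable at almost all sampled coordinates (isolated ReLU/max-pool
# kinks may legitimately disagree).
gradcheck_fraction <- function(cfg, n_coords = 40, eps = 1e-5, loss = "combined") {
  m <- build_resunet(cfg)
  set.seed(1234)
  m$params <- lapply(m$params, function(a) a + stats::rnorm(length(a), 0, 0.05))
  sz <- cfg$input_size
  x <- array(rnorm(sz * sz * 2), c(sz, sz, 2, 1))
  tgt <- array(sample(1:2, sz * sz * 2, TRUE), c(sz, sz, 2))
  th <- unlist(m$params, use.names = FALSE)
  S <- new.env(); S$cache <- list(); S$stats <- m$bn_stats
  fw <- resunetlv:::resunet_forward(m, x, training = TRUE, S = S)
  l <- resunetlv:::seg_loss(fw$probs, tgt, loss)
  gr <- unlist(resunetlv:::resunet_backward(m, S, l$dlogits), use.names = FALSE)
  loss_at <- function(th2) {
    mm <- m; mm$params <- resunetlv:::relist_params(th2, m$params)
    SS <- new.env(); SS$cache <- list(); SS$stats <- m$bn_stats
    resunetlv:::seg_loss(
      resunetlv:::resunet_forward(mm, x, TRUE, SS)$probs, tgt, loss)$value
  }
  ii <- sample(length(th), n_coords)
  ok <- vapply(ii, function(i) {
    tp <- th; tp[i] <- tp[i] + eps
    tm <- th; tm[i] <- tm[i] - eps
    num <- (loss_at(tp) - loss_at(tm)) / (2 * eps)
    abs(num - gr[i]) / max(abs(num) + abs(gr[i]), 1e-6) < 1e-4
  }, logical(1))
  mean(ok)
}
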