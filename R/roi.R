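#' Locate the LV center in a cine slice stack
#'
#' Temporal variation is the cue: the left ventricle moves and changes size
#' over the cardiac cycle while the chest wall is static. The per-pixel
#' temporal standard deviation across the frames is clustered with k-means
#' (k groups of variance values; deterministic quantile-seeded centers); the
#' highest-mean cluster is taken as candidate moving tissue, binarized, and
#' the connected component whose centroid lies nearest the frame center is
#' selected. When clustering yields no usable component the method falls back
#' to an Otsu threshold on the variance map.
#'
#' @param cine_stack List of >= 2 matrices of identical dimensions (frames of
#'   one slice position across the cycle, e.g. ED + ES).
#' @param k Number of k-means clusters (>= 2).
#' @return Estimated LV center `c(row, col)` in 1-based pixel coordinates.
#' @export
locate_lv_center <- function(cine_stack, k = 3) {
  if (!is.list(cine_stack) || length(cine_stack) < 2)
    stop("locate_lv_center() needs at least 2 frames (temporal variation is the cue)",
         call. = FALSE)
  dims <- dim(cine_stack[[1]])
  if (!all(vapply(cine_stack, function(f) identical(dim(f), dims), logical(1))))
    stop("all frames must share the same dimensions", call. = FALSE)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  frames <- simplify2array(cine_stack)           # H x W x T
  mu <- apply(frames, c(1, 2), mean)
  sdmap <- sqrt(pmax(apply(frames^2, c(1, 2), mean) - mu^2, 0))
  if (max(sdmap) < 1e-12)
    stop("degenerate input: frames are identical (no temporal variation to locate the LV)",
         call. = FALSE)
  v <- as.vector(sdmap)
  centers <- stats::quantile(v, probs = seq(0, 1, length.out = k + 2)[2:(k + 1)])
  centers <- unique(as.numeric(centers))
  cand <- NULL
  if (length(centers) >= 2) {
    km <- suppressWarnings(stats::kmeans(v, centers = matrix(centers, ncol = 1)))
    top <- which.max(km$centers)
    cand <- matrix(as.numeric(km$cluster == top), dims[1], dims[2])
  }
  if (is.null(cand) || sum(cand) == 0) {
    thr <- EBImage::otsu(sdmap / max(sdmap), range = c(0, 1))
    cand <- as_mask(sdmap / max(sdmap) > thr)
  }
  if (sum(cand) == 0)
    stop("degenerate input: no moving-tissue candidate found", call. = FALSE)
  # the moving region is an annulus that can fragment; close small gaps so
  # its pieces are scored as one component
  cand <- EBImage::closing(cand, EBImage::makeBrush(5, "disc"))
  lab <- EBImage::bwlabel(cand)
  ncomp <- max(lab)
  frame_center <- (dims + 1) / 2
  best <- NULL; best_d <- Inf
  for (comp in seq_len(ncomp)) {
    idx <- which(lab == comp, arr.ind = TRUE)
    cen <- colMeans(idx)
    d <- sqrt(sum((cen - frame_center)^2))
    if (d < best_d) { best_d <- d; best <- cen }
  }
  unname(best)
}

#' Crop a fixed-size ROI around a center point
#'
#' Extracts a `size` x `size` window centred on `center`, shifted (never
#' padded) to stay fully inside the frame, so every ROI pixel is real data.
#' The recorded 0-based top-left offset maps ROI predictions back to
#' full-frame coordinates.
#'
#' @param image Matrix (a full-frame slice).
#' @param center Target center `c(row, col)`, 1-based.
#' @param size ROI side length in px (default 128).
#' @return An `lv_roi`: list with `roi` (size x size matrix), `offset`
#'   (0-based `c(row, col)` of the ROI top-left in the source) and
#'   `center_estimate`.
#' @export
crop_roi <- function(image, center, size = 128) {
  nr <- nrow(image); nc <- ncol(image)
  if (size > min(nr, nc))
    stop("ROI size ", size, " exceeds image ", nr, "x", nc,
         "; resize or pad the input explicitly before cropping", call. = FALSE)
  # 0-based top-left = center - size/2; +1 converts to 1-based indexing
  top <- round(center[1]) - size %/% 2 + 1
  left <- round(center[2]) - size %/% 2 + 1
  top <- min(max(top, 1), nr - size + 1)
  left <- min(max(left, 1), nc - size + 1)
  structure(list(roi = image[top:(top + size - 1), left:(left + size - 1)],
                 offset = c(row = top - 1L, col = left - 1L),
                 center_estimate = center),
            class = "lv_roi")
}

#' Paste an ROI (or an ROI-sized mask) back into a full frame
#'
#' @param target Full-frame matrix to paste into (e.g. a zero mask canvas).
#' @param roi Matrix to paste (the ROI window or a prediction on it).
#' @param offset 0-based `c(row, col)` top-left offset from [crop_roi()].
#' @return The updated full-frame matrix.
#' @export
paste_roi <- function(target, roi, offset) {
  nr <- nrow(roi); nc <- ncol(roi)
  rows <- (offset[1] + 1):(offset[1] + nr)
  cols <- (offset[2] + 1):(offset[2] + nc)
  if (max(rows) > nrow(target) || max(cols) > ncol(target) || min(offset) < 0)
    stop("offset + ROI size exceeds target dimensions", call. = FALSE)
  target[rows, cols] <- roi
  target
}
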