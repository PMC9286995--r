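ROTATION_ANGLES <- c(45, 90, 135, 180, 225, 270, 315)

#' Rotate an image/mask pair
#'
#' Clockwise rotation about the image center. The image is resampled
#' bilinearly with out-of-frame corners filled with the image's border median
#' (a background estimate); the mask uses nearest-neighbour resampling with
#' zero fill, so it stays strictly binary. Multiples of 90 degrees are exact
#' pixel permutations.
#'
#' @param image Square numeric matrix.
#' @param mask Square binary matrix of the same size.
#' @param angle_deg One of 45, 90, 135, 180, 225, 270, 315.
#' @return List with rotated `image` and `mask`.
#' @export
rotate_pair <- function(image, mask, angle_deg) {
  if (nrow(image) != ncol(image))
    stop("rotation of non-square inputs is not supported ",
         "(45-degree rotations are ill-defined on non-square grids)", call. = FALSE)
  if (!identical(dim(image), dim(mask)))
    stop("image and mask dimensions differ", call. = FALSE)
  stop_if_not_mask(mask)
  if (!angle_deg %in% ROTATION_ANGLES)
    stop("angle must be one of ", paste(ROTATION_ANGLES, collapse = ", "),
         call. = FALSE)
  n <- nrow(image)
  bg <- stats::median(c(image[1, ], image[n, ], image[, 1], image[, n]))
  out_dim <- c(n, n)
  img_r <- EBImage::rotate(image, angle_deg, filter = "bilinear",
                           output.dim = out_dim, bg.col = bg)
  msk_r <- EBImage::rotate(as_mask(mask), angle_deg, filter = "none",
                           output.dim = out_dim, bg.col = 0)
  list(image = matrix(as.numeric(img_r), n, n),
       mask = as_mask(matrix(as.numeric(msk_r), n, n)))
}

flip_pair <- function(image, mask, which = c("h", "v")) {
  which <- match.arg(which)
  fl <- if (which == "h") function(m) m[, rev(seq_len(ncol(m)))]
        else function(m) m[rev(seq_len(nrow(m))), ]
  list(image = fl(image), mask = fl(as_mask(mask)))
}

#' Ten-fold augmentation of a training pair
#'
#' Expands one ROI/mask pair into exactly ten: the original, seven clockwise
#' rotations (45 to 315 degrees in 45-degree steps) and the horizontal and
#' vertical flips of the original. Image and mask are always transformed by
#' the same operator.
#'
#' @param image Square numeric matrix (an ROI).
#' @param mask Square binary matrix.
#' @return An `lv_augmented_set`: list of 10 elements, each
#'   `list(image, mask, tag)` with tag in `original`, `rot45`, ..., `rot315`,
#'   `hflip`, `vflip`.
#' @export
augment_tenfold <- function(image, mask) {
  stop_if_not_mask(mask)
  out <- list(list(image = image, mask = as_mask(mask), tag = "original"))
  for (a in ROTATION_ANGLES) {
    p <- rotate_pair(image, mask, a)
    out[[length(out) + 1]] <- list(image = p$image, mask = p$mask,
                                   tag = paste0("rot", a))
  }
  for (w in c("h", "v")) {
    p <- flip_pair(image, mask, w)
    out[[length(out) + 1]] <- list(image = p$image, mask = p$mask,
                                   tag = paste0(w, "flip"))
  }
  structure(out, class = "lv_augmented_set")
}

#' @export
print.lv_augmented_set <- function(x, ...) {
  cat("<lv_augmented_set> ", length(x), " pairs: ",
      paste(vapply(x, `[[`, character(1), "tag"), collapse = ", "), "\n", sep = "")
  invisible(x)
}
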