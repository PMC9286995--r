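#' Dice metric between two binary masks
#'
#' Region-overlap score \eqn{DM = 2|A_s \cap A_g| / (|A_s| + |A_g|)} between a
#' segmented area and a reference area. The score lies in \[0, 1\]; 1 means
#' identical regions.
#'
#' @param mask_s,mask_g Binary matrices of identical dimensions (segmentation
#'   and ground truth). Logical or 0/1 numeric.
#' @return A single number in \[0, 1\].
#' @examples
#' a <- matrix(0, 8, 8); a[2:5, 2:5] <- 1
#' b <- matrix(0, 8, 8); b[3:6, 3:6] <- 1
#' dice(a, b)
#' @export
dice <- function(mask_s, mask_g) {
  stop_if_not_mask(mask_s)
  stop_if_not_mask(mask_g)
  if (!identical(dim(mask_s), dim(mask_g)))
    stop("masks must have identical dimensions (", paste(dim(mask_s), collapse = "x"),
         " vs ", paste(dim(mask_g), collapse = "x"), ")", call. = FALSE)
  s <- as_mask(mask_s); g <- as_mask(mask_g)
  denom <- sum(s) + sum(g)
  if (denom == 0)
    stop("dice is undefined when both masks are empty", call. = FALSE)
  2 * sum(s * g) / denom
}

#' Extract the closed boundary contour of a binary mask
#'
#' Traces the 0.5-level iso-contour of the binary image (linear interpolation
#' between pixel centers, as in marching squares), giving a closed polyline at
#' sub-pixel resolution. Coordinates follow the image convention used
#' throughout the package: `x` is the column index, `y` the row index, both
#' 0-based, in pixel units. The contour runs half a pixel outside the
#' outermost foreground pixel centers with 45-degree corner cuts, so an
#' n-by-n filled block yields a perimeter slightly below 4n.
#'
#' @param mask Binary matrix with exactly one 4-connected foreground component.
#' @param spacing Pixel spacing in mm, a single number or a length-2 vector
#'   (row spacing, column spacing).
#' @return An object of class `lv_contour`: a list with `x`, `y` (open polyline
#'   vertices; the polygon is implicitly closed) and `spacing`.
#' @seealso [apd()], [contour_area()], [rasterize_contour()]
#' @export
mask_to_contour <- function(mask, spacing = 1) {
  stop_if_not_mask(mask)
  if (sum(mask) == 0) stop("cannot extract a contour from an empty mask", call. = FALSE)
  nc <- n_components(mask)
  if (nc > 1)
    stop("mask has ", nc, " connected components; expected exactly 1 ",
         "(consider keeping the largest component first)", call. = FALSE)
  m <- as_mask(mask)
  # pad with a zero border so contours touching the frame edge still close
  pm <- matrix(0, nrow(m) + 2, ncol(m) + 2)
  pm[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  cl <- grDevices::contourLines(x = seq_len(nrow(pm)), y = seq_len(ncol(pm)),
                                z = pm, levels = 0.5)
  if (length(cl) == 0) stop("no contour found at level 0.5", call. = FALSE)
  # keep the longest loop (a single component yields one outer loop)
  lens <- vapply(cl, function(l) length(l$x), numeric(1))
  loop <- cl[[which.max(lens)]]
  # contourLines x follows dim 1 (rows); convert to image x=col, y=row, 0-based
  # (subtract the pad offset of 1 and the 1-based origin)
  y <- loop$x - 2
  x <- loop$y - 2
  # drop the duplicated closing vertex; the polygon is implicitly closed
  n <- length(x)
  if (n > 1 && x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n] }
  lv_contour(x, y, spacing)
}

#' Construct a contour from coordinates
#'
#' Builds the closed-polyline contour object used by [apd()] and friends from
#' explicit vertex coordinates (x = column, y = row, 0-based pixel units).
#' The polygon closes implicitly from the last vertex back to the first.
#'
#' @param x,y Vertex coordinates (at least 3 points).
#' @param spacing Pixel spacing in mm (scalar or `c(row, col)`).
#' @return An object of class `lv_contour`.
#' @export
lv_contour <- function(x, y, spacing = 1) {
  if (length(x) < 3) stop("a contour needs at least 3 points", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- c(spacing, spacing)
  if (any(spacing <= 0)) stop("pixel spacing must be positive", call. = FALSE)
  structure(list(x = as.numeric(x), y = as.numeric(y), spacing = spacing),
            class = "lv_contour")
}

#' @export
print.lv_contour <- function(x, ...) {
  cat(sprintf("<lv_contour> %d vertices, spacing %.4g x %.4g mm/px\n",
              length(x$x), x$spacing[1], x$spacing[2]))
  invisible(x)
}

closed_xy <- function(contour) {
  list(x = c(contour$x, contour$x[1]), y = c(contour$y, contour$y[1]))
}

#' Polygon length and area of a closed contour
#'
#' `contour_perimeter()` is the polyline length of the closed contour;
#' `contour_area()` the enclosed area by the shoelace formula. Both are in
#' pixel units unless `physical = TRUE`, in which case the pixel spacing is
#' applied (mm and mm^2).
#'
#' @param contour An [mask_to_contour()] result (class `lv_contour`).
#' @param physical Apply the contour's pixel spacing?
#' @return A single non-negative number.
#' @export
contour_area <- function(contour, physical = FALSE) {
  p <- closed_xy(contour)
  x <- p$x; y <- p$y
  if (physical) { x <- x * contour$spacing[2]; y <- y * contour$spacing[1] }
  n <- length(x)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

#' @rdname contour_area
#' @export
contour_perimeter <- function(contour, physical = FALSE) {
  p <- closed_xy(contour)
  x <- p$x; y <- p$y
  if (physical) { x <- x * contour$spacing[2]; y <- y * contour$spacing[1] }
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Rasterize a contour back to a binary mask
#'
#' Marks every pixel whose center lies inside the closed polygon (even-odd
#' rule). Inverse operation of [mask_to_contour()] up to discretization.
#'
#' @param contour An `lv_contour`.
#' @param dim Output dimensions `c(nrow, ncol)`.
#' @return Binary matrix.
#' @export
rasterize_contour <- function(contour, dim) {
  p <- closed_xy(contour)
  px <- p$x; py <- p$y
  nr <- dim[1]; nc <- dim[2]
  out <- matrix(0, nr, nc)
  # restrict the scan to the bounding box
  rows <- max(1, floor(min(py)) + 1):min(nr, ceiling(max(py)) + 1)
  cols <- max(1, floor(min(px)) + 1):min(nc, ceiling(max(px)) + 1)
  grid <- expand.grid(r = rows, cc = cols)
  # point-in-polygon, even-odd ray casting; pixel (r, c) has center (x=c-1, y=r-1)
  xq <- grid$cc - 1; yq <- grid$r - 1
  n <- length(px) - 1
  inside <- rep(FALSE, length(xq))
  for (i in seq_len(n)) {
    x1 <- px[i]; y1 <- py[i]; x2 <- px[i + 1]; y2 <- py[i + 1]
    crosses <- ((y1 > yq) != (y2 > yq))
    if (any(crosses)) {
      xint <- x1 + (yq[crosses] - y1) / (y2 - y1) * (x2 - x1)
      flip <- xq[crosses] < xint
      inside[crosses][flip] <- !inside[crosses][flip]
    }
  }
  out[cbind(grid$r[inside], grid$cc[inside])] <- 1
  out
}

#' Average perpendicular distance between two contours
#'
#' Symmetric mean distance in mm: for every vertex of one contour the distance
#' to the nearest point on the other polyline (point-to-segment, not
#' point-to-vertex) is computed; the two directed means are averaged. This is
#' the contour-similarity measure used to grade automatic cardiac
#' segmentations, with anisotropic pixel spacing applied before distances are
#' taken.
#'
#' @param contour_a,contour_b `lv_contour` objects with identical pixel spacing.
#' @return Distance in mm (non-negative).
#' @seealso [classify_good()]
#' @export
apd <- function(contour_a, contour_b) {
  if (!inherits(contour_a, "lv_contour") || !inherits(contour_b, "lv_contour"))
    stop("apd() expects two lv_contour objects", call. = FALSE)
  if (!isTRUE(all.equal(contour_a$spacing, contour_b$spacing)))
    stop("contours have different pixel spacings (",
         paste(contour_a$spacing, collapse = "x"), " vs ",
         paste(contour_b$spacing, collapse = "x"), " mm)", call. = FALSE)
  sp <- contour_a$spacing
  pa <- cbind(contour_a$x * sp[2], contour_a$y * sp[1])
  pb <- cbind(contour_b$x * sp[2], contour_b$y * sp[1])
  (mean(points_to_polyline(pa, pb)) + mean(points_to_polyline(pb, pa))) / 2
}

# Min distance from each point (rows of P) to a closed polyline with vertex
# matrix V; fully vectorized over the n_points x n_segments grid.
points_to_polyline <- function(P, V) {
  a <- V
  b <- rbind(V[-1, , drop = FALSE], V[1, , drop = FALSE])
  dx <- b[, 1] - a[, 1]; dy <- b[, 2] - a[, 2]
  len2 <- dx^2 + dy^2
  len2[len2 == 0] <- 1e-300
  # t = clamp(((P-a).(b-a))/|b-a|^2, 0, 1) per point x segment
  tx <- outer(P[, 1], a[, 1], "-")   # n x m
  ty <- outer(P[, 2], a[, 2], "-")
  tt <- sweep(sweep(tx, 2, dx, "*") + sweep(ty, 2, dy, "*"), 2, len2, "/")
  tt[tt < 0] <- 0; tt[tt > 1] <- 1
  ex <- tx - sweep(tt, 2, dx, "*")
  ey <- ty - sweep(tt, 2, dy, "*")
  sqrt(apply(ex^2 + ey^2, 1, min))
}

#' Is a contour segmentation "good"?
#'
#' A slice segmentation is classified as good when its average perpendicular
#' distance to the reference contour is strictly below 5 mm.
#'
#' @param apd_mm Average perpendicular distance(s) in mm; `NA` (no contour
#'   detected) is never good.
#' @param threshold_mm Cut-off in mm (default 5).
#' @return Logical vector.
#' @export
classify_good <- function(apd_mm, threshold_mm = 5) {
  if (any(!is.na(apd_mm) & apd_mm < 0)) stop("APD cannot be negative", call. = FALSE)
  !is.na(apd_mm) & apd_mm < threshold_mm
}

#' Per-case contour evaluation
#'
#' Evaluates aligned lists of predicted and ground-truth masks slice by slice:
#' dice metric, APD in mm and the good/poor label per slice, then the case-level
#' summary. The percentage of good contours (PGC) uses all slices in the
#' denominator; mean dice and mean APD are computed over the good slices only.
#' A slice with an empty prediction counts as not good and contributes no
#' dice/APD.
#'
#' @param pred_masks,gt_masks Lists of binary matrices, same length and
#'   dimensions. Predictions with multiple components are reduced to their
#'   largest connected component before contour extraction.
#' @param spacing Pixel spacing in mm (scalar or length 2).
#' @return An object of class `lv_case_metrics`: list with `slices` (data frame
#'   of per-slice dm, apd_mm, good), `pgc_percent`, `mean_dm_of_good`,
#'   `mean_apd_of_good`, `n_slices`, `n_good`.
#' @export
evaluate_case <- function(pred_masks, gt_masks, spacing = 1) {
  if (length(pred_masks) != length(gt_masks))
    stop("pred and gt slice lists differ in length (", length(pred_masks),
         " vs ", length(gt_masks), ")", call. = FALSE)
  if (length(pred_masks) == 0) stop("no slices to evaluate", call. = FALSE)
  n <- length(pred_masks)
  dm <- apd_mm <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    pred <- as_mask(pred_masks[[i]]); gt <- as_mask(gt_masks[[i]])
    if (sum(gt) == 0) stop("ground-truth mask ", i, " is empty", call. = FALSE)
    if (sum(pred) == 0) next  # undetected structure: not good, no metrics
    pred <- largest_component(pred)
    dm[i] <- dice(pred, gt)
    apd_mm[i] <- apd(mask_to_contour(pred, spacing), mask_to_contour(gt, spacing))
  }
  good <- classify_good(apd_mm)
  res <- list(
    slices = data.frame(slice = seq_len(n), dm = dm, apd_mm = apd_mm, good = good),
    pgc_percent = 100 * sum(good) / n,
    mean_dm_of_good = if (any(good)) mean(dm[good]) else NA_real_,
    mean_apd_of_good = if (any(good)) mean(apd_mm[good]) else NA_real_,
    n_slices = n, n_good = sum(good))
  class(res) <- "lv_case_metrics"
  res
}

#' @export
print.lv_case_metrics <- function(x, ...) {
  cat(sprintf("<lv_case_metrics> %d slices, %d good\n", x$n_slices, x$n_good))
  cat(sprintf("  PGC %.2f%%  DM(good) %.3f  APD(good) %.3f mm\n",
              x$pgc_percent, x$mean_dm_of_good, x$mean_apd_of_good))
  invisible(x)
}

#' Cohort summary of case metrics
#'
#' Mean and sample standard deviation (n-1 denominator) of PGC, dice and APD
#' across cases, the summary rows of a challenge-style results table.
#'
#' @param cases List of [evaluate_case()] results.
#' @return Data frame with rows `mean` and `sd`, columns `pgc_percent`, `dm`,
#'   `apd_mm`.
#' @export
summarize_cases <- function(cases) {
  if (length(cases) == 0) stop("no cases to summarize", call. = FALSE)
  pull <- function(f) vapply(cases, function(cs) cs[[f]], numeric(1))
  m <- cbind(pgc_percent = pull("pgc_percent"),
             dm = pull("mean_dm_of_good"),
             apd_mm = pull("mean_apd_of_good"))
  sdv <- if (nrow(m) == 1) rep(0, 3) else apply(m, 2, stats::sd, na.rm = TRUE)
  out <- rbind(mean = colMeans(m, na.rm = TRUE), sd = sdv)
  as.data.frame(out)
}

#' Read and write contour point-list files
#'
#' Plain-text contour files with one "x y" coordinate pair per line (the
#' dialect of the public cardiac-segmentation challenge distributions).
#' Coordinates are 0-based pixel units, x = column, y = row.
#'
#' @param path File path.
#' @param contour An `lv_contour`.
#' @param spacing Pixel spacing (mm) attached to the contour on reading.
#' @return `read_contour()` returns an `lv_contour`; `write_contour()` returns
#'   `path` invisibly.
#' @export
read_contour <- function(path, spacing = 1) {
  tab <- utils::read.table(path, col.names = c("x", "y"))
  lv_contour(tab$x, tab$y, spacing)
}

#' @rdname read_contour
#' @export
write_contour <- function(contour, path) {
  utils::write.table(
    data.frame(x = sprintf("%.4f", contour$x), y = sprintf("%.4f", contour$y)),
    path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
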