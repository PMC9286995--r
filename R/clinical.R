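#' Volume of a stack of binary slice masks
#'
#' Slab summation: each slice contributes (pixel count x row spacing x column
#' spacing) x slice thickness, with an optional inter-slice gap added to the
#' slab height. Result in ml (1 ml = 1000 mm^3).
#'
#' @param mask_stack List of binary matrices (may be empty).
#' @param pixel_spacing_mm In-plane spacing in mm, scalar or length 2.
#' @param slice_thickness_mm Slice thickness in mm.
#' @param gap_mm Inter-slice gap in mm added to each slab (default 0).
#' @return Volume in ml.
#' @export
volume_ml <- function(mask_stack, pixel_spacing_mm, slice_thickness_mm, gap_mm = 0) {
  sp <- as.numeric(pixel_spacing_mm)
  if (length(sp) == 1) sp <- c(sp, sp)
  if (any(sp <= 0) || slice_thickness_mm <= 0 || gap_mm < 0)
    stop("spacing and thickness must be positive, gap non-negative", call. = FALSE)
  if (length(mask_stack) == 0) return(0)
  px <- vapply(mask_stack, function(m) { stop_if_not_mask(m, "slice"); sum(as_mask(m)) },
               numeric(1))
  sum(px) * sp[1] * sp[2] * (slice_thickness_mm + gap_mm) / 1000
}

#' Left-ventricular mass
#'
#' \eqn{LVM = (V_{epi}^{ED} - V_{end}^{ED}) \times 1.05} g, i.e. the myocardial
#' wall volume at end-diastole times the myocardial density of 1.05 g/ml.
#'
#' @param v_epi_ed_ml,v_end_ed_ml Epicardial and endocardial end-diastolic
#'   volumes in ml; the epicardium must enclose the endocardium.
#' @param density_g_ml Myocardial density (g/ml), default 1.05.
#' @return Mass in g.
#' @export
lvm_g <- function(v_epi_ed_ml, v_end_ed_ml, density_g_ml = 1.05) {
  if (any(v_epi_ed_ml < 0) || any(v_end_ed_ml < 0))
    stop("volumes must be non-negative", call. = FALSE)
  if (any(v_epi_ed_ml < v_end_ed_ml))
    stop("epicardial volume (", v_epi_ed_ml, " ml) is smaller than endocardial (",
         v_end_ed_ml, " ml); the epicardium must enclose the endocardium",
         call. = FALSE)
  (v_epi_ed_ml - v_end_ed_ml) * density_g_ml
}

#' Ejection fraction
#'
#' \eqn{EF = 100 (V_{end}^{ED} - V_{end}^{ES}) / V_{end}^{ED}} percent: the
#' relative endocardial volume change from end-diastole to end-systole.
#'
#' @param v_end_ed_ml,v_end_es_ml Endocardial ED and ES volumes in ml.
#' @return EF in percent.
#' @export
ef_percent <- function(v_end_ed_ml, v_end_es_ml) {
  if (any(v_end_ed_ml <= 0))
    stop("end-diastolic volume must be positive to compute EF", call. = FALSE)
  100 * (v_end_ed_ml - v_end_es_ml) / v_end_ed_ml
}

#' Agreement between automatic and manual measurements
#'
#' Bland-Altman statistics of the paired differences d = auto - manual (mean
#' bias, 1.96 SD limits of agreement, 95% confidence interval of the bias and
#' its one-sample t-test p-value, number of pairs outside the limits) together
#' with the ordinary least-squares regression of auto on manual (slope,
#' intercept, R^2).
#'
#' @param auto_values,manual_values Equal-length numeric vectors, n >= 3.
#' @return An object of class `lv_agreement` (a list of the statistics above).
#' @examples
#' agreement(c(10, 12, 14, 15, 18, 20) + rnorm(6, 0, 0.5),
#'           c(10, 12, 14, 15, 18, 20))
#' @export
agreement <- function(auto_values, manual_values) {
  if (length(auto_values) != length(manual_values))
    stop("auto and manual vectors differ in length", call. = FALSE)
  n <- length(auto_values)
  if (n < 3) stop("agreement statistics need at least 3 pairs", call. = FALSE)
  d <- auto_values - manual_values
  bias <- mean(d)
  sd_d <- stats::sd(d)
  limits <- bias + c(-1, 1) * 1.96 * sd_d
  if (sd_d > 0) {
    tt <- stats::t.test(d)
    p <- tt$p.value
    ci <- as.numeric(tt$conf.int)
  } else {  # constant differences: the location test is degenerate
    p <- NA_real_
    ci <- c(bias, bias)
  }
  fit <- stats::lm(auto_values ~ manual_values)
  co <- stats::coef(fit)
  r2 <- if (stats::var(auto_values) == 0 && sd_d == 0) 1
        else suppressWarnings(summary(fit)$r.squared)
  structure(list(
    n = n, bias = bias, sd_diff = sd_d,
    lower_limit = limits[1], upper_limit = limits[2],
    ci_bias = ci, p_bias = p,
    slope = unname(co[2]), intercept = unname(co[1]), r_squared = r2,
    n_outside = sum(d < limits[1] | d > limits[2]),
    differences = d), class = "lv_agreement")
}

#' @export
print.lv_agreement <- function(x, digits = 3, ...) {
  cat(sprintf("<lv_agreement> n = %d\n", x$n))
  cat(sprintf("  bias %s +/- 1.96 SD [%s, %s], CI(%s, %s), p = %s\n",
              format(x$bias, digits = digits),
              format(x$lower_limit, digits = digits),
              format(x$upper_limit, digits = digits),
              format(x$ci_bias[1], digits = digits),
              format(x$ci_bias[2], digits = digits),
              format(x$p_bias, digits = digits)))
  cat(sprintf("  regression: slope %s, intercept %s, R^2 %s; %d/%d outside limits\n",
              format(x$slope, digits = digits), format(x$intercept, digits = digits),
              format(x$r_squared, digits = digits), x$n_outside, x$n))
  invisible(x)
}

#' Bland-Altman plot of an agreement analysis
#'
#' @param x An [agreement()] result.
#' @param means Optional pair means for the x-axis; defaults to the pair index.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.lv_agreement <- function(x, means = NULL, ...) {
  xv <- means %||% seq_len(x$n)
  graphics::plot(xv, x$differences, xlab = if (is.null(means)) "pair" else "mean of pair",
                 ylab = "auto - manual", ...)
  graphics::abline(h = c(x$bias, x$lower_limit, x$upper_limit),
                   lty = c(1, 2, 2), col = c("black", "grey40", "grey40"))
  invisible(x)
}

#' Clinical indices from segmented mask stacks
#'
#' Convenience wrapper computing the three volumes and the derived LVM and EF
#' from endocardial ED/ES and epicardial ED mask stacks.
#'
#' @param endo_ed,endo_es,epi_ed Lists of binary slice masks.
#' @param pixel_spacing_mm,slice_thickness_mm,gap_mm Geometry, see [volume_ml()].
#' @return List with `v_epi_ed_ml`, `v_end_ed_ml`, `v_end_es_ml`, `lvm_g`,
#'   `ef_percent`.
#' @export
clinical_indices <- function(endo_ed, endo_es, epi_ed,
                             pixel_spacing_mm, slice_thickness_mm, gap_mm = 0) {
  v_end_ed <- volume_ml(endo_ed, pixel_spacing_mm, slice_thickness_mm, gap_mm)
  v_end_es <- volume_ml(endo_es, pixel_spacing_mm, slice_thickness_mm, gap_mm)
  v_epi_ed <- volume_ml(epi_ed, pixel_spacing_mm, slice_thickness_mm, gap_mm)
  list(v_epi_ed_ml = v_epi_ed, v_end_ed_ml = v_end_ed, v_end_es_ml = v_end_es,
       lvm_g = lvm_g(v_epi_ed, v_end_ed), ef_percent = ef_percent(v_end_ed, v_end_es))
}
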