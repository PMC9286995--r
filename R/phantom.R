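#' Configuration for the synthetic cardiac phantom
#'
#' The phantom emulates short-axis cine MR of the left ventricle: a bright,
#' roughly circular blood pool (endocardium) inside a darker myocardial ring
#' (epicardium) on a textured background, with an end-systolic size reduction,
#' a base-to-apex radius taper across 6-12 slices, per-case center jitter and
#' additive Gaussian noise. Ground-truth masks are exact (noiseless) discs, so
#' every downstream metric has an analytic oracle.
#'
#' A pixel belongs to a disc when its *center* lies strictly within the radius
#' (half-open rule); this rasterization convention is fixed because mask areas
#' feed the volume and dice oracles. `wobble_amp_px` adds a low-amplitude
#' sinusoidal perturbation to both boundaries so contours are not perfectly
#' circular (off by default).
#'
#' @param image_size Pixels per (square) side.
#' @param pixel_spacing_mm In-plane spacing, mm per pixel.
#' @param slice_thickness_mm Slice thickness in mm.
#' @param n_slices Slices per phase (typically 6-12).
#' @param endo_radius_px Range (min, max) of the base-slice ED endocardial
#'   radius, px.
#' @param wall_thickness_px Range of myocardial wall thickness, px.
#' @param es_scale Multiplicative endocardial radius factor at ES, in (0, 1].
#' @param intensity_pool,intensity_myo,intensity_bg Mean gray levels of blood
#'   pool, myocardium and background (pool must be brightest).
#' @param noise_sd Additive Gaussian noise SD on the image (masks unaffected).
#' @param center_jitter_px Max per-case uniform displacement of the LV center
#'   from the frame center, px.
#' @param apex_taper Per-slice multiplicative radius shrink toward the apex.
#' @param wobble_amp_px Amplitude of the sinusoidal boundary perturbation, px.
#' @param wobble_lobes Number of sinusoidal lobes around the boundary.
#' @param seed Default seed used by [generate_case()]/[generate_dataset()].
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 256,
                           pixel_spacing_mm = 1.367,
                           slice_thickness_mm = 8,
                           n_slices = 8,
                           endo_radius_px = c(12, 20),
                           wall_thickness_px = c(6, 10),
                           es_scale = 0.7,
                           intensity_pool = 0.9,
                           intensity_myo = 0.45,
                           intensity_bg = 0.2,
                           noise_sd = 0.03,
                           center_jitter_px = 8,
                           apex_taper = 0.93,
                           wobble_amp_px = 0,
                           wobble_lobes = 4,
                           seed = 1L) {
  cfg <- list(image_size = as.integer(image_size),
              pixel_spacing_mm = pixel_spacing_mm,
              slice_thickness_mm = slice_thickness_mm,
              n_slices = as.integer(n_slices),
              endo_radius_px = rep(endo_radius_px, length.out = 2),
              wall_thickness_px = rep(wall_thickness_px, length.out = 2),
              es_scale = es_scale,
              intensity_pool = intensity_pool,
              intensity_myo = intensity_myo,
              intensity_bg = intensity_bg,
              noise_sd = noise_sd,
              center_jitter_px = center_jitter_px,
              apex_taper = apex_taper,
              wobble_amp_px = wobble_amp_px,
              wobble_lobes = wobble_lobes,
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  with(cfg, {
    if (image_size < 16) stop("image_size must be at least 16 px", call. = FALSE)
    if (pixel_spacing_mm <= 0 || slice_thickness_mm <= 0)
      stop("spacing and thickness must be positive", call. = FALSE)
    if (n_slices < 1) stop("n_slices must be >= 1", call. = FALSE)
    if (es_scale <= 0 || es_scale > 1) stop("es_scale must be in (0, 1]", call. = FALSE)
    if (intensity_pool <= intensity_myo)
      stop("blood pool must be brighter than myocardium ",
           "(intensity_pool > intensity_myo)", call. = FALSE)
    if (any(endo_radius_px <= 0) || any(wall_thickness_px <= 0) || noise_sd < 0 ||
        center_jitter_px < 0 || wobble_amp_px < 0)
      stop("all sizes must be positive and noise/jitter/wobble non-negative",
           call. = FALSE)
    if (apex_taper <= 0 || apex_taper > 1)
      stop("apex_taper must be in (0, 1]", call. = FALSE)
    if (max(endo_radius_px) + max(wall_thickness_px) >= image_size / 2)
      stop("endo_radius + wall_thickness must stay below image_size/2",
           call. = FALSE)
  })
  invisible(cfg)
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf("<phantom_config> %dx%d px @ %.3f mm, %d slices x %g mm, seed %d\n",
              x$image_size, x$image_size, x$pixel_spacing_mm, x$n_slices,
              x$slice_thickness_mm, x$seed))
  cat(sprintf("  endo %g-%g px, wall %g-%g px, ES scale %g, taper %g, noise SD %g\n",
              x$endo_radius_px[1], x$endo_radius_px[2], x$wall_thickness_px[1],
              x$wall_thickness_px[2], x$es_scale, x$apex_taper, x$noise_sd))
  invisible(x)
}

# disc mask under the half-open pixel-center rule, with optional sinusoidal
# boundary wobble; center = (row, col), 1-based pixel centers at integers
disc_mask <- function(size, center, radius, wobble_amp = 0, wobble_lobes = 4,
                      wobble_phase = 0) {
  r <- matrix(seq_len(size), size, size) - center[1]
  cc <- matrix(seq_len(size), size, size, byrow = TRUE) - center[2]
  if (wobble_amp > 0) {
    theta <- atan2(cc, r)
    rad <- radius + wobble_amp * sin(wobble_lobes * theta + wobble_phase)
    as_mask((r^2 + cc^2) < rad^2)
  } else {
    as_mask((r^2 + cc^2) < radius^2)
  }
}

#' Generate one phantom slice
#'
#' Renders a single short-axis slice: background at `intensity_bg`, myocardial
#' annulus at `intensity_myo` with outer radius `endo_radius_px + wall_px`, and
#' blood pool at `intensity_pool` with radius `endo_radius_px` (multiplied by
#' `es_scale` when `phase = "ES"`), plus additive Gaussian noise. The returned
#' masks are the exact noiseless discs.
#'
#' @param config A [phantom_config()].
#' @param center LV center `c(row, col)` in px (1-based pixel centers).
#' @param endo_radius_px End-diastolic endocardial radius for this slice, px.
#' @param wall_px Myocardial wall thickness, px (the epicardial radius is
#'   `endo_radius_px + wall_px` in both phases: the wall thickens as the pool
#'   contracts).
#' @param phase `"ED"` or `"ES"`.
#' @param slice_index Stored in the record for provenance.
#' @param wobble_phase Rotation of the sinusoidal boundary perturbation, rad.
#' @return A `phantom_slice`: list with `image`, `endo_mask`, `epi_mask`,
#'   `phase`, `slice_index`, `center`, `endo_radius_px`, `epi_radius_px`.
#' @export
generate_slice <- function(config, center, endo_radius_px, wall_px,
                           phase = c("ED", "ES"), slice_index = 1L,
                           wobble_phase = 0) {
  phase <- match.arg(phase)
  size <- config$image_size
  endo_r <- endo_radius_px * if (phase == "ES") config$es_scale else 1
  epi_r <- endo_radius_px + wall_px
  max_excur <- epi_r + config$wobble_amp_px
  if (center[1] - max_excur < 1 || center[1] + max_excur > size ||
      center[2] - max_excur < 1 || center[2] + max_excur > size)
    stop(sprintf(paste0("slice geometry exceeds image bounds: center (%.1f, %.1f), ",
                        "epicardial radius %.1f px, image %d px"),
                 center[1], center[2], max_excur, size), call. = FALSE)
  endo <- disc_mask(size, center, endo_r, config$wobble_amp_px,
                    config$wobble_lobes, wobble_phase)
  epi <- disc_mask(size, center, epi_r, config$wobble_amp_px,
                   config$wobble_lobes, wobble_phase)
  img <- matrix(config$intensity_bg, size, size)
  img[epi == 1] <- config$intensity_myo
  img[endo == 1] <- config$intensity_pool
  if (config$noise_sd > 0)
    img <- img + matrix(stats::rnorm(size * size, 0, config$noise_sd), size, size)
  structure(list(image = img, endo_mask = endo, epi_mask = epi, phase = phase,
                 slice_index = as.integer(slice_index), center = center,
                 endo_radius_px = endo_r, epi_radius_px = epi_r),
            class = "phantom_slice")
}

#' Generate a full phantom case (ED + ES stacks)
#'
#' Samples a per-case geometry (base endocardial radius, wall thickness, center
#' jitter) and renders `n_slices` slices per phase, applying the apex taper
#' cumulatively so the true endocardial radius decreases base to apex. Slices
#' whose tapered radius would fall below 1 px are dropped with a warning.
#' Deterministic for a fixed seed.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A `phantom_case`: list with `slices` (ED records then ES records,
#'   each a `phantom_slice`), `config`, `seed`, and true per-case geometry
#'   (`center`, `base_endo_radius_px`, `wall_px`).
#' @export
generate_case <- function(config, seed = config$seed) {
  validate_phantom_config(config)
  with_seed(seed, {
    size <- config$image_size
    base_r <- stats::runif(1, config$endo_radius_px[1], config$endo_radius_px[2])
    wall <- stats::runif(1, config$wall_thickness_px[1], config$wall_thickness_px[2])
    jit <- stats::runif(2, -config$center_jitter_px, config$center_jitter_px)
    center <- (size + 1) / 2 + jit
    wphase <- stats::runif(1, 0, 2 * pi)
    radii <- base_r * config$apex_taper^(seq_len(config$n_slices) - 1)
    keep <- radii * config$es_scale >= 1
    if (!all(keep)) {
      warning(sprintf("apex taper drove %d slice(s) below 1 px radius; truncated",
                      sum(!keep)), call. = FALSE)
      radii <- radii[keep]
    }
    slices <- list()
    for (phase in c("ED", "ES"))
      for (s in seq_along(radii))
        slices[[length(slices) + 1]] <-
          generate_slice(config, center, radii[s], wall, phase, s, wphase)
    structure(list(slices = slices, config = config, seed = as.integer(seed),
                   center = center, base_endo_radius_px = base_r, wall_px = wall,
                   endo_radii_px = radii),
              class = "phantom_case")
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> seed %d: %d slices x 2 phases, center (%.1f, %.1f), endo %.1f px, wall %.1f px\n",
              x$seed, length(x$endo_radii_px), x$center[1], x$center[2],
              x$base_endo_radius_px, x$wall_px))
  invisible(x)
}

case_slices <- function(case, phase) {
  Filter(function(s) s$phase == phase, case$slices)
}

#' Write a phantom dataset to disk
#'
#' Generates `n_cases` cases (case seeds derived as `seed + case index`) and
#' writes, per case and phase, one NIfTI volume each for the image, the
#' endocardial mask and the epicardial mask (pixel spacing and slice thickness
#' in the header), per-slice contour "x y" text files, and a `manifest.csv`
#' with one row per slice (case, slice, phase, geometry, file paths, true
#' center/radii provenance).
#'
#' @param config A [phantom_config()].
#' @param n_cases Number of cases.
#' @param seed Base seed.
#' @param out_dir Output directory (created if missing).
#' @param overwrite Refuse to overwrite an existing manifest unless `TRUE`.
#' @return The manifest data frame, invisibly.
#' @export
generate_dataset <- function(config, n_cases, seed = config$seed, out_dir,
                             overwrite = FALSE) {
  manifest_path <- file.path(out_dir, "manifest.csv")
  if (file.exists(manifest_path) && !overwrite)
    stop("manifest already exists at ", manifest_path,
         "; use overwrite = TRUE to replace the dataset", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (ci in seq_len(n_cases)) {
    case_id <- sprintf("case%03d", ci)
    case <- generate_case(config, seed = seed + ci)
    for (phase in c("ED", "ES")) {
      sl <- case_slices(case, phase)
      vol <- function(field) {
        a <- array(0, c(config$image_size, config$image_size, length(sl)))
        for (i in seq_along(sl)) a[, , i] <- sl[[i]][[field]]
        a
      }
      paths <- c(image = sprintf("%s_%s_image.nii", case_id, phase),
                 endo = sprintf("%s_%s_endo.nii", case_id, phase),
                 epi = sprintf("%s_%s_epi.nii", case_id, phase))
      write_lv_nifti(vol("image"), file.path(out_dir, paths["image"]), config)
      write_lv_nifti(vol("endo_mask"), file.path(out_dir, paths["endo"]), config)
      write_lv_nifti(vol("epi_mask"), file.path(out_dir, paths["epi"]), config)
      for (i in seq_along(sl)) {
        for (struct in c("endo", "epi")) {
          cpath <- sprintf("%s_%s_s%02d_%s.txt", case_id, phase, i, struct)
          mask <- sl[[i]][[paste0(struct, "_mask")]]
          write_contour(mask_to_contour(mask, config$pixel_spacing_mm),
                        file.path(out_dir, cpath))
        }
        rows[[length(rows) + 1]] <- data.frame(
          case = case_id, slice = i, phase = phase,
          pixel_spacing_mm = config$pixel_spacing_mm,
          slice_thickness_mm = config$slice_thickness_mm,
          image_path = unname(paths["image"]),
          endo_path = unname(paths["endo"]),
          epi_path = unname(paths["epi"]),
          case_seed = seed + ci,
          true_center_row = case$center[1], true_center_col = case$center[2],
          true_endo_radius_px = sl[[i]]$endo_radius_px,
          true_epi_radius_px = sl[[i]]$epi_radius_px)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(manifest)
}

write_lv_nifti <- function(arr, path, config) {
  RNifti::writeNifti(RNifti::asNifti(
    arr, pixdim = c(config$pixel_spacing_mm, config$pixel_spacing_mm,
                    config$slice_thickness_mm)), path)
  invisible(path)
}

#' Read a slice stack written by [generate_dataset()]
#'
#' @param path Path to a NIfTI volume.
#' @return List of matrices, one per slice.
#' @export
read_slice_stack <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 2) return(list(arr))
  lapply(seq_len(dim(arr)[3]), function(i) arr[, , i])
}
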