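#' Configuration for the end-to-end phantom workflow
#'
#' Assembles the per-stage settings of [run_pipeline()] into one serializable
#' object. Stage seeds are derived deterministically from the single global
#' `seed`, so a run is reproducible from its stored configuration alone.
#'
#' The defaults describe a small, CPU-friendly study: 96 px phantom frames,
#' 64 px ROIs and a 3-level, 8-channel improved network. Paper-scale inputs
#' (256 px frames, 128 px ROIs, 4 levels, 32 base channels) are reached by
#' overriding `phantom`, `roi_size` and `arch`.
#'
#' @param out_dir Output directory of the run.
#' @param seed Global seed; every stage derives its own seed from it.
#' @param n_cases_train,n_cases_val,n_cases_test Cases per split (split is by
#'   case, never by slice).
#' @param phantom A [phantom_config()] for the simulated cohort.
#' @param roi_size ROI side length in px.
#' @param roi_k Cluster count of the ROI localisation.
#' @param arch Named list of [arch_config()] overrides (`input_size` is set to
#'   `roi_size` automatically).
#' @param train Named list of [train_config()] overrides.
#' @param targets Structures to train/evaluate: subset of `c("endo", "epi")`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            n_cases_train = 3, n_cases_val = 1, n_cases_test = 3,
                            phantom = phantom_config(
                              image_size = 96, endo_radius_px = c(8, 12),
                              wall_thickness_px = c(4, 6), center_jitter_px = 6,
                              n_slices = 6),
                            roi_size = 64, roi_k = 3,
                            arch = list(n_levels = 3, base_channels = 8),
                            train = list(n_epochs = 12, lr_end_epoch = 12,
                                         batch_size = 16),
                            targets = c("endo", "epi")) {
  stopifnot(inherits(phantom, "phantom_config"))
  targets <- match.arg(targets, several.ok = TRUE)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_cases_train = n_cases_train, n_cases_val = n_cases_val,
                 n_cases_test = n_cases_test, phantom = phantom,
                 roi_size = roi_size, roi_k = roi_k,
                 arch = arch, train = train, targets = targets),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> out %s, seed %d, cases %d/%d/%d, ROI %d px, targets %s\n",
              x$out_dir, x$seed, x$n_cases_train, x$n_cases_val, x$n_cases_test,
              x$roi_size, paste(x$targets, collapse = "+")))
  invisible(x)
}

pipeline_log <- function(verbose, out_dir, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
  if (verbose) message(msg)
  cat(msg, "\n", file = file.path(out_dir, "run.log"), append = TRUE)
}

#' Run the full phantom-to-report workflow
#'
#' Executes simulate, crop, augment, train, predict, evaluate and
#' clinical-index stages in order, writing all artifacts under
#' `config$out_dir`. Stages whose outputs already exist are skipped unless
#' `force = TRUE`, and the configuration is serialized to `config.yaml` so
#' every run directory documents exactly what produced it. Two runs with the
#' same configuration and seed produce identical reports.
#'
#' @param config A [pipeline_config()].
#' @param force Re-run stages whose outputs already exist?
#' @param verbose Log stage progress to stderr?
#' @return Invisibly, a list with `report` (contour metrics per case) and
#'   `clinical` (per-case LVM/EF and agreement statistics, when the test split
#'   has >= 3 cases).
#' @export
run_pipeline <- function(config, force = FALSE, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  od <- config$out_dir
  dir.create(od, recursive = TRUE, showWarnings = FALSE)
  writeLines(yaml::as.yaml(unclass_deep(config)), file.path(od, "config.yaml"))
  n_all <- config$n_cases_train + config$n_cases_val + config$n_cases_test
  splits <- rep(c("train", "val", "test"),
                c(config$n_cases_train, config$n_cases_val, config$n_cases_test))

  ## simulate ----------------------------------------------------------------
  data_dir <- file.path(od, "data")
  if (force || !file.exists(file.path(data_dir, "manifest.csv"))) {
    pipeline_log(verbose, od, "simulate: %d cases", n_all)
    generate_dataset(config$phantom, n_all, seed = config$seed,
                     out_dir = data_dir, overwrite = TRUE)
  } else pipeline_log(verbose, od, "simulate: cached")
  manifest <- utils::read.csv(file.path(data_dir, "manifest.csv"))
  case_ids <- unique(manifest$case)
  split_of <- stats::setNames(splits, case_ids)

  ## load cases into memory (images + masks per case) ------------------------
  cases <- lapply(case_ids, function(cid) {
    rows <- manifest[manifest$case == cid, ]
    out <- list()
    for (phase in c("ED", "ES")) {
      r1 <- rows[rows$phase == phase, ][1, ]
      out[[phase]] <- list(
        image = read_slice_stack(file.path(data_dir, r1$image_path)),
        endo = read_slice_stack(file.path(data_dir, r1$endo_path)),
        epi = read_slice_stack(file.path(data_dir, r1$epi_path)))
    }
    out
  })
  names(cases) <- case_ids
  spacing <- config$phantom$pixel_spacing_mm
  thickness <- config$phantom$slice_thickness_mm

  ## crop --------------------------------------------------------------------
  pipeline_log(verbose, od, "crop: ROI %d px (k = %d)", config$roi_size, config$roi_k)
  rois <- lapply(cases, function(cs) {
    stack <- c(cs$ED$image, cs$ES$image)
    center <- locate_lv_center(stack, k = config$roi_k)
    lapply(c(ED = "ED", ES = "ES"), function(phase) {
      n <- length(cs[[phase]]$image)
      lapply(seq_len(n), function(i) {
        rr <- crop_roi(cs[[phase]]$image[[i]], center, config$roi_size)
        list(roi = rr$roi, offset = rr$offset,
             endo = crop_roi(cs[[phase]]$endo[[i]], center, config$roi_size)$roi,
             epi = crop_roi(cs[[phase]]$epi[[i]], center, config$roi_size)$roi)
      })
    })
  })

  ## train (with augmentation of the training split) -------------------------
  train_pairs <- function(target) {
    out <- list()
    for (cid in case_ids[splits == "train"])
      for (phase in c("ED", "ES"))
        for (sl in rois[[cid]][[phase]]) {
          aug <- augment_tenfold(sl$roi, sl[[target]])
          for (a in aug) out[[length(out) + 1]] <- list(image = a$image, mask = a$mask)
        }
    out
  }
  val_pairs <- function(target) {
    out <- list()
    for (cid in case_ids[splits == "val"])
      for (phase in c("ED", "ES"))
        for (sl in rois[[cid]][[phase]])
          out[[length(out) + 1]] <- list(image = sl$roi, mask = sl[[target]])
    out
  }
  models <- list()
  for (target in config$targets) {
    ckpt <- file.path(od, sprintf("model_%s.ckpt", target))
    if (!force && file.exists(ckpt)) {
      pipeline_log(verbose, od, "train %s: cached checkpoint", target)
      models[[target]] <- load_checkpoint(ckpt)
      next
    }
    ac <- do.call(arch_config, c(list(input_size = config$roi_size,
                                      seed = config$seed + 101L),
                                 config$arch))
    tc <- do.call(train_config, c(list(seed = config$seed + 202L, target = target),
                                  config$train))
    pipeline_log(verbose, od, "train %s: %d pairs, %d epochs", target,
                 length(train_pairs(target)), tc$n_epochs)
    fit <- fit_resunet(build_resunet(ac), train_pairs(target), val_pairs(target),
                       tc, verbose = verbose)
    utils::write.csv(fit$history, file.path(od, sprintf("history_%s.csv", target)),
                     row.names = FALSE)
    save_checkpoint(fit, ckpt)
    models[[target]] <- fit$model
  }

  ## predict + evaluate on the test split ------------------------------------
  pipeline_log(verbose, od, "predict + evaluate: %d test cases",
               sum(splits == "test"))
  pred_dir <- file.path(od, "pred")
  dir.create(pred_dir, showWarnings = FALSE)
  report_rows <- list()
  case_metrics <- list()
  pred_masks <- list()
  for (cid in case_ids[splits == "test"]) {
    for (target in config$targets) {
      preds <- list(); gts <- list()
      for (phase in c("ED", "ES")) {
        sls <- rois[[cid]][[phase]]
        pr <- predict(models[[target]], lapply(sls, `[[`, "roi"))
        if (length(sls) == 1) pr <- list(pr)
        for (i in seq_along(sls)) {
          full <- paste_roi(matrix(0, config$phantom$image_size,
                                   config$phantom$image_size),
                            pr[[i]]$mask, sls[[i]]$offset)
          preds[[length(preds) + 1]] <- full
          gts[[length(gts) + 1]] <- cases[[cid]][[phase]][[target]][[i]]
          pred_masks[[cid]][[target]][[phase]][[i]] <- full
          if (sum(full) > 0)
            write_contour(mask_to_contour(largest_component(full), spacing),
                          file.path(pred_dir, sprintf("%s_%s_s%02d_%s.txt",
                                                      cid, phase, i, target)))
        }
      }
      cm <- evaluate_case(preds, gts, spacing)
      case_metrics[[target]] <- c(case_metrics[[target]], list(cm))
      report_rows[[length(report_rows) + 1]] <- data.frame(
        case = cid, structure = target, pgc_percent = cm$pgc_percent,
        dm = cm$mean_dm_of_good, apd_mm = cm$mean_apd_of_good,
        n_slices = cm$n_slices, n_good = cm$n_good)
    }
  }
  report <- do.call(rbind, report_rows)
  for (target in config$targets) {
    sm <- summarize_cases(case_metrics[[target]])
    report <- rbind(report, data.frame(
      case = c("MEAN", "STD"), structure = target,
      pgc_percent = sm$pgc_percent, dm = sm$dm, apd_mm = sm$apd_mm,
      n_slices = NA, n_good = NA))
  }
  utils::write.csv(format_report(report), file.path(od, "report.csv"),
                   row.names = FALSE)

  ## clinical indices (needs both structures) --------------------------------
  clinical <- NULL
  if (all(c("endo", "epi") %in% config$targets)) {
    rows <- list()
    for (cid in case_ids[splits == "test"]) {
      auto <- clinical_indices(pred_masks[[cid]]$endo$ED, pred_masks[[cid]]$endo$ES,
                               pred_masks[[cid]]$epi$ED, spacing, thickness)
      man <- clinical_indices(cases[[cid]]$ED$endo, cases[[cid]]$ES$endo,
                              cases[[cid]]$ED$epi, spacing, thickness)
      rows[[length(rows) + 1]] <- data.frame(
        case = cid, lvm_auto_g = auto$lvm_g, lvm_manual_g = man$lvm_g,
        ef_auto_percent = auto$ef_percent, ef_manual_percent = man$ef_percent)
    }
    ctab <- do.call(rbind, rows)
    clinical <- list(table = ctab)
    if (nrow(ctab) >= 3) {
      clinical$lvm_agreement <- agreement(ctab$lvm_auto_g, ctab$lvm_manual_g)
      clinical$ef_agreement <- agreement(ctab$ef_auto_percent, ctab$ef_manual_percent)
    }
    utils::write.csv(format_report(ctab), file.path(od, "clinical.csv"),
                     row.names = FALSE)
  }
  pipeline_log(verbose, od, "done")
  invisible(list(report = report, clinical = clinical))
}

# round numeric columns so reports are stable, diff-able text
format_report <- function(df) {
  for (nm in names(df))
    if (is.numeric(df[[nm]])) df[[nm]] <- round(df[[nm]], 6)
  df
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}
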