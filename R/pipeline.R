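# End-to-end orchestration: configuration, full pipeline run, detection
# scoring against ground truth.

#' Default pipeline configuration
#'
#' The segmentation stage deliberately exposes fewer than five tuning
#' parameters (bone threshold, planarity scale, hysteresis low/high,
#' spatial radius); everything else is fixed plumbing with safe defaults.
#'
#' @return nested named list with components `preprocess`, `segmentation`,
#'   `classification`, `section2d`, `output`.
#' @export
default_pipeline_config <- function() {
  list(
    preprocess = list(
      ring.enabled = TRUE, ring.radial_smooth_um = 42,
      norm.enabled = TRUE, norm.window_um = 200, norm.mode = "subtract"),
    segmentation = list(
      bone_threshold = "auto",          # knob 1
      planarity_sigma_um = 2.1,         # knob 2
      hysteresis_low = 0.3,             # knob 3
      hysteresis_high = 0.5,            # knob 4
      spatial_radius_um = 2.8,          # knob 5 (spatial radius)
      planarity_bandwidth = 0.2,
      closing_radius_um = 14,
      connectivity = 26,
      drop_open = TRUE),
    classification = list(min_volume_um3 = 500, max_ratio = 1 / 3),
    section2d = list(slices_averaged = 5, spacing_slices = 128, n = 8,
                     z0 = 0, enabled = FALSE),
    output = list(tbthlo = TRUE, smi = TRUE))
}

#' Validate and complete a pipeline configuration
#'
#' Merges a partial configuration over [default_pipeline_config()] and
#' checks every key before any computation starts.
#'
#' @param config named list with any subset of the default keys.
#' @return the completed configuration list.
#' @export
validate_config <- function(config) {
  cfg <- utils::modifyList(default_pipeline_config(), config)
  seg <- cfg$segmentation
  if (seg$hysteresis_low > seg$hysteresis_high)
    stop("config error: hysteresis low exceeds high")
  if (!seg$connectivity %in% c(6, 18, 26))
    stop("config error: connectivity must be 6, 18 or 26")
  if (seg$planarity_sigma_um <= 0 || seg$spatial_radius_um <= 0)
    stop("config error: scales must be positive")
  cls <- cfg$classification
  if (cls$min_volume_um3 < 0 || cls$max_ratio <= 0)
    stop("config error: bad classification cut-offs")
  cfg
}

config_hash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  # small deterministic rolling hash; avoids an external digest dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full microcrack analysis pipeline
#'
#' Pre-processing, porosity segmentation, per-object quantification,
#' classification, specimen metrics and (optionally) 2D virtual-section
#' metrics; optionally writes the label volume, the per-object CSV, the
#' specimen report (JSON) and a run log to `out_dir`.
#'
#' @param vol a [grey_volume()] (or a [phantom_config()], in which case
#'   the phantom is generated and scored against its own truth).
#' @param config pipeline configuration (see [default_pipeline_config()];
#'   partial lists are merged over the defaults).
#' @param out_dir optional output directory.
#' @return list of class `pipeline_result` with `records`, `report`,
#'   `segmentation`, `sections` (or `NULL`), `config`, `log`, and for
#'   phantom inputs `truth` and `detection`.
#' @export
run_pipeline <- function(vol, config = list(), out_dir = NULL) {
  cfg <- validate_config(config)
  truth <- NULL
  if (inherits(vol, "phantom_config")) {
    ph <- generate_phantom(vol)
    truth <- ph$truth
    vol <- ph$volume
  }
  if (!inherits(vol, "grey_volume")) stop("input must be a grey_volume")
  log <- list(config_hash = config_hash(cfg))

  pre <- preprocess_volume(vol, cfg$preprocess)
  seg <- segment_porosities(pre, cfg$segmentation)
  log$stage_counts <- seg$stage_counts

  records <- quantify_porosities(seg$labels,
                                 cfg$classification$min_volume_um3,
                                 cfg$classification$max_ratio)
  if (isTRUE(cfg$output$tbthlo) && nrow(records) > 0) {
    env_th <- thickness_map(seg$envelope)
    records$tbthlo_um <- NA_real_
    records$shape <- NA_character_
    for (r in seq_len(nrow(records))) {
      if (records$class[r] != "microcrack") next
      ctr <- c(records$centroid_y_um[r], records$centroid_x_um[r],
               records$centroid_z_um[r])
      records$tbthlo_um[r] <- tryCatch(
        local_trabecular_thickness(env_th, seg$envelope, ctr,
                                   records$cr_w_um[r]),
        error = function(e) NA_real_)
      records$shape[r] <- tryCatch(
        trabecular_shape(seg$envelope, ctr, records$cr_w_um[r]),
        error = function(e) NA_character_)
    }
  }
  report <- specimen_metrics(records, seg$envelope, seg$porosity,
                             smi = if (isTRUE(cfg$output$smi)) NULL else FALSE)

  sections <- NULL
  if (isTRUE(cfg$section2d$enabled)) {
    sc <- cfg$section2d
    ss <- make_virtual_sections(pre, sc$slices_averaged, sc$spacing_slices,
                                sc$n, sc$z0)
    sections <- measure_sections(ss, list(
      bone_threshold = seg$bone_threshold,
      closing_radius_um = cfg$segmentation$closing_radius_um,
      hysteresis_low = cfg$segmentation$hysteresis_low,
      hysteresis_high = cfg$segmentation$hysteresis_high))
  }

  detection <- NULL
  if (!is.null(truth))
    detection <- score_detection(seg$labels, truth$labels,
                                 truth_records = truth$records,
                                 pred_records = records)

  res <- structure(list(records = records, report = report,
                        segmentation = seg, sections = sections,
                        config = cfg, log = log, truth = truth,
                        detection = detection),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(res$segmentation$labels, file.path(out_dir, "labels.tif"))
  utils::write.csv(format_record_table(res$records),
                   file.path(out_dir, "porosities.csv"), row.names = FALSE)
  rep <- res$report
  jsonlite::write_json(unclass(rep), file.path(out_dir, "specimen.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(res$sections)) {
    s <- res$sections
    utils::write.csv(
      data.frame(`BV/TV 2D` = s$bvtv_2d, `Cr.N 2D` = s$cr_n_2d,
                 `Cr.Dn 2D` = s$cr_dn_2d_mm2,
                 `Cr.Le 2D mean` = s$cr_le_2d_mean_um,
                 `Cr.Le 2D std` = s$cr_le_2d_sd_um, check.names = FALSE),
      file.path(out_dir, "sections2d.csv"), row.names = FALSE)
  }
  log <- c(list(stage_counts = as.list(res$log$stage_counts),
                config_hash = res$log$config_hash),
           list(config = res$config))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  print(x$report)
  if (!is.null(x$detection))
    cat(sprintf("  detection: recall %.2f, precision %s\n",
                x$detection$recall,
                ifelse(is.na(x$detection$precision), "NA",
                       sprintf("%.2f", x$detection$precision))))
  invisible(x)
}

#' Score a predicted label map against ground truth
#'
#' A truth object is matched when some predicted component covers at least
#' `min_overlap` of its voxels. Recall is computed over truth cracks;
#' precision over predicted components classified as cracks (when records
#' are supplied) or all predicted components otherwise. Precision with no
#' predictions is reported as `NA`.
#'
#' @param pred a [label_map()] of segmented porosities.
#' @param truth a [label_map()] of ground-truth objects.
#' @param truth_records optional phantom truth records (to restrict recall
#'   to cracks).
#' @param pred_records optional porosity records (to restrict precision to
#'   predicted cracks).
#' @param min_overlap voxel-overlap fraction required for a match.
#' @return list with `recall`, `precision`, `matches` (data.frame per truth
#'   object: label, kind, voxels, best predicted label, overlap fraction).
#' @export
score_detection <- function(pred, truth, truth_records = NULL,
                            pred_records = NULL, min_overlap = 0.5) {
  if (!identical(dim(pred$data), dim(truth$data)))
    stop("dimension error: prediction and truth differ in shape")
  nt <- truth$n_labels
  kinds <- if (!is.null(truth_records))
    vapply(truth_records, `[[`, "", "kind") else rep("crack", nt)

  rows <- vector("list", nt)
  matched_pred <- integer(0)
  for (l in seq_len(nt)) {
    sel <- truth$data == l
    nvox <- sum(sel)
    pl <- pred$data[sel]
    pl <- pl[pl > 0]
    if (length(pl)) {
      tb <- tabulate(pl)
      best <- which.max(tb)
      ov <- tb[best] / nvox
    } else { best <- NA_integer_; ov <- 0 }
    if (!is.na(best) && ov >= min_overlap)
      matched_pred <- c(matched_pred, best)
    rows[[l]] <- data.frame(truth_label = l, kind = kinds[l],
                            n_vox = nvox, pred_label = best,
                            overlap = ov)
  }
  matches <- if (nt) do.call(rbind, rows) else
    data.frame(truth_label = integer(0), kind = character(0),
               n_vox = integer(0), pred_label = integer(0),
               overlap = numeric(0))
  cr <- matches[matches$kind == "crack", , drop = FALSE]
  recall <- if (nrow(cr)) mean(cr$overlap >= min_overlap) else NA_real_

  pred_ids <- if (!is.null(pred_records))
    pred_records$label[pred_records$class == "microcrack"]
  else seq_len(pred$n_labels)
  precision <- if (length(pred_ids))
    mean(pred_ids %in% matches$pred_label[matches$overlap >= min_overlap])
  else NA_real_
  list(recall = recall, precision = precision, matches = matches)
}
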