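# Disk-based pipeline stages shared with the command-line driver. Each
# stage reads and writes a common experiment directory:
#   <dir>/            raw TIFF frames (fov/time/plane filename pattern)
#   <dir>/channels/   per-channel crop stacks + classification.csv
#   <dir>/subtracted/ background-subtracted stacks + alignment.csv
#   <dir>/segmented/  labeled mask stacks
#   <dir>/cells/      cell exports (CSV + JSON) + kymographs
#   <dir>/evaluation/ segmentation evaluation reports
# The effective parameter set is logged to <dir>/params_used.yaml by every
# stage for provenance.

.stage_log <- function(verbose, ...) if (verbose) message(sprintf(...))

.log_params <- function(dir, params) {
  write_params(params, file.path(dir, "params_used.yaml"))
}

#' Pipeline stage: simulate a synthetic experiment
#'
#' Generates and writes a fixture experiment with ground truth (see
#' [simulate_experiment()] and [write_fixture()]).
#'
#' @param dir experiment directory.
#' @param seed RNG seed.
#' @param n_channels,n_frames,n_empty experiment size.
#' @param noise_sd render noise level.
#' @param fluor also render a fluorescence plane.
#' @param params pipeline parameters (rendering geometry).
#' @param verbose print per-stage progress.
#' @return the experiment object, invisibly.
#' @export
stage_simulate <- function(dir, seed = 1L, n_channels = 6L, n_frames = 50L,
                           n_empty = 1L, noise_sd = 0.043, fluor = FALSE,
                           params = mm_params(), verbose = TRUE) {
  sp <- sim_params(seed = seed)
  ex <- simulate_experiment(sp, n_channels, n_frames, n_empty, params,
                            fluor = fluor, noise_sd = noise_sd)
  write_fixture(ex, dir)
  .log_params(dir, params)
  .stage_log(verbose, "simulate: %d channels x %d frames -> %s (%d cells)",
             n_channels, n_frames, dir, nrow(ex$gt$cells))
  invisible(ex)
}

#' Pipeline stage: compile channels
#'
#' Reads the raw frames, corrects drift, detects channels, writes
#' per-channel crop stacks (\code{<fov>_<channel>_<plane>.tif}) and the
#' channel classification CSV. Edit \code{channels/classification.csv}
#' (column \code{label}) to override the full/empty calls before
#' subtracting.
#'
#' @param dir experiment directory with raw frames.
#' @param params pipeline parameters.
#' @param pattern raw filename pattern.
#' @param verbose print per-stage progress.
#' @return the classification data.frame, invisibly.
#' @export
stage_compile <- function(dir, params = mm_params(),
                          pattern = default_frame_pattern(), verbose = TRUE) {
  raw <- load_raw_dir(dir, pattern)
  outdir <- file.path(dir, "channels")
  dir.create(outdir, showWarnings = FALSE)
  all_cls <- list()
  for (fv in names(raw)) {
    cmp <- compile_fov(raw[[fv]], params)
    for (pl in seq_along(cmp$stacks)) {
      plname <- names(raw[[fv]])[pl]
      for (ch in names(cmp$stacks[[pl]])) {
        write_tiff_stack(cmp$stacks[[pl]][[ch]],
                         file.path(outdir, sprintf("%s_%s_%s.tif", fv, ch, plname)))
      }
    }
    cls <- cmp$classification
    cls$fov <- as.integer(fv)
    all_cls[[fv]] <- cls
    utils::write.csv(cmp$boxes, file.path(outdir, sprintf("%s_boxes.csv", fv)),
                     row.names = FALSE)
    utils::write.csv(data.frame(frame = seq_len(nrow(cmp$shifts)),
                                dx = cmp$shifts[, 1], dy = cmp$shifts[, 2]),
                     file.path(outdir, sprintf("%s_shifts.csv", fv)),
                     row.names = FALSE)
    .stage_log(verbose, "compile: fov %s -> %d channels (%d empty)",
               fv, nrow(cls), sum(cls$label == "empty"))
  }
  cls <- do.call(rbind, all_cls)
  utils::write.csv(cls, file.path(outdir, "classification.csv"),
                   row.names = FALSE)
  .log_params(dir, params)
  invisible(cls)
}

#' Pipeline stage: background subtraction
#'
#' Builds the per-fov empty template from channels labeled \code{empty} in
#' \code{channels/classification.csv} and writes subtracted stacks
#' (\code{<fov>_<channel>_sub.tif}) plus the alignment-score CSV.
#'
#' @inheritParams stage_compile
#' @return invisibly, the alignment-score data.frame.
#' @export
stage_subtract <- function(dir, params = mm_params(), verbose = TRUE) {
  chdir <- file.path(dir, "channels")
  cls <- utils::read.csv(file.path(chdir, "classification.csv"))
  outdir <- file.path(dir, "subtracted")
  dir.create(outdir, showWarnings = FALSE)
  scores <- list()
  for (fv in unique(cls$fov)) {
    sub_cls <- cls[cls$fov == fv, ]
    empties <- sub_cls$channel[sub_cls$label == "empty"]
    if (!length(empties)) {
      stop("fov ", fv, ": no channel labeled 'empty' in classification.csv; ",
           "mark at least one template channel", call. = FALSE)
    }
    tmpl <- empty_template(lapply(empties, function(ch)
      read_tiff_stack(file.path(chdir, sprintf("%s_%s_phase.tif", fv, ch)))))
    for (ch in sub_cls$channel[sub_cls$label == "full"]) {
      full <- read_tiff_stack(file.path(chdir, sprintf("%s_%s_phase.tif", fv, ch)))
      sub <- subtract_stack(full, tmpl, params)
      write_tiff_stack(sub$pixels,
                       file.path(outdir, sprintf("%s_%s_sub.tif", fv, ch)))
      scores[[length(scores) + 1L]] <- data.frame(
        fov = fv, channel = ch, frame = seq_along(sub$scores),
        dx = sub$shifts[, 1], dy = sub$shifts[, 2], score = sub$scores)
    }
    .stage_log(verbose, "subtract: fov %s, %d full channels against %d empties",
               fv, sum(sub_cls$label == "full"), length(empties))
  }
  sc <- do.call(rbind, scores)
  utils::write.csv(sc, file.path(outdir, "alignment.csv"), row.names = FALSE)
  .log_params(dir, params)
  invisible(sc)
}

#' Pipeline stage: segmentation
#'
#' Segments every subtracted stack and writes 16-bit label stacks
#' (\code{<fov>_<channel>_seg.tif}).
#'
#' @inheritParams stage_compile
#' @return invisibly, a data.frame of per-frame region counts.
#' @export
stage_segment <- function(dir, params = mm_params(), verbose = TRUE) {
  subdir <- file.path(dir, "subtracted")
  outdir <- file.path(dir, "segmented")
  dir.create(outdir, showWarnings = FALSE)
  files <- list.files(subdir, pattern = "_sub\\.tif$", full.names = TRUE)
  counts <- list()
  for (f in files) {
    key <- sub("_sub\\.tif$", "", basename(f))
    seg <- segment_stack(read_tiff_stack(f), params)
    write_tiff_stack(seg, file.path(outdir, paste0(key, "_seg.tif")),
                     labels = TRUE)
    counts[[key]] <- data.frame(stack = key,
                                frame = seq_along(attr(seg, "counts")),
                                regions = attr(seg, "counts"))
    .stage_log(verbose, "segment: %s -> %d frames, %.1f regions/frame", key,
               dim(seg)[3], mean(attr(seg, "counts")))
  }
  ct <- do.call(rbind, counts)
  utils::write.csv(ct, file.path(outdir, "region_counts.csv"), row.names = FALSE)
  .log_params(dir, params)
  invisible(ct)
}

#' Pipeline stage: tracking
#'
#' Tracks lineages on every segmented stack, exports cells (CSV + JSON) and
#' renders one kymograph per channel.
#'
#' @inheritParams stage_compile
#' @param calibration calibration list for the exported statistics.
#' @return invisibly, the combined \code{mm_forest}.
#' @export
stage_track <- function(dir, params = mm_params(),
                        calibration = params$calibration, verbose = TRUE) {
  segdir <- file.path(dir, "segmented")
  outdir <- file.path(dir, "cells")
  dir.create(outdir, showWarnings = FALSE)
  files <- list.files(segdir, pattern = "_seg\\.tif$", full.names = TRUE)
  forests <- list()
  for (f in files) {
    key <- sub("_seg\\.tif$", "", basename(f))
    parts <- strsplit(key, "_")[[1]]
    seg <- read_tiff_stack(f, labels = TRUE)
    forest <- build_lineages(seg, params, fov = as.integer(parts[1]),
                             channel = as.integer(parts[2]))
    export_cells(forest, file.path(outdir, key), calibration)
    grDevices::png(file.path(outdir, paste0(key, "_kymograph.png")),
                   width = 30 * dim(seg)[3], height = 2 * dim(seg)[1])
    plot_kymograph(seg > 0, forest)
    grDevices::dev.off()
    forests[[key]] <- forest
    .stage_log(verbose, "track: %s -> %d cells", key, length(forest))
  }
  .log_params(dir, params)
  invisible(if (length(forests)) combine_forests(forests) else NULL)
}

#' Pipeline stage: physiology statistics
#'
#' Reads the JSON cell exports, filters complete cycles, and writes the
#' distribution summary and the binned correlation tables of the adder
#' plots (added length, division length, generation time and elongation
#' rate against birth length).
#'
#' @inheritParams stage_track
#' @return invisibly, the summary data.frame.
#' @export
stage_stats <- function(dir, params = mm_params(),
                        calibration = params$calibration, verbose = TRUE) {
  cdir <- file.path(dir, "cells")
  files <- list.files(cdir, pattern = "\\.json$", full.names = TRUE)
  if (!length(files)) stop("no cell exports found; run the track stage first",
                           call. = FALSE)
  forest <- combine_forests(lapply(files, import_cells))
  comp <- filter_complete(forest)
  if (length(comp) < 2) {
    warning("fewer than 2 complete cycles; no statistics written")
    return(invisible(NULL))
  }
  summ <- physiology_summary(comp, calibration, filtered = TRUE)
  utils::write.csv(summ, file.path(cdir, "summary.csv"), row.names = FALSE)
  tab <- cell_cycle_table(comp, calibration)
  for (yv in c("delta", "sd", "tau", "lambda")) {
    bm <- tryCatch(binned_means(tab$sb, tab[[yv]]), error = function(e) NULL)
    if (!is.null(bm) && nrow(bm) >= 2) {
      utils::write.csv(bm, file.path(cdir, sprintf("binned_%s_vs_sb.csv", yv)),
                       row.names = FALSE)
    }
  }
  .stage_log(verbose, "stats: %d complete cycles of %d cells",
             nrow(tab), length(forest))
  invisible(summ)
}

#' Pipeline stage: segmentation evaluation
#'
#' Compares the segmented stacks against ground-truth masks (the simulated
#' fixture's \code{mask_xy*.tif}, cropped with the compile stage's boxes
#' and shifts) and writes the evaluation report (CSV + JSON).
#'
#' @inheritParams stage_compile
#' @param iou_min IoU matching threshold.
#' @return invisibly, the report data.frame.
#' @export
stage_evaluate <- function(dir, params = mm_params(), iou_min = 0.6,
                           verbose = TRUE) {
  chdir <- file.path(dir, "channels")
  segdir <- file.path(dir, "segmented")
  outdir <- file.path(dir, "evaluation")
  dir.create(outdir, showWarnings = FALSE)
  cls <- utils::read.csv(file.path(chdir, "classification.csv"))
  reports <- list()
  for (fv in unique(cls$fov)) {
    gt_path <- file.path(dir, sprintf("mask_xy%02d.tif", as.integer(fv)))
    if (!file.exists(gt_path)) {
      stop("no ground-truth masks (", gt_path, ") for fov ", fv, call. = FALSE)
    }
    gt <- read_tiff_stack(gt_path, labels = TRUE)
    boxes <- utils::read.csv(file.path(chdir, sprintf("%s_boxes.csv", fv)))
    shifts <- as.matrix(utils::read.csv(
      file.path(chdir, sprintf("%s_shifts.csv", fv)))[, c("dx", "dy")])
    gt_crops <- crop_channel_stacks(gt, boxes, shifts)
    for (ch in cls$channel[cls$fov == fv & cls$label == "full"]) {
      f <- file.path(segdir, sprintf("%s_%s_seg.tif", fv, ch))
      if (!file.exists(f)) next
      seg <- read_tiff_stack(f, labels = TRUE)
      gtc <- gt_crops[[as.character(ch)]]
      storage.mode(gtc) <- "integer"
      ev <- evaluate_segmentation(seg, gtc, iou_min)
      reports[[length(reports) + 1L]] <- data.frame(
        fov = fv, channel = ch, TP = ev$TP, FP = ev$FP, FN = ev$FN,
        JI = ev$JI, iou_min = iou_min)
      .stage_log(verbose, "evaluate: fov %s channel %s JI %.3f", fv, ch, ev$JI)
    }
  }
  rep <- do.call(rbind, reports)
  utils::write.csv(rep, file.path(outdir, "evaluation.csv"), row.names = FALSE)
  jsonlite::write_json(rep, file.path(outdir, "evaluation.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(rep)
}
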