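# Readers, writers and naming conventions: TIFF series named by a
# fov/time/plane filename pattern, 16-bit label masks, CSV/JSON cell
# exports, and the on-disk fixture layout used by the command-line stages.

#' Default raw-image filename pattern
#'
#' A Perl regex with named groups \code{time}, \code{fov}, \code{plane}
#' matching names like \code{exp_t0003_xy12_c1.tif}.
#' @return the pattern string.
#' @export
default_frame_pattern <- function() {
  "^.*_t(?<time>\\d+)_xy(?<fov>\\d+)_c(?<plane>\\d+)\\.tiff?$"
}

#' Parse a raw-image filename into its frame key
#'
#' Extracts (fov, time, plane) from a filename using a regex with named
#' groups \code{fov}, \code{time}, \code{plane}.
#'
#' @param filename file name (base name is used).
#' @param pattern Perl-compatible regex with the three named groups.
#' @return a list: fov, time, plane (integers).
#' @examples
#' parse_frame_key("exp_t0003_xy12_c1.tif")  # fov 12, time 3, plane 1
#' @export
parse_frame_key <- function(filename, pattern = default_frame_pattern()) {
  fn <- basename(filename)
  m <- regexpr(pattern, fn, perl = TRUE)
  if (m == -1) {
    stop("filename '", fn, "' does not match pattern '", pattern, "'",
         call. = FALSE)
  }
  st <- attr(m, "capture.start")[1, ]
  len <- attr(m, "capture.length")[1, ]
  grab <- function(g) as.integer(substr(fn, st[[g]], st[[g]] + len[[g]] - 1L))
  list(fov = grab("fov"), time = grab("time"), plane = grab("plane"))
}

#' Format a frame key into the default filename
#'
#' Inverse of [parse_frame_key()] for the default pattern.
#'
#' @param fov,time,plane integer ids.
#' @param prefix filename prefix.
#' @return the file name.
#' @export
format_frame_key <- function(fov, time, plane, prefix = "img") {
  sprintf("%s_t%04d_xy%02d_c%d.tif", prefix, time, fov, plane)
}

#' Write an image stack as a multi-page TIFF
#'
#' Intensities are expected in [0, 1] and are stored as 16-bit; label masks
#' (integer matrices) are stored as 16-bit labels and recovered exactly on
#' read (labels up to 65535).
#'
#' @param stack height x width x n_frames array (numeric in [0,1], or
#'   integer labels with \code{labels = TRUE}).
#' @param path output file.
#' @param labels write integer labels rather than intensities.
#' @return \code{path}, invisibly.
#' @export
write_tiff_stack <- function(stack, path, labels = FALSE) {
  if (length(dim(stack)) == 2) stack <- array(stack, c(dim(stack), 1))
  pages <- lapply(seq_len(dim(stack)[3]), function(t) {
    m <- stack[, , t]
    if (labels) m <- m / 65535
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as an array
#'
#' @param path TIFF file written by [write_tiff_stack()] (or any grayscale
#'   multi-page TIFF).
#' @param labels recover integer labels (inverse of the label encoding).
#' @return a height x width x n_frames array.
#' @export
read_tiff_stack <- function(path, labels = FALSE) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
  for (t in seq_along(pages)) {
    p <- pages[[t]]
    if (length(dim(p)) == 3) p <- p[, , 1]
    arr[, , t] <- p
  }
  if (labels) {
    arr <- round(arr * 65535)
    storage.mode(arr) <- "integer"
  }
  arr
}

#' Write a synthetic experiment to disk
#'
#' Writes the rendered planes as single-frame TIFFs named by the default
#' fov/time/plane pattern (phase = plane 1, fluorescence = plane 2), the
#' ground-truth masks as 16-bit label TIFFs, the lineage table and
#' per-frame positions as CSV, and the drift trajectory as CSV.
#'
#' @param ex experiment from [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @param fov fov id used in the file names.
#' @param prefix image filename prefix.
#' @return \code{dir}, invisibly.
#' @export
write_fixture <- function(ex, dir, fov = 1L, prefix = "img") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Tn <- dim(ex$phase)[3]
  for (t in seq_len(Tn)) {
    tiff::writeTIFF(ex$phase[, , t],
                    file.path(dir, format_frame_key(fov, t, 1L, prefix)),
                    bits.per.sample = 16L)
    if (!is.null(ex$fluor)) {
      tiff::writeTIFF(ex$fluor[, , t],
                      file.path(dir, format_frame_key(fov, t, 2L, prefix)),
                      bits.per.sample = 16L)
    }
  }
  write_tiff_stack(ex$masks, file.path(dir, sprintf("mask_xy%02d.tif", fov)),
                   labels = TRUE)
  utils::write.csv(ex$gt$cells, file.path(dir, "gt_cells.csv"), row.names = FALSE)
  utils::write.csv(ex$gt$frames, file.path(dir, "gt_frames.csv"), row.names = FALSE)
  utils::write.csv(data.frame(frame = seq_len(Tn), dx = ex$drift[, 1],
                              dy = ex$drift[, 2]),
                   file.path(dir, "gt_drift.csv"), row.names = FALSE)
  invisible(dir)
}

#' Load a directory of raw frames into per-plane stacks
#'
#' Collates single-frame TIFFs whose names match the frame-key pattern into
#' height x width x n_frames arrays, one per (fov, plane).
#'
#' @param dir directory of TIFF files.
#' @param pattern frame-key regex (see [parse_frame_key()]).
#' @return nested list: \code{result[[fov]][[plane]]} = array; names are
#'   \code{"1"}, \code{"2"}, ... Plane 1 is conventionally phase contrast.
#' @export
load_raw_dir <- function(dir, pattern = default_frame_pattern()) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[grepl(pattern, basename(files), perl = TRUE)]
  if (!length(files)) stop("no files in '", dir, "' match the pattern", call. = FALSE)
  keys <- lapply(files, parse_frame_key, pattern = pattern)
  df <- data.frame(file = files,
                   fov = vapply(keys, `[[`, integer(1), "fov"),
                   time = vapply(keys, `[[`, integer(1), "time"),
                   plane = vapply(keys, `[[`, integer(1), "plane"))
  out <- list()
  for (fv in sort(unique(df$fov))) {
    planes <- list()
    for (pl in sort(unique(df$plane[df$fov == fv]))) {
      sel <- df[df$fov == fv & df$plane == pl, ]
      sel <- sel[order(sel$time), ]
      pages <- lapply(sel$file, function(f) {
        p <- tiff::readTIFF(f)
        if (length(dim(p)) == 3) p[, , 1] else p
      })
      arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
      for (t in seq_along(pages)) arr[, , t] <- pages[[t]]
      planes[[as.character(pl)]] <- arr
    }
    names(planes)[1] <- "phase"
    out[[as.character(fv)]] <- planes
  }
  out
}

#' Export tracked cells to CSV and JSON
#'
#' Writes three files under \code{base}: \code{<base>_frames.csv} (one row
#' per cell observation), \code{<base>_summary.csv} (one row per cell with
#' the cycle statistics; columns sb_um, sd_um, delta_um, tau_min,
#' lambda_per_min, septum_ratio when calibrated), \code{<base>_edges.csv}
#' (parent-daughter links), and \code{<base>.json} (full nested records,
#' schema version 1). [import_cells()] reverses the JSON export.
#'
#' @param forest an \code{mm_forest}.
#' @param base output path prefix (directories are created).
#' @param calibration calibration list for the summary units.
#' @return invisibly, the vector of files written.
#' @export
export_cells <- function(forest, base, calibration = list(pixel_size = 1,
                                                          frame_interval = 1)) {
  dir.create(dirname(base), showWarnings = FALSE, recursive = TRUE)
  frames <- do.call(rbind, lapply(forest, function(cell) {
    if (!length(cell$frames)) return(NULL)
    data.frame(id = cell$id, frame = cell$frames,
               centroid_y = cell$centroid_y, centroid_x = cell$centroid_x,
               length_px = cell$length, width_px = cell$width,
               area_px = cell$area, volume_px = cell$volume,
               interpolated = cell$interpolated)
  }))
  if (is.null(frames)) {
    frames <- data.frame(id = character(), frame = integer(),
                         centroid_y = numeric(), centroid_x = numeric(),
                         length_px = numeric(), width_px = numeric(),
                         area_px = numeric(), volume_px = numeric(),
                         interpolated = logical())
  }
  rownames(frames) <- NULL
  f1 <- paste0(base, "_frames.csv")
  utils::write.csv(frames, f1, row.names = FALSE)

  summ <- if (length(forest)) cell_cycle_table(forest, calibration) else
    data.frame(id = character())
  if (nrow(summ)) {
    names(summ)[names(summ) == "sb"] <- "sb_um"
    names(summ)[names(summ) == "sd"] <- "sd_um"
    names(summ)[names(summ) == "delta"] <- "delta_um"
    names(summ)[names(summ) == "tau"] <- "tau_min"
    names(summ)[names(summ) == "lambda"] <- "lambda_per_min"
  }
  f2 <- paste0(base, "_summary.csv")
  utils::write.csv(summ, f2, row.names = FALSE)

  edges <- do.call(rbind, lapply(forest, function(cell) {
    if (!length(cell$daughters)) return(NULL)
    data.frame(parent = cell$id, daughter = cell$daughters)
  }))
  if (is.null(edges)) edges <- data.frame(parent = character(),
                                          daughter = character())
  rownames(edges) <- NULL
  f3 <- paste0(base, "_edges.csv")
  utils::write.csv(edges, f3, row.names = FALSE)

  f4 <- paste0(base, ".json")
  payload <- list(schema = 1L,
                  fov = attr(forest, "fov"), channel = attr(forest, "channel"),
                  n_frames = attr(forest, "n_frames"),
                  cells = unname(lapply(forest, unclass)))
  jsonlite::write_json(payload, f4, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(c(f1, f2, f3, f4))
}

#' Re-import a JSON cell export
#'
#' @param path JSON file written by [export_cells()].
#' @return an \code{mm_forest} equal (up to attribute order) to the
#'   exported one.
#' @export
import_cells <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  cells <- lapply(payload$cells, function(cell) {
    cell$parent <- if (is.null(cell$parent)) NA_character_ else cell$parent
    cell$division_frame <- if (is.null(cell$division_frame)) NA_integer_ else
      as.integer(cell$division_frame)
    cell$sd_px <- if (is.null(cell$sd_px)) NA_real_ else cell$sd_px
    cell$septum_ratio <- if (is.null(cell$septum_ratio)) NA_real_ else
      cell$septum_ratio
    cell$daughters <- as.character(cell$daughters)
    cell$birth_frame <- as.integer(cell$birth_frame)
    cell$frames <- as.integer(cell$frames)
    cell
  })
  names(cells) <- vapply(cells, `[[`, character(1), "id")
  structure(cells, class = "mm_forest",
            fov = payload$fov, channel = payload$channel,
            n_frames = payload$n_frames)
}
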