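# Default parameter set. Two-element values are (min, max) ranges.
.mm_defaults <- function() {
  list(
    compile = list(
      channel_width = 10,        # px, expected growth-channel width
      channel_separation = 45,   # px, center-to-center spacing
      y_pad = 10,                # px, padding beyond detected channel extent
      empty_threshold = 0.97     # y-profile time-correlation cutoff
    ),
    subtract = list(
      align_pad = 10             # px, max alignment search shift
    ),
    segment = list(
      first_opening = 2,         # px, radius of first morphological opening
      distance_threshold = 2,    # px, cut on the Euclidean distance transform
      second_opening = 1,        # px, radius of second opening
      otsu_scale = 1,            # dimensionless multiplier on Otsu threshold
      min_object_size = 25,      # px^2, minimum region area
      walker_beta = 500          # random-walker edge-weight sharpness
    ),
    track = list(
      growth_length_ratio = c(0.8, 1.3),  # (min, max) frame-to-frame length ratio
      growth_area_ratio = c(0.8, 1.3),    # (min, max) frame-to-frame area ratio
      lost_cell_time = 3,        # frames a vanished cell is retried
      new_cell_y_cutoff = 150    # px from the closed end; new cells beyond are discarded
    ),
    calibration = list(
      pixel_size = 1,            # um/px; 1 = report in pixels
      frame_interval = 1         # min/frame; 1 = report in frames
    )
  )
}

.mm_range_keys <- c("track.growth_length_ratio", "track.growth_area_ratio")

.flatten_params <- function(p) {
  out <- list()
  for (sec in names(p)) for (key in names(p[[sec]])) {
    out[[paste(sec, key, sep = ".")]] <- p[[sec]][[key]]
  }
  out
}

#' Pipeline parameters
#'
#' Construct the full parameter set shared by all pipeline stages. Values not
#' supplied take the package defaults (the standard parameterization for a
#' 10 px wide growth channel imaged in phase contrast). Parameters are
#' addressed by dotted keys, e.g. \code{segment.otsu_scale}.
#'
#' @param ... overrides as dotted keys, e.g.
#'   \code{mm_params(segment.otsu_scale = 1.2)}. Range-valued parameters
#'   (\code{track.growth_length_ratio}, \code{track.growth_area_ratio}) take a
#'   numeric vector \code{c(min, max)}.
#' @return an object of class \code{mm_params}: a nested list with sections
#'   \code{compile}, \code{subtract}, \code{segment}, \code{track},
#'   \code{calibration}.
#' @examples
#' p <- mm_params(segment.otsu_scale = 1.2)
#' p$segment$otsu_scale
#' @export
mm_params <- function(...) {
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1]])) {
    over <- over[[1]]
  }
  p <- .mm_defaults()
  flat <- .flatten_params(p)
  for (key in names(over)) {
    if (!key %in% names(flat)) {
      stop("unknown parameter key: ", key, call. = FALSE)
    }
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    val <- over[[key]]
    if (is.list(val)) val <- unlist(val)
    p[[parts[1]]][[parts[2]]] <- val
  }
  validate_params(p)
  class(p) <- "mm_params"
  p
}

#' Validate a parameter set
#'
#' Checks the structural invariants of the parameter set: all lengths, areas
#' and counts strictly positive; ratio ranges satisfy min < 1 < max;
#' correlation thresholds within (0, 1].
#'
#' @param p a parameter list as produced by [mm_params()] or [load_params()].
#' @return \code{p}, invisibly; errors name the offending key.
#' @export
validate_params <- function(p) {
  flat <- .flatten_params(p)
  for (key in names(flat)) {
    v <- flat[[key]]
    if (!is.numeric(v) || anyNA(v)) {
      stop("parameter ", key, " must be numeric and non-missing", call. = FALSE)
    }
    if (key %in% .mm_range_keys) {
      if (length(v) != 2L) {
        stop("parameter ", key, " must be a (min, max) pair", call. = FALSE)
      }
      if (!(v[1] < 1 && 1 < v[2])) {
        stop("parameter ", key, ": range must satisfy min < 1 < max, got (",
             v[1], ", ", v[2], ")", call. = FALSE)
      }
    } else {
      if (length(v) != 1L) {
        stop("parameter ", key, " must be a single value", call. = FALSE)
      }
      if (key == "compile.empty_threshold") {
        if (v <= 0 || v > 1) {
          stop("parameter ", key, " must lie in (0, 1]", call. = FALSE)
        }
      } else if (v <= 0) {
        stop("parameter ", key, " must be strictly positive, got ", v,
             call. = FALSE)
      }
    }
  }
  invisible(p)
}

#' Load pipeline parameters from a configuration file
#'
#' Reads a flat key/value configuration document (YAML syntax, keys with
#' dotted section prefixes such as \code{segment.otsu_scale}). Missing keys
#' are filled with the package defaults; unknown keys are rejected; the
#' resulting set is validated.
#'
#' @param path path to the configuration file, or \code{NULL} for the full
#'   default set.
#' @param overrides optional named list of dotted-key overrides applied after
#'   the file (command-line flags take precedence over the file).
#' @return an \code{mm_params} object.
#' @seealso [write_params()] for the inverse.
#' @export
load_params <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    doc <- tryCatch(yaml::read_yaml(path),
                    error = function(e) stop("malformed configuration file: ",
                                             conditionMessage(e), call. = FALSE))
    if (is.null(doc)) doc <- list()
    if (!is.list(doc) || (length(doc) && is.null(names(doc)))) {
      stop("malformed configuration file: expected key/value pairs", call. = FALSE)
    }
    vals <- doc
  }
  for (key in names(overrides)) vals[[key]] <- overrides[[key]]
  mm_params(vals)
}

#' Write pipeline parameters to a configuration file
#'
#' Serializes the parameter set as a flat dotted-key YAML document so the
#' effective parameterization of a run can be logged next to its outputs and
#' reloaded with [load_params()].
#'
#' @param p an \code{mm_params} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_params <- function(p, path) {
  flat <- .flatten_params(p)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @export
print.mm_params <- function(x, ...) {
  cat("mother machine pipeline parameters\n")
  flat <- .flatten_params(x)
  for (key in names(flat)) {
    v <- flat[[key]]
    cat(sprintf("  %-28s %s\n", key,
                if (length(v) > 1) paste0("(", paste(v, collapse = ", "), ")") else v))
  }
  invisible(x)
}

#' Effective pixel size of the imaging system
#'
#' The physical size of one image pixel in the sample plane, given the camera
#' pixel pitch and the total magnification: \code{camera_pixel /
#' magnification}. For a 6.5 um camera pixel under 100x magnification the
#' pixel size is 0.065 um, which is non-negligible relative to submicron
#' bacterial cell widths.
#'
#' @param camera_pixel physical camera pixel pitch, um.
#' @param magnification total optical magnification (dimensionless).
#' @return pixel size in um/px.
#' @examples
#' effective_pixel_size(6.5, 100) # 0.065
#' @export
effective_pixel_size <- function(camera_pixel, magnification) {
  if (!is.numeric(camera_pixel) || !is.numeric(magnification) ||
      camera_pixel <= 0 || magnification <= 0) {
    stop("camera_pixel and magnification must be positive numbers", call. = FALSE)
  }
  camera_pixel / magnification
}
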