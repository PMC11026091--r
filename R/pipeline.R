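# End-to-end in-memory pipeline driver and helpers shared by the
# command-line stages.

#' Combine per-channel lineage forests
#'
#' @param forests list of \code{mm_forest} objects (ids must be unique,
#'   which holds when fov/channel differ).
#' @return a single \code{mm_forest}.
#' @export
combine_forests <- function(forests) {
  out <- do.call(c, unname(lapply(forests, unclass)))
  structure(out, class = "mm_forest",
            n_frames = max(vapply(forests, attr, numeric(1), "n_frames")))
}

#' Run the full analysis pipeline on one field of view
#'
#' compile (drift correction, channel detection, crop, classification) ->
#' background subtraction of every full channel against the averaged empty
#' template -> classical segmentation -> lineage tracking. Channels
#' classified empty are used as subtraction templates; if none is detected
#' the analysis stops with an error.
#'
#' @param planes named list of height x width x n_frames arrays with at
#'   least \code{"phase"}.
#' @param params pipeline parameters.
#' @param fov fov id for the cell ids.
#' @param correct_drift logical, see [compile_fov()].
#' @param refine random-walker refinement toggle, see [segment_frame()].
#' @return a list: \code{compile} (boxes, shifts, stacks, classification),
#'   \code{subtracted} (per full channel), \code{masks} (per full channel),
#'   \code{forests} (per full channel), \code{cells} (combined forest).
#' @export
run_pipeline <- function(planes, params = mm_params(), fov = 1L,
                         correct_drift = TRUE, refine = TRUE) {
  cmp <- compile_fov(planes, params, correct_drift = correct_drift)
  cls <- cmp$classification
  empties <- as.character(cls$channel[cls$label == "empty"])
  fulls <- as.character(cls$channel[cls$label == "full"])
  if (!length(empties)) {
    stop("no empty channel detected for background subtraction; ",
         "inspect the classification (compile_fov()$classification) and ",
         "override a channel to 'empty'", call. = FALSE)
  }
  tmpl <- empty_template(cmp$stacks$phase[empties])
  subtracted <- masks <- forests <- list()
  for (ch in fulls) {
    sub <- subtract_stack(cmp$stacks$phase[[ch]], tmpl, params)
    seg <- segment_stack(sub, params, refine = refine)
    forest <- build_lineages(seg, params, fov = fov, channel = as.integer(ch))
    subtracted[[ch]] <- sub
    masks[[ch]] <- seg
    forests[[ch]] <- forest
  }
  list(compile = cmp, subtracted = subtracted, masks = masks,
       forests = forests,
       cells = if (length(forests)) combine_forests(forests) else NULL)
}

#' Render a kymograph of one channel
#'
#' Tiles the frames of a channel stack side by side (x = time, y = position
#' along the channel) and optionally overlays the tracked lineage: cell
#' centroid traces, with division points marked.
#'
#' @param stack height x width x n_frames channel array (raw, subtracted
#'   pixels, or labels).
#' @param forest optional \code{mm_forest} tracked on this stack.
#' @param every subsample frames by this stride to keep the montage narrow.
#' @param file optional PNG path; when given, the plot is written there.
#' @return invisibly, the montage matrix.
#' @export
plot_kymograph <- function(stack, forest = NULL, every = 1L, file = NULL) {
  stopifnot(length(dim(stack)) == 3)
  idx <- seq(1L, dim(stack)[3], by = every)
  w <- dim(stack)[2]
  mont <- do.call(cbind, lapply(idx, function(t) stack[, , t]))
  if (!is.null(file)) {
    grDevices::png(file, width = ncol(mont), height = nrow(mont))
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(0, 0, 0, 0))
  }
  graphics::image(x = seq_len(ncol(mont)), y = seq_len(nrow(mont)),
                  z = t(mont)[, rev(seq_len(nrow(mont)))],
                  col = grDevices::gray.colors(256, start = 0, end = 1),
                  useRaster = TRUE, axes = FALSE, xlab = "", ylab = "")
  if (!is.null(forest)) {
    H <- nrow(mont)
    cols <- grDevices::hcl.colors(max(8L, length(forest)), "Dark 3")
    k <- 0L
    for (cell in forest) {
      k <- k + 1L
      sel <- cell$frames %in% idx
      if (!any(sel)) next
      xs <- match(cell$frames[sel], idx) * w - w / 2
      ys <- H + 1 - cell$centroid_y[sel]
      graphics::lines(xs, ys, col = cols[(k - 1L) %% length(cols) + 1L],
                      lwd = 2)
      if (!is.na(cell$division_frame)) {
        graphics::points(xs[length(xs)], ys[length(ys)], pch = 4,
                         col = "white")
      }
    }
  }
  invisible(mont)
}
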