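# Empty-channel background subtraction. Aligning an empty-channel template
# onto each full channel and subtracting removes the dark device image;
# after inversion the cells are the only bright objects on a near-zero
# background, which is what the classical segmentation expects.

# normalized cross-correlation of the overlap of a and b when b is shifted
# by (dx, dy)
.ncc_shift <- function(a, b, dx, dy) {
  H <- nrow(a); W <- ncol(a)
  ra <- max(1, 1 + dy):min(H, H + dy)
  ca <- max(1, 1 + dx):min(W, W + dx)
  rb <- ra - dy; cb <- ca - dx
  x <- as.vector(a[ra, ca]); y <- as.vector(b[rb, cb])
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) return(0)
  stats::cor(x, y)
}

#' Align an empty-channel template to a full-channel frame
#'
#' Exhaustive integer-shift search over the +/-\code{align_pad} window (both
#' axes) for the shift of the template that maximizes the normalized
#' cross-correlation of the overlapping region.
#'
#' @param full_frame matrix: one frame of a full channel crop.
#' @param empty_frame matrix of the same size: the empty template.
#' @param align_pad maximum search shift, px.
#' @return a list: \code{shift} = integer c(dx, dy) to apply to the template,
#'   \code{score} = the maximal correlation.
#' @export
align_empty <- function(full_frame, empty_frame, align_pad = 10L) {
  stopifnot(all(dim(full_frame) == dim(empty_frame)), align_pad >= 0)
  if (align_pad >= min(dim(full_frame))) {
    stop("align_pad must be smaller than the frame dimensions", call. = FALSE)
  }
  best <- c(0L, 0L); best_score <- -Inf
  for (dy in -align_pad:align_pad) for (dx in -align_pad:align_pad) {
    s <- .ncc_shift(full_frame, empty_frame, dx, dy)
    if (s > best_score) { best_score <- s; best <- c(dx, dy) }
  }
  list(shift = best, score = best_score)
}

#' Build an empty-channel template
#'
#' Averages one or more empty-channel stacks over time into a single
#' low-noise template for the FOV.
#'
#' @param empty_stacks a list of height x width x n_frames arrays (channels
#'   classified empty), or a single such array.
#' @return a height x width matrix.
#' @export
empty_template <- function(empty_stacks) {
  if (!is.list(empty_stacks)) empty_stacks <- list(empty_stacks)
  if (!length(empty_stacks)) {
    stop("no empty channel available: classify channels first and mark at ",
         "least one channel as an empty template", call. = FALSE)
  }
  means <- lapply(empty_stacks, function(s) apply(s, c(1, 2), mean))
  Reduce(`+`, means) / length(means)
}

#' Subtract the background from a full-channel stack
#'
#' Per frame: aligns the empty template to the frame ([align_empty()]),
#' subtracts and inverts in one step as \code{clip(template - frame, 0)},
#' leaving the (phase-dark) cells as the brightest objects on a near-zero
#' background. Alignment scores below 0.5 are reported with a warning, as
#' imperfect alignment leaves wall artifacts that interfere with
#' segmentation.
#'
#' @param full height x width x n_frames array of a full channel.
#' @param empty template matrix from [empty_template()], or an array with
#'   the same dimensions as \code{full} (averaged over time), or a matrix.
#' @param params pipeline parameters; uses \code{subtract.align_pad}.
#' @return an object of class \code{mm_subtracted}: list with \code{pixels}
#'   (same shape as \code{full}), \code{shifts} (n_frames x 2), and
#'   \code{scores} (per-frame alignment correlation).
#' @export
subtract_stack <- function(full, empty, params = mm_params()) {
  stopifnot(length(dim(full)) == 3)
  if (length(dim(empty)) == 3) empty <- apply(empty, c(1, 2), mean)
  stopifnot(all(dim(empty) == dim(full)[1:2]))
  pad <- params$subtract$align_pad
  Tn <- dim(full)[3]
  out <- array(0, dim = dim(full))
  shifts <- matrix(0L, Tn, 2)
  scores <- numeric(Tn)
  for (t in seq_len(Tn)) {
    fr <- full[, , t]
    al <- align_empty(fr, empty, pad)
    shifts[t, ] <- al$shift
    scores[t] <- al$score
    tmpl <- .shift_image(empty, al$shift[1], al$shift[2])
    out[, , t] <- pmax(tmpl - fr, 0)
  }
  low <- scores < 0.5
  if (any(low)) {
    warning(sum(low), " frame(s) with alignment score < 0.5; ",
            "subtraction artifacts likely")
  }
  structure(list(pixels = out, shifts = shifts, scores = scores),
            class = "mm_subtracted")
}
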