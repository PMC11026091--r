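# Channel detection, drift correction, cropping and full/empty
# classification. The unit of downstream analysis is the per-channel crop
# stack; everything here exists to produce well-registered crops.

# Ricker (Mexican hat) kernel, scale a in px.
.ricker <- function(a, half_width = ceiling(4 * a)) {
  x <- seq(-half_width, half_width)
  (1 - (x / a)^2) * exp(-x^2 / (2 * a^2))
}

#' Detect growth channels in a field of view
#'
#' Finds the x-positions of the vertical growth channels as maxima of a
#' matched-filter (Mexican hat at the expected channel width) response of the
#' column-intensity profile of the time-mean image, then keeps the peaks that
#' sit on the best-fitting lattice with the expected channel separation. The
#' y-extent is taken from the rows over which the cross-column intensity
#' variation of the channel structure persists, padded by
#' \code{compile.y_pad}.
#'
#' @param time_mean_image matrix: temporal mean (or median) of one FOV's
#'   phase-contrast plane, ideally drift-corrected (see [estimate_drift()]).
#' @param params pipeline parameters; uses \code{compile.channel_width},
#'   \code{compile.channel_separation}, \code{compile.y_pad}.
#' @return a data.frame of channel boxes (one row per channel, ordered by x):
#'   \code{channel}, \code{center}, and inclusive 1-based pixel bounds
#'   \code{x0}, \code{x1}, \code{y0}, \code{y1}. Zero rows (with a warning)
#'   if no periodic structure is found.
#' @export
detect_channels <- function(time_mean_image, params = mm_params()) {
  img <- time_mean_image
  wpx <- params$compile$channel_width
  sep <- params$compile$channel_separation
  prof <- colMeans(img)
  prof <- prof - mean(prof)
  k <- .ricker(wpx / 2)
  resp <- stats::filter(prof, k, method = "convolution", sides = 2)
  resp[is.na(resp)] <- 0
  resp <- as.numeric(resp)
  if (max(resp) <= 0 || stats::sd(prof) < 1e-8) {
    warning("no periodic channel structure found")
    return(data.frame(channel = integer(), center = numeric(),
                      x0 = integer(), x1 = integer(),
                      y0 = integer(), y1 = integer()))
  }
  # local maxima, suppressed within half a separation, above 30% of the peak
  half <- floor(sep / 2)
  n <- length(resp)
  cand <- which(resp > 0.3 * max(resp))
  cand <- cand[vapply(cand, function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    resp[i] >= max(resp[lo:hi])
  }, logical(1))]
  if (!length(cand)) {
    warning("no periodic channel structure found")
    return(data.frame(channel = integer(), center = numeric(),
                      x0 = integer(), x1 = integer(),
                      y0 = integer(), y1 = integer()))
  }
  # snap candidates onto the lattice with spacing `sep` that best explains them
  phase <- cand %% sep
  # circular median of phases: pick the candidate phase minimizing total
  # circular distance
  dists <- vapply(phase, function(p) {
    d <- abs(phase - p); sum(pmin(d, sep - d))
  }, numeric(1))
  p0 <- phase[which.min(dists)]
  d <- abs(cand %% sep - p0)
  keep <- pmin(d, sep - d) <= sep / 4
  centers <- sort(cand[keep])
  # refine each center to the brightness centroid within one channel width
  centers <- vapply(centers, function(cc) {
    win <- max(1, cc - wpx):min(n, cc + wpx)
    w <- prof[win] - min(prof[win])
    if (sum(w) <= 0) return(as.numeric(cc))
    sum(win * w) / sum(w)
  }, numeric(1))
  # y extent: rows where cross-column variation of the channel structure lives
  rsd <- apply(img, 1, stats::sd)
  active <- which(rsd > 0.5 * max(rsd))
  ypad <- params$compile$y_pad
  y0 <- max(1L, min(active) - ypad)
  y1 <- min(nrow(img), max(active) + ypad)
  xpad <- 2L
  li <- as.integer(round(centers - wpx / 2 + 0.5))  # first interior column
  x0 <- pmax(1L, li - xpad)
  x1 <- pmin(ncol(img), li + as.integer(wpx) - 1L + xpad)
  data.frame(channel = seq_along(centers), center = centers,
             x0 = x0, x1 = x1, y0 = y0, y1 = y1)
}

# integer-shift an image, replicating edge values into vacated pixels
.shift_image <- function(img, dx, dy) {
  H <- nrow(img); W <- ncol(img)
  rows <- pmin(pmax(seq_len(H) - dy, 1L), H)
  cols <- pmin(pmax(seq_len(W) - dx, 1L), W)
  img[rows, cols, drop = FALSE]
}

#' Estimate stage drift over time
#'
#' Integer-pixel (dx, dy) shift of each frame relative to the first frame,
#' found by maximizing the circular cross-correlation of the mean-subtracted
#' whole-FOV images (FFT-based), restricted to a +/-\code{max_shift} window.
#'
#' @param frames height x width x n_frames array of one FOV's phase plane.
#' @param max_shift largest shift considered, px.
#' @return an n_frames x 2 integer matrix of (dx, dy); the first row is
#'   (0, 0). A flat correlation surface yields (0, 0) with a warning.
#' @export
estimate_drift <- function(frames, max_shift = 10L) {
  stopifnot(length(dim(frames)) == 3)
  Tn <- dim(frames)[3]
  out <- matrix(0L, Tn, 2)
  if (Tn < 2) return(out)
  ref <- frames[, , 1]
  ref <- ref - mean(ref)
  Fref <- stats::fft(ref)
  H <- nrow(ref); W <- ncol(ref)
  win_y <- c(seq_len(max_shift + 1L), (H - max_shift + 1L):H)
  win_x <- c(seq_len(max_shift + 1L), (W - max_shift + 1L):W)
  for (t in 2:Tn) {
    cur <- frames[, , t]
    cur <- cur - mean(cur)
    cc <- Re(stats::fft(stats::fft(cur) * Conj(Fref), inverse = TRUE))
    sub <- cc[win_y, win_x]
    if (max(sub) - min(sub) < 1e-9) {
      warning("flat correlation surface at frame ", t, "; assuming zero drift")
      next
    }
    idx <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    lag <- function(i, win, n) { v <- win[i]; if (v > n / 2) v - n - 1L else v - 1L }
    out[t, ] <- c(lag(idx[2], win_x, W), lag(idx[1], win_y, H))
  }
  out
}

#' Crop per-channel stacks
#'
#' Crops each frame at each channel box, offset by that frame's drift, so
#' the channel walls are stationary in the crop. Out-of-bounds crops are
#' padded by edge replication.
#'
#' @param frames height x width x n_frames array (one imaging plane).
#' @param boxes channel boxes from [detect_channels()].
#' @param shifts n_frames x 2 integer (dx, dy) matrix from
#'   [estimate_drift()]; \code{NULL} for no drift correction.
#' @return a named list (one element per channel id) of
#'   box-height x box-width x n_frames arrays.
#' @export
crop_channel_stacks <- function(frames, boxes, shifts = NULL) {
  stopifnot(length(dim(frames)) == 3)
  H <- dim(frames)[1]; W <- dim(frames)[2]; Tn <- dim(frames)[3]
  if (is.null(shifts)) shifts <- matrix(0L, Tn, 2)
  stopifnot(nrow(shifts) == Tn)
  out <- vector("list", nrow(boxes))
  names(out) <- as.character(boxes$channel)
  for (b in seq_len(nrow(boxes))) {
    rows0 <- boxes$y0[b]:boxes$y1[b]
    cols0 <- boxes$x0[b]:boxes$x1[b]
    st <- array(0, dim = c(length(rows0), length(cols0), Tn))
    for (t in seq_len(Tn)) {
      rows <- rows0 + shifts[t, 2]; cols <- cols0 + shifts[t, 1]
      if (all(rows < 1) || all(rows > H) || all(cols < 1) || all(cols > W)) {
        stop("channel box ", boxes$channel[b],
             " falls entirely outside the image at frame ", t, call. = FALSE)
      }
      rows <- pmin(pmax(rows, 1L), H)      # edge replication at the boundary
      cols <- pmin(pmax(cols, 1L), W)
      st[, , t] <- frames[rows, cols, t]
    }
    out[[b]] <- st
  }
  out
}

#' Classify a channel as full or empty
#'
#' Empty channels are static over time, so their per-frame y-profiles (row
#' means of the crop) stay highly correlated, while channels containing
#' growing, dividing cells decorrelate as the cells elongate and move. The
#' default score is the mean Pearson correlation between each frame's
#' y-profile and the temporal mean profile, which averages down pixel noise
#' in the reference; \code{method = "adjacent"} instead averages the
#' correlation over consecutive frame pairs (t, t+1). Profile pairs with
#' zero variance score 1 by convention (a perfectly static scene).
#'
#' @param stack box-height x box-width x n_frames channel crop array.
#' @param params pipeline parameters; \code{compile.empty_threshold} is the
#'   score above which a channel is called empty.
#' @param method \code{"mean"} (frame vs temporal-mean profile, default) or
#'   \code{"adjacent"} (consecutive frame pairs).
#' @return a list: \code{label} ("full" or "empty") and \code{score} in
#'   [-1, 1]. Single-frame stacks are labeled full with a warning.
#' @export
classify_channels <- function(stack, params = mm_params(),
                              method = c("mean", "adjacent")) {
  method <- match.arg(method)
  stopifnot(length(dim(stack)) == 3)
  Tn <- dim(stack)[3]
  if (Tn < 2) {
    warning("cannot classify a single-frame stack; labeling full")
    return(list(label = "full", score = NA_real_))
  }
  prof <- apply(stack, 3, rowMeans)           # rows = y, cols = frames
  safe_cor <- function(a, b) {
    if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(1)
    stats::cor(a, b)
  }
  cors <- if (method == "mean") {
    mp <- rowMeans(prof)
    vapply(seq_len(Tn), function(t) safe_cor(prof[, t], mp), numeric(1))
  } else {
    vapply(seq_len(Tn - 1L), function(t)
      safe_cor(prof[, t], prof[, t + 1L]), numeric(1))
  }
  score <- mean(cors)
  list(label = if (score >= params$compile$empty_threshold) "empty" else "full",
       score = score)
}

#' Compile one field of view into channel stacks
#'
#' The full compile stage for one FOV: estimates drift, detects channel
#' boxes on the drift-corrected temporal mean, crops per-channel stacks for
#' every imaging plane, and classifies each channel as full or empty from
#' the phase plane.
#'
#' @param planes named list of height x width x n_frames arrays; must
#'   contain the phase plane named \code{"phase"}.
#' @param params pipeline parameters.
#' @param correct_drift logical; set \code{FALSE} for pre-registered input.
#' @return a list: \code{boxes}, \code{shifts}, \code{stacks} (per plane: a
#'   list of per-channel arrays), and \code{classification} (data.frame with
#'   channel, label, score).
#' @export
compile_fov <- function(planes, params = mm_params(), correct_drift = TRUE) {
  stopifnot(is.list(planes), "phase" %in% names(planes))
  phase <- planes[["phase"]]
  Tn <- dim(phase)[3]
  shifts <- if (correct_drift) estimate_drift(phase,
                                              max_shift = params$subtract$align_pad)
            else matrix(0L, Tn, 2)
  aligned_mean <- Reduce(`+`, lapply(seq_len(Tn), function(t)
    .shift_image(phase[, , t], -shifts[t, 1], -shifts[t, 2]))) / Tn
  boxes <- detect_channels(aligned_mean, params)
  stacks <- lapply(planes, crop_channel_stacks, boxes = boxes, shifts = shifts)
  cls <- lapply(stacks[["phase"]], classify_channels, params = params)
  classification <- data.frame(
    channel = boxes$channel,
    label = vapply(cls, `[[`, character(1), "label"),
    score = vapply(cls, `[[`, numeric(1), "score"))
  list(boxes = boxes, shifts = shifts, stacks = stacks,
       classification = classification)
}
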