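# Phase-contrast-like rendering of synthetic experiments.
#
# Scene model (intensities in [0, 1], 16-bit quantized): bright field
# background, dark PDMS device between and above the channels, light channel
# interiors, cells as dark rounded rods (capsules), a bright feeding trench
# across the open ends. Rendering applies integer drift, Gaussian blur and
# additive Gaussian read noise.

#' Field-of-view rendering geometry
#'
#' Lays out \code{n_channels} evenly spaced vertical growth channels (closed
#' end up) over a dark device background, with a bright flow trench across
#' the open ends. Channel width and spacing follow the compile parameters so
#' that rendered fixtures match what the detection stage expects.
#'
#' @param sp simulation parameters ([sim_params()]); sets the um/px scale.
#' @param n_channels number of channels in the field of view.
#' @param params pipeline parameters ([mm_params()]); channel width and
#'   separation are taken from its \code{compile} section.
#' @param noise_sd additive Gaussian noise SD (intensity units). The default
#'   puts the cell/background separation at about 10 noise SD (an easy,
#'   well-resolved phase-contrast render); raise it to stress-test
#'   segmentation (at about 5 SD of separation the distance-transform cores
#'   begin to fragment and counts become unreliable).
#' @param blur_sigma Gaussian blur SD in px.
#' @return a list describing the layout: image size, channel x-centers and
#'   interior column ranges, channel interior row range, trench rows, and the
#'   rendering intensities.
#' @export
fov_geometry <- function(sp, n_channels, params = mm_params(),
                         noise_sd = 0.043, blur_sigma = 1) {
  wpx <- params$compile$channel_width
  sep <- params$compile$channel_separation
  margin_x <- 30L
  top <- 20L
  len_px <- as.integer(round(sp$channel_length / sp$pixel_size))
  trench_h <- 28L
  bottom <- 12L
  centers <- margin_x + wpx / 2 + (seq_len(n_channels) - 1L) * sep
  x0 <- as.integer(ceiling(centers - wpx / 2))     # first interior column
  x1 <- x0 + as.integer(wpx) - 1L
  list(
    n_channels = n_channels,
    width = as.integer(2L * margin_x + (n_channels - 1L) * sep + wpx),
    height = as.integer(top + len_px + trench_h + bottom),
    centers = (x0 + x1) / 2,                        # cells centered in the interior
    x0 = x0,
    x1 = x1,
    y0 = top + 1L,                                  # first interior row (closed end)
    y1 = top + len_px,                              # last interior row (open end)
    trench = (top + len_px + 1L):(top + len_px + trench_h),
    intensity = c(device = 0.25, interior = 0.78, trench = 0.82, cell = 0.35),
    noise_sd = noise_sd,
    blur_sigma = blur_sigma,
    pixel_size = sp$pixel_size,
    cell_width_px = sp$cell_width / sp$pixel_size
  )
}

# anti-aliased capsule coverage added onto a scene matrix (in place).
# y0/y1 um from closed end along the channel; returns modified scene.
.draw_capsule <- function(scene, geom, channel, y0_um, y1_um, value,
                          drift = c(0L, 0L), hard = FALSE, label = NULL) {
  cy <- geom$centers[channel] + drift[1]          # x center, px
  w <- geom$cell_width_px
  ya <- geom$y0 - 0.5 + y0_um / geom$pixel_size + drift[2]  # px edge coords
  yb <- geom$y0 - 0.5 + y1_um / geom$pixel_size + drift[2]
  r <- w / 2
  # capsule = points within r of the axis segment [ya + r, yb - r]
  sa <- ya + r; sb <- max(yb - r, sa)
  rows <- max(1L, floor(ya - 1)):min(nrow(scene), ceiling(yb + 1))
  cols <- max(1L, floor(cy - r - 1)):min(ncol(scene), ceiling(cy + r + 1))
  if (!length(rows) || !length(cols)) return(scene)
  py <- matrix(rows, length(rows), length(cols))        # pixel centers
  px <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  dy <- pmax(0, pmax(sa - py, py - sb))
  d <- sqrt(dy^2 + (px - cy)^2)
  if (hard) {
    inside <- d <= r
    sub <- scene[rows, cols]
    sub[inside] <- label
    scene[rows, cols] <- sub
  } else {
    cov <- pmin(1, pmax(0, r - d + 0.5))                # 1 px linear edge ramp
    sub <- scene[rows, cols]
    scene[rows, cols] <- sub + (value - sub) * cov
  }
  scene
}

#' Render one field of view
#'
#' Renders the scene for one frame of a simulated experiment: the device
#' background with channel interiors and trench, the cells present in that
#' frame, an integer drift offset, Gaussian blur and additive noise
#' (\code{what = "phase"}); the ground-truth labeled mask with the same
#' geometry and drift but no optics (\code{what = "mask"}); or a
#' fluorescence plane in which each cell is filled with its own uniform
#' level on a dark background (\code{what = "fluor"}).
#'
#' @param gt ground truth from [simulate_lineages()].
#' @param frame frame index (1-based).
#' @param geom geometry from [fov_geometry()].
#' @param drift integer \code{c(dx, dy)} scene offset for this frame, px.
#' @param what one of \code{"phase"}, \code{"mask"}, \code{"fluor"}.
#' @param noise_sd noise SD override; \code{NULL} uses \code{geom$noise_sd}.
#' @return a height x width matrix: intensities in [0, 1] quantized to
#'   16 bits (\code{"phase"}, \code{"fluor"}) or integer labels equal to
#'   ground-truth cell ids (\code{"mask"}).
#' @export
render_fov <- function(gt, frame, geom, drift = c(0L, 0L),
                       what = c("phase", "mask", "fluor"), noise_sd = NULL) {
  what <- match.arg(what)
  stopifnot(frame >= 1, frame <= gt$n_frames)
  if (geom$n_channels != gt$n_channels) {
    stop("geometry channel count does not match the experiment", call. = FALSE)
  }
  drift <- as.integer(round(drift))
  H <- geom$height; W <- geom$width
  ints <- geom$intensity
  fr <- gt$frames[gt$frames$frame == frame, , drop = FALSE]

  if (what == "mask") {
    scene <- matrix(0L, H, W)
    if (nrow(fr)) for (i in seq_len(nrow(fr))) {
      scene <- .draw_capsule(scene, geom, fr$channel[i], fr$y0[i], fr$y1[i],
                             value = NA, drift = drift, hard = TRUE,
                             label = fr$id[i])
    }
    return(scene)
  }

  if (what == "fluor") {
    scene <- matrix(0.05, H, W)
    if (nrow(fr)) {
      lev <- gt$cells$fluor[match(fr$id, gt$cells$id)]
      for (i in seq_len(nrow(fr))) {
        scene <- .draw_capsule(scene, geom, fr$channel[i], fr$y0[i], fr$y1[i],
                               value = lev[i], drift = drift)
      }
    }
  } else {
    scene <- matrix(ints[["device"]], H, W)
    for (ch in seq_len(geom$n_channels)) {
      rows <- (geom$y0 + drift[2]):(geom$y1 + drift[2])
      cols <- (geom$x0[ch] + drift[1]):(geom$x1[ch] + drift[1])
      rows <- rows[rows >= 1 & rows <= H]; cols <- cols[cols >= 1 & cols <= W]
      scene[rows, cols] <- ints[["interior"]]
    }
    trench <- geom$trench + drift[2]
    trench <- trench[trench >= 1 & trench <= H]
    scene[trench, ] <- ints[["trench"]]
    if (nrow(fr)) for (i in seq_len(nrow(fr))) {
      scene <- .draw_capsule(scene, geom, fr$channel[i], fr$y0[i], fr$y1[i],
                             value = ints[["cell"]], drift = drift)
    }
  }

  if (geom$blur_sigma > 0) {
    scene <- matrix(as.numeric(EBImage::gblur(scene, sigma = geom$blur_sigma)), H, W)
  }
  nsd <- if (is.null(noise_sd)) geom$noise_sd else noise_sd
  if (nsd > 0) scene <- scene + matrix(stats::rnorm(H * W, 0, nsd), H, W)
  scene <- pmin(1, pmax(0, scene))
  matrix(round(scene * 65535) / 65535, H, W)  # 16-bit quantization (TIFF round trips exactly)
}

#' Simulate and render a complete experiment
#'
#' Convenience wrapper tying the generator together: simulates lineages,
#' generates a bounded random-walk drift trajectory, and renders the phase
#' plane, the ground-truth mask stack, and (optionally) a fluorescence plane
#' for every frame.
#'
#' @param sp simulation parameters ([sim_params()]); seeds all randomness.
#' @param n_channels total channels in the field of view.
#' @param n_frames number of frames.
#' @param n_empty number of channels (taken from the right edge) left empty
#'   as background-subtraction templates.
#' @param params pipeline parameters used for the rendering geometry.
#' @param drift logical: apply a +/-1 px per frame random-walk stage drift
#'   (clipped to +/-5 px), or a 2-column matrix of integer (dx, dy) shifts.
#' @param fluor logical: also render a fluorescence plane.
#' @param noise_sd noise override passed to the geometry.
#' @return a list: \code{gt}, \code{geom}, \code{drift} (n_frames x 2),
#'   \code{phase} and \code{masks} (height x width x n_frames arrays),
#'   optionally \code{fluor}.
#' @export
simulate_experiment <- function(sp, n_channels = 6, n_frames = 50,
                                n_empty = 1, params = mm_params(),
                                drift = TRUE, fluor = FALSE,
                                noise_sd = 0.043) {
  empty <- if (n_empty > 0) (n_channels - n_empty + 1L):n_channels else integer()
  gt <- simulate_lineages(sp, n_channels, n_frames, empty_channels = empty)
  geom <- fov_geometry(sp, n_channels, params, noise_sd = noise_sd)
  if (is.logical(drift)) {
    dr <- matrix(0L, n_frames, 2)
    if (drift) {
      steps <- matrix(sample(c(-1L, 0L, 1L), 2L * (n_frames - 1L), replace = TRUE),
                      ncol = 2)
      dr[-1L, ] <- pmax(-5L, pmin(5L, apply(steps, 2, cumsum)))
    }
  } else {
    dr <- drift
    stopifnot(is.matrix(dr), nrow(dr) == n_frames, ncol(dr) == 2)
  }
  phase <- array(0, dim = c(geom$height, geom$width, n_frames))
  masks <- array(0L, dim = c(geom$height, geom$width, n_frames))
  fl <- if (fluor) array(0, dim = c(geom$height, geom$width, n_frames)) else NULL
  for (t in seq_len(n_frames)) {
    phase[, , t] <- render_fov(gt, t, geom, drift = dr[t, ], what = "phase")
    masks[, , t] <- render_fov(gt, t, geom, drift = dr[t, ], what = "mask")
    if (fluor) fl[, , t] <- render_fov(gt, t, geom, drift = dr[t, ], what = "fluor")
  }
  out <- list(gt = gt, geom = geom, drift = dr, phase = phase, masks = masks)
  if (fluor) out$fluor <- fl
  out
}
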