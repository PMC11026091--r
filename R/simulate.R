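# Synthetic mother-machine experiments with known ground truth.
#
# Cells grow exponentially and divide by the adder principle: each cell
# divides once it has added a (per-cell) target length since birth. Daughters
# split the division length at a (per-cell) septum fraction. Cells are
# stacked single-file from the closed channel end and flushed once they are
# pushed past the open end.

# truncated normal draw: mean m, sd s, truncated to [lo, hi] (rejection).
.rtnorm <- function(n, m, s, lo = m - 3 * s, hi = m + 3 * s) {
  if (s <= 0) return(rep(m, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), m, s)
    ok <- x >= lo & x <= hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Simulation parameters
#'
#' Parameters of the synthetic mother-machine generator. Defaults emulate
#' slow-growing rod-shaped bacteria (60 min doubling time, imaged every
#' 2 min): mean added length 2 um with CV 0.15, elongation rate ln(2)/60
#' per min with CV 0.07, symmetric division with septum SD 0.03. Noise terms
#' are drawn per cell from normal distributions truncated at +/-3 SD (the
#' septum fraction additionally to (0.1, 0.9)).
#'
#' @param mean_delta mean added length between birth and division, um.
#' @param cv_delta coefficient of variation of the added length.
#' @param mean_lambda mean elongation rate, 1/min; 0 gives non-growing cells.
#' @param cv_lambda coefficient of variation of the elongation rate.
#' @param septum_mean mean septum position (fraction of division length given
#'   to the daughter nearer the closed end); must lie in (0, 1).
#' @param septum_sd SD of the septum position.
#' @param cell_width cell width, um.
#' @param frame_interval imaging interval, min.
#' @param pixel_size rendering scale, um/px.
#' @param channel_length usable growth-channel length, um.
#' @param cell_gap rendered gap between stacked cells, um.
#' @param seed RNG seed for the experiment.
#' @return an object of class \code{mm_sim_params}.
#' @export
sim_params <- function(mean_delta = 2, cv_delta = 0.15,
                       mean_lambda = log(2) / 60, cv_lambda = 0.07,
                       septum_mean = 0.5, septum_sd = 0.03,
                       cell_width = 0.8, frame_interval = 2,
                       pixel_size = 0.1, channel_length = 13,
                       cell_gap = 0.3, seed = 1) {
  p <- list(mean_delta = mean_delta, cv_delta = cv_delta,
            mean_lambda = mean_lambda, cv_lambda = cv_lambda,
            septum_mean = septum_mean, septum_sd = septum_sd,
            cell_width = cell_width, frame_interval = frame_interval,
            pixel_size = pixel_size, channel_length = channel_length,
            cell_gap = cell_gap, seed = seed)
  stopifnot(mean_delta > 0, cv_delta >= 0, mean_lambda >= 0, cv_lambda >= 0,
            septum_mean > 0, septum_mean < 1, septum_sd >= 0,
            cell_width > 0, frame_interval > 0, pixel_size > 0,
            channel_length > cell_width, cell_gap >= 0)
  class(p) <- "mm_sim_params"
  p
}

.draw_cell_noise <- function(sp) {
  list(
    delta = .rtnorm(1, sp$mean_delta, sp$cv_delta * sp$mean_delta),
    lambda = .rtnorm(1, sp$mean_lambda, sp$cv_lambda * sp$mean_lambda),
    fluor = stats::runif(1, 0.3, 0.8)
  )
}

#' Simulate ground-truth lineages
#'
#' Runs the adder growth/division model in every (non-empty) channel for
#' \code{n_frames} frames and returns the full ground truth: a per-cell
#' lineage table and per-frame cell positions along each channel. Division is
#' resolved at frame resolution: the first frame at which a cell's added
#' length reaches its target is the mother's division frame and the
#' daughters' birth frame; at that frame the mother's division length equals
#' the sum of the daughters' birth lengths exactly.
#'
#' @param sp simulation parameters from [sim_params()].
#' @param n_channels number of growth channels.
#' @param n_frames number of frames (>= 2).
#' @param empty_channels integer indices of channels left without cells
#'   (background-subtraction templates).
#' @return an object of class \code{mm_ground_truth} with elements
#'   \code{cells} (lineage table: id, channel, parent, birth/division frame,
#'   last observed frame, fate, sb, sd, delta, tau, lambda, septum, fluor,
#'   daughters), \code{frames} (frame, channel, id, y0, y1, length; um from
#'   the closed end), \code{sim_params}, \code{n_channels}, \code{n_frames},
#'   \code{empty_channels}.
#' @export
simulate_lineages <- function(sp, n_channels, n_frames, empty_channels = integer()) {
  stopifnot(inherits(sp, "mm_sim_params"), n_channels >= 1, n_frames >= 2)
  dt <- sp$frame_interval
  if (sp$mean_lambda * dt >= log(2)) {
    stop("degenerate parameters: a cell more than doubles per frame ",
         "(mean_lambda * frame_interval >= ln 2)", call. = FALSE)
  }
  set.seed(sp$seed)
  next_id <- 1L
  cells <- list()    # per-cell static records, filled as cells are created
  live <- list()     # per channel: list of live cell states, closed end first
  frame_rows <- vector("list", n_frames)

  new_cell <- function(channel, birth_frame, l_b, parent, noise) {
    id <- next_id; next_id <<- next_id + 1L
    cells[[id]] <<- list(id = id, channel = channel, parent = parent,
                         birth_frame = birth_frame, division_frame = NA_integer_,
                         last_frame = NA_integer_, fate = "end",
                         sb = l_b, sd = NA_real_, delta = NA_real_,
                         tau = NA_real_, lambda = noise$lambda,
                         septum = NA_real_, fluor = noise$fluor,
                         daughter1 = NA_integer_, daughter2 = NA_integer_)
    list(id = id, birth_frame = birth_frame, l_b = l_b,
         lambda = noise$lambda, delta_target = noise$delta)
  }

  # seed each occupied channel with cells at random cycle phases
  for (ch in seq_len(n_channels)) {
    if (ch %in% empty_channels) { live[[ch]] <- list(); next }
    states <- list()
    y <- 0
    repeat {
      noise <- .draw_cell_noise(sp)
      lb0 <- .rtnorm(1, sp$mean_delta, sp$cv_delta * sp$mean_delta)
      age <- stats::runif(1)  # fraction of the cycle already elapsed
      l_now <- lb0 + age * noise$delta
      if (y + l_now > sp$channel_length) break
      st <- new_cell(ch, 1L, l_now, NA_integer_, noise)
      st$delta_target <- max(noise$delta - (l_now - lb0), 0.05 * sp$mean_delta)
      states[[length(states) + 1L]] <- st
      y <- y + l_now + sp$cell_gap
    }
    live[[ch]] <- states
  }

  for (t in seq_len(n_frames)) {
    rows <- list()
    for (ch in seq_len(n_channels)) {
      states <- live[[ch]]
      if (!length(states)) next
      # grow
      lens <- vapply(states, function(s)
        s$l_b * exp(s$lambda * (t - s$birth_frame) * dt), numeric(1))
      # divide (may cascade positions but each cell divides at most once/frame)
      out <- list()
      for (i in seq_along(states)) {
        s <- states[[i]]; l <- lens[[i]]
        if (l - s$l_b >= s$delta_target && s$lambda > 0) {
          r <- .rtnorm(1, sp$septum_mean, sp$septum_sd, lo = 0.1, hi = 0.9)
          r <- max(0.1, min(0.9, r))
          d1 <- new_cell(ch, t, r * l, s$id, .draw_cell_noise(sp))
          d2 <- new_cell(ch, t, (1 - r) * l, s$id, .draw_cell_noise(sp))
          m <- cells[[s$id]]
          m$division_frame <- t; m$last_frame <- t - 1L; m$fate <- "divided"
          m$sd <- l; m$delta <- l - m$sb
          m$tau <- (t - m$birth_frame) * dt
          m$septum <- r
          m$daughter1 <- d1$id; m$daughter2 <- d2$id
          cells[[s$id]] <- m
          out[[length(out) + 1L]] <- d1
          out[[length(out) + 1L]] <- d2
        } else {
          out[[length(out) + 1L]] <- s
        }
      }
      # stack from the closed end and flush past the open end
      y <- 0
      keep <- list()
      ids <- integer(); y0s <- y1s <- lens <- numeric()
      for (s in out) {
        l <- s$l_b * exp(s$lambda * (t - s$birth_frame) * dt)
        y0 <- y; y1 <- y + l
        if (y1 > sp$channel_length) {
          m <- cells[[s$id]]
          # flushed before appearing at this frame
          m$last_frame <- if (is.na(m$last_frame)) t - 1L else m$last_frame
          m$fate <- "flushed"
          cells[[s$id]] <- m
          next
        }
        keep[[length(keep) + 1L]] <- s
        ids <- c(ids, s$id); y0s <- c(y0s, y0); y1s <- c(y1s, y1)
        lens <- c(lens, l)
        y <- y1 + sp$cell_gap
      }
      if (length(ids)) {
        rows[[length(rows) + 1L]] <- list(frame = rep(t, length(ids)),
                                          channel = rep(ch, length(ids)),
                                          id = ids, y0 = y0s, y1 = y1s,
                                          length = lens)
      }
      live[[ch]] <- keep
    }
    frame_rows[[t]] <- rows
  }

  # finalize cells alive at the end
  for (ch in seq_len(n_channels)) for (s in live[[ch]]) {
    m <- cells[[s$id]]
    if (is.na(m$last_frame)) { m$last_frame <- n_frames; m$fate <- "end" }
    cells[[s$id]] <- m
  }
  flat <- unlist(frame_rows, recursive = FALSE)
  cell_df <- do.call(rbind, lapply(cells, function(m)
    data.frame(id = m$id, channel = m$channel, parent = m$parent,
               birth_frame = m$birth_frame, division_frame = m$division_frame,
               last_frame = m$last_frame, fate = m$fate,
               sb = m$sb, sd = m$sd, delta = m$delta, tau = m$tau,
               lambda = m$lambda, septum = m$septum, fluor = m$fluor,
               daughter1 = m$daughter1, daughter2 = m$daughter2)))
  rownames(cell_df) <- NULL
  frames <- data.frame(
    frame = unlist(lapply(flat, `[[`, "frame")),
    channel = unlist(lapply(flat, `[[`, "channel")),
    id = unlist(lapply(flat, `[[`, "id")),
    y0 = unlist(lapply(flat, `[[`, "y0")),
    y1 = unlist(lapply(flat, `[[`, "y1")),
    length = unlist(lapply(flat, `[[`, "length")))
  structure(list(cells = cell_df, frames = frames, sim_params = sp,
                 n_channels = n_channels, n_frames = n_frames,
                 empty_channels = as.integer(empty_channels)),
            class = "mm_ground_truth")
}

#' @export
print.mm_ground_truth <- function(x, ...) {
  cat(sprintf("mother machine ground truth: %d channels (%d empty), %d frames, %d cells (%d divisions)\n",
              x$n_channels, length(x$empty_channels), x$n_frames,
              nrow(x$cells), sum(x$cells$fate == "divided")))
  invisible(x)
}

#' Ground-truth cell-cycle table of completed cycles
#'
#' Convenience accessor: the subset of the ground-truth lineage table with an
#' observed birth, an observed division, a tracked parent and two tracked
#' daughters -- the same filtering the analysis applies before population
#' statistics.
#'
#' @param gt ground truth from [simulate_lineages()].
#' @return a data.frame of complete cycles with columns sb, sd, delta, tau,
#'   lambda, septum (um / min units of the simulation).
#' @export
gt_complete_cycles <- function(gt) {
  cdf <- gt$cells
  ok <- cdf$fate == "divided" & !is.na(cdf$parent) &
    !is.na(cdf$daughter1) & !is.na(cdf$daughter2)
  # daughters must themselves be observed at least once
  obs <- cdf$id[cdf$last_frame >= cdf$birth_frame | cdf$fate == "divided"]
  ok <- ok & cdf$daughter1 %in% obs & cdf$daughter2 %in% obs
  cdf[ok, , drop = FALSE]
}
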