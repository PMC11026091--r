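# Lineage tracking: link labeled regions through time with a decision tree
# built on the a priori constraints of growth and binary fission in a
# one-ended channel — cells grow by a small factor between frames, divide
# into two similarly sized daughters, and cannot pass each other.

#' Measure labeled regions in one mask frame
#'
#' One feature row per label, ordered by centroid y (closed channel end
#' first). Length is the extent of the region along the channel axis
#' (\code{"extent"}, rows spanned) or the equivalent-ellipse major axis from
#' the second moments (\code{"moment"}); width is the mean row width; the
#' volume uses the capsule (spherocylinder) model
#' \eqn{V = \pi (w/2)^2 (l - w) + (4/3)\pi (w/2)^3}.
#'
#' @param mask_frame integer label matrix (0 = background).
#' @param length_method \code{"extent"} (default) or \code{"moment"}.
#' @return data.frame: label, centroid_y, centroid_x, length, width, area,
#'   volume (px units). Zero rows for an empty frame.
#' @export
extract_regions <- function(mask_frame, length_method = c("extent", "moment")) {
  length_method <- match.arg(length_method)
  k <- max(mask_frame)
  empty <- data.frame(label = integer(), centroid_y = numeric(),
                      centroid_x = numeric(), length = numeric(),
                      width = numeric(), area = numeric(), volume = numeric())
  if (k == 0) return(empty)
  idx <- which(mask_frame > 0, arr.ind = TRUE)
  lab <- mask_frame[idx]
  rows <- lapply(sort(unique(lab)), function(l) {
    pts <- idx[lab == l, , drop = FALSE]
    a <- nrow(pts)
    cy <- mean(pts[, 1]); cx <- mean(pts[, 2])
    len <- if (length_method == "extent") {
      diff(range(pts[, 1])) + 1
    } else {
      # 4 * sqrt of the largest eigenvalue of the second central moments
      mu <- stats::cov(pts) * (a - 1) / a
      ev <- eigen(mu, symmetric = TRUE, only.values = TRUE)$values
      4 * sqrt(max(ev[1], 0))
    }
    wid <- a / (diff(range(pts[, 1])) + 1)          # mean row width
    len <- max(len, wid)
    r <- wid / 2
    vol <- pi * r^2 * (len - wid) + 4 / 3 * pi * r^3
    data.frame(label = l, centroid_y = cy, centroid_x = cx, length = len,
               width = wid, area = a, volume = vol)
  })
  out <- do.call(rbind, rows)
  out[order(out$centroid_y), , drop = FALSE]
}

# decision for one frame: match active cells (ordered by y) to regions
# (ordered by y). Returns a list of decisions; used by build_lineages and
# exported for inspection/testing.

#' Link one frame's regions to the active cells
#'
#' The per-frame decision step. Cells and regions are both ordered along the
#' channel axis and matched with a two-pointer scan that cannot cross links
#' (cells cannot pass each other). For each cell, a one-region (growth) and
#' a two-region (division) hypothesis are scored: growth requires the
#' frame-to-frame length and area ratios to fall inside
#' \code{track.growth_length_ratio} / \code{track.growth_area_ratio};
#' division requires the combined daughters to satisfy the same ratios
#' against the mother and each daughter to hold a plausible fraction
#' (0.25-0.75) of the pair. If both hypotheses pass, the one whose total
#' length ratio is closest (in log) to the geometric mean of the growth
#' bounds wins. Cells matching nothing become candidate-lost; leftover
#' regions become new cells if their centroid lies within
#' \code{track.new_cell_y_cutoff} of the closed end, else they are
#' discarded.
#'
#' @param active data.frame of active cells ordered by y with columns
#'   \code{length}, \code{area} (their last observation).
#' @param regions region table from [extract_regions()], ordered by y.
#' @param params pipeline parameters (the \code{track} section).
#' @return a list with \code{cell_match}: for each active cell, a list with
#'   \code{type} ("growth", "division", "lost") and \code{regions} (indices
#'   into \code{regions}); \code{new_cells}: indices of regions starting new
#'   records; \code{discarded}: indices of ignored regions.
#' @export
link_frame <- function(active, regions, params = mm_params()) {
  tp <- params$track
  glr <- tp$growth_length_ratio; gar <- tp$growth_area_ratio
  target <- sqrt(glr[1] * glr[2])      # expected per-frame growth factor
  nR <- nrow(regions)
  used <- rep(FALSE, nR)
  match_list <- vector("list", nrow(active))
  j <- 1L
  for (i in seq_len(nrow(active))) {
    L <- active$length[i]; A <- active$area[i]
    # skip regions already rejected for earlier cells? regions before j are
    # either consumed or left for new-cell triage
    h1 <- h2 <- NULL
    if (j <= nR) {
      lr <- regions$length[j] / L
      ar <- regions$area[j] / A
      if (lr >= glr[1] && lr <= glr[2] && ar >= gar[1] && ar <= gar[2]) {
        h1 <- list(type = "growth", regions = j, dev = abs(log(lr / target)))
      }
    }
    if (j + 1L <= nR) {
      lsum <- regions$length[j] + regions$length[j + 1L]
      asum <- regions$area[j] + regions$area[j + 1L]
      lr <- lsum / L; ar <- asum / A
      frac <- regions$length[j] / lsum
      if (lr >= glr[1] && lr <= glr[2] && ar >= gar[1] && ar <= gar[2] &&
          frac >= 0.25 && frac <= 0.75) {
        h2 <- list(type = "division", regions = c(j, j + 1L),
                   dev = abs(log(lr / target)))
      }
    }
    pick <- if (!is.null(h1) && !is.null(h2)) {
      if (h2$dev < h1$dev) h2 else h1
    } else if (!is.null(h1)) h1 else if (!is.null(h2)) h2 else NULL
    if (is.null(pick)) {
      match_list[[i]] <- list(type = "lost", regions = integer())
    } else {
      match_list[[i]] <- pick[c("type", "regions")]
      used[pick$regions] <- TRUE
      j <- max(pick$regions) + 1L
    }
  }
  left <- setdiff(seq_len(nR), which(used))
  new_cells <- left[regions$centroid_y[left] <= tp$new_cell_y_cutoff]
  discarded <- setdiff(left, new_cells)
  list(cell_match = match_list, new_cells = new_cells, discarded = discarded)
}

#' Build cell lineages from a labeled mask stack
#'
#' Frame loop applying [link_frame()]: growth links extend a record,
#' division links finalize the mother (its division length is the summed
#' birth length of the two daughters, so length is conserved at the split)
#' and open two daughter records, unmatched cells are retried for
#' \code{track.lost_cell_time} frames (gaps linearly interpolated and
#' flagged) and then finalized as lost.
#'
#' @param mask_stack height x width x n_frames integer label array from
#'   [segment_stack()] (or ground-truth masks).
#' @param params pipeline parameters.
#' @param fov,channel identifiers baked into the cell ids
#'   (\code{f<fov>c<channel>t<birth frame>r<rank>}).
#' @param length_method passed to [extract_regions()].
#' @return an object of class \code{mm_forest}: a list of cell records, each
#'   with id, parent, daughters, birth_frame, division_frame, status
#'   (\code{divided}, \code{lost}, \code{end}), per-frame observations
#'   (frame, centroid, length, width, area, volume, interpolated flag), and
#'   at division sd_px (summed daughter birth length) and septum_ratio
#'   (upper daughter / total).
#' @export
build_lineages <- function(mask_stack, params = mm_params(), fov = 1L,
                           channel = 1L, length_method = "extent") {
  stopifnot(length(dim(mask_stack)) == 3)
  Tn <- dim(mask_stack)[3]
  cells <- list()          # finalized + live records by id
  counter <- 0L
  new_record <- function(t, feat, parent = NA_character_, rank = 1L) {
    counter <<- counter + 1L
    id <- sprintf("f%02dc%02dt%04dr%d", fov, channel, t, rank)
    while (!is.null(cells[[id]])) id <- paste0(id, "x")   # collision guard
    cells[[id]] <<- list(
      id = id, parent = parent, daughters = character(),
      birth_frame = t, division_frame = NA_integer_, status = "growing",
      frames = feat$frame, centroid_y = feat$centroid_y,
      centroid_x = feat$centroid_x, length = feat$length, width = feat$width,
      area = feat$area, volume = feat$volume, interpolated = FALSE,
      sd_px = NA_real_, septum_ratio = NA_real_)
    id
  }
  append_obs <- function(id, feat, gap_fill = NULL) {
    rec <- cells[[id]]
    if (!is.null(gap_fill) && nrow(gap_fill)) {
      rec$frames <- c(rec$frames, gap_fill$frame)
      rec$centroid_y <- c(rec$centroid_y, gap_fill$centroid_y)
      rec$centroid_x <- c(rec$centroid_x, gap_fill$centroid_x)
      rec$length <- c(rec$length, gap_fill$length)
      rec$width <- c(rec$width, gap_fill$width)
      rec$area <- c(rec$area, gap_fill$area)
      rec$volume <- c(rec$volume, gap_fill$volume)
      rec$interpolated <- c(rec$interpolated, rep(TRUE, nrow(gap_fill)))
    }
    rec$frames <- c(rec$frames, feat$frame)
    rec$centroid_y <- c(rec$centroid_y, feat$centroid_y)
    rec$centroid_x <- c(rec$centroid_x, feat$centroid_x)
    rec$length <- c(rec$length, feat$length)
    rec$width <- c(rec$width, feat$width)
    rec$area <- c(rec$area, feat$area)
    rec$volume <- c(rec$volume, feat$volume)
    rec$interpolated <- c(rec$interpolated, FALSE)
    cells[[id]] <<- rec
  }
  # active cells: data.frame id, centroid_y, length, area, missed
  active <- data.frame(id = character(), centroid_y = numeric(),
                       length = numeric(), area = numeric(), missed = integer())

  for (t in seq_len(Tn)) {
    regions <- extract_regions(mask_stack[, , t], length_method = length_method)
    regions$frame <- rep(t, nrow(regions))
    if (nrow(active)) {
      lk <- link_frame(active, regions, params)
      nxt <- active[0, ]
      for (i in seq_len(nrow(active))) {
        dec <- lk$cell_match[[i]]
        id <- active$id[i]
        if (dec$type == "growth") {
          feat <- regions[dec$regions, , drop = FALSE]
          gap <- NULL
          if (active$missed[i] > 0) gap <- .interp_gap(cells[[id]], feat)
          append_obs(id, feat, gap)
          nxt <- rbind(nxt, data.frame(id = id, centroid_y = feat$centroid_y,
                                       length = feat$length, area = feat$area,
                                       missed = 0L))
        } else if (dec$type == "division") {
          f1 <- regions[dec$regions[1], , drop = FALSE]
          f2 <- regions[dec$regions[2], , drop = FALSE]
          rec <- cells[[id]]
          rec$division_frame <- t
          rec$status <- "divided"
          rec$sd_px <- f1$length + f2$length
          rec$septum_ratio <- f1$length / (f1$length + f2$length)
          d1 <- new_record(t, f1, parent = id, rank = 1L)
          d2 <- new_record(t, f2, parent = id, rank = 2L)
          rec$daughters <- c(d1, d2)
          cells[[id]] <- rec
          nxt <- rbind(nxt,
                       data.frame(id = d1, centroid_y = f1$centroid_y,
                                  length = f1$length, area = f1$area, missed = 0L),
                       data.frame(id = d2, centroid_y = f2$centroid_y,
                                  length = f2$length, area = f2$area, missed = 0L))
        } else {  # lost this frame
          miss <- active$missed[i] + 1L
          if (miss > params$track$lost_cell_time) {
            rec <- cells[[id]]
            rec$status <- "lost"
            cells[[id]] <- rec
          } else {
            row <- active[i, ]; row$missed <- miss
            nxt <- rbind(nxt, row)
          }
        }
      }
      # positions of cells that went unmatched this frame: a region next to
      # one of them is almost certainly that cell (a transient ratio-check
      # failure), not a genuinely new cell -- cells cannot appear
      # mid-channel in this device. Leave such regions unclaimed so the
      # candidate-lost cell can re-match them on a later frame.
      lost_pos <- active$centroid_y[vapply(lk$cell_match, function(d)
        d$type == "lost", logical(1))]
      lost_len <- active$length[vapply(lk$cell_match, function(d)
        d$type == "lost", logical(1))]
      for (r in lk$new_cells) {
        feat <- regions[r, , drop = FALSE]
        if (length(lost_pos) &&
            any(abs(lost_pos - feat$centroid_y) < pmax(lost_len, feat$length))) {
          next
        }
        id <- new_record(t, feat, parent = NA_character_,
                         rank = sum(regions$centroid_y <= feat$centroid_y))
        nxt <- rbind(nxt, data.frame(id = id, centroid_y = feat$centroid_y,
                                     length = feat$length, area = feat$area,
                                     missed = 0L))
      }
      active <- nxt[order(nxt$centroid_y), , drop = FALSE]
    } else if (nrow(regions)) {
      keep <- regions$centroid_y <= params$track$new_cell_y_cutoff
      for (r in which(keep)) {
        feat <- regions[r, , drop = FALSE]
        id <- new_record(t, feat, parent = NA_character_, rank = r)
        active <- rbind(active,
                        data.frame(id = id, centroid_y = feat$centroid_y,
                                   length = feat$length, area = feat$area,
                                   missed = 0L))
      }
    }
  }
  for (i in seq_len(nrow(active))) {
    id <- active$id[i]
    rec <- cells[[id]]
    if (rec$status == "growing") {
      rec$status <- if (active$missed[i] > 0) "lost" else "end"
      cells[[id]] <- rec
    }
  }
  structure(cells, class = "mm_forest",
            fov = fov, channel = channel, n_frames = Tn)
}

# linear interpolation of missed frames between a record's last observation
# and the re-found feature
.interp_gap <- function(rec, feat) {
  t0 <- rec$frames[length(rec$frames)]
  t1 <- feat$frame
  if (t1 - t0 <= 1L) return(NULL)
  tg <- (t0 + 1L):(t1 - 1L)
  f <- (tg - t0) / (t1 - t0)
  n0 <- length(rec$frames)
  data.frame(frame = tg,
             centroid_y = rec$centroid_y[n0] + f * (feat$centroid_y - rec$centroid_y[n0]),
             centroid_x = rec$centroid_x[n0] + f * (feat$centroid_x - rec$centroid_x[n0]),
             length = rec$length[n0] + f * (feat$length - rec$length[n0]),
             width = rec$width[n0] + f * (feat$width - rec$width[n0]),
             area = rec$area[n0] + f * (feat$area - rec$area[n0]),
             volume = rec$volume[n0] + f * (feat$volume - rec$volume[n0]))
}

#' @export
print.mm_forest <- function(x, ...) {
  st <- table(vapply(x, `[[`, character(1), "status"))
  cat(sprintf("mm_forest: %d cells over %d frames (%s)\n", length(x),
              attr(x, "n_frames"),
              paste(names(st), st, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Cell-cycle statistics of one tracked cell
#'
#' Derived quantities of a cell record: length at birth \eqn{S_b} (first
#' observation), length at division \eqn{S_d} (summed daughter birth
#' lengths, recorded when the division was linked), added length
#' \eqn{\Delta = S_d - S_b}, generation time \eqn{\tau} (division frame
#' minus birth frame, times the frame interval), elongation rate
#' \eqn{\lambda} (least-squares slope of log length against time over the
#' cell's observations), and septum ratio (upper daughter's birth length
#' over \eqn{S_d}). Lengths are converted with \code{calibration.pixel_size}
#' (um/px) and times with \code{calibration.frame_interval} (min/frame);
#' with the default calibration of 1 the units are px and frames.
#'
#' @param cell one record of an \code{mm_forest}.
#' @param calibration the \code{calibration} element of [mm_params()] (or a
#'   list with \code{pixel_size} and \code{frame_interval}).
#' @return a one-row data.frame: id, parent, status, birth_frame,
#'   division_frame, n_obs, sb, sd, delta, tau, lambda, septum_ratio,
#'   complete (TRUE when birth and division were both observed). For
#'   incomplete cycles sd, delta, tau and septum_ratio are NA but lambda is
#'   still fitted.
#' @export
compute_cell_cycle <- function(cell, calibration = list(pixel_size = 1,
                                                        frame_interval = 1)) {
  px <- calibration$pixel_size
  dt <- calibration$frame_interval
  n <- length(cell$frames)
  stopifnot(n >= 1)
  lambda <- NA_real_
  if (n >= 2 && all(cell$length > 0)) {
    tt <- cell$frames * dt
    ll <- log(cell$length)
    lambda <- stats::cov(tt, ll) / stats::var(tt)
  }
  complete <- !is.na(cell$division_frame) && !is.na(cell$parent)
  divided <- !is.na(cell$division_frame)
  data.frame(
    id = cell$id, parent = cell$parent, status = cell$status,
    birth_frame = cell$birth_frame, division_frame = cell$division_frame,
    n_obs = n,
    sb = cell$length[1] * px,
    sd = if (divided) cell$sd_px * px else NA_real_,
    delta = if (divided) (cell$sd_px - cell$length[1]) * px else NA_real_,
    tau = if (divided) (cell$division_frame - cell$birth_frame) * dt else NA_real_,
    lambda = lambda,          # slope of log length per unit time
    septum_ratio = if (divided) cell$septum_ratio else NA_real_,
    complete = complete)
}

#' Cell-cycle table of a lineage forest
#'
#' Applies [compute_cell_cycle()] to every record and returns one row per
#' cell.
#'
#' @param forest an \code{mm_forest} from [build_lineages()].
#' @param calibration calibration list (see [compute_cell_cycle()]).
#' @return a data.frame with one row per cell.
#' @export
cell_cycle_table <- function(forest, calibration = list(pixel_size = 1,
                                                        frame_interval = 1)) {
  out <- do.call(rbind, lapply(forest, compute_cell_cycle,
                               calibration = calibration))
  rownames(out) <- NULL
  out
}

#' Match tracked complete cycles against ground truth
#'
#' Compares a tracked forest with the generator's lineage table: for every
#' ground-truth complete cycle (observed birth and division, tracked parent
#' and two tracked daughters), looks for an unused tracked complete cell in
#' the same channel whose birth and division frames agree within
#' \code{frame_tol} frames. The tolerance absorbs the frame-quantized
#' boundary of division detection in intensity-based segmentation, which
#' can split cells a frame or two later than the geometric ground truth.
#'
#' @param forest a tracked \code{mm_forest} (multi-channel forests from
#'   [combine_forests()] are fine: the channel is parsed from the cell id).
#' @param gt an \code{mm_ground_truth}.
#' @param frame_tol allowed birth/division frame mismatch, frames.
#' @return a list: \code{n_gt} (ground-truth complete cycles),
#'   \code{n_matched}, \code{fraction} matched.
#' @export
match_lineages <- function(forest, gt, frame_tol = 2L) {
  gcc <- gt_complete_cycles(gt)
  comp <- filter_complete(forest)
  if (!length(comp)) {
    return(list(n_gt = nrow(gcc), n_matched = 0L, fraction = 0))
  }
  tr <- data.frame(
    channel = vapply(comp, function(cell)
      as.integer(sub("^f\\d+c(\\d+)t.*$", "\\1", cell$id)), integer(1)),
    birth = vapply(comp, `[[`, integer(1), "birth_frame"),
    division = vapply(comp, function(cell) as.integer(cell$division_frame),
                      integer(1)),
    used = FALSE)
  matched <- 0L
  for (i in seq_len(nrow(gcc))) {
    cand <- which(!tr$used & tr$channel == gcc$channel[i] &
                    abs(tr$birth - gcc$birth_frame[i]) <= frame_tol &
                    abs(tr$division - gcc$division_frame[i]) <= frame_tol)
    if (length(cand)) {
      tr$used[cand[1]] <- TRUE
      matched <- matched + 1L
    }
  }
  list(n_gt = nrow(gcc), n_matched = matched,
       fraction = if (nrow(gcc)) matched / nrow(gcc) else NA_real_)
}
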