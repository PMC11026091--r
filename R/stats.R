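# Population physiology statistics: distribution summaries and CVs of the
# cell-cycle parameters, binned correlations (the adder signature), per-cell
# fluorescence quantification, and fluorescent focus detection.

#' Filter for cells with fully tracked relatives
#'
#' Keeps cells whose complete cycle is reliable: observed birth and
#' division, a tracked parent, and two tracked daughters. First-generation
#' cells, cells lost before division, and cells whose daughters were not
#' followed are excluded. This is the standard filtering applied before any
#' population statistic.
#'
#' @param forest an \code{mm_forest} (or a list of them, concatenated).
#' @return the subset of records (same class) passing the filter.
#' @export
filter_complete <- function(forest) {
  ids <- names(forest)
  keep <- vapply(forest, function(cell) {
    !is.na(cell$parent) && cell$parent %in% ids &&
      !is.na(cell$division_frame) &&
      length(cell$daughters) == 2L && all(cell$daughters %in% ids)
  }, logical(1))
  out <- forest[keep]
  class(out) <- class(forest)
  attr(out, "n_frames") <- attr(forest, "n_frames")
  out
}

#' Summarize a parameter distribution
#'
#' Sample size, mean, standard deviation (n - 1 denominator) and coefficient
#' of variation CV = SD/mean.
#'
#' @param values numeric vector (NAs dropped), n >= 2 after removal.
#' @param name optional parameter name carried into the output.
#' @return a one-row data.frame: name, n, mean, sd, cv.
#' @export
summarize_distributions <- function(values, name = NA_character_) {
  v <- values[!is.na(values)]
  if (length(v) < 2) stop("need at least 2 values to summarize", call. = FALSE)
  m <- mean(v); s <- stats::sd(v)
  data.frame(name = name, n = length(v), mean = m, sd = s, cv = s / m)
}

#' Physiology summary of a lineage forest
#'
#' Distribution summaries (n, mean, SD, CV) of the six cell-cycle
#' parameters -- birth length, division length, added length, generation
#' time, elongation rate and septum ratio -- over the complete-cycle cells
#' of the forest (after [filter_complete()]).
#'
#' @param forest an \code{mm_forest}.
#' @param calibration calibration list (see [compute_cell_cycle()]).
#' @param filtered set \code{FALSE} if \code{forest} is already filtered.
#' @return a data.frame with one row per parameter.
#' @export
physiology_summary <- function(forest, calibration = list(pixel_size = 1,
                                                          frame_interval = 1),
                               filtered = FALSE) {
  if (!filtered) forest <- filter_complete(forest)
  tab <- cell_cycle_table(forest, calibration)
  pars <- c(sb = "sb", sd = "sd", delta = "delta", tau = "tau",
            lambda = "lambda", septum_ratio = "septum_ratio")
  out <- do.call(rbind, lapply(names(pars), function(p)
    summarize_distributions(tab[[pars[[p]]]], name = p)))
  rownames(out) <- NULL
  out
}

#' Binned mean of y against x
#'
#' Equal-count (quantile) bins on x; per-bin mean of y, standard error of
#' the mean, and count. Bins with fewer than \code{min_n} points are
#' dropped. This is the standard display for single-cell correlation plots
#' (e.g. added length against birth length, whose flat binned mean is the
#' adder signature).
#'
#' @param x,y paired numeric vectors.
#' @param n_bins number of quantile bins (>= 2).
#' @param min_n minimum points per retained bin.
#' @return a data.frame: bin_center (mean x in bin), mean (mean y), sem, n.
#' @export
binned_means <- function(x, y, n_bins = 8, min_n = 20) {
  stopifnot(length(x) == length(y), n_bins >= 2)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2) stop("all x values identical", call. = FALSE)
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  g <- cut(x, breaks = br, include.lowest = TRUE)
  out <- do.call(rbind, lapply(levels(g), function(l) {
    i <- g == l
    n <- sum(i)
    data.frame(bin_center = mean(x[i]), mean = mean(y[i]),
               sem = stats::sd(y[i]) / sqrt(n), n = n)
  }))
  out <- out[out$n >= min_n, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Weighted straight-line fit through binned means
#'
#' Least-squares line through the bin means, weighted by the inverse
#' squared standard errors; used to test the slope of binned correlations
#' (e.g. slope 0 of added length vs birth length under the adder).
#'
#' @param bm output of [binned_means()].
#' @return a list: slope, intercept, slope_se.
#' @export
binned_slope <- function(bm) {
  stopifnot(nrow(bm) >= 2)
  w <- 1 / pmax(bm$sem, 1e-12)^2
  fit <- stats::lm(mean ~ bin_center, data = bm, weights = w)
  s <- summary(fit)$coefficients
  list(slope = unname(s["bin_center", "Estimate"]),
       intercept = unname(s["(Intercept)", "Estimate"]),
       slope_se = unname(s["bin_center", "Std. Error"]))
}

#' Per-cell fluorescence quantification
#'
#' For every observation of every cell, sums the fluorescence plane over the
#' cell's mask pixels: integrated signal, signal per unit area and per unit
#' (capsule-model) volume.
#'
#' @param forest an \code{mm_forest} tracked from \code{mask_stack}.
#' @param mask_stack the label array the forest was tracked on.
#' @param fluor_stack fluorescence array of identical dimensions, registered
#'   to the masks.
#' @return a data.frame: id, frame, integrated, per_area, per_volume.
#' @export
measure_fluorescence <- function(forest, mask_stack, fluor_stack) {
  if (!all(dim(mask_stack) == dim(fluor_stack))) {
    stop("mask and fluorescence stacks have different dimensions", call. = FALSE)
  }
  rows <- list()
  for (cell in forest) {
    for (k in seq_along(cell$frames)) {
      if (cell$interpolated[k]) next
      t <- cell$frames[k]
      m <- mask_stack[, , t]
      # the cell's region at frame t: nearest label at its centroid
      lab <- m[round(cell$centroid_y[k]), round(cell$centroid_x[k])]
      if (lab == 0) next
      px <- fluor_stack[, , t][m == lab]
      integ <- sum(px)
      rows[[length(rows) + 1L]] <- data.frame(
        id = cell$id, frame = t, integrated = integ,
        per_area = integ / cell$area[k],
        per_volume = integ / cell$volume[k])
    }
  }
  if (!length(rows)) {
    return(data.frame(id = character(), frame = integer(),
                      integrated = numeric(), per_area = numeric(),
                      per_volume = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect fluorescent foci in one frame
#'
#' Laplacian-of-Gaussian spot detection: the negated LoG response at the
#' configured spot scale is searched for local maxima above
#' \code{threshold} times the response SD; each focus is assigned to the
#' cell whose mask contains its peak pixel (or none).
#'
#' @param fluor_frame fluorescence intensity matrix.
#' @param mask_frame integer label matrix registered to it (0 allowed
#'   everywhere if no masks are available).
#' @param spot_sigma spot scale in px (the LoG kernel SD).
#' @param threshold detection threshold in units of the response SD.
#' @return a data.frame: x, y (px), response, intensity, label (owning
#'   region label, 0 if outside all cells). Zero rows when nothing exceeds
#'   the threshold.
#' @export
detect_foci <- function(fluor_frame, mask_frame = NULL, spot_sigma = 1.5,
                        threshold = 5) {
  H <- nrow(fluor_frame); W <- ncol(fluor_frame)
  if (is.null(mask_frame)) mask_frame <- matrix(0L, H, W)
  stopifnot(all(dim(mask_frame) == c(H, W)))
  # LoG via difference of Gaussians is avoided: build the exact LoG kernel
  hw <- max(3L, ceiling(3 * spot_sigma))
  xs <- seq(-hw, hw)
  g <- exp(-xs^2 / (2 * spot_sigma^2))
  gx <- matrix(g, 2 * hw + 1, 2 * hw + 1)
  gy <- t(gx)
  G <- gx * gy; G <- G / sum(G)
  r2 <- outer(xs^2, xs^2, `+`)
  log_k <- G * (r2 - 2 * spot_sigma^2) / spot_sigma^4
  log_k <- log_k - mean(log_k)              # zero-DC so flat areas respond 0
  resp <- -matrix(as.numeric(EBImage::filter2(fluor_frame, log_k,
                                              boundary = "replicate")), H, W)
  s <- stats::sd(resp)
  if (s < 1e-12) {
    return(data.frame(x = numeric(), y = numeric(), response = numeric(),
                      intensity = numeric(), label = integer()))
  }
  cut <- threshold * s
  # 8-neighborhood local maxima via dilation
  dil <- matrix(as.numeric(EBImage::dilate(resp, EBImage::makeBrush(3, "box"))),
                H, W)
  peaks <- which(resp >= cut & resp >= dil, arr.ind = TRUE)
  if (!nrow(peaks)) {
    return(data.frame(x = numeric(), y = numeric(), response = numeric(),
                      intensity = numeric(), label = integer()))
  }
  out <- data.frame(x = peaks[, 2], y = peaks[, 1],
                    response = resp[peaks],
                    intensity = fluor_frame[peaks],
                    label = mask_frame[peaks])
  out[order(-out$response), , drop = FALSE]
}
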