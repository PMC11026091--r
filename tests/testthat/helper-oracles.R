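# Independent straight-line oracles used to cross-check the implementation.
# Everything here is deliberately written with plain loops and base R only.

# exhaustive Otsu scan over 256 levels of the image range; returns the
# foreground mask (the quantity the threshold exists to produce)
oracle_otsu_foreground <- function(img, scale = 1) {
  v <- as.vector(img)
  lo <- min(v); hi <- max(v)
  bins <- pmin(floor((v - lo) / (hi - lo) * 256), 255)
  h <- rep(0, 256)
  for (b in bins) h[b + 1] <- h[b + 1] + 1
  n <- length(v)
  best <- -1; best_t <- integer()
  for (t in 0:254) {                         # class 0 = bins 0..t
    n0 <- sum(h[1:(t + 1)]); n1 <- n - n0
    if (n0 == 0 || n1 == 0) { s <- 0 } else {
      mu0 <- sum((0:t) * h[1:(t + 1)]) / n0
      mu1 <- sum(((t + 1):255) * h[(t + 2):256]) / n1
      s <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    }
    if (s > best) { best <- s; best_t <- t }
  }
  if (scale != 1) {
    # a scaled threshold leaves the bin lattice; convert via the plateau
    # midpoint intensity (scan the plateau to its end first)
    t_hi <- best_t
    # identical sigma over trailing empty bins extends the plateau
    while (t_hi < 254 && h[t_hi + 2] == 0) t_hi <- t_hi + 1
    thr <- lo + ((best_t + t_hi) / 2 + 0.5) / 256 * (hi - lo)
    return(matrix(img > scale * thr, nrow(img), ncol(img)))
  }
  # class 1 = bins above the argmax split: the partition itself
  matrix(bins > best_t, nrow(img), ncol(img))
}

# disc structuring element: offsets within radius r + 0.5 of the center
oracle_disc <- function(r) {
  o <- expand.grid(dy = -r:r, dx = -r:r)
  o[o$dy^2 + o$dx^2 <= (r + 0.5)^2, ]
}

# erosion/dilation with out-of-bounds offsets ignored (image border neutral)
oracle_erode <- function(b, r) {
  H <- nrow(b); W <- ncol(b); D <- oracle_disc(r)
  out <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ok <- TRUE
    for (k in seq_len(nrow(D))) {
      y <- i + D$dy[k]; x <- j + D$dx[k]
      if (y >= 1 && y <= H && x >= 1 && x <= W && !b[y, x]) { ok <- FALSE; break }
    }
    out[i, j] <- ok
  }
  out
}

oracle_dilate <- function(b, r) {
  H <- nrow(b); W <- ncol(b); D <- oracle_disc(r)
  out <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    hit <- FALSE
    for (k in seq_len(nrow(D))) {
      y <- i + D$dy[k]; x <- j + D$dx[k]
      if (y >= 1 && y <= H && x >= 1 && x <= W && b[y, x]) { hit <- TRUE; break }
    }
    out[i, j] <- hit
  }
  out
}

oracle_opening <- function(b, r) oracle_dilate(oracle_erode(b, r), r)

# fill holes: background components not connected (4-conn) to the border
oracle_fill_holes <- function(b) {
  lab <- oracle_label(!b)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  out <- b
  out[lab > 0 & !(lab %in% border)] <- TRUE
  out
}

# exact Euclidean distance transform by brute force
oracle_edt <- function(b) {
  H <- nrow(b); W <- ncol(b)
  bg <- which(!b, arr.ind = TRUE)
  out <- matrix(0, H, W)
  if (!nrow(bg)) { out[] <- Inf; return(out) }
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (b[i, j]) out[i, j] <- sqrt(min((bg[, 1] - i)^2 + (bg[, 2] - j)^2))
  }
  out
}

# 4-connected component labeling by BFS, labels in raster order
oracle_label <- function(b) {
  H <- nrow(b); W <- ncol(b)
  lab <- matrix(0L, H, W)
  k <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {   # column-major like R
    if (b[i, j] && lab[i, j] == 0L) {
      k <- k + 1L
      queue <- list(c(i, j)); lab[i, j] <- k
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          y <- p[1] + d[1]; x <- p[2] + d[2]
          if (y >= 1 && y <= H && x >= 1 && x <= W && b[y, x] && lab[y, x] == 0L) {
            lab[y, x] <- k
            queue[[length(queue) + 1L]] <- c(y, x)
          }
        }
      }
    }
  }
  lab
}

# the classical pipeline steps (1)-(7), straight-line
oracle_segment_steps <- function(img, params) {
  p <- params$segment
  if (diff(range(img)) < 1e-12) return(matrix(0L, nrow(img), ncol(img)))
  bin <- oracle_otsu_foreground(img, p$otsu_scale)
  if (!any(bin)) return(matrix(0L, nrow(img), ncol(img)))
  bin <- oracle_opening(bin, p$first_opening)
  if (!any(bin)) return(matrix(0L, nrow(img), ncol(img)))
  bin <- oracle_fill_holes(bin)
  edt <- oracle_edt(bin)
  core <- edt >= p$distance_threshold
  core <- oracle_opening(core, p$second_opening)
  lab <- oracle_label(core)
  # remove small regions and regions touching the border
  if (max(lab) > 0) {
    for (l in seq_len(max(lab))) {
      pts <- which(lab == l, arr.ind = TRUE)
      touches <- any(pts[, 1] == 1 | pts[, 1] == nrow(lab) |
                       pts[, 2] == 1 | pts[, 2] == ncol(lab))
      if (nrow(pts) < p$min_object_size || touches) lab[lab == l] <- 0L
    }
  }
  lab
}

# canonical form of a label image: relabel 1..k in raster (column-major)
# order of first occurrence, so two segmentations can be compared exactly
canonical_labels <- function(lab) {
  ids <- unique(lab[lab > 0])
  out <- lab
  out[lab > 0] <- match(lab[lab > 0], ids)
  out
}

# optimal one-to-one assignment by exhaustive search: the maximum number of
# (pred, gt) pairs with IoU >= thr, each region used once
oracle_optimal_matches <- function(iou, thr) {
  np <- nrow(iou); ng <- ncol(iou)
  ok <- iou >= thr
  best <- 0L
  recurse <- function(i, used_g, count) {
    if (count + (np - i + 1L) <= best) return()
    if (i > np) { best <<- max(best, count); return() }
    recurse(i + 1L, used_g, count)              # leave prediction i unmatched
    for (j in seq_len(ng)) {
      if (!used_g[j] && ok[i, j]) {
        used_g[j] <- TRUE
        recurse(i + 1L, used_g, count + 1L)
        used_g[j] <- FALSE
      }
    }
  }
  if (np > 0 && ng > 0) recurse(1L, rep(FALSE, ng), 0L)
  best
}

# independent log-linear least squares (normal equations, no lm)
oracle_loglinear_slope <- function(t, y) {
  x <- t; z <- log(y)
  n <- length(x)
  (n * sum(x * z) - sum(x) * sum(z)) / (n * sum(x^2) - sum(x)^2)
}
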