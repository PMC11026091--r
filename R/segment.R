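# Classical segmentation of background-subtracted channel crops: scaled Otsu
# threshold, morphological cleanup on the Euclidean distance transform, size
# and border filters, then seeded random-walker refinement of the cell
# boundaries on the intensity image.

#' Otsu threshold of an image
#'
#' The binary threshold maximizing the between-class (inter-region) variance
#' of the discrete intensity histogram. The image range is divided into
#' \code{levels} bins; when several thresholds tie (e.g. a two-point
#' histogram), the midpoint of the tying plateau is returned.
#'
#' @param image numeric matrix with at least two distinct values.
#' @param levels number of histogram levels (256 mirrors 8-bit data).
#' @return the threshold on the intensity scale of \code{image}; foreground
#'   is \code{image > otsu_scale * threshold}.
#' @export
otsu_threshold <- function(image, levels = 256L) {
  v <- as.vector(image)
  lo <- min(v); hi <- max(v)
  if (hi - lo < .Machine$double.eps * 4) {
    stop("no contrast: image is constant", call. = FALSE)
  }
  bin <- pmin(floor((v - lo) / (hi - lo) * levels), levels - 1L)
  h <- tabulate(bin + 1L, nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)                       # class-0 weight for t = 0..levels-1
  mu <- cumsum(p * (seq_len(levels) - 1L)) # class-0 first moment
  mu_t <- mu[levels]
  t_idx <- seq_len(levels - 1L)            # split after bin t-1
  w0 <- omega[t_idx]; w1 <- 1 - w0
  sigma_b <- ifelse(w0 > 0 & w1 > 0, (mu_t * w0 - mu[t_idx])^2 / (w0 * w1), 0)
  best <- which(sigma_b == max(sigma_b))
  t_star <- mean(best - 1L)                # 0-based bin index (plateau midpoint)
  lo + (t_star + 0.5) / levels * (hi - lo)
}

#' Seeded random-walker segmentation
#'
#' Assigns every unseeded pixel to the seed class at which a random walker
#' started from that pixel is most likely to be absorbed, on the 4-connected
#' lattice with edge weights \code{exp(-beta * dI^2)} computed from the
#' range-normalized intensities (plus a small conductance floor). The
#' resulting Dirichlet problem is solved exactly with a sparse linear solve,
#' so the output is deterministic.
#'
#' @param img numeric intensity matrix.
#' @param seeds integer matrix of the same size: 0 = unseeded, k > 0 = seed
#'   class k.
#' @param beta edge-weight sharpness (dimensionless, for intensities scaled
#'   to [0, 1]).
#' @return an integer matrix of class labels covering every pixel.
#' @export
random_walker <- function(img, seeds, beta = 500) {
  stopifnot(all(dim(img) == dim(seeds)))
  H <- nrow(img); W <- ncol(img); N <- H * W
  classes <- sort(unique(seeds[seeds > 0]))
  if (!length(classes)) stop("random_walker needs at least one seed", call. = FALSE)
  if (length(classes) == 1L) { out <- seeds; out[] <- classes; return(out) }
  if (!any(seeds == 0)) return(seeds)
  rng <- range(img)
  x <- if (diff(rng) > 0) (as.vector(img) - rng[1]) / diff(rng) else numeric(N)
  # vertical edges (i, i+1) within columns; horizontal edges (i, i+H)
  iv <- which((seq_len(N) - 1L) %% H != H - 1L)
  ih <- seq_len(N - H)
  ei <- c(iv, ih); ej <- c(iv + 1L, ih + H)
  w <- exp(-beta * (x[ei] - x[ej])^2) + 1e-6
  deg <- numeric(N)
  agg <- rowsum(c(w, w), c(ei, ej))
  deg[as.integer(rownames(agg))] <- agg[, 1]
  L <- Matrix::sparseMatrix(i = c(ei, ej, seq_len(N)),
                            j = c(ej, ei, seq_len(N)),
                            x = c(-w, -w, deg), dims = c(N, N))
  sv <- as.vector(seeds)
  U <- which(sv == 0L); S <- which(sv > 0L)
  M <- Matrix::sparseMatrix(i = seq_along(S), j = match(sv[S], classes),
                            x = 1, dims = c(length(S), length(classes)))
  rhs <- -L[U, S, drop = FALSE] %*% M
  P <- Matrix::solve(L[U, U, drop = FALSE], rhs)
  P <- as.matrix(P)
  out <- sv
  out[U] <- classes[max.col(P, ties.method = "first")]
  matrix(as.integer(out), H, W)
}

# remove labeled regions below a size or touching the border; relabel 1..k
.filter_regions <- function(lab, min_size, drop_border = TRUE) {
  if (max(lab) == 0) return(lab)
  ids <- seq_len(max(lab))
  area <- tabulate(lab[lab > 0], nbins = max(lab))
  bad <- area < min_size
  if (drop_border) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    bad[border[border > 0]] <- TRUE
  }
  if (any(bad)) {
    lab[lab %in% ids[bad]] <- 0L
  }
  old <- sort(unique(lab[lab > 0]))
  if (length(old)) lab[lab > 0] <- match(lab[lab > 0], old)
  lab
}

#' Segment one background-subtracted frame
#'
#' The classical segmentation pipeline, in order: (1) binarize at
#' \code{otsu_scale} times the Otsu threshold; (2) morphological opening with
#' a disk of radius \code{first_opening}; (3) Euclidean distance transform of
#' the binary mask; (4) keep pixels with distance >= \code{distance_threshold};
#' (5) opening with a disk of radius \code{second_opening}; (6) remove
#' regions smaller than \code{min_object_size} and regions touching the
#' image border; (7) label connected components; (8, optional) use the
#' labels to seed a random walker on the subtracted intensities, with the
#' background class seeded from pixels farther than twice
#' \code{distance_threshold} from the binary foreground; each refined region
#' contains its seed, so the filters are not re-applied.
#'
#' @param sub_frame matrix: one frame of a subtracted stack (cells bright).
#' @param params pipeline parameters (the \code{segment} section).
#' @param refine run the random-walker refinement step (8); \code{FALSE}
#'   stops after step (7), i.e. the labeled distance-transform cores.
#' @return an integer label matrix (0 = background, 1..k = cells, labeled in
#'   order of increasing centroid y). A blank frame yields an all-zero mask.
#' @export
segment_frame <- function(sub_frame, params = mm_params(), refine = TRUE) {
  zero <- matrix(0L, nrow(sub_frame), ncol(sub_frame))
  if (diff(range(sub_frame)) < .Machine$double.eps * 4) return(zero)
  p <- params$segment
  th <- otsu_threshold(sub_frame)
  bin <- sub_frame > p$otsu_scale * th
  if (!any(bin)) return(zero)
  bin <- EBImage::opening(bin, EBImage::makeBrush(2 * p$first_opening + 1, "disc"))
  if (!any(bin > 0)) return(zero)
  # fill enclosed holes (isolated sub-threshold pixels inside cells) so the
  # distance transform reflects region geometry, not pixel noise; a no-op on
  # hole-free masks and cannot bridge the open gap between adjacent cells
  bin <- EBImage::fillHull(bin)
  edt <- EBImage::distmap(bin)
  core <- edt >= p$distance_threshold
  core <- EBImage::opening(core, EBImage::makeBrush(2 * p$second_opening + 1, "disc"))
  lab <- EBImage::bwlabel(core)
  lab <- .filter_regions(matrix(as.integer(lab), nrow(lab)), p$min_object_size)
  if (max(lab) == 0 || !refine) return(.relabel_by_y(lab))
  # background seeds: far from the binary foreground
  bgdist <- EBImage::distmap(1 - bin)
  bg_seed <- bgdist > 2 * p$distance_threshold
  if (!any(bg_seed)) bg_seed <- bgdist >= max(bgdist)
  k <- max(lab)
  seeds <- lab
  seeds[bg_seed & lab == 0] <- k + 1L
  rw <- random_walker(sub_frame, seeds, beta = p$walker_beta)
  rw[rw == k + 1L] <- 0L
  # every refined region contains its (already filtered) seed, so the size
  # and border filters are not re-applied after refinement
  .relabel_by_y(rw)
}

# relabel regions 1..k in order of increasing centroid row (closed end first)
.relabel_by_y <- function(lab) {
  k <- max(lab)
  if (k == 0) return(lab)
  cy <- vapply(seq_len(k), function(i) mean(which(lab == i, arr.ind = TRUE)[, 1]),
               numeric(1))
  ord <- order(cy)
  out <- lab
  out[lab > 0] <- match(lab[lab > 0], ord)
  out
}

#' Segment a subtracted channel stack
#'
#' Frame-wise application of [segment_frame()]. Per-frame region counts are
#' attached as the \code{"counts"} attribute.
#'
#' @param sub an \code{mm_subtracted} object from [subtract_stack()], or a
#'   height x width x n_frames array of subtracted intensities.
#' @param params pipeline parameters.
#' @param refine run the random-walker refinement (see [segment_frame()]).
#' @return an integer height x width x n_frames label array.
#' @export
segment_stack <- function(sub, params = mm_params(), refine = TRUE) {
  px <- if (inherits(sub, "mm_subtracted")) sub$pixels else sub
  stopifnot(length(dim(px)) == 3)
  Tn <- dim(px)[3]
  out <- array(0L, dim = dim(px))
  counts <- integer(Tn)
  for (t in seq_len(Tn)) {
    m <- segment_frame(px[, , t], params, refine = refine)
    out[, , t] <- m
    counts[t] <- max(m)
  }
  attr(out, "counts") <- counts
  out
}
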