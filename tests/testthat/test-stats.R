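test_that("the complete-cycle filter applies the relative-tracking predicate", {
  # hand-built forest: grandmother -> mother -> two daughters
  mk <- function(id, parent, daughters, division) {
    list(id = id, parent = parent, daughters = daughters,
         birth_frame = 1L, division_frame = division, status = "divided",
         frames = 1:2, centroid_y = c(1, 1), centroid_x = c(1, 1),
         length = c(10, 11), width = c(4, 4), area = c(40, 44),
         volume = c(1, 1), interpolated = c(FALSE, FALSE),
         sd_px = 20, septum_ratio = 0.5)
  }
  forest <- list(
    g = mk("g", NA_character_, c("m", "s"), 5L),
    m = mk("m", "g", c("d1", "d2"), 9L),
    s = mk("s", "g", character(), NA_integer_),
    d1 = mk("d1", "m", character(), NA_integer_),
    d2 = mk("d2", "m", character(), NA_integer_))
  class(forest) <- "mm_forest"
  kept <- filter_complete(forest)
  # only 'm' has a parent, a division, and two tracked daughters
  expect_identical(names(kept), "m")

  # the fixture's tracked filter agrees with a brute-force scan of the
  # ground-truth lineage table under the same predicate
  ex <- small_experiment()
  gcc <- gt_complete_cycles(ex$gt)
  cdf <- ex$gt$cells
  brute <- sum(vapply(seq_len(nrow(cdf)), function(i) {
    r <- cdf[i, ]
    if (is.na(r$parent) || is.na(r$division_frame)) return(FALSE)
    if (is.na(r$daughter1) || is.na(r$daughter2)) return(FALSE)
    obs <- function(id) {
      d <- cdf[cdf$id == id, ]
      d$last_frame >= d$birth_frame || d$fate == "divided"
    }
    obs(r$daughter1) && obs(r$daughter2)
  }, logical(1)))
  expect_equal(nrow(gcc), brute)
})

test_that("distribution summaries match closed forms", {
  expect_equal(summarize_distributions(rep(3, 10))$cv, 0)
  expect_error(summarize_distributions(c(1)), "at least 2")

  set.seed(12)
  v <- rlnorm(40000, meanlog = 1, sdlog = 0.2)
  s <- summarize_distributions(v)
  cv_true <- sqrt(exp(0.2^2) - 1)
  # CV sampling error at this n is well under 0.005
  expect_lt(abs(s$cv - cv_true), 0.005)

  # summaries are invariant to ordering
  expect_equal(summarize_distributions(rev(v))[, -1],
               s[, -1])
})

test_that("binned means reproduce known relationships", {
  set.seed(5)
  x <- runif(2000, 0, 10)
  bm <- binned_means(x, x, n_bins = 8)
  expect_equal(bm$mean, bm$bin_center, tolerance = 1e-12)
  expect_true(all(bm$n >= 20))

  y <- 2 * x + rnorm(2000, 0, 0.5)
  sl <- binned_slope(binned_means(x, y, n_bins = 8))
  expect_lt(abs(sl$slope - 2), 3 * sl$slope_se)

  expect_error(binned_means(rep(1, 100), rnorm(100)), "identical")
})

test_that("fluorescence measures are exact on painted cells and additive", {
  # one cell of known area with uniform fluorescence f
  m <- array(0L, c(30, 12, 2))
  m[8:19, 4:9, ] <- 1L
  f <- array(0, c(30, 12, 2))
  f[m == 1L] <- 0.5
  forest <- build_lineages(m)
  fl <- measure_fluorescence(forest, m, f)
  A <- sum(m[, , 1] == 1L)
  expect_equal(fl$integrated, rep(0.5 * A, 2))
  expect_equal(fl$per_area, rep(0.5, 2))

  # zero plane: all zero
  fl0 <- measure_fluorescence(forest, m, array(0, dim(m)))
  expect_true(all(fl0$integrated == 0))

  # additivity under mask partition
  top <- m; top[15:19, , ] <- 0L
  bot <- m; bot[8:14, , ] <- 0L
  s_top <- sum(f[, , 1][top[, , 1] == 1L])
  s_bot <- sum(f[, , 1][bot[, , 1] == 1L])
  expect_equal(s_top + s_bot, fl$integrated[1])

  expect_error(measure_fluorescence(forest, m, array(0, c(30, 12, 3))),
               "dimensions")
})

test_that("focus detection finds painted spots and respects the threshold", {
  set.seed(3)
  H <- 60; W <- 30
  img <- matrix(rnorm(H * W, 0.05, 0.01), H, W)
  spots <- rbind(c(15, 10), c(30, 20), c(45, 12))
  for (i in seq_len(nrow(spots))) {
    yy <- matrix(seq_len(H), H, W); xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    img <- img + 0.6 * exp(-((yy - spots[i, 1])^2 + (xx - spots[i, 2])^2) / (2 * 1.5^2))
  }
  mask <- matrix(0L, H, W)
  mask[10:20, 5:15] <- 1L
  mask[25:35, 15:25] <- 2L
  mask[40:50, 7:17] <- 3L

  foci <- detect_foci(img, mask, spot_sigma = 1.5, threshold = 5)
  expect_equal(nrow(foci), 3)
  for (i in 1:3) {
    d <- sqrt((foci$y - spots[i, 1])^2 + (foci$x - spots[i, 2])^2)
    j <- which.min(d)
    expect_lte(d[j], 1)
    expect_equal(foci$label[j], i)
  }

  # nothing painted: nothing found
  none <- detect_foci(matrix(rnorm(H * W, 0.05, 0.01), H, W), mask,
                      threshold = 5)
  expect_equal(nrow(none), 0)

  # raising the threshold never finds more foci
  lo <- detect_foci(img, mask, threshold = 3)
  hi <- detect_foci(img, mask, threshold = 8)
  expect_lte(nrow(hi), nrow(lo))
})
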