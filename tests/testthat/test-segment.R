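test_that("otsu threshold separates a two-point histogram", {
  img <- matrix(c(rep(0, 50), rep(100, 50)), 10, 10)
  th <- otsu_threshold(img)
  expect_gt(th, 0)
  expect_lt(th, 100)
  expect_identical(img > th, img == 100)
  expect_error(otsu_threshold(matrix(1, 5, 5)), "no contrast")
})

test_that("otsu threshold equals the exhaustive 256-level scan", {
  set.seed(42)
  for (case in 1:100) {
    n1 <- sample(50:200, 1); n2 <- sample(50:200, 1)
    img <- matrix(round(c(pmin(pmax(rnorm(n1, 30, 12), 0), 255),
                          pmin(pmax(rnorm(n2, 180, 20), 0), 255))),
                  nrow = 1)
    th <- otsu_threshold(img)
    expect_identical(img > th, oracle_otsu_foreground(img))
  }
})

test_that("classical steps (1)-(7) match the straight-line oracle pixel for pixel", {
  set.seed(8)
  p <- mm_params()
  for (case in 1:12) {
    # toy channel: 16 x 64, two or three bright rods on a dark background
    img <- matrix(rnorm(16 * 64, 0.05, 0.02), 64, 16)
    ncell <- sample(2:3, 1)
    tops <- sort(sample(seq(3, 40, by = 18), ncell))
    for (tp in tops) {
      h <- sample(10:14, 1)
      img[tp:(tp + h), 5:12] <- img[tp:(tp + h), 5:12] + 0.4
    }
    img <- pmin(pmax(img, 0), 1)
    mine <- segment_frame(img, p, refine = FALSE)
    theirs <- oracle_segment_steps(img, p)
    expect_identical(canonical_labels(mine), canonical_labels(theirs))
  }
})

test_that("the random walker is deterministic and recovers a seeded shape", {
  img <- matrix(0.05, 40, 20)
  img[10:30, 6:14] <- 0.6
  seeds <- matrix(0L, 40, 20)
  seeds[18:22, 9:11] <- 1L
  seeds[1:3, ] <- 2L
  a <- random_walker(img, seeds)
  b <- random_walker(img, seeds)
  expect_identical(a, b)
  expect_gt(mask_iou(a == 1, img > 0.3), 0.9)
  expect_error(random_walker(img, matrix(0L, 40, 20)), "seed")
  # all-seeded and single-class degenerate cases
  expect_identical(random_walker(img, seeds * 0L + 1L),
                   matrix(1L, 40, 20))
})

test_that("blank frames, specks, and well-separated cells behave as specified", {
  p <- mm_params()
  # blank frame: no regions
  expect_equal(max(segment_frame(matrix(0.2, 60, 16), p)), 0)

  # three well-separated synthetic cells, default parameters
  ex <- small_experiment()
  pipe <- small_pipeline()
  f <- pipe$subtracted[["1"]]$pixels[, , 1]
  gtc <- crop_channel_stacks(ex$masks, pipe$compile$boxes,
                             pipe$compile$shifts)[["1"]][, , 1]
  m <- segment_frame(f, p)
  expect_equal(max(m), length(setdiff(unique(as.vector(gtc)), 0)))
  for (id in setdiff(unique(as.vector(gtc)), 0)) {
    ious <- vapply(seq_len(max(m)), function(l) {
      mask_iou(m == l, gtc == id)
    }, numeric(1))
    expect_gt(max(ious), 0.8)
  }

  # a 4x4 speck (16 px^2 < the 25 px^2 minimum) never becomes a region
  bg_rows <- which(rowSums(gtc) == 0)
  r0 <- bg_rows[which(diff(bg_rows, lag = 3) == 3)[1]]
  sp <- f
  sp[r0:(r0 + 3), 7:10] <- max(f)
  m2 <- segment_frame(sp, p, refine = FALSE)
  expect_true(all(m2[r0:(r0 + 3), 7:10] == 0))
})

test_that("region filters honor size and border rules", {
  lab <- matrix(0L, 40, 20)
  lab[5:10, 5:10] <- 1L           # 36 px, interior: kept
  lab[20:22, 5:10] <- 2L          # 18 px < 25: dropped
  lab[30:40, 5:10] <- 3L          # touches the bottom border: dropped
  out <- mmpipe:::.filter_regions(lab, 25)
  expect_equal(sort(unique(as.vector(out))), c(0L, 1L))
  expect_true(all(out[5:10, 5:10] == 1L))
})

test_that("stacks segment deterministically and shrink with the threshold scale", {
  pipe <- small_pipeline()
  sub <- pipe$subtracted[["1"]]$pixels[, , 1:6]
  rep1 <- segment_stack(sub)
  rep2 <- segment_stack(sub)
  expect_identical(rep1, rep2)
  # identical frames give identical masks
  same <- array(rep(sub[, , 1], 3), c(dim(sub)[1:2], 3))
  ms <- segment_stack(same)
  expect_identical(ms[, , 1], ms[, , 2])
  expect_identical(ms[, , 2], ms[, , 3])
  # doubling the otsu scale never enlarges the binary foreground
  p2 <- mm_params(segment.otsu_scale = 2)
  for (t in 1:6) {
    th <- otsu_threshold(sub[, , t])
    expect_lte(sum(sub[, , t] > 2 * th), sum(sub[, , t] > th))
  }
  hi <- segment_stack(sub, p2)
  expect_true(all(apply(hi > 0, 3, sum) <= apply(rep1 > 0, 3, sum) + 1e-9))
})
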