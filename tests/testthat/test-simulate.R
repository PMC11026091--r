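test_that("noise-free adder sits at its fixed point", {
  # ln2/(lambda * dt) = 30 frames exactly, so cells born at the fixed point
  # double in exactly 60 min and split symmetrically
  sp <- sim_params(cv_delta = 0, cv_lambda = 0, septum_sd = 0,
                   mean_delta = 2, mean_lambda = log(2) / 60,
                   frame_interval = 2, seed = 3)
  gt <- simulate_lineages(sp, 2, 200)
  div <- gt$cells[gt$cells$fate == "divided" & !is.na(gt$cells$parent), ]
  expect_gt(nrow(div), 5)
  expect_true(all(abs(div$septum - 0.5) < 1e-12))
  # cells born at or above the fixed-point length divide at tau = ln2/lambda
  fp <- div[div$sb >= 2 - 1e-9, ]
  expect_gt(nrow(fp), 0)
  expect_true(all(abs(fp$tau - 60) < 1e-9))
  expect_true(all(abs(fp$sd - 2 * fp$sb) < 1e-9))
})

test_that("zero elongation rate yields no divisions and constant lengths", {
  sp <- sim_params(mean_lambda = 0, cv_lambda = 0, seed = 5)
  gt <- simulate_lineages(sp, 2, 30)
  expect_equal(sum(gt$cells$fate == "divided"), 0)
  for (id in gt$cells$id) {
    ln <- gt$frames$length[gt$frames$id == id]
    if (length(ln) > 1) expect_equal(diff(range(ln)), 0)
  }
})

test_that("per-cell added lengths follow the stated distribution", {
  # fine time resolution so the frame-quantization overshoot is negligible
  # relative to the Monte-Carlo standard error
  sp <- sim_params(cv_delta = 0.15, frame_interval = 0.25, seed = 11)
  gt <- simulate_lineages(sp, 60, 2000)
  cc <- gt_complete_cycles(gt)
  expect_gt(nrow(cc), 1000)
  se <- stats::sd(cc$delta) / sqrt(nrow(cc))
  expect_lt(abs(mean(cc$delta) - sp$mean_delta), 3 * se + 0.25 * sp$mean_lambda * max(cc$sd))
})

test_that("degenerate growth parameters are rejected", {
  sp <- sim_params(mean_lambda = 0.5, frame_interval = 2, seed = 1)
  expect_error(simulate_lineages(sp, 1, 10), "doubles per frame")
})

test_that("same seed reproduces the experiment exactly, different seeds differ", {
  sp <- sim_params(seed = 21)
  a <- simulate_lineages(sp, 3, 60)
  b <- simulate_lineages(sp, 3, 60)
  expect_identical(a$cells, b$cells)
  expect_identical(a$frames, b$frames)
  c3 <- simulate_lineages(sim_params(seed = 22), 3, 60)
  div_a <- a$cells$division_frame[!is.na(a$cells$division_frame)]
  div_c <- c3$cells$division_frame[!is.na(c3$cells$division_frame)]
  expect_false(identical(div_a, div_c))
})

test_that("length is conserved exactly at division", {
  sp <- sim_params(seed = 13)
  gt <- simulate_lineages(sp, 3, 150)
  div <- gt$cells[gt$cells$fate == "divided", ]
  for (i in seq_len(nrow(div))) {
    d1 <- gt$cells[gt$cells$id == div$daughter1[i], ]
    d2 <- gt$cells[gt$cells$id == div$daughter2[i], ]
    expect_equal(d1$sb + d2$sb, div$sd[i], tolerance = 1e-12)
    expect_equal(d1$birth_frame, div$division_frame[i])
    expect_equal(d2$birth_frame, div$division_frame[i])
  }
})

test_that("cells never overlap and never exchange order along the channel", {
  sp <- sim_params(seed = 17)
  gt <- simulate_lineages(sp, 2, 100)
  for (t in unique(gt$frames$frame)) {
    for (ch in 1:2) {
      fr <- gt$frames[gt$frames$frame == t & gt$frames$channel == ch, ]
      if (nrow(fr) < 2) next
      fr <- fr[order(fr$y0), ]
      expect_true(all(fr$y1[-nrow(fr)] <= fr$y0[-1] + 1e-12))
    }
  }
  # order: a cell's rank among coexisting cells never decreases/increases
  # between consecutive frames (positions are strictly stacked, so ranks
  # follow y0)
  prev <- NULL
  for (t in unique(gt$frames$frame)) {
    fr <- gt$frames[gt$frames$frame == t & gt$frames$channel == 1, ]
    fr <- fr[order(fr$y0), ]
    if (!is.null(prev)) {
      common <- intersect(prev$id, fr$id)
      if (length(common) > 1) {
        expect_identical(order(match(common, prev$id)),
                         order(match(common, fr$id)))
      }
    }
    prev <- fr
  }
})

test_that("renders are faithful: statics, drift, and oracle re-segmentation", {
  sp <- sim_params(seed = 9)
  gt <- simulate_lineages(sp, 3, 10, empty_channels = 3L)
  geom <- fov_geometry(sp, 3)

  # an empty channel renders identically across frames without noise
  a <- render_fov(gt, 1, geom, noise_sd = 0)
  b <- render_fov(gt, 2, geom, noise_sd = 0)
  cols <- geom$x0[3]:geom$x1[3]
  expect_identical(a[, cols], b[, cols])

  # a scripted drift shifts the scene content by exactly that offset
  d <- render_fov(gt, 1, geom, drift = c(3, -2), noise_sd = 0)
  inner_r <- 20:(geom$height - 20); inner_c <- 20:(geom$width - 20)
  expect_equal(d[inner_r - 2, inner_c + 3], a[inner_r, inner_c],
               tolerance = 1e-6)

  # independent threshold scan of the noiseless render (within each channel
  # interior) recovers the ground-truth masks at IoU > 0.8 per cell
  mask <- render_fov(gt, 5, geom, what = "mask")
  img <- render_fov(gt, 5, geom, noise_sd = 0)
  mid <- (geom$intensity[["cell"]] + geom$intensity[["interior"]]) / 2
  rows <- geom$y0:geom$y1
  for (ch in 1:2) {
    # central columns only: blur darkens the interior's outermost columns
    # toward the wall intensity, which a single global cut cannot separate
    cols <- (geom$x0[ch] + 2):(geom$x1[ch] - 2)
    sub <- img[rows, cols]
    msk <- mask[rows, cols]
    lab <- oracle_label(sub < mid)
    ids <- setdiff(unique(as.vector(msk)), 0)
    expect_gt(length(ids), 0)
    for (id in ids) {
      gtc <- msk == id
      hits <- lab[gtc]
      l <- as.integer(names(which.max(table(hits[hits > 0]))))
      expect_gt(mask_iou(lab == l, gtc), 0.8)
    }
  }
})
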