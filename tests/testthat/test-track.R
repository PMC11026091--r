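test_that("region measurement matches constructed geometry", {
  m <- matrix(0L, 30, 20)
  m[5:14, 3:6] <- 1L              # 10 x 4 rod
  r <- extract_regions(m)
  expect_equal(r$length, 10)
  expect_equal(r$width, 4)
  expect_equal(r$area, 40)
  expect_equal(r$centroid_y, 9.5)

  # capsule volume: l = 4, w = 2 gives 10*pi/3
  m2 <- matrix(0L, 10, 10)
  m2[3:6, 4:5] <- 1L
  r2 <- extract_regions(m2)
  expect_equal(r2$volume, 10 * pi / 3, tolerance = 1e-12)

  # sphere limit: l = w
  m3 <- matrix(0L, 10, 10)
  m3[3:6, 3:6] <- 1L
  r3 <- extract_regions(m3)
  expect_equal(r3$volume, 4 / 3 * pi * (r3$width / 2)^3, tolerance = 1e-12)

  # empty frame
  expect_equal(nrow(extract_regions(matrix(0L, 5, 5))), 0)

  # regions come out ordered by centroid y
  m4 <- matrix(0L, 40, 10)
  m4[25:30, 2:8] <- 1L
  m4[5:10, 2:8] <- 2L
  r4 <- extract_regions(m4)
  expect_equal(r4$label, c(2L, 1L))
})

test_that("frame linking follows the growth and division rules", {
  p <- mm_params()
  reg <- function(len, y) data.frame(label = 1, centroid_y = y,
                                     centroid_x = 5, length = len,
                                     width = 4, area = len * 4,
                                     volume = 0)
  # growth: 10 px -> 12 px, ratio 1.2 inside (0.8, 1.3)
  act <- data.frame(id = "a", centroid_y = 10, length = 10, area = 40,
                    missed = 0L)
  lk <- link_frame(act, reg(12, 10), p)
  expect_equal(lk$cell_match[[1]]$type, "growth")

  # division: 20 px -> 9 + 11 px (sum ratio 1.0, fractions 0.45/0.55)
  act2 <- data.frame(id = "a", centroid_y = 10, length = 20, area = 80,
                     missed = 0L)
  regs2 <- rbind(reg(9, 6), reg(11, 16))
  lk2 <- link_frame(act2, regs2, p)
  expect_equal(lk2$cell_match[[1]]$type, "division")
  expect_equal(lk2$cell_match[[1]]$regions, c(1L, 2L))

  # a lone half-size region is no valid continuation
  lk3 <- link_frame(act, reg(5, 10), p)
  expect_equal(lk3$cell_match[[1]]$type, "lost")
  # ... and the orphan region within the y-cutoff becomes a new cell
  expect_equal(lk3$new_cells, 1L)
  # ... but beyond the cutoff it is discarded
  lk4 <- link_frame(act, reg(5, p$track$new_cell_y_cutoff + 5), p)
  expect_equal(lk4$discarded, 1L)
})

test_that("lineages built from noiseless ground-truth masks match the truth", {
  sp <- sim_params(seed = 31)
  gt <- simulate_lineages(sp, 1, 90)
  geom <- fov_geometry(sp, 1)
  masks <- array(0L, c(geom$height, geom$width, 90))
  for (t in 1:90) masks[, , t] <- render_fov(gt, t, geom, what = "mask")
  forest <- build_lineages(masks, channel = 1L)
  # every ground-truth division appears at the exact frame
  iso <- match_lineages(forest, gt, frame_tol = 0L)
  expect_gt(iso$n_gt, 2)
  expect_equal(iso$n_matched, iso$n_gt)
  # parent/daughter invariants
  for (cell in forest) {
    expect_true(length(cell$daughters) %in% c(0L, 2L))
    if (length(cell$daughters) == 2L) {
      for (d in cell$daughters) {
        expect_equal(forest[[d]]$birth_frame, cell$division_frame)
        expect_equal(forest[[d]]$parent, cell$id)
      }
    }
    expect_equal(cell$frames, seq(cell$frames[1], cell$frames[length(cell$frames)]))
  }
})

test_that("static and disappearing cells get the right status", {
  # one static cell to the end of the stack
  m <- array(0L, c(40, 12, 6))
  m[10:25, 4:9, ] <- 1L
  f <- build_lineages(m)
  expect_equal(length(f), 1L)
  expect_equal(f[[1]]$status, "end")
  expect_equal(length(f[[1]]$daughters), 0L)

  # the cell vanishes at frame 4 and never returns: lost, last seen frame 3
  m2 <- m
  m2[, , 4:6] <- 0L
  f2 <- build_lineages(m2)
  expect_equal(f2[[1]]$status, "lost")
  expect_equal(max(f2[[1]]$frames), 3)

  # a short gap within the lost-cell window is bridged and interpolated
  m3 <- m
  m3[, , 3] <- 0L
  f3 <- build_lineages(m3)
  expect_equal(length(f3), 1L)
  expect_equal(f3[[1]]$frames, 1:6)
  expect_true(f3[[1]]$interpolated[3])
  expect_equal(f3[[1]]$status, "end")
})

test_that("cell-cycle statistics are exact on constructed records", {
  cal <- list(pixel_size = 1, frame_interval = 1)
  # exact exponential: doubling in 60 min sampled every minute
  lengths <- 10 * 2^((0:59) / 60)
  cell <- list(id = "x", parent = "p", daughters = c("d1", "d2"),
               birth_frame = 1L, division_frame = 61L, status = "divided",
               frames = 1:60, centroid_y = rep(1, 60), centroid_x = rep(1, 60),
               length = lengths, width = rep(4, 60), area = rep(40, 60),
               volume = rep(1, 60), interpolated = rep(FALSE, 60),
               sd_px = 20, septum_ratio = 0.5)
  st <- compute_cell_cycle(cell, cal)
  expect_equal(st$lambda, log(2) / 60, tolerance = 1e-12)
  expect_equal(st$tau, 60)
  expect_equal(st$sb, 10)
  expect_equal(st$sd, 20)
  expect_equal(st$delta, 10)
  expect_true(st$complete)

  # constant length: zero elongation rate
  cell$length <- rep(10, 60)
  expect_equal(compute_cell_cycle(cell, cal)$lambda, 0)

  # noisy exponential: equals an independent least-squares fit to 1e-12
  set.seed(99)
  cell$length <- 10 * exp(0.01 * (1:60)) * exp(rnorm(60, 0, 0.05))
  lam <- compute_cell_cycle(cell, cal)$lambda
  expect_equal(lam, oracle_loglinear_slope(1:60, cell$length),
               tolerance = 1e-12)

  # incomplete cycle: lambda still fitted, the rest NA
  cell$division_frame <- NA_integer_
  st2 <- compute_cell_cycle(cell, cal)
  expect_false(is.na(st2$lambda))
  expect_true(is.na(st2$sd) && is.na(st2$tau) && is.na(st2$delta))
})

test_that("tracking invariants hold on a segmented fixture", {
  pipe <- small_pipeline()
  forest <- pipe$cells
  ids <- names(forest)
  # records are keyed by their ids
  expect_identical(ids, unname(vapply(forest, `[[`, character(1), "id")))
  used_regions <- list()
  for (cell in forest) {
    # parent/daughter cardinality and back-links
    expect_true(length(cell$daughters) %in% c(0L, 2L))
    if (!is.na(cell$parent)) {
      expect_true(cell$id %in% forest[[cell$parent]]$daughters)
    }
    if (length(cell$daughters) == 2L) {
      expect_false(is.na(cell$division_frame))
      for (d in cell$daughters) {
        expect_equal(forest[[d]]$birth_frame, cell$division_frame)
      }
    }
    # contiguous observations
    expect_equal(cell$frames,
                 seq(cell$frames[1], cell$frames[length(cell$frames)]))
  }
  # no two cells share a region: (channel, frame, centroid) occupancy is
  # unique across the forest
  occ <- do.call(rbind, lapply(forest, function(cell) {
    k <- !cell$interpolated
    data.frame(channel = sub("^f\\d+(c\\d+)t.*$", "\\1", cell$id),
               frame = cell$frames[k],
               y = round(cell$centroid_y[k], 1))
  }))
  expect_false(any(duplicated(occ)))
  # order preservation: y-ranks of coexisting cells never swap
  ch_of <- function(id) sub("^f\\d+(c\\d+)t.*$", "\\1", id)
  for (ch in unique(vapply(ids, ch_of, character(1)))) {
    sub_ids <- ids[vapply(ids, ch_of, character(1)) == ch]
    Tn <- attr(forest, "n_frames")
    prev <- NULL
    for (t in seq_len(Tn)) {
      pres <- list()
      for (id in sub_ids) {
        cell <- forest[[id]]
        k <- match(t, cell$frames)
        if (!is.na(k) && !cell$interpolated[k]) pres[[id]] <- cell$centroid_y[k]
      }
      if (length(pres) > 1) {
        cur <- names(sort(unlist(pres)))
        if (!is.null(prev)) {
          common <- intersect(prev, cur)
          if (length(common) > 1) {
            expect_identical(common[order(match(common, prev))],
                             common[order(match(common, cur))])
          }
        }
        prev <- cur
      }
    }
  }
})
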