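test_that("z partition splits 12 slices into 7 + 5 without overlap", {
  st <- array(seq_len(12 * 4 * 4), c(12, 4, 4))
  zp <- z_partition(st)
  expect_equal(zp$n_bottom, 7)
  expect_equal(zp$n_top, 5)
  expect_equal(zp$bottom, apply(st[1:7, , ], c(2, 3), max))
  expect_equal(zp$top, apply(st[8:12, , ], c(2, 3), max))
  zpm <- z_partition(st, method = "mean")
  expect_equal(zpm$bottom, colMeans(st[1:7, , ], dims = 1))
  expect_error(z_partition(st, bottom_slices = 12), "partitions")
})

test_that("nucleus detection finds rendered nuclei within a pixel", {
  expect_equal(nrow(detect_nuclei(matrix(0, 50, 50))), 0)

  m <- small_model()
  im <- tiny_imaging(pixel_size = 1.66, fov = c(120, 90), n_slices = 6)
  place <- data.frame(x = c(40, 90), y = c(30, 60))
  cells <- data.frame(id = 1:2, x = place$x, y = place$y, z = 6,
                      diameter = 15, nucleus_diameter = 8,
                      brightness_nuclei = 1, brightness_cytoplasm = 0.5,
                      chamber_id = 1, unit = 1, in_niche = FALSE)
  tl <- simulate_timelapse(m, cells, motion_spec(step_scale = 0), im,
                           seed = 3, render = TRUE)
  proj <- z_partition(tl$frames[[1]], bottom_slices = 3)$bottom
  det <- detect_nuclei(proj, pixel_size = im$pixel_size)
  expect_equal(nrow(det), 2)
  got <- det[order(det$x_px), ]
  expect_lt(max(abs(got$x_px * im$pixel_size - place$x)), 1.66)
  expect_lt(max(abs(got$y_px * im$pixel_size - place$y)), 1.66)
})

test_that("greedy linking follows constructed step sequences exactly", {
  cfg <- tracking_config(N = 10, pixel_size = 1.66)
  # one stationary cell across 6 timepoints
  det <- replicate(6, data.frame(x_px = 5, y_px = 5), simplify = FALSE)
  ts <- link_tracks(det, cfg)
  expect_equal(nrow(ts$tracks), 1)
  expect_equal(ts$tracks$total_px, 0)
  # 3 px per frame for 5 steps: 15 px = 24.9 um
  det <- lapply(0:5, function(t) data.frame(x_px = 5 + 3 * t, y_px = 5))
  ts <- link_tracks(det, cfg)
  expect_equal(ts$tracks$total_px, 15)
  expect_equal(ts$tracks$total_um, 24.9)
  expect_equal(ts$tracks$n_points, 6)
})

test_that("a jump beyond N terminates the track and short tracks drop", {
  cfg <- tracking_config(N = 10)
  # jump of N + 1 px between t = 2 and t = 3 splits a 6-point trajectory
  # into fragments of 3 + 3, both below the 5-point minimum
  xs <- c(0, 3, 6, 6 + 11, 6 + 14, 6 + 17)
  det <- lapply(xs, function(x) data.frame(x_px = x, y_px = 0))
  ts <- link_tracks(det, cfg)
  expect_equal(nrow(ts$tracks), 0)
  # with a lower minimum both fragments appear, pass 1 then pass 2
  cfg3 <- tracking_config(N = 10, min_track_points = 3)
  ts3 <- link_tracks(det, cfg3)
  expect_equal(nrow(ts3$tracks), 2)
  expect_equal(sort(ts3$tracks$pass), c(1L, 2L))
  expect_equal(ts3$tracks$n_points, c(3L, 3L))
})

test_that("claims are exclusive and steps never exceed N", {
  set.seed(6)
  cfg <- tracking_config(N = 8, min_track_points = 3)
  det <- lapply(1:6, function(t) {
    data.frame(x_px = stats::runif(12, 0, 60), y_px = stats::runif(12, 0, 60))
  })
  ts <- link_tracks(det, cfg)
  if (nrow(ts$tracks)) {
    expect_true(all(ts$points$step_px <= cfg$N + 1e-12))
    # no detection claimed twice: points are unique per (t, x, y)
    key <- paste(ts$points$t, ts$points$x_px, ts$points$y_px)
    expect_equal(anyDuplicated(key), 0)
    expect_lte(nrow(ts$points), 6 * 12)
  }
  # determinism
  expect_identical(link_tracks(det, cfg), link_tracks(det, cfg))
})

test_that("greedy linking matches the exhaustive assignment oracle", {
  cfg <- tracking_config(N = 10)
  # five well-separated cells (> 2N apart at all timepoints) drifting
  set.seed(2)
  base <- cbind(x = c(10, 60, 110, 160, 210), y = c(10, 80, 20, 90, 30))
  det <- lapply(0:5, function(t) {
    drift <- matrix(stats::runif(10, -4, 4), 5)
    data.frame(x_px = base[, 1] + t * 2 + drift[, 1],
               y_px = base[, 2] + drift[, 2])
  })
  ts <- link_tracks(det, cfg)
  expect_equal(nrow(ts$tracks), 5)
  oracle <- oracle_assignment_tracks(lapply(det, as.matrix), N = 10)
  expect_false(is.null(oracle))
  # same positions claimed per track, same totals
  oracle_tot <- sort(vapply(oracle, function(tr) {
    sum(sqrt(rowSums(diff(tr)^2)))
  }, numeric(1)))
  expect_equal(sort(ts$tracks$total_px), oracle_tot, tolerance = 1e-9)
  # and the greedy result is globally optimal in summed distance
  expect_equal(sum(ts$tracks$total_px), sum(oracle_tot), tolerance = 1e-9)
})

test_that("kernel radius converts to micrometres", {
  expect_equal(kernel_to_um(10, 1.66), 16.6)
  expect_equal(kernel_to_um(1, 1), 1)
  expect_equal(kernel_to_um(2, 1.66), 3.32)
  expect_error(kernel_to_um(0), "> 0")
})

test_that("gradient maps deposit track totals and clip at the display max", {
  cfg <- tracking_config(N = 10, min_track_points = 3)
  empty <- link_tracks(replicate(3, data.frame(x_px = numeric(0),
                                               y_px = numeric(0)),
                                 simplify = FALSE), cfg)
  gm0 <- render_gradient_map(empty, c(40, 40))
  expect_true(all(gm0$field == 0))

  one <- lapply(0:2, function(t) data.frame(x_px = 20 + 3 * t, y_px = 20))
  ts1 <- link_tracks(one, cfg)
  d1 <- ts1$tracks$total_um
  gm1 <- render_gradient_map(ts1, c(40, 40), display_max = 30)
  expect_equal(max(gm1$field), min(d1, 30), tolerance = 1e-9)

  # two overlapping tracks combine by maximum
  two <- lapply(0:2, function(t) {
    data.frame(x_px = c(20 + 3 * t, 20 + 6 * t), y_px = c(20, 20.5))
  })
  ts2 <- link_tracks(two, cfg)
  d <- sort(ts2$tracks$total_um)
  gm2 <- render_gradient_map(ts2, c(40, 40), display_max = 30)
  expect_equal(max(gm2$field), min(max(d), 30), tolerance = 1e-9)
  # clipping at display_max
  gm3 <- render_gradient_map(ts2, c(40, 40), display_max = 5)
  expect_equal(max(gm3$field), 5, tolerance = 1e-9)
})

test_that("motility summary assigns regions and orders motilities", {
  m <- small_model(separations = c(20, 35))
  im <- tiny_imaging(pixel_size = 1.66)
  mask <- rasterize_scaffold(m, 1.66)
  cells <- place_cells(m, 24, seed = 14, diameter = 8, nucleus_diameter = 4)
  ms <- motion_spec(step_scale = c("20" = 1, "35" = 6))
  tl <- simulate_timelapse(m, cells, ms, im, seed = 9, render = FALSE)
  # build detections from ground truth and link
  det <- lapply(sort(unique(tl$tracks$t)), function(t) {
    tr <- tl$tracks[tl$tracks$t == t, ]
    data.frame(x_px = tr$x / 1.66, y_px = tr$y / 1.66)
  })
  ts <- link_tracks(det, tracking_config(N = 10))
  out <- summarize_motility(ts, m, mask)
  expect_true(all(out$region %in% c("20", "35", "control")))
  m20 <- out$mean_total_um[out$region == "20"]
  m35 <- out$mean_total_um[out$region == "35"]
  expect_lt(m20, m35)   # region-dependent motility recovered in order
  expect_true(all(out$niche_fraction >= 0 & out$niche_fraction <= 1))

  # stationary tracks in niches: fraction 1, distance 0
  nich <- place_cells(m, 10, niche_bias = 1, seed = 3, diameter = 8,
                      nucleus_diameter = 4)
  tl0 <- simulate_timelapse(m, nich, motion_spec(step_scale = 0), im,
                            seed = 1, render = FALSE)
  det0 <- lapply(0:5, function(t) {
    tr <- tl0$tracks[tl0$tracks$t == t, ]
    data.frame(x_px = tr$x / 1.66, y_px = tr$y / 1.66)
  })
  out0 <- summarize_motility(link_tracks(det0, tracking_config()), m, mask)
  expect_true(all(out0$mean_total_um == 0))
  # niche membership is read off the 1.66 um mask, so boundary centres can
  # quantize out of the zone
  expect_gt(sum(out0$n_tracks * out0$niche_fraction) / sum(out0$n_tracks), 0.7)
})

test_that("frame alignment recovers injected integer shifts", {
  m <- small_model()
  mask <- rasterize_scaffold(m, 1.66)
  ref <- (mask$grid == 1L) * 1
  shift_im <- function(img, dy, dx) {
    out <- matrix(0, nrow(img), ncol(img))
    src_r <- seq_len(nrow(img)) + dy
    src_c <- seq_len(ncol(img)) + dx
    ok_r <- src_r >= 1 & src_r <= nrow(img)
    ok_c <- src_c >= 1 & src_c <= ncol(img)
    out[which(ok_r), which(ok_c)] <- img[src_r[ok_r], src_c[ok_c]]
    out
  }
  frames <- list(shift_im(ref, 3, -2), shift_im(ref, -5, 4), ref)
  al <- align_frames(frames, ref, max_shift = 10)
  expect_equal(unname(al$shifts),
               matrix(c(-3L, 2L, 5L, -4L, 0L, 0L), 3, byrow = TRUE),
               ignore_attr = TRUE)
  # de-shifted frames agree with the reference away from vacated margins
  inner_r <- 11:(nrow(ref) - 10); inner_c <- 11:(ncol(ref) - 10)
  for (i in 1:2) {
    expect_equal(al$aligned[[i]][inner_r, inner_c], ref[inner_r, inner_c])
  }
})

test_that("tracking config validates its bounds", {
  expect_error(tracking_config(N = 0), "N must be")
  expect_error(tracking_config(min_track_points = 7, n_timepoints = 6),
               "min_track_points")
})
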