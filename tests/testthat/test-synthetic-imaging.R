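test_that("cell placement is seeded, wall-avoiding and bias-aware", {
  m <- small_model()
  a <- place_cells(m, 40, niche_bias = 0.5, seed = 9)
  b <- place_cells(m, 40, niche_bias = 0.5, seed = 9)
  expect_identical(a, b)                       # determinism
  d <- place_cells(m, 40, niche_bias = 0.5, seed = 10)
  expect_false(identical(a, d))

  # no centre on wall material, no overlapping pair
  for (i in seq_len(nrow(a))) {
    expect_false(nichemetry:::on_wall_material(m, a$x[i], a$y[i]))
  }
  dd <- as.matrix(stats::dist(a[, c("x", "y", "z")]))
  diag(dd) <- Inf
  expect_true(min(dd) >= a$diameter[1])

  # niche_bias = 1 puts every centre within the contact zone
  n1 <- place_cells(m, 30, niche_bias = 1, seed = 2)
  wall_y <- m$walls$y
  dist_wall <- vapply(n1$y, function(y) min(abs(y - wall_y)), numeric(1))
  expect_true(all(dist_wall <= m$params$niche_depth))
  expect_true(all(n1$in_niche))

  expect_error(place_cells(m, 10, niche_bias = 2), "niche_bias")
  expect_error(place_cells(m, 10, nucleus_diameter = 20), "smaller")
  # an impossible packing request fails after bounded retries
  expect_error(place_cells(m, 2000, seed = 1, max_tries = 10),
               "non-overlapping")
})

test_that("uniform placement matches the isotropic zone probability", {
  m <- small_model(separations = c(20, 35))
  nd <- m$params$niche_depth; th <- m$params$line_thickness
  cells <- place_cells(m, 600, niche_bias = 0, seed = 31, diameter = 4,
                       nucleus_diameter = 2)
  sep <- m$chambers$wall_separation[match(cells$chamber_id, m$chambers$id)]
  for (s in c(20, 35)) {
    sel <- sep == s
    # occupiable zone fraction given centres keep off the wall material
    p <- 2 * (nd - th / 2) / (s - th)
    phat <- mean(cells$in_niche[sel])
    n <- sum(sel)
    expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("rendering is linear in sources and mass-conserving at walls", {
  m <- small_model()
  im <- tiny_imaging(fov = c(220, 96), n_slices = 12)
  ems <- default_endmembers()
  ca <- place_cells(m, 3, seed = 1, diameter = 8, nucleus_diameter = 4)
  cb <- place_cells(m, 3, seed = 2, diameter = 8, nucleus_diameter = 4)
  cb$id <- cb$id + 3
  s_a <- render_stack(m, ca, ems, im, noise = FALSE)
  s_b <- render_stack(m, cb, ems, im, noise = FALSE)
  s_ab <- render_stack(m, rbind(ca, cb), ems, im, noise = FALSE)
  s_0 <- render_stack(m, NULL, ems, im, noise = FALSE)
  expect_equal(s_ab$data, s_a$data + s_b$data - s_0$data, tolerance = 1e-10)

  # nuclei mass is conserved: sum over the stack equals the nuclear volume
  # in voxel units times brightness, regardless of wall clipping
  vx <- im$pixel_size^2 * im$z_step
  expected <- nrow(ca) * (4 / 3) * pi * 4^3 / vx * ca$brightness_nuclei[1]
  expect_equal(sum(s_a$truth$nuclei), expected, tolerance = 0.02 * expected)
  # and no nuclear mass sits on wall material
  wall <- s_a$mask$grid == 1L
  for (k in seq_len(im$n_slices)) {
    expect_true(all(s_a$truth$nuclei[k, , ][wall] == 0))
  }
})

test_that("noiseless stacks contain only the expected spectra", {
  m <- small_model()
  im <- tiny_imaging(fov = c(60, 60), n_slices = 4)
  ems <- default_endmembers()
  st <- render_stack(m, NULL, ems, im, noise = FALSE, background_level = 0)
  # every non-background voxel spectrum is proportional to the scaffold line
  wall <- which(st$mask$grid == 1L, arr.ind = TRUE)
  spec <- st$data[1, , wall[1, 1], wall[1, 2]]
  expect_equal(spec / sum(spec), ems$scaffold$weights, tolerance = 1e-12)
  off <- which(st$mask$grid == 0L, arr.ind = TRUE)
  expect_equal(st$data[1, , off[1, 1], off[1, 2]], rep(0, 32))

  # a single cell: nuclei signal inside the nucleus, none outside the cell
  cells <- data.frame(id = 1, x = 30, y = 30, z = 4, diameter = 10,
                      nucleus_diameter = 5, brightness_nuclei = 1,
                      brightness_cytoplasm = 0.5, chamber_id = 1, unit = 1,
                      in_niche = FALSE)
  st1 <- render_stack(m, cells, ems, im, noise = FALSE, background_level = 0)
  centre <- st1$truth$nuclei[2, 30, 30]
  expect_gt(centre, 0)
  expect_equal(st1$truth$nuclei[2, 30, 50], 0)
  expect_equal(st1$truth$cytoplasm[2, 30, 50], 0)
})

test_that("rendered stacks are reproducible from config plus seed", {
  m <- small_model()
  im <- tiny_imaging()
  cells <- place_cells(m, 5, seed = 4, diameter = 8, nucleus_diameter = 4)
  s1 <- render_stack(m, cells, default_endmembers(), im, seed = 77)
  s2 <- render_stack(m, cells, default_endmembers(), im, seed = 77)
  expect_identical(s1$data, s2$data)
  expect_true(all(is.finite(s1$data)))
})

test_that("timelapse ground truth respects the motion spec", {
  m <- small_model()
  im <- tiny_imaging()
  cells <- place_cells(m, 8, seed = 3, diameter = 8, nucleus_diameter = 4)

  # zero step scale: everything stationary
  tl0 <- simulate_timelapse(m, cells, motion_spec(step_scale = 0), im,
                            seed = 1, render = FALSE)
  disp <- tapply(seq_len(nrow(tl0$tracks)), tl0$tracks$cell_id, function(i) {
    sum(sqrt(diff(tl0$tracks$x[i])^2 + diff(tl0$tracks$y[i])^2))
  })
  expect_true(all(disp == 0))

  # positions never on wall material, at every timepoint
  tl <- simulate_timelapse(m, cells, motion_spec(step_scale = 6), im,
                           seed = 2, render = FALSE)
  on_wall <- mapply(function(x, y) nichemetry:::on_wall_material(m, x, y),
                    tl$tracks$x, tl$tracks$y)
  expect_false(any(on_wall))
  # determinism
  tl2 <- simulate_timelapse(m, cells, motion_spec(step_scale = 6), im,
                            seed = 2, render = FALSE)
  expect_identical(tl$tracks, tl2$tracks)
})

test_that("free-space steps have the configured mean displacement", {
  # one huge chamber acts as a free 2D region
  m <- build_scaffold(scaffold_params(
    n_sets = 1, walls_per_set = 2, units_per_wall = 1,
    unit_wall_length = 210, niche_sections = 210, wall_separations = 200,
    cross_wall_length = 0, cross_wall_half = 0, total_depth = NULL))
  im <- tiny_imaging(fov = c(210, 200))
  cells <- place_cells(m, 60, seed = 8, diameter = 6, nucleus_diameter = 3)
  set.seed(99)
  cells$x <- stats::runif(60, 60, 150); cells$y <- stats::runif(60, 60, 140)
  s <- 5
  tl <- simulate_timelapse(m, cells, motion_spec(step_scale = s,
                                                 wall_blocking = FALSE),
                           im, seed = 12, render = FALSE)
  steps <- unlist(tapply(seq_len(nrow(tl$tracks)), tl$tracks$cell_id,
                         function(i) sqrt(diff(tl$tracks$x[i])^2 +
                                            diff(tl$tracks$y[i])^2)))
  n <- length(steps)
  sd_step <- s * sqrt(2 / pi) * sqrt(2 - pi / 2)   # Rayleigh sd
  expect_lt(abs(mean(steps) - s), 4 * sd_step / sqrt(n))
})

test_that("wall blocking truncates displacements against free motion", {
  m <- small_model(separations = c(20, 35))
  im <- tiny_imaging()
  cells <- place_cells(m, 25, seed = 21, diameter = 8, nucleus_diameter = 4)
  big <- motion_spec(step_scale = 15)
  free <- motion_spec(step_scale = 15, wall_blocking = FALSE)
  tl_b <- simulate_timelapse(m, cells, big, im, seed = 5, render = FALSE)
  tl_f <- simulate_timelapse(m, cells, free, im, seed = 5, render = FALSE)
  span <- function(tr) tapply(tr$y, tr$cell_id, function(y) diff(range(y)))
  # cross-wall y excursions are bounded by the chamber in the blocked walk
  expect_lt(mean(span(tl_b$tracks)), mean(span(tl_f$tracks)))
})

test_that("region-dependent step scales are honoured", {
  m <- small_model(separations = c(20, 35))
  im <- tiny_imaging()
  cells <- place_cells(m, 30, seed = 6, diameter = 8, nucleus_diameter = 4)
  ms <- motion_spec(step_scale = c("20" = 1, "35" = 8))
  tl <- simulate_timelapse(m, cells, ms, im, seed = 3, render = FALSE)
  tot <- tapply(seq_len(nrow(tl$tracks)), tl$tracks$cell_id, function(i) {
    sum(sqrt(diff(tl$tracks$x[i])^2 + diff(tl$tracks$y[i])^2))
  })
  sep <- tapply(tl$tracks$wall_separation, tl$tracks$cell_id, `[`, 1)
  expect_lt(mean(tot[sep == 20]), mean(tot[sep == 35]))
  bad <- motion_spec(step_scale = c("99" = 1))
  expect_error(simulate_timelapse(m, cells, bad, im, render = FALSE),
               "no entry")
})
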