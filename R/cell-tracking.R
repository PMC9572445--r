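#' Tracking configuration
#'
#' Settings of the radius-kernel greedy nucleus tracker: the movement
#' kernel `N` is the radius (in pixels) within which a tracked nucleus must
#' be found at the next timepoint.
#'
#' @param N Movement kernel radius in pixels (default 10, i.e. 16.6 µm at
#'   1.66 µm/px — about one cell diameter).
#' @param pixel_size Pixel size (µm/px).
#' @param n_passes Number of linking passes; later passes re-seed from
#'   detections not claimed earlier.
#' @param min_track_points Minimum number of consecutive timepoints a track
#'   must span to be kept.
#' @param n_timepoints Number of timepoints in the series.
#' @return An object of class `tracking_config`.
#' @export
tracking_config <- function(N = 10, pixel_size = 1.66, n_passes = 2,
                            min_track_points = 5, n_timepoints = 6) {
  if (N < 1) stop("tracking_config: N must be >= 1", call. = FALSE)
  if (min_track_points > n_timepoints) {
    stop("tracking_config: min_track_points must be <= n_timepoints", call. = FALSE)
  }
  structure(list(N = N, pixel_size = pixel_size, n_passes = as.integer(n_passes),
                 min_track_points = as.integer(min_track_points),
                 n_timepoints = as.integer(n_timepoints)),
            class = "tracking_config")
}

#' Movement kernel radius in micrometres
#'
#' @param N Kernel radius in pixels.
#' @param pixel_size Pixel size (µm/px).
#' @return `N * pixel_size` in µm.
#' @examples
#' kernel_to_um(10, 1.66)  # 16.6
#' @export
kernel_to_um <- function(N, pixel_size = 1.66) {
  if (any(N <= 0) || any(pixel_size <= 0)) {
    stop("kernel_to_um: N and pixel_size must be > 0", call. = FALSE)
  }
  N * pixel_size
}

#' Partition a Z stack into bottom and top projections
#'
#' Splits a Z x Y x X stack into a bottom part (first `bottom_slices`
#' slices — with the 12-slice default acquisition, 7 slices = 14 µm, the
#' average cell size) and a top part (the remaining slices), and projects
#' each to a single 2D image.
#'
#' @param stack Numeric Z x Y x X array.
#' @param bottom_slices Number of slices in the bottom partition.
#' @param method Projection operator, `"max"` (default) or `"mean"`.
#' @return List with 2D matrices `bottom` and `top` and the slice counts.
#' @export
z_partition <- function(stack, bottom_slices = 7, method = c("max", "mean")) {
  method <- match.arg(method)
  d <- dim(stack)
  if (length(d) != 3) stop("z_partition: stack must be Z x Y x X", call. = FALSE)
  if (bottom_slices < 1 || bottom_slices >= d[1]) {
    stop("z_partition: bottom_slices must leave both partitions non-empty",
         call. = FALSE)
  }
  proj <- function(sl) {
    sub <- stack[sl, , , drop = FALSE]
    if (method == "max") apply(sub, c(2, 3), max) else colMeans(sub, dims = 1)
  }
  list(bottom = proj(seq_len(bottom_slices)),
       top = proj((bottom_slices + 1):d[1]),
       n_bottom = bottom_slices, n_top = d[1] - bottom_slices,
       method = method)
}

#' Detect nucleus centroids in a projection image
#'
#' Gaussian smoothing, Otsu thresholding, connected-component labelling and
#' an area filter derived from the nominal nucleus size, followed by
#' intensity-weighted centroids. Deterministic.
#'
#' @param image 2D numeric matrix (rows = Y, cols = X).
#' @param pixel_size Pixel size (µm/px).
#' @param nucleus_diameter Nominal nucleus diameter (µm) used for the
#'   component area window.
#' @param smooth_sigma Gaussian smoothing sigma in pixels.
#' @param area_range Component area window in pixels; default
#'   `c(0.2, 6) *` the nominal nucleus cross-section (the upper factor
#'   admits small clusters of touching nuclei).
#' @return data.frame with `x_px`, `y_px` (pixel units, pixel centre at
#'   index - 0.5) sorted by detection (label) order; zero rows when nothing
#'   is found.
#' @export
detect_nuclei <- function(image, pixel_size = 1.66, nucleus_diameter = 8,
                          smooth_sigma = 1, area_range = NULL) {
  if (!is.matrix(image) || !length(image)) {
    stop("detect_nuclei: image must be a non-empty matrix", call. = FALSE)
  }
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0))
  rng <- range(image)
  if (rng[2] <= rng[1]) return(empty)
  im <- (image - rng[1]) / (rng[2] - rng[1])
  if (smooth_sigma > 0) im <- EBImage::gblur(im, sigma = smooth_sigma)
  th <- EBImage::otsu(EBImage::Image(im))
  bw <- im > th
  lab <- EBImage::bwlabel(bw)
  nlab <- max(lab)
  if (nlab == 0) return(empty)
  nominal <- pi * (nucleus_diameter / 2 / pixel_size)^2
  if (is.null(area_range)) area_range <- c(0.2, 6) * nominal
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  w <- image[lab > 0]
  areas <- tabulate(labs, nbins = nlab)
  keep <- which(areas >= area_range[1] & areas <= area_range[2])
  if (!length(keep)) return(empty)
  sw <- tapply(w, labs, sum)
  sx <- tapply(w * (idx[, 2] - 0.5), labs, sum)
  sy <- tapply(w * (idx[, 1] - 0.5), labs, sum)
  out <- data.frame(x_px = as.numeric(sx / sw)[keep],
                    y_px = as.numeric(sy / sw)[keep])
  out[order(keep), , drop = FALSE]
}

#' Link detections into tracks with a radius kernel
#'
#' Greedy nearest-neighbour linking: tracks are seeded from the detections
#' of the first timepoint in input order and each track repeatedly claims
#' the nearest unclaimed detection within `N` pixels at the next timepoint
#' (ties broken by lowest detection index); a track terminates when none is
#' found. Further passes re-seed from the earliest still-unclaimed
#' detections to recover cells that appear later. Tracks spanning fewer
#' than `min_track_points` consecutive timepoints are discarded. Claims are
#' exclusive: no detection feeds two tracks. Deterministic for a fixed
#' input order.
#'
#' @param detections List (one element per timepoint) of data.frames or
#'   matrices with columns `x_px`, `y_px`.
#' @param config A [tracking_config()].
#' @return An object of class `track_set`: list with `points` (data.frame:
#'   track_id, pass, t, x_px, y_px, step_px) and `tracks` (data.frame:
#'   track_id, pass, t_start, n_points, total_px, total_um), plus the
#'   config.
#' @export
link_tracks <- function(detections, config = tracking_config()) {
  nT <- length(detections)
  if (nT < 2) stop("link_tracks: need >= 2 timepoints", call. = FALSE)
  det <- lapply(detections, function(d) {
    d <- as.data.frame(d)
    if (!nrow(d)) return(data.frame(x_px = numeric(0), y_px = numeric(0)))
    if (!all(c("x_px", "y_px") %in% names(d))) names(d)[1:2] <- c("x_px", "y_px")
    d[, c("x_px", "y_px")]
  })
  claimed <- lapply(det, function(d) rep(FALSE, nrow(d)))
  pts <- list()
  track_id <- 0L
  for (pass in seq_len(config$n_passes)) {
    seed_ts <- if (pass == 1) 1L else seq_len(nT - 1L)
    for (t0 in seed_ts) {
      for (i0 in seq_len(nrow(det[[t0]]))) {
        if (claimed[[t0]][i0]) next
        # grow one track to completion before seeding the next
        claimed[[t0]][i0] <- TRUE
        xs <- det[[t0]]$x_px[i0]; ys <- det[[t0]]$y_px[i0]; ts <- t0
        repeat {
          tn <- ts[length(ts)] + 1L
          if (tn > nT || !nrow(det[[tn]])) break
          free <- which(!claimed[[tn]])
          if (!length(free)) break
          dx <- det[[tn]]$x_px[free] - xs[length(xs)]
          dy <- det[[tn]]$y_px[free] - ys[length(ys)]
          dd <- sqrt(dx^2 + dy^2)
          ok <- which(dd <= config$N)
          if (!length(ok)) break
          j <- free[ok[which.min(dd[ok])]]  # which.min takes the lowest index on ties
          claimed[[tn]][j] <- TRUE
          xs <- c(xs, det[[tn]]$x_px[j]); ys <- c(ys, det[[tn]]$y_px[j])
          ts <- c(ts, tn)
        }
        if (length(ts) >= config$min_track_points) {
          track_id <- track_id + 1L
          pts[[track_id]] <- data.frame(
            track_id = track_id, pass = pass, t = ts - 1L,
            x_px = xs, y_px = ys,
            step_px = c(0, sqrt(diff(xs)^2 + diff(ys)^2)))
        }
      }
    }
  }
  points <- if (length(pts)) do.call(rbind, pts) else
    data.frame(track_id = integer(0), pass = integer(0), t = integer(0),
               x_px = numeric(0), y_px = numeric(0), step_px = numeric(0))
  tracks <- if (nrow(points)) {
    agg <- lapply(split(points, points$track_id), function(d) {
      data.frame(track_id = d$track_id[1], pass = d$pass[1],
                 t_start = min(d$t), n_points = nrow(d),
                 total_px = sum(d$step_px))
    })
    out <- do.call(rbind, agg)
    out$total_um <- out$total_px * config$pixel_size
    out[order(out$track_id), , drop = FALSE]
  } else {
    data.frame(track_id = integer(0), pass = integer(0), t_start = integer(0),
               n_points = integer(0), total_px = numeric(0), total_um = numeric(0))
  }
  structure(list(points = points, tracks = tracks, config = config),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat("track_set:", nrow(x$tracks), "tracks (N =", x$config$N, "px,",
      "min", x$config$min_track_points, "points)\n")
  if (nrow(x$tracks)) {
    cat("  total distance:", signif(min(x$tracks$total_um), 3), "-",
        signif(max(x$tracks$total_um), 3), "um\n")
  }
  invisible(x)
}

#' Render a motility gradient map
#'
#' Deposits each track's total travelled distance (µm) as a Gaussian bump
#' around every one of its positions; overlapping deposits combine by
#' maximum and the field is clipped at `display_max` for display, so the
#' field maximum equals the largest (clipped) track distance.
#'
#' @param tracks A `track_set`.
#' @param shape Output image shape `c(ny, nx)` in pixels.
#' @param mask Optional `label_mask` whose wall outline is stored for
#'   overlay plotting.
#' @param display_max Display ceiling in µm (default 30).
#' @param kernel_sigma Gaussian deposit sigma in pixels.
#' @return An object of class `gradient_map`: list with `field` (ny x nx,
#'   µm), `display_max`, `kernel_sigma`, `tracks`, `mask`.
#' @export
render_gradient_map <- function(tracks, shape, mask = NULL, display_max = 30,
                                kernel_sigma = 5) {
  ny <- shape[1]; nx <- shape[2]
  field <- matrix(0, ny, nx)
  pts <- tracks$points
  if (nrow(pts)) {
    totals <- tracks$tracks$total_um[match(pts$track_id, tracks$tracks$track_id)]
    halfw <- ceiling(3 * kernel_sigma)
    for (i in seq_len(nrow(pts))) {
      cx <- pts$x_px[i]; cy <- pts$y_px[i]
      cols <- max(1, floor(cx - halfw)):min(nx, ceiling(cx + halfw))
      rows <- max(1, floor(cy - halfw)):min(ny, ceiling(cy + halfw))
      if (!length(cols) || !length(rows)) next
      d2 <- outer((rows - 0.5 - cy)^2, (cols - 0.5 - cx)^2, `+`)
      bump <- totals[i] * exp(-d2 / (2 * kernel_sigma^2))
      field[rows, cols] <- pmax(field[rows, cols], bump)
      # the pixel containing the position carries the full track total
      pr <- min(max(ceiling(cy), 1), ny); pc <- min(max(ceiling(cx), 1), nx)
      field[pr, pc] <- max(field[pr, pc], totals[i])
    }
  }
  field <- pmin(field, display_max)
  structure(list(field = field, display_max = display_max,
                 kernel_sigma = kernel_sigma, tracks = tracks, mask = mask),
            class = "gradient_map")
}

#' Plot a gradient map
#'
#' Image of the motility field (blue = stationary, red = highly motile)
#' with the scaffold wall outline and per-timepoint track positions
#' overlaid as coloured circles.
#'
#' @param x A `gradient_map`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.gradient_map <- function(x, ...) {
  pal <- grDevices::colorRampPalette(c("navy", "dodgerblue", "cyan",
                                       "yellow", "orange", "red"))(64)
  f <- t(x$field)[, rev(seq_len(nrow(x$field))), drop = FALSE]
  graphics::image(f, col = pal, zlim = c(0, x$display_max), axes = FALSE,
                  useRaster = TRUE, ...)
  ny <- nrow(x$field); nx <- ncol(x$field)
  if (!is.null(x$mask)) {
    wall <- t(x$mask$grid == 1L)[, rev(seq_len(ny)), drop = FALSE]
    graphics::contour(seq(0, 1, length.out = nx), seq(0, 1, length.out = ny),
                      wall + 0, levels = 0.5, add = TRUE, drawlabels = FALSE,
                      col = "grey40")
  }
  pts <- x$tracks$points
  if (nrow(pts)) {
    tcol <- grDevices::hcl.colors(max(pts$t) + 1, "Zissou 1")
    graphics::points(pts$x_px / nx, 1 - pts$y_px / ny, col = tcol[pts$t + 1],
                     cex = 0.7)
  }
  invisible(x)
}

#' Summarize track motility by scaffold region
#'
#' Assigns each track to a scaffold region by its first position — the
#' wall-separation class of the set of walls it starts between, or
#' `"control"` for the planar area outside the wall sets — and reports per
#' region the track count, mean and maximum total distance and the
#' fraction of tracks starting inside a niche (wall-contact) zone.
#'
#' @param tracks A `track_set`, optionally with a `partition` column in
#'   `$tracks` (added by the caller when tracking Z partitions separately).
#' @param model The `scaffold_model`.
#' @param mask A `label_mask` over the tracked area, used for niche-zone
#'   membership: a start position on a niche-zone or wall pixel counts as
#'   wall contact (a centroid reported on a wall pixel necessarily belongs
#'   to a cell hugging that wall); positions outside the mask do not.
#' @return data.frame per region (x partition when present): `region`,
#'   `n_tracks`, `mean_total_um`, `max_total_um`, `niche_fraction`.
#' @export
summarize_motility <- function(tracks, model, mask) {
  tr <- tracks$tracks
  if (!nrow(tr)) {
    return(data.frame(region = character(0), n_tracks = integer(0),
                      mean_total_um = numeric(0), max_total_um = numeric(0),
                      niche_fraction = numeric(0)))
  }
  pts <- tracks$points
  first <- pts[!duplicated(pts$track_id), ]
  first <- first[match(tr$track_id, first$track_id), ]
  px <- mask$pixel_size
  x_um <- first$x_px * px
  y_um <- first$y_px * px

  walls <- model$walls
  region <- rep("control", nrow(tr))
  for (s in unique(walls$set)) {
    ws <- walls[walls$set == s, ]
    inside <- y_um >= min(ws$y) & y_um <= max(ws$y) &
      x_um >= min(ws$x0) & x_um <= max(ws$x1)
    region[inside] <- as.character(model$params$wall_separations[s])
  }
  row <- ceiling(first$y_px)
  col <- ceiling(first$x_px)
  inside <- row >= 1 & row <= nrow(mask$grid) & col >= 1 & col <= ncol(mask$grid)
  lab <- rep(0L, nrow(tr))
  lab[inside] <- mask$grid[cbind(row[inside], col[inside])]
  # a centroid on a wall pixel is, at pixel granularity, in wall contact
  in_niche <- lab > 0L

  grp <- if (!is.null(tr$partition)) {
    interaction(region, tr$partition, drop = TRUE)
  } else factor(region)
  out <- do.call(rbind, lapply(levels(grp), function(g) {
    i <- which(grp == g)
    data.frame(region = if (is.null(tr$partition)) g else
                 strsplit(g, ".", fixed = TRUE)[[1]][1],
               partition = if (is.null(tr$partition)) NA_character_ else
                 strsplit(g, ".", fixed = TRUE)[[1]][2],
               n_tracks = length(i),
               mean_total_um = mean(tr$total_um[i]),
               max_total_um = max(tr$total_um[i]),
               niche_fraction = mean(in_niche[i]))
  }))
  if (all(is.na(out$partition))) out$partition <- NULL
  out
}

#' Align time-lapse frames by integer-pixel cross-correlation
#'
#' Estimates the integer XY shift of each image against a reference (e.g.
#' the t = 0 scaffold channel, whose wall structures act as registration
#' markers) by FFT cross-correlation, and returns the de-shifted images.
#'
#' @param frames List of 2D matrices.
#' @param reference Reference 2D matrix (same dimensions).
#' @param max_shift Largest shift considered, in pixels.
#' @return List with `shifts` (n x 2 matrix of applied dy, dx) and
#'   `aligned` (list of de-shifted matrices; vacated margins are zero).
#' @export
align_frames <- function(frames, reference, max_shift = 20) {
  d <- dim(reference)
  fr <- stats::fft(reference - mean(reference))
  shifts <- matrix(0L, length(frames), 2,
                   dimnames = list(NULL, c("dy", "dx")))
  aligned <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!identical(dim(f), d)) stop("align_frames: dimension mismatch", call. = FALSE)
    cc <- Re(stats::fft(fr * Conj(stats::fft(f - mean(f))), inverse = TRUE))
    wrap <- function(k, n) ifelse(k > n / 2, k - n, k)
    ok_y <- wrap(seq_len(d[1]) - 1, d[1])
    ok_x <- wrap(seq_len(d[2]) - 1, d[2])
    cc[abs(ok_y) > max_shift, ] <- -Inf
    cc[, abs(ok_x) > max_shift] <- -Inf
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    dy <- -wrap(pk[1] - 1, d[1]); dx <- -wrap(pk[2] - 1, d[2])
    shifts[i, ] <- c(dy, dx)
    out <- matrix(0, d[1], d[2])
    src_r <- seq_len(d[1]) + dy; src_c <- seq_len(d[2]) + dx
    ok_r <- src_r >= 1 & src_r <= d[1]; ok_c <- src_c >= 1 & src_c <= d[2]
    out[which(ok_r), which(ok_c)] <- f[src_r[ok_r], src_c[ok_c]]
    aligned[[i]] <- out
  }
  list(shifts = shifts, aligned = aligned)
}

#' Export tracks to CSV
#'
#' @param tracks A `track_set`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  pts <- tracks$points
  px <- tracks$config$pixel_size
  pts$x_um <- pts$x_px * px
  pts$y_um <- pts$y_px * px
  pts$step_um <- pts$step_px * px
  pts$total_um <- tracks$tracks$total_um[match(pts$track_id,
                                               tracks$tracks$track_id)]
  utils::write.csv(pts, path, row.names = FALSE)
  invisible(path)
}
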