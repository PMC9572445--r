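# Run code with a temporarily fixed RNG state; restores the caller's state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Imaging configuration
#'
#' Acquisition geometry and noise settings of the synthetic confocal
#' generator. The defaults emulate a 10x lambda-mode acquisition: 1.66
#' µm/px over a 630 x 520 µm field of view, 12 Z slices at 2 µm covering a
#' 24 µm tall scaffold.
#'
#' @param pixel_size Pixel size (µm/px).
#' @param fov Field of view `c(width, height)` in µm.
#' @param n_slices Number of Z slices.
#' @param z_step Z step (µm).
#' @param spectral A [spectral_config()].
#' @param counts_scale Detected photon counts per unit abundance; Poisson
#'   shot noise is applied on this count scale and the data returned on the
#'   abundance scale.
#' @param gaussian_sd Additive Gaussian read noise, in counts.
#' @param poisson Apply Poisson shot noise?
#' @param clip_at Optional full-well value (abundance units) at which the
#'   rendered signal saturates; `NULL` for no clipping.
#' @return An object of class `imaging_config`.
#' @export
imaging_config <- function(pixel_size = 1.66, fov = c(630, 520),
                           n_slices = 12, z_step = 2,
                           spectral = spectral_config(405),
                           counts_scale = 5000, gaussian_sd = 2,
                           poisson = TRUE, clip_at = NULL) {
  if (pixel_size <= 0 || any(fov <= 0) || n_slices < 1 || z_step <= 0) {
    stop("imaging_config: non-positive geometry parameter", call. = FALSE)
  }
  cfg <- list(pixel_size = pixel_size, fov = fov,
              n_slices = as.integer(n_slices), z_step = z_step,
              spectral = spectral, counts_scale = counts_scale,
              gaussian_sd = gaussian_sd, poisson = poisson, clip_at = clip_at,
              nx = as.integer(ceiling(fov[1] / pixel_size)),
              ny = as.integer(ceiling(fov[2] / pixel_size)))
  class(cfg) <- "imaging_config"
  cfg
}

#' Place synthetic cells in a scaffold
#'
#' Draws non-overlapping spherical cells inside the scaffold chambers. With
#' probability `niche_bias` a cell centre is drawn uniformly from the niche
#' (wall-contact) zones, otherwise uniformly from the whole chamber
#' interior; centres never fall on wall material and cells never overlap
#' each other. Z centres are uniform over the heights the cell fits into.
#'
#' @param model A `scaffold_model`.
#' @param n Number of cells.
#' @param niche_bias Probability in `[0, 1]` that a cell is seeded in a
#'   niche zone.
#' @param seed Optional RNG seed; identical seeds give identical placements.
#' @param diameter Cell diameter (µm).
#' @param nucleus_diameter Nucleus diameter (µm), smaller than `diameter`.
#' @param brightness Named vector with `nuclei` and `cytoplasm` emitter
#'   brightness (abundance units of a fully occupied voxel).
#' @param max_tries Proposal budget per cell before giving up.
#' @return data.frame of cells: id, x, y, z (µm), diameter,
#'   nucleus_diameter, brightness columns, chamber_id, unit, in_niche.
#' @export
place_cells <- function(model, n, niche_bias = 0, seed = NULL,
                        diameter = 15, nucleus_diameter = 8,
                        brightness = c(nuclei = 1, cytoplasm = 0.5),
                        max_tries = 1000) {
  if (niche_bias < 0 || niche_bias > 1) {
    stop("place_cells: niche_bias must be in [0, 1]", call. = FALSE)
  }
  if (nucleus_diameter >= diameter) {
    stop("place_cells: nucleus_diameter must be smaller than diameter", call. = FALSE)
  }
  p <- model$params
  ht <- p$line_thickness / 2
  nd <- p$niche_depth
  reps <- merge(model$chamber_replicates,
                model$chambers[, c("id", "wall_separation", "niche_size")],
                by.x = "chamber_id", by.y = "id")
  # sampling strips per replicate: niche strips hug the two walls, the
  # interior is the whole chamber; both exclude wall material
  reps$xin0 <- reps$x0 + ht
  reps$xin1 <- reps$x1 - ht
  reps$yin0 <- reps$y0 + ht
  reps$yin1 <- reps$y1 - ht
  area_int <- (reps$xin1 - reps$xin0) * (reps$yin1 - reps$yin0)
  area_niche <- (reps$xin1 - reps$xin0) * pmin(2 * (nd - ht), reps$yin1 - reps$yin0)
  if (all(area_int <= 0)) stop("place_cells: no chamber interior to sample", call. = FALSE)

  height <- unname(model$bounding_box["height"])
  r <- diameter / 2
  zlo <- min(r, height / 2); zhi <- max(height - r, height / 2)

  with_seed(seed, {
    xs <- ys <- zs <- numeric(n)
    cid <- un <- integer(n)
    inn <- logical(n)
    placed <- 0L
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        use_niche <- stats::runif(1) < niche_bias
        w <- if (use_niche) area_niche else area_int
        if (sum(w) <= 0) w <- area_int
        j <- sample.int(nrow(reps), 1, prob = w)
        x <- stats::runif(1, reps$xin0[j], reps$xin1[j])
        if (use_niche) {
          d <- stats::runif(1, 0, min(nd - ht, (reps$yin1[j] - reps$yin0[j]) / 2))
          y <- if (stats::runif(1) < 0.5) reps$yin0[j] + d else reps$yin1[j] - d
        } else {
          y <- stats::runif(1, reps$yin0[j], reps$yin1[j])
        }
        z <- stats::runif(1, zlo, zhi)
        if (placed > 0) {
          dd <- (xs[1:placed] - x)^2 + (ys[1:placed] - y)^2 + (zs[1:placed] - z)^2
          if (min(dd) < diameter^2) next
        }
        placed <- placed + 1L
        xs[placed] <- x; ys[placed] <- y; zs[placed] <- z
        cid[placed] <- reps$chamber_id[j]; un[placed] <- reps$unit[j]
        inn[placed] <- use_niche ||
          (y - reps$yin0[j] < nd - ht) || (reps$yin1[j] - y < nd - ht)
        ok <- TRUE
        break
      }
      if (!ok) {
        stop("place_cells: could not place ", n, " non-overlapping cells (",
             placed, " placed)", call. = FALSE)
      }
    }
    data.frame(id = seq_len(n), x = xs, y = ys, z = zs,
               diameter = diameter, nucleus_diameter = nucleus_diameter,
               brightness_nuclei = unname(brightness["nuclei"]),
               brightness_cytoplasm = unname(brightness["cytoplasm"]),
               chamber_id = cid, unit = un, in_niche = inn)
  })
}

# Deposit spherical emitters into per-endmember (Z, Y, X) abundance arrays.
# Per voxel the abundance is the column length of the sphere through the
# slice slab divided by the slab height, i.e. the voxel volume fraction in
# the thin-column approximation, times the emitter brightness. When a wall
# pixel map is given, mass falling on wall material is redistributed over
# the cell's remaining voxels (cells deform against the solid walls rather
# than interpenetrate them, and their fluorophore content is conserved).
render_cells_abundance <- function(cells, imaging, wall = NULL) {
  nz <- imaging$n_slices; ny <- imaging$ny; nx <- imaging$nx
  px <- imaging$pixel_size; dz <- imaging$z_step
  nuc <- array(0, c(nz, ny, nx))
  cyt <- array(0, c(nz, ny, nx))
  if (is.null(cells) || nrow(cells) == 0) return(list(nuclei = nuc, cytoplasm = cyt))
  xc_all <- (seq_len(nx) - 0.5) * px
  yc_all <- (seq_len(ny) - 0.5) * px
  za <- (seq_len(nz) - 1) * dz
  zb <- za + dz
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    r <- cl$diameter / 2; rn <- cl$nucleus_diameter / 2
    cols <- which(abs(xc_all - cl$x) < r)
    rows <- which(abs(yc_all - cl$y) < r)
    if (!length(cols) || !length(rows)) next
    d2 <- outer((yc_all[rows] - cl$y)^2, (xc_all[cols] - cl$x)^2, `+`)
    colfrac <- function(rad) {
      h2 <- rad^2 - d2
      h <- sqrt(pmax(h2, 0))
      out <- array(0, c(length(za), nrow(d2), ncol(d2)))
      for (k in seq_along(za)) {
        lo <- pmax(cl$z - h, za[k])
        hi <- pmin(cl$z + h, zb[k])
        out[k, , ] <- pmax(hi - lo, 0) / dz
      }
      out
    }
    fc <- colfrac(r)
    fn <- colfrac(rn)
    if (!is.null(wall)) {
      wz <- array(rep(wall[rows, cols, drop = FALSE], each = nz), dim(fc))
      clip <- function(f) {
        tot <- sum(f)
        lost <- sum(f[wz])
        f[wz] <- 0
        if (lost > 0 && tot > lost) f <- f * tot / (tot - lost)
        f
      }
      fc <- clip(fc)
      fn <- clip(fn)
    }
    nuc[, rows, cols] <- nuc[, rows, cols, drop = FALSE] +
      fn * cl$brightness_nuclei
    cyt[, rows, cols] <- cyt[, rows, cols, drop = FALSE] +
      pmax(fc - fn, 0) * cl$brightness_cytoplasm
  }
  list(nuclei = nuc, cytoplasm = cyt)
}

# Apply the generator noise model on the photon-count scale and return to
# the abundance scale.
apply_noise <- function(vals, imaging) {
  out <- cpp_detection_noise(as.vector(vals), imaging$counts_scale,
                             imaging$gaussian_sd, imaging$poisson)
  dim(out) <- dim(vals)
  out
}

#' Render a hyperspectral confocal stack of cells in a scaffold
#'
#' Composes per-voxel abundances of the four emitters (scaffold walls at
#' their UV-quenched brightness, cell nuclei, cytoplasm shells and a flat
#' background), mixes them through the endmember spectra and applies
#' Poisson-plus-Gaussian detection noise. The noiseless per-voxel intensity
#' is linear in the sources.
#'
#' @param model A `scaffold_model`.
#' @param cells Cell table from [place_cells()] (may be `NULL`).
#' @param endmembers Endmember list covering scaffold, nuclei, cytoplasm and
#'   background (see [default_endmembers()]).
#' @param imaging An [imaging_config()]; its spectral grid must match the
#'   endmembers.
#' @param quench_time UV-treatment time (minutes) scaling the scaffold
#'   brightness through `quench`.
#' @param quench A [quench_model()] for the scaffold autofluorescence. The
#'   default puts the scaffold at 5x the unit cell brightness after 150 min
#'   of treatment.
#' @param background_level Background abundance per voxel.
#' @param noise Apply the configured noise model?
#' @param seed Optional RNG seed for the noise.
#' @param mask Optional precomputed `label_mask` over the field of view
#'   (saves rasterizing when rendering repeatedly).
#' @return An object of class `hyperspectral_stack`: list with `data`
#'   (Z x C x Y x X array, abundance-scaled intensities), `imaging`,
#'   `excitation_nm`, `endmember_names`, ground-`truth` per-emitter
#'   abundance arrays (Z x Y x X), the `mask` used, and `spectra`, a
#'   voxels-by-channels copy of the data that [unmix()] consumes directly
#'   (drop it if you modify `data` by hand).
#' @export
render_stack <- function(model, cells, endmembers, imaging = imaging_config(),
                         quench_time = 150,
                         quench = quench_model(I0 = 5 / 0.22, k = quench_rate()),
                         background_level = 0.05, noise = TRUE, seed = NULL,
                         mask = NULL) {
  needed <- c("scaffold", "nuclei", "cytoplasm", "background")
  if (!all(needed %in% names(endmembers))) {
    stop("render_stack: endmembers must cover ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  E <- endmember_matrix(endmembers[needed])
  if (nrow(E) != imaging$spectral$n_channels) {
    stop("render_stack: endmember channel grid does not match the imaging config",
         call. = FALSE)
  }
  nz <- imaging$n_slices; ny <- imaging$ny; nx <- imaging$nx
  nc <- nrow(E)
  if (is.null(mask)) {
    mask <- rasterize_scaffold(model, imaging$pixel_size,
                               width = nx * imaging$pixel_size,
                               height = ny * imaging$pixel_size)
  }
  if (nrow(mask$grid) != ny || ncol(mask$grid) != nx) {
    stop("render_stack: mask grid is not congruent with the field of view",
         call. = FALSE)
  }

  scaffold_brightness <- quench_intensity(quench, quench_time)
  wall2d <- (mask$grid == 1L) * scaffold_brightness
  # walls span [0, wall_height]; per-slice overlap fraction with each slab
  za <- (seq_len(nz) - 1) * imaging$z_step
  hfrac <- pmin(pmax((model$params$wall_height - za) / imaging$z_step, 0), 1)
  sca <- array(0, c(nz, ny, nx))
  for (k in seq_len(nz)) sca[k, , ] <- wall2d * hfrac[k]

  cellab <- render_cells_abundance(cells, imaging, wall = mask$grid == 1L)
  truth <- list(scaffold = sca, nuclei = cellab$nuclei,
                cytoplasm = cellab$cytoplasm,
                background = array(background_level, c(nz, ny, nx)))

  M <- cbind(as.vector(truth$scaffold), as.vector(truth$nuclei),
             as.vector(truth$cytoplasm), as.vector(truth$background))
  clip <- if (is.null(imaging$clip_at)) -1 else imaging$clip_at
  spectra <- with_seed(seed, {
    cpp_mix_noise(M, E, imaging$counts_scale, imaging$gaussian_sd,
                  imaging$poisson, noise, clip)      # (Z*Y*X) x C
  })
  rm(M)
  data <- aperm(array(spectra, c(nz, ny, nx, nc)), c(1, 4, 2, 3))
  out <- list(data = data, imaging = imaging,
              excitation_nm = imaging$spectral$excitation_nm,
              endmember_names = needed, truth = truth, mask = mask,
              spectra = spectra)
  class(out) <- "hyperspectral_stack"
  out
}

#' @export
print.hyperspectral_stack <- function(x, ...) {
  d <- dim(x$data)
  cat("hyperspectral_stack:", d[1], "slices x", d[2], "channels x", d[3], "x",
      d[4], "px (exc.", x$excitation_nm, "nm,", x$imaging$pixel_size, "um/px)\n")
  invisible(x)
}

#' Motion model for time-lapse simulation
#'
#' Confined random-walk settings for the synthetic time-lapse: per interval
#' each cell takes an isotropic Gaussian step whose mean displacement is
#' `step_scale` µm, reflected off wall material so cells never cross the
#' solid walls. Vertical (Z) motion is not modelled.
#'
#' @param step_scale Mean per-interval displacement in µm; either a single
#'   number or a named vector keyed by wall separation (e.g.
#'   `c("20" = 2, "55" = 8)`) for region-dependent motility.
#' @param n_timepoints Number of timepoints (default 6).
#' @param interval_min Minutes between timepoints (default 65, so 5
#'   intervals span 5 h 25 min).
#' @param wall_blocking Reflect steps off wall material?
#' @return An object of class `motion_spec`.
#' @export
motion_spec <- function(step_scale = 5, n_timepoints = 6, interval_min = 65,
                        wall_blocking = TRUE) {
  if (any(step_scale < 0) || n_timepoints < 2 || interval_min <= 0) {
    stop("motion_spec: invalid motion parameters", call. = FALSE)
  }
  structure(list(step_scale = step_scale, n_timepoints = as.integer(n_timepoints),
                 interval_min = interval_min, wall_blocking = wall_blocking),
            class = "motion_spec")
}

# TRUE where (x, y) lies on wall material (centre-line rectangles dilated by
# half the line thickness).
on_wall_material <- function(model, x, y) {
  ht <- model$params$line_thickness / 2
  for (i in seq_len(nrow(model$walls))) {
    w <- model$walls[i, ]
    if (abs(y - w$y) <= ht && x >= w$x0 - ht && x <= w$x1 + ht) return(TRUE)
  }
  cw <- model$cross_walls
  hit <- abs(cw$x - x) <= ht & y >= cw$y0 - ht & y <= cw$y1 + ht
  any(hit)
}

# Reflect a proposed step off wall centrelines; returns the final position.
reflect_step <- function(model, x0, y0, x1, y1) {
  ht <- model$params$line_thickness / 2
  bbw <- unname(model$bounding_box["width"])
  yr <- range(model$walls$y)
  for (iter in 1:10) {
    moved <- FALSE
    for (i in seq_len(nrow(model$walls))) {
      yw <- model$walls$y[i]
      in_x <- max(x0, x1) >= model$walls$x0[i] - ht &&
        min(x0, x1) <= model$walls$x1[i] + ht
      crosses <- in_x && ((y0 - yw) * (y1 - yw) < 0 || abs(y1 - yw) <= ht)
      if (crosses) {
        y1 <- 2 * yw - y1 + sign(y0 - yw) * 2 * ht
        moved <- TRUE
      }
    }
    cw <- model$cross_walls
    in_y <- pmax(y0, y1) >= cw$y0 - ht & pmin(y0, y1) <= cw$y1 + ht
    for (j in which(in_y)) {
      xw <- cw$x[j]
      if ((x0 - xw) * (x1 - xw) < 0 || abs(x1 - xw) <= ht) {
        x1 <- 2 * xw - x1 + sign(x0 - xw) * 2 * ht
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  x1 <- min(max(x1, 0), bbw)
  y1 <- min(max(y1, yr[1] - 50), yr[2] + 50)
  if (on_wall_material(model, x1, y1)) c(x0, y0) else c(x1, y1)
}

#' Simulate a time-lapse of moving cells
#'
#' Advances the cells of [place_cells()] through a confined random walk and
#' (optionally) renders a nuclei-channel intensity stack per timepoint with
#' the generator's noise model. The exact trajectory table is always
#' returned as ground truth; positions never lie on wall material.
#'
#' @param model A `scaffold_model`.
#' @param cells Cell table from [place_cells()].
#' @param motion A [motion_spec()].
#' @param imaging An [imaging_config()].
#' @param seed Optional RNG seed.
#' @param render Render image stacks? `FALSE` returns trajectories only.
#' @param background_level Background abundance per voxel in the rendered
#'   frames.
#' @return List with `tracks` (data.frame: cell_id, t, time_min, x, y, z,
#'   partition, wall_separation), `frames` (list of Z x Y x X arrays or
#'   `NULL`), `motion`, `imaging`.
#' @export
simulate_timelapse <- function(model, cells, motion = motion_spec(),
                               imaging = imaging_config(), seed = NULL,
                               render = TRUE, background_level = 0.05) {
  nT <- motion$n_timepoints
  sep_of_cell <- model$chambers$wall_separation[match(cells$chamber_id,
                                                      model$chambers$id)]
  step_of_cell <- if (length(motion$step_scale) == 1 && is.null(names(motion$step_scale))) {
    rep(unname(motion$step_scale), nrow(cells))
  } else {
    s <- motion$step_scale[as.character(sep_of_cell)]
    if (any(is.na(s))) {
      stop("simulate_timelapse: step_scale has no entry for some wall separation",
           call. = FALSE)
    }
    unname(s)
  }
  height_bottom <- 14  # Z split used downstream; recorded for convenience

  with_seed(seed, {
    pos <- cells[, c("x", "y")]
    traj <- vector("list", nT)
    for (tt in seq_len(nT)) {
      if (tt > 1) {
        sigma <- step_of_cell * sqrt(2 / pi)
        dx <- stats::rnorm(nrow(pos), 0, sigma)
        dy <- stats::rnorm(nrow(pos), 0, sigma)
        for (i in seq_len(nrow(pos))) {
          if (motion$wall_blocking) {
            np <- reflect_step(model, pos$x[i], pos$y[i],
                               pos$x[i] + dx[i], pos$y[i] + dy[i])
          } else {
            np <- c(pos$x[i] + dx[i], pos$y[i] + dy[i])
          }
          pos$x[i] <- np[1]; pos$y[i] <- np[2]
        }
      }
      traj[[tt]] <- data.frame(cell_id = cells$id, t = tt - 1L,
                               time_min = (tt - 1L) * motion$interval_min,
                               x = pos$x, y = pos$y, z = cells$z,
                               partition = ifelse(cells$z <= height_bottom,
                                                  "bottom", "top"),
                               wall_separation = sep_of_cell)
    }
    tracks <- do.call(rbind, traj)
    frames <- NULL
    if (render) {
      wall <- rasterize_scaffold(model, imaging$pixel_size,
                                 width = imaging$nx * imaging$pixel_size,
                                 height = imaging$ny * imaging$pixel_size)$grid == 1L
      frames <- vector("list", nT)
      for (tt in seq_len(nT)) {
        snap <- cells
        snap$x <- traj[[tt]]$x; snap$y <- traj[[tt]]$y
        ab <- render_cells_abundance(snap, imaging, wall = wall)
        v <- ab$nuclei + background_level
        frames[[tt]] <- array(apply_noise(as.vector(v), imaging), dim(v))
      }
    }
    list(tracks = tracks, frames = frames, motion = motion, imaging = imaging)
  })
}
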