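#' Scaffold design parameters
#'
#' Parameter set describing the graded wall-and-niche scaffold: long walls
#' subdivided by short cross walls into niches, replicated in sets of parallel
#' walls at increasing separations. All lengths are in micrometres and refer
#' to the centre of a traced line; the finite line thickness is carried
#' separately in `line_thickness`.
#'
#' @param unit_wall_length Length of one unit wall (µm).
#' @param wall_height Wall height (µm); extruded vertically.
#' @param niche_sections Ordered section lengths along one unit wall (µm).
#'   Must sum to `unit_wall_length`.
#' @param cross_wall_length Total length of a cross wall (µm), spanning
#'   `cross_wall_half` on each side of the long wall.
#' @param cross_wall_half Cross-wall half-length (µm).
#' @param wall_separations Centre-to-centre separations of adjacent walls,
#'   one per wall set (µm).
#' @param walls_per_set Number of parallel long walls in each set.
#' @param n_sets Number of wall sets.
#' @param units_per_wall Number of unit walls concatenated into one long
#'   wall. For an even count the second half is mirrored, so niche sizes
#'   ramp up and jump back down along the wall.
#' @param line_thickness Fabricated line thickness (µm); material extends
#'   half of it either side of a centreline and past line ends.
#' @param z_slice Fabrication slicing distance (µm); metadata only.
#' @param niche_depth Distance from a wall centreline within which material
#'   counts as "in the niche" / in wall contact (µm).
#' @param total_depth Overall scaffold depth (first to last wall centreline,
#'   µm). The separations within sets are fixed by `wall_separations`; any
#'   remaining depth is split equally over the gaps between sets. `NULL`
#'   spaces sets by the largest separation instead.
#'
#' @return An object of class `scaffold_params` (a validated list).
#' @export
scaffold_params <- function(unit_wall_length = 210,
                            wall_height = 24,
                            niche_sections = c(10, 10, 10, 30, 30, 50, 70),
                            cross_wall_length = 15,
                            cross_wall_half = cross_wall_length / 2,
                            wall_separations = c(20, 25, 35, 55),
                            walls_per_set = 4,
                            n_sets = 4,
                            units_per_wall = 4,
                            line_thickness = 2,
                            z_slice = 4,
                            niche_depth = 7.5,
                            total_depth = 520) {
  p <- list(
    unit_wall_length = unit_wall_length, wall_height = wall_height,
    niche_sections = niche_sections, cross_wall_length = cross_wall_length,
    cross_wall_half = cross_wall_half, wall_separations = wall_separations,
    walls_per_set = walls_per_set, n_sets = n_sets,
    units_per_wall = units_per_wall, line_thickness = line_thickness,
    z_slice = z_slice, niche_depth = niche_depth, total_depth = total_depth
  )
  class(p) <- "scaffold_params"
  validate_scaffold_params(p)
  p
}

validate_scaffold_params <- function(p) {
  if (!isTRUE(all.equal(sum(p$niche_sections), p$unit_wall_length))) {
    stop("invalid scaffold_params: sum(niche_sections) == unit_wall_length is violated (",
         sum(p$niche_sections), " != ", p$unit_wall_length, ")", call. = FALSE)
  }
  if (!isTRUE(all.equal(p$cross_wall_length, 2 * p$cross_wall_half))) {
    stop("invalid scaffold_params: cross_wall_length == 2 * cross_wall_half is violated",
         call. = FALSE)
  }
  if (any(p$wall_separations <= 0)) {
    stop("invalid scaffold_params: all separations > 0 is violated", call. = FALSE)
  }
  if (p$line_thickness < 0) {
    stop("invalid scaffold_params: line_thickness >= 0 is violated", call. = FALSE)
  }
  if (any(p$niche_sections <= 0)) {
    stop("invalid scaffold_params: niche_sections must be positive", call. = FALSE)
  }
  for (f in c("walls_per_set", "n_sets", "units_per_wall")) {
    if (p[[f]] < 1 || p[[f]] != round(p[[f]])) {
      stop("invalid scaffold_params: ", f, " must be a positive integer", call. = FALSE)
    }
  }
  if (p$wall_height <= 0) stop("invalid scaffold_params: wall_height must be > 0", call. = FALSE)
  if (p$niche_depth <= 0) stop("invalid scaffold_params: niche_depth must be > 0", call. = FALSE)
  invisible(p)
}

#' Chamber footprint area
#'
#' Design footprint of a chamber delimited by two parallel walls and one
#' niche section, using the centre-of-traced-line convention (no thickness
#' correction).
#'
#' @param niche_size Niche section length (µm).
#' @param wall_separation Wall centre-to-centre separation (µm).
#' @return Footprint area in µm².
#' @examples
#' chamber_footprint(10, 20)  # smallest chamber, 200 um^2
#' chamber_footprint(70, 55)  # largest chamber, 3850 um^2
#' @export
chamber_footprint <- function(niche_size, wall_separation) {
  if (any(niche_size <= 0) || any(wall_separation <= 0)) {
    stop("chamber_footprint: niche_size and wall_separation must be > 0", call. = FALSE)
  }
  niche_size * wall_separation
}

#' Chamber opening size
#'
#' Width of the gap left between the opposing cross walls at a chamber's
#' open end: the wall separation minus the cross-wall length, floored at 0.
#'
#' @param wall_separation Wall separation (µm).
#' @param cross_wall_length Cross-wall length (µm).
#' @return Opening size in µm.
#' @export
chamber_opening <- function(wall_separation, cross_wall_length = 15) {
  if (any(wall_separation <= 0)) {
    stop("chamber_opening: wall_separation must be > 0", call. = FALSE)
  }
  if (any(cross_wall_length < 0)) {
    stop("chamber_opening: cross_wall_length must be >= 0", call. = FALSE)
  }
  pmax(0, wall_separation - cross_wall_length)
}

#' Isotropic niche-occupancy ratio
#'
#' Expected fraction of uniformly (isotropically) distributed material that
#' falls within `niche_depth` of either bounding wall of a chamber. The two
#' contact strips cover `2 * niche_depth` of the separation, so the ratio is
#' `min(1, 2 * niche_depth / wall_separation)`. This is the null expectation
#' against which wall-contact enrichment is judged.
#'
#' @param wall_separation Wall separation (µm).
#' @param niche_depth Contact-zone depth from a wall centreline (µm).
#' @return Expected niche fraction in `[0, 1]`.
#' @examples
#' isotropic_niche_ratio(c(20, 25, 35, 55))  # 0.75 0.60 0.43 0.27 (rounded)
#' @export
isotropic_niche_ratio <- function(wall_separation, niche_depth = 7.5) {
  if (any(wall_separation <= 0) || any(niche_depth <= 0)) {
    stop("isotropic_niche_ratio: arguments must be > 0", call. = FALSE)
  }
  pmin(1, 2 * niche_depth / wall_separation)
}

# Section pattern along one full wall: units concatenated, with the second
# half of an even unit count mirrored. Returns a data.frame with per-section
# unit index, within-pattern start/end x and the originating section index.
full_wall_pattern <- function(p) {
  s <- p$niche_sections
  u <- p$units_per_wall
  half <- floor(u / 2)
  pattern <- list()
  for (k in seq_len(u)) {
    mirrored <- (u %% 2 == 0) && (k > half)
    sec <- if (mirrored) rev(s) else s
    idx <- if (mirrored) rev(seq_along(s)) else seq_along(s)
    offs <- (k - 1) * p$unit_wall_length
    x1 <- offs + cumsum(sec)
    x0 <- c(offs, x1[-length(x1)])
    pattern[[k]] <- data.frame(unit = k, section = idx, x0 = x0, x1 = x1)
  }
  do.call(rbind, pattern)
}

#' Build a scaffold model
#'
#' Constructs the full vector geometry: long walls (one per set member),
#' cross walls at every section boundary, and the chamber table. A chamber
#' is the compartment between two adjacent walls spanned by one niche
#' section of the unit-wall pattern; the unit replicates of the same section
#' along the wall are recorded as replicate rectangles of that chamber.
#'
#' @param params A [scaffold_params()] object.
#' @return An object of class `scaffold_model` with elements `params`,
#'   `walls` (data.frame: id, set, y, x0, x1), `cross_walls` (data.frame:
#'   wall_id, x, y0, y1), `chambers` (data.frame, one row per chamber),
#'   `chamber_replicates` (data.frame: chamber_id, unit, x0, x1) and
#'   `bounding_box` (width, depth, height in µm).
#' @export
build_scaffold <- function(params = scaffold_params()) {
  validate_scaffold_params(params)
  p <- params
  wall_length <- p$units_per_wall * p$unit_wall_length

  # wall y positions: walls_per_set walls per set at the set's separation,
  # sets spaced so the outermost centrelines span total_depth
  in_set_span <- (p$walls_per_set - 1) * p$wall_separations
  if (length(in_set_span) != p$n_sets) {
    stop("invalid scaffold_params: wall_separations must have one entry per set",
         call. = FALSE)
  }
  if (p$n_sets > 1) {
    if (is.null(p$total_depth)) {
      inter_gap <- max(p$wall_separations)
    } else {
      inter_gap <- (p$total_depth - sum(in_set_span)) / (p$n_sets - 1)
      if (inter_gap <= 0) {
        stop("invalid scaffold_params: total_depth smaller than the in-set wall spans",
             call. = FALSE)
      }
    }
  } else {
    inter_gap <- 0
  }

  walls <- list()
  y <- 0
  id <- 0L
  for (s in seq_len(p$n_sets)) {
    sep <- p$wall_separations[s]
    for (w in seq_len(p$walls_per_set)) {
      id <- id + 1L
      walls[[id]] <- data.frame(id = id, set = s, idx_in_set = w, y = y,
                                x0 = 0, x1 = wall_length)
      if (w < p$walls_per_set) y <- y + sep
    }
    if (s < p$n_sets) y <- y + inter_gap
  }
  walls <- do.call(rbind, walls)
  depth <- max(walls$y) - min(walls$y)

  pattern <- full_wall_pattern(p)
  bounds <- sort(unique(c(pattern$x0, pattern$x1)))
  cross_walls <- do.call(rbind, lapply(seq_len(nrow(walls)), function(i) {
    data.frame(wall_id = walls$id[i], x = bounds,
               y0 = walls$y[i] - p$cross_wall_half,
               y1 = walls$y[i] + p$cross_wall_half)
  }))

  # chambers: per set, per inter-wall gap, one row per unit-pattern section
  canon <- pattern[pattern$unit == 1, ]
  chambers <- list()
  replicates <- list()
  cid <- 0L
  for (s in seq_len(p$n_sets)) {
    ws <- walls[walls$set == s, ]
    sep <- p$wall_separations[s]
    for (g in seq_len(nrow(ws) - 1)) {
      y0 <- ws$y[g]; y1 <- ws$y[g + 1]
      for (j in seq_along(p$niche_sections)) {
        cid <- cid + 1L
        ns <- p$niche_sections[j]
        chambers[[cid]] <- data.frame(
          id = cid, set = s, gap = g, section = j,
          niche_size = ns, wall_separation = sep,
          footprint_area = chamber_footprint(ns, sep),
          opening_size = chamber_opening(sep, p$cross_wall_length),
          isotropic_ratio = isotropic_niche_ratio(sep, p$niche_depth),
          y0 = y0, y1 = y1,
          x0 = canon$x0[canon$section == j][1],
          x1 = canon$x1[canon$section == j][1]
        )
        reps <- pattern[pattern$section == j, ]
        replicates[[cid]] <- data.frame(
          chamber_id = cid, unit = reps$unit, x0 = reps$x0, x1 = reps$x1,
          y0 = y0, y1 = y1
        )
      }
    }
  }
  chambers <- do.call(rbind, chambers)
  replicates <- do.call(rbind, replicates)

  model <- list(
    params = p,
    walls = walls,
    cross_walls = cross_walls,
    chambers = chambers,
    chamber_replicates = replicates,
    bounding_box = c(width = wall_length, depth = depth, height = p$wall_height)
  )
  class(model) <- "scaffold_model"
  model
}

#' @export
print.scaffold_model <- function(x, ...) {
  bb <- x$bounding_box
  cat("scaffold_model:", nrow(x$walls), "walls of", bb["width"], "um,",
      nrow(x$chambers), "chambers\n")
  cat("  bounding box:", bb["width"], "x", bb["depth"], "x", bb["height"],
      "um =", format(scaffold_volume(x), big.mark = ","), "um^3\n")
  cat("  separations:", paste(x$params$wall_separations, collapse = ", "),
      "um; niche sections:", paste(x$params$niche_sections, collapse = ", "), "um\n")
  invisible(x)
}

#' Chamber polygon
#'
#' Axis-aligned polygon (4 x 2 matrix of µm vertices, counter-clockwise) of
#' a chamber's canonical rectangle, or of one of its unit replicates.
#'
#' @param model A `scaffold_model`.
#' @param id Chamber id.
#' @param unit Unit replicate index; `NULL` for the canonical rectangle.
#' @return A 4 x 2 matrix with columns x, y.
#' @export
chamber_polygon <- function(model, id, unit = NULL) {
  ch <- model$chambers[model$chambers$id == id, ]
  if (nrow(ch) != 1) stop("chamber_polygon: unknown chamber id ", id, call. = FALSE)
  if (is.null(unit)) {
    x0 <- ch$x0; x1 <- ch$x1
  } else {
    rep <- model$chamber_replicates
    rep <- rep[rep$chamber_id == id & rep$unit == unit, ]
    if (nrow(rep) != 1) stop("chamber_polygon: unknown unit replicate", call. = FALSE)
    x0 <- rep$x0; x1 <- rep$x1
  }
  cbind(x = c(x0, x1, x1, x0), y = c(ch$y0, ch$y0, ch$y1, ch$y1))
}

#' Scaffold bounding volume
#'
#' Product of the bounding-box width, depth and height (design dimensions,
#' centre-of-line convention).
#'
#' @param model A `scaffold_model`.
#' @return Volume in µm³.
#' @export
scaffold_volume <- function(model) {
  prod(model$bounding_box)
}

#' Rasterize a scaffold to a label mask
#'
#' Draws wall material (long and cross walls, dilated by half the line
#' thickness, including line ends) and niche zones (within `niche_depth` of
#' a long-wall centreline along its extent, excluding wall material) onto a
#' pixel grid. Pixel (row i, col j) has its centre at
#' `((j - 0.5) * pixel_size, (i - 0.5) * pixel_size)` in µm, origin at the
#' scaffold corner.
#'
#' @param model A `scaffold_model`.
#' @param pixel_size Pixel size (µm/px).
#' @param width,height Raster extent in µm; default the bounding box.
#' @return An object of class `label_mask`: list with integer matrix `grid`
#'   (0 background, 1 wall material, 2 niche zone), `pixel_size`, `extent`.
#' @export
rasterize_scaffold <- function(model, pixel_size = 1.66,
                               width = NULL, height = NULL) {
  if (pixel_size <= 0) stop("rasterize_scaffold: pixel_size must be > 0", call. = FALSE)
  p <- model$params
  if (pixel_size > p$line_thickness && p$line_thickness > 0) {
    warning("pixel_size exceeds line_thickness; rasterized walls may vanish")
  }
  if (is.null(width)) width <- unname(model$bounding_box["width"])
  if (is.null(height)) height <- unname(model$bounding_box["depth"])
  nx <- max(1L, ceiling(width / pixel_size))
  ny <- max(1L, ceiling(height / pixel_size))
  xc <- (seq_len(nx) - 0.5) * pixel_size
  yc <- (seq_len(ny) - 0.5) * pixel_size
  half <- p$line_thickness / 2

  grid <- matrix(0L, nrow = ny, ncol = nx)
  if (nrow(model$walls) > 0) {
    # niche zones first, wall material drawn on top
    for (i in seq_len(nrow(model$walls))) {
      w <- model$walls[i, ]
      rows <- which(abs(yc - w$y) <= p$niche_depth)
      cols <- which(xc >= w$x0 & xc < w$x1)
      grid[rows, cols] <- 2L
    }
    for (i in seq_len(nrow(model$walls))) {
      w <- model$walls[i, ]
      rows <- which(abs(yc - w$y) <= half)
      cols <- which(xc >= w$x0 - half & xc <= w$x1 + half)
      grid[rows, cols] <- 1L
    }
    cw <- model$cross_walls
    for (i in seq_len(nrow(cw))) {
      cols <- which(abs(xc - cw$x[i]) <= half)
      rows <- which(yc >= cw$y0[i] - half & yc <= cw$y1[i] + half)
      grid[rows, cols] <- 1L
    }
  }
  mask <- list(grid = grid, pixel_size = pixel_size,
               extent = c(width = nx * pixel_size, height = ny * pixel_size))
  class(mask) <- "label_mask"
  mask
}

#' @export
print.label_mask <- function(x, ...) {
  tab <- table(factor(x$grid, levels = 0:2))
  cat("label_mask:", nrow(x$grid), "x", ncol(x$grid), "px at",
      x$pixel_size, "um/px\n")
  cat("  background:", tab[["0"]], " wall:", tab[["1"]], " niche zone:",
      tab[["2"]], "px\n")
  invisible(x)
}

# Pixel (row, col) index sets of one chamber replicate rectangle, from pixel
# centres, half-open in x and between the bounding wall centrelines in y.
# Wall-material pixels are excluded.
chamber_pixel_sets <- function(model, mask, id) {
  reps <- model$chamber_replicates[model$chamber_replicates$chamber_id == id, ]
  px <- mask$pixel_size
  ny <- nrow(mask$grid); nx <- ncol(mask$grid)
  xc <- (seq_len(nx) - 0.5) * px
  yc <- (seq_len(ny) - 0.5) * px
  lapply(seq_len(nrow(reps)), function(i) {
    r <- reps[i, ]
    rows <- which(yc > r$y0 & yc < r$y1)
    cols <- which(xc >= r$x0 & xc < r$x1)
    if (!length(rows) || !length(cols)) {
      return(list(cells = integer(0), niche = integer(0)))
    }
    idx <- as.vector(outer(rows, (cols - 1L) * ny, `+`))
    lab <- mask$grid[idx]
    list(cells = idx[lab != 1L], niche = idx[lab == 2L])
  })
}
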