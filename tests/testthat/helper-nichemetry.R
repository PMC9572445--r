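# Small geometries and imaging configs shared across tests.

# Two sets of two walls, one unit per wall: 14 chambers, fast to rasterize.
small_model <- function(separations = c(20, 35)) {
  build_scaffold(scaffold_params(
    n_sets = length(separations), walls_per_set = 2, units_per_wall = 1,
    wall_separations = separations, total_depth = NULL))
}

# Coarse acquisition over a small field of view.
tiny_imaging <- function(pixel_size = 1, fov = c(60, 40), n_slices = 4,
                         counts_scale = 5000, gaussian_sd = 2) {
  imaging_config(pixel_size = pixel_size, fov = fov, n_slices = n_slices,
                 z_step = 2, spectral = spectral_config(405),
                 counts_scale = counts_scale, gaussian_sd = gaussian_sd)
}

# A hyperspectral stack built directly from an abundance matrix and an
# endmember matrix, bypassing the renderer (for unmixing oracles).
stack_from_abundance <- function(A, E, nz = 1, ny = NULL, nx = NULL,
                                 spectral = spectral_config(405)) {
  N <- ncol(A)
  if (is.null(ny)) { ny <- 1; nx <- N / nz } else if (is.null(nx)) nx <- N / (nz * ny)
  Y <- E %*% A                       # C x N
  data <- array(0, c(nz, nrow(E), ny, nx))
  flat <- array(t(Y), c(nz, ny, nx, nrow(E)))
  data <- aperm(flat, c(1, 4, 2, 3))
  im <- imaging_config(pixel_size = 1, fov = c(nx, ny), n_slices = nz,
                       z_step = 2, spectral = spectral)
  structure(list(data = data, imaging = im,
                 excitation_nm = spectral$excitation_nm,
                 endmember_names = colnames(E)),
            class = "hyperspectral_stack")
}

# Reference NNLS through pracma, one voxel at a time (independent oracle).
oracle_nnls <- function(E, y) {
  if (!requireNamespace("pracma", quietly = TRUE)) {
    testthat::skip("pracma not available for the NNLS oracle")
  }
  as.numeric(pracma::lsqnonneg(E, as.numeric(y))$x)
}

# Exhaustive minimum-total-distance assignment tracker for <= 5 cells:
# considers every per-timepoint permutation assignment linking all cells,
# subject to the same radius bound, and minimises the summed step length.
oracle_assignment_tracks <- function(detections, N) {
  nT <- length(detections)
  k <- nrow(detections[[1]])
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  stopifnot(all(vapply(detections, nrow, integer(1)) == k), k <= 5)
  assign_seq <- list(seq_len(k))
  best <- NULL; best_cost <- Inf
  recurse <- function(t, maps, cost) {
    if (cost >= best_cost) return()
    if (t > nT) { best_cost <<- cost; best <<- maps; return() }
    for (p in perms(seq_len(k))) {
      prev <- detections[[t - 1]][maps[[t - 1]], , drop = FALSE]
      nxt <- detections[[t]][p, , drop = FALSE]
      d <- sqrt(rowSums((prev - nxt)^2))
      if (all(d <= N)) recurse(t + 1, c(maps, list(p)), cost + sum(d))
    }
  }
  recurse(2, list(seq_len(k)), 0)
  if (is.null(best)) return(NULL)
  lapply(seq_len(k), function(i) {
    t(vapply(seq_len(nT), function(t) {
      as.numeric(detections[[t]][best[[t]][i], ])
    }, numeric(2)))
  })
}
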