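#' ROI set for endmember estimation
#'
#' Named regions of interest, one per endmember, on a single Z slice of a
#' stack. Each region is a logical Y x X matrix; regions must be non-empty
#' and pairwise disjoint.
#'
#' @param regions Named list of logical matrices of identical dimensions.
#' @param slice Z slice index the ROIs refer to.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(regions, slice = 1) {
  if (is.null(names(regions)) || any(names(regions) == "")) {
    stop("roi_set: regions must be named", call. = FALSE)
  }
  dims <- unique(lapply(regions, dim))
  if (length(dims) != 1) stop("roi_set: regions have differing dimensions", call. = FALSE)
  npix <- vapply(regions, sum, numeric(1))
  if (any(npix < 1)) {
    stop("roi_set: empty ROI: ", paste(names(regions)[npix < 1], collapse = ", "),
         call. = FALSE)
  }
  overlap <- Reduce(`+`, lapply(regions, function(m) m * 1L))
  if (any(overlap > 1)) stop("roi_set: ROIs overlap", call. = FALSE)
  structure(list(regions = regions, slice = as.integer(slice)), class = "roi_set")
}

#' Rectangular ROI helper
#'
#' @param dim Image dimensions `c(ny, nx)`.
#' @param rows,cols Pixel row and column index ranges included in the ROI.
#' @return Logical matrix usable in [roi_set()].
#' @export
roi_rect <- function(dim, rows, cols) {
  m <- matrix(FALSE, dim[1], dim[2])
  m[rows, cols] <- TRUE
  m
}

#' Estimate endmember spectra from ROIs
#'
#' Per ROI, the mean spectrum over the selected pixels of the given slice,
#' unit-sum normalized — the manual-ROI step of lambda-mode linear
#' unmixing. A warning is raised when the resulting endmember matrix is
#' ill-conditioned (near-identical ROI spectra).
#'
#' @param stack A `hyperspectral_stack`.
#' @param rois A [roi_set()] congruent with the stack's XY plane.
#' @param condition_threshold Condition number above which to warn.
#' @return Named list of `endmember` objects.
#' @export
estimate_endmembers <- function(stack, rois, condition_threshold = 1e6) {
  d <- dim(stack$data)
  rd <- dim(rois$regions[[1]])
  if (!identical(as.integer(rd), as.integer(d[3:4]))) {
    stop("estimate_endmembers: ROI dimensions ", paste(rd, collapse = "x"),
         " do not match image plane ", paste(d[3:4], collapse = "x"), call. = FALSE)
  }
  if (rois$slice < 1 || rois$slice > d[1]) {
    stop("estimate_endmembers: ROI slice outside the stack", call. = FALSE)
  }
  plane <- stack$data[rois$slice, , , , drop = TRUE]  # C x Y x X
  dim(plane) <- c(d[2], d[3] * d[4])
  centers <- stack$imaging$spectral$channel_centers
  ems <- lapply(names(rois$regions), function(nm) {
    idx <- which(as.vector(rois$regions[[nm]]))
    w <- rowMeans(plane[, idx, drop = FALSE])
    w <- pmax(w, 0)
    if (sum(w) <= 0) stop("estimate_endmembers: ROI '", nm, "' has no signal",
                          call. = FALSE)
    structure(list(name = nm, weights = w / sum(w), channel_centers = centers),
              class = "endmember")
  })
  names(ems) <- names(rois$regions)
  E <- endmember_matrix(ems)
  if (ncol(E) > 1) {
    kap <- kappa(E, exact = TRUE)
    if (!is.finite(kap) || kap > condition_threshold) {
      warning("estimate_endmembers: endmember matrix is ill-conditioned (",
              format(kap, digits = 3), "); ROI spectra may be near-identical")
    }
  }
  ems
}

# Names of the most collinear endmember pair, for the rank-deficiency error.
most_collinear_pair <- function(E) {
  nms <- colnames(E)
  best <- c(NA, NA); bc <- -1
  for (i in seq_len(ncol(E) - 1)) {
    for (j in (i + 1):ncol(E)) {
      cc <- abs(sum(E[, i] * E[, j]) / sqrt(sum(E[, i]^2) * sum(E[, j]^2)))
      if (cc > bc) { bc <- cc; best <- c(nms[i], nms[j]) }
    }
  }
  best
}

#' Linearly unmix a hyperspectral stack
#'
#' Per-voxel least-squares decomposition of the measured spectrum into
#' endmember abundances: `min ||E a - y||` over `a` (with `a >= 0` in
#' `"nnls"` mode). Voxels are independent; the result is deterministic.
#'
#' @param stack A `hyperspectral_stack`.
#' @param endmembers Endmember list (e.g. from [estimate_endmembers()] or
#'   [default_endmembers()]); the mixing matrix must have full column rank.
#' @param mode `"nnls"` (non-negative, the default — abundances are physical
#'   material amounts) or `"ols"` (unconstrained).
#' @return An object of class `abundance_stack`: list with `abundance`
#'   (named list of Z x Y x X arrays), `residual` (Z x Y x X per-voxel RMS
#'   misfit), `mode` and `endmember_names`.
#' @export
unmix <- function(stack, endmembers, mode = c("nnls", "ols")) {
  mode <- match.arg(mode)
  E <- endmember_matrix(endmembers)
  d <- dim(stack$data)
  if (nrow(E) != d[2]) {
    stop("unmix: endmember channel count ", nrow(E),
         " does not match stack channels ", d[2], call. = FALSE)
  }
  if (qr(E)$rank < ncol(E)) {
    pair <- most_collinear_pair(E)
    stop("unmix: endmember matrix is rank deficient; '", pair[1], "' and '",
         pair[2], "' are collinear", call. = FALSE)
  }
  N <- prod(d[c(1, 3, 4)])
  if (!is.null(stack$spectra) &&
      all(dim(stack$spectra) == c(N, d[2]))) {
    Y <- stack$spectra   # voxels-by-channel layout cached by the renderer
  } else {
    Y <- aperm(stack$data, c(1, 3, 4, 2))
    dim(Y) <- c(N, d[2])
  }
  sol <- cpp_unmix(E, Y, mode == "nnls", 1e-9)
  A <- sol$A
  resid <- sqrt(pmax(sol$rss, 0) / d[2])
  rm(Y)
  nms <- colnames(E)
  ab <- lapply(seq_len(ncol(E)), function(i) array(A[i, ], d[c(1, 3, 4)]))
  names(ab) <- nms
  out <- list(abundance = ab, residual = array(resid, d[c(1, 3, 4)]),
              mode = mode, endmember_names = nms)
  class(out) <- "abundance_stack"
  out
}

#' @export
print.abundance_stack <- function(x, ...) {
  d <- dim(x$residual)
  cat("abundance_stack (", x$mode, "): ", paste(x$endmember_names, collapse = ", "),
      "; ", d[1], " x ", d[2], " x ", d[3], " voxels\n", sep = "")
  cat("  mean residual:", signif(mean(x$residual), 4), "\n")
  invisible(x)
}

#' Mask scaffold pixels out of cell abundance maps
#'
#' Zeroes wall-material pixels (label 1) in every non-scaffold abundance
#' map, across all Z slices. The scaffold abundance itself is retained
#' unchanged as a position marker.
#'
#' @param abundances An `abundance_stack`.
#' @param mask A `label_mask` congruent with the stack's XY plane.
#' @return The masked `abundance_stack` (field `masked = TRUE`).
#' @export
masked_views <- function(abundances, mask) {
  d <- dim(abundances$residual)
  if (nrow(mask$grid) != d[2] || ncol(mask$grid) != d[3]) {
    stop("masked_views: mask grid ", nrow(mask$grid), "x", ncol(mask$grid),
         " does not match stack plane ", d[2], "x", d[3], call. = FALSE)
  }
  wall <- mask$grid == 1L
  for (nm in setdiff(abundances$endmember_names, "scaffold")) {
    arr <- abundances$abundance[[nm]]
    for (k in seq_len(d[1])) {
      plane <- arr[k, , ]
      plane[wall] <- 0
      arr[k, , ] <- plane
    }
    abundances$abundance[[nm]] <- arr
  }
  abundances$masked <- TRUE
  abundances
}
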