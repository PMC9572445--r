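#' Spectral detection configuration
#'
#' Channel grid of a lambda-mode (spectrally resolved) confocal acquisition.
#' Channel centres are evenly spaced from `range_start_nm` to `range_end_nm`;
#' with the instrument presets this gives 32 channels (405 nm excitation,
#' 416-687 nm) or 23 channels (488 nm excitation, 494-687 nm) at a nominal
#' 9 nm bin width.
#'
#' @param excitation_nm Excitation wavelength; 405 and 488 select presets.
#' @param range_start_nm,range_end_nm Detection range endpoints (nm).
#' @param n_channels Number of detection channels.
#' @param bin_width_nm Nominal channel width (nm).
#' @return An object of class `spectral_config` with channel centres and
#'   bin edges.
#' @export
spectral_config <- function(excitation_nm = 405,
                            range_start_nm = NULL, range_end_nm = NULL,
                            n_channels = NULL, bin_width_nm = 9) {
  if (is.null(range_start_nm)) {
    if (excitation_nm == 405) {
      range_start_nm <- 416; range_end_nm <- 687; n_channels <- 32L
    } else if (excitation_nm == 488) {
      range_start_nm <- 494; range_end_nm <- 687; n_channels <- 23L
    } else {
      stop("spectral_config: no preset for excitation ", excitation_nm,
           " nm; supply the range and channel count", call. = FALSE)
    }
  }
  if (is.null(n_channels) || n_channels < 2) {
    stop("spectral_config: n_channels must be >= 2", call. = FALSE)
  }
  centers <- seq(range_start_nm, range_end_nm, length.out = n_channels)
  spacing <- centers[2] - centers[1]
  if (abs(n_channels * bin_width_nm - (range_end_nm - range_start_nm)) >
      max(2 * bin_width_nm, 2 * spacing)) {
    stop("spectral_config: channel count, bin width and range are inconsistent",
         call. = FALSE)
  }
  cfg <- list(excitation_nm = excitation_nm,
              range_start_nm = range_start_nm, range_end_nm = range_end_nm,
              n_channels = as.integer(n_channels),
              bin_width_nm = bin_width_nm,
              channel_centers = centers, channel_spacing = spacing)
  class(cfg) <- "spectral_config"
  cfg
}

#' @export
print.spectral_config <- function(x, ...) {
  cat("spectral_config: exc.", x$excitation_nm, "nm,", x$n_channels,
      "channels", x$range_start_nm, "-", x$range_end_nm, "nm (",
      round(x$channel_spacing, 2), "nm spacing )\n")
  invisible(x)
}

#' Construct an endmember emission spectrum
#'
#' Builds a reference (endmember) spectrum on a detection channel grid.
#' Gaussian line shapes are integrated over each channel bin; `"broad"`
#' gives a sloped profile spanning all channels (polymer autofluorescence
#' style, stronger at the blue end); `"flat"` gives a constant profile
#' (background). All spectra are normalized to unit sum so that unmixed
#' abundances carry the intensity units of the data.
#'
#' @param name Endmember name, e.g. `"scaffold"`, `"nuclei"`, `"cytoplasm"`,
#'   `"background"`.
#' @param config A [spectral_config()].
#' @param shape Either the string `"broad"` or `"flat"`, or a list with
#'   `peak_nm` and `fwhm_nm` for a Gaussian line.
#' @return An object of class `endmember`: list with `name`, unit-sum
#'   `weights` and `channel_centers`.
#' @export
make_endmember <- function(name, config, shape) {
  centers <- config$channel_centers
  sp <- config$channel_spacing
  if (is.character(shape) && length(shape) == 1) {
    if (shape == "broad") {
      # downward slope, 3:1 blue-to-red
      w <- 3 - 2 * (centers - centers[1]) / (centers[length(centers)] - centers[1])
    } else if (shape == "flat") {
      w <- rep(1, length(centers))
    } else {
      stop("make_endmember: unknown shape '", shape, "'", call. = FALSE)
    }
  } else {
    if (is.null(shape$peak_nm) || is.null(shape$fwhm_nm)) {
      stop("make_endmember: shape needs peak_nm and fwhm_nm", call. = FALSE)
    }
    if (shape$fwhm_nm <= 0) {
      stop("make_endmember: fwhm_nm must be > 0", call. = FALSE)
    }
    sigma <- shape$fwhm_nm / (2 * sqrt(2 * log(2)))
    lo <- centers - sp / 2
    hi <- centers + sp / 2
    w <- stats::pnorm(hi, shape$peak_nm, sigma) - stats::pnorm(lo, shape$peak_nm, sigma)
    if (sum(w) <= 0) {
      stop("make_endmember: peak lies entirely outside the detection range",
           call. = FALSE)
    }
  }
  em <- list(name = name, weights = w / sum(w), channel_centers = centers)
  class(em) <- "endmember"
  em
}

#' Default endmember set
#'
#' The four emitters of the synthetic imaging model on a given channel grid:
#' broad scaffold autofluorescence, a Hoechst-like nucleus stain (peak
#' 460 nm, FWHM 50 nm), a CF488-like cytoplasm stain (peak 515 nm, FWHM
#' 40 nm) and a flat background.
#'
#' @param config A [spectral_config()].
#' @return Named list of [make_endmember()] objects.
#' @export
default_endmembers <- function(config = spectral_config(405)) {
  list(
    scaffold   = make_endmember("scaffold", config, "broad"),
    nuclei     = make_endmember("nuclei", config, list(peak_nm = 460, fwhm_nm = 50)),
    cytoplasm  = make_endmember("cytoplasm", config, list(peak_nm = 515, fwhm_nm = 40)),
    background = make_endmember("background", config, "flat")
  )
}

#' Endmember matrix
#'
#' Stacks endmember weight vectors into the channels x endmembers mixing
#' matrix used by the unmixer.
#'
#' @param endmembers List of `endmember` objects.
#' @return Numeric matrix, one unit-sum column per endmember.
#' @export
endmember_matrix <- function(endmembers) {
  n <- vapply(endmembers, function(e) length(e$weights), integer(1))
  if (length(unique(n)) != 1) {
    stop("endmember_matrix: endmembers are on different channel grids", call. = FALSE)
  }
  E <- vapply(endmembers, function(e) e$weights, numeric(n[1]))
  colnames(E) <- vapply(endmembers, function(e) e$name, character(1))
  E
}

#' UV-quench decay model
#'
#' Single-exponential decay of scaffold autofluorescence under UV
#' treatment: `I(t) = I0 * exp(-k * t)`.
#'
#' @param I0 Intensity at `t = 0` (arbitrary units, > 0).
#' @param k Decay rate (per minute, >= 0).
#' @return An object of class `quench_model`.
#' @export
quench_model <- function(I0 = 1, k = quench_rate()) {
  if (I0 <= 0) stop("quench_model: I0 must be > 0", call. = FALSE)
  if (k < 0) stop("quench_model: k must be >= 0", call. = FALSE)
  structure(list(I0 = I0, k = k), class = "quench_model")
}

#' Decay rate from an endpoint fraction
#'
#' Rate constant of a single exponential that retains `fraction` of its
#' initial intensity after `t` minutes: `k = log(1/fraction) / t`. The
#' defaults correspond to autofluorescence reduced to 22% after 150 min of
#' UV treatment.
#'
#' @param fraction Remaining intensity fraction at time `t`.
#' @param t Treatment duration (minutes).
#' @return Decay rate in min^-1.
#' @export
quench_rate <- function(fraction = 0.22, t = 150) {
  if (fraction <= 0 || fraction > 1 || t <= 0) {
    stop("quench_rate: need 0 < fraction <= 1 and t > 0", call. = FALSE)
  }
  log(1 / fraction) / t
}

#' Quenched intensity
#'
#' @param model A [quench_model()].
#' @param t Time in minutes (>= 0); vectorized.
#' @return Intensity `I0 * exp(-k * t)`.
#' @export
quench_intensity <- function(model, t) {
  if (any(t < 0)) stop("quench_intensity: t must be >= 0", call. = FALSE)
  model$I0 * exp(-model$k * t)
}

#' Fit the quench decay to timed intensity samples
#'
#' Least-squares line fit of log-intensity against time, mirroring the
#' log-scale linear trend of the bleaching data. Returns the implied
#' exponential parameters and the fit R².
#'
#' @param t Times (minutes), at least 3 distinct values.
#' @param intensity Positive integrated intensities, same length as `t`.
#' @return An object of class `quench_fit`: list with `I0`, `k`,
#'   `r_squared` (NA when the response is constant) and `constant` flag.
#' @export
fit_quench <- function(t, intensity) {
  if (length(t) != length(intensity)) {
    stop("fit_quench: t and intensity lengths differ", call. = FALSE)
  }
  if (length(unique(t)) < 3) {
    stop("fit_quench: need >= 3 distinct time points", call. = FALSE)
  }
  if (any(intensity <= 0)) {
    stop("fit_quench: intensities must be > 0 (log-linear fit)", call. = FALSE)
  }
  y <- log(intensity)
  fit <- stats::lm(y ~ t)
  k <- -unname(stats::coef(fit)[2])
  I0 <- exp(unname(stats::coef(fit)[1]))
  ssy <- sum((y - mean(y))^2)
  constant <- ssy < .Machine$double.eps * length(y)
  r2 <- if (constant) NA_real_ else 1 - sum(stats::residuals(fit)^2) / ssy
  structure(list(I0 = I0, k = k, r_squared = r2, constant = constant),
            class = "quench_fit")
}

#' @export
print.quench_fit <- function(x, ...) {
  cat("quench_fit: I0 =", signif(x$I0, 6), ", k =", signif(x$k, 6),
      "min^-1, R^2 =", signif(x$r_squared, 4), "\n")
  invisible(x)
}

#' Write endmember spectra to CSV
#'
#' @param endmembers List of `endmember` objects on one channel grid.
#' @param path Output CSV path (columns: channel_center_nm, one per endmember).
#' @return The path, invisibly.
#' @export
write_endmembers <- function(endmembers, path) {
  E <- endmember_matrix(endmembers)
  df <- data.frame(channel_center_nm = endmembers[[1]]$channel_centers, E,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read endmember spectra from CSV
#'
#' @param path CSV written by [write_endmembers()].
#' @return Named list of `endmember` objects (weights re-normalized to unit
#'   sum).
#' @export
read_endmembers <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  centers <- df$channel_center_nm
  nms <- setdiff(names(df), "channel_center_nm")
  out <- lapply(nms, function(nm) {
    w <- df[[nm]]
    structure(list(name = nm, weights = w / sum(w), channel_centers = centers),
              class = "endmember")
  })
  names(out) <- nms
  out
}
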