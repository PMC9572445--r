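#' Write a hyperspectral stack to multi-page TIFF
#'
#' Pages are ordered Z-major, channel-minor (page = (z-1)*C + c). A JSON
#' sidecar (`<path>.json`) records the axis order, dimensions, calibration
#' and the intensity scale used to fit the data into the 32-bit float
#' `[0, 1]` range; [read_stack()] restores the original values from it.
#'
#' @param stack A `hyperspectral_stack`, or a plain Z x C x Y x X (or Z x Y
#'   x X, or Y x X) numeric array.
#' @param path Output TIFF path.
#' @param pixel_size,z_step Calibration (µm) recorded in the sidecar when
#'   `stack` is a plain array.
#' @return The path, invisibly.
#' @export
write_stack <- function(stack, path, pixel_size = NA, z_step = NA) {
  if (inherits(stack, "hyperspectral_stack")) {
    data <- stack$data
    pixel_size <- stack$imaging$pixel_size
    z_step <- stack$imaging$z_step
    excitation <- stack$excitation_nm
    centers <- stack$imaging$spectral$channel_centers
  } else {
    data <- stack
    excitation <- NA
    centers <- NULL
  }
  d <- dim(data)
  if (is.null(d)) d <- c(1L, 1L, 1L, length(data))
  if (length(d) == 2) d <- c(1L, 1L, d)
  if (length(d) == 3) d <- c(d[1], 1L, d[2], d[3])
  dim(data) <- d
  lo <- min(data); hi <- max(data)
  scale <- if (hi > lo) hi - lo else 1
  pages <- vector("list", d[1] * d[2])
  k <- 0L
  for (z in seq_len(d[1])) {
    for (cc in seq_len(d[2])) {
      k <- k + 1L
      pages[[k]] <- (data[z, cc, , ] - lo) / scale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(axes = "ZCYX", dim = as.integer(d), offset = lo, scale = scale,
               pixel_size_um = pixel_size, z_step_um = z_step,
               excitation_nm = excitation, channel_centers_nm = centers)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a stack written by [write_stack()]
#'
#' Restores a Z x C x Y x X array (missing axes broadcast to length 1) and
#' its calibration from the TIFF pages and the JSON sidecar. Without a
#' sidecar, a single-page TIFF is read as Z = 1, C = 1; a multi-page TIFF
#' needs an explicit `axes` override, otherwise the axis assignment is
#' ambiguous and an error lists what was found.
#'
#' @param path TIFF path.
#' @param axes Optional override, e.g. `list(n_z = 12, n_c = 32)`, used when
#'   no sidecar is present.
#' @return List with `data` (Z x C x Y x X array), `pixel_size_um`,
#'   `z_step_um`, `excitation_nm`, `channel_centers_nm`.
#' @export
read_stack <- function(path, axes = NULL) {
  if (!file.exists(path)) stop("read_stack: no such file: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  np <- length(pages)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else NULL
  if (is.null(meta)) {
    if (np == 1 && is.null(axes)) {
      d <- c(1L, 1L, dim(pages[[1]]))
      meta <- list(offset = 0, scale = 1, pixel_size_um = NA, z_step_um = NA,
                   excitation_nm = NA, channel_centers_nm = NULL)
    } else if (!is.null(axes)) {
      d <- c(as.integer(axes$n_z), as.integer(axes$n_c), dim(pages[[1]]))
      if (prod(d[1:2]) != np) {
        stop("read_stack: axes override (", d[1], " x ", d[2],
             ") does not match ", np, " pages", call. = FALSE)
      }
      meta <- list(offset = 0, scale = 1, pixel_size_um = axes$pixel_size_um %||% NA,
                   z_step_um = axes$z_step_um %||% NA, excitation_nm = NA,
                   channel_centers_nm = NULL)
    } else {
      stop("read_stack: ", np, " pages of ", nrow(pages[[1]]), " x ",
           ncol(pages[[1]]), " px but no sidecar metadata; axis order is ",
           "ambiguous - pass an `axes` override", call. = FALSE)
    }
  } else {
    d <- as.integer(meta$dim)
    if (prod(d[1:2]) != np) {
      stop("read_stack: sidecar declares ", prod(d[1:2]), " pages, file has ",
           np, call. = FALSE)
    }
  }
  data <- array(0, d)
  k <- 0L
  for (z in seq_len(d[1])) {
    for (cc in seq_len(d[2])) {
      k <- k + 1L
      data[z, cc, , ] <- pages[[k]] * meta$scale + meta$offset
    }
  }
  list(data = data, pixel_size_um = meta$pixel_size_um,
       z_step_um = meta$z_step_um, excitation_nm = meta$excitation_nm,
       channel_centers_nm = meta$channel_centers_nm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a run configuration
#'
#' One document holding the scaffold, imaging and tracking settings and the
#' single seed governing a run; round-trips through YAML unchanged.
#'
#' @param scaffold A [scaffold_params()].
#' @param imaging An [imaging_config()].
#' @param tracking A [tracking_config()].
#' @param seed Integer seed for the whole run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(scaffold = scaffold_params(),
                       imaging = imaging_config(),
                       tracking = tracking_config(), seed = 1L) {
  structure(list(scaffold = scaffold, imaging = imaging, tracking = tracking,
                 seed = as.integer(seed)), class = "run_config")
}

#' Write a run configuration to YAML
#'
#' @param config A [run_config()].
#' @param path Output YAML path.
#' @return The path, invisibly.
#' @export
write_config <- function(config, path) {
  im <- unclass(config$imaging)
  im$nx <- NULL; im$ny <- NULL  # derived
  sp <- unclass(config$imaging$spectral)
  sp$channel_centers <- NULL; sp$channel_spacing <- NULL  # derived
  im$spectral <- sp
  doc <- list(scaffold = unclass(config$scaffold), imaging = im,
              tracking = unclass(config$tracking), seed = config$seed)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' @param path YAML written by [write_config()].
#' @return A [run_config()].
#' @export
read_config <- function(path) {
  doc <- yaml::read_yaml(path)
  sc <- do.call(scaffold_params, doc$scaffold)
  sp <- do.call(spectral_config, doc$imaging$spectral)
  im_args <- doc$imaging
  im_args$spectral <- NULL
  im <- do.call(imaging_config, c(im_args, list(spectral = sp)))
  tr <- do.call(tracking_config, doc$tracking)
  run_config(scaffold = sc, imaging = im, tracking = tr, seed = doc$seed)
}

md_table <- function(df, digits = 4) {
  fmt <- function(x) {
    if (is.numeric(x)) formatC(x, digits = digits, format = "g") else as.character(x)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, rule, body)
}

#' Write a run report
#'
#' Deterministic Markdown summary of analysis outputs: the per-chamber
#' packing table (with its aggregation over wall-separation classes) and
#' the per-region motility table. At least one input must be supplied;
#' anything missing is listed in the error.
#'
#' @param path Output Markdown path.
#' @param packing Optional `packing_table`.
#' @param motility Optional motility summary from [summarize_motility()].
#' @param title Report title.
#' @return The path, invisibly.
#' @export
report <- function(path, packing = NULL, motility = NULL,
                   title = "nichemetry run report") {
  if (is.null(packing) && is.null(motility)) {
    stop("report: nothing to report - missing inputs: packing, motility",
         call. = FALSE)
  }
  lines <- c(paste("#", title), "")
  if (!is.null(packing)) {
    lines <- c(lines, "## Per-chamber packing", "",
               paste0("Chambers: ", length(unique(packing$chamber_id)),
                      "; endmembers: ",
                      paste(unique(packing$endmember), collapse = ", ")), "",
               md_table(as.data.frame(packing)), "",
               "## Packing by wall separation", "",
               md_table(aggregate_packing(packing)), "")
  }
  if (!is.null(motility)) {
    lines <- c(lines, "## Motility by region", "", md_table(motility), "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the chamber design table to CSV
#'
#' One row per chamber: identity, niche size, wall separation, footprint,
#' opening and isotropic niche-occupancy ratio.
#'
#' @param model A `scaffold_model`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_chamber_table <- function(model, path) {
  cols <- c("id", "set", "gap", "section", "niche_size", "wall_separation",
            "footprint_area", "opening_size", "isotropic_ratio")
  utils::write.csv(model$chambers[, cols], path, row.names = FALSE)
  invisible(path)
}
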