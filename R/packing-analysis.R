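#' Per-chamber abundance sums
#'
#' Sums unmixed cellular abundance per chamber over the full stack height,
#' splitting off the part inside the niche (wall-contact) zones. Pixels are
#' assigned by pixel centre; wall-material pixels belong to neither the
#' numerator nor the denominator (cells cannot occupy polymer). A chamber's
#' unit replicates along the wall are pooled and the per-replicate mean
#' reported, so chambers of different replication remain comparable.
#'
#' @param abundances An `abundance_stack` (typically after [masked_views()]).
#' @param model The `scaffold_model` that generated the geometry.
#' @param mask A `label_mask` congruent with the abundance XY plane.
#' @param endmembers Which abundance maps to tabulate.
#' @param unit_area Reference area for density normalization (µm²); default
#'   the smallest chamber footprint, 200 µm².
#' @return A `packing_table` data.frame with one row per chamber x
#'   endmember: chamber identity and design columns, `n_replicates`,
#'   `n_pixels` (per replicate, canonical), `total_abundance` and
#'   `niche_abundance` (per-replicate means over the full height),
#'   `density_per_unit_area`, `niche_ratio`, `isotropic_ratio`, `flagged`.
#'   Attribute `out_of_chamber` holds, per endmember, the image abundance
#'   not assigned to any chamber replicate, so that
#'   `sum(total * n_replicates) + out_of_chamber` equals the grand total.
#' @export
sum_per_chamber <- function(abundances, model, mask,
                            endmembers = intersect(c("nuclei", "cytoplasm"),
                                                   abundances$endmember_names),
                            unit_area = 200) {
  d <- dim(abundances$residual)
  if (nrow(mask$grid) != d[2] || ncol(mask$grid) != d[3]) {
    stop("sum_per_chamber: mask grid does not match abundance plane", call. = FALSE)
  }
  zsums <- lapply(endmembers, function(nm) {
    arr <- abundances$abundance[[nm]]
    if (is.null(arr)) stop("sum_per_chamber: no abundance map '", nm, "'",
                           call. = FALSE)
    colSums(arr, dims = 1)  # Y x X
  })
  names(zsums) <- endmembers

  ch <- model$chambers
  rows <- vector("list", nrow(ch) * length(endmembers))
  allocated <- stats::setNames(numeric(length(endmembers)), endmembers)
  k <- 0L
  for (i in seq_len(nrow(ch))) {
    sets <- chamber_pixel_sets(model, mask, ch$id[i])
    nrep <- length(sets)
    npix <- vapply(sets, function(s) length(s$cells), integer(1))
    for (nm in endmembers) {
      zs <- zsums[[nm]]
      tot <- vapply(sets, function(s) sum(zs[s$cells]), numeric(1))
      nic <- vapply(sets, function(s) sum(zs[s$niche]), numeric(1))
      allocated[nm] <- allocated[nm] + sum(tot)
      total <- mean(tot)
      niche <- mean(nic)
      k <- k + 1L
      rows[[k]] <- data.frame(
        chamber_id = ch$id[i], endmember = nm, set = ch$set[i],
        niche_size = ch$niche_size[i], wall_separation = ch$wall_separation[i],
        footprint_area = ch$footprint_area[i], opening_size = ch$opening_size[i],
        n_replicates = nrep, n_pixels = npix[1],
        total_abundance = total, niche_abundance = niche,
        density_per_unit_area = if (total > 0)
          density_per_unit_area(total, ch$footprint_area[i], unit_area) else 0,
        niche_ratio = if (total > 0) niche / total else NA_real_,
        isotropic_ratio = ch$isotropic_ratio[i],
        flagged = any(npix == 0) || total == 0
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("packing_table", "data.frame")
  attr(out, "out_of_chamber") <-
    vapply(endmembers, function(nm) sum(zsums[[nm]]), numeric(1)) - allocated
  attr(out, "unit_area") <- unit_area
  out
}

#' Unit-area-normalized density
#'
#' Rescales a chamber total to the reference (smallest-chamber) area:
#' `total * unit_area / footprint_area`.
#'
#' @param total Summed abundance in the chamber.
#' @param footprint_area Chamber footprint (µm², > 0).
#' @param unit_area Reference area (µm²).
#' @return Density in abundance per `unit_area`.
#' @export
density_per_unit_area <- function(total, footprint_area, unit_area = 200) {
  if (any(footprint_area <= 0)) {
    stop("density_per_unit_area: footprint_area must be > 0", call. = FALSE)
  }
  total * unit_area / footprint_area
}

#' Excess niche occupancy over the isotropic expectation
#'
#' Adds the signed excess `niche_ratio - isotropic_ratio` per row. Positive
#' excess means wall-contact enrichment beyond uniform packing; rows with
#' zero total are flagged and get `NA` excess.
#'
#' @param table A `packing_table` from [sum_per_chamber()].
#' @return The table with an `excess` column.
#' @export
compare_to_isotropic <- function(table) {
  if (!inherits(table, "packing_table")) {
    stop("compare_to_isotropic: not a packing_table", call. = FALSE)
  }
  table$excess <- ifelse(table$flagged | is.na(table$niche_ratio),
                         NA_real_, table$niche_ratio - table$isotropic_ratio)
  table
}

#' Aggregate a packing table over chamber classes
#'
#' Pools the replicate-weighted abundance sums within groups (by default the
#' wall-separation classes, for which the isotropic expectation is a single
#' number) and recomputes pooled niche ratios and mean densities.
#'
#' @param table A `packing_table`, or a row-bound concatenation of several
#'   (e.g. across simulation seeds).
#' @param by Grouping columns.
#' @return data.frame with pooled `total_abundance`, `niche_abundance`,
#'   `niche_ratio`, mean `density_per_unit_area` and `isotropic_ratio` per
#'   group and endmember.
#' @export
aggregate_packing <- function(table, by = "wall_separation") {
  f <- interaction(table[c(by, "endmember")], drop = TRUE)
  tot <- tapply(table$total_abundance * table$n_replicates, f, sum)
  nic <- tapply(table$niche_abundance * table$n_replicates, f, sum)
  den <- tapply(table$density_per_unit_area, f, mean)
  iso <- tapply(table$isotropic_ratio, f, mean)
  keys <- do.call(rbind, strsplit(names(tot), ".", fixed = TRUE))
  out <- data.frame(keys, total_abundance = as.numeric(tot),
                    niche_abundance = as.numeric(nic),
                    niche_ratio = as.numeric(nic / tot),
                    density_per_unit_area = as.numeric(den),
                    isotropic_ratio = as.numeric(iso))
  names(out)[seq_along(c(by, "endmember"))] <- c(by, "endmember")
  for (cl in by) {
    num <- suppressWarnings(as.numeric(out[[cl]]))
    if (!any(is.na(num))) out[[cl]] <- num
  }
  out[order(out$endmember, out[[by[1]]]), , drop = FALSE]
}
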