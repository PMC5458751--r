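# AIS segmentation (bounding-box filtered), apposition-based varicosity
# classification, and cartridge grouping.

#' Segment AIS objects from the AnkG-like channel
#'
#' Connected components of the thresholded AIS channel are measured by
#' their axis-aligned bounding box; a component is retained only if the box
#' exceeds 10 um in height (the y, pial-to-ventricular axis) and 2 um in
#' width.  The cutoffs follow the size of the smallest genuine AIS and are
#' strict (">").
#'
#' @param stack A `volume_stack` with an `ais` channel.
#' @param threshold Channel threshold; `NULL` uses [otsu_threshold()].
#' @param min_height_um,min_width_um Bounding-box cutoffs.
#' @param width_rule `"max"` (default) takes the larger of the x and z box
#'   extents as the width, `"min"` the smaller.
#' @return A list of `ais_object`s: `id`, `coords_um` (voxel centres),
#'   `bounding_box` (`height_um`, `width_um`), `principal_axis`, `n_voxels`.
#' @export
segment_ais <- function(stack, threshold = NULL,
                        min_height_um = 10, min_width_um = 2,
                        width_rule = c("max", "min")) {
  width_rule <- match.arg(width_rule)
  ch <- stack_channel(stack, "ais")
  th <- threshold %||% otsu_threshold(ch)
  fg_idx <- which(ch > th)
  if (!length(fg_idx)) return(list())
  dims <- dim(ch)
  memb <- foreground_components(fg_idx, dims)
  v <- stack$voxel_size
  out <- list()
  for (ci in seq_len(max(memb))) {
    sel <- fg_idx[memb == ci]
    if (length(sel) < 4L) next
    coords <- voxel_centers_um(arrayInd(sel, dims), stack)
    height <- diff(range(coords[, 2])) + v[2]
    wx <- diff(range(coords[, 1])) + v[1]
    wz <- diff(range(coords[, 3])) + v[3]
    width <- if (width_rule == "max") max(wx, wz) else min(wx, wz)
    if (!(height > min_height_um && width > min_width_um)) next
    pax <- stats::prcomp(coords, center = TRUE)$rotation[, 1]
    if (pax[2] < 0) pax <- -pax
    out[[length(out) + 1L]] <- structure(
      list(id = length(out) + 1L, coords_um = coords,
           bounding_box = c(height_um = height, width_um = width),
           principal_axis = pax, n_voxels = length(sel)),
      class = "ais_object")
  }
  out
}

#' @export
print.ais_object <- function(x, ...) {
  cat(sprintf("ais_object %d: %d voxels, bbox %.1f x %.1f um\n", x$id,
              x$n_voxels, x$bounding_box[1], x$bounding_box[2]))
  invisible(x)
}

#' Classification summary of AIS vs off-target varicosities
#'
#' The off-target count is defined by subtraction from the total, and the
#' per-AIS varicosity ratio by pooled division, mirroring how the summary
#' quantities are derived from the raw counts.
#'
#' @param n_total Total varicosities.
#' @param n_ais Varicosities apposed to an AIS.
#' @param n_cartridges Number of innervated AISs (optional).
#' @return An object of class `classification_summary` with fields
#'   `n_total`, `n_ais`, `n_off_target`, `pct_off_target` (fraction),
#'   `n_cartridges`, `varicosities_per_ais`.
#' @export
classification_summary <- function(n_total, n_ais, n_cartridges = NA_integer_) {
  if (n_ais > n_total) stop_chc("n_ais cannot exceed n_total")
  structure(list(
    n_total = n_total,
    n_ais = n_ais,
    n_off_target = n_total - n_ais,
    pct_off_target = if (n_total > 0) (n_total - n_ais) / n_total else NA_real_,
    n_cartridges = n_cartridges,
    varicosities_per_ais = if (!is.na(n_cartridges) && n_cartridges > 0)
      n_ais / n_cartridges else NA_real_
  ), class = "classification_summary")
}

#' @export
print.classification_summary <- function(x, ...) {
  cat(sprintf("varicosities: %d total = %d AIS + %d off-target (%.0f%% off)\n",
              x$n_total, x$n_ais, x$n_off_target, 100 * x$pct_off_target))
  if (!is.na(x$n_cartridges)) {
    cat(sprintf("cartridges: %d (%.1f varicosities per AIS)\n",
                x$n_cartridges, x$varicosities_per_ais))
  }
  invisible(x)
}

# Ellipsoid radius of a varicosity along unit direction u.
ellipsoid_radius <- function(u, r_xy, r_z) {
  1 / sqrt((u[, 1]^2 + u[, 2]^2) / r_xy^2 + u[, 3]^2 / r_z^2)
}

#' Classify varicosities as AIS or off-target by apposition
#'
#' A varicosity is apposed to an AIS when the gap between its fitted
#' ellipsoid surface and the AIS voxel set is at most `apposition_tol_um`
#' (contact at light-microscope resolution).  A varicosity apposed to two
#' AISs is assigned to the nearer one, ties to the lower id.  Every
#' varicosity receives exactly one label.
#'
#' @param varicosities Data frame from [detect_varicosities()] (or
#'   [manifest_varicosities()]).
#' @param ais_objects List from [segment_ais()].
#' @param apposition_tol_um Maximum surface-to-surface gap (um).
#' @return The input data frame with `label` (`"AIS"`/`"off_target"`),
#'   `ais_id`, and `ais_gap_um` columns filled in; the corresponding
#'   [classification_summary()] is attached as attribute `summary`.
#' @export
classify_varicosities <- function(varicosities, ais_objects,
                                  apposition_tol_um = 0.5) {
  n <- nrow(varicosities)
  varicosities$label <- rep("off_target", n)
  varicosities$ais_id <- rep(NA_integer_, n)
  varicosities$ais_gap_um <- rep(NA_real_, n)
  if (n > 0 && length(ais_objects)) {
    r_xy <- varicosities$diameter_xy_um / 2
    r_z <- varicosities$diameter_z_um / 2
    centers <- as.matrix(varicosities[, c("x_um", "y_um", "z_um")])
    for (i in seq_len(n)) {
      best_gap <- Inf
      best_id <- NA_integer_
      for (ao in ais_objects) {
        dvec <- sweep(ao$coords_um, 2, centers[i, ])
        dist <- sqrt(rowSums(dvec^2))
        u <- dvec / pmax(dist, 1e-9)
        gap <- dist - ellipsoid_radius(u, r_xy[i], r_z[i])
        gmin <- min(gap)
        if (gmin < best_gap - 1e-12) {
          best_gap <- gmin
          best_id <- ao$id
        }
      }
      if (best_gap <= apposition_tol_um) {
        varicosities$label[i] <- "AIS"
        varicosities$ais_id[i] <- best_id
        varicosities$ais_gap_um[i] <- best_gap
      }
    }
  }
  n_ais <- sum(varicosities$label == "AIS")
  n_cart <- length(unique(stats::na.omit(varicosities$ais_id)))
  attr(varicosities, "summary") <-
    classification_summary(n, n_ais, n_cart)
  varicosities
}

#' Group AIS varicosities into cartridges
#'
#' One cartridge per AIS object hosting at least one apposed varicosity.
#'
#' @param classified Output of [classify_varicosities()].
#' @param ais_objects The AIS objects used for classification.
#' @return A data frame (`ais_id`, `n_varicosities`, `varicosity_ids`) with
#'   attribute `varicosities_per_ais` (pooled AIS varicosities divided by
#'   the number of cartridges).
#' @export
group_cartridges <- function(classified, ais_objects) {
  sel <- classified$label == "AIS"
  if (!any(sel)) {
    out <- data.frame(ais_id = integer(0), n_varicosities = integer(0))
    out$varicosity_ids <- list()
    attr(out, "varicosities_per_ais") <- NA_real_
    return(out)
  }
  sp <- split(classified$id[sel], classified$ais_id[sel])
  out <- data.frame(ais_id = as.integer(names(sp)),
                    n_varicosities = vapply(sp, length, integer(1)))
  out$varicosity_ids <- unname(sp)
  rownames(out) <- NULL
  stopifnot(all(out$n_varicosities >= 1L))
  attr(out, "varicosities_per_ais") <- sum(out$n_varicosities) / nrow(out)
  out
}

#' Pooled cartridge statistics from group totals
#'
#' @param n_varicosities Pooled AIS varicosity count.
#' @param n_cartridges Pooled cartridge count.
#' @param n_cells Number of cells pooled (optional).
#' @return List with `varicosities_per_ais` and, when `n_cells` is given,
#'   `cartridges_per_cell`.
#' @export
pooled_cartridge_stats <- function(n_varicosities, n_cartridges,
                                   n_cells = NULL) {
  out <- list(varicosities_per_ais = n_varicosities / n_cartridges)
  if (!is.null(n_cells)) out$cartridges_per_cell <- n_cartridges / n_cells
  out
}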