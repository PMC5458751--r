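# Presynaptic-marker colocalization: somatic-cytosol background estimation
# and per-varicosity positivity calls.

#' Somatic mask from the fill channel
#'
#' Region-grows the soma from its centre within a bounding ball: voxels
#' connected to the centre whose fill-channel intensity exceeds
#' `grow_frac` of the centre's intensity above background.
#'
#' @param stack A `volume_stack` with an `axon` (fill) channel.
#' @param soma_center Soma position in um (defaults to stored value).
#' @param max_radius_um Bounding ball radius.
#' @param grow_frac Intensity fraction defining the soma boundary.
#' @return Logical array marking somatic voxels.
#' @export
soma_mask <- function(stack, soma_center = stack$soma_center_um,
                      max_radius_um = 6, grow_frac = 0.4) {
  if (is.null(soma_center)) stop_chc("soma_center is required")
  ax <- stack_channel(stack, "axon")
  dims <- dim(ax)
  bg <- stats::median(ax)
  cvox <- um_to_voxel(matrix(soma_center, ncol = 3), stack)
  level <- bg + grow_frac * (ax[cvox] - bg)
  mask <- array(FALSE, dim = dims)
  ball <- !mask_soma_ball(array(TRUE, dim = dims), stack, soma_center,
                          max_radius_um)
  cand <- ball & ax > level
  idx <- which(cand)
  if (!length(idx)) stop_chc("no somatic voxels above the growth level")
  memb <- foreground_components(idx, dims)
  cl <- um_to_voxel(matrix(soma_center, ncol = 3), stack)
  clin <- cl[1] + (cl[2] - 1L) * dims[1] + (cl[3] - 1L) * dims[1] * dims[2]
  seed <- match(clin, idx)
  if (is.na(seed)) {
    # centre voxel itself below level (noise): use the largest component
    seed_memb <- which.max(tabulate(memb))
  } else {
    seed_memb <- memb[seed]
  }
  mask[idx[memb == seed_memb]] <- TRUE
  mask
}

# 3D binary erosion by a physical radius.
erode_mask <- function(mask, voxel, r_um) {
  offs <- offset_ball(r_um, voxel)
  dims <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(mask)
  coord <- arrayInd(idx, dims)
  keep <- rep(TRUE, length(idx))
  nyx <- dims[1] * dims[2]
  for (k in seq_len(nrow(offs))) {
    yy <- coord[, 1] + offs[k, 1]
    xx <- coord[, 2] + offs[k, 2]
    zz <- coord[, 3] + offs[k, 3]
    oob <- yy < 1L | yy > dims[1] | xx < 1L | xx > dims[2] |
      zz < 1L | zz > dims[3]
    lin <- yy + (xx - 1L) * dims[1] + (zz - 1L) * nyx
    lin[oob] <- 1L
    keep <- keep & !oob & mask[lin]
  }
  out <- array(FALSE, dim = dims)
  out[idx[keep]] <- TRUE
  out
}

#' Estimate the marker background from the somatic cytosol
#'
#' Mean marker-channel intensity over the soma mask eroded by `erode_um`
#' (which strips the membrane and leaves cytosol).  Marker puncta are
#' called positive only when brighter than this level.
#'
#' @param stack A `volume_stack` with a `marker` channel.
#' @param mask Logical soma mask (e.g. from [soma_mask()]).
#' @param erode_um Erosion radius in um.
#' @return The background intensity (scalar).
#' @export
estimate_background <- function(stack, mask, erode_um = 1) {
  if (!any(mask)) stop_chc("soma mask is empty")
  er <- erode_mask(mask, stack$voxel_size, erode_um)
  if (!any(er)) stop_chc("eroded soma mask is empty")
  mk <- stack_channel(stack, "marker")
  mean(mk[er])
}

#' Call marker positivity for classified varicosities
#'
#' For each varicosity the mean marker intensity over its fitted ellipsoid
#' is compared with the somatic-cytosol background; a varicosity is
#' positive iff its mean is strictly above the background.  Per class
#' (AIS / off-target) the percentage of positive varicosities is reported;
#' classes with fewer than `min_scored` varicosities are flagged
#' under-sampled but not dropped.
#'
#' @param varicosities Classified varicosity data frame.
#' @param stack A `volume_stack` with a `marker` channel.
#' @param background Background intensity from [estimate_background()].
#' @param min_scored Minimum varicosities per class for a reliable
#'   percentage.
#' @return List with `calls` (per-varicosity data frame: id, label,
#'   marker_mean, background, positive) and `summary` (per-class data
#'   frame: label, n_scored, n_positive, pct_positive in percent,
#'   under_sampled flag).
#' @export
call_markers <- function(varicosities, stack, background, min_scored = 50L) {
  mk <- stack_channel(stack, "marker")
  dims <- dim(mk)
  v <- stack$voxel_size
  o <- stack$origin_um
  n <- nrow(varicosities)
  marker_mean <- numeric(n)
  for (i in seq_len(n)) {
    cx <- varicosities$x_um[i]; cy <- varicosities$y_um[i]
    cz <- varicosities$z_um[i]
    rxy <- varicosities$diameter_xy_um[i] / 2
    rz <- varicosities$diameter_z_um[i] / 2
    ix <- which(abs(o[1] + (seq_len(dims[2]) - 0.5) * v[1] - cx) <= rxy)
    iy <- which(abs(o[2] + (seq_len(dims[1]) - 0.5) * v[2] - cy) <= rxy)
    iz <- which(abs(o[3] + (seq_len(dims[3]) - 0.5) * v[3] - cz) <= rz)
    if (!length(ix) || !length(iy) || !length(iz)) {
      # varicosity smaller than a voxel: use the nearest voxel
      vox <- um_to_voxel(matrix(c(cx, cy, cz), ncol = 3), stack)
      marker_mean[i] <- mk[vox]
      next
    }
    qx <- ((o[1] + (ix - 0.5) * v[1] - cx) / rxy)^2
    qy <- ((o[2] + (iy - 0.5) * v[2] - cy) / rxy)^2
    qz <- ((o[3] + (iz - 0.5) * v[3] - cz) / rz)^2
    inside <- outer(outer(qy, qx, "+"), qz, "+") <= 1
    sub <- mk[iy, ix, iz, drop = FALSE]
    marker_mean[i] <- mean(sub[inside])
  }
  calls <- data.frame(id = varicosities$id,
                      label = varicosities$label,
                      marker_mean = marker_mean,
                      background = background,
                      positive = marker_mean > background)
  classes <- intersect(c("AIS", "off_target"), unique(calls$label))
  summary <- do.call(rbind, lapply(classes, function(cl) {
    sel <- calls$label == cl
    data.frame(label = cl, n_scored = sum(sel),
               n_positive = sum(calls$positive[sel]),
               pct_positive = 100 * mean(calls$positive[sel]),
               under_sampled = sum(sel) < min_scored)
  }))
  list(calls = calls, summary = summary)
}

#' Varicosity records from a ground-truth manifest
#'
#' Builds the same data frame schema as [detect_varicosities()] from the
#' generator's ground truth (nominal diameters, true class labels), so the
#' colocalization and classification stages can be exercised directly
#' against known truth.
#'
#' @param manifest Manifest from [generate_stack()].
#' @param cfg The [gen_config()] that produced it.
#' @return A varicosity data frame with true labels.
#' @export
manifest_varicosities <- function(manifest, cfg) {
  vr <- manifest$varicosities
  data.frame(id = vr$id, x_um = vr$x, y_um = vr$y, z_um = vr$z,
             diameter_xy_um = cfg$varicosity_diam_xy_um,
             diameter_z_um = cfg$varicosity_diam_z_um,
             peak_intensity = NA_real_, shaft_intensity = NA_real_,
             brightness_ratio = cfg$varicosity_brightness_ratio,
             label = vr$class, ais_id = vr$host_ais_id,
             marker_present = vr$marker_present)
}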