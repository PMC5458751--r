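# Varicosity detection: bright axonal swellings satisfying the printed
# size criteria (< 3 um in x-y, < 3.5 um in z) and at least twice as bright
# as the adjacent axonal shaft.

#' Selection criteria for a candidate varicosity
#'
#' Implements the printed rules with their boundary semantics: diameters
#' must be strictly smaller than the cutoffs ("smaller than 3 um"), while
#' the brightness ratio is inclusive ("at least two times brighter").
#'
#' @param diameter_xy_um,diameter_z_um Fitted full widths in um.
#' @param brightness_ratio Peak / shaft intensity ratio.
#' @param max_xy_um,max_z_um,min_ratio Cutoffs.
#' @return Logical: retained or not (vectorised).
#' @export
varicosity_criteria <- function(diameter_xy_um, diameter_z_um,
                                brightness_ratio,
                                max_xy_um = 3.0, max_z_um = 3.5,
                                min_ratio = 2.0) {
  diameter_xy_um < max_xy_um & diameter_z_um < max_z_um &
    brightness_ratio >= min_ratio
}

# Separable Gaussian blur of a small 3D window; sigma in voxel units per dim.
blur3d <- function(win, sigma_vox) {
  d <- dim(win)
  for (k in 1:3) {
    if (sigma_vox[k] <= 0) next
    n <- d[k]
    kk <- outer(seq_len(n), seq_len(n),
                function(i, j) stats::dnorm(i - j, sd = sigma_vox[k]))
    kk <- kk / rowSums(kk)
    m <- apply(win, setdiff(1:3, k), function(vec) as.numeric(kk %*% vec))
    win <- aperm(array(m, dim = c(d[k], d[setdiff(1:3, k)])),
                 order(c(k, setdiff(1:3, k))))
  }
  win
}

# Discrete 6-neighbour Laplacian with physical spacing.
laplacian3d <- function(win, voxel) {
  d <- dim(win)
  out <- array(0, dim = d)
  idx <- function(n, s) pmin(pmax(seq_len(n) + s, 1L), n)
  out <- (win[idx(d[1], -1), , ] + win[idx(d[1], 1), , ] - 2 * win) /
    voxel[2]^2 +
    (win[, idx(d[2], -1), ] + win[, idx(d[2], 1), ] - 2 * win) / voxel[1]^2 +
    (win[, , idx(d[3], -1)] + win[, , idx(d[3], 1)] - 2 * win) / voxel[3]^2
  out
}

# Trilinear interpolation of arr at fractional voxel coordinates
# (iy, ix, iz) given as an n x 3 matrix; out-of-range clamped.
interp3 <- function(arr, p) {
  d <- dim(arr)
  p[, 1] <- pmin(pmax(p[, 1], 1), d[1])
  p[, 2] <- pmin(pmax(p[, 2], 1), d[2])
  p[, 3] <- pmin(pmax(p[, 3], 1), d[3])
  f <- floor(p)
  f[, 1] <- pmin(f[, 1], d[1] - 1L); f[, 2] <- pmin(f[, 2], d[2] - 1L)
  f[, 3] <- pmin(f[, 3], d[3] - 1L)
  t <- p - f
  v <- 0
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    wgt <- (a * t[, 1] + (1 - a) * (1 - t[, 1])) *
      (b * t[, 2] + (1 - b) * (1 - t[, 2])) *
      (cc * t[, 3] + (1 - cc) * (1 - t[, 3]))
    v <- v + wgt * arr[cbind(f[, 1] + a, f[, 2] + b, f[, 3] + cc)]
  }
  v
}

# FWHM along a direction (um): crossing of baseline + (peak-baseline)/2,
# found by sub-voxel sampling on both sides of the centre.
fwhm_along <- function(arr, stack, center_um, dir, half_level, max_r = 4) {
  v <- stack$voxel_size
  o <- stack$origin_um
  rs <- seq(0.05, max_r, by = 0.05)
  width <- 0
  for (s in c(-1, 1)) {
    pts <- cbind(center_um[1] + s * rs * dir[1],
                 center_um[2] + s * rs * dir[2],
                 center_um[3] + s * rs * dir[3])
    pv <- cbind((pts[, 2] - o[2]) / v[2] + 0.5,
                (pts[, 1] - o[1]) / v[1] + 0.5,
                (pts[, 3] - o[3]) / v[3] + 0.5)
    prof <- interp3(arr, pv)
    below <- which(prof < half_level)
    if (!length(below)) return(Inf)
    k <- below[1]
    if (k == 1L) {
      width <- width + rs[1]
    } else {
      # linear interpolation between the last sample above and first below
      r0 <- rs[k - 1]; r1 <- rs[k]
      p0 <- prof[k - 1]; p1 <- prof[k]
      width <- width + r0 + (p0 - half_level) / (p0 - p1) * (r1 - r0)
    }
  }
  width
}

#' Median shaft intensity adjacent to a point on the skeleton
#'
#' Samples the axon channel along the skeleton at arc distance
#' `arc_range` (default 2-5 um) from the skeleton point nearest to
#' `center`, excluding voxels flagged as belonging to candidate blobs, and
#' returns the median.  This is the reference the "at least two times
#' brighter than the adjacent axonal shaft" criterion compares against.
#'
#' @param skel A [skeleton()].
#' @param stack The `volume_stack` the skeleton was traced from.
#' @param center `(x, y, z)` point in um (within 1 um of the skeleton).
#' @param arc_range Arc-distance window in um.
#' @param exclude_mask Optional logical array flagging voxels (candidate
#'   blobs) to exclude from the reference.
#' @return Median shaft intensity, or `NA` if no shaft voxels fall in the
#'   annulus (the caller flags the varicosity unscorable).
#' @export
shaft_reference <- function(skel, stack, center, arc_range = c(2, 5),
                            exclude_mask = NULL) {
  d2 <- (skel$nodes[, 1] - center[1])^2 + (skel$nodes[, 2] - center[2])^2 +
    (skel$nodes[, 3] - center[3])^2
  k <- which.min(d2)
  if (sqrt(d2[k]) > 1.0) {
    stop_chc("center is more than 1 um from the skeleton")
  }
  g <- skeleton_graph(skel)
  arc <- as.numeric(igraph::distances(g, v = k))
  shaft_reference_nodes(skel, stack, arc, arc_range, exclude_mask)
}

# Internal: given precomputed arc distances from the nearest node.
shaft_reference_nodes <- function(skel, stack, arc, arc_range, exclude_mask) {
  sel <- which(arc >= arc_range[1] & arc <= arc_range[2])
  if (!length(sel)) return(NA_real_)
  ax <- stack_channel(stack, "axon")
  vox <- um_to_voxel(skel$nodes[sel, , drop = FALSE], stack)
  if (!is.null(exclude_mask)) {
    inside <- exclude_mask[vox]
    vox <- vox[!inside, , drop = FALSE]
  }
  if (!nrow(vox)) return(NA_real_)
  stats::median(ax[vox])
}

#' Detect axonal varicosities on a traced skeleton
#'
#' Candidate swellings are connected regions of the axon channel brighter
#' than `candidate_factor` times the median shaft level; each candidate is
#' refined by a windowed multiscale Laplacian-of-Gaussian (the
#' scale-normalised blob operator) to localise its centre, then measured:
#' full widths at half maximum above the local shaft baseline along
#' sampled x-y directions (the largest is the x-y diameter) and along z,
#' and the raw peak-to-shaft brightness ratio.  A candidate is retained iff
#' it satisfies [varicosity_criteria()] and its centre lies within 1 um of
#' the skeleton.  Detection is deterministic.
#'
#' @param roi_stack A `volume_stack` with an `axon` channel.
#' @param skel The [skeleton()] traced from the same ROI.
#' @param max_xy_um,max_z_um,min_ratio Selection cutoffs.
#' @param candidate_factor Candidate threshold in units of the net median
#'   shaft intensity above background.
#' @param log_sigmas_um Scales of the blob operator.
#' @param soma_mask_radius_um Exclusion ball around the stored soma.
#' @return A data frame of retained varicosities (id, centre, diameters,
#'   peak / shaft intensities, brightness ratio, label `"unclassified"`),
#'   with attributes `n_candidates` and `n_unscorable`.
#' @export
detect_varicosities <- function(roi_stack, skel,
                                max_xy_um = 3.0, max_z_um = 3.5,
                                min_ratio = 2.0,
                                candidate_factor = 1.4,
                                log_sigmas_um = c(0.5, 0.75, 1.0, 1.25),
                                soma_mask_radius_um = 6.0) {
  if (!inherits(skel, "chc_skeleton")) stop_chc("a traced skeleton is required")
  ax <- stack_channel(roi_stack, "axon")
  v <- roi_stack$voxel_size
  o <- roi_stack$origin_um
  dims <- dim(ax)
  bg <- stats::median(ax)
  node_vox <- um_to_voxel(skel$nodes, roi_stack)
  shaft_med <- stats::median(ax[node_vox])
  tau <- bg + candidate_factor * (shaft_med - bg)
  bright <- ax > tau
  if (!is.null(roi_stack$soma_center_um)) {
    bright <- mask_soma_ball(bright, roi_stack, roi_stack$soma_center_um,
                             soma_mask_radius_um)
  }
  bright_idx <- which(bright)
  empty <- data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), diameter_xy_um = numeric(0),
                      diameter_z_um = numeric(0), peak_intensity = numeric(0),
                      shaft_intensity = numeric(0),
                      brightness_ratio = numeric(0), label = character(0))
  if (!length(bright_idx)) return(empty)
  memb <- foreground_components(bright_idx, dims)
  ncomp <- max(memb)
  coord <- arrayInd(bright_idx, dims)

  # batched arc distances for shaft references
  g <- skeleton_graph(skel)

  win_r <- c(ceiling(2.5 / v[1]), ceiling(2.5 / v[2]), ceiling(3.0 / v[3]))
  dirs <- lapply(seq(0, pi - 1e-9, by = pi / 8),
                 function(a) c(cos(a), sin(a), 0))
  out <- list()
  n_unscorable <- 0L
  for (ci in seq_len(ncomp)) {
    sel <- memb == ci
    if (sum(sel) < 3L) next
    cc <- coord[sel, , drop = FALSE]
    vals <- ax[bright_idx[sel]]
    seedv <- cc[which.max(vals), ]
    iy <- max(1L, seedv[1] - win_r[2]):min(dims[1], seedv[1] + win_r[2])
    ix <- max(1L, seedv[2] - win_r[1]):min(dims[2], seedv[2] + win_r[1])
    iz <- max(1L, seedv[3] - win_r[3]):min(dims[3], seedv[3] + win_r[3])
    win <- ax[iy, ix, iz, drop = FALSE]
    # multiscale scale-normalised LoG; the strongest bright-blob response
    # near this component's seed localises the centre (the search is
    # restricted to the seed's vicinity so a brighter neighbouring blob
    # inside the window cannot capture it)
    dy2 <- ((iy - seedv[1]) * v[2])^2
    dx2 <- ((ix - seedv[2]) * v[1])^2
    dz2 <- ((iz - seedv[3]) * v[3])^2
    near_seed <- outer(outer(dy2, dx2, "+"), dz2, "+") <= 1.2^2
    best <- NULL
    for (s_um in log_sigmas_um) {
      sv <- c(s_um / v[2], s_um / v[1], s_um / v[3])
      resp <- -s_um^2 * laplacian3d(blur3d(win, sv), v)
      resp[!near_seed] <- -Inf
      pk <- which(resp == max(resp), arr.ind = TRUE)[1, , drop = TRUE]
      if (is.null(best) || max(resp) > best$val) {
        best <- list(val = max(resp), at = pk, sigma = s_um)
      }
    }
    cen_vox <- c(iy[best$at[1]], ix[best$at[2]], iz[best$at[3]])
    center <- as.numeric(voxel_centers_um(matrix(cen_vox, ncol = 3),
                                          roi_stack))
    peak <- ax[cen_vox[1], cen_vox[2], cen_vox[3]]

    # within 1 um of the skeleton?
    d2 <- (skel$nodes[, 1] - center[1])^2 + (skel$nodes[, 2] - center[2])^2 +
      (skel$nodes[, 3] - center[3])^2
    kmin <- which.min(d2)
    if (sqrt(d2[kmin]) > 1.0) next

    arc <- as.numeric(igraph::distances(g, v = kmin))
    shaft <- shaft_reference_nodes(skel, roi_stack, arc, c(2, 5), bright)
    if (is.na(shaft) || shaft <= 0) {
      n_unscorable <- n_unscorable + 1L
      next
    }
    half <- shaft + (peak - shaft) / 2
    dxy <- max(vapply(dirs, function(dd)
      fwhm_along(ax, roi_stack, center, dd, half), numeric(1)))
    dz <- fwhm_along(ax, roi_stack, center, c(0, 0, 1), half, max_r = 4.5)
    ratio <- peak / shaft
    if (!varicosity_criteria(dxy, dz, ratio, max_xy_um, max_z_um,
                             min_ratio)) next
    out[[length(out) + 1L]] <- data.frame(
      x_um = center[1], y_um = center[2], z_um = center[3],
      diameter_xy_um = dxy, diameter_z_um = dz,
      peak_intensity = peak, shaft_intensity = shaft,
      brightness_ratio = ratio, label = "unclassified")
  }
  if (n_unscorable > 0L) {
    warning(n_unscorable, " candidate(s) unscorable: no shaft reference in ",
            "the 2-5 um annulus", call. = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else empty[, -1]
  res <- cbind(id = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  stopifnot(all(varicosity_criteria(res$diameter_xy_um, res$diameter_z_um,
                                    res$brightness_ratio, max_xy_um,
                                    max_z_um, min_ratio)))
  attr(res, "n_candidates") <- ncomp
  attr(res, "n_unscorable") <- n_unscorable
  res
}
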