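# Synthetic confocal-like stack generator with complete ground truth.
#
# Geometry model: a chandelier-cell soma sits at the top edge of the volume;
# a bifurcating axonal tree grows downward with per-step direction jitter and
# a clearance constraint keeping non-adjacent branches >= 2.5 um apart (so
# the imaged tubes never fuse).  A subset of terminal tips is extended into
# near-vertical "cartridge" branches, each paralleled by an AnkG-like AIS
# tube at a fixed lateral offset; AIS-class varicosities sit on the
# cartridge branch, apposed to the tube.  Off-target varicosities are placed
# on the remaining tree, far (> 4 um) from every tube axis.

# Fixed geometric/intensity constants of the generator (um unless noted).
GEN <- list(
  soma_y = 2,            # soma centre depth below the stack top
  soma_core = 4,         # flat-top soma radius in the fill channel
  soma_edge = 0.7,       # Gaussian edge of the soma profile
  shaft_sigma_xy = 0.25, # shaft tube Gaussian cross-section
  shaft_sigma_z = 0.35,
  clearance = 2.5,       # min distance between non-adjacent branch axes
  junction_free = 3.0,   # radius around a junction exempt from clearance
  step = 2.0,            # growth step length
  child_min = 4.5,       # every branch is at least this long at creation
  child_max = 6.5,
  tube_edge = 0.2,       # AIS tube Gaussian edge beyond its core radius
  tube_gap = 0.2,        # varicosity surface to tube surface distance
  tube_axis_sep = 7.0,   # min separation between AIS tube axes
  site_spacing = 3.0,    # min distance between same-branch varicosity centres
  site_cross = 3.5,      # cross-branch site spacing (z-compressed metric)
  site_line_clear = 2.3, # site to any foreign branch centreline (scaled)
  zc = 0.78,             # z compression: blobs reach farther axially, so a
                         # given separation in z is worth less than in x-y
  site_axis_clear = 4.0, # off-target centre to any tube axis
  soma_clear = 8.0,      # varicosity centre to soma centre
  marker_sigma_xy = 0.35,
  marker_sigma_z = 0.45,
  max_intensity = 4095   # 12-bit dynamic range
)

# --- occupancy store (spatial hash over grown centreline samples) -----------

new_occupancy <- function(cell = 3) {
  e <- new.env(parent = emptyenv())
  e$P <- matrix(NA_real_, nrow = 4096, ncol = 3)
  e$branch <- integer(4096)
  e$arc <- numeric(4096)
  e$alive <- logical(4096)
  e$n <- 0L
  e$cell <- cell
  e$hash <- new.env(parent = emptyenv(), hash = TRUE)
  e
}

occ_key <- function(p, cell) {
  paste(floor(p[, 1] / cell), floor(p[, 2] / cell), floor(p[, 3] / cell))
}

occ_add <- function(occ, pts, bid, arcs) {
  pts <- matrix(pts, ncol = 3)
  m <- nrow(pts)
  while (occ$n + m > nrow(occ$P)) {
    occ$P <- rbind(occ$P, matrix(NA_real_, nrow = nrow(occ$P), ncol = 3))
    occ$branch <- c(occ$branch, integer(length(occ$branch)))
    occ$arc <- c(occ$arc, numeric(length(occ$arc)))
    occ$alive <- c(occ$alive, logical(length(occ$alive)))
  }
  ids <- occ$n + seq_len(m)
  occ$P[ids, ] <- pts
  occ$branch[ids] <- bid
  occ$arc[ids] <- arcs
  occ$alive[ids] <- TRUE
  occ$n <- occ$n + m
  keys <- occ_key(pts, occ$cell)
  for (i in seq_len(m)) {
    k <- keys[i]
    occ$hash[[k]] <- c(occ$hash[[k]], ids[i])
  }
  ids
}

occ_near <- function(occ, p, r) {
  cell <- occ$cell
  span <- ceiling(r / cell)
  cx <- floor(p[1] / cell); cy <- floor(p[2] / cell); cz <- floor(p[3] / cell)
  ids <- integer(0)
  for (dx in -span:span) for (dy in -span:span) for (dz in -span:span) {
    v <- occ$hash[[paste(cx + dx, cy + dy, cz + dz)]]
    if (!is.null(v)) ids <- c(ids, v)
  }
  if (!length(ids)) return(integer(0))
  ids <- ids[occ$alive[ids]]
  if (!length(ids)) return(integer(0))
  d2 <- (occ$P[ids, 1] - p[1])^2 + (occ$P[ids, 2] - p[2])^2 +
    (occ$P[ids, 3] - p[3])^2
  ids[d2 <= r^2]
}

# A proposed centreline piece is admissible if every existing point within
# the clearance radius belongs to the same branch or lies in the
# junction-free zone around the branch's attachment point.
occ_clear_ok <- function(occ, seg_pts, bid, start_ref,
                         clearance = GEN$clearance) {
  seg_pts <- matrix(seg_pts, ncol = 3)
  for (i in seq_len(nrow(seg_pts))) {
    ids <- occ_near(occ, seg_pts[i, ], clearance)
    if (!length(ids)) next
    foreign <- ids[occ$branch[ids] != bid]
    if (!length(foreign)) next
    dref <- sqrt((occ$P[foreign, 1] - start_ref[1])^2 +
                   (occ$P[foreign, 2] - start_ref[2])^2 +
                   (occ$P[foreign, 3] - start_ref[3])^2)
    if (any(dref > GEN$junction_free)) return(FALSE)
  }
  TRUE
}

# --- tree growth ------------------------------------------------------------

gen_geometry <- function(cfg) {
  W <- cfg$roi_um[1]
  H <- GEN$soma_y + cfg$roi_um[2]
  D <- cfg$slice_depth_um
  list(W = W, H = H, D = D,
       soma = c(W / 2, GEN$soma_y, D / 2),
       lo = c(1.5, GEN$soma_y, 3), hi = c(W - 1.5, H - 1.5, D - 3))
}

in_growth_bounds <- function(p, geom) {
  all(p >= geom$lo) && all(p <= geom$hi)
}

new_branch <- function(id, start, dir, start_arc0 = 0) {
  list(id = id, start = start, dir = dir, end = start, len = 0,
       nodes = matrix(start, ncol = 3), pt_ids = integer(0),
       has_children = FALSE, fails = 0L, cart_start = NA_real_)
}

# Try to extend branch `b` by one step; returns updated branch or NULL.
step_branch <- function(b, occ, geom, step = GEN$step, tries = 25L,
                        down_bias = 0.05) {
  for (t in seq_len(tries)) {
    sd <- if (t <= 10) 0.18 else 0.4
    dir_c <- unit(b$dir + stats::rnorm(3, 0, sd) + c(0, down_bias, 0))
    end <- b$end + dir_c * step
    if (!in_growth_bounds(end, geom)) next
    ns <- max(2L, ceiling(step / 0.5) + 1L)
    ts <- seq(0, 1, length.out = ns)[-1]
    seg <- cbind(b$end[1] + ts * (end[1] - b$end[1]),
                 b$end[2] + ts * (end[2] - b$end[2]),
                 b$end[3] + ts * (end[3] - b$end[3]))
    if (!occ_clear_ok(occ, seg, b$id, b$start)) next
    arcs <- b$len + ts * step
    b$pt_ids <- c(b$pt_ids, occ_add(occ, seg, b$id, arcs))
    b$end <- end
    b$dir <- dir_c
    b$len <- b$len + step
    b$nodes <- rbind(b$nodes, end)
    return(b)
  }
  NULL
}

grow_branch_to <- function(b, occ, geom, target_len, ...) {
  while (b$len < target_len) {
    nb <- step_branch(b, occ, geom, step = min(GEN$step, target_len - b$len + 1e-9), ...)
    if (is.null(nb)) return(list(branch = b, ok = FALSE))
    b <- nb
  }
  list(branch = b, ok = TRUE)
}

# Grow the full arbor: returns branches, branch points, occupancy.
grow_tree <- function(cfg, geom) {
  occ <- new_occupancy()
  branches <- list()
  primary <- new_branch(1L, geom$soma, c(0, 1, 0))
  # keep the primary straight through the somatic exclusion zone so the
  # soma mask later cuts it in exactly one place
  straight_len <- 8
  ts <- seq(0.5, straight_len, by = 0.5)
  straight <- cbind(geom$soma[1], geom$soma[2] + ts, geom$soma[3])
  primary$pt_ids <- occ_add(occ, straight, 1L, ts)
  primary$end <- c(geom$soma[1], geom$soma[2] + straight_len, geom$soma[3])
  primary$len <- straight_len
  primary$nodes <- rbind(primary$nodes, primary$end)
  res <- grow_branch_to(primary, occ, geom, straight_len + 4)
  if (!res$ok) stop_capacity("ROI too small to seed the primary axon")
  branches[[1]] <- res$branch
  active <- 1L
  bps <- matrix(numeric(0), ncol = 3)
  next_id <- 2L
  guard <- 0L
  max_guard <- 60L * max(1L, cfg$n_branch_points) + 2000L
  while (nrow(bps) < cfg$n_branch_points) {
    guard <- guard + 1L
    if (!length(active) || guard > max_guard) {
      stop_capacity("ROI too small for the requested branch-point count (",
                    nrow(bps), " of ", cfg$n_branch_points, " placed)")
    }
    bi <- if (length(active) == 1L) active else sample(active, 1L)
    b <- branches[[bi]]
    if (stats::runif(1) < 0.45) {  # plain extension
      nb <- step_branch(b, occ, geom)
      if (is.null(nb)) {
        b$fails <- b$fails + 1L
        if (b$fails >= 3L) active <- setdiff(active, bi)
      } else b <- nb
      branches[[bi]] <- b
      next
    }
    # attempt a bifurcation at the current tip
    done <- FALSE
    for (t in 1:6) {
      u <- rotate3(perp_of(b$dir), b$dir, stats::runif(1, 0, 2 * pi))
      d1 <- unit(rotate3(b$dir, u, stats::runif(1, 0.45, 0.9)) + c(0, 0.3, 0))
      d2 <- unit(rotate3(b$dir, u, -stats::runif(1, 0.45, 0.9)) + c(0, 0.3, 0))
      if (sum(d1 * d2) > cos(0.75)) next
      mark <- occ$n
      c1 <- new_branch(next_id, b$end, d1)
      r1 <- grow_branch_to(c1, occ, geom, stats::runif(1, GEN$child_min, GEN$child_max))
      c2 <- new_branch(next_id + 1L, b$end, d2)
      r2 <- if (r1$ok)
        grow_branch_to(c2, occ, geom, stats::runif(1, GEN$child_min, GEN$child_max))
      else list(ok = FALSE)
      if (r1$ok && r2$ok) {
        branches[[next_id]] <- r1$branch
        branches[[next_id + 1L]] <- r2$branch
        b$has_children <- TRUE
        branches[[bi]] <- b
        active <- c(setdiff(active, bi), next_id, next_id + 1L)
        next_id <- next_id + 2L
        bps <- rbind(bps, b$end)
        done <- TRUE
        break
      }
      # roll back partial growth
      if (occ$n > mark) occ$alive[(mark + 1L):occ$n] <- FALSE
    }
    if (!done) {
      b$fails <- b$fails + 1L
      branches[[bi]] <- b
      if (b$fails >= 3L) active <- setdiff(active, bi)
    }
  }
  # variety in terminal lengths; a failed extension is acceptable here
  for (bi in active) {
    extra <- stats::runif(1, 0, 3)
    if (extra > 0.5) {
      res <- grow_branch_to(branches[[bi]], occ, geom, branches[[bi]]$len + extra)
      branches[[bi]] <- res$branch
    }
  }
  if (cfg$n_branch_points == 0L) {  # degenerate case: one unbranched curve
    res <- grow_branch_to(branches[[1]], occ, geom,
                          min(0.55 * cfg$roi_um[2], 40))
    branches[[1]] <- res$branch
    active <- 1L
  }
  list(branches = branches, active = active, bps = bps, occ = occ)
}

# --- cartridges and AIS tubes ----------------------------------------------

place_cartridges <- function(cfg, geom, tree) {
  n_ais <- as.integer(round(cfg$frac_on_ais * cfg$n_varicosities_total))
  tubes <- list()
  if (cfg$n_ais_tubes == 0L) {
    return(list(tubes = tubes, tree = tree, n_ais = n_ais,
                ais_sites = NULL))
  }
  tube_r <- cfg$ais_width_um / 2
  vari_r <- cfg$varicosity_diam_xy_um / 2
  offset <- tube_r + vari_r + GEN$tube_gap
  tube_len <- cfg$ais_length_um
  kmax <- floor((tube_len - 3.5) / GEN$site_spacing) + 1
  counts <- integer(cfg$n_ais_tubes)
  if (n_ais > 0) {
    base <- n_ais %/% cfg$n_ais_tubes
    counts <- rep(base, cfg$n_ais_tubes)
    extra <- n_ais %% cfg$n_ais_tubes
    if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
    if (max(counts) > kmax) {
      stop_capacity("AIS tubes of length ", tube_len,
                    " um cannot host ", max(counts), " varicosities each")
    }
  }
  margin <- offset + tube_r + 1
  tips <- tree$active
  tips <- tips[sample.int(length(tips))]
  ais_sites <- NULL
  occ <- tree$occ
  for (ti in tips) {
    if (length(tubes) >= cfg$n_ais_tubes) break
    b <- tree$branches[[ti]]
    p0 <- b$end
    if (p0[1] < margin || p0[1] > geom$W - margin ||
        p0[3] < margin || p0[3] > geom$D - margin ||
        p0[2] + tube_len + 2 > geom$H) next
    tilt <- stats::runif(1, 0, 8 * pi / 180)
    psi <- stats::runif(1, 0, 2 * pi)
    dirT <- c(sin(tilt) * cos(psi), cos(tilt), sin(tilt) * sin(psi))
    p1 <- p0 + dirT * tube_len
    if (!in_growth_bounds(p1, geom)) next
    ts <- seq(0.5, tube_len, by = 0.5)
    ext <- cbind(p0[1] + dirT[1] * ts, p0[2] + dirT[2] * ts,
                 p0[3] + dirT[3] * ts)
    # cartridge branches carry varicosities along their whole length, so
    # they need more clearance than plain branches
    if (!occ_clear_ok(occ, ext, b$id, p0, clearance = 3.2)) next
    placed <- FALSE
    for (s in sample(c(-1, 1))) {
      a0 <- p0 + c(s * offset, 0, 0)
      a1 <- p1 + c(s * offset, 0, 0)
      if (a0[1] < tube_r + 0.8 || a0[1] > geom$W - tube_r - 0.8 ||
          a1[1] < tube_r + 0.8 || a1[1] > geom$W - tube_r - 0.8) next
      sep_ok <- TRUE
      axs <- cbind(a0[1] + dirT[1] * ts, a0[2] + dirT[2] * ts,
                   a0[3] + dirT[3] * ts)
      for (tb in tubes) {
        if (min(dist_point_segment(axs, tb$p0, tb$p1)) < GEN$tube_axis_sep) {
          sep_ok <- FALSE; break
        }
      }
      if (!sep_ok) next
      # commit: extension joins the branch, tube is recorded
      cart_start <- b$len
      b$pt_ids <- c(b$pt_ids, occ_add(occ, ext, b$id, b$len + ts))
      b$nodes <- rbind(b$nodes, p1)
      b$end <- p1
      b$dir <- dirT
      b$cart_start <- cart_start
      b$len <- b$len + tube_len
      tree$branches[[ti]] <- b
      tid <- length(tubes) + 1L
      tubes[[tid]] <- list(id = tid, p0 = a0, p1 = a1, radius = tube_r)
      k <- counts[tid]
      if (k > 0) {
        arcs <- 2 + GEN$site_spacing * (seq_len(k) - 1)
        centers <- cbind(p0[1] + dirT[1] * arcs, p0[2] + dirT[2] * arcs,
                         p0[3] + dirT[3] * arcs)
        ais_sites <- rbind(ais_sites,
                           cbind(centers, host = tid))
      }
      placed <- TRUE
      break
    }
    if (placed) next
  }
  if (length(tubes) < cfg$n_ais_tubes) {
    stop_capacity("could only place ", length(tubes), " of ",
                  cfg$n_ais_tubes, " AIS tubes; enlarge the ROI or reduce ",
                  "n_ais_tubes/n_branch_points")
  }
  list(tubes = tubes, tree = tree, n_ais = n_ais, ais_sites = ais_sites)
}

# --- off-target sites -------------------------------------------------------

place_off_sites <- function(cfg, geom, tree, tubes, ais_sites, n_off) {
  if (n_off == 0L) return(NULL)
  occ <- tree$occ
  ids <- which(occ$alive[seq_len(occ$n)])
  P <- occ$P[ids, , drop = FALSE]
  br <- occ$branch[ids]
  arc <- occ$arc[ids]
  keep <- rep(TRUE, length(ids))
  for (b in tree$branches) {
    sel <- br == b$id
    if (!any(sel)) next
    lo <- 2
    hi <- if (b$has_children) b$len - 2 else b$len - 0.5
    if (!is.na(b$cart_start)) hi <- min(hi, b$cart_start - 3)
    keep[sel] <- keep[sel] & arc[sel] >= lo & arc[sel] <= hi
  }
  m <- 1.8
  keep <- keep &
    P[, 1] >= m & P[, 1] <= geom$W - m &
    P[, 2] <= geom$H - m &
    P[, 3] >= 2.6 & P[, 3] <= geom$D - 2.6
  keep <- keep & sqrt((P[, 1] - geom$soma[1])^2 + (P[, 2] - geom$soma[2])^2 +
                        (P[, 3] - geom$soma[3])^2) >= GEN$soma_clear
  for (tb in tubes) {
    if (!any(keep)) break
    keep[keep] <- dist_point_segment(P[keep, , drop = FALSE], tb$p0, tb$p1) >=
      GEN$site_axis_clear
  }
  # blobs reach farther along z than in x-y, so separation requirements use
  # a z-compressed metric: a candidate too close (in that metric) to a
  # FOREIGN branch centreline would fuse with it in the image
  zc <- GEN$zc
  Ps <- cbind(P[, 1], P[, 2], P[, 3] * zc)
  cand_idx <- which(keep)
  ok_line <- logical(length(cand_idx))
  chunk <- 500L
  for (s in seq(1, length(cand_idx), by = chunk)) {
    ii <- cand_idx[s:min(s + chunk - 1L, length(cand_idx))]
    dx <- outer(Ps[ii, 1], Ps[, 1], "-")
    dy <- outer(Ps[ii, 2], Ps[, 2], "-")
    dz <- outer(Ps[ii, 3], Ps[, 3], "-")
    d2 <- dx^2 + dy^2 + dz^2
    foreign <- outer(br[ii], br, "!=")
    d2[!foreign] <- Inf
    ok_line[s:(s + length(ii) - 1L)] <-
      apply(d2, 1, min) >= GEN$site_line_clear^2
  }
  cand_idx <- cand_idx[ok_line]
  if (length(cand_idx) > 0) cand_idx <- cand_idx[sample.int(length(cand_idx))]
  taken <- matrix(numeric(0), ncol = 3)   # scaled coords
  taken_br <- integer(0)
  if (!is.null(ais_sites)) {
    taken <- cbind(ais_sites[, 1], ais_sites[, 2], ais_sites[, 3] * zc)
    taken_br <- -as.integer(ais_sites[, 4])  # per-tube pseudo ids, never == br
  }
  out <- matrix(numeric(0), ncol = 3)
  for (i in cand_idx) {
    p <- Ps[i, ]
    if (nrow(taken)) {
      d2 <- (taken[, 1] - p[1])^2 + (taken[, 2] - p[2])^2 +
        (taken[, 3] - p[3])^2
      lim <- ifelse(taken_br == br[i], GEN$site_spacing, GEN$site_cross)
      if (any(d2 < lim^2)) next
    }
    out <- rbind(out, P[i, ])
    taken <- rbind(taken, p)
    taken_br <- c(taken_br, br[i])
    if (nrow(out) == n_off) break
  }
  if (nrow(out) < n_off) {
    stop_capacity("could only place ", nrow(out), " of ", n_off,
                  " off-target varicosities; the arbor is too small for ",
                  "the requested count")
  }
  out
}

# --- rasterization ----------------------------------------------------------

# Stamp anisotropic Gaussian bumps (max-combined) at centres (n x 3 um).
stamp_gauss <- function(arr, centers, amp, sxy, sz, voxel) {
  centers <- matrix(centers, ncol = 3)
  if (length(amp) == 1L) amp <- rep(amp, nrow(centers))
  d <- dim(arr)
  rx <- ceiling(3 * sxy / voxel[1]); rz <- ceiling(3 * sz / voxel[3])
  for (i in seq_len(nrow(centers))) {
    p <- centers[i, ]
    cx <- p[1] / voxel[1] + 0.5; cy <- p[2] / voxel[2] + 0.5
    cz <- p[3] / voxel[3] + 0.5
    if (cx + rx < 1 || cx - rx > d[2] || cy + rx < 1 || cy - rx > d[1] ||
        cz + rz < 1 || cz - rz > d[3]) next
    ix <- max(1L, floor(cx - rx)):min(d[2], ceiling(cx + rx))
    iy <- max(1L, floor(cy - rx)):min(d[1], ceiling(cy + rx))
    iz <- max(1L, floor(cz - rz)):min(d[3], ceiling(cz + rz))
    dx2 <- ((ix - cx) * voxel[1])^2
    dy2 <- ((iy - cy) * voxel[2])^2
    dz2 <- ((iz - cz) * voxel[3])^2
    gxy <- outer(dy2, dx2, "+") / (2 * sxy^2)
    val <- amp[i] * exp(-outer(gxy, dz2 / (2 * sz^2), "+"))
    arr[iy, ix, iz] <- pmax(arr[iy, ix, iz], val)
  }
  arr
}

# Stamp flat-core spheres with Gaussian edges (soma, AIS tube samples).
stamp_core <- function(arr, centers, amp, core, edge, voxel) {
  centers <- matrix(centers, ncol = 3)
  d <- dim(arr)
  rr <- core + 3 * edge
  rx <- ceiling(rr / voxel[1]); rz <- ceiling(rr / voxel[3])
  for (i in seq_len(nrow(centers))) {
    p <- centers[i, ]
    cx <- p[1] / voxel[1] + 0.5; cy <- p[2] / voxel[2] + 0.5
    cz <- p[3] / voxel[3] + 0.5
    if (cx + rx < 1 || cx - rx > d[2] || cy + rx < 1 || cy - rx > d[1] ||
        cz + rz < 1 || cz - rz > d[3]) next
    ix <- max(1L, floor(cx - rx)):min(d[2], ceiling(cx + rx))
    iy <- max(1L, floor(cy - rx)):min(d[1], ceiling(cy + rx))
    iz <- max(1L, floor(cz - rz)):min(d[3], ceiling(cz + rz))
    dx2 <- ((ix - cx) * voxel[1])^2
    dy2 <- ((iy - cy) * voxel[2])^2
    dz2 <- ((iz - cz) * voxel[3])^2
    dist <- sqrt(outer(outer(dy2, dx2, "+"), dz2, "+"))
    ex <- pmax(0, dist - core)
    val <- amp * exp(-ex^2 / (2 * edge^2))
    arr[iy, ix, iz] <- pmax(arr[iy, ix, iz], val)
  }
  arr
}

finalize_channel <- function(arr, baseline, noise_sd) {
  arr <- arr + baseline
  if (noise_sd > 0) arr <- arr + stats::rnorm(length(arr), 0, noise_sd)
  arr <- round(arr)
  arr[arr < 0] <- 0
  arr[arr > GEN$max_intensity] <- GEN$max_intensity
  array(arr, dim = dim(arr))
}

# --- main entry -------------------------------------------------------------

#' Generate a synthetic 3-channel confocal stack with ground truth
#'
#' Produces a `volume_stack` (channels `axon`, `ais`, `marker`) emulating a
#' sparsely labelled layer-2 chandelier cell: a bifurcating axonal tree with
#' exactly `n_branch_points` bifurcations, bright varicosities on the tree
#' (a configured fraction apposed to near-vertical AnkG-like AIS tubes, the
#' rest off-target), and presynaptic-marker puncta present per class with
#' the configured probabilities.  Identical `(seed, config)` give
#' bit-identical output.
#'
#' @param cfg A [gen_config()].
#' @return A list with elements `stack` (a [volume_stack()]) and `manifest`
#'   (ground truth: branch-point coordinates, varicosity table with class /
#'   marker / host-tube annotations, AIS tube axes, soma position, and the
#'   branch polylines of the generating tree).
#' @export
generate_stack <- function(cfg) {
  stopifnot(inherits(cfg, "gen_config"))
  validate_gen_config(cfg)
  set.seed(cfg$seed)
  geom <- gen_geometry(cfg)
  tree <- grow_tree(cfg, geom)
  n_ais <- as.integer(round(cfg$frac_on_ais * cfg$n_varicosities_total))
  n_off <- cfg$n_varicosities_total - n_ais
  cart <- place_cartridges(cfg, geom, tree)
  tree <- cart$tree
  tubes <- cart$tubes
  ais_sites <- cart$ais_sites
  off_sites <- place_off_sites(cfg, geom, tree, tubes, ais_sites, n_off)

  # ground-truth varicosity table
  vari <- NULL
  if (n_ais > 0) {
    vari <- data.frame(x = ais_sites[, 1], y = ais_sites[, 2],
                       z = ais_sites[, 3], class = "AIS",
                       host_ais_id = as.integer(ais_sites[, 4]))
  }
  if (n_off > 0) {
    vari <- rbind(vari, data.frame(x = off_sites[, 1], y = off_sites[, 2],
                                   z = off_sites[, 3], class = "off_target",
                                   host_ais_id = NA_integer_))
  }
  if (is.null(vari)) {
    vari <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                       class = character(0), host_ais_id = integer(0))
  }
  vari <- cbind(id = seq_len(nrow(vari)), vari)
  vari$marker_present <- logical(nrow(vari))
  if (nrow(vari)) {
    is_ais <- vari$class == "AIS"
    vari$marker_present[is_ais] <-
      stats::rbinom(sum(is_ais), 1, cfg$marker_prob_ais) == 1
    vari$marker_present[!is_ais] <-
      stats::rbinom(sum(!is_ais), 1, cfg$marker_prob_off) == 1
  }
  vari$in_roi <- rep(TRUE, nrow(vari))

  # class-separation internal check (manifest invariant)
  if (n_off > 0 && length(tubes)) {
    for (tb in tubes) {
      surf <- dist_point_segment(off_sites, tb$p0, tb$p1) - tb$radius
      stopifnot(all(surf > 0.5))
    }
  }

  # rasterize
  voxel <- c(cfg$voxel_size_xy_um, cfg$voxel_size_xy_um, cfg$voxel_size_z_um)
  dims <- c(ny = round(geom$H / voxel[2]), nx = round(geom$W / voxel[1]),
            nz = round(geom$D / voxel[3]))
  axon <- array(0, dim = dims)
  polylines <- lapply(tree$branches, function(b) b$nodes)
  shaft_pts <- do.call(rbind, lapply(polylines, resample_polyline,
                                     spacing = 0.1))
  axon <- stamp_gauss(axon, shaft_pts, cfg$shaft_intensity,
                      GEN$shaft_sigma_xy, GEN$shaft_sigma_z, voxel)
  axon <- stamp_core(axon, matrix(geom$soma, ncol = 3),
                     1.5 * cfg$shaft_intensity, GEN$soma_core, GEN$soma_edge,
                     voxel)
  if (nrow(vari)) {
    # raw blob peak = ratio x raw shaft peak, so the measured raw-intensity
    # ratio matches the configured one
    blob_amp <- cfg$varicosity_brightness_ratio *
      (cfg$shaft_intensity + cfg$background_level) - cfg$background_level
    sxy <- cfg$varicosity_diam_xy_um / (2 * sqrt(2 * log(2)))
    sz <- cfg$varicosity_diam_z_um / (2 * sqrt(2 * log(2)))
    axon <- stamp_gauss(axon, as.matrix(vari[, c("x", "y", "z")]),
                        blob_amp, sxy, sz, voxel)
  }

  ais_ch <- array(0, dim = dims)
  if (length(tubes)) {
    tube_pts <- do.call(rbind, lapply(tubes, function(tb) {
      ts <- seq(0, sqrt(sum((tb$p1 - tb$p0)^2)), by = 0.25)
      dirT <- unit(tb$p1 - tb$p0)
      cbind(tb$p0[1] + dirT[1] * ts, tb$p0[2] + dirT[2] * ts,
            tb$p0[3] + dirT[3] * ts)
    }))
    ais_ch <- stamp_core(ais_ch, tube_pts, cfg$ais_intensity,
                         tubes[[1]]$radius, GEN$tube_edge, voxel)
  }

  marker <- array(0, dim = dims)
  # soma cytosol sits at background_level while the field is 0.8 x level:
  # the diffuse cytosolic signal the thresholding method references
  marker <- stamp_core(marker, matrix(geom$soma, ncol = 3),
                       0.2 * cfg$background_level, GEN$soma_core, 0.5, voxel)
  if (any(vari$marker_present)) {
    marker <- stamp_gauss(marker,
                          as.matrix(vari[vari$marker_present,
                                         c("x", "y", "z")]),
                          cfg$marker_intensity, GEN$marker_sigma_xy,
                          GEN$marker_sigma_z, voxel)
  }

  axon <- finalize_channel(axon, cfg$background_level, cfg$noise_sd)
  ais_ch <- finalize_channel(ais_ch, cfg$background_level, cfg$noise_sd)
  marker <- finalize_channel(marker, 0.8 * cfg$background_level, cfg$noise_sd)

  stack <- volume_stack(list(axon = axon, ais = ais_ch, marker = marker),
                        voxel, origin_um = c(0, 0, 0),
                        soma_center_um = geom$soma)

  tube_df <- if (length(tubes)) {
    do.call(rbind, lapply(tubes, function(tb)
      data.frame(id = tb$id, p0x = tb$p0[1], p0y = tb$p0[2], p0z = tb$p0[3],
                 p1x = tb$p1[1], p1y = tb$p1[2], p1z = tb$p1[3],
                 radius_um = tb$radius)))
  } else {
    data.frame(id = integer(0), p0x = numeric(0), p0y = numeric(0),
               p0z = numeric(0), p1x = numeric(0), p1y = numeric(0),
               p1z = numeric(0), radius_um = numeric(0))
  }
  manifest <- list(
    seed = cfg$seed,
    soma_center = geom$soma,
    n_branch_points = nrow(tree$bps),
    branch_point_coords = tree$bps,
    varicosities = vari,
    ais_tubes = tube_df,
    tree = lapply(polylines, function(m) unname(m)),
    voxel_size_um = voxel,
    apposition_note = "off-target centres are > 0.5 um from every tube surface"
  )
  list(stack = stack, manifest = manifest)
}
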