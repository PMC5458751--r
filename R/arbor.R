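# Axonal arbor morphometry: ROI selection, tracing (threshold -> largest
# component -> geodesic farthest-point skeletonization -> spur pruning), and
# branch-point / length measurement.

#' Skeleton of a traced axon
#'
#' A spatial graph: `nodes` are 3D points in um, `edges` connect node
#' indices and carry their Euclidean arc length, `soma_node` is the root.
#' A branch point is a node of degree >= 3.
#'
#' @param nodes Numeric matrix (n x 3) of `(x, y, z)` positions in um.
#' @param edges Data frame or matrix with columns `from`, `to` (1-based node
#'   indices); a `length_um` column is recomputed from the node positions if
#'   absent.
#' @param soma_node Index of the root node.
#' @return An object of class `chc_skeleton`.
#' @export
skeleton <- function(nodes, edges, soma_node = 1L) {
  nodes <- matrix(as.numeric(as.matrix(nodes)), ncol = 3)
  edges <- as.data.frame(edges)
  if (!all(c("from", "to") %in% names(edges))) {
    names(edges)[1:2] <- c("from", "to")
  }
  edges$from <- as.integer(edges$from)
  edges$to <- as.integer(edges$to)
  if (nrow(edges) && (max(edges$from, edges$to) > nrow(nodes) ||
                      min(edges$from, edges$to) < 1L)) {
    stop_chc("edge indices out of range")
  }
  edges$length_um <- sqrt(rowSums((nodes[edges$from, , drop = FALSE] -
                                     nodes[edges$to, , drop = FALSE])^2))
  structure(list(nodes = nodes, edges = edges,
                 soma_node = as.integer(soma_node)),
            class = "chc_skeleton")
}

#' @export
print.chc_skeleton <- function(x, ...) {
  deg <- skeleton_degrees(x)
  cat(sprintf("chc_skeleton: %d nodes, %d edges, %.1f um total, %d branch points\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$length_um),
              sum(deg >= 3)))
  invisible(x)
}

skeleton_degrees <- function(skel) {
  tabulate(c(skel$edges$from, skel$edges$to), nbins = nrow(skel$nodes))
}

skeleton_graph <- function(skel) {
  g <- igraph::make_empty_graph(n = nrow(skel$nodes), directed = FALSE)
  g <- igraph::add_edges(g, rbind(skel$edges$from, skel$edges$to))
  igraph::E(g)$weight <- skel$edges$length_um
  g
}

#' Crop the analysis ROI directly below the soma
#'
#' Returns the sub-volume spanning `roi_um[1]` um in x centred on the soma,
#' `roi_um[2]` um in y starting at the soma (the square "directly below the
#' soma"), and the full z extent.  If the requested window exceeds the
#' stack, it is clipped and the result carries `attr(, "truncated") = TRUE`
#' with a warning.
#'
#' @param stack A [volume_stack()].
#' @param soma_center `(x, y, z)` soma position in um (defaults to the
#'   stack's stored soma position).
#' @param roi_um ROI width and height in um.
#' @return A cropped `volume_stack` (origin updated, soma position kept).
#' @export
select_roi <- function(stack, soma_center = stack$soma_center_um,
                       roi_um = c(100, 100)) {
  if (is.null(soma_center)) stop_chc("soma_center is required")
  ext <- stack_extent_um(stack)
  if (soma_center[1] < ext[1, 1] || soma_center[1] > ext[1, 2] ||
      soma_center[2] < ext[2, 1] || soma_center[2] > ext[2, 2] ||
      soma_center[3] < ext[3, 1] || soma_center[3] > ext[3, 2]) {
    stop_chc("soma_center lies outside the stack")
  }
  want <- rbind(x = c(soma_center[1] - roi_um[1] / 2,
                      soma_center[1] + roi_um[1] / 2),
                y = c(soma_center[2], soma_center[2] + roi_um[2]))
  got <- rbind(x = c(max(want[1, 1], ext[1, 1]), min(want[1, 2], ext[1, 2])),
               y = c(max(want[2, 1], ext[2, 1]), min(want[2, 2], ext[2, 2])))
  truncated <- any(abs(got - want) > 1e-6)
  v <- stack$voxel_size
  o <- stack$origin_um
  d <- dim(stack$channels[[1]])
  ix <- (floor((got[1, 1] - o[1]) / v[1] + 1e-9) + 1L):
    min(d[2], ceiling((got[1, 2] - o[1]) / v[1] - 1e-9))
  iy <- (floor((got[2, 1] - o[2]) / v[2] + 1e-9) + 1L):
    min(d[1], ceiling((got[2, 2] - o[2]) / v[2] - 1e-9))
  if (length(ix) < 1 || length(iy) < 1 || got[2, 2] - got[2, 1] < v[2]) {
    stop_chc("ROI below the soma is empty (soma at the lower stack edge)")
  }
  channels <- lapply(stack$channels, function(a) a[iy, ix, , drop = FALSE])
  out <- volume_stack(channels, v,
                      origin_um = c(o[1] + (ix[1] - 1L) * v[1],
                                    o[2] + (iy[1] - 1L) * v[2], o[3]),
                      soma_center_um = stack$soma_center_um)
  if (truncated) {
    warning("ROI clipped to stack bounds", call. = FALSE)
  }
  attr(out, "truncated") <- truncated
  out
}

# Capped distance-from-boundary (DBF) for foreground voxels: the distance to
# the nearest background voxel centre, found by probing offset shells of
# increasing radius.  Out-of-bounds counts as background.  Used to keep
# centreline paths medial and to scale the path capture radius to the local
# structure thickness (thin shaft vs varicosity swelling).
dbf_foreground <- function(mask, fg_idx, coord, dims, voxel, cap = 1.6) {
  offs <- offset_ball(cap, voxel)
  d <- sqrt((offs[, 2] * voxel[1])^2 + (offs[, 1] * voxel[2])^2 +
              (offs[, 3] * voxel[3])^2)
  keep <- d > 0
  offs <- offs[keep, , drop = FALSE]
  d <- d[keep]
  shells <- split(seq_along(d), round(d, 6))
  shell_d <- as.numeric(names(shells))
  ord <- order(shell_d)
  dbf <- rep(cap + min(voxel), length(fg_idx))
  un <- seq_along(fg_idx)
  nyx <- dims[1] * dims[2]
  for (s in ord) {
    if (!length(un)) break
    hit <- logical(length(un))
    for (k in shells[[s]]) {
      yy <- coord[un, 1] + offs[k, 1]
      xx <- coord[un, 2] + offs[k, 2]
      zz <- coord[un, 3] + offs[k, 3]
      oob <- yy < 1L | yy > dims[1] | xx < 1L | xx > dims[2] |
        zz < 1L | zz > dims[3]
      lin <- yy + (xx - 1L) * dims[1] + (zz - 1L) * nyx
      lin[oob] <- 1L
      hit <- hit | oob | !mask[lin]
    }
    if (any(hit)) {
      dbf[un[hit]] <- shell_d[s]
      un <- un[!hit]
    }
  }
  dbf
}

# Remove a ball of voxels around the soma from a logical mask.
mask_soma_ball <- function(mask, stack, center, radius_um) {
  d <- dim(mask)
  v <- stack$voxel_size
  o <- stack$origin_um
  ix <- which(abs(o[1] + (seq_len(d[2]) - 0.5) * v[1] - center[1]) <= radius_um)
  iy <- which(abs(o[2] + (seq_len(d[1]) - 0.5) * v[2] - center[2]) <= radius_um)
  iz <- which(abs(o[3] + (seq_len(d[3]) - 0.5) * v[3] - center[3]) <= radius_um)
  if (!length(ix) || !length(iy) || !length(iz)) return(mask)
  dx2 <- (o[1] + (ix - 0.5) * v[1] - center[1])^2
  dy2 <- (o[2] + (iy - 0.5) * v[2] - center[2])^2
  dz2 <- (o[3] + (iz - 0.5) * v[3] - center[3])^2
  inside <- outer(outer(dy2, dx2, "+"), dz2, "+") <= radius_um^2
  sub <- mask[iy, ix, iz, drop = FALSE]
  sub[inside] <- FALSE
  mask[iy, ix, iz] <- sub
  mask
}

#' Trace the axon of an ROI stack into a skeleton
#'
#' Automatic stand-in for interactive filament tracing: the axon channel is
#' thresholded (Otsu by default), a ball around the soma is masked out, the
#' largest connected foreground component is kept, and its centreline is
#' extracted by geodesic farthest-point skeletonization: shortest-path
#' distances from the root are computed over the 26-connected foreground
#' voxel graph with medial-axis edge weighting (edges through voxels far
#' from the boundary are cheaper, so paths run through the middle of tubes
#' and swellings), and centreline paths are peeled off farthest-tip-first.
#' Each traced path invalidates the foreground it explains within an
#' adaptive capture radius `1.3 * DBF + capture_margin_um`, where DBF is the
#' voxel's distance from the boundary - large inside a varicosity, small
#' on a thin shaft.  Terminal spurs shorter than `spur_min_um` are pruned.
#'
#' @param roi_stack A `volume_stack` containing an `axon` channel.
#' @param soma_center Root position in um (defaults to stored soma).
#' @param threshold Foreground threshold; `NULL` uses [otsu_threshold()].
#' @param spur_min_um Minimum terminal branch length retained.
#' @param soma_mask_radius_um Radius of the somatic exclusion ball.
#' @param capture_margin_um Margin added to the local boundary distance to
#'   form the capture radius of a traced path.
#' @param dbf_cap_um Cap on the boundary-distance field; should be at
#'   least the radius of the thickest swelling expected on the axon.
#' @return A [skeleton()] whose `soma_node` is the traced root.
#' @export
trace_axon <- function(roi_stack, soma_center = roi_stack$soma_center_um,
                       threshold = NULL, spur_min_um = 1.0,
                       soma_mask_radius_um = 6.0,
                       capture_margin_um = 1.4,
                       dbf_cap_um = 1.6) {
  ax <- stack_channel(roi_stack, "axon")
  th <- threshold %||% otsu_threshold(ax)
  mask <- ax > th
  if (!is.null(soma_center)) {
    mask <- mask_soma_ball(mask, roi_stack, soma_center, soma_mask_radius_um)
  }
  fg_idx <- which(mask)
  if (!length(fg_idx)) stop_chc("no axon detected above threshold")
  dims <- dim(ax)
  v <- roi_stack$voxel_size
  fge <- foreground_graph_edges(fg_idx, dims, v)
  g <- igraph::make_empty_graph(n = length(fg_idx), directed = FALSE)
  g <- igraph::add_edges(g, t(fge$edges))
  igraph::E(g)$weight <- fge$weights
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  g <- igraph::induced_subgraph(g, keep)
  fg_idx <- fg_idx[keep]
  coord <- fge$coord[keep, , drop = FALSE]
  pts <- voxel_centers_um(coord, roi_stack)
  n <- length(fg_idx)

  root <- if (!is.null(soma_center)) {
    which.min((pts[, 1] - soma_center[1])^2 + (pts[, 2] - soma_center[2])^2 +
                (pts[, 3] - soma_center[3])^2)
  } else which.min(pts[, 2])

  # medial-axis weighting: penalise edges near the foreground boundary so
  # shortest paths stay centred inside tubes and swellings
  dbf <- dbf_foreground(mask, fg_idx, coord, dims, v, cap = dbf_cap_um)
  fpen <- 1 + 4 * (1 - pmin(dbf, dbf_cap_um) / dbf_cap_um)^2
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight * (fpen[el[, 1]] + fpen[el[, 2]]) / 2
  igraph::E(g)$weight <- w
  d <- as.numeric(igraph::distances(g, v = root))
  # parent of each vertex on some shortest path from the root
  cf <- c(el[, 1], el[, 2]); ct <- c(el[, 2], el[, 1]); cw <- c(w, w)
  ok <- is.finite(d[cf]) & abs(d[cf] + cw - d[ct]) < 1e-6
  cf <- cf[ok]; ct <- ct[ok]
  ord <- order(ct, d[cf], cf)
  ct <- ct[ord]; cf <- cf[ord]
  first <- !duplicated(ct)
  parent <- integer(n)
  parent[ct[first]] <- cf[first]
  parent[root] <- 0L

  # adjacency list for merge detection
  o2 <- order(c(el[, 1], el[, 2]))
  nb_from <- c(el[, 1], el[, 2])[o2]
  nb_to <- c(el[, 2], el[, 1])[o2]
  adj <- vector("list", n)
  adj[unique(nb_from)] <- split(nb_to, nb_from)

  # map voxel linear index -> vertex id for ball invalidation
  id_of <- integer(prod(dims))
  id_of[fg_idx] <- seq_len(n)
  # adaptive capture radius, bucketed so offset balls can be cached
  rad <- round((1.3 * pmin(dbf, dbf_cap_um) + capture_margin_um) / 0.2) * 0.2
  balls <- new.env(parent = emptyenv())
  nyx <- dims[1] * dims[2]

  valid <- is.finite(d)
  skel_flag <- logical(n)
  edge_acc <- vector("list", 256L)
  n_edge_chunks <- 0L
  dv <- d
  dv[!valid] <- -Inf
  while (TRUE) {
    t_id <- which.max(dv)
    if (!valid[t_id] || !is.finite(dv[t_id])) break
    vtx <- t_id
    path <- integer(0)
    merge_to <- NA_integer_
    repeat {
      if (skel_flag[vtx]) { merge_to <- vtx; break }
      nb <- adj[[vtx]]
      hits <- nb[skel_flag[nb]]
      if (length(hits)) {
        path <- c(path, vtx)
        merge_to <- hits[which.min(d[hits])]
        break
      }
      path <- c(path, vtx)
      pv <- parent[vtx]
      if (pv == 0L) break
      vtx <- pv
    }
    if (length(path)) {
      skel_flag[path] <- TRUE
      seg <- NULL
      if (length(path) > 1L) {
        seg <- cbind(path[-length(path)], path[-1L])
      }
      if (!is.na(merge_to) && merge_to != path[length(path)]) {
        seg <- rbind(seg, c(path[length(path)], merge_to))
      }
      if (!is.null(seg)) {
        n_edge_chunks <- n_edge_chunks + 1L
        if (n_edge_chunks > length(edge_acc)) {
          edge_acc <- c(edge_acc, vector("list", length(edge_acc)))
        }
        edge_acc[[n_edge_chunks]] <- seg
      }
    }
    # invalidate explained foreground around the path (adaptive radius)
    inv_src <- c(path, if (!is.na(merge_to)) merge_to)
    for (rk in unique(rad[inv_src])) {
      key <- sprintf("%.1f", rk)
      ball <- balls[[key]]
      if (is.null(ball)) {
        ball <- offset_ball(rk, v)
        balls[[key]] <- ball
      }
      pc <- coord[inv_src[rad[inv_src] == rk], , drop = FALSE]
      np <- nrow(pc); nbl <- nrow(ball)
      yy <- rep(pc[, 1], each = nbl) + rep(ball[, 1], np)
      xx <- rep(pc[, 2], each = nbl) + rep(ball[, 2], np)
      zz <- rep(pc[, 3], each = nbl) + rep(ball[, 3], np)
      okb <- yy >= 1L & yy <= dims[1] & xx >= 1L & xx <= dims[2] &
        zz >= 1L & zz <= dims[3]
      lin <- yy[okb] + (xx[okb] - 1L) * dims[1] + (zz[okb] - 1L) * nyx
      hit <- id_of[lin]
      hit <- hit[hit > 0L]
      valid[hit] <- FALSE
      dv[hit] <- -Inf
    }
  }
  edges <- do.call(rbind, edge_acc[seq_len(n_edge_chunks)])
  if (is.null(edges)) {
    # a single voxel (or no edges traced): degenerate one-node skeleton
    return(skeleton(pts[root, , drop = FALSE],
                    data.frame(from = integer(0), to = integer(0)), 1L))
  }
  used <- sort(unique(c(edges[, 1], edges[, 2], root)))
  remap <- integer(n)
  remap[used] <- seq_along(used)
  skel <- skeleton(pts[used, , drop = FALSE],
                   data.frame(from = remap[edges[, 1]],
                              to = remap[edges[, 2]]),
                   soma_node = remap[root])
  prune_spurs(skel, spur_min_um)
}

#' Prune terminal spurs shorter than a minimum length
#'
#' Iteratively removes leaf-to-junction arcs whose total length is below
#' `min_um`; such spurs are thinning artefacts below the biological branch
#' scale.  The root node is never pruned.
#'
#' @param skel A [skeleton()].
#' @param min_um Minimum retained terminal arc length (um).
#' @return The pruned skeleton.
#' @export
prune_spurs <- function(skel, min_um = 1.0) {
  repeat {
    deg <- skeleton_degrees(skel)
    nb <- skeleton_adjacency(skel)
    leaves <- setdiff(which(deg == 1L), skel$soma_node)
    drop_nodes <- logical(nrow(skel$nodes))
    changed <- FALSE
    for (leaf in leaves) {
      if (drop_nodes[leaf]) next
      arc <- leaf
      prev <- 0L
      len <- 0
      cur <- leaf
      repeat {
        nxt <- setdiff(nb[[cur]], prev)
        if (length(nxt) != 1L) break  # junction, root-end or isolated
        len <- len + sqrt(sum((skel$nodes[cur, ] - skel$nodes[nxt, ])^2))
        if (deg[nxt] >= 3L || nxt == skel$soma_node) {
          if (len < min_um) {
            drop_nodes[arc] <- TRUE
            changed <- TRUE
          }
          break
        }
        prev <- cur
        cur <- nxt
        arc <- c(arc, cur)
        if (len >= min_um) break
      }
    }
    if (!changed) break
    keep <- which(!drop_nodes)
    remap <- integer(nrow(skel$nodes))
    remap[keep] <- seq_along(keep)
    e <- skel$edges[!drop_nodes[skel$edges$from] & !drop_nodes[skel$edges$to], ]
    skel <- skeleton(skel$nodes[keep, , drop = FALSE],
                     data.frame(from = remap[e$from], to = remap[e$to]),
                     soma_node = remap[skel$soma_node])
  }
  skel
}

skeleton_adjacency <- function(skel) {
  n <- nrow(skel$nodes)
  ef <- c(skel$edges$from, skel$edges$to)
  et <- c(skel$edges$to, skel$edges$from)
  o <- order(ef)
  adj <- vector("list", n)
  adj[unique(ef[o])] <- split(et[o], ef[o])
  adj
}

#' Measure arbor morphometrics from a skeleton
#'
#' @param skel A [skeleton()].
#' @return An object of class `arbor_metrics`: `total_length_um` (sum of
#'   edge arc lengths), `n_branch_points` (nodes of degree >= 3), and
#'   `n_tips` (non-root leaves).
#' @export
measure_arbor <- function(skel) {
  stopifnot(inherits(skel, "chc_skeleton"))
  deg <- skeleton_degrees(skel)
  out <- list(total_length_um = sum(skel$edges$length_um),
              n_branch_points = sum(deg >= 3L),
              n_tips = length(setdiff(which(deg == 1L), skel$soma_node)))
  class(out) <- "arbor_metrics"
  out
}

#' @export
print.arbor_metrics <- function(x, ...) {
  cat(sprintf("arbor_metrics: %.1f um total length, %d branch points, %d tips\n",
              x$total_length_um, x$n_branch_points, x$n_tips))
  invisible(x)
}

#' Write a skeleton as an SWC morphology file
#'
#' Nodes are written in root-first (breadth-first) order with SWC type code
#' 2 (axon).
#'
#' @param skel A [skeleton()].
#' @param path Output file.
#' @param radius_um Constant radius recorded per node.
#' @return `path`, invisibly.
#' @export
write_swc <- function(skel, path, radius_um = 0.3) {
  g <- skeleton_graph(skel)
  bfs <- igraph::bfs(g, root = skel$soma_node, unreachable = FALSE,
                     father = TRUE)
  ord <- as.integer(bfs$order)
  ord <- ord[!is.na(ord)]
  father <- as.integer(bfs$father)
  swc_id <- integer(nrow(skel$nodes))
  swc_id[ord] <- seq_along(ord)
  parent <- ifelse(is.na(father[ord]) | father[ord] == 0L, -1L,
                   swc_id[father[ord]])
  df <- data.frame(id = seq_along(ord), type = 2L,
                   x = skel$nodes[ord, 1], y = skel$nodes[ord, 2],
                   z = skel$nodes[ord, 3], radius = radius_um,
                   parent = parent)
  utils::write.table(df, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an SWC morphology file into a skeleton
#' @param path SWC file.
#' @return A [skeleton()]; the root (parent -1) becomes `soma_node`.
#' @export
read_swc <- function(path) {
  df <- utils::read.table(path, col.names = c("id", "type", "x", "y", "z",
                                              "radius", "parent"))
  remap <- integer(max(df$id))
  remap[df$id] <- seq_len(nrow(df))
  has_parent <- df$parent > 0
  skeleton(as.matrix(df[, c("x", "y", "z")]),
           data.frame(from = remap[df$parent[has_parent]],
                      to = remap[df$id[has_parent]]),
           soma_node = remap[df$id[which(df$parent == -1L)[1]]])
}
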