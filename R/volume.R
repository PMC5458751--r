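#' Multi-channel 3D voxel volume with physical voxel size
#'
#' The container every detection stage operates on.  Intensity arrays are
#' stored `dim = c(ny, nx, nz)` (one image matrix per z-slice); all public
#' coordinates are right-handed `(x, y, z)` in micrometres with `y`
#' increasing towards deeper cortical layers.  Voxel `(iy, ix, iz)` is
#' centred at `origin + ((ix - 0.5) vx, (iy - 0.5) vy, (iz - 0.5) vz)`.
#'
#' @param channels Named list of 3D numeric arrays with identical dims.
#'   Names give the channel roles; `axon` is mandatory, `ais` and `marker`
#'   optional.
#' @param voxel_size Numeric length-3 `(x, y, z)` voxel pitch in um.
#' @param origin_um Physical position of the array corner (default 0,0,0).
#' @param soma_center_um Optional soma position carried as metadata.
#'
#' @return An object of class `volume_stack`.
#' @export
volume_stack <- function(channels, voxel_size, origin_um = c(0, 0, 0),
                         soma_center_um = NULL) {
  if (is.null(names(channels)) || !("axon" %in% names(channels))) {
    stop_config("channels must be a named list containing at least 'axon'")
  }
  dims <- dim(channels[[1]])
  if (length(dims) != 3) stop_config("channel arrays must be 3D")
  for (ch in channels) {
    if (!identical(dim(ch), dims)) stop_config("channel dims differ")
  }
  if (length(voxel_size) != 3 || any(voxel_size <= 0)) {
    stop_config("voxel_size must be three positive lengths (x, y, z)")
  }
  structure(list(channels = channels,
                 voxel_size = as.numeric(voxel_size),
                 origin_um = as.numeric(origin_um),
                 soma_center_um = if (!is.null(soma_center_um))
                   as.numeric(soma_center_um) else NULL),
            class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "volume_stack: %d x %d x %d voxels (y,x,z), voxel %.3g x %.3g x %.3g um\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat("channels:", paste(names(x$channels), collapse = ", "), "\n")
  ext <- stack_extent_um(x)
  cat(sprintf("extent: x [%.1f, %.1f], y [%.1f, %.1f], z [%.1f, %.1f] um\n",
              ext[1, 1], ext[1, 2], ext[2, 1], ext[2, 2], ext[3, 1], ext[3, 2]))
  invisible(x)
}

#' Get one channel array from a stack
#' @param stack A `volume_stack`.
#' @param role Channel name (`"axon"`, `"ais"`, `"marker"`).
#' @return The 3D intensity array.
#' @export
stack_channel <- function(stack, role) {
  if (!role %in% names(stack$channels)) {
    stop_chc("stack has no '", role, "' channel")
  }
  stack$channels[[role]]
}

stack_extent_um <- function(stack) {
  d <- dim(stack$channels[[1]])  # (ny, nx, nz)
  o <- stack$origin_um
  v <- stack$voxel_size
  rbind(x = c(o[1], o[1] + d[2] * v[1]),
        y = c(o[2], o[2] + d[1] * v[2]),
        z = c(o[3], o[3] + d[3] * v[3]))
}

# Voxel (iy, ix, iz) centres in um for an index matrix (n x 3, cols iy,ix,iz).
voxel_centers_um <- function(idx, stack) {
  idx <- matrix(idx, ncol = 3)
  v <- stack$voxel_size
  o <- stack$origin_um
  cbind(x = o[1] + (idx[, 2] - 0.5) * v[1],
        y = o[2] + (idx[, 1] - 0.5) * v[2],
        z = o[3] + (idx[, 3] - 0.5) * v[3])
}

# Nearest voxel indices for um points (n x 3, cols x,y,z), clipped in-bounds.
um_to_voxel <- function(pts, stack) {
  pts <- matrix(pts, ncol = 3)
  d <- dim(stack$channels[[1]])
  v <- stack$voxel_size
  o <- stack$origin_um
  iy <- pmin(d[1], pmax(1L, as.integer(ceiling((pts[, 2] - o[2]) / v[2]))))
  ix <- pmin(d[2], pmax(1L, as.integer(ceiling((pts[, 1] - o[1]) / v[1]))))
  iz <- pmin(d[3], pmax(1L, as.integer(ceiling((pts[, 3] - o[3]) / v[3]))))
  cbind(iy = iy, ix = ix, iz = iz)
}

#' Global Otsu threshold of an intensity array
#'
#' Histogram-based automatic threshold over the full array (the
#' parameter-free stand-in for interactive automatic thresholding).
#'
#' @param x Numeric array of intensities.
#' @param levels Number of histogram levels.
#' @return The threshold on the intensity scale of `x`.
#' @export
otsu_threshold <- function(x, levels = 4096L) {
  r <- range(x)
  if (diff(r) <= 0) return(r[1])
  xn <- (as.numeric(x) - r[1]) / diff(r)
  th <- EBImage::otsu(EBImage::Image(xn), range = c(0, 1), levels = levels)
  r[1] + th * diff(r)
}

# --- foreground voxel graph -------------------------------------------------

# 13 positive half-space neighbour offsets of 26-connectivity.
neighbor_offsets_26 <- function() {
  off <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dz = -1:1))
  off <- off[!(off[, 1] == 0 & off[, 2] == 0 & off[, 3] == 0), ]
  key <- off[, 3] * 9 + off[, 2] * 3 + off[, 1]
  off[key > 0, , drop = FALSE]
}

# Build the 26-connected adjacency of a set of foreground voxels.
# fg_idx: linear indices into an array of dims; returns list(edges = 2-col
# matrix of positions within fg_idx, weights = physical lengths, coord =
# voxel index matrix).
foreground_graph_edges <- function(fg_idx, dims, voxel_size) {
  n <- length(fg_idx)
  id_of <- integer(prod(dims))
  id_of[fg_idx] <- seq_len(n)
  coord <- arrayInd(fg_idx, dims)  # (iy, ix, iz)
  offs <- neighbor_offsets_26()
  ny <- dims[1]; nx <- dims[2]; nz <- dims[3]
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    dy <- offs[k, 1]; dx <- offs[k, 2]; dz <- offs[k, 3]
    ok <- coord[, 1] + dy >= 1 & coord[, 1] + dy <= ny &
      coord[, 2] + dx >= 1 & coord[, 2] + dx <= nx &
      coord[, 3] + dz >= 1 & coord[, 3] + dz <= nz
    src <- which(ok)
    if (!length(src)) next
    nb_lin <- fg_idx[src] + dy + dx * ny + dz * ny * nx
    nb_id <- id_of[nb_lin]
    hit <- nb_id > 0L
    if (!any(hit)) next
    from <- c(from, src[hit])
    to <- c(to, nb_id[hit])
    w <- c(w, rep(sqrt(sum((c(dx, dy, dz) * voxel_size)^2)), sum(hit)))
  }
  list(edges = cbind(from, to), weights = w, coord = coord, id_of = id_of)
}

# Connected-component labels (26-connectivity) for foreground voxels.
# Returns an integer membership vector parallel to fg_idx.
foreground_components <- function(fg_idx, dims) {
  if (!length(fg_idx)) return(integer(0))
  fge <- foreground_graph_edges(fg_idx, dims, c(1, 1, 1))
  g <- igraph::make_empty_graph(n = length(fg_idx), directed = FALSE)
  g <- igraph::add_edges(g, t(fge$edges))
  igraph::components(g)$membership
}

# Precomputed voxel-offset ball of physical radius r_um.
offset_ball <- function(r_um, voxel_size) {
  rv <- ceiling(r_um / voxel_size)
  off <- as.matrix(expand.grid(dy = -rv[2]:rv[2], dx = -rv[1]:rv[1],
                               dz = -rv[3]:rv[3]))
  d2 <- (off[, 2] * voxel_size[1])^2 + (off[, 1] * voxel_size[2])^2 +
    (off[, 3] * voxel_size[3])^2
  off[d2 <= r_um^2, , drop = FALSE]
}

# --- I/O ---------------------------------------------------------------------

#' Write a stack as multi-page TIFF files plus a JSON sidecar
#'
#' One 16-bit multi-page TIFF per channel (pages are z-slices, channel
#' order axon, ais, marker) and a `stack.json` sidecar recording voxel
#' size, origin, and soma position.
#'
#' @param stack A `volume_stack`.
#' @param dir Output directory (created if missing).
#' @param max_intensity Intensity mapped to the 16-bit full scale.
#' @return `dir`, invisibly.
#' @export
write_stack <- function(stack, dir, max_intensity = 4095) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  order_pref <- intersect(c("axon", "ais", "marker"), names(stack$channels))
  for (ch in order_pref) {
    arr <- stack$channels[[ch]]
    pages <- lapply(seq_len(dim(arr)[3]), function(k)
      pmin(pmax(arr[, , k] / max_intensity, 0), 1))
    tiff::writeTIFF(pages, file.path(dir, paste0(ch, ".tif")),
                    bits.per.sample = 16L, compression = "none")
  }
  meta <- list(voxel_size_um = stack$voxel_size,
               origin_um = stack$origin_um,
               soma_center_um = stack$soma_center_um,
               channels = order_pref,
               max_intensity = max_intensity)
  jsonlite::write_json(meta, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a stack written by [write_stack()]
#' @param dir Directory containing channel TIFFs and `stack.json`.
#' @return A `volume_stack`.
#' @export
read_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"),
                              simplifyVector = TRUE)
  channels <- list()
  for (ch in meta$channels) {
    pages <- tiff::readTIFF(file.path(dir, paste0(ch, ".tif")), all = TRUE)
    arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
    channels[[ch]] <- round(arr * meta$max_intensity)
  }
  volume_stack(channels, meta$voxel_size_um, meta$origin_um,
               meta$soma_center_um)
}

#' Write a ground-truth manifest as JSON
#' @param manifest A manifest list as returned by [generate_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a ground-truth manifest written by [write_manifest()]
#' @param path JSON file path.
#' @return The manifest list.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
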