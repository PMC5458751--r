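# EM vesicle morphometry: polygon shape descriptors, profile metrics, and
# a simple dark-ring vesicle segmenter for synthetic micrographs.

#' Shoelace area of a closed polygon
#' @param poly n x 2 matrix of vertices (closed implicitly).
#' @return Absolute enclosed area (squared input units).
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Perimeter of a closed polygon
#' @param poly n x 2 matrix of vertices.
#' @return Sum of Euclidean edge lengths including the closing edge.
#' @export
polygon_perimeter <- function(poly) {
  poly <- as.matrix(poly)
  d <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE]) - poly
  sum(sqrt(rowSums(d^2)))
}

# O(n^2) simplicity check; skipped above n_max vertices (finely sampled
# analytic outlines are simple by construction).
polygon_is_simple <- function(poly, n_max = 1500L) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (n > n_max) return(TRUE)
  a <- poly
  b <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # closing edge shares a vertex with edge 1
      if (seg_int(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

#' Roundness of a vesicle outline
#'
#' The shape descriptor `4 * pi * area / perimeter^2`: 1 for a circle,
#' smaller for elongated ("jellybean") outlines.  Area by the shoelace
#' formula, perimeter as the Euclidean edge-length sum.
#'
#' @param poly n x 2 closed polygon (>= 3 vertices), any length unit.
#' @return Roundness in (0, 1] (up to discretisation).
#' @export
roundness <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3) stop_chc("a polygon needs at least 3 vertices")
  if (!polygon_is_simple(poly)) stop_chc("polygon is self-intersecting")
  4 * pi * polygon_area(poly) / polygon_perimeter(poly)^2
}

#' Maximum Feret diameter of a polygon
#' @param poly n x 2 polygon.
#' @return Largest vertex-to-vertex distance (computed on the convex hull).
#' @export
feret_diameter <- function(poly) {
  poly <- as.matrix(poly)
  h <- poly[grDevices::chull(poly), , drop = FALSE]
  max(stats::dist(h))
}

#' Morphometrics of one EM varicosity profile
#'
#' Computes the gold-subtracted profile area, vesicle density over that
#' net area, per-vesicle roundness with its per-profile mean, and whether
#' the profile qualifies as a varicosity (maximum Feret diameter above
#' 200 nm).
#'
#' @param profile_polygon Profile outline, n x 2 in nm.
#' @param vesicles List of vesicle outlines (each n x 2, nm).
#' @param gold_area_nm2 Total thresholded immunogold area to subtract.
#' @param min_feret_nm Varicosity qualification cutoff.
#' @return An object of class `vesicle_profile`: areas in um^2, `n_vesicles`,
#'   `density_per_um2`, `roundness` (per vesicle), `mean_roundness`,
#'   `qualifies_as_varicosity`.
#' @export
profile_metrics <- function(profile_polygon, vesicles = list(),
                            gold_area_nm2 = 0, min_feret_nm = 200) {
  area_nm2 <- polygon_area(profile_polygon)
  if (gold_area_nm2 >= area_nm2) {
    stop_chc("gold area exceeds the profile area")
  }
  net_nm2 <- area_nm2 - gold_area_nm2
  rnd <- vapply(vesicles, roundness, numeric(1))
  out <- list(
    profile_area_um2 = area_nm2 / 1e6,
    gold_area_um2 = gold_area_nm2 / 1e6,
    net_area_um2 = net_nm2 / 1e6,
    n_vesicles = length(vesicles),
    density_per_um2 = length(vesicles) / (net_nm2 / 1e6),
    roundness = rnd,
    mean_roundness = if (length(rnd)) mean(rnd) else NA_real_,
    feret_nm = feret_diameter(profile_polygon),
    qualifies_as_varicosity = feret_diameter(profile_polygon) > min_feret_nm
  )
  class(out) <- "vesicle_profile"
  out
}

#' @export
print.vesicle_profile <- function(x, ...) {
  cat(sprintf(
    "vesicle_profile: %.3f um^2 net area, %d vesicles (%.0f /um^2), mean roundness %.3f%s\n",
    x$net_area_um2, x$n_vesicles, x$density_per_um2,
    ifelse(is.na(x$mean_roundness), NaN, x$mean_roundness),
    if (x$qualifies_as_varicosity) "" else " [does not qualify as varicosity]"))
  invisible(x)
}

#' Segment vesicle outlines from a synthetic EM image
#'
#' Dark-ring segmentation: pixels darker than `ring_level` are grouped
#' into connected components, holes are filled, and each component's
#' contour is extracted and smoothed (moving-average over neighbouring
#' chain vertices) to approximate a sub-pixel outline, limiting the
#' staircase bias that would otherwise inflate the perimeter and deflate
#' roundness.
#'
#' @param image Grayscale matrix (rows = y), 0-255.
#' @param nm_per_px Pixel pitch in nm.
#' @param ring_level Intensity below which a pixel is membrane-dark.
#' @param gold_level Intensity below which a pixel is immunogold (denser
#'   than membrane) and therefore excluded.
#' @param min_px Minimum component size in pixels.
#' @param smooth Half-width of the contour moving average.
#' @return List of vesicle outlines (n x 2 matrices, nm).
#' @export
segment_em_vesicles <- function(image, nm_per_px, ring_level = 80,
                                gold_level = 35, min_px = 20L, smooth = 2L) {
  mask <- EBImage::Image(t(image < ring_level & image > gold_level) * 1)
  lab <- EBImage::bwlabel(mask)
  lab <- EBImage::fillHull(lab)
  contours <- EBImage::ocontour(lab)
  out <- list()
  for (ct in contours) {
    if (nrow(ct) < min_px) next
    # circular moving average for sub-pixel smoothing
    n <- nrow(ct)
    k <- 2L * smooth + 1L
    idx <- outer(seq_len(n), -smooth:smooth, "+")
    idx <- ((idx - 1L) %% n) + 1L
    sm <- cbind(rowMeans(matrix(ct[idx, 1], n)), rowMeans(matrix(ct[idx, 2], n)))
    out[[length(out) + 1L]] <- sm * nm_per_px
  }
  out
}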