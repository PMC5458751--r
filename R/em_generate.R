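# Synthetic EM micrograph generator: one varicosity profile containing
# non-overlapping elliptical vesicles and dark immunogold particles, with
# analytic ground-truth outlines.

ellipse_polygon <- function(center, a, b, phi, n = 128L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x <- a * cos(t); y <- b * sin(t)
  cbind(center[1] + x * cos(phi) - y * sin(phi),
        center[2] + x * sin(phi) + y * cos(phi))
}

# Even-odd point-in-polygon for a pixel grid (vectorised over pixels).
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Generate a synthetic EM image of one varicosity profile
#'
#' Draws a smoothly irregular profile outline, packs `n_vesicles`
#' non-overlapping elliptical vesicles of the configured aspect ratio
#' inside it (aspect 1 = round, excitatory-like; > 1 = flattened
#' GABAergic "jellybean"), and adds dark immunogold discs.  Ground truth
#' records every analytic outline.
#'
#' @param cfg An [em_gen_config()].
#' @return List with `image` (grayscale matrix, rows = y, 0-255) and
#'   `truth` (profile polygon in nm, list of vesicle polygons, gold
#'   particle table and total gold area, pixel pitch).
#' @export
generate_em_image <- function(cfg) {
  stopifnot(inherits(cfg, "em_gen_config"))
  set.seed(cfg$seed)
  R0 <- cfg$profile_diameter_nm / 2
  field <- cfg$profile_diameter_nm + 160
  npx <- ceiling(field / cfg$nm_per_px)
  C <- c(field / 2, field / 2)

  # profile outline: low-order harmonic perturbation of a circle
  amp <- stats::runif(3, 0, 0.06)
  pha <- stats::runif(3, 0, 2 * pi)
  th <- seq(0, 2 * pi, length.out = 91L)[-91L]
  rr <- R0 * (1 + amp[1] * cos(th + pha[1]) + amp[2] * cos(2 * th + pha[2]) +
                amp[3] * cos(3 * th + pha[3]))
  profile <- cbind(C[1] + rr * cos(th), C[2] + rr * sin(th))
  r_of <- stats::approxfun(c(th, 2 * pi), c(rr, rr[1]), rule = 2)

  # vesicles: equivalent-circle diameter ~ lognormal around the mean,
  # aspect ratio fixed, random orientation, rejection-packed
  rho <- cfg$vesicle_aspect_ratio
  ves <- list()
  ves_par <- NULL
  if (cfg$n_vesicles > 0) {
    tries <- 0L
    max_tries <- 4000L * cfg$n_vesicles
    while (length(ves) < cfg$n_vesicles) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop_capacity("cannot pack ", cfg$n_vesicles,
                      " vesicles into the profile without overlap")
      }
      d_eq <- cfg$vesicle_mean_diameter_nm * exp(stats::rnorm(1, 0, 0.08))
      a <- d_eq / 2 * sqrt(rho)
      b <- d_eq / 2 / sqrt(rho)
      ang <- stats::runif(1, 0, 2 * pi)
      u <- sqrt(stats::runif(1))
      margin <- a + 6
      rmax <- r_of(ang %% (2 * pi)) * 0.82 - margin
      if (rmax <= 0) next
      cen <- C + u * rmax * c(cos(ang), sin(ang))
      phi <- stats::runif(1, 0, pi)
      ok <- TRUE
      if (!is.null(ves_par)) {
        dd <- sqrt((ves_par[, 1] - cen[1])^2 + (ves_par[, 2] - cen[2])^2)
        ok <- all(dd >= ves_par[, 3] + a + 10)
      }
      if (!ok) next
      ves[[length(ves) + 1L]] <- ellipse_polygon(cen, a, b, phi)
      ves_par <- rbind(ves_par, c(cen, a, b, phi))
    }
  }

  # gold particles: dark discs avoiding vesicles
  gold <- NULL
  if (cfg$gold_particle_count > 0) {
    gr <- cfg$gold_diameter_nm / 2
    tries <- 0L
    while (is.null(gold) || nrow(gold) < cfg$gold_particle_count) {
      tries <- tries + 1L
      if (tries > 4000L * cfg$gold_particle_count) {
        stop_capacity("cannot place the requested gold particles")
      }
      ang <- stats::runif(1, 0, 2 * pi)
      u <- sqrt(stats::runif(1))
      rmax <- r_of(ang) * 0.85 - gr - 4
      if (rmax <= 0) next
      cen <- C + u * rmax * c(cos(ang), sin(ang))
      ok <- TRUE
      if (!is.null(ves_par)) {
        dd <- sqrt((ves_par[, 1] - cen[1])^2 + (ves_par[, 2] - cen[2])^2)
        ok <- all(dd >= ves_par[, 3] + gr + 10)
      }
      if (ok && !is.null(gold)) {
        dd <- sqrt((gold[, 1] - cen[1])^2 + (gold[, 2] - cen[2])^2)
        ok <- all(dd >= 2 * gr + 2)
      }
      if (!ok) next
      gold <- rbind(gold, c(x = cen[1], y = cen[2], r = gr))
    }
  }

  # rasterize
  s <- cfg$nm_per_px
  pxc <- (seq_len(npx) - 0.5) * s
  gx <- rep(pxc, each = npx)   # column-major: x varies by column
  gy <- rep(pxc, npx)
  img <- matrix(200, nrow = npx, ncol = npx)
  inside_prof <- points_in_polygon(gx, gy, profile)
  img[matrix(inside_prof, nrow = npx)] <- 140
  if (length(ves)) {
    for (k in seq_along(ves)) {
      p <- ves_par[k, ]
      dx <- gx - p[1]; dy <- gy - p[2]
      ct <- cos(p[5]); st <- sin(p[5])
      xr <- dx * ct + dy * st
      yr <- -dx * st + dy * ct
      q <- sqrt((xr / p[3])^2 + (yr / p[4])^2)
      lum <- q < 1 - 3 / p[4]
      ring <- abs(q - 1) * p[4] <= 3
      img[matrix(lum, nrow = npx)] <- 120
      img[matrix(ring, nrow = npx)] <- 50
    }
  }
  if (!is.null(gold)) {
    for (k in seq_len(nrow(gold))) {
      hit <- (gx - gold[k, 1])^2 + (gy - gold[k, 2])^2 <= gold[k, 3]^2
      img[matrix(hit, nrow = npx)] <- 20
    }
  }
  img <- img + stats::rnorm(length(img), 0, 4)
  img <- round(pmin(pmax(img, 0), 255))

  truth <- list(
    nm_per_px = s,
    profile_polygon = profile,
    vesicles = ves,
    gold = if (!is.null(gold))
      data.frame(x = gold[, 1], y = gold[, 2], r = gold[, 3])
    else data.frame(x = numeric(0), y = numeric(0), r = numeric(0)),
    gold_area_nm2 = if (!is.null(gold)) sum(pi * gold[, 3]^2) else 0
  )
  list(image = img, truth = truth)
}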