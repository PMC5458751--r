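# Shared fixtures.  Synthetic stacks are generated once per session and
# memoised; sizes are kept small so the whole suite stays fast.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Small tube-free config for multi-seed sweeps (branch recovery).
cfg_sweep <- function(seed, noise_sd = 0) {
  gen_config(seed = seed, roi_um = c(44, 48), slice_depth_um = 24,
             n_branch_points = 6L, n_varicosities_total = 10L,
             frac_on_ais = 0, n_ais_tubes = 0L, noise_sd = noise_sd)
}

# Small config with AIS tubes (seed 1 verified feasible).
cfg_tiny <- function(noise_sd = 0) {
  gen_config(seed = 1L, roi_um = c(44, 48), slice_depth_um = 24,
             n_branch_points = 6L, n_varicosities_total = 10L,
             frac_on_ais = 0.4, n_ais_tubes = 2L, ais_length_um = 12,
             noise_sd = noise_sd)
}

# Mid-size config exercising all stages together.
cfg_mid <- function(seed = 1L, noise_sd = 0) {
  gen_config(seed = seed, roi_um = c(70, 70), slice_depth_um = 40,
             n_branch_points = 30L, n_varicosities_total = 60L,
             frac_on_ais = 0.4, n_ais_tubes = 6L, noise_sd = noise_sd)
}

# Full mid-size pipeline, memoised: stack, skeleton, detections, AIS
# objects, classification.
fixture_mid <- function() {
  memo("mid", {
    cfg <- cfg_mid()
    gen <- generate_stack(cfg)
    roi <- select_roi(gen$stack, roi_um = cfg$roi_um)
    skel <- trace_axon(roi)
    vari <- detect_varicosities(roi, skel)
    ais <- segment_ais(roi)
    cl <- classify_varicosities(vari, ais)
    list(cfg = cfg, gen = gen, roi = roi, skel = skel, vari = vari,
         ais = ais, classified = cl)
  })
}

fixture_tiny <- function() {
  memo("tiny", {
    cfg <- cfg_tiny()
    gen <- generate_stack(cfg)
    roi <- select_roi(gen$stack, roi_um = cfg$roi_um)
    list(cfg = cfg, gen = gen, roi = roi)
  })
}

# A straight axon-like tube along y with optional Gaussian blobs, built
# directly (independent of the generator) on a coarse grid.
make_tube_stack <- function(length_um = 80, shaft = 1000, background = 100,
                            blob_centers = NULL, blob_peak = NULL,
                            sigma_xy = 0.3, sigma_z = 0.4,
                            blob_sxy = 0.85, blob_sz = 1.0,
                            voxel = c(0.25, 0.25, 0.5), pad_um = 6,
                            noise_sd = 0, seed = 1) {
  set.seed(seed)
  W <- 2 * pad_um
  H <- length_um + 2 * pad_um
  D <- 2 * pad_um
  dims <- c(round(H / voxel[2]), round(W / voxel[1]), round(D / voxel[3]))
  xs <- (seq_len(dims[2]) - 0.5) * voxel[1]
  ys <- (seq_len(dims[1]) - 0.5) * voxel[2]
  zs <- (seq_len(dims[3]) - 0.5) * voxel[3]
  # snap the tube axis (and blob centres) to voxel centres so nominal
  # intensities are realised exactly on the grid
  snap <- function(u, pitch) (round(u / pitch + 0.5) - 0.5) * pitch
  cx <- snap(W / 2, voxel[1]); cz <- snap(D / 2, voxel[3])
  on_y <- as.numeric(ys >= pad_um & ys <= pad_um + length_um)
  arr <- array(0, dim = dims)
  for (k in seq_len(dims[3])) {
    gz <- exp(-(zs[k] - cz)^2 / (2 * sigma_z^2))
    arr[, , k] <- shaft * gz * (on_y %o% exp(-(xs - cx)^2 / (2 * sigma_xy^2)))
  }
  if (!is.null(blob_centers)) {
    blob_centers <- matrix(blob_centers, ncol = 3)
    blob_centers[, 1] <- snap(blob_centers[, 1], voxel[1])
    blob_centers[, 2] <- snap(blob_centers[, 2], voxel[2])
    blob_centers[, 3] <- snap(blob_centers[, 3], voxel[3])
    blob_centers[, 1] <- cx; blob_centers[, 3] <- cz
    for (i in seq_len(nrow(blob_centers))) {
      b <- blob_centers[i, ]
      gx <- exp(-(xs - b[1])^2 / (2 * blob_sxy^2))
      gy <- exp(-(ys - b[2])^2 / (2 * blob_sxy^2))
      gz <- exp(-(zs - b[3])^2 / (2 * blob_sz^2))
      bump <- blob_peak[min(i, length(blob_peak))] *
        (gy %o% gx) %o% gz
      arr <- pmax(arr, bump)
    }
  }
  arr <- arr + background
  if (noise_sd > 0) arr <- arr + rnorm(length(arr), 0, noise_sd)
  arr <- round(pmin(pmax(arr, 0), 4095))
  out <- volume_stack(list(axon = array(arr, dim = dims)), voxel)
  attr(out, "axis_xz") <- c(cx, cz)
  attr(out, "blobs") <- blob_centers
  out
}

# Analytic ellipse polygon (for shape-descriptor oracles).
ellipse_poly <- function(a, b, n = 128L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(a * cos(t), b * sin(t))
}

expect_capacity_error <- function(expr) {
  testthat::expect_error(expr, class = "chc_capacity_error")
}

expect_config_error <- function(expr) {
  testthat::expect_error(expr, class = "chc_config_error")
}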