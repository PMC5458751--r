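test_that("selection criteria use the printed boundary semantics", {
  # satisfies both size rules and the brightness rule
  expect_true(varicosity_criteria(2.5, 3.0, 2.2))
  # too wide in x-y, rejected regardless of brightness
  expect_false(varicosity_criteria(3.5, 3.0, 10))
  # too dim
  expect_false(varicosity_criteria(2.5, 3.0, 1.5))
  # "at least two times": exactly 2.0 is retained
  expect_true(varicosity_criteria(2.5, 3.0, 2.0))
  # "smaller than 3 um": exactly 3.0 is rejected
  expect_false(varicosity_criteria(3.0, 3.0, 2.5))
  expect_false(varicosity_criteria(2.5, 3.5, 2.5))
})

test_that("a bright swelling on a tube is detected and measured", {
  stk <- make_tube_stack(length_um = 60, blob_centers = c(6, 30, 6),
                         blob_peak = 2650)
  truth <- attr(stk, "blobs")[1, ]
  skel <- trace_axon(stk, soma_center = NULL)
  vd <- detect_varicosities(stk, skel)
  expect_equal(nrow(vd), 1L)
  expect_lt(sqrt(sum((c(vd$x_um, vd$y_um, vd$z_um) - truth)^2)), 0.5)
  expect_gte(vd$brightness_ratio, 2)
  # raw ratio close to (2650 + 100) / (1000 + 100)
  expect_lt(abs(vd$brightness_ratio - 2.5), 0.2)
  expect_lt(vd$diameter_xy_um, 3)
  expect_lt(vd$diameter_z_um, 3.5)
})

test_that("the shaft reference recovers the configured shaft intensity", {
  refs <- vapply(1:10, function(seed) {
    stk <- make_tube_stack(length_um = 40, shaft = 100, background = 0,
                           noise_sd = 5, seed = seed)
    ax <- attr(stk, "axis_xz")
    skel <- trace_axon(stk, soma_center = NULL, threshold = 40)
    shaft_reference(skel, stk, center = c(ax[1], 20, ax[2]))
  }, numeric(1))
  expect_true(all(refs >= 95 & refs <= 105))
})

test_that("a swelling with no adjacent shaft is flagged unscorable", {
  # blob on a 4 um stub: after excluding blob voxels, the 2-5 um arc
  # annulus holds no shaft reference
  stk <- make_tube_stack(length_um = 4, blob_centers = c(6, 8, 6),
                         blob_peak = 2650)
  skel <- trace_axon(stk, soma_center = NULL, spur_min_um = 0.3)
  expect_warning(vd <- detect_varicosities(stk, skel, candidate_factor = 0.5),
                 "unscorable")
  expect_equal(nrow(vd), 0L)
  expect_equal(attr(vd, "n_unscorable"), 1L)
})

test_that("noiseless detections match the manifest one-to-one", {
  fx <- fixture_mid()
  truth <- as.matrix(fx$gen$manifest$varicosities[, c("x", "y", "z")])
  det <- as.matrix(fx$vari[, c("x_um", "y_um", "z_um")])
  expect_equal(nrow(det), nrow(truth))
  near <- apply(det, 1, function(p) {
    d <- sqrt(colSums((t(truth) - p)^2)); c(which.min(d), min(d))
  })
  expect_true(all(near[2, ] < 1))          # matched within 1 um
  expect_equal(length(unique(near[1, ])), nrow(truth))  # one-to-one
  # output invariants
  expect_true(all(varicosity_criteria(fx$vari$diameter_xy_um,
                                      fx$vari$diameter_z_um,
                                      fx$vari$brightness_ratio)))
})

test_that("detection under default noise recovers at least 95% with under 2% spurious", {
  cfg <- cfg_mid(seed = 2, noise_sd = 20)
  gen <- generate_stack(cfg)
  roi <- select_roi(gen$stack, roi_um = cfg$roi_um)
  skel <- trace_axon(roi)
  vd <- detect_varicosities(roi, skel)
  truth <- as.matrix(gen$manifest$varicosities[, c("x", "y", "z")])
  det <- as.matrix(vd[, c("x_um", "y_um", "z_um")])
  dmin <- apply(det, 1, function(p) min(sqrt(colSums((t(truth) - p)^2))))
  n_spurious <- sum(dmin >= 1)
  matched <- length(unique(apply(det[dmin < 1, , drop = FALSE], 1,
                                 function(p)
                                   which.min(colSums((t(truth) - p)^2)))))
  expect_gte(matched, ceiling(0.95 * nrow(truth)))
  expect_lte(n_spurious, 2L)
})

test_that("raising the brightness threshold never adds detections", {
  fx <- fixture_mid()
  n <- vapply(c(2.0, 2.4, 2.8, 3.2), function(r)
    nrow(detect_varicosities(fx$roi, fx$skel, min_ratio = r)), integer(1))
  expect_true(all(diff(n) <= 0))
})

test_that("detection is deterministic on identical input", {
  fx <- fixture_tiny()
  roi <- fx$roi
  skel <- trace_axon(roi)
  v1 <- detect_varicosities(roi, skel)
  v2 <- detect_varicosities(roi, skel)
  expect_identical(v1, v2)
})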