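test_that("the background is the mean somatic-cytosol marker intensity", {
  dims <- c(40, 40, 16)
  marker <- array(10, dims)
  mask <- array(FALSE, dims)
  mask[10:30, 10:30, 4:12] <- TRUE
  stk <- volume_stack(list(axon = array(0, dims), marker = marker),
                      c(0.5, 0.5, 0.5))
  expect_equal(estimate_background(stk, mask), 10)
  # empty and over-eroded masks are errors
  expect_error(estimate_background(stk, array(FALSE, dims)), "empty")
  thin <- array(FALSE, dims); thin[20, 10:30, 8] <- TRUE
  expect_error(estimate_background(stk, thin), "empty")
})

test_that("soma detection and background recovery hit the configured level", {
  for (seed in 1:3) {
    cfg <- gen_config(seed = seed, roi_um = c(44, 48), slice_depth_um = 24,
                      n_branch_points = 6L, n_varicosities_total = 10L,
                      frac_on_ais = 0, n_ais_tubes = 0L, noise_sd = 5)
    gen <- generate_stack(cfg)
    sm <- soma_mask(gen$stack)
    bg <- estimate_background(gen$stack, sm)
    expect_true(bg >= 98 && bg <= 102)
  }
})

test_that("positivity is strict: a mean equal to background is negative", {
  dims <- c(30, 30, 12)
  stk <- volume_stack(list(axon = array(0, dims), marker = array(50, dims)),
                      c(0.5, 0.5, 0.5))
  vari <- data.frame(id = 1L, x_um = 7.5, y_um = 7.5, z_um = 3,
                     diameter_xy_um = 2, diameter_z_um = 2.5,
                     peak_intensity = NA, shaft_intensity = NA,
                     brightness_ratio = 2.5, label = "AIS")
  mc <- call_markers(vari, stk, background = 50)
  expect_false(mc$calls$positive)
  # any value strictly above flips it
  mc2 <- call_markers(vari, stk, background = 49.999)
  expect_true(mc2$calls$positive)
})

test_that("calls are invariant to joint affine rescaling", {
  fx <- fixture_tiny()
  cl <- manifest_varicosities(fx$gen$manifest, fx$cfg)
  sm <- soma_mask(fx$roi)
  bg <- estimate_background(fx$roi, sm)
  mc <- call_markers(cl, fx$roi, bg)
  scaled <- fx$roi
  scaled$channels$marker <- 3 * scaled$channels$marker + 7
  mc2 <- call_markers(cl, scaled, 3 * bg + 7)
  expect_equal(mc$calls$positive, mc2$calls$positive)
  expect_equal(mc$summary$pct_positive, mc2$summary$pct_positive)
})

test_that("marker calls reproduce the generator's ground truth per varicosity", {
  fx <- fixture_mid()
  cl <- manifest_varicosities(fx$gen$manifest, fx$cfg)
  sm <- soma_mask(fx$roi)
  bg <- estimate_background(fx$roi, sm)
  mc <- call_markers(cl, fx$roi, bg)
  truth <- fx$gen$manifest$varicosities
  expect_equal(mc$calls$positive, truth$marker_present)
  # under-sampled classes (< 50 scored) are flagged, not dropped
  expect_true(all(mc$summary$under_sampled))
  expect_equal(sum(mc$summary$n_scored), nrow(truth))
})

test_that("a zero marker probability yields zero positives", {
  cfg <- gen_config(seed = 5, roi_um = c(44, 48), slice_depth_um = 24,
                    n_branch_points = 6L, n_varicosities_total = 10L,
                    frac_on_ais = 0, n_ais_tubes = 0L,
                    marker_prob_off = 0, noise_sd = 0)
  gen <- generate_stack(cfg)
  cl <- manifest_varicosities(gen$manifest, cfg)
  bg <- estimate_background(gen$stack, soma_mask(gen$stack))
  mc <- call_markers(cl, gen$stack, bg)
  expect_equal(mc$summary$pct_positive[mc$summary$label == "off_target"], 0)
})

test_that("recovered positive fractions are unbiased estimates of the probabilities", {
  pct_ais <- numeric(0); pct_off <- numeric(0)
  n_ais <- 0L; n_off <- 0L
  for (seed in 1:3) {
    cfg <- cfg_mid(seed)
    gen <- generate_stack(cfg)
    cl <- manifest_varicosities(gen$manifest, cfg)
    bg <- estimate_background(gen$stack, soma_mask(gen$stack))
    mc <- call_markers(cl, gen$stack, bg)
    s <- mc$summary
    pct_ais <- c(pct_ais, s$pct_positive[s$label == "AIS"])
    pct_off <- c(pct_off, s$pct_positive[s$label == "off_target"])
    n_ais <- n_ais + s$n_scored[s$label == "AIS"]
    n_off <- n_off + s$n_scored[s$label == "off_target"]
  }
  # binomial bands around the configured probabilities (3 sigma)
  se_ais <- 100 * sqrt(0.9 * 0.1 / n_ais)
  se_off <- 100 * sqrt(0.15 * 0.85 / n_off)
  expect_lt(abs(mean(pct_ais) - 90), 3 * se_ais + 1e-9)
  expect_lt(abs(mean(pct_off) - 15), 3 * se_off + 1e-9)
})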