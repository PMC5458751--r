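test_that("generated counts and classes follow the configuration", {
  fx <- fixture_mid()
  m <- fx$gen$manifest
  cfg <- fx$cfg
  expect_equal(m$n_branch_points, cfg$n_branch_points)
  expect_equal(nrow(m$branch_point_coords), cfg$n_branch_points)
  vr <- m$varicosities
  expect_equal(nrow(vr), cfg$n_varicosities_total)
  n_ais <- round(cfg$frac_on_ais * cfg$n_varicosities_total)
  expect_equal(sum(vr$class == "AIS"), n_ais)
  expect_equal(sum(vr$class == "off_target"),
               cfg$n_varicosities_total - n_ais)
  expect_equal(nrow(m$ais_tubes), cfg$n_ais_tubes)
  # every AIS varicosity references an existing tube
  expect_true(all(vr$host_ais_id[vr$class == "AIS"] %in% m$ais_tubes$id))
  expect_true(all(is.na(vr$host_ais_id[vr$class == "off_target"])))
  expect_true(all(vr$in_roi))
})

test_that("off-target varicosities keep their distance from every AIS tube", {
  for (seed in 1:3) {
    cfg <- cfg_mid(seed)
    m <- generate_stack(cfg)$manifest
    vr <- m$varicosities
    off <- as.matrix(vr[vr$class == "off_target", c("x", "y", "z")])
    for (k in seq_len(nrow(m$ais_tubes))) {
      tb <- m$ais_tubes[k, ]
      d <- chcmorph:::dist_point_segment(off, c(tb$p0x, tb$p0y, tb$p0z),
                                         c(tb$p1x, tb$p1y, tb$p1z))
      # surface distance must exceed the apposition tolerance
      expect_gt(min(d - tb$radius_um), 0.5)
    }
  }
})

test_that("a configuration without branches yields a single unbranched curve", {
  cfg <- gen_config(seed = 3, roi_um = c(40, 40), slice_depth_um = 20,
                    n_branch_points = 0L, n_varicosities_total = 0L,
                    frac_on_ais = 0, n_ais_tubes = 0L, noise_sd = 0)
  gen <- generate_stack(cfg)
  expect_equal(gen$manifest$n_branch_points, 0L)
  expect_equal(nrow(gen$manifest$varicosities), 0L)
  skel <- trace_axon(select_roi(gen$stack, roi_um = cfg$roi_um))
  expect_equal(measure_arbor(skel)$n_branch_points, 0L)
})

test_that("the forced rounding rule splits varicosities between classes", {
  # frac 0.4 of 60 must give exactly 24 AIS / 36 off-target
  m <- fixture_mid()$gen$manifest
  expect_equal(sum(m$varicosities$class == "AIS"), 24L)
  expect_equal(sum(m$varicosities$class == "off_target"), 36L)
})

test_that("identical seed and config give bit-identical stacks and files", {
  cfg <- cfg_tiny(noise_sd = 15)
  g1 <- generate_stack(cfg)
  g2 <- generate_stack(cfg)
  expect_identical(g1$stack$channels, g2$stack$channels)
  expect_identical(g1$manifest, g2$manifest)
  d1 <- file.path(tempdir(), "stk1"); d2 <- file.path(tempdir(), "stk2")
  write_stack(g1$stack, d1); write_stack(g2$stack, d2)
  write_manifest(g1$manifest, file.path(d1, "truth.json"))
  write_manifest(g2$manifest, file.path(d2, "truth.json"))
  for (f in c("axon.tif", "ais.tif", "marker.tif", "truth.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("stack TIFF round-trip preserves intensities and metadata", {
  fx <- fixture_tiny()
  d <- file.path(tempdir(), "stk_rt")
  write_stack(fx$gen$stack, d)
  back <- read_stack(d)
  expect_equal(back$voxel_size, fx$gen$stack$voxel_size)
  expect_equal(back$soma_center_um, fx$gen$stack$soma_center_um)
  # 12-bit data written into 16-bit pages round-trips within quantisation
  expect_lt(max(abs(back$channels$axon - fx$gen$stack$channels$axon)), 1)
  unlink(d, recursive = TRUE)
})

test_that("invalid configurations are rejected with classed errors", {
  expect_config_error(gen_config(frac_on_ais = 0.5, n_ais_tubes = 0))
  expect_config_error(gen_config(varicosity_diam_xy_um = 3.0))
  expect_config_error(gen_config(varicosity_diam_z_um = 3.6))
  expect_config_error(gen_config(varicosity_brightness_ratio = 1.5))
  expect_config_error(gen_config(ais_length_um = 9))
  expect_config_error(gen_config(ais_width_um = 1.5))
  expect_config_error(gen_config(frac_on_ais = 1.2))
  expect_config_error(em_gen_config(profile_diameter_nm = 150))
  expect_config_error(em_gen_config(vesicle_aspect_ratio = 0.8))
})

test_that("impossible geometry raises a capacity error", {
  expect_capacity_error(generate_stack(
    gen_config(seed = 1, roi_um = c(20, 20), slice_depth_um = 12,
               n_branch_points = 400L, n_varicosities_total = 0L,
               frac_on_ais = 0, n_ais_tubes = 0L)))
  expect_capacity_error(generate_stack(
    gen_config(seed = 1, roi_um = c(44, 48), slice_depth_um = 24,
               n_branch_points = 6L, n_varicosities_total = 500L,
               frac_on_ais = 0, n_ais_tubes = 0L)))
  expect_capacity_error(generate_em_image(
    em_gen_config(profile_diameter_nm = 210, n_vesicles = 200L)))
})

test_that("EM ground truth matches the analytic ellipse geometry", {
  # no vesicles
  em0 <- generate_em_image(em_gen_config(seed = 1, n_vesicles = 0L))
  expect_length(em0$truth$vesicles, 0L)
  # aspect 1: outlines are circles, roundness 1 in the continuum
  em1 <- generate_em_image(em_gen_config(seed = 2, n_vesicles = 12L,
                                         vesicle_aspect_ratio = 1))
  r1 <- vapply(em1$truth$vesicles, roundness, numeric(1))
  expect_true(all(abs(r1 - 1) < 2e-3))
  # aspect 2: roundness equals the elliptic-integral value
  em2 <- generate_em_image(em_gen_config(seed = 2, n_vesicles = 12L,
                                         vesicle_aspect_ratio = 2))
  r2 <- vapply(em2$truth$vesicles, roundness, numeric(1))
  oracle <- 4 * pi * (pi * 2 * 1) / (4 * 2 * pracma::ellipke(1 - 1 / 4)$e)^2
  expect_true(all(abs(r2 - oracle) < 2e-3))
  # determinism
  em2b <- generate_em_image(em_gen_config(seed = 2, n_vesicles = 12L,
                                          vesicle_aspect_ratio = 2))
  expect_identical(em2$image, em2b$image)
})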