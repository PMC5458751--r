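# Build a stack whose AIS channel holds one vertical tube of given size.
ais_tube_stack <- function(height_um, width_um, voxel = c(0.25, 0.25, 0.5)) {
  dims <- c(round(30 / voxel[2]), round(12 / voxel[1]), round(12 / voxel[3]))
  # spherical end caps add one radius per end to the rendered height
  ts <- seq(0, max(height_um - width_um, 0.5), by = 0.25)
  pts <- cbind(6, 4 + ts, 6)
  arr <- chcmorph:::stamp_core(array(0, dims), pts, 1200, width_um / 2 - 0.2,
                               0.12, voxel)
  volume_stack(list(axon = array(0, dims), ais = arr + 100), voxel)
}

test_that("the bounding-box filter retains only AIS-sized objects", {
  keep <- segment_ais(ais_tube_stack(12, 2.5))
  expect_length(keep, 1L)
  expect_gt(keep[[1]]$bounding_box["height_um"], 10)
  expect_gt(keep[[1]]$bounding_box["width_um"], 2)
  # 8 um tall: fails the height rule
  expect_length(segment_ais(ais_tube_stack(8, 2.5)), 0L)
  # too narrow
  expect_length(segment_ais(ais_tube_stack(12, 1.2)), 0L)
  # empty channel
  empty <- volume_stack(list(axon = array(0, c(10, 10, 4)),
                             ais = array(100, c(10, 10, 4))),
                        c(0.5, 0.5, 0.5))
  expect_length(segment_ais(empty), 0L)
})

test_that("segmented AIS objects match the generated tubes", {
  fx <- fixture_mid()
  expect_length(fx$ais, fx$cfg$n_ais_tubes)
  tubes <- fx$gen$manifest$ais_tubes
  # each object centroid lies on one tube axis (within its radius + voxel)
  for (ao in fx$ais) {
    cen <- colMeans(ao$coords_um)
    d <- vapply(seq_len(nrow(tubes)), function(k)
      min(chcmorph:::dist_point_segment(
        matrix(cen, ncol = 3),
        c(tubes$p0x[k], tubes$p0y[k], tubes$p0z[k]),
        c(tubes$p1x[k], tubes$p1y[k], tubes$p1z[k]))), numeric(1))
    expect_lt(min(d), tubes$radius_um[1] + 0.5)
    # near-vertical principal axis
    expect_gt(abs(ao$principal_axis[2]), 0.95)
  }
})

test_that("off-target counts follow by subtraction from the totals", {
  s <- classification_summary(167, 66)
  expect_equal(s$n_off_target, 101)
  expect_equal(s$pct_off_target, 101 / 167)
  expect_error(classification_summary(10, 12), "exceed")
})

test_that("with no AIS objects every varicosity is off-target", {
  fx <- fixture_mid()
  cl <- classify_varicosities(fx$vari, list())
  expect_true(all(cl$label == "off_target"))
  s <- attr(cl, "summary")
  expect_equal(s$n_off_target, s$n_total)
  expect_equal(s$n_cartridges, 0L)
  expect_equal(nrow(group_cartridges(cl, list())), 0L)
})

test_that("apposition labels equal the manifest classes on noiseless data", {
  fx <- fixture_mid()
  truth <- fx$gen$manifest$varicosities
  det <- as.matrix(fx$classified[, c("x_um", "y_um", "z_um")])
  near <- apply(det, 1, function(p)
    which.min(colSums((t(as.matrix(truth[, c("x", "y", "z")])) - p)^2)))
  expect_equal(fx$classified$label, truth$class[near])
  # partition identity
  s <- attr(fx$classified, "summary")
  expect_equal(s$n_ais + s$n_off_target, s$n_total)
})

test_that("widening the apposition tolerance never loses AIS labels", {
  fx <- fixture_mid()
  n_ais <- vapply(c(0.2, 0.5, 1.0, 2.0), function(tol) {
    cl <- classify_varicosities(fx$vari, fx$ais, apposition_tol_um = tol)
    s <- attr(cl, "summary")
    expect_equal(s$n_ais + s$n_off_target, s$n_total)
    s$n_ais
  }, integer(1))
  expect_true(all(diff(n_ais) >= 0))
})

test_that("ties between two nearby AISs resolve to the nearer object", {
  # two parallel tubes; one varicosity slightly nearer the first
  voxel <- c(0.25, 0.25, 0.5)
  dims <- c(120, 80, 24)
  ts <- seq(0, 14, by = 0.25)
  a1 <- chcmorph:::stamp_core(array(0, dims), cbind(6, 4 + ts, 6), 1200,
                              1.05, 0.12, voxel)
  a2 <- chcmorph:::stamp_core(array(0, dims), cbind(13, 4 + ts, 6), 1200,
                              1.05, 0.12, voxel)
  stk <- volume_stack(list(axon = array(0, dims), ais = pmax(a1, a2) + 100),
                      voxel)
  ais <- segment_ais(stk)
  expect_length(ais, 2L)
  vari <- data.frame(id = 1L, x_um = 9.2, y_um = 10, z_um = 6,
                     diameter_xy_um = 2, diameter_z_um = 2.5,
                     peak_intensity = NA, shaft_intensity = NA,
                     brightness_ratio = 2.5, label = "unclassified")
  cl <- classify_varicosities(vari, ais, apposition_tol_um = 2)
  expect_equal(cl$label, "AIS")
  expect_equal(cl$ais_id, 1L)   # nearer tube (centre at x = 6)
})

test_that("cartridge grouping reproduces the pooled ratios", {
  expect_equal(round(pooled_cartridge_stats(1438, 292)$varicosities_per_ais,
                     1), 4.9)
  expect_equal(round(pooled_cartridge_stats(1407, 271)$varicosities_per_ais,
                     1), 5.2)
  expect_equal(round(pooled_cartridge_stats(1438, 292,
                                            n_cells = 10)$cartridges_per_cell),
               29)
  expect_equal(round(pooled_cartridge_stats(1407, 271,
                                            n_cells = 10)$cartridges_per_cell),
               27)
  # one AIS with three apposed varicosities: one cartridge, ratio 3
  cl <- data.frame(id = 1:3, label = "AIS", ais_id = 7L)
  cart <- group_cartridges(cl, list())
  expect_equal(nrow(cart), 1L)
  expect_equal(cart$n_varicosities, 3L)
  expect_equal(attr(cart, "varicosities_per_ais"), 3)
})

test_that("cartridges on generated data cover every hosting tube", {
  fx <- fixture_mid()
  cart <- group_cartridges(fx$classified, fx$ais)
  truth <- fx$gen$manifest$varicosities
  hosts <- table(truth$host_ais_id[truth$class == "AIS"])
  expect_equal(nrow(cart), length(hosts))
  expect_equal(sum(cart$n_varicosities), sum(truth$class == "AIS"))
})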