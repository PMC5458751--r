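test_that("the ROI is a soma-anchored square clipped to the stack", {
  arr <- array(0, dim = c(200, 200, 60))  # 1 um voxels
  stk <- volume_stack(list(axon = arr), c(1, 1, 1))
  roi <- select_roi(stk, soma_center = c(50, 10, 30))
  ext <- chcmorph:::stack_extent_um(roi)
  expect_equal(unname(ext["x", ]), c(0, 100))
  expect_equal(unname(ext["y", ]), c(10, 110))
  expect_equal(unname(ext["z", ]), c(0, 60))
  expect_false(attr(roi, "truncated"))
  # soma near the right edge: clipped with a warning and a flag
  expect_warning(roi2 <- select_roi(stk, soma_center = c(180, 10, 30)),
                 "clipped")
  expect_true(attr(roi2, "truncated"))
  # soma at the bottom edge: nothing below it
  expect_error(select_roi(stk, soma_center = c(100, 200, 30)), "empty")
  expect_error(select_roi(stk, soma_center = c(100, 300, 30)), "outside")
})

test_that("a straight tube is traced at its true length with no branches", {
  stk <- make_tube_stack(length_um = 80)
  skel <- trace_axon(stk, soma_center = NULL, soma_mask_radius_um = 0)
  am <- measure_arbor(skel)
  expect_equal(am$n_branch_points, 0L)
  expect_lt(abs(am$total_length_um - 80) / 80, 0.02)
  deg <- chcmorph:::skeleton_degrees(skel)
  expect_equal(sum(deg), 2L * nrow(skel$edges))  # degree-sum identity
})

test_that("tracing sub-volumes never yields more length than the union", {
  stk <- make_tube_stack(length_um = 80)
  full <- measure_arbor(trace_axon(stk, soma_center = NULL))$total_length_um
  d <- dim(stk$channels$axon)
  half <- floor(d[1] / 2)
  a <- volume_stack(list(axon = stk$channels$axon[1:half, , , drop = FALSE]),
                    stk$voxel_size)
  b <- volume_stack(list(axon = stk$channels$axon[(half + 1):d[1], , ,
                                                  drop = FALSE]),
                    stk$voxel_size)
  la <- measure_arbor(trace_axon(a, soma_center = NULL))$total_length_um
  lb <- measure_arbor(trace_axon(b, soma_center = NULL))$total_length_um
  expect_lte(la + lb, full + 2 * max(stk$voxel_size))
})

test_that("a Y-shaped tube has exactly one bifurcation", {
  # two tubes sharing a stem: stamp a second oblique arm onto a straight one
  stk <- make_tube_stack(length_um = 60, pad_um = 16)
  ax <- attr(stk, "axis_xz")
  arr <- stk$channels$axon
  v <- stk$voxel_size
  ts <- seq(0, 25, by = 0.1)  # oblique arm heading down-right
  pts <- cbind(ax[1] + ts * sin(pi / 5), 36 + ts * cos(pi / 5), ax[2])
  arr2 <- chcmorph:::stamp_gauss(array(0, dim(arr)), pts, 1000, 0.3, 0.4, v)
  stk2 <- volume_stack(list(axon = pmax(arr, arr2 + 100)), v)
  skel <- trace_axon(stk2, soma_center = NULL)
  expect_equal(measure_arbor(skel)$n_branch_points, 1L)
})

test_that("arbor metrics follow from the skeleton graph alone", {
  # three collinear nodes, 1 um apart
  path <- skeleton(rbind(c(0, 0, 0), c(0, 1, 0), c(0, 2, 0)),
                   data.frame(from = 1:2, to = 2:3))
  am <- measure_arbor(path)
  expect_equal(am$total_length_um, 2)
  expect_equal(am$n_branch_points, 0L)
  # perfect binary tree on a stem: 7 internal degree-3 nodes
  set.seed(1)
  nodes <- matrix(rnorm(16 * 3), ncol = 3)
  edges <- data.frame(from = c(16L, rep(1:7, each = 2)), to = c(1L, 2:15))
  tree <- skeleton(nodes, edges, soma_node = 16L)
  expect_equal(measure_arbor(tree)$n_branch_points, 7L)
  expect_equal(sum(chcmorph:::skeleton_degrees(tree)), 2L * 15L)
})

test_that("noiseless branch counts equal the generator ground truth", {
  for (seed in 1:3) {
    cfg <- cfg_sweep(seed)
    gen <- generate_stack(cfg)
    skel <- trace_axon(select_roi(gen$stack, roi_um = cfg$roi_um))
    expect_equal(measure_arbor(skel)$n_branch_points,
                 gen$manifest$n_branch_points)
  }
  fx <- fixture_mid()
  expect_equal(measure_arbor(fx$skel)$n_branch_points,
               fx$gen$manifest$n_branch_points)
})

test_that("branch counts stay within 5% of truth under imaging noise", {
  err <- vapply(1:10, function(seed) {
    cfg <- cfg_sweep(seed, noise_sd = 20)
    gen <- generate_stack(cfg)
    skel <- trace_axon(select_roi(gen$stack, roi_um = cfg$roi_um))
    abs(measure_arbor(skel)$n_branch_points -
          gen$manifest$n_branch_points) / gen$manifest$n_branch_points
  }, numeric(1))
  expect_lte(mean(err), 0.05)
})

test_that("spur pruning removes short terminal artefacts only", {
  # path of 10 nodes with a 0.4 um spur off node 5
  nodes <- rbind(cbind(0, seq(0, 9), 0), c(0.4, 4, 0))
  edges <- data.frame(from = c(1:9, 5), to = c(2:10, 11))
  skel <- skeleton(nodes, edges, soma_node = 1L)
  pruned <- prune_spurs(skel, min_um = 1.0)
  expect_equal(measure_arbor(pruned)$n_branch_points, 0L)
  expect_equal(nrow(pruned$nodes), 10L)
  # a 3 um spur survives
  nodes2 <- rbind(cbind(0, seq(0, 9), 0), c(3, 4, 0))
  skel2 <- skeleton(nodes2, edges, soma_node = 1L)
  expect_equal(measure_arbor(prune_spurs(skel2, 1.0))$n_branch_points, 1L)
})

test_that("SWC export and import round-trip the skeleton", {
  fx <- fixture_mid()
  f <- tempfile(fileext = ".swc")
  write_swc(fx$skel, f)
  back <- read_swc(f)
  expect_equal(nrow(back$nodes), nrow(fx$skel$nodes))
  expect_equal(measure_arbor(back)$n_branch_points,
               measure_arbor(fx$skel)$n_branch_points)
  expect_equal(measure_arbor(back)$total_length_um,
               measure_arbor(fx$skel)$total_length_um, tolerance = 1e-6)
  # type code 2 (axon) on every node
  swc <- utils::read.table(f)
  expect_true(all(swc[[2]] == 2L))
  unlink(f)
})

test_that("an empty threshold result is reported as an error", {
  stk <- volume_stack(list(axon = array(100, dim = c(20, 20, 8))),
                      c(0.5, 0.5, 0.5))
  expect_error(trace_axon(stk, soma_center = NULL, threshold = 500),
               "no axon")
})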