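test_that("membrane type counts follow largest-remainder apportionment", {
  expect_equal(
    peritraj:::largest_remainder(c(CDL = .14, PE = .30, PG = .46, PC = .10), 100),
    c(CDL = 14L, PE = 30L, PG = 46L, PC = 10L))
  expect_equal(peritraj:::largest_remainder(c(a = 1/3, b = 1/3, c = 1/3), 100),
               c(a = 34L, b = 33L, c = 33L))

  cfg <- generator_config(n_lipids_per_leaflet = 100, seed = 1)
  set.seed(1)
  mem <- generate_membrane(cfg)
  upper <- mem$lipids[mem$lipids$leaflet == "upper", ]
  expect_equal(table(upper$type)[c("CDL", "PE", "PG", "PC")],
               table(factor(c(rep("CDL", 14), rep("PE", 30), rep("PG", 46),
                              rep("PC", 10))))[c("CDL", "PE", "PG", "PC")],
               ignore_attr = TRUE)
})

test_that("a pure-PG membrane has one phosphate per lipid and no nitrogens", {
  cfg <- generator_config(composition = c(PG = 1), n_lipids_per_leaflet = 50,
                          seed = 4)
  set.seed(4)
  mem <- generate_membrane(cfg)
  expect_equal(sum(mem$atoms$name == "P1"), 100)  # both leaflets
  expect_equal(sum(mem$atoms$element == "N"), 0)
  expect_equal(sum(mem$atoms$name == "P2"), 0)
})

test_that("without enrichment the disc and outside have the same composition", {
  counts <- matrix(0, 2, 2, dimnames = list(c("in", "out"), c("CDL", "other")))
  for (s in 1:6) {
    cfg <- generator_config(n_lipids_per_leaflet = 150, cdl_enrichment = 1,
                            seed = s)
    set.seed(s)
    up <- generate_membrane(cfg)$lipids
    up <- up[up$leaflet == "upper", ]
    counts["in", ] <- counts["in", ] +
      c(sum(up$in_disc & up$type == "CDL"), sum(up$in_disc & up$type != "CDL"))
    counts["out", ] <- counts["out", ] +
      c(sum(!up$in_disc & up$type == "CDL"), sum(!up$in_disc & up$type != "CDL"))
  }
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("enrichment concentrates CDL inside the disc", {
  cfg <- generator_config(n_lipids_per_leaflet = 190, cdl_enrichment = 3,
                          seed = 8)
  set.seed(8)
  up <- generate_membrane(cfg)$lipids
  up <- up[up$leaflet == "upper", ]
  frac_in <- mean(up$type[up$in_disc] == "CDL")
  frac_out <- mean(up$type[!up$in_disc] == "CDL")
  expect_gt(frac_in, frac_out)
})

test_that("identical config and seed give bit-identical output, different seeds differ", {
  cfg <- generator_config(n_frames = 10, n_lipids_per_leaflet = 20, seed = 6)
  g1 <- generate_trajectory(cfg)
  g2 <- generate_trajectory(cfg)
  expect_identical(g1$trajectory$coords, g2$trajectory$coords)
  expect_identical(g1$truth$state, g2$truth$state)
  g3 <- generate_trajectory(cfg, replicate = 2)
  expect_false(identical(g1$trajectory$coords, g3$trajectory$coords))
  # replicate streams are disjoint across nearby base seeds
  cfg7 <- generator_config(n_frames = 10, n_lipids_per_leaflet = 20, seed = 7)
  s6 <- vapply(1:10, function(r) peritraj:::.replicate_seed(6, r), integer(1))
  s7 <- vapply(1:10, function(r) peritraj:::.replicate_seed(7, r), integer(1))
  expect_length(intersect(s6, s7), 0)
  expect_false(identical(generate_trajectory(cfg7)$trajectory$coords,
                         g1$trajectory$coords))
})

test_that("a zero unbinding rate makes the bound state absorbing", {
  cfg <- generator_config(n_frames = 300, n_lipids_per_leaflet = 12,
                          k_unbind = 0, initial_state = "BOUND",
                          descent = FALSE, seed = 9)
  g <- generate_trajectory(cfg)
  expect_true(all(g$truth$state == "BOUND"))
})

test_that("the realized depth and angles match the analysis modules exactly", {
  cfg <- generator_config(n_frames = 80, n_lipids_per_leaflet = 40,
                          descent = FALSE, seed = 13)
  g <- generate_trajectory(cfg)
  ds <- depth_series(g$trajectory)
  expect_equal(ds$depth, g$truth$depth, tolerance = 1e-9)
  os <- orientation_series(g$trajectory)
  expect_false(any(os$degenerate))
  expect_equal(os$phi_beta, unname(g$truth$angles[, "phi_beta"]),
               tolerance = 1e-6)
  expect_equal(os$phi_alpha, unname(g$truth$angles[, "phi_alpha"]),
               tolerance = 1e-6)
  expect_equal(os$phi_gamma, unname(g$truth$angles[, "phi_gamma"]),
               tolerance = 1e-6)
  com <- com_series(g$trajectory)
  truth_xy <- sweep(g$truth$com[, 1:2], 2, g$truth$com[1, 1:2])
  expect_equal(com[, 1:2], truth_xy, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the descent phase starts at the configured height and relaxes down", {
  cfg <- generator_config(n_frames = 400, n_lipids_per_leaflet = 12,
                          descent = TRUE, seed = 21)
  g <- generate_trajectory(cfg)
  ds <- depth_series(g$trajectory)
  start_above_mid <- unname(g$truth$com[1, "z"])
  expect_equal(start_above_mid, 40, tolerance = 3)   # noise about the mean
  expect_true(all(g$truth$state[1:50] == "HOVER"))   # still descending
  expect_lt(mean(ds$depth[300:400]), 10)             # arrived near the surface
})

test_that("emitted files round-trip through the loader with ground truth attached", {
  cfg <- generator_config(n_frames = 5, n_lipids_per_leaflet = 10,
                          n_replicates = 2, seed = 3, descent = FALSE)
  dir <- withr::local_tempdir()
  paths <- emit_synthetic(cfg, dir)
  expect_length(paths$trajectories, 2)
  expect_true(file.exists(paths$ground_truth))
  gt <- jsonlite::read_json(paths$ground_truth)
  expect_length(gt, 2)
  expect_equal(gt[[1]]$seed, peritraj:::.replicate_seed(3, 1))
  expect_false(gt[[1]]$seed == gt[[2]]$seed)
  expect_length(gt[[1]]$state, 5)
  traj <- load_trajectory(paths$trajectories[1],
                          selections = synthetic_selections(), dt = cfg$dt)
  ref <- generate_trajectory(cfg, replicate = 1)$trajectory
  expect_equal(traj$coords, ref$coords, tolerance = 1e-3)
  # single-frame emission loads but frame-dependent analyses fail cleanly
  cfg1 <- generator_config(n_frames = 1, n_lipids_per_leaflet = 10, seed = 3,
                           n_replicates = 1, descent = FALSE)
  p1 <- emit_synthetic(cfg1, dir)
  t1 <- load_trajectory(p1$trajectories[1], selections = synthetic_selections())
  expect_equal(t1$n_frames, 1)
  expect_error(depth_histogram(depth_series(t1)), "at least two")
})

test_that("generator rejects inconsistent configurations", {
  expect_error(generator_config(composition = c(CDL = 0.5, PG = 0.4)),
               "sum to 1")
  expect_error(generator_config(k_bind = -1), "rates")
  expect_error(generator_config(cdl_enrichment = 0.5), "enrichment")
  expect_error(generator_config(n_lipids_per_leaflet = 2), "at least 4")
})
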