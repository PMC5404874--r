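test_that("streamline bundles are reproducible and jitter-controlled", {
  spec <- list(start = c(4, 0, 28), end = c(7, 3, -28), bow_mm = 3,
               bundle_sd_mm = 1.5, n_points = 51)
  a <- generate_streamlines(5, spec, jitter_sd_mm = 0.3, seed = 10)
  b <- generate_streamlines(5, spec, jitter_sd_mm = 0.3, seed = 10)
  c <- generate_streamlines(5, spec, jitter_sd_mm = 0.3, seed = 11)
  expect_identical(lapply(a, `[[`, "points"), lapply(b, `[[`, "points"))
  expect_false(identical(a[[1]]$points, c[[1]]$points))
  expect_length(a, 5)

  # zero jitter: points lie exactly on a rigid offset of the centerline
  z <- generate_streamlines(2, spec, jitter_sd_mm = 0, seed = 1)
  d <- z[[1]]$points - z[[2]]$points
  expect_lt(max(abs(sweep(d, 2, colMeans(d)))), 1e-9)

  expect_error(generate_streamlines(2, list(start = c(0, 0, 0),
                                            end = c(0, 0, 0), bow_mm = 0,
                                            bundle_sd_mm = 1, n_points = 10)),
               "degenerate")
})

test_that("smoothing spline preserves lines and interpolates at zero smoothing", {
  tt <- seq(0, 20, by = 0.4)
  line <- streamline(cbind(1 + 0.3 * tt, 2 - 0.1 * tt, tt))
  sm <- fit_smoothing_spline(line, smoothing = 0.6, resample_step_mm = 0.5)
  dir <- c(0.3, -0.1, 1) / sqrt(sum(c(0.3, -0.1, 1)^2))
  rel <- sweep(sm$points, 2, c(1, 2, 0))
  off <- rel - (rel %*% dir) %*% t(dir)
  expect_lt(max(abs(off)), 1e-6)

  set.seed(2)
  wig <- streamline(cbind(sin(tt / 3), cos(tt / 3), tt) +
                      matrix(rnorm(3 * length(tt), 0, 0.2), ncol = 3))
  interp <- fit_smoothing_spline(wig, smoothing = 0, resample_step_mm = 0.05)
  # an interpolating spline passes through every input point (up to the
  # resampling discretization of the output polyline)
  for (i in seq(1, nrow(wig$points), by = 10)) {
    dmin <- min(sqrt(rowSums(sweep(interp$points, 2, wig$points[i, ])^2)))
    expect_lt(dmin, 0.03)
  }
  expect_error(fit_smoothing_spline(streamline(cbind(0:2, 0, 0))), "4 points")
})

test_that("smoothing reduces second-nodal-difference noise of sampled potentials", {
  set.seed(5)
  tt <- seq(0, 30, by = 0.25)
  helix <- cbind(2.5 + 0.8 * sin(tt / 5), 0.8 * cos(tt / 5), tt - 15)
  raw <- streamline(helix + matrix(rnorm(3 * length(tt), 0, 0.3), ncol = 3))
  sm <- fit_smoothing_spline(raw, resample_step_mm = 0.25)
  f <- test_field()
  geom <- fiber_geometry(5.7)
  node_v <- function(s) {
    pos <- seq(geom$node_length_um / 2000, arc_length(s),
               by = geom$internode_um / 1000)
    pts <- cbind(stats::approx(s$arc_mm, s$points[, 1], pos)$y,
                 stats::approx(s$arc_mm, s$points[, 2], pos)$y,
                 stats::approx(s$arc_mm, s$points[, 3], pos)$y)
    sample_potentials(f, pts)
  }
  d2 <- function(v) diff(v, differences = 2)
  expect_lt(mean(d2(node_v(sm))^2), mean(d2(node_v(raw))^2))
})

test_that("the default spline operator is idempotent within tolerance", {
  set.seed(6)
  jitter_sd <- 0.3
  tt <- seq(0, 40, by = 0.5)
  raw <- streamline(cbind(3 + tt * 0.05, sin(tt / 8), tt - 20) +
                      matrix(rnorm(3 * length(tt), 0, jitter_sd), ncol = 3))
  once <- fit_smoothing_spline(raw, resample_step_mm = 0.5)
  twice <- fit_smoothing_spline(once, resample_step_mm = 0.5)
  n <- min(nrow(once$points), nrow(twice$points))
  moved <- sqrt(rowSums((once$points[1:n, ] - twice$points[1:n, ])^2))
  # re-smoothing moves points by a few microns at most: the residual is
  # the arc-length feedback of the 0.5 mm polyline representation, well
  # below both the jitter being removed and the compartment scale
  expect_lt(max(moved), 0.03 * jitter_sd)
  # and the resampled output is uniform in its own (geometric) arc length
  steps <- sqrt(rowSums(diff(once$points)^2))
  expect_lt(max(abs(steps - 0.5)), 0.01)
})

test_that("fiber geometry reproduces the published table and stays consistent", {
  g <- fiber_geometry(5.7)
  expect_equal(g$internode_um, 500)
  expect_equal(g$node_diameter_um, 1.9)
  expect_equal(g$flut_diameter_um, 3.4)
  expect_equal(g$flut_length_um, 35)
  expect_equal(g$stin_length_um, (500 - 1 - 6 - 70) / 6)
  expect_equal(g$n_lamellae, 80)
  g10 <- fiber_geometry(10)
  expect_equal(g10$internode_um, 1150)
  expect_equal(g10$node_diameter_um, 3.3)
  # interpolation between published rows
  g8 <- fiber_geometry(8)
  expect_gt(g8$internode_um, 750); expect_lt(g8$internode_um, 1000)
  # sub-table diameters stay positive and consistent
  g18 <- fiber_geometry(1.8)
  expect_true(all(unlist(g18[grepl("_um$", names(g18))]) > 0))
  for (g_ in list(g, g10, g8, g18)) {
    expect_equal(g_$node_length_um + 2 * g_$mysa_length_um +
                   2 * g_$flut_length_um + 6 * g_$stin_length_um,
                 g_$internode_um, tolerance = 1e-9)
  }
})

test_that("compartment placement walks the arc length correctly", {
  L <- 10.0003
  s <- streamline(cbind(2, 0, seq(0, L, length.out = 200)))
  morph <- compartmentalize(axon_trajectory(s))
  df <- morph$compartments
  # 11-compartment repeat: node counts and per-internode pattern
  n_nodes <- sum(df$type == "node")
  expect_equal(nrow(df), (n_nodes - 1) * 11 + 1)
  expect_equal(df$type[1:12],
               c("node", "mysa", "flut", rep("stin", 6), "flut", "mysa", "node"))
  # node midpoints at multiples of the internodal length
  nodes <- df[df$type == "node", ]
  geom <- morph$main_geom
  expected <- (seq_len(n_nodes) - 1) * geom$internode_um / 1000 +
    geom$node_length_um / 2000
  expect_equal(nodes$z, expected, tolerance = 1e-3)
  # truncation: total length within one internode of the arc length
  tot <- sum(df$length_um) / 1000
  expect_lte(tot, arc_length(s))
  expect_lt(arc_length(s) - tot, geom$internode_um / 1000)
  # midpoints on the source curve
  expect_lt(max(abs(df$x - 2)), 1e-9)
  expect_error(compartmentalize(axon_trajectory(
    streamline(cbind(0, 0, c(0, 0.2))))), "shorter")
})

test_that("collateral construction respects anatomy and electrode clearance", {
  el <- electrode_spec()
  main <- streamline(cbind(3, 0, seq(-14, 14, by = 0.25)))
  geom <- fiber_geometry(5.7)

  # a mask whose axial extent contains exactly one node: the branch point
  # is forced, and the arc must end at a voxel center
  vox <- rbind(c(1.2, 1.2, 0), c(1.4, 1.0, 0.4))
  anat1 <- anatomy_context(vox, 0.5, el)
  traj <- build_collateral(main, geom, anat1)
  arc <- traj$collateral$points
  node_z <- seq(geom$node_length_um / 2000, arc_length(main),
                by = geom$internode_um / 1000) - 14
  forced <- which(node_z >= 0 & node_z <= 0.4)
  expect_length(forced, 1)
  expect_equal(traj$branch_node_index, forced)
  expect_equal(arc[1, ], c(3, 0, node_z[forced]), tolerance = 1e-6)
  d_end <- apply(vox, 1, function(v) sqrt(sum((arc[nrow(arc), ] - v)^2)))
  expect_lt(min(d_end), 1e-9)
  # clearance from the electrode axis
  expect_true(all(axis_distance(el, arc) >= el$shaft_radius_mm))

  # electrode sits between the branch region and all voxels but one:
  # the reachable voxel must always be selected
  blocked <- rbind(c(-2, 0, 0.4), c(-2, 0, -0.4), c(-2, 0.2, 0))
  open <- c(2.4, 0.6, 0)
  anat2 <- anatomy_context(rbind(blocked, open), 0.5, el)
  set.seed(8)
  for (k in 1:10) {
    tr <- build_collateral(main, geom, anat2, arc_bulge = 0)
    expect_equal(tr$collateral$points[nrow(tr$collateral$points), ], open,
                 tolerance = 1e-9)
  }

  # no eligible node: mask entirely outside the main path's axial range
  anat3 <- anatomy_context(cbind(1, 1, 40), 0.5, el)
  expect_error(build_collateral(main, geom, anat3), "no node of Ranvier")
})

test_that("collateral compartments follow the shortened-node rules", {
  el <- electrode_spec()
  main <- streamline(cbind(3, 0, seq(-14, 14, by = 0.25)))
  anat <- anatomy_context(rbind(c(1.2, 1.2, 0), c(1.4, 1.0, 0.4)), 0.5, el)
  traj <- build_collateral(main, fiber_geometry(5.7), anat)
  morph <- compartmentalize(traj)
  df <- morph$compartments
  coll <- df[df$section == "collateral", ]
  expect_equal(coll$length_um[1], 0.5)
  expect_equal(coll$type[1], "node")
  last <- coll[nrow(coll), ]
  expect_equal(last$type, "node")
  expect_false(last$active)
  expect_true(all(coll$active[coll$type == "node"][-sum(coll$type == "node")]))
  # branch parent is a node on the main path
  expect_equal(df$type[morph$branch_parent], "node")
  expect_equal(df$section[morph$branch_parent], "main")
})

test_that("population sampling is disjoint, exhaustive and reproducible", {
  sl <- as.list(seq_len(200))
  set.seed(20)
  pop1 <- sample_population(sl, 60, c(40, 20))
  set.seed(20)
  pop2 <- sample_population(sl, 60, c(40, 20))
  expect_identical(pop1, pop2)
  expect_length(pop1$fibers_of_passage, 40)
  expect_length(pop1$hyperdirect, 20)
  expect_length(intersect(pop1$fibers_of_passage, pop1$hyperdirect), 0)
  expect_false(anyDuplicated(unlist(pop1)) > 0)
  # full draw is a permutation
  set.seed(1)
  all_of <- sample_population(sl, 200, c(100, 100))
  expect_setequal(unlist(all_of), seq_len(200))
  expect_error(sample_population(sl, 300, c(150, 150)), "available")
  expect_error(sample_population(sl, 60, c(30, 20)), "sum")
})

test_that("streamlines round-trip through the text format", {
  sl <- generate_streamlines(3, jitter_sd_mm = 0.2, seed = 3)
  path <- withr::local_tempfile(fileext = ".txt")
  write_streamlines(sl, path)
  back <- read_streamlines(path)
  expect_length(back, 3)
  for (i in 1:3)
    expect_equal(back[[i]]$points, sl[[i]]$points, tolerance = 1e-12,
                 ignore_attr = TRUE)
})
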