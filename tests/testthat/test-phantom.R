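test_that("tree generation respects depth, forced ratios and determinism", {
  # depth 1: no bifurcation possible
  t1 <- generate_vessel_tree(tree_spec(root_radius = 10, max_depth = 1),
                             seed = 1)
  expect_equal(nrow(t1$segments), 1)
  expect_equal(nrow(t1$junctions), 0)

  # forced symmetric split: both daughters at 0.7 x parent
  t2 <- generate_vessel_tree(
    tree_spec(root_radius = 10, max_depth = 2, radius_ratio_mean = 0.7,
              radius_ratio_sd = 0, asymmetry = 0), seed = 1)
  expect_equal(nrow(t2$segments), 3)
  expect_equal(nrow(t2$junctions), 1)
  expect_equal(sort(t2$segments$radius_um), c(7, 7, 10))

  # identical seeds reproduce bit-identical trees; different seeds differ
  a <- generate_vessel_tree(tree_spec(max_depth = 5), seed = 42)
  b <- generate_vessel_tree(tree_spec(max_depth = 5), seed = 42)
  c <- generate_vessel_tree(tree_spec(max_depth = 5), seed = 43)
  expect_identical(a, b)
  expect_false(identical(a$segments, c$segments))

  # non-terminating spec rejected
  expect_error(tree_spec(radius_ratio_mean = 1.2), "terminate")
})

test_that("generated ratio statistics match the requested mean", {
  spec <- tree_spec(root_radius = 14, max_depth = 6,
                    radius_ratio_mean = 0.794, radius_ratio_sd = 0.05,
                    min_radius = 1)
  tree <- generate_vessel_tree(spec, seed = 1)
  # recompute the per-junction mean daughter/parent ratio from the segments
  j <- tree$junctions
  ratio <- (tree$segments$radius_um[j$child1] +
              tree$segments$radius_um[j$child2]) / 2 /
    tree$segments$radius_um[j$parent_seg]
  expect_gt(nrow(j), 10)
  expect_lt(abs(mean(ratio) - 0.794), 0.03)

  # structural invariants: children thinner than parents, tree connected
  expect_true(all(ratio < 1))
  expect_true(all(tree$segments$radius_um > 0))
  parents <- tree$segments$parent
  expect_equal(sum(is.na(parents)), 1)  # exactly one root
  expect_true(all(stats::na.omit(parents) >= 1))
})

test_that("voxelization renders tube cross-sections and guarantees axes", {
  seg <- data.frame(x0 = 0, y0 = 0, z0 = 0, x1 = 0, y1 = 0, z1 = 40,
                    radius_um = 5, parent = NA, depth = 1)
  ph <- suppressWarnings(voxelize_tree(seg, grid_spec(c(32, 32, 48), 1)))
  # interior slices: lumen area within 10% of pi r^2
  areas <- apply(ph$true_mask[, , 10:38], 3, sum)
  expect_true(all(abs(areas - pi * 25) / (pi * 25) < 0.1))
  # mu and mask consistent, mu >= 0
  expect_true(all(ph$mu[ph$true_mask] == 0))
  expect_true(all(ph$mu[!ph$true_mask] > 0))

  # empty tree: uniform tissue
  ph0 <- voxelize_tree(seg[0, ], grid_spec(c(16, 16, 16), 2))
  expect_false(any(ph0$true_mask))
  expect_equal(length(unique(as.vector(ph0$mu))), 1)

  # sub-voxel segment still marks its axis voxels
  seg2 <- data.frame(x0 = 0, y0 = 0, z0 = -10, x1 = 0, y1 = 0, z1 = 10,
                     radius_um = 0.4, parent = NA, depth = 1)
  ph2 <- suppressWarnings(voxelize_tree(seg2, grid_spec(c(16, 16, 24), 1)))
  expect_gte(sum(ph2$true_mask), 21)
  # coarse-grid warning fired
  expect_warning(voxelize_tree(seg2, grid_spec(c(16, 16, 24), 1)),
                 "voxel size exceeds")
})

test_that("simulated projections obey the contact-regime physics", {
  # uniform phantom at distance 0, no noise: constant frames at
  # exp(-mu * path) * photons + dark
  ph <- voxelize_tree(data.frame()[0, ], grid_spec(c(32, 32, 16), 2),
                      tissue_mu = 5e-4)
  geom <- acquisition_geometry(n_angles = 2, distance_mm = 0)
  ns <- noise_off(photons_per_pixel = 1000, dark_offset = 50,
                  vignette_strength = 0)
  raw <- simulate_projections(ph, geom, ns)
  # expected value from the independent ray-marching oracle (the analytic
  # exp(-mu * extent) differs only through the shared ray discretization)
  expected <- exp(-oracle_projection(ph$mu, 0, 2)[16, 8]) * 1000 + 50
  expect_equal(raw$frames[16, 8, 1], expected, tolerance = 1e-10)
  expect_equal(raw$frames[16, 8, 1], exp(-5e-4 * 31 * 2) * 1000 + 50,
               tolerance = 2e-3)
  # constant across the fully-covered interior columns
  expect_lt(diff(range(raw$frames[8:24, , 1])), 1e-9)
  expect_true(all(raw$flat > raw$dark))
})

test_that("zero-distance correction matches an independent ray-sum oracle", {
  spec <- tree_spec(root_radius = 6, max_depth = 3, min_radius = 1.5,
                    radius_ratio_sd = 0)
  tree <- generate_vessel_tree(spec, seed = 3)
  phan <- suppressWarnings(voxelize_tree(tree, grid_spec(c(32, 32, 32), 4)))
  geom <- acquisition_geometry(n_angles = 3, distance_mm = 0)
  raw <- simulate_projections(phan, geom,
                              noise_off(vignette_strength = 0.2,
                                        dark_offset = 40))
  corr <- correct_projection_set(raw)
  for (a in seq_len(geom$n_angles)) {
    expected <- exp(-oracle_projection(phan$mu, geom$angles_deg[a] * pi / 180,
                                       4))
    expect_lt(max(abs(corr$frames[, , a] - expected) / pmax(expected, 1e-12)),
              1e-6)
  }
})

test_that("edge fringes grow with propagation distance", {
  spec <- tree_spec(root_radius = 6, max_depth = 2, min_radius = 1.5,
                    radius_ratio_sd = 0)
  tree <- generate_vessel_tree(spec, seed = 3)
  phan <- suppressWarnings(voxelize_tree(tree, grid_spec(c(48, 48, 32), 2)))
  grad_at <- function(d) {
    g <- acquisition_geometry(n_angles = 1, distance_mm = d)
    r <- simulate_projections(phan, g, noise_off())
    f <- correct_projection_set(r)$frames[, , 1]
    max(abs(diff(f[, 16])))
  }
  g <- vapply(c(0, 100, 400, 700), grad_at, numeric(1))
  expect_true(all(diff(g) > 0))  # strictly growing edge contrast

  # distance beyond the detector's Fresnel limit rejected
  tiny <- suppressWarnings(voxelize_tree(tree, grid_spec(c(16, 16, 16), 0.05)))
  expect_error(simulate_projections(
    tiny, acquisition_geometry(n_angles = 1, distance_mm = 900), noise_off()),
    "too large")
})

test_that("projection noise model is seeded and reproducible", {
  ph <- voxelize_tree(data.frame()[0, ], grid_spec(c(16, 16, 16), 2))
  geom <- acquisition_geometry(n_angles = 3, distance_mm = 0)
  r1 <- simulate_projections(ph, geom, noise_spec(seed = 9))
  r2 <- simulate_projections(ph, geom, noise_spec(seed = 9))
  r3 <- simulate_projections(ph, geom, noise_spec(seed = 10))
  expect_identical(r1$frames, r2$frames)
  expect_identical(r1$dark, r2$dark)
  expect_false(identical(r1$frames, r3$frames))
  # Poisson noise present: frames vary pixel to pixel
  expect_gt(stats::sd(r1$frames[, , 1]), 0)
  expect_true(all(r1$flat > r1$dark))
})

test_that("ground-truth branch table implements the K definition", {
  toy <- structure(list(
    segments = data.frame(x0 = 0, y0 = 0, z0 = c(0, 10, 10),
                          x1 = 0, y1 = 0, z1 = c(10, 20, 20),
                          radius_um = c(10, 8, 6), parent = c(NA, 1, 1),
                          depth = c(1, 2, 2)),
    junctions = data.frame(x = 0, y = 0, z = 10, parent_seg = 1,
                           child1 = 2, child2 = 3)), class = "vessel_tree")
  tb <- true_branch_table(toy)
  expect_equal(tb$pre_radius_um, 10)
  expect_equal(tb$post_radius_um, 7)
  expect_equal(tb$K, 0.7)

  # symmetric fixed-ratio tree: every K equals the ratio
  tr <- generate_vessel_tree(
    tree_spec(root_radius = 10, max_depth = 4, radius_ratio_mean = 0.794,
              radius_ratio_sd = 0, asymmetry = 0, min_radius = 1), seed = 2)
  tb2 <- true_branch_table(tr)
  expect_true(all(abs(tb2$K - 0.794) < 1e-12))

  # no junctions: empty table
  t1 <- generate_vessel_tree(tree_spec(max_depth = 1), seed = 1)
  expect_equal(nrow(true_branch_table(t1)), 0)
})
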