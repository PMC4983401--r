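test_that("sinogram assembly is a lossless reindexing", {
  # 3 angles, frames 5 detector columns x 4 rows -> 4 sinograms of 3 x 5
  frames <- array(seq_len(5 * 4 * 3), c(5, 4, 3))
  corr <- structure(list(frames = frames, angles_deg = c(0, 60, 120),
                         pixel_size_um = 1, geometry = NULL),
                    class = "corrected_projection_set")
  sinos <- build_sinograms(corr)
  expect_length(sinos, 4)
  expect_equal(dim(sinos[[1]]$values), c(3, 5))
  # row theta of slice r equals frame theta's row r
  for (r in 1:4) for (a in 1:3)
    expect_equal(sinos[[r]]$values[a, ], frames[, r, a])
  # round trip: rebuilding frames from sinograms is bit-identical
  rebuilt <- array(0, dim(frames))
  for (r in 1:4) rebuilt[, r, ] <- t(sinos[[r]]$values)
  expect_identical(rebuilt, frames * 1)
  expect_error(build_sinograms(corr, slices = 9), "out of range")
})

test_that("FBP reconstructs an analytic disk phantom", {
  n <- 128; R <- 30; mu <- 0.01
  sino <- disk_sinogram(n, 180, R, mu)
  slice <- fbp_slice(sino, "ramlak", angles_deg = (0:179) * 1,
                     pixel_size_um = 1)
  s <- (seq_len(n) - (n + 1) / 2)
  rr <- sqrt(outer(s^2, s^2, "+"))
  inside <- rr < R - 3
  expect_lt(abs(mean(slice[inside]) - mu) / mu, 0.03)
  expect_lt(sqrt(mean((slice[inside] - mu)^2)) / mu, 0.05)
  # outside the disk the reconstruction returns to ~zero
  expect_lt(mean(abs(slice[rr > R + 5 & rr < n / 2 - 2])), 0.1 * mu)

  # zero sinogram -> zero slice; superposition of two disjoint disks
  expect_equal(fbp_slice(matrix(0, 180, n), "ramlak",
                         angles_deg = (0:179) * 1, pixel_size_um = 1),
               matrix(0, n, n))
  shift_row <- ifelse(abs(s - 40) < 12, 2 * mu * sqrt(pmax(144 - (s - 40)^2, 0)), 0)
  sino2 <- matrix(rep(shift_row, each = 180), 180, n)
  lhs <- fbp_slice(sino + sino2, "ramlak", angles_deg = (0:179) * 1,
                   pixel_size_um = 1)
  rhs <- fbp_slice(sino, "ramlak", angles_deg = (0:179) * 1, pixel_size_um = 1) +
    fbp_slice(sino2, "ramlak", angles_deg = (0:179) * 1, pixel_size_um = 1)
  expect_lt(max(abs(lhs - rhs)), 1e-10)

  # apodized windows remain close to the ramp answer inside the disk
  for (fl in c("shepp-logan", "hann")) {
    sl <- fbp_slice(sino, fl, angles_deg = (0:179) * 1, pixel_size_um = 1)
    expect_lt(abs(mean(sl[inside]) - mu) / mu, 0.05)
  }
  expect_error(fbp_slice(sino, "boxcar", angles_deg = (0:179) * 1,
                         pixel_size_um = 1), "unknown filter")
})

test_that("volume reconstruction recovers the attenuation map", {
  spec <- tree_spec(root_radius = 8, max_depth = 4, min_radius = 4,
                    radius_ratio_sd = 0.02, length_per_radius = 3.5)
  tree <- generate_vessel_tree(spec, seed = 7)
  phan <- voxelize_tree(tree, grid_spec(c(64, 64, 64), 2), tissue_mu = 1e-3)
  geom <- acquisition_geometry(n_angles = 180, distance_mm = 0)
  raw <- simulate_projections(phan, geom, noise_off())
  corr <- correct_projection_set(raw)
  vol <- reconstruct_volume(corr, "ramlak")
  # compare within the field-of-view cylinder
  s <- seq_len(64) - 32.5
  cyl <- sqrt(outer(s^2, s^2, "+")) < 26
  sel <- array(FALSE, c(64, 64, 64))
  for (k in 5:60) sel[, , k] <- cyl
  expect_gt(cor(vol$values[sel], phan$mu[sel]), 0.95)

  # slice subset equals those slices of the full run
  sub <- reconstruct_volume(corr, "ramlak", slices = 10:20)
  expect_equal(sub$values, vol$values[, , 10:20], tolerance = 1e-12)

  # shuffled acquisition order reconstructs identically after sorting
  ord <- sample(seq_along(corr$angles_deg))
  shuf <- corr
  shuf$frames <- corr$frames[, , ord]
  shuf$angles_deg <- corr$angles_deg[ord]
  expect_equal(reconstruct_volume(shuf, "ramlak", slices = 30)$values,
               reconstruct_volume(corr, "ramlak", slices = 30)$values)
})

test_that("reconstruction error shrinks as the number of angles grows", {
  seg <- data.frame(x0 = 0, y0 = 0, z0 = -20, x1 = 0, y1 = 0, z1 = 20,
                    radius_um = 8, parent = NA, depth = 1)
  phan <- suppressWarnings(  # the rod intentionally spans the grid
    voxelize_tree(seg, grid_spec(c(48, 48, 16), 2), tissue_mu = 1e-3))
  rmse_at <- function(nang) {
    geom <- acquisition_geometry(n_angles = nang, distance_mm = 0)
    raw <- simulate_projections(phan, geom, noise_off())
    vol <- reconstruct_volume(correct_projection_set(raw), "ramlak",
                              slices = 8)
    s <- seq_len(48) - 24.5
    cyl <- sqrt(outer(s^2, s^2, "+")) < 19
    sqrt(mean((vol$values[, , 1][cyl] - phan$mu[, , 8][cyl])^2))
  }
  expect_lt(rmse_at(360), rmse_at(45))
})
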