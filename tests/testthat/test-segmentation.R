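test_that("ridge strength is zero for structureless volumes", {
  expect_warning(e <- enhance_vessels(array(1, c(20, 20, 20)), scales_um = 2,
                                      voxel_size_um = 1), "constant")
  expect_true(all(e$strength == 0))
  expect_equal(nrow(detect_ridge_points(e, 0.5)), 0)
})

test_that("the scale response peaks at the matched tube radius", {
  v <- tube_volume(48, r = 5)
  resp <- vapply(c(2, 3, 5, 9), function(s) {
    e <- enhance_vessels(v, scales_um = s, voxel_size_um = 1)
    mean(e$strength[24, 24, ])  # mean strength along the true axis
  }, numeric(1))
  expect_equal(c(2, 3, 5, 9)[which.max(resp)], 5)
})

test_that("tubes outscore plates and blobs at matched contrast", {
  peak <- function(vv) max(enhance_vessels(vv, scales_um = 5,
                                           voxel_size_um = 1)$strength)
  r_tube <- peak(tube_volume(48, 5))
  r_plate <- peak(plate_volume(48, 5))
  r_blob <- peak(ball_volume(48, 5))
  expect_gt(r_tube / max(r_plate, 1e-12), 2)
  expect_gt(r_tube / max(r_blob, 1e-12), 2)
})

test_that("ridge candidates concentrate on the tube axis", {
  e <- enhance_vessels(tube_volume(48, 5), scales_um = c(3, 5, 8),
                       voxel_size_um = 1)
  cand <- detect_ridge_points(e, 0.5)
  expect_gt(nrow(cand), 10)
  d_axis <- sqrt((cand$i - 24.5)^2 + (cand$j - 24.5)^2)
  expect_gte(mean(d_axis <= 1.5), 0.9)

  # two parallel tubes 20 voxels apart give two distinct candidate clusters
  v2 <- array(1, c(64, 64, 32))
  for (k in 1:32) {
    xx <- matrix(seq_len(64), 64, 64)
    yy <- t(xx)
    v2[, , k][sqrt((xx - 22)^2 + (yy - 32)^2) <= 4] <- 0
    v2[, , k][sqrt((xx - 42)^2 + (yy - 32)^2) <= 4] <- 0
  }
  e2 <- enhance_vessels(v2, scales_um = 4, voxel_size_um = 1)
  c2 <- detect_ridge_points(e2, 0.5)
  expect_gt(sum(abs(c2$i - 22) <= 2), 5)
  expect_gt(sum(abs(c2$i - 42) <= 2), 5)
  expect_equal(sum(c2$i > 26 & c2$i < 38), 0)
})

test_that("asymmetric Gaussian fits recover known profiles", {
  x <- seq(-10, 10, by = 1)
  # symmetric, noise-free: near-exact recovery
  f <- fit_asymmetric_gaussian(2 * exp(-x^2 / 18), x)
  expect_equal(f$A, 2, tolerance = 1e-4)
  expect_equal(f$b, 0, tolerance = 1e-4)
  expect_equal(f$c, 0, tolerance = 1e-4)
  expect_equal(f$sigma_left, 3, tolerance = 1e-4)
  expect_equal(f$sigma_right, 3, tolerance = 1e-4)
  expect_lt(f$rmse, 1e-6)

  # asymmetric widths recovered within 5%, order preserved
  y <- ifelse(x < 1, 3 + 1.5 * exp(-(x - 1)^2 / (2 * 4)),
              3 + 1.5 * exp(-(x - 1)^2 / (2 * 25)))
  f2 <- fit_asymmetric_gaussian(y, x)
  expect_lt(f2$sigma_left, f2$sigma_right)
  expect_lt(abs(f2$sigma_left - 2) / 2, 0.05)
  expect_lt(abs(f2$sigma_right - 5) / 5, 0.05)

  # flat profile: vanishing amplitude, clean residual
  f3 <- fit_asymmetric_gaussian(rep(4, 11), seq(-5, 5))
  expect_lt(abs(f3$A), 1e-6)
  expect_lt(f3$rmse, 1e-9)

  expect_error(fit_asymmetric_gaussian(1:6), "at least 7")
})

test_that("amplitude clustering finds the equal-posterior threshold", {
  set.seed(1)
  a <- c(rnorm(500, 1, 0.1), rnorm(500, 5, 0.3))
  thr <- cluster_ridges(data.frame(A = a))
  expect_equal(attr(thr, "method"), "gmm")
  mu <- attr(thr, "means"); sd <- attr(thr, "sds"); w <- attr(thr, "weights")
  lo <- which.min(mu); hi <- which.max(mu)
  # independent recomputation of the equal-posterior point from the fitted
  # mixture components
  f <- function(x) w[lo] * dnorm(x, mu[lo], sd[lo]) -
    w[hi] * dnorm(x, mu[hi], sd[hi])
  expect_equal(as.numeric(thr), uniroot(f, c(mu[lo], mu[hi]))$root,
               tolerance = 1e-8)
  expect_gt(as.numeric(thr), mu[lo])
  expect_lt(as.numeric(thr), mu[hi])

  # identical amplitudes degenerate to the fallback
  thr2 <- cluster_ridges(data.frame(A = rep(2, 50)))
  expect_equal(attr(thr2, "method"), "otsu")
  expect_error(cluster_ridges(data.frame(A = 1:5)), "fewer than 10")
})

test_that("a clean tube is segmented with high overlap", {
  v <- tube_volume(48, 5)
  m <- segment_vasculature(v, scales_um = c(3, 5, 8), voxel_size_um = 1)
  expect_gt(dice_coef(m$values, v == 0), 0.8)
})

test_that("pure-noise volumes yield an almost empty mask", {
  set.seed(8)
  v <- array(rnorm(48^3), c(48, 48, 48))
  m <- suppressWarnings(segment_vasculature(v, scales_um = c(2, 4),
                                            voxel_size_um = 1))
  expect_lt(mean(m$values), 0.001)
})

test_that("the mask is invariant to intensity shift and positive scaling", {
  v <- tube_volume(32, 4)
  m0 <- segment_vasculature(v, scales_um = c(3, 5), voxel_size_um = 1)
  m_shift <- segment_vasculature(v + 11, scales_um = c(3, 5), voxel_size_um = 1)
  m_scale <- segment_vasculature(v * 7.3, scales_um = c(3, 5), voxel_size_um = 1)
  expect_identical(m0$values, m_shift$values)
  expect_identical(m0$values, m_scale$values)
})

test_that("component cleanup only removes small components, monotonically", {
  v <- tube_volume(40, 4)
  # add a tiny decoy blob far from the tube
  v[3:4, 3:4, 3:4] <- 0
  m0 <- segment_vasculature(v, scales_um = c(3, 5), voxel_size_um = 1,
                            min_component_voxels = 0)
  m50 <- segment_vasculature(v, scales_um = c(3, 5), voxel_size_um = 1,
                             min_component_voxels = 50)
  # raising the floor never adds voxels
  expect_true(all(m50$values <= m0$values))
  removed <- m0$values & !m50$values
  if (any(removed)) {
    lab <- pctomo:::cpp_label3d(m0$values, dim(m0$values))
    sizes <- tabulate(lab[lab > 0])
    # every removed voxel belonged to a sub-threshold component
    expect_true(all(sizes[unique(lab[removed])] < 50))
  }
})
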