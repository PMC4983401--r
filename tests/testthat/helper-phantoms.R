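# shared fixture builders; everything is generated in code at test time

# solid tube of radius r along z in an n^3 volume: value 0 inside (air),
# 1 outside (tissue-like), mimicking the polarity of a reconstruction
tube_volume <- function(n = 48, r = 5) {
  v <- array(1, c(n, n, n))
  c0 <- (n + 1) / 2
  xx <- matrix(seq_len(n) - c0, n, n)
  m <- sqrt(xx^2 + t(xx)^2) <= r
  for (k in seq_len(n)) v[, , k][m] <- 0
  v
}

tube_mask <- function(n = 48, r = 5) tube_volume(n, r) == 0

# slab (plate) and ball fixtures with matched contrast
plate_volume <- function(n = 48, half = 5) {
  v <- array(1, c(n, n, n))
  mid <- round(n / 2)
  v[, (mid - half):(mid + half), ] <- 0
  v
}

ball_volume <- function(n = 48, r = 5) {
  v <- array(1, c(n, n, n))
  c0 <- (n + 1) / 2
  for (k in seq_len(n)) {
    xx <- matrix(seq_len(n) - c0, n, n)
    m <- sqrt(xx^2 + t(xx)^2 + (k - c0)^2) <= r
    v[, , k][m] <- 0
  }
  v
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# independent line-integral oracle: R-level ray marching with approx-style
# bilinear interpolation, same parametrization as the projector contract
# (step in voxel units, rays in the x-y plane, detector column = x index)
oracle_projection <- function(vol, theta, voxel_um, t_step = 0.5) {
  nx <- dim(vol)[1]; ny <- dim(vol)[2]; nz <- dim(vol)[3]
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  hd <- sqrt(nx^2 + ny^2) / 2
  nt <- ceiling(2 * hd / t_step) + 1
  ts <- -hd + (seq_len(nt) - 1) * t_step
  out <- matrix(0, nx, nz)
  for (s in 0:(nx - 1)) {
    x <- cx + (s - cx) * cos(theta) - ts * sin(theta)
    y <- cy + (s - cx) * sin(theta) + ts * cos(theta)
    ok <- x >= 0 & x <= nx - 1 & y >= 0 & y <= ny - 1
    if (!any(ok)) next
    x <- x[ok]; y <- y[ok]
    x0 <- floor(x); y0 <- floor(y)
    x1 <- pmin(x0 + 1, nx - 1); y1 <- pmin(y0 + 1, ny - 1)
    fx <- x - x0; fy <- y - y0
    for (k in seq_len(nz)) {
      sl <- vol[, , k]
      v <- (1 - fx) * (1 - fy) * sl[cbind(x0 + 1, y0 + 1)] +
        fx * (1 - fy) * sl[cbind(x1 + 1, y0 + 1)] +
        (1 - fx) * fy * sl[cbind(x0 + 1, y1 + 1)] +
        fx * fy * sl[cbind(x1 + 1, y1 + 1)]
      out[s + 1, k] <- sum(v) * t_step
    }
  }
  out * voxel_um
}

# analytic parallel-beam sinogram of a centred disk (radius R, value mu)
disk_sinogram <- function(n_det, n_angles, R, mu, pixel = 1) {
  s <- (seq_len(n_det) - (n_det + 1) / 2) * pixel
  prow <- ifelse(abs(s) < R, 2 * mu * sqrt(pmax(R^2 - s^2, 0)), 0)
  matrix(rep(prow, each = n_angles), n_angles, n_det)
}

# hand-built vessel_graph for branch-record unit tests: one junction with
# incident branch radii `radii`
toy_junction_graph <- function(radii) {
  n <- length(radii)
  nodes <- data.frame(id = seq_len(n + 1),
                      x_um = c(0, seq_len(n)), y_um = 0, z_um = 0,
                      type = c("junction", rep("endpoint", n)),
                      radius_um = c(max(radii), radii),
                      degree = c(n, rep(1L, n)))
  edges <- data.frame(id = seq_len(n), from = 1L, to = seq_len(n) + 1L,
                      n_voxels = 10L, radius_um = radii)
  structure(list(nodes = nodes, edges = edges, paths = vector("list", n),
                 voxel_size_um = 1),
            class = "vessel_graph")
}

# study conditions for the fine-voxel bifurcation phantoms used in the
# radius-ratio recovery and cohort studies (sub-7.4 um junction radii)
cohort_tree_spec <- function(K_true) {
  tree_spec(root_radius = 6, max_depth = 4, min_radius = 2.4,
            radius_ratio_mean = K_true, radius_ratio_sd = 0,
            asymmetry = 0.1, length_per_radius = 4, branch_angle_deg = 38)
}

# full simulate -> correct -> reconstruct -> segment -> measure chain under
# the fine-voxel conditions; returns the binned branch table and diagnostics
measure_phantom <- function(seed, K_true = 0.794, photons = NULL,
                            n = 112, voxel = 0.9, n_angles = 120) {
  tree <- generate_vessel_tree(cohort_tree_spec(K_true), seed = seed)
  phan <- voxelize_tree(tree, grid_spec(c(n, n, n), voxel), tissue_mu = 1e-3)
  geom <- acquisition_geometry(n_angles = n_angles, distance_mm = 0)
  noise <- if (is.null(photons)) noise_off(seed = seed)
  else noise_spec(photons_per_pixel = photons, seed = seed)
  raw <- simulate_projections(phan, geom, noise)
  vol <- suppressWarnings(reconstruct_volume(correct_projection_set(raw),
                                             "ramlak"))
  mk <- suppressWarnings(segment_vasculature(
    vol, scales_um = voxel * c(2, 3, 5, 7), voxel_size_um = voxel))
  g <- build_vessel_graph(skeletonize_mask(mk))
  rec <- branch_records(g)
  list(tree = tree, truth = true_branch_table(tree), records = rec,
       binned = filter_and_bin(rec),
       dice = dice_coef(mk$values, phan$true_mask),
       n_junctions = sum(g$nodes$type == "junction"))
}
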