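test_that("skeletons of simple shapes are thin, centred and contained", {
  # straight tube: a single 26-connected path with the right radius
  tm <- tube_mask(48, 4)
  sk <- skeletonize_mask(tm, voxel_size_um = 1)
  expect_gt(sum(sk$skeleton), 20)
  lab <- pctomo:::cpp_label3d(sk$skeleton, dim(sk$skeleton))
  expect_equal(max(lab), 1)  # one component
  rads <- sk$radius_um[sk$skeleton]
  expect_lt(abs(median(rads) - 4), 1)  # within one voxel of the true radius
  w <- which(sk$skeleton, arr.ind = TRUE)
  expect_true(all(abs(w[, 1] - 24.5) < 1.6 & abs(w[, 2] - 24.5) < 1.6))

  # solid ball: skeleton non-empty and contained
  bm <- ball_volume(21, 7) == 0
  skb <- skeletonize_mask(bm, voxel_size_um = 1)
  expect_gt(sum(skb$skeleton), 0)
  expect_true(all(bm[skb$skeleton]))

  # empty mask: empty skeleton
  sk0 <- skeletonize_mask(array(FALSE, c(8, 8, 8)), voxel_size_um = 1)
  expect_false(any(sk0$skeleton))
  g0 <- build_vessel_graph(sk0)
  expect_equal(nrow(g0$nodes), 0)
  expect_equal(nrow(g0$edges), 0)
})

test_that("vessel graphs identify junctions, endpoints and branches", {
  # hand-built Y: three straight arms meeting at one voxel
  sk <- array(FALSE, c(32, 32, 32))
  sk[16, 16, 4:16] <- TRUE
  for (d in 1:10) {
    sk[16 + d, 16, 16 + d] <- TRUE
    sk[16 - d, 16, 16 + d] <- TRUE
  }
  skel <- structure(list(skeleton = sk,
                         radius_um = array(2, c(32, 32, 32)),
                         voxel_size_um = 1), class = "vessel_skeleton")
  g <- build_vessel_graph(skel, prune_spur_len_vox = 0)
  expect_equal(sum(g$nodes$type == "junction"), 1)
  expect_equal(nrow(g$edges), 3)
  expect_equal(sum(g$nodes$type == "endpoint"), 3)

  # straight path: no junctions, one branch, two endpoints
  sk2 <- array(FALSE, c(16, 16, 16))
  sk2[8, 8, 3:13] <- TRUE
  skel2 <- structure(list(skeleton = sk2,
                          radius_um = array(1.5, c(16, 16, 16)),
                          voxel_size_um = 1), class = "vessel_skeleton")
  g2 <- build_vessel_graph(skel2)
  expect_equal(sum(g2$nodes$type == "junction"), 0)
  expect_equal(nrow(g2$edges), 1)
  expect_equal(sum(g2$nodes$type == "endpoint"), 2)
})

test_that("junction count is recovered exactly from a clean voxelized tree", {
  # full binary tree with 3 levels of bifurcation: exactly 7 junctions
  spec <- tree_spec(root_radius = 10, max_depth = 4, min_radius = 3,
                    radius_ratio_mean = 0.75, radius_ratio_sd = 0,
                    asymmetry = 0, length_per_radius = 4.5,
                    branch_angle_deg = 40)
  tree <- generate_vessel_tree(spec, seed = 5)
  expect_equal(nrow(tree$junctions), 7)
  phan <- voxelize_tree(tree, grid_spec(c(128, 128, 128), 1.6))
  sk <- skeletonize_mask(phan$true_mask, voxel_size_um = 1.6)
  g <- build_vessel_graph(sk)
  rec <- branch_records(g)
  expect_equal(nrow(rec), 7)
  expect_equal(sum(g$nodes$type == "junction"), 7)
  # conservation: one record per junction node
  expect_equal(nrow(rec), sum(g$nodes$type == "junction"))
  # measured radii within a voxel of truth for >= 2-voxel vessels
  tb <- true_branch_table(tree)
  expect_lt(abs(median(rec$pre_radius_um) - median(tb$pre_radius_um)), 1.6)
  # K close to the generating ratio
  expect_lt(abs(mean(rec$K) - 0.75), 0.08)
})

test_that("branch records implement the largest-radius parent rule", {
  rec <- branch_records(toy_junction_graph(c(10, 8, 6)))
  expect_equal(rec$pre_radius_um, 10)
  expect_equal(rec$post_radius_um, 7)
  expect_equal(rec$K, 0.7)
  expect_false(rec$tie_flag)

  rec2 <- branch_records(toy_junction_graph(c(5, 4, 4)))
  expect_equal(rec2$K, 0.8)

  # all-equal radii: deterministic tie-break, flagged
  rec3 <- branch_records(toy_junction_graph(c(4, 4, 4)))
  expect_true(rec3$tie_flag)
  expect_equal(rec3$K, 1)

  # scale equivariance: radii in nm instead of um leave K unchanged
  g <- toy_junction_graph(c(10, 8, 6))
  g$edges$radius_um <- g$edges$radius_um * 1000
  g$nodes$radius_um <- g$nodes$radius_um * 1000
  expect_equal(branch_records(g)$K, 0.7)
})

test_that("radius filtering and binning follow the microvascular band", {
  rec <- data.frame(junction_id = 1:3, x_um = 0, y_um = 0, z_um = 0,
                    pre_radius_um = c(5, 10, 25),
                    post_radius_um = c(4, 8, 20),
                    K = c(0.8, 0.8, 0.8), n_daughters = 2, tie_flag = FALSE)
  fb <- filter_and_bin(rec)
  expect_equal(nrow(fb), 2)                       # 25 um dropped
  expect_equal(as.character(fb$bin), c("[0,7.4)", "[7.4,20)"))

  # boundary case: exactly 7.4 um goes to the upper bin
  rec74 <- rec[1, ]; rec74$pre_radius_um <- 7.4
  expect_equal(as.character(filter_and_bin(rec74)$bin), "[7.4,20)")

  # everything at or above 20 um: both bins empty
  big <- rec; big$pre_radius_um <- c(20, 30, 40)
  expect_equal(nrow(filter_and_bin(big)), 0)
})

test_that("group comparison behaves like a two-sample t-test on animals", {
  mk_animal <- function(k_small, k_large) {
    data.frame(K = c(k_small, k_large),
               bin = factor(c("[0,7.4)", "[7.4,20)"),
                            levels = c("[0,7.4)", "[7.4,20)")))
  }
  ga <- lapply(c(0.80, 0.79, 0.81), function(k) mk_animal(k, 0.8))
  # identical groups: t = 0, p = 1
  cmp <- group_compare(ga, ga)
  expect_equal(cmp$t_statistic, c(0, 0))
  expect_equal(cmp$p_value, c(1, 1))

  gb <- lapply(c(0.70, 0.69, 0.71), function(k) mk_animal(k, 0.8))
  c1 <- group_compare(ga, gb)
  c2 <- group_compare(gb, ga)
  expect_equal(c1$t_statistic, -c2$t_statistic)   # label swap negates t
  expect_equal(c1$p_value, c2$p_value)
  expect_lt(c1$p_value[1], 0.05)
  # matches stats::t.test run directly on the per-animal means
  tt <- t.test(c(0.80, 0.79, 0.81), c(0.70, 0.69, 0.71), var.equal = TRUE)
  expect_equal(c1$t_statistic[1], unname(tt$statistic))
  expect_equal(c1$p_value[1], tt$p.value)
})

test_that("the per-animal t-test has power at the published design size", {
  # groups of 7 animals at K ~ N(0.79, 0.01) vs N(0.70, 0.01):
  # significance in at least 95% of simulated replicates
  set.seed(31)
  hits <- 0
  for (rep in 1:200) {
    ka <- rnorm(7, 0.79, 0.01)
    kb <- rnorm(7, 0.70, 0.01)
    if (t.test(ka, kb, var.equal = TRUE)$p.value < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.95)
})
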