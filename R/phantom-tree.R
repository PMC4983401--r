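#' Specification of a synthetic bifurcating vessel tree
#'
#' Describes the ground-truth vascular phantom used to exercise the whole
#' imaging and morphometry chain. Trees are binary (every junction is a
#' bifurcation). At each junction the two daughter radii average to
#' `ratio * parent_radius`, where the per-junction ratio is drawn from
#' `Normal(radius_ratio_mean, radius_ratio_sd)` and clipped to (0.3, 0.95);
#' the `asymmetry` parameter splits the two daughters as
#' `mean_daughter * (1 +/- asymmetry)`. Growth stops when a daughter radius
#' would fall below `min_radius` or the depth reaches `max_depth`.
#'
#' The default `radius_ratio_mean` of 0.794 is the symmetric Murray's-law
#' value 2^(-1/3), the classical expectation for healthy arterial
#' bifurcations; angiogenic (newly sprouting) microvasculature is emulated by
#' lowering it.
#'
#' @param root_radius radius of the root segment, micrometres.
#' @param radius_ratio_mean target mean daughter/parent radius ratio K per
#'   bifurcation (dimensionless, in (0, 1)).
#' @param radius_ratio_sd standard deviation of the per-junction ratio.
#' @param asymmetry daughter radius imbalance in `[0, 1)`.
#' @param min_radius stop criterion, micrometres.
#' @param length_per_radius segment length as a multiple of its radius.
#' @param branch_angle_deg half-angle between the daughters and the parent
#'   direction, degrees.
#' @param max_depth maximum bifurcation depth (1 = a single unbranched root).
#' @return an object of class `tree_spec`.
#' @examples
#' spec <- tree_spec(root_radius = 10, max_depth = 4)
#' tree <- generate_vessel_tree(spec, seed = 1)
#' @export
tree_spec <- function(root_radius = 12,
                      radius_ratio_mean = 0.794,
                      radius_ratio_sd = 0.05,
                      asymmetry = 0.1,
                      min_radius = 2,
                      length_per_radius = 6,
                      branch_angle_deg = 35,
                      max_depth = 6) {
  stopifnot(root_radius > 0, min_radius > 0, root_radius > min_radius)
  if (radius_ratio_mean >= 1)
    stop("radius_ratio_mean must be < 1 or the tree would not terminate")
  stopifnot(radius_ratio_mean > 0, radius_ratio_sd >= 0,
            asymmetry >= 0, asymmetry < 1,
            length_per_radius > 0, max_depth >= 1)
  structure(list(root_radius = root_radius,
                 radius_ratio_mean = radius_ratio_mean,
                 radius_ratio_sd = radius_ratio_sd,
                 asymmetry = asymmetry,
                 min_radius = min_radius,
                 length_per_radius = length_per_radius,
                 branch_angle_deg = branch_angle_deg,
                 max_depth = max_depth),
            class = "tree_spec")
}

# orthonormal basis completing unit vector d
.basis_perp <- function(d) {
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * d) * d
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  list(u = u, v = v)
}

#' Generate a ground-truth bifurcating vessel tree
#'
#' Grows a binary tree of straight cylindrical segments from a single root.
#' Deterministic given `seed`.
#'
#' @param spec a [tree_spec()].
#' @param seed integer RNG seed.
#' @return an object of class `vessel_tree`: a list with `segments`
#'   (data frame: start/end coordinates in micrometres, `radius_um`, `parent`
#'   segment index, `depth`) and `junctions` (data frame: position,
#'   `parent_seg` and the two child segment indices).
#' @export
generate_vessel_tree <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "tree_spec"))
  with_seed(seed, {
    seg <- list()   # each: c(start, end, radius, parent, depth) + direction
    jun <- list()
    root_dir <- c(0, 0, 1)
    len0 <- spec$length_per_radius * spec$root_radius
    seg[[1]] <- list(start = c(0, 0, 0), end = root_dir * len0,
                     radius = spec$root_radius, parent = NA_integer_,
                     depth = 1L, dir = root_dir)
    queue <- 1L
    while (length(queue) > 0) {
      i <- queue[1]
      queue <- queue[-1]
      s <- seg[[i]]
      if (s$depth >= spec$max_depth) next
      ratio <- rnorm(1, spec$radius_ratio_mean, spec$radius_ratio_sd)
      # keep daughters strictly thinner than the parent even when asymmetric
      hi <- min(0.95, 0.99 / (1 + spec$asymmetry))
      ratio <- min(max(ratio, 0.3), hi)
      r_mean <- ratio * s$radius
      r1 <- r_mean * (1 + spec$asymmetry)
      r2 <- r_mean * (1 - spec$asymmetry)
      if (min(r1, r2) < spec$min_radius) next
      b <- .basis_perp(s$dir)
      phi <- runif(1, 0, 2 * pi)
      ang <- spec$branch_angle_deg * pi / 180
      mk_dir <- function(theta, azim) {
        d <- cos(theta) * s$dir +
          sin(theta) * (cos(azim) * b$u + sin(azim) * b$v)
        d / sqrt(sum(d^2))
      }
      d1 <- mk_dir(ang, phi)
      d2 <- mk_dir(ang, phi + pi)
      ids <- integer(2)
      for (ci in 1:2) {
        r <- if (ci == 1) r1 else r2
        d <- if (ci == 1) d1 else d2
        child <- list(start = s$end, end = s$end + d * spec$length_per_radius * r,
                      radius = r, parent = i, depth = s$depth + 1L, dir = d)
        seg[[length(seg) + 1L]] <- child
        ids[ci] <- length(seg)
        queue <- c(queue, length(seg))
      }
      jun[[length(jun) + 1L]] <- list(pos = s$end, parent_seg = i,
                                      child1 = ids[1], child2 = ids[2])
    }
    segments <- do.call(rbind, lapply(seq_along(seg), function(i) {
      s <- seg[[i]]
      data.frame(x0 = s$start[1], y0 = s$start[2], z0 = s$start[3],
                 x1 = s$end[1], y1 = s$end[2], z1 = s$end[3],
                 radius_um = s$radius, parent = s$parent, depth = s$depth)
    }))
    junctions <- if (length(jun) == 0) {
      data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                 parent_seg = integer(0), child1 = integer(0),
                 child2 = integer(0))
    } else {
      do.call(rbind, lapply(jun, function(j) {
        data.frame(x = j$pos[1], y = j$pos[2], z = j$pos[3],
                   parent_seg = j$parent_seg, child1 = j$child1,
                   child2 = j$child2)
      }))
    }
    structure(list(segments = segments, junctions = junctions, spec = spec,
                   seed = seed),
              class = "vessel_tree")
  })
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat("vessel_tree:", nrow(x$segments), "segments,",
      nrow(x$junctions), "junctions\n")
  cat("  radii [um]:", signif(min(x$segments$radius_um), 3), "-",
      signif(max(x$segments$radius_um), 3), "\n")
  invisible(x)
}

#' Ground-truth branch table of a vessel tree
#'
#' One row per junction with the pre-branching (parent) radius, the
#' post-branching radius (arithmetic mean of the daughter radii), and their
#' ratio `K = post / pre`. This is the ground-truth twin of the table
#' measured from a segmented volume by [branch_records()].
#'
#' @param tree a [generate_vessel_tree()] result.
#' @return data frame with columns `junction_id`, `pre_radius_um`,
#'   `daughter1_radius_um`, `daughter2_radius_um`, `post_radius_um`, `K`.
#' @export
true_branch_table <- function(tree) {
  stopifnot(inherits(tree, "vessel_tree"))
  j <- tree$junctions
  if (nrow(j) == 0) {
    return(data.frame(junction_id = integer(0), pre_radius_um = numeric(0),
                      daughter1_radius_um = numeric(0),
                      daughter2_radius_um = numeric(0),
                      post_radius_um = numeric(0), K = numeric(0)))
  }
  pre <- tree$segments$radius_um[j$parent_seg]
  d1 <- tree$segments$radius_um[j$child1]
  d2 <- tree$segments$radius_um[j$child2]
  post <- (d1 + d2) / 2
  data.frame(junction_id = seq_len(nrow(j)), pre_radius_um = pre,
             daughter1_radius_um = d1, daughter2_radius_um = d2,
             post_radius_um = post, K = post / pre)
}
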