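#' Skeletonize a vessel mask
#'
#' Medial-axis thinning of the binary mask by sequential deletion of simple
#' (topology-preserving) border voxels in six directional subiterations,
#' keeping curve endpoints. The local vessel radius at each skeleton voxel
#' is derived from the Euclidean distance transform of the mask: the
#' distance to the nearest background voxel centre overshoots the physical
#' surface by about half a voxel, so half a voxel is subtracted before
#' scaling (disable with `surface_offset_vox = 0`).
#'
#' @param mask a [segment_vasculature()] result or a logical 3D array.
#' @param voxel_size_um needed for plain arrays.
#' @param surface_offset_vox half-voxel surface correction subtracted from
#'   the distance-transform values (floored at half a voxel).
#' @return object of class `vessel_skeleton`: `skeleton` (logical 3D array),
#'   `radius_um` (numeric 3D array, radius at every mask voxel),
#'   `voxel_size_um`.
#' @export
skeletonize_mask <- function(mask, voxel_size_um = NULL,
                             surface_offset_vox = 0.5) {
  if (inherits(mask, "vessel_mask")) {
    values <- mask$values
    voxel_size_um <- voxel_size_um %||% mask$voxel_size_um
  } else {
    values <- mask
    if (is.null(voxel_size_um)) stop("voxel_size_um required for plain arrays")
  }
  stopifnot(is.logical(values), length(dim(values)) == 3)
  if (!any(values)) {
    return(structure(list(skeleton = values,
                          radius_um = array(0, dim = dim(values)),
                          voxel_size_um = voxel_size_um),
                     class = "vessel_skeleton"))
  }
  skel <- cpp_skeletonize3d(values, dim(values))
  edt <- cpp_edt3d(values, dim(values))
  radius <- pmax(edt - surface_offset_vox, 0.5 * (edt > 0)) * voxel_size_um
  dim(radius) <- dim(values)
  structure(list(skeleton = skel, radius_um = radius,
                 voxel_size_um = voxel_size_um),
            class = "vessel_skeleton")
}

# iteratively remove terminal branches shorter than min_len voxels whose far
# end attaches to a junction voxel
.prune_spurs <- function(sk, min_len, max_iter = 3) {
  for (it in seq_len(max_iter)) {
    cnt <- .neighbor_counts(sk)
    jmask <- sk & cnt >= 3
    bmask <- sk & !jmask
    if (!any(bmask) || !any(jmask)) return(sk)
    blab <- cpp_label3d(bmask, dim(bmask))
    emask <- sk & cnt == 1
    removed <- FALSE
    d <- dim(sk)
    for (bid in seq_len(max(blab))) {
      vox <- which(blab == bid, arr.ind = TRUE)
      if (nrow(vox) >= min_len) next
      if (!any(emask[vox])) next          # not terminal
      touches_junction <- FALSE
      for (r in seq_len(nrow(vox))) {
        ii <- max(1, vox[r, 1] - 1):min(d[1], vox[r, 1] + 1)
        jj <- max(1, vox[r, 2] - 1):min(d[2], vox[r, 2] + 1)
        kk <- max(1, vox[r, 3] - 1):min(d[3], vox[r, 3] + 1)
        if (any(jmask[ii, jj, kk])) { touches_junction <- TRUE; break }
      }
      if (touches_junction) { sk[vox] <- FALSE; removed <- TRUE }
    }
    if (!removed) break
  }
  sk
}

# 26-neighbour count of each TRUE voxel (returns array of counts)
.neighbor_counts <- function(skel) {
  d <- dim(skel)
  cnt <- array(0L, dim = d)
  sk <- skel
  for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    src_i <- max(1, 1 - di):min(d[1], d[1] - di)
    src_j <- max(1, 1 - dj):min(d[2], d[2] - dj)
    src_k <- max(1, 1 - dk):min(d[3], d[3] - dk)
    cnt[src_i + di, src_j + dj, src_k + dk] <-
      cnt[src_i + di, src_j + dj, src_k + dk] +
      sk[src_i, src_j, src_k]
  }
  cnt * skel
}

#' Build a vessel graph from a skeleton
#'
#' Junction voxels are skeleton voxels with three or more skeleton
#' neighbours (26-connectivity); 26-adjacent junction voxels are merged into
#' one junction node at their centroid. Removing junction voxels splits the
#' skeleton into branch paths; each becomes an edge between the nodes
#' (junctions or endpoints) it touches. A branch's radius is the median of
#' its per-voxel radii after discarding voxels inside the junction exclusion
#' zone (within `2 x` the junction's local radius of the junction centre),
#' which avoids the junction-bulge bias.
#'
#' Short terminal branches (fewer than `prune_spur_len_vox` skeleton voxels
#' ending in an endpoint) are pruned before the graph is assembled: thinning
#' surface bumps into small spurs is a known artifact that would otherwise
#' create phantom junctions.
#'
#' @param skel a [skeletonize_mask()] result.
#' @param prune_spur_len_vox prune terminal branches shorter than this many
#'   voxels (0 disables pruning).
#' @return object of class `vessel_graph`: `nodes` (data frame: `id`,
#'   positions in um, `type` "junction"/"endpoint", `radius_um`, `degree`),
#'   `edges` (data frame: `id`, `from`, `to`, `n_voxels`, `radius_um`),
#'   `paths` (list of voxel-index matrices per edge), `voxel_size_um`.
#' @export
build_vessel_graph <- function(skel, prune_spur_len_vox = 5) {
  stopifnot(inherits(skel, "vessel_skeleton"))
  voxel <- skel$voxel_size_um
  sk <- skel$skeleton
  if (prune_spur_len_vox > 0 && any(sk))
    sk <- .prune_spurs(sk, prune_spur_len_vox)
  empty <- structure(list(
    nodes = data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                       z_um = numeric(0), type = character(0),
                       radius_um = numeric(0), degree = integer(0)),
    edges = data.frame(id = integer(0), from = integer(0), to = integer(0),
                       n_voxels = integer(0), radius_um = numeric(0)),
    paths = list(), voxel_size_um = voxel), class = "vessel_graph")
  if (!any(sk)) return(empty)

  cnt <- .neighbor_counts(sk)
  jmask <- sk & cnt >= 3
  emask <- sk & cnt == 1

  # junction nodes: clusters of junction voxels
  nodes <- list()
  jlab <- array(0L, dim = dim(sk))
  if (any(jmask)) {
    jlab <- cpp_label3d(jmask, dim(jmask))
    for (id in seq_len(max(jlab))) {
      vox <- which(jlab == id, arr.ind = TRUE)
      ctr <- colMeans(vox)
      nodes[[length(nodes) + 1]] <- data.frame(
        id = length(nodes) + 1L,
        x_um = ctr[1] * voxel, y_um = ctr[2] * voxel, z_um = ctr[3] * voxel,
        type = "junction",
        radius_um = max(skel$radius_um[vox]),
        degree = 0L)
    }
  }
  n_junc <- length(nodes)

  # branch paths: skeleton minus junction voxels
  bmask <- sk & !jmask
  edges <- list(); paths <- list()
  add_endpoint_node <- function(vx) {
    nodes[[length(nodes) + 1]] <<- data.frame(
      id = length(nodes) + 1L,
      x_um = vx[1] * voxel, y_um = vx[2] * voxel, z_um = vx[3] * voxel,
      type = "endpoint", radius_um = skel$radius_um[matrix(vx, 1)],
      degree = 0L)
    length(nodes)
  }
  if (any(bmask)) {
    blab <- cpp_label3d(bmask, dim(bmask))
    d <- dim(sk)
    for (bid in seq_len(max(blab))) {
      vox <- which(blab == bid, arr.ind = TRUE)
      # junction clusters 26-adjacent to this branch
      adj <- integer(0)
      for (r in seq_len(nrow(vox))) {
        ii <- max(1, vox[r, 1] - 1):min(d[1], vox[r, 1] + 1)
        jj <- max(1, vox[r, 2] - 1):min(d[2], vox[r, 2] + 1)
        kk <- max(1, vox[r, 3] - 1):min(d[3], vox[r, 3] + 1)
        loc <- jlab[ii, jj, kk]
        adj <- union(adj, loc[loc > 0])
      }
      # endpoint voxels inside this branch
      end_rows <- which(emask[vox])
      node_ids <- adj
      for (er in end_rows) node_ids <- c(node_ids, add_endpoint_node(vox[er, ]))
      if (length(node_ids) == 0) {
        # isolated loop: represent with a synthetic endpoint at first voxel
        node_ids <- add_endpoint_node(vox[1, ])
      }
      from <- node_ids[1]
      to <- if (length(node_ids) >= 2) node_ids[2] else node_ids[1]

      # branch radius: median outside junction exclusion zones
      rads <- skel$radius_um[vox]
      keep <- rep(TRUE, nrow(vox))
      for (nid in adj) {
        nd <- nodes[[nid]]
        dist <- sqrt((vox[, 1] * voxel - nd$x_um)^2 +
                       (vox[, 2] * voxel - nd$y_um)^2 +
                       (vox[, 3] * voxel - nd$z_um)^2)
        keep <- keep & dist > 2 * nd$radius_um
      }
      rad <- if (any(keep)) median(rads[keep]) else median(rads)
      edges[[length(edges) + 1]] <- data.frame(
        id = length(edges) + 1L, from = from, to = to,
        n_voxels = nrow(vox), radius_um = rad)
      paths[[length(paths) + 1]] <- vox
    }
  }
  # direct junction-junction contacts with no interior branch voxels are rare
  # on thinned skeletons and are not represented as edges.

  nodes_df <- if (length(nodes)) do.call(rbind, nodes) else empty$nodes
  edges_df <- if (length(edges)) do.call(rbind, edges) else empty$edges

  # self-loops (a branch leaving and re-entering the same junction cluster)
  # carry no daughter-radius information and would double-count in node
  # degrees; drop them
  if (nrow(edges_df) > 0) {
    keep <- edges_df$from != edges_df$to
    edges_df <- edges_df[keep, , drop = FALSE]
    paths <- paths[keep]
  }

  # contract short junction-junction bridges: thinning splits a Y-junction
  # into two nearby T-nodes joined by a few-voxel bridge, which would double
  # the junction count and duplicate branch records
  if (nrow(edges_df) > 0 && nrow(nodes_df) > 0) {
    repeat {
      is_j <- nodes_df$type == "junction"
      br <- which(edges_df$from != edges_df$to &
                    is_j[match(edges_df$from, nodes_df$id)] &
                    is_j[match(edges_df$to, nodes_df$id)])
      if (length(br) == 0) break
      lim <- vapply(br, function(e) {
        ra <- nodes_df$radius_um[match(edges_df$from[e], nodes_df$id)]
        rb <- nodes_df$radius_um[match(edges_df$to[e], nodes_df$id)]
        max(3, 1.5 * max(ra, rb) / voxel)
      }, numeric(1))
      short <- br[edges_df$n_voxels[br] < lim]
      if (length(short) == 0) break
      e <- short[which.min(edges_df$n_voxels[short])]
      a <- edges_df$from[e]; b <- edges_df$to[e]
      ia <- match(a, nodes_df$id); ib <- match(b, nodes_df$id)
      nodes_df$x_um[ia] <- (nodes_df$x_um[ia] + nodes_df$x_um[ib]) / 2
      nodes_df$y_um[ia] <- (nodes_df$y_um[ia] + nodes_df$y_um[ib]) / 2
      nodes_df$z_um[ia] <- (nodes_df$z_um[ia] + nodes_df$z_um[ib]) / 2
      nodes_df$radius_um[ia] <- max(nodes_df$radius_um[ia],
                                    nodes_df$radius_um[ib])
      edges_df$from[edges_df$from == b] <- a
      edges_df$to[edges_df$to == b] <- a
      keep <- seq_len(nrow(edges_df)) != e
      edges_df <- edges_df[keep, , drop = FALSE]
      paths <- paths[keep]
      nodes_df <- nodes_df[-ib, , drop = FALSE]
    }
  }

  # contraction can turn a parallel bridge into a self-loop: drop those too
  if (nrow(edges_df) > 0) {
    keep <- edges_df$from != edges_df$to
    edges_df <- edges_df[keep, , drop = FALSE]
    paths <- paths[keep]
  }

  if (nrow(edges_df)) {
    degs <- table(factor(c(edges_df$from, edges_df$to),
                         levels = nodes_df$id))
    nodes_df$degree <- as.integer(degs)
  }
  # a junction label needs >= 3 incident branches; clusters left with fewer
  # after pruning/contraction are ordinary transit points on a branch
  nodes_df$type[nodes_df$type == "junction" & nodes_df$degree < 3] <- "transit"
  structure(list(nodes = nodes_df, edges = edges_df, paths = paths,
                 voxel_size_um = voxel),
            class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat("vessel_graph:", nrow(x$nodes), "nodes (",
      sum(x$nodes$type == "junction"), "junctions ),",
      nrow(x$edges), "branches\n")
  invisible(x)
}
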