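#' Configuration for a full simulate-to-morphometry run
#'
#' Bundles and validates every stage's parameters. `tree` may be a
#' [tree_spec()] or a plain list of its arguments (validated on the spot).
#' Morphometry thresholds default to the microvascular analysis band:
#' pre-branching radius below 20 um, binned at 7.4 um.
#'
#' @param tree a [tree_spec()] or argument list.
#' @param grid a [grid_spec()].
#' @param geometry an [acquisition_geometry()].
#' @param noise a [noise_spec()]; its seed is overridden by `seed`.
#' @param tissue_mu,tissue_delta phantom optical constants, see
#'   [voxelize_tree()].
#' @param recon_filter FBP apodization window.
#' @param scales_um,min_strength_quantile,min_component_voxels segmentation
#'   parameters, see [segment_vasculature()].
#' @param max_pre_radius_um,bin_edge_um morphometry thresholds, see
#'   [filter_and_bin()].
#' @param retrieve also run single-distance phase retrieval on the first
#'   corrected frame (side branch; the CT path always uses corrected
#'   images).
#' @param seed master seed controlling tree generation and detector noise.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(tree = tree_spec(),
                            grid = grid_spec(c(96, 96, 96), 2),
                            geometry = acquisition_geometry(n_angles = 180,
                                                            distance_mm = 0),
                            noise = noise_spec(),
                            tissue_mu = 1e-4, tissue_delta = 1e-6,
                            recon_filter = "ramlak",
                            scales_um = NULL,
                            min_strength_quantile = 0.98,
                            min_component_voxels = 27,
                            max_pre_radius_um = 20, bin_edge_um = 7.4,
                            retrieve = FALSE, seed = 1) {
  if (!inherits(tree, "tree_spec")) tree <- do.call(tree_spec, as.list(tree))
  stopifnot(inherits(grid, "grid_spec"),
            inherits(geometry, "acquisition_geometry"),
            inherits(noise, "noise_spec"),
            tissue_mu > 0, tissue_delta > 0,
            max_pre_radius_um > bin_edge_um, bin_edge_um > 0)
  scales_um <- scales_um %||%
    (grid$voxel_size_um * c(1, 2, 3, 5))
  stopifnot(all(scales_um >= grid$voxel_size_um))
  noise$seed <- as.integer(seed)
  structure(list(tree = tree, grid = grid, geometry = geometry,
                 noise = noise, tissue_mu = tissue_mu,
                 tissue_delta = tissue_delta, recon_filter = recon_filter,
                 scales_um = scales_um,
                 min_strength_quantile = min_strength_quantile,
                 min_component_voxels = min_component_voxels,
                 max_pre_radius_um = max_pre_radius_um,
                 bin_edge_um = bin_edge_um, retrieve = retrieve,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# plain-text checksum of a config (no external digest dependency)
.config_checksum <- function(config) {
  s <- yaml::as.yaml(.config_as_list(config))
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 251)) %% 4294967291)
}

.config_as_list <- function(config) {
  rapply(unclass(config), function(x) x, how = "replace")
}

#' Run the full pipeline: simulate, correct, reconstruct, segment, measure
#'
#' Executes phantom generation, projection simulation, flat/dark correction,
#' optional phase retrieval, filtered back projection, ridge segmentation,
#' skeletonization and branch morphometry under one seed. When `out_dir` is
#' given, writes the projections, dark/flat frames, ground-truth mask,
#' reconstructed volume and segmentation mask as TIFF stacks, the branch
#' tables as CSV, and a YAML provenance sidecar with the full configuration
#' and its checksum.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param keep_volumes keep the large intermediate arrays in the returned
#'   object (set `FALSE` to save memory).
#' @return list of class `pipeline_result`: `tree`, `true_branches`,
#'   `phantom`, `corrected`, `volume`, `mask`, `skeleton`, `graph`,
#'   `records`, `binned`, `retrieved` (optional), `config`, `checksum`.
#' @export
run_pipeline <- function(config, out_dir = NULL, keep_volumes = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  tree <- generate_vessel_tree(config$tree, config$seed)
  phantom <- voxelize_tree(tree, config$grid, config$tissue_mu,
                           config$tissue_delta)
  raw <- simulate_projections(phantom, config$geometry, config$noise)
  corrected <- correct_projection_set(raw)
  retrieved <- NULL
  if (isTRUE(config$retrieve)) {
    params <- phase_retrieval_params(
      delta = config$tissue_delta, beta = config$tissue_mu *
        xray_wavelength_um(config$geometry$energy_keV) / (4 * pi),
      energy_keV = config$geometry$energy_keV,
      distance_mm = config$geometry$distance_mm,
      pixel_size_um = corrected$pixel_size_um)
    retrieved <- paganin_retrieve(corrected$frames[, , 1], params)
  }
  volume <- reconstruct_volume(corrected, config$recon_filter)
  mask <- segment_vasculature(volume, config$scales_um,
                              config$min_strength_quantile,
                              config$min_component_voxels)
  skeleton <- skeletonize_mask(mask)
  graph <- build_vessel_graph(skeleton)
  records <- branch_records(graph)
  binned <- filter_and_bin(records, config$max_pre_radius_um,
                           config$bin_edge_um)
  checksum <- .config_checksum(config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    meta <- list(config_checksum = checksum, seed = config$seed)
    write_tiff_stack(round(raw$frames), file.path(out_dir, "projections.tiff"),
                     "uint16", meta)
    write_tiff_stack(round(raw$dark), file.path(out_dir, "dark.tiff"),
                     "uint16", meta)
    write_tiff_stack(round(raw$flat), file.path(out_dir, "flat.tiff"),
                     "uint16", meta)
    write_tiff_stack(volume$values, file.path(out_dir, "volume.tiff"),
                     "float32", meta)
    write_tiff_stack(phantom$true_mask + 0,
                     file.path(out_dir, "true_mask.tiff"), "uint16", meta)
    write_tiff_stack(mask$values + 0, file.path(out_dir, "mask.tiff"),
                     "uint16", meta)
    write_csv_table(true_branch_table(tree),
                    file.path(out_dir, "true_branches.csv"))
    write_csv_table(records, file.path(out_dir, "branches.csv"))
    write_csv_table(binned, file.path(out_dir, "branches_binned.csv"))
    prov <- .config_as_list(config)
    prov$checksum <- checksum
    yaml::write_yaml(prov, file.path(out_dir, "provenance.yaml"))
  }

  res <- list(tree = tree, true_branches = true_branch_table(tree),
              phantom = if (keep_volumes) phantom else NULL,
              corrected = if (keep_volumes) corrected else NULL,
              volume = if (keep_volumes) volume else NULL,
              mask = mask, skeleton = if (keep_volumes) skeleton else NULL,
              graph = graph, records = records, binned = binned,
              retrieved = retrieved, config = config, checksum = checksum)
  structure(res, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result (config", x$checksum, ")\n")
  cat("  true junctions:", nrow(x$tree$junctions),
      "| measured junctions:", nrow(x$records), "\n")
  if (nrow(x$binned) > 0)
    cat("  mean measured K (radius <", x$config$max_pre_radius_um, "um):",
        signif(mean(x$binned$K), 4), "\n")
  invisible(x)
}
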