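#' Write a 3D array as a multi-page TIFF stack
#'
#' Two storage modes: `"uint16"` stores integer counts 0..65535 losslessly
#' (raw and corrected-count frames); `"float32"` stores arbitrary numeric
#' volumes min-max normalized to 32-bit float pages. Both write a plain-text
#' YAML sidecar (`<path>.yaml`) recording the mode, value range, dimensions
#' and any extra metadata, so [read_tiff_stack()] can restore the original
#' values.
#'
#' @param x numeric 3D array (pages along the third dimension) or a matrix.
#' @param path output file path.
#' @param mode `"uint16"` or `"float32"`.
#' @param metadata named list stored in the sidecar (geometry, seed, ...).
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(x, path, mode = c("uint16", "float32"),
                             metadata = list()) {
  mode <- match.arg(mode)
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1))
  stopifnot(length(dim(x)) == 3)
  if (mode == "uint16") {
    if (any(x < 0 | x > 65535) || any(x != round(x)))
      stop("uint16 mode requires integer values in [0, 65535]")
    pages <- lapply(seq_len(dim(x)[3]), function(k) x[, , k] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
    side <- list(mode = "uint16", dim = dim(x))
  } else {
    mn <- min(x); mx <- max(x)
    scale <- if (mx > mn) mx - mn else 1
    pages <- lapply(seq_len(dim(x)[3]), function(k) (x[, , k] - mn) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
    side <- list(mode = "float32", dim = dim(x), min = mn, max = mx)
  }
  side$metadata <- metadata
  # full double precision for the scaling bounds, or restored values drift
  yaml::write_yaml(side, paste0(path, ".yaml"), precision = 15)
  invisible(path)
}

#' Read a multi-page TIFF stack written by [write_tiff_stack()]
#'
#' @param path TIFF file path; the YAML sidecar `<path>.yaml` is consulted
#'   when present to restore original values, otherwise pages are returned
#'   in the reader's native 0..1 scaling.
#' @return 3D numeric array with attribute `metadata` (sidecar contents).
#' @export
read_tiff_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar <- paste0(path, ".yaml")
  side <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else NULL
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  if (!is.null(side)) {
    if (side$mode == "uint16") arr <- round(arr * 65535)
    else arr <- arr * (side$max - side$min) + side$min
    attr(arr, "metadata") <- side$metadata
  }
  arr
}

#' Write a records table as CSV
#'
#' @param records data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_csv_table <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}
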