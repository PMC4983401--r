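#' Flat-field and dark-field correction of a projection frame
#'
#' Computes the corrected (transmittance-like) image
#' `I_p = (I - I_d) / (I_f - I_d)` pixelwise. Pixels where
#' `flat - dark <= 0` carry no radiometric information; they are repaired
#' with the median of their valid 8-neighbours. If more than `max_bad_frac`
#' of the pixels are bad the frame is rejected.
#'
#' @param raw_frame,dark,flat numeric matrices of identical shape.
#' @param max_bad_frac maximum tolerated fraction of unrepairable pixels.
#' @return corrected numeric matrix.
#' @export
correct_projection <- function(raw_frame, dark, flat, max_bad_frac = 0.01) {
  if (!all(dim(raw_frame) == dim(dark)) || !all(dim(raw_frame) == dim(flat)))
    stop("raw, dark and flat frames must share one shape")
  denom <- flat - dark
  bad <- denom <= 0
  nbad <- sum(bad)
  if (nbad > max_bad_frac * length(denom))
    stop(sprintf("%.1f%% of pixels have flat - dark <= 0 (limit %.1f%%)",
                 100 * nbad / length(denom), 100 * max_bad_frac))
  ip <- (raw_frame - dark) / ifelse(bad, 1, denom)
  if (nbad > 0) {
    warning(nbad, " pixel(s) with flat - dark <= 0 repaired from neighbours")
    idx <- which(bad, arr.ind = TRUE)
    n1 <- nrow(ip); n2 <- ncol(ip)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      ii <- max(1, i - 1):min(n1, i + 1)
      jj <- max(1, j - 1):min(n2, j + 1)
      nb <- ip[ii, jj]
      ok <- !bad[ii, jj]
      ok[which(ii == i), which(jj == j)] <- FALSE
      ip[i, j] <- if (any(ok)) median(nb[ok]) else 1
    }
  }
  ip
}

#' Correct every frame of a raw projection set
#'
#' @param raw a [simulate_projections()] result (or compatible list).
#' @param max_bad_frac see [correct_projection()].
#' @return object of class `corrected_projection_set`: `frames` (same array
#'   layout as the raw set, values dimensionless), `angles_deg`,
#'   `pixel_size_um`, `geometry`.
#' @export
correct_projection_set <- function(raw, max_bad_frac = 0.01) {
  stopifnot(inherits(raw, "raw_projection_set"))
  frames <- raw$frames
  for (a in seq_len(dim(frames)[3]))
    frames[, , a] <- correct_projection(raw$frames[, , a], raw$dark, raw$flat,
                                        max_bad_frac)
  structure(list(frames = frames, angles_deg = raw$angles_deg,
                 pixel_size_um = raw$pixel_size_um, geometry = raw$geometry),
            class = "corrected_projection_set")
}

#' Fringe visibility of a region of interest
#'
#' `V = (I_max - I_min) / (I_max + I_min)` over the region, the standard
#' fringe-contrast measure used to choose the sample-to-detector distance.
#' An optional robust variant uses the 0.5% / 99.5% percentiles instead of
#' the raw extrema (for noisy data; off by default).
#'
#' @param frame numeric matrix (a corrected projection).
#' @param roi integer vector `c(i1, i2, j1, j2)`: inclusive index ranges of
#'   the region (first/second matrix index).
#' @param robust use percentile extrema instead of min/max.
#' @return object of class `visibility_result`: list with `V`, `I_max`,
#'   `I_min`, `roi`.
#' @export
visibility <- function(frame, roi = c(1, nrow(frame), 1, ncol(frame)),
                       robust = FALSE) {
  stopifnot(length(roi) == 4)
  roi <- as.integer(roi)
  if (roi[1] < 1 || roi[2] > nrow(frame) || roi[3] < 1 ||
      roi[4] > ncol(frame) || roi[1] > roi[2] || roi[3] > roi[4])
    stop("roi out of bounds or empty")
  sub <- frame[roi[1]:roi[2], roi[3]:roi[4]]
  if (robust) {
    q <- quantile(sub, c(0.005, 0.995), names = FALSE)
    imin <- q[1]; imax <- q[2]
  } else {
    imin <- min(sub); imax <- max(sub)
  }
  if (imax + imin == 0) stop("visibility undefined: I_max + I_min = 0")
  structure(list(V = (imax - imin) / (imax + imin), I_max = imax,
                 I_min = imin, roi = roi),
            class = "visibility_result")
}

#' @export
print.visibility_result <- function(x, ...) {
  cat(sprintf("visibility V = %.4f (I_max = %.4g, I_min = %.4g)\n",
              x$V, x$I_max, x$I_min))
  invisible(x)
}

#' Sweep the sample-to-detector distance and track fringe visibility
#'
#' Simulates the same phantom at each distance (identical noise seed),
#' applies flat/dark correction, and averages the visibility over the given
#' regions and all frames. Also reports the plateau onset: the smallest
#' distance whose mean visibility reaches `1 - plateau_tol` of the sweep
#' maximum, the operational definition of an optimal propagation distance.
#'
#' @param phantom a [voxelize_tree()] result.
#' @param geometry_base an [acquisition_geometry()]; its `distance_mm` is
#'   overridden by each element of `distances_mm`. Use few angles here: the
#'   visibility of a static region does not depend on the view count.
#' @param distances_mm numeric vector (>= 2) of distances to test.
#' @param rois list of `c(i1, i2, j1, j2)` regions passed to [visibility()].
#' @param noise a [noise_spec()]; the same seed is reused at every distance.
#' @param plateau_tol relative tolerance defining the plateau.
#' @param robust passed to [visibility()].
#' @return object of class `distance_sweep`: list with `table` (data frame
#'   `distance_mm`, `visibility`) and `plateau_onset_mm`.
#' @export
distance_sweep <- function(phantom, geometry_base, distances_mm, rois,
                           noise = noise_off(), plateau_tol = 0.05,
                           robust = FALSE) {
  stopifnot(length(distances_mm) >= 2, length(rois) >= 1)
  vis <- vapply(distances_mm, function(d) {
    g <- geometry_base
    g$distance_mm <- d
    raw <- simulate_projections(phantom, g, noise)
    corr <- correct_projection_set(raw)
    mean(vapply(seq_len(dim(corr$frames)[3]), function(a) {
      mean(vapply(rois, function(r)
        visibility(corr$frames[, , a], r, robust = robust)$V, numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  tab <- data.frame(distance_mm = distances_mm, visibility = vis)
  plateau <- distances_mm[which(vis >= (1 - plateau_tol) * max(vis))[1]]
  structure(list(table = tab, plateau_onset_mm = plateau,
                 plateau_tol = plateau_tol),
            class = "distance_sweep")
}

#' @export
print.distance_sweep <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("plateau onset:", x$plateau_onset_mm, "mm (tolerance",
      x$plateau_tol, ")\n")
  invisible(x)
}
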