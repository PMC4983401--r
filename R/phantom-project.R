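#' Parallel-beam acquisition geometry
#'
#' Either `n_angles` or `angle_step_deg` may be given; the other is derived
#' from `angle_range_deg` (`n_angles = floor(range / step)`). The defaults
#' mirror a synchrotron microtomography protocol: a 180 degree scan in 0.12
#' degree steps (1500 projections) at 16 keV with 200 ms exposures.
#'
#' @param n_angles number of projections.
#' @param angle_range_deg total rotation range, degrees.
#' @param angle_step_deg angular step, degrees.
#' @param distance_mm sample-to-detector propagation distance, millimetres.
#' @param energy_keV photon energy.
#' @param exposure_s exposure per projection, seconds.
#' @return object of class `acquisition_geometry` with an `angles_deg` vector.
#' @export
acquisition_geometry <- function(n_angles = NULL, angle_range_deg = 180,
                                 angle_step_deg = NULL, distance_mm = 700,
                                 energy_keV = 16, exposure_s = 0.2) {
  stopifnot(angle_range_deg > 0, distance_mm >= 0, energy_keV > 0)
  if (is.null(n_angles) && is.null(angle_step_deg)) {
    angle_step_deg <- 0.12
  }
  if (is.null(n_angles)) {
    # small epsilon so an exact divisor is not lost to floating-point error
    n_angles <- floor(angle_range_deg / angle_step_deg + 1e-9)
  } else if (is.null(angle_step_deg)) {
    angle_step_deg <- angle_range_deg / n_angles
  }
  n_angles <- as.integer(n_angles)
  stopifnot(n_angles >= 1)
  structure(list(n_angles = n_angles, angle_range_deg = angle_range_deg,
                 angle_step_deg = angle_step_deg,
                 angles_deg = (seq_len(n_angles) - 1) * angle_step_deg,
                 distance_mm = distance_mm, energy_keV = energy_keV,
                 exposure_s = exposure_s),
            class = "acquisition_geometry")
}

#' Detector noise and illumination model
#'
#' @param photons_per_pixel expected flat-field photon count per pixel.
#' @param dark_offset mean dark level, detector counts.
#' @param dark_sd Gaussian read-noise standard deviation, counts.
#' @param vignette_strength relative fall-off of the flat field at the image
#'   corner, in `[0, 1)`.
#' @param seed integer seed; every frame draws from its own substream derived
#'   from this seed and the frame index, so simulations are reproducible and
#'   frames independent.
#' @param poisson apply Poisson photon noise (set `FALSE` together with
#'   `dark_sd = 0` for an ideal noise-free detector).
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(photons_per_pixel = 5000, dark_offset = 100,
                       dark_sd = 5, vignette_strength = 0.1, seed = 1,
                       poisson = TRUE) {
  stopifnot(photons_per_pixel > 0, dark_sd >= 0,
            vignette_strength >= 0, vignette_strength < 1)
  structure(list(photons_per_pixel = photons_per_pixel,
                 dark_offset = dark_offset, dark_sd = dark_sd,
                 vignette_strength = vignette_strength,
                 seed = as.integer(seed), poisson = isTRUE(poisson)),
            class = "noise_spec")
}

#' Noise-free detector model
#'
#' Convenience wrapper for [noise_spec()] with Poisson noise and read noise
#' switched off (vignetting and dark offset retained unless overridden).
#' @param ... passed to [noise_spec()].
#' @export
noise_off <- function(...) {
  args <- list(...)
  args$poisson <- FALSE
  args$dark_sd <- 0
  do.call(noise_spec, args)
}

# 2D Laplacian with replicated edges, pixel spacing h (result in 1/h^2 units)
.laplacian2d <- function(m, h) {
  n1 <- nrow(m); n2 <- ncol(m)
  up <- m[c(1, seq_len(n1 - 1)), , drop = FALSE]
  dn <- m[c(seq_len(n1 - 1) + 1, n1), , drop = FALSE]
  lf <- m[, c(1, seq_len(n2 - 1)), drop = FALSE]
  rt <- m[, c(seq_len(n2 - 1) + 1, n2), drop = FALSE]
  (up + dn + lf + rt - 4 * m) / h^2
}

.vignette_profile <- function(nx, nz, strength) {
  cx <- (nx + 1) / 2; cz <- (nz + 1) / 2
  r2max <- (nx - cx)^2 + (nz - cz)^2
  r2 <- outer((seq_len(nx) - cx)^2, (seq_len(nz) - cz)^2, "+")
  1 - strength * r2 / r2max
}

#' Simulate propagation-based phase-contrast projections
#'
#' For each rotation angle the attenuation and phase-decrement volumes are
#' line-integrated along parallel rays (rotation about the z axis). The
#' contact-plane intensity is `I0 = exp(-integral(mu))`; free-space
#' propagation to the detector is modelled in the transport-of-intensity
#' (weak-defocus) regime as
#' `I_z = I0 + z * Laplacian_perp(I0 * integral(delta))`
#' (the sign following from the phase lag `phi = -k * integral(delta)` of a
#' refractive-index decrement), which reproduces the characteristic
#' distance-dependent growth of edge fringes at vessel boundaries. The frame is then multiplied by the
#' (vignetted) flat field, offset by the dark level, and optionally
#' degraded by Poisson photon noise and Gaussian read noise. Matching dark
#' and flat frames are generated with the same noise model.
#'
#' The transport-of-intensity model is valid in the near-field (weak
#' defocus) regime, i.e. while the first Fresnel fringe width
#' `sqrt(lambda * z)` stays small against the imaged structures; for a
#' 10-110 cm propagation distance at 16 keV and micrometre pixels this
#' holds comfortably.
#'
#' @param phantom a [voxelize_tree()] result.
#' @param geometry an [acquisition_geometry()].
#' @param noise a [noise_spec()].
#' @param t_step ray-integration step in voxel units.
#' @return object of class `raw_projection_set`: list with `frames` (array
#'   `n_det x n_rows x n_angles`; first index the horizontal detector pixel,
#'   second the vertical/z row), `dark`, `flat`, `angles_deg`, `geometry`,
#'   `noise`, `pixel_size_um`.
#' @export
simulate_projections <- function(phantom, geometry, noise = noise_spec(),
                                 t_step = 0.5) {
  stopifnot(inherits(phantom, "phantom_volume"),
            inherits(geometry, "acquisition_geometry"),
            inherits(noise, "noise_spec"))
  voxel <- phantom$grid$voxel_size_um
  nx <- phantom$grid$shape[1]; nz <- phantom$grid$shape[3]
  z_um <- geometry$distance_mm * 1000
  lambda <- xray_wavelength_um(geometry$energy_keV)
  if (sqrt(lambda * z_um) > nx * voxel / 2)
    stop("propagation distance too large: the Fresnel fringe width exceeds ",
         "half the detector")

  angles_rad <- geometry$angles_deg * pi / 180
  p_mu <- cpp_forward_project(phantom$mu, dim(phantom$mu), angles_rad,
                              t_step) * voxel
  p_delta <- cpp_forward_project(phantom$delta, dim(phantom$delta),
                                 angles_rad, t_step) * voxel

  flat_ideal <- noise$photons_per_pixel *
    .vignette_profile(nx, nz, noise$vignette_strength)

  na <- geometry$n_angles
  frames <- array(0, dim = c(nx, nz, na))
  for (a in seq_len(na)) {
    i0 <- exp(-p_mu[, , a])
    iz <- if (z_um > 0) {
      # weak-defocus transport of intensity with phase lag phi = -k*P_delta:
      # I_z = I0 + z * Laplacian_perp(I0 * P_delta); dense structures darken
      # with a bright rim, air-filled lumina brighten
      pmax(i0 + z_um * .laplacian2d(i0 * p_delta[, , a], voxel), 0)
    } else i0
    signal <- iz * flat_ideal
    frames[, , a] <- with_seed(noise$seed + a, {
      s <- if (noise$poisson) {
        array(rpois(length(signal), signal), dim = dim(signal))
      } else signal
      d <- if (noise$dark_sd > 0) {
        rnorm(length(signal), noise$dark_offset, noise$dark_sd)
      } else noise$dark_offset
      s + d
    })
  }
  dark <- with_seed(noise$seed + na + 1L, {
    if (noise$dark_sd > 0)
      array(rnorm(nx * nz, noise$dark_offset, noise$dark_sd), dim = c(nx, nz))
    else array(noise$dark_offset, dim = c(nx, nz))
  })
  flat <- with_seed(noise$seed + na + 2L, {
    s <- if (noise$poisson) {
      array(rpois(length(flat_ideal), flat_ideal), dim = dim(flat_ideal))
    } else flat_ideal
    d <- if (noise$dark_sd > 0) rnorm(length(s), noise$dark_offset, noise$dark_sd)
    else noise$dark_offset
    s + d
  })

  structure(list(frames = frames, angles_deg = geometry$angles_deg,
                 dark = dark, flat = flat, geometry = geometry,
                 noise = noise, pixel_size_um = voxel),
            class = "raw_projection_set")
}

#' @export
print.raw_projection_set <- function(x, ...) {
  d <- dim(x$frames)
  cat("raw_projection_set:", d[3], "frames of", d[1], "x", d[2],
      "pixels @", x$pixel_size_um, "um,",
      "distance", x$geometry$distance_mm, "mm\n")
  invisible(x)
}
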