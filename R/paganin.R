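#' Parameters for single-distance phase retrieval
#'
#' The single-material assumption needs the ratio `delta / beta` of the
#' refractive-index decrement to the absorption index. For soft tissue at
#' 16 keV the phase cross-section is roughly three orders of magnitude above
#' the absorption cross-section, hence the default ratio of 1000.
#'
#' @param delta refractive-index decrement of the (single) material.
#' @param beta absorption index of the material.
#' @param energy_keV photon energy (wavelength derived from it).
#' @param distance_mm propagation distance, millimetres.
#' @param pixel_size_um detector pixel size, micrometres.
#' @return object of class `phase_retrieval_params`.
#' @export
phase_retrieval_params <- function(delta = 1e-6, beta = 1e-9,
                                   energy_keV = 16, distance_mm = 700,
                                   pixel_size_um = 3.7) {
  stopifnot(delta > 0, beta > 0, distance_mm >= 0, pixel_size_um > 0,
            energy_keV > 0)
  structure(list(delta = delta, beta = beta, energy_keV = energy_keV,
                 distance_mm = distance_mm, pixel_size_um = pixel_size_um),
            class = "phase_retrieval_params")
}

# DFT frequencies in cycles per physical unit for n samples of spacing d
.fft_freq <- function(n, d) {
  k <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)
  if (n %% 2 == 0) k <- c(0:(n / 2 - 1), -(n / 2):-1)
  k / (n * d)
}

#' Single-distance (Paganin) phase retrieval
#'
#' Recovers the projected thickness of a homogeneous object from one
#' corrected propagation image by low-pass filtering in the frequency
#' domain and taking the logarithm:
#' `T = -(1/mu) * ln( IFFT( FFT(I_p) / (1 + lambda*z*delta/(4*pi*beta) * |k|^2) ) )`
#' with `mu = 4*pi*beta/lambda` and `|k|` the spatial frequency in physical
#' units (radians per micrometre). At `z = 0` the filter is the identity and
#' the result reduces to the pure absorption thickness `-ln(I_p)/mu`.
#'
#' @param frame corrected projection `I_p` (numeric matrix, positive).
#' @param params a [phase_retrieval_params()].
#' @param eps floor applied to non-positive intensities before the log.
#' @return thickness map in micrometres (matrix, same shape as `frame`).
#' @export
paganin_retrieve <- function(frame, params, eps = 1e-8) {
  stopifnot(inherits(params, "phase_retrieval_params"), is.matrix(frame))
  lambda <- xray_wavelength_um(params$energy_keV)
  mu <- 4 * pi * params$beta / lambda
  z_um <- params$distance_mm * 1000
  n1 <- nrow(frame); n2 <- ncol(frame)
  fx <- .fft_freq(n1, params$pixel_size_um)
  fy <- .fft_freq(n2, params$pixel_size_um)
  k2 <- outer((2 * pi * fx)^2, (2 * pi * fy)^2, "+")
  denom <- 1 + (lambda * z_um * params$delta / (4 * pi * params$beta)) * k2
  filt <- Re(fft(fft(frame) / denom, inverse = TRUE)) / (n1 * n2)
  if (any(filt <= 0)) {
    warning("non-positive intensities clipped to eps before the logarithm")
    filt <- pmax(filt, eps)
  }
  if (any(frame <= 0))
    warning("input frame contains non-positive intensities")
  -log(filt) / mu
}
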