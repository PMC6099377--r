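#' Multispectral camera model
#'
#' A four-channel UV-capable camera: three visible channels (vis-LW, vis-MW,
#' vis-SW) behind a UV/IR blocking filter passing 400--700 nm, and one UV
#' channel behind a UV-pass filter transmitting 300--400 nm. The sensor's
#' nonlinear response is modeled as a single power law with exponent
#' `response_exponent` applied to the gain-scaled linear signal; calibration
#' treats the exponent as unknown and estimates it from the grey standards.
#'
#' @param response_exponent Positive power-law exponent (default 0.45, a
#'   typical encoding gamma).
#' @param wl Wavelength grid.
#' @return An object of class `apo_camera` with `channel_sensitivities`
#'   (named list of 4 spectra), `response_exponent`, and
#'   `standard_reflectances` c(0.07, 0.93).
#' @export
camera_system <- function(response_exponent = 0.45, wl = wavelength_grid()) {
  if (!is.finite(response_exponent) || response_exponent <= 0) {
    stop("response_exponent must be a positive number")
  }
  vis_block <- stats::plogis((wl - 408) / 4)   # UV/IR-cut: passes > ~400 nm
  uv_pass <- stats::plogis((400 - wl) / 4)     # U-filter: passes < ~400 nm
  gauss <- function(center, width) exp(-0.5 * ((wl - center) / width)^2)
  sens <- list(
    vis_lw = spectrum(wl, gauss(600, 48) * vis_block, kind = "irradiance"),
    vis_mw = spectrum(wl, gauss(535, 42) * vis_block, kind = "irradiance"),
    vis_sw = spectrum(wl, gauss(460, 38) * vis_block, kind = "irradiance"),
    uv     = spectrum(wl, gauss(355, 28) * uv_pass, kind = "irradiance")
  )
  structure(
    list(channel_sensitivities = sens,
         response_exponent = response_exponent,
         standard_reflectances = c(std7 = 0.07, std93 = 0.93)),
    class = "apo_camera"
  )
}

camera_channel_names <- function() c("vis_lw", "vis_mw", "vis_sw", "uv")

# Linear channel responses: integral of refl * illum * sensitivity over the
# grid, one value per channel.
linear_channel_response <- function(refl, camera, illum) {
  stopifnot_same_grid(refl, illum)
  vapply(camera$channel_sensitivities, function(sens) {
    stopifnot_same_grid(refl, sens)
    pracma::trapz(refl$wavelength_nm, refl$value * illum$value * sens$value)
  }, numeric(1))
}

#' True channel-level reflectance of a spectrum
#'
#' The illuminant-and-sensitivity-weighted mean reflectance per camera
#' channel; this is the quantity the calibration round trip
#' (render -> linearize -> normalize) recovers.
#'
#' @param refl Reflectance spectrum.
#' @param camera An `apo_camera`.
#' @param illum Illuminant spectrum.
#' @return Named numeric vector, one value per channel.
#' @export
channel_reflectance <- function(refl, camera, illum) {
  linear_channel_response(refl, camera, illum) /
    linear_channel_response(flat_spectrum(1), camera, illum)
}

#' Render a reflectance spectrum into a raw camera patch
#'
#' Forward model of calibrated wing photography: the linear channel response
#' is scaled by a frame gain, passed through the camera's power-law
#' nonlinearity, and corrupted with Gaussian noise proportional to the linear
#' signal (sensor noise precedes the encoding nonlinearity). The 7% and 93%
#' grey standards are rendered through the identical path in the same frame.
#'
#' @param refl Reflectance spectrum on the working grid.
#' @param camera An `apo_camera`.
#' @param illum Illuminant spectrum.
#' @param gain_jitter Multiplicative frame gain (1 = nominal lighting).
#' @param noise_sd Relative (fractional) Gaussian noise on the linear signal.
#' @param seed Integer seed for the noise draws.
#' @param area_mm2 Patch area in mm^2 carried through for size metrics.
#' @return An object of class `apo_raw_patch` with `channel_values`,
#'   `standard_values` (rows std7/std93), `area_mm2`, and
#'   `scale_px_per_mm = 100`.
#' @export
render_patch <- function(refl, camera, illum, gain_jitter = 1, noise_sd = 0,
                         seed = 1L, area_mm2 = 1) {
  if (area_mm2 <= 0) stop("area_mm2 must be positive")
  if (gain_jitter <= 0) stop("gain_jitter must be positive")
  forward <- function(linear, eps) {
    (pmax(gain_jitter * linear * (1 + eps), 0))^camera$response_exponent
  }
  lin_patch <- linear_channel_response(refl, camera, illum)
  lin_white <- linear_channel_response(flat_spectrum(1), camera, illum)
  withr::with_seed(seed, {
    n <- length(lin_patch)
    patch <- forward(lin_patch, stats::rnorm(n, 0, noise_sd))
    std7 <- forward(0.07 * lin_white, stats::rnorm(n, 0, noise_sd))
    std93 <- forward(0.93 * lin_white, stats::rnorm(n, 0, noise_sd))
    structure(
      list(channel_values = patch,
           standard_values = rbind(std7 = std7, std93 = std93),
           area_mm2 = area_mm2,
           scale_px_per_mm = 100),
      class = "apo_raw_patch"
    )
  })
}

#' Invert the camera's power-law response
#'
#' @param values Non-negative raw camera values (vector or matrix).
#' @param exponent Positive power-law exponent of the camera response.
#' @return Linearized values, `values^(1/exponent)`.
#' @export
linearize <- function(values, exponent) {
  if (!is.finite(exponent) || exponent <= 0) stop("exponent must be positive")
  if (any(values < 0, na.rm = TRUE)) stop("raw camera values must be >= 0")
  values^(1 / exponent)
}

#' Estimate the response exponent from the two grey standards
#'
#' The standards share the frame gain and channel sensitivity, so their raw
#' ratio depends only on the exponent g: (std93/std7) = (0.93/0.07)^g.
#' With per-channel vectors the per-channel estimates are averaged.
#'
#' @param std7,std93 Raw responses of the 7% and 93% standards (scalars or
#'   per-channel vectors).
#' @param reference_pair Reflectances of the two standards.
#' @return Estimated exponent (scalar).
#' @export
estimate_exponent <- function(std7, std93, reference_pair = c(0.07, 0.93)) {
  if (any(std7 <= 0) || any(std93 <= std7)) {
    stop("impossible standards: need 0 < std7 < std93 in every channel")
  }
  mean(log(std93 / std7) / log(reference_pair[2] / reference_pair[1]))
}

#' Normalize linearized values to the grey standards
#'
#' Per channel, the affine map sending the linearized standard responses to
#' their known reflectances (0.07, 0.93). A two-point map removes both frame
#' gain and black-level offset; any common positive factor applied to patch
#' and standards cancels exactly. Values may fall outside \[0.07, 0.93\] for
#' patches darker/brighter than the standards; negative values are clipped
#' to 0 with a warning since downstream log-ratio contrasts need positive
#' catches.
#'
#' @param linear_patch,linear_std7,linear_std93 Linearized per-channel values.
#' @param reference_pair Reflectances of the standards.
#' @return Reflectance-scale channel values.
#' @export
normalize_to_standards <- function(linear_patch, linear_std7, linear_std93,
                                   reference_pair = c(0.07, 0.93)) {
  if (any(linear_std93 <= linear_std7)) {
    stop("equal or inverted standards in at least one channel")
  }
  slope <- (reference_pair[2] - reference_pair[1]) / (linear_std93 - linear_std7)
  out <- reference_pair[1] + (linear_patch - linear_std7) * slope
  if (any(out < 0)) {
    warning(sprintf("%d normalized channel value(s) clipped to 0", sum(out < 0)))
    out <- pmax(out, 0)
  }
  out
}

#' Calibrate a raw patch to reflectance-scale channel values
#'
#' Convenience wrapper: estimate the exponent from the in-frame standards
#' (or use a supplied one), linearize, and normalize.
#'
#' @param raw An `apo_raw_patch`.
#' @param exponent `"auto"` to estimate from the standards, or a positive
#'   number.
#' @return Named per-channel reflectance-scale values.
#' @export
calibrate_patch <- function(raw, exponent = "auto") {
  g <- if (identical(exponent, "auto")) {
    estimate_exponent(raw$standard_values["std7", ], raw$standard_values["std93", ])
  } else {
    exponent
  }
  lin <- linearize(raw$channel_values, g)
  s7 <- linearize(raw$standard_values["std7", ], g)
  s93 <- linearize(raw$standard_values["std93", ], g)
  normalize_to_standards(lin, s7, s93)
}
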