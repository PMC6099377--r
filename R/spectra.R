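#' Working wavelength grid
#'
#' All spectra in the package live on a shared 1-nm grid covering the avian
#' visual range, 300--700 nm.
#'
#' @return Integer vector of wavelengths in nm.
#' @export
wavelength_grid <- function() 300:700

#' Construct a spectrum
#'
#' A spectrum is a plain data frame with columns `wavelength_nm` and `value`.
#' Values are reflectances (dimensionless, typically in \[0, 1\]) or relative
#' irradiances; only relative shape matters downstream.
#'
#' @param wavelength_nm Strictly ascending wavelength grid in nm.
#' @param value Non-negative reflectance or irradiance values, same length.
#' @param kind `"reflectance"` (bounded at 1.5 to allow specular glint) or
#'   `"irradiance"` (unbounded above).
#' @return A `data.frame` of class `apo_spectrum`.
#' @export
spectrum <- function(wavelength_nm, value, kind = c("reflectance", "irradiance")) {
  kind <- match.arg(kind)
  if (length(wavelength_nm) != length(value)) {
    stop("wavelength_nm and value must have equal length")
  }
  if (any(diff(wavelength_nm) <= 0)) {
    stop("wavelength grid must be strictly ascending")
  }
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("spectrum values must be finite and non-negative")
  }
  if (kind == "reflectance" && any(value > 1.5)) {
    stop("reflectance values above 1.5 are not physical for matte wing scales")
  }
  out <- data.frame(wavelength_nm = as.numeric(wavelength_nm), value = as.numeric(value))
  class(out) <- c("apo_spectrum", "data.frame")
  attr(out, "kind") <- kind
  out
}

#' Flat spectrum at a constant reflectance
#'
#' @param level Constant reflectance level.
#' @param wl Wavelength grid (defaults to [wavelength_grid()]).
#' @return An `apo_spectrum`.
#' @export
flat_spectrum <- function(level, wl = wavelength_grid()) {
  spectrum(wl, rep(level, length(wl)))
}

stopifnot_same_grid <- function(a, b) {
  if (nrow(a) != nrow(b) || any(a$wavelength_nm != b$wavelength_nm)) {
    stop("spectra are defined on different wavelength grids")
  }
  invisible(TRUE)
}

#' Smooth daylight-like illuminant
#'
#' An analytic approximation to mid-day open daylight (D65-like) on the
#' 300--700 nm grid: a broad visible hump with a smooth roll-off into the
#' ultraviolet. Only the relative spectral shape is used by the visual model
#' (quantum catches are von Kries normalized), so an analytic curve is
#' sufficient and keeps the package self-contained.
#'
#' @param wl Wavelength grid.
#' @return An `apo_spectrum` with `kind = "irradiance"`.
#' @export
daylight_illuminant <- function(wl = wavelength_grid()) {
  # broad hump peaking near 480 nm plus a UV shoulder tapering below 340 nm
  hump <- exp(-0.5 * ((wl - 480) / 180)^2)
  uv_rolloff <- stats::plogis((wl - 315) / 12)
  spectrum(wl, 100 * hump * uv_rolloff, kind = "irradiance")
}

# Parametric reflectance templates. Each returns values on `wl` given a
# jitter list drawn by make_reflectance_library(). Shapes are stand-ins for
# the real materials: a long-pass step for red pterin markings, low flat for
# melanized black scales, a chlorophyll-like curve for leaves, and plateau
# curves for yellow and purple petals.
reflectance_families <- function() {
  c("red_marking", "black_scale", "green_leaf", "yellow_petal", "purple_petal")
}

template_value <- function(family, wl, par) {
  switch(family,
    red_marking = par$base +
      par$amp * stats::plogis((wl - par$edge) / par$width),
    black_scale = pmin(par$base + par$tilt * (wl - 500) / 400, 0.099),
    green_leaf = par$base +
      par$amp * exp(-0.5 * ((wl - 550) / 45)^2) +
      0.25 * par$amp * stats::plogis((wl - 700) / 10),
    yellow_petal = par$base +
      par$amp * stats::plogis((wl - par$edge) / 22),
    purple_petal = par$base +
      par$amp * exp(-0.5 * ((wl - 440) / 55)^2) +
      0.8 * par$amp * stats::plogis((wl - 640) / 25),
    stop(sprintf(
      "unknown reflectance family '%s'; valid families: %s",
      family, paste(reflectance_families(), collapse = ", ")
    ))
  )
}

template_parameters <- function(family) {
  # each entry: c(mean, sd) of a jittered template parameter
  switch(family,
    red_marking = list(base = c(0.040, 0.006), amp = c(0.55, 0.05),
                       edge = c(600, 8), width = c(15, 2)),
    black_scale = list(base = c(0.035, 0.008), tilt = c(0.015, 0.005)),
    green_leaf = list(base = c(0.045, 0.008), amp = c(0.13, 0.02)),
    yellow_petal = list(base = c(0.05, 0.01), amp = c(0.55, 0.06),
                        edge = c(500, 6)),
    purple_petal = list(base = c(0.07, 0.01), amp = c(0.32, 0.04)),
    template_value(family, 300, list()) # triggers the unknown-family error
  )
}

#' Generate a library of synthetic reflectance spectra
#'
#' Draws `n_per_family` spectra per family from parametric templates with
#' jittered parameters. Families model the materials photographed in a wing
#' coloration study: red wing markings, black wing background, host-plant
#' leaves, and yellow/purple flower petals.
#'
#' @param n_per_family Number of spectra per family (>= 1).
#' @param families Character vector of family names; see
#'   [reflectance_families()].
#' @param seed Integer seed; output is deterministic given the seed.
#' @return Named list of `apo_spectrum` objects; each carries a `family`
#'   attribute.
#' @export
make_reflectance_library <- function(n_per_family,
                                     families = reflectance_families(),
                                     seed = 1L) {
  if (n_per_family < 1) stop("n_per_family must be >= 1")
  for (f in families) template_parameters(f) # validates names up front
  wl <- wavelength_grid()
  withr::with_seed(seed, {
    out <- list()
    for (family in families) {
      pars <- template_parameters(family)
      for (i in seq_len(n_per_family)) {
        par <- lapply(pars, function(ms) stats::rnorm(1, ms[1], ms[2]))
        val <- pmax(template_value(family, wl, par), 1e-4)
        sp <- spectrum(wl, val)
        attr(sp, "family") <- family
        out[[paste0(family, "_", i)]] <- sp
      }
    }
    out
  })
}

#' Write / read spectra as long-form CSV
#'
#' Two-column per-spectrum layout (`wavelength_nm`, `value`) concatenated
#' long-form with a `spectrum_id` column.
#'
#' @param spectra Named list of `apo_spectrum`.
#' @param path Output CSV path.
#' @return `path`, invisibly (write); named list of spectra (read).
#' @export
write_spectra_csv <- function(spectra, path) {
  rows <- lapply(names(spectra), function(id) {
    data.frame(spectrum_id = id,
               wavelength_nm = spectra[[id]]$wavelength_nm,
               value = spectra[[id]]$value)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  long <- utils::read.csv(path)
  out <- lapply(split(long, long$spectrum_id),
                function(d) spectrum(d$wavelength_nm, d$value))
  out[unique(long$spectrum_id)]
}
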