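#' Avian visual systems
#'
#' Tetrachromatic receptor sets for the two avian color-vision classes: the
#' ultraviolet-sensitive (UVS, blue tit-like) and violet-sensitive (VS,
#' peafowl-like) systems, plus the double cone mediating achromatic vision.
#' Spectral sensitivities are log-normal template curves on the working grid
#' with class-typical peak wavelengths (UVS: 371, 445, 508, 565 nm; VS: 420,
#' 455, 505, 567 nm; double cone broad at 560 nm). Relative cone abundances
#' are UV:SW:MW:LW = 1 : 1.92 : 2.68 : 2.7 for UVS and V:SW:MW:LW =
#' 1 : 1.9 : 2.2 : 2.1 for VS, with a Weber fraction of 0.05 for the most
#' abundant cone type.
#'
#' @param name `"uvs"` or `"vs"`.
#' @param weber_omega Weber fraction attached to the most abundant cone.
#' @param wl Wavelength grid.
#' @return An object of class `apo_visual_system` with
#'   `receptor_sensitivities` (named list u/s/m/l/double of spectra),
#'   `abundances` (named numeric), and `weber_omega`.
#' @export
visual_system <- function(name = c("uvs", "vs"), weber_omega = 0.05,
                          wl = wavelength_grid()) {
  name <- match.arg(name)
  if (weber_omega <= 0 || weber_omega >= 1) stop("weber_omega must be in (0, 1)")
  peaks <- switch(name,
    uvs = c(u = 371, s = 445, m = 508, l = 565),
    vs  = c(u = 420, s = 455, m = 505, l = 567)
  )
  abundances <- switch(name,
    uvs = c(u = 1, s = 1.92, m = 2.68, l = 2.7),
    vs  = c(u = 1, s = 1.9, m = 2.2, l = 2.1)
  )
  lognorm <- function(peak, sigma) {
    spectrum(wl, exp(-0.5 * (log(wl / peak) / sigma)^2), kind = "irradiance")
  }
  sigmas <- c(u = 0.055, s = 0.06, m = 0.065, l = 0.07)
  sens <- mapply(lognorm, peaks, sigmas, SIMPLIFY = FALSE)
  sens$double <- lognorm(560, 0.13)
  structure(
    list(name = toupper(name),
         receptor_sensitivities = sens,
         abundances = abundances,
         weber_omega = weber_omega),
    class = "apo_visual_system"
  )
}

#' Quantum catches of a reflectance spectrum
#'
#' Von Kries-normalized receptor quantum catches:
#' q_i = int(R * I * S_i) / int(I * S_i), so a perfect white gives q = 1 in
#' every receptor and the catches are invariant to rescaling the illuminant.
#' The double cone is treated identically.
#'
#' @param refl Reflectance spectrum.
#' @param illum Illuminant spectrum.
#' @param system An `apo_visual_system`.
#' @return An object of class `apo_cone_catch`: list with `q` (named u/s/m/l),
#'   `double`, and `system`.
#' @export
cone_catch_from_spectrum <- function(refl, illum, system) {
  stopifnot_same_grid(refl, illum)
  catches <- vapply(system$receptor_sensitivities, function(sens) {
    stopifnot_same_grid(refl, sens)
    denom <- pracma::trapz(refl$wavelength_nm, illum$value * sens$value)
    if (denom <= 0) stop("receptor with all-zero effective sensitivity")
    pracma::trapz(refl$wavelength_nm, refl$value * illum$value * sens$value) / denom
  }, numeric(1))
  cone_catch(catches[c("u", "s", "m", "l")], catches[["double"]], system$name)
}

#' Construct a cone-catch object
#'
#' @param q Named (u, s, m, l) non-negative single-cone catches.
#' @param double Non-negative double-cone catch.
#' @param system_name Label of the visual system.
#' @return An `apo_cone_catch`.
#' @export
cone_catch <- function(q, double, system_name = "UVS") {
  q <- stats::setNames(as.numeric(q), c("u", "s", "m", "l"))
  if (any(!is.finite(q)) || any(q < 0) || !is.finite(double) || double < 0) {
    stop("cone catches must be finite and non-negative")
  }
  structure(list(q = q, double = as.numeric(double), system = system_name),
            class = "apo_cone_catch")
}

# polynomial feature expansion of the 4 normalized camera channels
mapping_terms <- function(degree) {
  ch <- camera_channel_names()
  terms <- ch
  if (degree >= 2) {
    terms <- c(terms, paste0(ch, "^2"),
               utils::combn(ch, 2, paste, collapse = ":"))
  }
  if (degree >= 3) stop("polynomial degree > 2 is not supported")
  terms
}

mapping_design <- function(channels, degree) {
  channels <- matrix(channels, ncol = 4,
                     dimnames = list(NULL, camera_channel_names()))
  cols <- list(`(Intercept)` = rep(1, nrow(channels)))
  for (term in mapping_terms(degree)) {
    cols[[term]] <- if (grepl("\\^2$", term)) {
      channels[, sub("\\^2$", "", term)]^2
    } else if (grepl(":", term)) {
      parts <- strsplit(term, ":")[[1]]
      channels[, parts[1]] * channels[, parts[2]]
    } else {
      channels[, term]
    }
  }
  do.call(cbind, cols)
}

#' Fit the camera-to-cone-catch polynomial mapping
#'
#' Trains, per receptor (four single cones plus the double cone), a
#' polynomial regression from normalized camera channel values to true
#' quantum catches. Training pairs are produced by a noise-free forward
#' render of the training spectra followed by calibration (the same path
#' measurements take), with the true catches obtained by direct quadrature.
#' A fixed 80/20 split (every 5th spectrum held out) provides per-receptor
#' held-out R-squared diagnostics.
#'
#' @param training_spectra List of reflectance spectra (>= 5x the number of
#'   polynomial terms).
#' @param camera An `apo_camera`.
#' @param illum Illuminant spectrum.
#' @param system An `apo_visual_system`.
#' @param degree Polynomial degree (1 or 2; default 2 with all pairwise
#'   channel interactions).
#' @return An object of class `apo_catch_mapping` with `degree`,
#'   `coefficients` (terms x receptors matrix), `r_squared` (held-out, per
#'   receptor), and `system`.
#' @export
fit_catch_mapping <- function(training_spectra, camera, illum, system,
                              degree = 2) {
  n <- length(training_spectra)
  p <- length(mapping_terms(degree)) + 1
  if (n < 5 * p) {
    stop(sprintf(
      "need at least 5x more training spectra than polynomial terms (%d terms, %d spectra)",
      p, n
    ))
  }
  channels <- t(vapply(training_spectra, function(sp) {
    calibrate_patch(render_patch(sp, camera, illum, noise_sd = 0),
                    exponent = camera$response_exponent)
  }, numeric(4)))
  truth <- t(vapply(training_spectra, function(sp) {
    cc <- cone_catch_from_spectrum(sp, illum, system)
    c(cc$q, double = cc$double)
  }, numeric(5)))
  X <- mapping_design(channels, degree)
  holdout <- seq_len(n) %% 5 == 0
  qr_train <- qr(X[!holdout, , drop = FALSE])
  if (qr_train$rank < ncol(X)) {
    stop(sprintf("rank-deficient mapping design (%d terms, %d training spectra)",
                 ncol(X), sum(!holdout)))
  }
  coefs <- qr.coef(qr_train, truth[!holdout, , drop = FALSE])
  pred <- X[holdout, , drop = FALSE] %*% coefs
  obs <- truth[holdout, , drop = FALSE]
  r2 <- 1 - colSums((obs - pred)^2) / colSums(sweep(obs, 2, colMeans(obs))^2)
  structure(
    list(degree = degree, coefficients = coefs,
         r_squared = stats::setNames(r2, colnames(truth)),
         system = system$name, clip_floor = 1e-6),
    class = "apo_catch_mapping"
  )
}

#' Predict cone catches from normalized camera channels
#'
#' Evaluates the fitted polynomial per receptor. Negative predictions
#' (possible when extrapolating) are clipped to a small positive floor with
#' a warning, since downstream log-ratio contrasts require positive catches.
#'
#' @param mapping An `apo_catch_mapping`.
#' @param normalized_channels Per-channel reflectance-scale values (length-4
#'   vector, or a matrix with one row per patch).
#' @return An `apo_cone_catch` (single patch) or a data frame with columns
#'   u, s, m, l, double.
#' @export
apply_catch_mapping <- function(mapping, normalized_channels) {
  if (!inherits(mapping, "apo_catch_mapping")) {
    stop("mapping must be a fitted apo_catch_mapping")
  }
  single <- is.null(dim(normalized_channels))
  X <- mapping_design(normalized_channels, mapping$degree)
  pred <- X %*% mapping$coefficients
  if (any(pred <= 0)) {
    warning(sprintf("%d predicted catch(es) clipped to floor %g",
                    sum(pred <= 0), mapping$clip_floor))
    pred <- pmax(pred, mapping$clip_floor)
  }
  if (single) {
    cone_catch(pred[1, c("u", "s", "m", "l")], pred[1, "double"], mapping$system)
  } else {
    as.data.frame(pred)
  }
}

#' Serialize / load a catch mapping as JSON
#'
#' @param mapping An `apo_catch_mapping`.
#' @param path JSON file path.
#' @return `path` invisibly (write); an `apo_catch_mapping` (read).
#' @export
write_catch_mapping <- function(mapping, path) {
  obj <- list(degree = mapping$degree,
              system = mapping$system,
              terms = rownames(mapping$coefficients),
              receptors = colnames(mapping$coefficients),
              coefficients = unclass(mapping$coefficients),
              r_squared = as.list(mapping$r_squared),
              clip_floor = mapping$clip_floor)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_catch_mapping
#' @export
read_catch_mapping <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- matrix(as.numeric(obj$coefficients), ncol = length(obj$receptors),
                  dimnames = list(obj$terms, obj$receptors))
  structure(
    list(degree = obj$degree, coefficients = coefs,
         r_squared = unlist(obj$r_squared), system = obj$system,
         clip_floor = obj$clip_floor),
    class = "apo_catch_mapping"
  )
}
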