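#' Latent color axes and the metrics they drive
#'
#' The generator draws, per specimen, standardized latent values on a small
#' set of color axes; each observable metric is an affine function of one
#' latent. Saturation and hue share the `fw_chroma` / `hw_chroma` latent
#' (they are computed from the same cone catches in real data and are
#' near-collinear, Pearson r > 0.99), which is what forces the downstream
#' regression to include only one of them.
#' @keywords internal
cohort_latents <- function() {
  c("fw_luminance", "fw_chroma", "fw_chromatic_contrast",
    "fw_luminance_contrast", "fw_spot_area",
    "hw_luminance", "hw_chroma", "hw_chromatic_contrast",
    "hw_luminance_contrast")
}

#' @keywords internal
cohort_metrics <- function() {
  c("fw_luminance", "fw_saturation", "fw_hue", "fw_chromatic_contrast",
    "fw_luminance_contrast", "fw_rel_spot_area",
    "hw_luminance", "hw_saturation", "hw_hue", "hw_chromatic_contrast",
    "hw_luminance_contrast")
}

# metric = location + scale * latent_z (+ tiny metric-specific jitter for
# the two chroma-derived metrics, so their correlation is high but not 1)
metric_maps <- function() {
  list(
    fw_luminance          = list(latent = "fw_luminance", loc = 0.120, scale = 0.015),
    fw_saturation         = list(latent = "fw_chroma", loc = 0.42, scale = 0.030, jitter = 0.002),
    fw_hue                = list(latent = "fw_chroma", loc = 2.60, scale = 0.250, jitter = 0.015),
    fw_chromatic_contrast = list(latent = "fw_chromatic_contrast", loc = 8.0, scale = 1.0),
    fw_luminance_contrast = list(latent = "fw_luminance_contrast", loc = 9.0, scale = 1.2),
    fw_rel_spot_area      = list(latent = "fw_spot_area", loc = 0.22, scale = 0.025),
    hw_luminance          = list(latent = "hw_luminance", loc = 0.150, scale = 0.018),
    hw_saturation         = list(latent = "hw_chroma", loc = 0.45, scale = 0.030, jitter = 0.002),
    hw_hue                = list(latent = "hw_chroma", loc = 2.80, scale = 0.260, jitter = 0.015),
    hw_chromatic_contrast = list(latent = "hw_chromatic_contrast", loc = 7.5, scale = 1.0),
    hw_luminance_contrast = list(latent = "hw_luminance_contrast", loc = 8.5, scale = 1.1)
  )
}

#' Default sexual-dimorphism offsets
#'
#' Latent-scale offsets (male minus female, in residual SD units) matching
#' the dimorphism directions reported for burnet moths: males redder, more
#' saturated, and more chromatically contrasting; females with larger
#' relative spot area and lighter hindwings; no forewing luminance
#' dimorphism.
#'
#' @return Named numeric vector over the latents.
#' @export
default_sex_effects <- function() {
  c(fw_luminance = 0, fw_chroma = 0.8, fw_chromatic_contrast = 0.8,
    fw_luminance_contrast = 0.3, fw_spot_area = -0.8,
    hw_luminance = -0.8, hw_chroma = 0.8, hw_chromatic_contrast = 0.4,
    hw_luminance_contrast = 0.2)
}

#' Scenario configuration for cohort simulation
#'
#' Defines the study conditions under which specimen cohorts are drawn:
#' cohort structure, the color-toxin relationship (honest, null, or
#' dishonest), sexual dimorphism, and measurement noise. Defaults mirror a
#' field study of burnet moths: three populations with around 24 specimens
#' each, females heavier than males, toxin concentration log-normally
#' distributed, and no color-toxin relationship (`honesty_slope = 0`).
#'
#' @param n_populations Number of populations (>= 1).
#' @param n_per_pop_per_sex Specimens per population per sex (>= 1).
#' @param honesty_slope Standardized effect of (log) toxin concentration on
#'   the color latents: a scalar applied to every latent, or a named vector
#'   over [cohort_latents()]. Positive values make more-toxic specimens more
#'   colorful (honest); 0 is the null scenario; negative is dishonest.
#' @param sex_effects Named latent-scale offsets (male minus female); see
#'   [default_sex_effects()].
#' @param toxin_lognormal_params `c(mu, sigma)` of log concentration
#'   (nmol per mg fresh mass).
#' @param mass_params List with per-sex `c(mean, sd)` of body mass in mg;
#'   females are drawn larger by default.
#' @param noise_sd Residual SD of each latent (the measurement/individual
#'   noise against which effects are standardized).
#' @param pop_sd SD of population-level offsets on each latent.
#' @param seed Integer seed; a fixed seed makes the cohort byte-identical
#'   across runs.
#' @return A list of class `apo_scenario_config`.
#' @export
scenario_config <- function(n_populations = 3,
                            n_per_pop_per_sex = 12,
                            honesty_slope = 0,
                            sex_effects = default_sex_effects(),
                            toxin_lognormal_params = c(mu = log(20), sigma = 0.4),
                            mass_params = list(male = c(mean = 60, sd = 8),
                                               female = c(mean = 85, sd = 10)),
                            noise_sd = 1,
                            pop_sd = 0.3,
                            seed = 1L) {
  if (n_populations < 1 || n_per_pop_per_sex < 1) {
    stop("population and per-sex counts must be >= 1")
  }
  if (any(!is.finite(honesty_slope))) stop("honesty_slope must be finite")
  if (toxin_lognormal_params[["sigma"]] < 0 || noise_sd < 0 || pop_sd < 0) {
    stop("sigma and noise SDs must be non-negative")
  }
  slopes <- stats::setNames(rep(0, length(cohort_latents())), cohort_latents())
  if (is.null(names(honesty_slope))) {
    slopes[] <- honesty_slope
  } else {
    slopes[names(honesty_slope)] <- honesty_slope
  }
  sexes <- stats::setNames(rep(0, length(cohort_latents())), cohort_latents())
  sexes[names(sex_effects)] <- sex_effects
  structure(
    list(n_populations = n_populations,
         n_per_pop_per_sex = n_per_pop_per_sex,
         honesty_slope = slopes,
         sex_effects = sexes,
         toxin_lognormal_params = toxin_lognormal_params,
         mass_params = mass_params,
         noise_sd = noise_sd,
         pop_sd = pop_sd,
         seed = as.integer(seed)),
    class = "apo_scenario_config"
  )
}

#' Read a scenario configuration from YAML
#'
#' @param path YAML file; keys match the arguments of [scenario_config()].
#' @return An `apo_scenario_config`.
#' @export
read_scenario_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configs")
  }
  cfg <- yaml::read_yaml(path)
  do.call(scenario_config, lapply(cfg, function(x) {
    if (is.list(x) && !is.null(names(x)) &&
        all(vapply(x, is.numeric, logical(1))) &&
        all(lengths(x) == 1) && !any(names(x) %in% c("male", "female"))) {
      unlist(x)
    } else if (is.list(x) && all(names(x) %in% c("male", "female"))) {
      lapply(x, unlist)
    } else if (is.list(x)) unlist(x) else x
  }))
}

#' Simulate a specimen cohort with known ground truth
#'
#' Draws specimens (population, sex, mass, toxin concentration) and their
#' latent color metrics under the configured honesty scenario, and
#' optionally renders camera patches whose spectra are driven by the
#' latents. The returned ground-truth table is the reference for all
#' recovery tests: the honesty slope acts on standardized log
#' concentration, so under `honesty_slope = 0` every metric is independent
#' of toxin level by construction.
#'
#' @param config An `apo_scenario_config`.
#' @param render If `TRUE`, render forewing/hindwing red-marking and black
#'   background patches per specimen through the camera forward model
#'   (slower; disable for large statistical simulations).
#' @param camera,illum Camera and illuminant used when `render = TRUE`.
#' @param render_noise_sd Relative sensor noise for rendered patches.
#' @return A list of class `apo_cohort`: `specimens` (ground-truth data
#'   frame, one row per specimen), and if rendered, `patches` (named list
#'   per specimen of `apo_raw_patch` for fw_red, fw_black, hw_red,
#'   hw_black) and `areas` (per-specimen spot/wing areas in mm^2).
#' @export
make_cohort <- function(config = scenario_config(), render = FALSE,
                        camera = camera_system(),
                        illum = daylight_illuminant(),
                        render_noise_sd = 0.002) {
  stopifnot(inherits(config, "apo_scenario_config"))
  withr::with_seed(config$seed, {
    pops <- sprintf("pop_%02d", seq_len(config$n_populations))
    n <- config$n_populations * config$n_per_pop_per_sex * 2
    population <- rep(pops, each = config$n_per_pop_per_sex * 2)
    sex <- rep(rep(c("male", "female"), each = config$n_per_pop_per_sex),
               times = config$n_populations)
    mass_mg <- numeric(n)
    for (s in c("male", "female")) {
      idx <- sex == s
      mp <- config$mass_params[[s]]
      mass_mg[idx] <- pmax(stats::rnorm(sum(idx), mp[["mean"]], mp[["sd"]]), 1)
    }
    tp <- config$toxin_lognormal_params
    conc <- stats::rlnorm(n, tp[["mu"]], tp[["sigma"]])
    zc <- as.numeric(scale(log(conc)))

    latents <- cohort_latents()
    pop_fx <- matrix(stats::rnorm(length(pops) * length(latents), 0, config$pop_sd),
                     nrow = length(pops),
                     dimnames = list(pops, latents))
    z <- sapply(latents, function(lat) {
      pop_fx[population, lat] +
        config$sex_effects[[lat]] * (sex == "male") +
        config$honesty_slope[[lat]] * zc +
        stats::rnorm(n, 0, config$noise_sd)
    })

    specimens <- data.frame(
      specimen_id = sprintf("sp_%03d", seq_len(n)),
      population = population,
      sex = sex,
      mass_mg = mass_mg,
      concentration_nmol_per_mg = conc,
      total_amount_nmol = conc * mass_mg
    )
    for (m in names(metric_maps())) {
      mm <- metric_maps()[[m]]
      jit <- if (is.null(mm$jitter)) 0 else stats::rnorm(n, 0, mm$jitter)
      specimens[[m]] <- mm$loc + mm$scale * z[, mm$latent] + jit
    }
    specimens <- cbind(specimens,
                       stats::setNames(as.data.frame(z), paste0("latent_", latents)))

    out <- list(specimens = specimens, config = config)
    if (render) {
      clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
      seeds <- sample.int(2^30, n)
      wl <- wavelength_grid()
      patches <- vector("list", n)
      areas <- data.frame(specimen_id = specimens$specimen_id,
                          wing_area_mm2 = pmax(90 + 0.6 * (mass_mg - 70) +
                                                 stats::rnorm(n, 0, 4), 20))
      areas$spot_area_mm2 <- areas$wing_area_mm2 *
        clamp(0.22 + 0.025 * z[, "fw_spot_area"], 0.05, 0.5)
      for (i in seq_len(n)) {
        red_spec <- function(lum_z, chroma_z) {
          par <- list(base = 0.04,
                      amp = clamp(0.55 + 0.05 * lum_z, 0.3, 0.75),
                      edge = clamp(600 + 5 * chroma_z, 575, 625),
                      width = 15)
          spectrum(wl, pmax(template_value("red_marking", wl, par), 1e-4))
        }
        black_spec <- spectrum(wl, pmax(template_value(
          "black_scale", wl, list(base = 0.035, tilt = 0.015)), 1e-4))
        specs <- list(
          fw_red = red_spec(z[i, "fw_luminance"], z[i, "fw_chroma"]),
          fw_black = black_spec,
          hw_red = red_spec(z[i, "hw_luminance"], z[i, "hw_chroma"]),
          hw_black = black_spec
        )
        patches[[i]] <- lapply(seq_along(specs), function(j) {
          render_patch(specs[[j]], camera, illum,
                       gain_jitter = exp(stats::rnorm(1, 0, 0.05)),
                       noise_sd = render_noise_sd,
                       seed = (seeds[i] + j) %% 2^30,
                       area_mm2 = if (j == 1) areas$spot_area_mm2[i] else 5)
        })
        names(patches[[i]]) <- names(specs)
      }
      names(patches) <- specimens$specimen_id
      out$patches <- patches
      out$areas <- areas
    }
    out
  })
}
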