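#' Compound table for cyanogenic glucoside LC-MS
#'
#' Sodium-adduct m/z channels, retention times, chromatographic peak widths,
#' and instrument response factors (area units per nmol) for the two
#' defence compounds and the amygdalin internal standard. Response factors
#' are arbitrary instrument units; only ratios to the internal standard
#' matter for quantification.
#'
#' @return Data frame with columns compound, mz, rt_min, width_min,
#'   response_factor.
#' @export
lcms_compounds <- function() {
  data.frame(
    compound = c("linamarin", "lotaustralin", "amygdalin"),
    mz = c(270, 284, 480),
    rt_min = c(2.6, 5.5, 6.6),
    width_min = c(0.060, 0.080, 0.070),
    response_factor = c(1500, 1200, 1000)
  )
}

#' Simulate an LC-MS chromatogram
#'
#' Three extracted-ion traces (m/z 270, 284, 480) on a 0--17 min grid, with
#' Gaussian peaks at the compound retention times. Peak area is
#' amount x response factor x global drift; `area_cv` adds per-peak
#' multiplicative (injection/ionization) noise and `noise_sd` additive
#' baseline noise.
#'
#' @param amounts_nmol Named vector `c(linamarin = , lotaustralin = )` of
#'   analyte amounts in nmol (>= 0).
#' @param is_amount_nmol Internal-standard (amygdalin) amount in nmol.
#' @param drift Global multiplicative instrument drift (> 0).
#' @param noise_sd Additive baseline noise SD (intensity units).
#' @param area_cv Relative SD of per-peak multiplicative amplitude noise.
#' @param seed Integer seed.
#' @param specimen_id Optional label stored in the metadata.
#' @return An object of class `apo_chromatogram`: `time_min`, `traces`
#'   (matrix, columns mz270/mz284/mz480), and `meta`.
#' @export
make_chromatogram <- function(amounts_nmol, is_amount_nmol, drift = 1,
                              noise_sd = 0, area_cv = 0, seed = 1L,
                              specimen_id = NA_character_) {
  cmp <- lcms_compounds()
  amounts <- c(amounts_nmol[["linamarin"]], amounts_nmol[["lotaustralin"]],
               is_amount_nmol)
  if (any(amounts < 0)) stop("compound amounts must be non-negative")
  if (drift <= 0) stop("drift must be positive")
  time_min <- seq(0, 17, by = 0.005)
  withr::with_seed(seed, {
    traces <- vapply(seq_len(nrow(cmp)), function(i) {
      area <- amounts[i] * cmp$response_factor[i] * drift *
        (1 + stats::rnorm(1, 0, area_cv))
      amp <- area / (cmp$width_min[i] * sqrt(2 * pi))
      peak <- amp * exp(-0.5 * ((time_min - cmp$rt_min[i]) / cmp$width_min[i])^2)
      baseline <- 2 + stats::rnorm(length(time_min), 0, noise_sd)
      pmax(peak + baseline, 0)
    }, numeric(length(time_min)))
    colnames(traces) <- paste0("mz", cmp$mz)
    structure(
      list(time_min = time_min, traces = traces,
           meta = list(specimen_id = specimen_id,
                       is_amount_nmol = is_amount_nmol)),
      class = "apo_chromatogram"
    )
  })
}

#' Extract an ion-chromatogram segment
#'
#' The sub-trace of one m/z channel on
#' \[rt_center - window/2, rt_center + window/2\].
#'
#' @param chrom An `apo_chromatogram`.
#' @param mz m/z channel (270, 284, or 480).
#' @param rt_center_min Window center in minutes.
#' @param window_min Full window width in minutes.
#' @return Data frame with columns `time_min` and `intensity`.
#' @export
extract_eic <- function(chrom, mz, rt_center_min, window_min) {
  col <- paste0("mz", mz)
  if (!col %in% colnames(chrom$traces)) {
    stop(sprintf("m/z channel %s not present (have: %s)", mz,
                 paste(sub("mz", "", colnames(chrom$traces)), collapse = ", ")))
  }
  keep <- chrom$time_min >= rt_center_min - window_min / 2 &
    chrom$time_min <= rt_center_min + window_min / 2
  if (!any(keep)) stop("empty retention-time window")
  data.frame(time_min = chrom$time_min[keep],
             intensity = chrom$traces[keep, col])
}

#' Integrate a chromatographic peak
#'
#' Trapezoidal integral of the segment after subtracting the straight
#' baseline through its endpoints, floored at zero.
#'
#' @param segment Data frame from [extract_eic()].
#' @return Peak area (>= 0).
#' @export
integrate_peak <- function(segment) {
  n <- nrow(segment)
  if (n < 3) stop("segment too short to integrate (need >= 3 samples)")
  t <- segment$time_min
  y <- segment$intensity
  baseline <- y[1] + (y[n] - y[1]) * (t - t[1]) / (t[n] - t[1])
  max(pracma::trapz(t, y - baseline), 0)
}

#' Fit a calibration curve
#'
#' Ordinary least-squares line of analyte/internal-standard area ratio on
#' standard amount.
#'
#' @param standard_amounts_nmol Amounts of the dilution series (>= 3,
#'   spanning a positive range).
#' @param area_ratios Observed analyte/IS area ratios.
#' @param compound Compound label.
#' @return An object of class `apo_calibration`: `compound`, `slope`,
#'   `intercept`, `r_squared`.
#' @export
fit_calibration <- function(standard_amounts_nmol, area_ratios,
                            compound = NA_character_) {
  if (length(standard_amounts_nmol) < 3) stop("need at least 3 standards")
  if (stats::sd(standard_amounts_nmol) == 0) {
    stop("standard amounts have zero variance")
  }
  fit <- stats::lm(area_ratios ~ standard_amounts_nmol)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) stop("calibration slope must be positive")
  structure(
    list(compound = compound, slope = slope,
         intercept = unname(stats::coef(fit)[1]),
         r_squared = suppressWarnings(summary(fit)$r.squared)),
    class = "apo_calibration"
  )
}

peak_area_ratio <- function(chrom, compound, window_min = 0.6) {
  cmp <- lcms_compounds()
  row <- cmp[cmp$compound == compound, ]
  is_row <- cmp[cmp$compound == "amygdalin", ]
  area <- integrate_peak(extract_eic(chrom, row$mz, row$rt_min, window_min))
  is_area <- integrate_peak(extract_eic(chrom, is_row$mz, is_row$rt_min, window_min))
  if (is_area <= 0) stop("vanishing internal-standard peak: failed injection")
  area / is_area
}

#' Quantify a specimen's cyanogenic glucosides
#'
#' Computes EIC peak-area ratios to the amygdalin internal standard for
#' linamarin and lotaustralin, inverts the calibration curves, and derives
#' the total amount and concentration per mg body mass. The
#' internal-standard ratio cancels any whole-run multiplicative drift.
#'
#' @param chrom An `apo_chromatogram`.
#' @param curves Named list of `apo_calibration` objects (`linamarin`,
#'   `lotaustralin`).
#' @param mass_mg Specimen fresh mass in mg (> 0).
#' @param window_min Full integration-window width in minutes (default 0.6,
#'   i.e. +/- 0.3 min around each retention time).
#' @return List of class `apo_toxin_result`: per-compound amounts (nmol),
#'   `total_nmol`, and `concentration_nmol_per_mg`.
#' @export
quantify_specimen <- function(chrom, curves, mass_mg, window_min = 0.6) {
  if (mass_mg <= 0) stop("specimen mass must be positive")
  amounts <- vapply(c("linamarin", "lotaustralin"), function(compound) {
    ratio <- peak_area_ratio(chrom, compound, window_min)
    curve <- curves[[compound]]
    max((ratio - curve$intercept) / curve$slope, 0)
  }, numeric(1))
  total <- sum(amounts)
  structure(
    list(linamarin_nmol = amounts[["linamarin"]],
         lotaustralin_nmol = amounts[["lotaustralin"]],
         total_nmol = total,
         concentration_nmol_per_mg = total / mass_mg),
    class = "apo_toxin_result"
  )
}

#' Build calibration curves from a simulated dilution series
#'
#' Renders standard chromatograms at the given amounts (each spiked with
#' the same internal-standard amount) and fits per-compound calibration
#' curves from their measured area ratios.
#'
#' @param standard_amounts_nmol Dilution-series amounts (applied to both
#'   analytes).
#' @param is_amount_nmol Internal-standard amount per injection.
#' @param noise_sd,area_cv,seed Passed to [make_chromatogram()].
#' @return Named list of `apo_calibration` objects.
#' @export
simulate_calibration_curves <- function(standard_amounts_nmol = c(1, 2, 5, 10, 20),
                                        is_amount_nmol = 10,
                                        noise_sd = 0, area_cv = 0, seed = 1L) {
  chroms <- lapply(seq_along(standard_amounts_nmol), function(i) {
    make_chromatogram(
      c(linamarin = standard_amounts_nmol[i],
        lotaustralin = standard_amounts_nmol[i]),
      is_amount_nmol, noise_sd = noise_sd, area_cv = area_cv,
      seed = seed + i
    )
  })
  out <- lapply(c("linamarin", "lotaustralin"), function(compound) {
    ratios <- vapply(chroms, peak_area_ratio, numeric(1), compound = compound)
    fit_calibration(standard_amounts_nmol, ratios, compound)
  })
  stats::setNames(out, c("linamarin", "lotaustralin"))
}

#' Write / read chromatograms as long-form CSV
#'
#' Columns: `time_min`, `mz_channel`, `intensity`.
#'
#' @param chrom An `apo_chromatogram`.
#' @param path CSV path.
#' @return `path` invisibly (write); an `apo_chromatogram` (read).
#' @export
write_chromatogram_csv <- function(chrom, path) {
  mz <- as.integer(sub("mz", "", colnames(chrom$traces)))
  long <- do.call(rbind, lapply(seq_along(mz), function(j) {
    data.frame(time_min = chrom$time_min, mz_channel = mz[j],
               intensity = chrom$traces[, j])
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chromatogram_csv
#' @export
read_chromatogram_csv <- function(path) {
  long <- utils::read.csv(path)
  channels <- sort(unique(long$mz_channel))
  time_min <- sort(unique(long$time_min))
  traces <- vapply(channels, function(ch) {
    d <- long[long$mz_channel == ch, ]
    d$intensity[order(d$time_min)]
  }, numeric(length(time_min)))
  colnames(traces) <- paste0("mz", channels)
  structure(list(time_min = time_min, traces = traces, meta = list()),
            class = "apo_chromatogram")
}
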