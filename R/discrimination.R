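#' Receptor noise from relative cone abundances
#'
#' Noise in each receptor channel scales inversely with the square root of
#' its relative abundance: e_i = omega * sqrt(eta_max / eta_i), so the most
#' abundant cone has e equal to the Weber fraction.
#'
#' @param system An `apo_visual_system`, or a named positive abundance
#'   vector.
#' @param omega Weber fraction (used only when `system` is a bare vector).
#' @return Named per-receptor noise values.
#' @export
receptor_noise <- function(system, omega = 0.05) {
  if (inherits(system, "apo_visual_system")) {
    eta <- system$abundances
    omega <- system$weber_omega
  } else {
    eta <- system
  }
  if (any(eta <= 0)) stop("cone abundances must be positive")
  omega * sqrt(max(eta) / eta)
}

#' Receptor-noise-limited distance on log catch differences
#'
#' The generalized noise-limited color distance for any number of
#' receptors: the weighted distance of the log-catch difference vector from
#' the achromatic (all-equal) direction,
#' \deqn{\Delta S^2 = \min_c \sum_i \left(\frac{\Delta f_i - c}{e_i}\right)^2,}
#' which for two receptors reduces to the familiar dichromat form
#' |df1 - df2| / sqrt(e1^2 + e2^2) and for four receptors equals the
#' published tetrachromat formula.
#'
#' @param delta_f Numeric vector of log catch differences, one per receptor.
#' @param e Per-receptor noise values (same length).
#' @return Distance in just-noticeable differences (JND).
#' @export
rnl_distance <- function(delta_f, e) {
  if (length(delta_f) != length(e) || length(e) < 2) {
    stop("delta_f and e must have equal length >= 2")
  }
  if (any(e <= 0)) stop("receptor noise values must be positive")
  w <- 1 / e^2
  center <- sum(w * delta_f) / sum(w)
  sqrt(sum(w * (delta_f - center)^2))
}

#' Chromatic contrast in JND
#'
#' Log version of the receptor-noise-limited color discrimination model for
#' a tetrachromat: log catch ratios per single cone combined with
#' abundance-derived receptor noise. Symmetric in its two arguments; zero
#' exactly when the two patches differ only by a common (achromatic)
#' factor. Values below 1 JND predict indiscriminable colors.
#'
#' @param catch_a,catch_b `apo_cone_catch` objects or named (u, s, m, l)
#'   vectors of positive catches.
#' @param system An `apo_visual_system`.
#' @return Chromatic contrast in JND.
#' @export
chromatic_jnd <- function(catch_a, catch_b, system) {
  qa <- if (inherits(catch_a, "apo_cone_catch")) catch_a$q else as.numeric(catch_a)
  qb <- if (inherits(catch_b, "apo_cone_catch")) catch_b$q else as.numeric(catch_b)
  if (any(qa <= 0) || any(qb <= 0)) {
    stop("zero cone catch: apply the mapping clip floor before log-ratio contrasts")
  }
  rnl_distance(log(qa / qb), receptor_noise(system))
}

#' Luminance contrast in JND
#'
#' Absolute natural-log ratio of the double-cone catches, divided by the
#' Weber fraction. The absolute value makes the contrast symmetric in its
#' arguments.
#'
#' @param double_a,double_b Positive double-cone catches.
#' @param omega Weber fraction (default 0.05).
#' @return Luminance contrast in JND.
#' @export
luminance_jnd <- function(double_a, double_b, omega = 0.05) {
  if (any(double_a <= 0) || any(double_b <= 0) || omega <= 0) {
    stop("double-cone catches and omega must be positive")
  }
  abs(log(double_a / double_b)) / omega
}

#' Conspicuousness of wing markings against plant backgrounds
#'
#' Plant catches are first averaged per plant type (a single color per
#' plant species and tissue type), then chromatic and luminance JNDs are
#' computed between each specimen's marking and each plant-type average.
#'
#' @param specimen_patches Data frame with columns `specimen_id`, `u`, `s`,
#'   `m`, `l`, `double` (marking catches, one row per specimen).
#' @param plant_patches Data frame with columns `plant_type`, `u`, `s`, `m`,
#'   `l`, `double` (one row per measured plant patch).
#' @param system An `apo_visual_system`.
#' @return Data frame, one row per specimen x plant type, with
#'   `chromatic_jnd` and `luminance_jnd`.
#' @export
background_conspicuousness <- function(specimen_patches, plant_patches, system) {
  if (nrow(plant_patches) == 0) stop("no plant patches supplied")
  cols <- c("u", "s", "m", "l", "double")
  plant_means <- do.call(rbind, lapply(
    split(plant_patches, plant_patches$plant_type),
    function(d) {
      if (nrow(d) == 0) stop("empty plant group")
      cbind(data.frame(plant_type = d$plant_type[1]),
            as.data.frame(t(colMeans(d[, cols]))))
    }
  ))
  out <- do.call(rbind, lapply(seq_len(nrow(specimen_patches)), function(i) {
    sp <- specimen_patches[i, ]
    do.call(rbind, lapply(seq_len(nrow(plant_means)), function(j) {
      pl <- plant_means[j, ]
      data.frame(
        specimen_id = sp$specimen_id,
        plant_type = pl$plant_type,
        chromatic_jnd = chromatic_jnd(unlist(sp[c("u", "s", "m", "l")]),
                                      unlist(pl[c("u", "s", "m", "l")]), system),
        luminance_jnd = luminance_jnd(sp$double, pl$double, system$weber_omega)
      )
    }))
  }))
  rownames(out) <- NULL
  out
}
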