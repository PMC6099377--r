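#' Standardize cone catches to proportions
#'
#' Divides each single-cone catch by the sum over the four single cones, so
#' the result sums to 1. These proportions are the coordinates used in the
#' tetrahedral color space and in the hue ratio.
#'
#' @param catch An `apo_cone_catch`, or a named (u, s, m, l) numeric vector.
#' @return Named numeric vector (u, s, m, l) summing to 1.
#' @export
standardize_catches <- function(catch) {
  q <- if (inherits(catch, "apo_cone_catch")) catch$q else
    stats::setNames(as.numeric(catch), c("u", "s", "m", "l"))
  total <- sum(q)
  if (!is.finite(total) || total <= 0) stop("cone catches sum to zero")
  q / total
}

# Regular tetrahedron, centroid at origin, unit centroid-to-vertex distance.
# Rows: u, s, m, l vertices. Any regular-tetrahedron convention agrees with
# this one up to a positive scale, which cannot affect correlations or
# regressions downstream.
tetra_vertices <- function() {
  rbind(
    u = c(0, 0, 1),
    s = c(2 * sqrt(2) / 3, 0, -1 / 3),
    m = c(-sqrt(2) / 3, sqrt(6) / 3, -1 / 3),
    l = c(-sqrt(2) / 3, -sqrt(6) / 3, -1 / 3)
  )
}

check_relative_catches <- function(rel) {
  rel <- stats::setNames(as.numeric(rel), c("u", "s", "m", "l"))
  if (any(!is.finite(rel)) || any(rel < 0) || abs(sum(rel) - 1) > 1e-9) {
    stop("relative catches must be non-negative and sum to 1")
  }
  rel
}

#' Tetrahedral-colorspace saturation
#'
#' Position of a color in the regular tetrahedron whose vertices are the
#' four cone classes (centroid at origin, unit centroid-to-vertex distance),
#' as the abundance-weighted vertex sum; saturation is the Euclidean
#' distance from the achromatic center, in \[0, 1\].
#'
#' @param rel Relative catches from [standardize_catches()].
#' @return Saturation (scalar).
#' @export
tetra_saturation <- function(rel) {
  rel <- check_relative_catches(rel)
  sqrt(sum((rel %*% tetra_vertices())^2))
}

#' Long-wavelength hue channel
#'
#' Ratio of the relative LW catch to the mean of the other three channels:
#' hue = l / ((u + s + m) / 3). High values correspond to colors with
#' relatively greater long-wavelength reflectance, i.e. redder colors. The
#' achromatic point gives hue = 1.
#'
#' @param rel Relative catches from [standardize_catches()].
#' @return Hue (positive scalar).
#' @export
hue_channel <- function(rel) {
  rel <- check_relative_catches(rel)
  denom <- (rel[["u"]] + rel[["s"]] + rel[["m"]]) / 3
  if (denom <= 0) stop("degenerate pure-LW color: u = s = m = 0")
  rel[["l"]] / denom
}

#' First principal component of an ensemble of relative catches
#'
#' Eigen-decomposition of the 4x4 covariance matrix of relative catches
#' across patches. Used to justify a one-dimensional color channel: when one
#' axis of variation dominates (variance share near 1), a single ratio of
#' cone catches summarizes color variation. The loading sign is fixed so
#' that the LW loading is non-negative.
#'
#' @param catch_table Matrix or data frame of relative catches, columns
#'   u, s, m, l, one row per patch (>= 3 rows).
#' @return List with `loadings` (named length-4 vector) and
#'   `variance_proportion`.
#' @export
pca_first_component <- function(catch_table) {
  X <- as.matrix(catch_table)[, c("u", "s", "m", "l")]
  if (nrow(X) < 3) stop("need at least 3 patches for a covariance PCA")
  V <- stats::cov(X)
  if (all(abs(V) < 1e-14)) stop("constant ensemble: zero covariance matrix")
  eig <- eigen(V, symmetric = TRUE)
  pc1 <- eig$vectors[, 1]
  if (pc1[4] < 0) pc1 <- -pc1
  list(loadings = stats::setNames(pc1, c("u", "s", "m", "l")),
       variance_proportion = eig$values[1] / sum(eig$values))
}

#' Relative spot area
#'
#' Total red spot area as a proportion of total wing area.
#'
#' @param spot_areas_mm2 Numeric vector of individual spot areas (may be
#'   empty).
#' @param wing_area_mm2 Total wing area (> 0).
#' @return Proportion in \[0, 1\].
#' @export
relative_spot_area <- function(spot_areas_mm2, wing_area_mm2) {
  if (wing_area_mm2 <= 0) stop("wing area must be positive")
  if (any(spot_areas_mm2 < 0)) stop("spot areas must be non-negative")
  total <- sum(spot_areas_mm2)
  if (total > wing_area_mm2 + 1e-12) {
    stop("spot areas exceed the wing area")
  }
  total / wing_area_mm2
}

#' Per-patch color metrics
#'
#' Convenience wrapper computing the three catch-based metrics for one
#' patch: luminance (the double-cone catch, on the normalized scale where a
#' perfect white is 1), tetrahedral saturation, and the LW hue ratio.
#'
#' @param catch An `apo_cone_catch`.
#' @return Named numeric vector (luminance, saturation, hue).
#' @export
color_metrics <- function(catch) {
  rel <- standardize_catches(catch)
  c(luminance = catch$double,
    saturation = tetra_saturation(rel),
    hue = hue_channel(rel))
}
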