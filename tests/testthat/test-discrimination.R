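uvs <- visual_system("uvs")
illum <- daylight_illuminant()

test_that("receptor noise follows the abundance square-root law", {
  e <- receptor_noise(uvs)
  expect_equal(e[["l"]], 0.05)                      # most abundant cone
  expect_equal(e[["u"]], 0.05 * sqrt(2.7 / 1), tolerance = 1e-12)
  expect_equal(e[["u"]], 0.0822, tolerance = 1e-3)  # hand evaluation
  expect_equal(unname(receptor_noise(c(a = 2, b = 2, c = 2), omega = 0.1)),
               rep(0.1, 3))
  expect_error(receptor_noise(c(a = -1, b = 2)), "positive")
})

test_that("chromatic contrast vanishes for identical and achromatic pairs", {
  q <- cone_catch(c(0.1, 0.2, 0.3, 0.4), 0.5)
  expect_equal(chromatic_jnd(q, q, uvs), 0)
  q_scaled <- cone_catch(3.7 * q$q, 0.5)
  expect_equal(chromatic_jnd(q, q_scaled, uvs), 0, tolerance = 1e-12)
  expect_error(chromatic_jnd(cone_catch(c(1e-12, 1, 1, 1), 1), q, uvs), NA)
  expect_error(
    chromatic_jnd(c(0, 1, 1, 1), c(1, 1, 1, 1), uvs),
    "clipping floor|zero cone catch"
  )
})

test_that("a UV-only log-ratio shift matches the brute-force tetrachromat formula", {
  e <- receptor_noise(uvs)
  qa <- c(0.2 * exp(0.1), 0.2, 0.2, 0.2)
  qb <- c(0.2, 0.2, 0.2, 0.2)
  expect_equal(chromatic_jnd(qa, qb, uvs), oracle_tetra_jnd(qa, qb, e),
               tolerance = 1e-12)
})

test_that("the general distance reduces to the dichromat closed form", {
  e <- c(0.05, 0.08)
  df <- c(0.3, -0.1)
  expect_equal(rnl_distance(df, e), abs(df[1] - df[2]) / sqrt(sum(e^2)),
               tolerance = 1e-12)
  # 4-receptor version with two receptors drowned in noise behaves dichromatically
  e4 <- c(0.05, 0.08, 1e6, 1e6)
  df4 <- c(0.3, -0.1, 0.25, -0.4)
  expect_equal(rnl_distance(df4, e4), abs(df4[1] - df4[2]) / sqrt(sum(e[1:2]^2)),
               tolerance = 1e-6)
})

test_that("chromatic JND is a symmetric pseudo-metric obeying the triangle inequality", {
  e <- receptor_noise(uvs)
  withr::with_seed(17, {
    for (i in 1:50) {
      qa <- runif(4, 0.01, 1); qb <- runif(4, 0.01, 1); qc <- runif(4, 0.01, 1)
      dab <- chromatic_jnd(qa, qb, uvs)
      dba <- chromatic_jnd(qb, qa, uvs)
      expect_gte(dab, 0)
      expect_equal(dab, dba, tolerance = 1e-12)
      expect_lte(dab, chromatic_jnd(qa, qc, uvs) + chromatic_jnd(qc, qb, uvs) + 1e-12)
    }
  })
})

test_that("moving one channel away from the others' center never decreases contrast", {
  e <- receptor_noise(uvs)
  base_df <- c(0.05, -0.1, 0.2, 0)
  w <- 1 / e^2
  for (ch in 1:4) {
    center_others <- sum(w[-ch] * base_df[-ch]) / sum(w[-ch])
    prev <- -Inf
    for (extra in seq(0, 1, by = 0.1)) {
      df <- base_df
      df[ch] <- center_others + extra
      cur <- rnl_distance(df, e)
      expect_gte(cur, prev - 1e-12)
      prev <- cur
    }
  }
})

test_that("luminance contrast is the log double-cone ratio over the Weber fraction", {
  expect_equal(luminance_jnd(1, 1), 0)
  expect_equal(luminance_jnd(2, 1, omega = 0.05), log(2) / 0.05, tolerance = 1e-12)
  expect_equal(luminance_jnd(2, 1), luminance_jnd(1, 2))
  expect_error(luminance_jnd(0, 1), "positive")
})

test_that("plant-background conspicuousness averages plants before contrasting", {
  specimens <- data.frame(specimen_id = c("a", "b"),
                          u = c(0.05, 0.06), s = c(0.06, 0.07),
                          m = c(0.07, 0.08), l = c(0.3, 0.35),
                          double = c(0.2, 0.25))
  plants <- data.frame(
    plant_type = rep(c("leaf", "flower"), each = 3),
    u = rep(c(0.08, 0.2), each = 3) + rep(c(-0.01, 0, 0.01), 2),
    s = rep(c(0.1, 0.25), each = 3),
    m = rep(c(0.25, 0.3), each = 3),
    l = rep(c(0.12, 0.4), each = 3),
    double = rep(c(0.3, 0.5), each = 3)
  )
  out <- background_conspicuousness(specimens, plants, uvs)
  expect_equal(nrow(out), 2 * 2)
  expect_true(all(out$chromatic_jnd >= 0))
  # marking identical to a plant-type average contrasts at exactly zero
  leaf_mean <- colMeans(plants[plants$plant_type == "leaf",
                               c("u", "s", "m", "l", "double")])
  same <- data.frame(specimen_id = "z", t(leaf_mean))
  out2 <- background_conspicuousness(same, plants, uvs)
  expect_equal(out2$chromatic_jnd[out2$plant_type == "leaf"], 0, tolerance = 1e-12)
  expect_equal(out2$luminance_jnd[out2$plant_type == "leaf"], 0, tolerance = 1e-12)
})

test_that("red markings are chromatically conspicuous against leaves", {
  camera <- camera_system()
  red <- cone_catch_from_spectrum(
    make_reflectance_library(1, "red_marking", seed = 3)[[1]], illum, uvs)
  leaf <- cone_catch_from_spectrum(
    make_reflectance_library(1, "green_leaf", seed = 3)[[1]], illum, uvs)
  expect_gt(chromatic_jnd(red, leaf, uvs), 1)
})
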