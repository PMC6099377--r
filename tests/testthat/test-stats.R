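test_that("a perfect linear relationship gives adjusted R-squared 1 and tiny p", {
  d <- data.frame(x = 1:10)
  d$y <- 2 + 3 * d$x
  r <- ols_with_f_tests(y ~ x, d)
  expect_lt(r$p, 1e-12)
  expect_equal(r$r_squared_adj, 1, tolerance = 1e-9)
  expect_equal(unname(r$df), c(1, 8))
})

test_that("the F test agrees with a brute-force permutation reference", {
  d <- withr::with_seed(3, data.frame(x = rnorm(12)))
  d$y <- withr::with_seed(4, 0.5 * d$x + rnorm(12))
  r <- ols_with_f_tests(y ~ x, d)
  r2_obs <- cor(d$x, d$y)^2
  r2_perm <- withr::with_seed(5, replicate(1e5, cor(d$x, sample(d$y))^2))
  p_perm <- mean(r2_perm >= r2_obs)
  expect_equal(r$p, p_perm, tolerance = 0.02)
  # F consistent with its own r^2 identity
  expect_equal(r$F, 10 * r2_obs / (1 - r2_obs), tolerance = 1e-9)
})

test_that("among-population regression finds a strong population-level slope", {
  cfg <- scenario_config(n_populations = 12, n_per_pop_per_sex = 20,
                         honesty_slope = 1.0, pop_sd = 0.1, seed = 41)
  d <- make_cohort(cfg)$specimens
  r <- among_population_regression(d, "fw_luminance", "female")
  expect_gt(r$coefficients["conc_mean", "Estimate"], 0)
  expect_lt(r$p, 0.05)
  expect_error(among_population_regression(d[d$population %in% c("pop_01", "pop_02"), ],
                                           "fw_luminance", "female"),
               "at least 3 populations")
})

test_that("per-sex among-population runs use disjoint specimen subsets", {
  d <- make_null_specimens(seed = 2)
  ids_m <- d$specimen_id[d$sex == "male"]
  ids_f <- d$specimen_id[d$sex == "female"]
  expect_length(intersect(ids_m, ids_f), 0)
  expect_setequal(c(ids_m, ids_f), d$specimen_id)
})

test_that("stepwise regression retains a driving predictor with high power", {
  n_rep <- 500
  kept_lum <- logical(n_rep)
  kept_null <- logical(n_rep)
  sign_ok <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    cfg <- scenario_config(n_populations = 1, n_per_pop_per_sex = 13,
                           honesty_slope = c(fw_luminance = 0.8),
                           seed = 5000 + i)
    d <- make_cohort(cfg)$specimens
    sw <- within_population_regression(d, "saturation", "fw")
    kept_lum[i] <- "fw_luminance" %in% sw$minimal$terms
    kept_null[i] <- length(setdiff(sw$minimal$terms, "fw_luminance")) > 0
    sign_ok[i] <-
      sw$full$coefficients["fw_luminance", "Estimate"] > 0
  }
  # theoretical retention power at standardized slope 0.8, n = 26 is ~0.97;
  # each of the 4 null predictors is retained at ~alpha
  expect_gte(mean(kept_lum), 0.90)
  expect_lte(mean(kept_null), 0.30)
  expect_gte(mean(sign_ok), 0.95)
})

test_that("offering saturation and hue together is rejected as collinear", {
  d <- make_null_specimens(seed = 3)
  expect_error(
    within_population_regression(d[d$population == "pop_01", ], "both", "fw"),
    "collinear"
  )
})

test_that("gross outliers are flagged by Cook's distance and refit without them", {
  cfg <- scenario_config(n_populations = 1, n_per_pop_per_sex = 13,
                         honesty_slope = c(fw_luminance = 0.9), seed = 77)
  d <- make_cohort(cfg)$specimens
  # a gross outlier: brightest marking in the sample, toxin level 10-fold low
  d$fw_luminance[5] <- max(d$fw_luminance) + 3 * sd(d$fw_luminance)
  d$concentration_nmol_per_mg[5] <- d$concentration_nmol_per_mg[5] * 0.1
  sw <- within_population_regression(d, "saturation", "fw")
  expect_true(d$specimen_id[5] %in% sw$outliers)
  expect_false(is.null(sw$minimal_without_outliers))
  expect_identical(sw$minimal_without_outliers$excluded_outliers, sw$outliers)
  # flagged distances agree with the definition of Cook's distance
  cooks_ref <- oracle_cooks(sw$full$fit)
  expect_equal(unname(sw$cooks_distance), unname(cooks_ref), tolerance = 1e-9)
  expect_gt(cooks_ref[5], 1)
})

test_that("a strong sex offset is detected by the dimorphism model", {
  cfg <- scenario_config(n_populations = 3, n_per_pop_per_sex = 20,
                         sex_effects = c(fw_chroma = 2), seed = 51)
  d <- make_cohort(cfg)$specimens
  dm <- dimorphism_model(d, "fw_saturation")
  expect_lt(dm$anova_table$p[dm$anova_table$term == "sex"], 0.001)
  expect_equal(nrow(dm$tukey), 3)
  expect_error(dimorphism_model(d[d$sex == "male", ], "fw_saturation"),
               "both sexes")
})

test_that("balanced two-group Tukey matches a pooled t test up to range scaling", {
  cfg <- scenario_config(n_populations = 2, n_per_pop_per_sex = 15, seed = 61)
  d <- make_cohort(cfg)$specimens
  dm <- dimorphism_model(d, "hw_luminance")
  fit <- stats::lm(hw_luminance ~ sex + population, data = d)
  tstat <- summary(fit)$coefficients["populationpop_02", "t value"]
  p_t <- 2 * stats::pt(abs(tstat), fit$df.residual, lower.tail = FALSE)
  expect_equal(dm$tukey$p_adj, p_t, tolerance = 1e-6)
})

test_that("stepwise elimination is order-independent for orthogonal predictors", {
  withr::with_seed(71, {
    X <- qr.Q(qr(matrix(rnorm(40 * 4), ncol = 4)))
    colnames(X) <- paste0("p", 1:4)
    d <- data.frame(X)
    d$y <- 1 + 2 * d$p1 + 1.5 * d$p3 + rnorm(40, 0, 0.3)
    sel <- lapply(list(c(1, 2, 3, 4), c(4, 3, 2, 1), c(2, 4, 1, 3)), function(ord) {
      fit <- stats::lm(stats::reformulate(colnames(X)[ord], "y"), data = d)
      sort(attr(stats::terms(aposignal:::backward_eliminate(fit, d)),
                "term.labels"))
    })
    expect_identical(sel[[1]], sel[[2]])
    expect_identical(sel[[1]], sel[[3]])
  })
})

make_plant_table <- function(d, sigma_u = 0, plant_fx = c(0, 3, 4), sd = 1,
                             seed = 1) {
  withr::with_seed(seed, {
    u <- stats::rnorm(nrow(d), 0, sigma_u)
    pj <- expand.grid(specimen_id = d$specimen_id,
                      plant_type = c("leaf", "flower_lotus", "flower_knautia"),
                      stringsAsFactors = FALSE)
    pj <- merge(pj, d[, c("specimen_id", "sex", "population")])
    idx <- match(pj$specimen_id, d$specimen_id)
    fx <- plant_fx[match(pj$plant_type, c("leaf", "flower_lotus", "flower_knautia"))]
    pj$chromatic_jnd <- 10 + fx + u[idx] + stats::rnorm(nrow(pj), 0, sd)
    pj$luminance_jnd <- abs(5 + fx + u[idx] + stats::rnorm(nrow(pj), 0, sd))
    pj
  })
}

test_that("with no between-individual variance the mixed model collapses to OLS", {
  d <- make_null_specimens(n_per_cell = 10, seed = 81)
  pj <- make_plant_table(d, sigma_u = 0, seed = 2)
  mm <- plant_contrast_mixed_model(pj, "chromatic")
  ols <- stats::lm(chromatic_jnd ~ sex + population + plant_type, data = pj)
  expect_equal(unname(lme4::fixef(mm$fit)), unname(stats::coef(ols)),
               tolerance = 1e-6)
  # likelihood-ratio statistic for the random intercept is essentially zero
  lrt <- 2 * (as.numeric(stats::logLik(mm$fit)) - as.numeric(stats::logLik(ols)))
  expect_lt(abs(lrt), 1)
})

test_that("plant-type effects are detected by the likelihood-ratio test", {
  d <- make_null_specimens(n_per_cell = 5, seed = 82) # 30 specimens
  pj <- make_plant_table(d, sigma_u = 1, plant_fx = c(0, 3, 4), seed = 3)
  mm <- plant_contrast_mixed_model(pj, "chromatic")
  fx <- mm$fixed_effects
  expect_lt(fx$p[fx$term == "plant_type"], 0.001)
  expect_equal(nrow(mm$tukey_plant), 3)
  mm_l <- plant_contrast_mixed_model(pj, "luminance")
  expect_lt(mm_l$fixed_effects$p[mm_l$fixed_effects$term == "plant_type"], 0.001)
})

test_that("the random-intercept variance is recovered across replicates", {
  d <- make_null_specimens(n_per_cell = 17, seed = 83) # ~100 specimens
  vars <- sapply(1:200, function(i) {
    pj <- make_plant_table(d, sigma_u = 1, seed = 100 + i)
    mm <- plant_contrast_mixed_model(pj, "chromatic")
    unname(lme4::VarCorr(mm$fit)$specimen_id[1])
  })
  expect_lt(abs(median(vars) - 1), 0.2)
})

test_that("single observations per individual are rejected with advice", {
  d <- make_null_specimens(n_per_cell = 5, seed = 84)
  pj <- make_plant_table(d, seed = 4)
  pj <- pj[pj$plant_type == "leaf", ]
  expect_error(plant_contrast_mixed_model(pj, "chromatic"), "fixed-effects")
})
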