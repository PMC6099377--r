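#' Run the full simulation-to-analysis pipeline
#'
#' End-to-end driver reproducing the structure of a wing-coloration honesty
#' study on synthetic data: simulate a cohort and plant backgrounds, render
#' and calibrate camera patches, fit and apply the camera-to-cone-catch
#' mapping, compute per-specimen color metrics and internal contrasts,
#' compute conspicuousness against plant backgrounds, simulate and quantify
#' LC-MS chromatograms, and run the statistical analyses. All results are
#' written as CSV files under `out_dir`; given a fixed seed the output
#' files are byte-identical across runs.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer master seed.
#' @param config Scenario configuration; defaults to the standard study
#'   conditions with the seed substituted.
#' @param system Visual system to analyze (`"uvs"` or `"vs"`).
#' @param n_training_spectra Spectra per family for the mapping library.
#' @return Invisibly, a list with the in-memory tables and fitted objects.
#' @export
run_pipeline <- function(out_dir, seed = 1L, config = NULL,
                         system = c("uvs", "vs"), n_training_spectra = 35) {
  system <- match.arg(system)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config)) config <- scenario_config(seed = seed)
  camera <- camera_system()
  illum <- daylight_illuminant()
  vis <- visual_system(system)
  log_lines <- c(sprintf("seed: %d", seed),
                 sprintf("visual system: %s", vis$name))
  withr::with_seed(seed, {

  # -- simulate ------------------------------------------------------------
  cohort <- make_cohort(config, render = TRUE, camera = camera, illum = illum)
  specimens <- cohort$specimens

  # -- mapping library and fit --------------------------------------------
  library_spectra <- make_reflectance_library(n_training_spectra,
                                              seed = seed + 101L)
  mapping <- fit_catch_mapping(library_spectra, camera, illum, vis, degree = 2)
  log_lines <- c(log_lines, sprintf(
    "mapping held-out R^2: %s",
    paste(sprintf("%s=%.4f", names(mapping$r_squared), mapping$r_squared),
          collapse = " ")
  ))

  # -- calibrate and map every wing patch ---------------------------------
  measure_patch <- function(raw) {
    channels <- calibrate_patch(raw, exponent = "auto")
    suppressWarnings(apply_catch_mapping(mapping, channels))
  }
  catches <- lapply(cohort$patches, function(p) lapply(p, measure_patch))

  metrics <- do.call(rbind, lapply(specimens$specimen_id, function(id) {
    cc <- catches[[id]]
    m_red <- color_metrics(cc$fw_red)
    area_row <- cohort$areas[cohort$areas$specimen_id == id, ]
    data.frame(
      specimen_id = id,
      measured_fw_luminance = m_red[["luminance"]],
      measured_fw_saturation = m_red[["saturation"]],
      measured_fw_hue = m_red[["hue"]],
      measured_fw_chromatic_jnd = chromatic_jnd(cc$fw_red, cc$fw_black, vis),
      measured_fw_luminance_jnd = luminance_jnd(cc$fw_red$double,
                                                cc$fw_black$double,
                                                vis$weber_omega),
      measured_fw_rel_spot_area = relative_spot_area(area_row$spot_area_mm2,
                                                     area_row$wing_area_mm2)
    )
  }))

  # PCA diagnostic over all measured red/black patches
  rel_table <- do.call(rbind, lapply(catches, function(cc) {
    rbind(standardize_catches(cc$fw_red), standardize_catches(cc$fw_black))
  }))
  pca <- pca_first_component(rel_table)
  log_lines <- c(log_lines, sprintf("PC1 variance share: %.4f",
                                    pca$variance_proportion))

  # -- plant backgrounds ---------------------------------------------------
  plant_families <- c(leaf = "green_leaf", flower_lotus = "yellow_petal",
                      flower_knautia = "purple_petal")
  plant_lib <- make_reflectance_library(5, unname(plant_families),
                                        seed = seed + 202L)
  plant_patches <- do.call(rbind, lapply(names(plant_lib), function(id) {
    fam <- sub("_[0-9]+$", "", id)
    type <- names(plant_families)[match(fam, plant_families)]
    cc <- measure_patch(render_patch(plant_lib[[id]], camera, illum,
                                     noise_sd = 0.002,
                                     seed = seed + match(id, names(plant_lib))))
    data.frame(plant_type = type, t(cc$q), double = cc$double)
  }))
  specimen_catch_df <- do.call(rbind, lapply(specimens$specimen_id, function(id) {
    cc <- catches[[id]]$fw_red
    data.frame(specimen_id = id, t(cc$q), double = cc$double)
  }))
  plant_jnd <- background_conspicuousness(specimen_catch_df, plant_patches, vis)
  plant_jnd <- merge(plant_jnd,
                     specimens[, c("specimen_id", "sex", "population")],
                     by = "specimen_id", sort = TRUE)
  plant_jnd <- plant_jnd[order(plant_jnd$specimen_id, plant_jnd$plant_type), ]

  # -- LC-MS quantification ------------------------------------------------
  curves <- simulate_calibration_curves(seed = seed + 303L)
  lin_frac <- 0.7 # linamarin share of the cyanogenic glucoside pool
  toxins <- do.call(rbind, lapply(seq_len(nrow(specimens)), function(i) {
    truth <- specimens$total_amount_nmol[i]
    chrom <- make_chromatogram(
      c(linamarin = lin_frac * truth, lotaustralin = (1 - lin_frac) * truth),
      is_amount_nmol = 10,
      drift = exp(stats::rnorm(1, 0, 0.05)),
      area_cv = 0.01, seed = seed + 1000L + i
    )
    res <- quantify_specimen(chrom, curves, specimens$mass_mg[i])
    data.frame(specimen_id = specimens$specimen_id[i],
               linamarin_nmol = res$linamarin_nmol,
               lotaustralin_nmol = res$lotaustralin_nmol,
               total_nmol = res$total_nmol,
               concentration_nmol_per_mg = res$concentration_nmol_per_mg)
  }))

  # -- statistics ----------------------------------------------------------
  # honesty analyses use the LC-MS-measured concentration, end to end
  analysis_table <- specimens
  analysis_table$concentration_nmol_per_mg <- toxins$concentration_nmol_per_mg
  among <- do.call(rbind, lapply(c("male", "female"), function(sx) {
    do.call(rbind, lapply(cohort_metrics(), function(m) {
      r <- among_population_regression(analysis_table, m, sx)
      data.frame(sex = sx, metric = m, F = r$F, df1 = r$df[1], df2 = r$df[2],
                 p = r$p, r_squared_adj = r$r_squared_adj)
    }))
  }))
  within <- do.call(rbind, lapply(split(analysis_table, analysis_table$population),
    function(pop_records) {
      sw <- within_population_regression(pop_records, "saturation", "fw")
      data.frame(population = pop_records$population[1],
                 minimal_terms = paste(sw$minimal$terms, collapse = "+"),
                 F = sw$minimal$F, df1 = sw$minimal$df[1],
                 df2 = sw$minimal$df[2], p = sw$minimal$p,
                 r_squared_adj = sw$minimal$r_squared_adj,
                 n_outliers = length(sw$outliers))
    }))
  dimorphism <- do.call(rbind, lapply(
    c("fw_saturation", "fw_hue", "fw_luminance", "fw_rel_spot_area"),
    function(m) {
      dm <- dimorphism_model(specimens, m)
      cbind(metric = m, dm$anova_table)
    }))
  mixed_chr <- plant_contrast_mixed_model(plant_jnd, "chromatic")
  mixed_lum <- plant_contrast_mixed_model(plant_jnd, "luminance")
  mixed <- rbind(cbind(response = "chromatic", mixed_chr$fixed_effects),
                 cbind(response = "luminance", mixed_lum$fixed_effects))

  # -- write ---------------------------------------------------------------
  outputs <- list(
    specimens = specimens, metrics = metrics, plant_jnd = plant_jnd,
    toxins = toxins, among_population = among, within_population = within,
    dimorphism = dimorphism, mixed_models = mixed
  )
  for (name in names(outputs)) {
    utils::write.csv(outputs[[name]], file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(c(outputs, list(mapping = mapping, pca = pca, curves = curves,
                            mixed_chromatic = mixed_chr,
                            mixed_luminance = mixed_lum)))
  }) # with_seed
}
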