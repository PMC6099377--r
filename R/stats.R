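#' Ordinary least squares with a nested-model F test
#'
#' Fits the full model by least squares and tests it against a nested
#' reduced model with the residual-sum-of-squares F statistic. Adjusted
#' R-squared is reported (it can be negative for models explaining less
#' than their degrees of freedom cost).
#'
#' @param formula Full-model formula.
#' @param data Data frame.
#' @param reduced Reduced-model formula (default intercept-only on the same
#'   response).
#' @return A list of class `apo_regression`: `response`, `terms`,
#'   `F`, `df` (numerator, denominator), `p`, `r_squared_adj`,
#'   `coefficients` (estimate/SE/t/p table), `excluded_outliers`, `fit`.
#' @export
ols_with_f_tests <- function(formula, data, reduced = NULL) {
  fit <- stats::lm(formula, data = data)
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient design: aliased coefficients in the full model")
  }
  if (fit$df.residual < 1) stop("too few observations for the model")
  if (is.null(reduced)) {
    reduced <- stats::reformulate("1", response = all.vars(formula)[1])
  }
  fit0 <- stats::lm(reduced, data = data)
  rss1 <- sum(stats::resid(fit)^2)
  rss0 <- sum(stats::resid(fit0)^2)
  df1 <- fit0$df.residual - fit$df.residual
  df2 <- fit$df.residual
  if (df1 < 1) stop("reduced model is not nested below the full model")
  F <- ((rss0 - rss1) / df1) / (rss1 / df2)
  structure(
    list(response = all.vars(formula)[1],
         terms = attr(stats::terms(fit), "term.labels"),
         F = F, df = c(df1, df2),
         p = stats::pf(F, df1, df2, lower.tail = FALSE),
         r_squared_adj = suppressWarnings(summary(fit)$adj.r.squared),
         coefficients = suppressWarnings(summary(fit)$coefficients),
         excluded_outliers = character(0),
         fit = fit),
    class = "apo_regression"
  )
}

#' @export
print.apo_regression <- function(x, ...) {
  cat(sprintf("%s ~ %s\n", x$response,
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "1"))
  cat(sprintf("F[%d,%d] = %.4g, p = %.4g, adj R^2 = %.4g\n",
              x$df[1], x$df[2], x$F, x$p, x$r_squared_adj))
  if (length(x$excluded_outliers)) {
    cat("excluded outliers:", paste(x$excluded_outliers, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Among-population regression of a color metric on mean toxin level
#'
#' Collapses the cohort to one point per population (means of the metric
#' and of toxin concentration, for one sex) and regresses the mean metric
#' on mean concentration. Sexes are analyzed separately because sex ratios
#' vary between collection sites.
#'
#' @param records Specimen table (needs `population`, `sex`,
#'   `concentration_nmol_per_mg`, and the metric column).
#' @param metric Name of the color-metric column.
#' @param sex `"male"` or `"female"`.
#' @return An `apo_regression` on the population means.
#' @export
among_population_regression <- function(records, metric, sex) {
  d <- records[records$sex == sex, ]
  means <- do.call(rbind, lapply(split(d, d$population), function(g) {
    data.frame(population = g$population[1],
               metric_mean = mean(g[[metric]]),
               conc_mean = mean(g$concentration_nmol_per_mg))
  }))
  if (nrow(means) < 3) stop("need at least 3 populations with specimens of that sex")
  out <- ols_with_f_tests(metric_mean ~ conc_mean, means)
  out$response <- metric
  out
}

backward_eliminate <- function(fit, data, alpha = 0.05) {
  repeat {
    terms_left <- attr(stats::terms(fit), "term.labels")
    if (length(terms_left) == 0) return(fit)
    dr <- stats::drop1(fit, test = "F")
    p <- dr[["Pr(>F)"]][-1]
    worst <- which.max(p)
    if (length(p) == 0 || is.na(p[worst]) || p[worst] <= alpha) return(fit)
    fit <- stats::lm(stats::reformulate(
      if (length(terms_left) > 1) terms_left[-worst] else "1",
      response = all.vars(stats::formula(fit))[1]
    ), data = data)
  }
}

regression_from_fit <- function(fit, data) {
  fit0 <- stats::lm(stats::reformulate("1",
    response = all.vars(stats::formula(fit))[1]), data = data)
  rss1 <- sum(stats::resid(fit)^2)
  rss0 <- sum(stats::resid(fit0)^2)
  df1 <- fit0$df.residual - fit$df.residual
  df2 <- fit$df.residual
  F <- if (df1 >= 1) ((rss0 - rss1) / df1) / (rss1 / df2) else NA_real_
  structure(
    list(response = all.vars(stats::formula(fit))[1],
         terms = attr(stats::terms(fit), "term.labels"),
         F = F, df = c(df1, df2),
         p = if (is.na(F)) NA_real_ else stats::pf(F, df1, df2, lower.tail = FALSE),
         r_squared_adj = suppressWarnings(summary(fit)$adj.r.squared),
         coefficients = suppressWarnings(summary(fit)$coefficients),
         excluded_outliers = character(0),
         fit = fit),
    class = "apo_regression"
  )
}

#' Within-population multiple regression of toxin concentration on color
#'
#' The within-population honesty test: toxin concentration regressed on all
#' wing color metrics for one wing, with either saturation or hue excluded
#' up front (the two are computed from the same cone catches and are
#' near-perfectly correlated). Collinearity is screened with variance
#' inflation factors (all must be below 10); the minimal model is found by
#' backward elimination using nested-model F tests at `alpha`; observations
#' with Cook's distance above 1 in the full model are flagged, the
#' elimination is re-run without them, and both results are reported.
#'
#' @param records Specimens of a single population.
#' @param channel_choice Which chroma metric to keep: `"saturation"`,
#'   `"hue"`, or `"both"` (rejected when their sample correlation
#'   exceeds 0.995).
#' @param wing `"fw"` or `"hw"`.
#' @param alpha Significance threshold for elimination (default 0.05).
#' @return List of class `apo_stepwise` with `full`, `minimal`, and (when
#'   outliers were flagged) `minimal_without_outliers` regressions, plus
#'   `vif` and `outliers`.
#' @export
within_population_regression <- function(records,
                                         channel_choice = c("saturation", "hue", "both"),
                                         wing = c("fw", "hw"),
                                         alpha = 0.05) {
  channel_choice <- match.arg(channel_choice)
  wing <- match.arg(wing)
  metrics <- grep(paste0("^", wing, "_"), cohort_metrics(), value = TRUE)
  drop_metric <- switch(channel_choice,
    saturation = paste0(wing, "_hue"),
    hue = paste0(wing, "_saturation"),
    both = character(0)
  )
  if (channel_choice == "both") {
    r <- stats::cor(records[[paste0(wing, "_saturation")]],
                    records[[paste0(wing, "_hue")]])
    if (r > 0.995) {
      stop(sprintf(
        "saturation and hue are collinear (r = %.4f > 0.995); include only one",
        r
      ))
    }
  }
  predictors <- setdiff(metrics, drop_metric)
  if (nrow(records) <= length(predictors) + 2) {
    stop("too few specimens for the candidate predictor set")
  }
  full_formula <- stats::reformulate(predictors,
                                     response = "concentration_nmol_per_mg")
  full <- stats::lm(full_formula, data = records)
  vifs <- car::vif(full)
  if (any(vifs >= 10)) {
    bad <- names(sort(vifs, decreasing = TRUE))[1:2]
    stop(sprintf("collinear predictors (VIF >= 10): %s", paste(bad, collapse = ", ")))
  }
  minimal <- backward_eliminate(full, records, alpha)
  cooks <- stats::cooks.distance(full)
  flagged <- which(cooks > 1)
  out <- list(full = regression_from_fit(full, records),
              minimal = regression_from_fit(minimal, records),
              vif = vifs,
              cooks_distance = cooks,
              outliers = records$specimen_id[flagged])
  if (length(flagged)) {
    kept <- records[-flagged, ]
    refit <- backward_eliminate(stats::lm(full_formula, data = kept), kept, alpha)
    res <- regression_from_fit(refit, kept)
    res$excluded_outliers <- records$specimen_id[flagged]
    out$minimal_without_outliers <- res
  }
  class(out) <- "apo_stepwise"
  out
}

#' Sex-by-population model of a color metric with Tukey post-hoc tests
#'
#' Fits `metric ~ sex * population`; if the interaction is not significant
#' at `alpha` (sequential F test) the model is simplified to the additive
#' form before main effects are read. Pairwise population differences are
#' tested with Tukey's HSD on the fitted analysis-of-variance model
#' (Tukey-Kramer standard errors under unbalanced sampling).
#'
#' @param records Specimen table with both sexes in >= 2 populations.
#' @param metric Color-metric column name.
#' @param alpha Threshold for dropping the interaction.
#' @return List of class `apo_dimorphism`: `anova_table` (F/df/p per term
#'   from the reported model), `interaction_p`, `tukey` (population
#'   pairwise table), `fit`.
#' @export
dimorphism_model <- function(records, metric, alpha = 0.05) {
  records$population <- factor(records$population)
  records$sex <- factor(records$sex)
  if (nlevels(records$population) < 2 || nlevels(records$sex) < 2) {
    stop("need both sexes and at least 2 populations")
  }
  if (any(table(records$sex, records$population) == 0)) {
    stop("empty sex x population cell")
  }
  f_full <- stats::as.formula(paste(metric, "~ sex * population"))
  fit_full <- stats::aov(f_full, data = records)
  an_full <- summary(fit_full)[[1]]
  inter_p <- an_full["sex:population", "Pr(>F)"]
  fit <- if (!is.na(inter_p) && inter_p < alpha) {
    fit_full
  } else {
    stats::aov(stats::as.formula(paste(metric, "~ sex + population")),
               data = records)
  }
  an <- summary(fit)[[1]]
  an_terms <- trimws(rownames(an))
  keep <- an_terms != "Residuals"
  anova_table <- data.frame(
    term = an_terms[keep],
    F = an[keep, "F value"],
    df1 = an[keep, "Df"],
    df2 = an["Residuals", "Df"],
    p = an[keep, "Pr(>F)"]
  )
  tk <- stats::TukeyHSD(fit, "population")$population
  tukey <- data.frame(comparison = rownames(tk),
                      diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"])
  rownames(tukey) <- NULL
  structure(list(metric = metric, anova_table = anova_table,
                 interaction_p = inter_p, tukey = tukey, fit = fit),
            class = "apo_dimorphism")
}

logit_rescale <- function(y, eps = 1e-6) {
  p <- y / (max(y) + eps)
  stats::qlogis(pmin(pmax(p, eps), 1 - eps))
}

lrt_row <- function(full, reduced) {
  chisq <- max(2 * (as.numeric(stats::logLik(full)) -
                      as.numeric(stats::logLik(reduced))), 0)
  df <- attr(stats::logLik(full), "df") - attr(stats::logLik(reduced), "df")
  c(chisq = chisq, df = df,
    p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Mixed model for contrast against plant backgrounds
#'
#' Random-intercept-per-individual linear mixed model of marking-to-plant
#' contrast, fitted by maximum likelihood, with sex, population, and plant
#' type as fixed effects. Fixed effects are tested by likelihood-ratio
#' chi-square between nested fits (the sex-by-population interaction is
#' tested first and dropped when non-significant). Luminance contrast,
#' which is a non-negative JND, is rescaled to (0, 1) by dividing by its
#' maximum plus a small epsilon and then logit-transformed before fitting.
#' Tukey post-hoc comparisons are reported for plant type and population.
#'
#' @param contrasts Long table, one row per specimen x plant type, with
#'   columns `specimen_id`, `sex`, `population`, `plant_type`, and the two
#'   JND columns `chromatic_jnd`, `luminance_jnd`.
#' @param response `"chromatic"` or `"luminance"`.
#' @param alpha Threshold for dropping the sex:population interaction.
#' @return List of class `apo_mixed`: `fixed_effects` (chisq/df/p per
#'   term), `tukey_plant`, `tukey_population`, `fit`.
#' @export
plant_contrast_mixed_model <- function(contrasts,
                                       response = c("chromatic", "luminance"),
                                       alpha = 0.05) {
  response <- match.arg(response)
  d <- contrasts
  if (max(table(d$specimen_id)) < 2) {
    stop(paste("every individual has a single observation; the random",
               "intercept is inestimable - use a fixed-effects model instead"))
  }
  d$y <- if (response == "chromatic") d$chromatic_jnd else
    logit_rescale(d$luminance_jnd)
  d$sex <- factor(d$sex)
  d$population <- factor(d$population)
  d$plant_type <- factor(d$plant_type)
  ml_fit <- function(rhs) {
    suppressWarnings(suppressMessages(lme4::lmer(
      stats::as.formula(paste("y ~", rhs, "+ (1 | specimen_id)")),
      data = d, REML = FALSE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE)
    )))
  }
  fit_inter <- ml_fit("sex * population + plant_type")
  fit_add <- ml_fit("sex + population + plant_type")
  inter <- lrt_row(fit_inter, fit_add)
  rows <- list(`sex:population` = inter)
  if (inter[["p"]] < alpha) {
    fit <- fit_inter
  } else {
    fit <- fit_add
    rows$sex <- lrt_row(fit_add, ml_fit("population + plant_type"))
    rows$population <- lrt_row(fit_add, ml_fit("sex + plant_type"))
    rows$plant_type <- lrt_row(fit_add, ml_fit("sex + population"))
  }
  fixed <- data.frame(term = names(rows), do.call(rbind, rows))
  rownames(fixed) <- NULL
  tukey <- function(term) {
    spec <- stats::setNames(list("Tukey"), term)
    # when the sex:population interaction is retained, Tukey contrasts on the
    # population main effect are still reported (at the reference levels);
    # multcomp warns about this deliberate choice
    gh <- suppressWarnings(summary(
      multcomp::glht(fit, linfct = do.call(multcomp::mcp, spec))
    ))
    data.frame(comparison = names(gh$test$coefficients),
               estimate = unname(gh$test$coefficients),
               p_adj = unname(gh$test$pvalues))
  }
  structure(
    list(response = response, fixed_effects = fixed,
         tukey_plant = tukey("plant_type"),
         tukey_population = tukey("population"),
         fit = fit),
    class = "apo_mixed"
  )
}
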