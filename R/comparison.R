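check_pair <- function(actual, predicted) {
  actual <- as.numeric(actual)
  predicted <- as.numeric(predicted)
  if (length(actual) != length(predicted))
    stop("actual and predicted must have the same length")
  if (length(actual) < 1) stop("need at least one observation")
  list(a = actual, p = predicted)
}

#' Root-mean-square error
#'
#' sqrt(mean((predicted - actual)^2)) with divisor `n` (not `n - p`).
#'
#' @param actual,predicted Numeric vectors of equal length.
#' @return A nonnegative scalar in the response units.
#' @export
#' @examples
#' d <- sep_design()
#' rmse(d$response, sep_predicted_reference())
rmse <- function(actual, predicted) {
  v <- check_pair(actual, predicted)
  sqrt(mean((v$p - v$a)^2))
}

#' Standard percent error (RMSE as percent of the mean observation)
#'
#' `rmse(actual, predicted) / mean(actual) * 100`; unit-free.
#'
#' @inheritParams rmse
#' @return A percentage.
#' @export
spe <- function(actual, predicted) {
  v <- check_pair(actual, predicted)
  if (mean(v$a) == 0) stop("spe undefined: mean of actual values is zero")
  rmse(v$a, v$p) / mean(v$a) * 100
}

#' Coefficient of determination for a prediction set
#'
#' The primary definition is 1 - SSE/SST = 1 - sum((actual - predicted)^2) /
#' sum((actual - mean(actual))^2), which for a least-squares fit equals the
#' ANOVA R2. The squared Pearson correlation of predictions and observations
#' is exposed as an alternative (`method = "pearson"`); the two agree for an
#' OLS fit evaluated on its own training data but differ in general.
#'
#' @inheritParams rmse
#' @param method `"sse"` (default) or `"pearson"`.
#' @return A scalar <= 1 (the `"sse"` form can be negative for a bad model).
#' @export
r2_pair <- function(actual, predicted, method = c("sse", "pearson")) {
  method <- match.arg(method)
  v <- check_pair(actual, predicted)
  sst <- sum((v$a - mean(v$a))^2)
  if (sst == 0) stop("r2 undefined: actual values have zero variance")
  switch(method,
         sse = 1 - sum((v$a - v$p)^2) / sst,
         pearson = stats::cor(v$a, v$p)^2)
}

#' Mean absolute deviation percentage
#'
#' Two variants are reported side by side. `"conventional"` is the usual
#' relative prediction error, mean(|predicted - actual| / |actual|) * 100.
#' `"printed"` is mean(|actual - mean(actual)| / |actual|) * 100 -- a
#' dispersion summary of the observations that involves no predictions at all
#' and is therefore identical for every model compared on the same data. Both
#' are kept because published comparison tables are not always explicit about
#' which was used; see the package vignette for why neither is asserted
#' against a reference value.
#'
#' @inheritParams rmse
#' @param variant `"conventional"` (default) or `"printed"`.
#' @return A percentage.
#' @export
mad_percent <- function(actual, predicted = NULL,
                        variant = c("conventional", "printed")) {
  variant <- match.arg(variant)
  actual <- as.numeric(actual)
  if (any(actual == 0)) stop("mad_percent undefined with zero actual values")
  if (variant == "printed")
    return(mean(abs(actual - mean(actual)) / abs(actual)) * 100)
  if (is.null(predicted))
    stop("the conventional variant needs predictions")
  v <- check_pair(actual, predicted)
  mean(abs(v$p - v$a) / abs(v$a)) * 100
}

#' Relative deviation between a predicted and a measured optimum
#'
#' |predicted - measured| / measured * 100, the verification-column arithmetic
#' of an optimum-conditions comparison table.
#'
#' @param predicted,measured Positive scalars (mg/g).
#' @return A percentage.
#' @export
relative_deviation <- function(predicted, measured) {
  if (measured == 0) stop("relative deviation undefined for measured = 0")
  abs(predicted - measured) / measured * 100
}

#' Assemble the response-surface vs neural-surrogate comparison report
#'
#' Computes, for each model, R2 (1 - SSE/SST), RMSE, both MAD variants and
#' SPE over the design's measured responses, plus an optimum block: the
#' response-surface box optimum (from [optimize_surface()]) and the GA optimum
#' over the surrogate, each with its predicted response and, when a measured
#' verification value is supplied, the relative deviation.
#'
#' @param design A [design_table()] with a response.
#' @param rsm_model A fitted `rsm_fit`.
#' @param surrogate A trained `neural_surrogate` (or `NULL` to skip the ANN
#'   row).
#' @param ga_result A `ga_result` from [optimize_extraction()] (or `NULL`).
#' @param measured_optima Optional named numeric vector with elements `rsm`
#'   and/or `ann`: protein contents measured at the respective predicted
#'   optima.
#' @param rsm_optimum Optional actual-unit settings at which to evaluate the
#'   response-surface optimum instead of the computed box maximizer (e.g. the
#'   conditions a desirability analysis reported).
#' @return An object of class `comparison_report`: `metrics` and `optima`
#'   data frames plus `per_run` predicted-vs-actual pairs.
#' @export
build_report <- function(design, rsm_model, surrogate = NULL,
                         ga_result = NULL, measured_optima = NULL,
                         rsm_optimum = NULL) {
  y <- design$response
  metric_row <- function(model, pred) {
    data.frame(model = model,
               r2 = r2_pair(y, pred),
               rmse = rmse(y, pred),
               mad_printed = mad_percent(y, variant = "printed"),
               mad_conventional = mad_percent(y, pred),
               spe = spe(y, pred))
  }
  pred_rsm <- predict(rsm_model, design$settings)
  metrics <- metric_row("RSM", pred_rsm)
  per_run <- data.frame(run = design$run, actual = y, rsm = pred_rsm)
  if (!is.null(surrogate)) {
    pred_ann <- predict(surrogate, design$settings)
    metrics <- rbind(metrics, metric_row("ANN", pred_ann))
    per_run$ann <- pred_ann
  }

  opt_row <- function(model, settings, predicted, measured) {
    data.frame(model = model,
               temperature_C = settings[1], time_h = settings[2],
               alkali_mol_L = settings[3], ratio_mL_g = settings[4],
               predicted_mg_g = predicted,
               measured_mg_g = if (is.null(measured)) NA_real_ else measured,
               rel_dev_pct = if (is.null(measured)) NA_real_
                             else relative_deviation(predicted, measured))
  }
  measured_at <- function(key)
    if (!is.null(measured_optima) && key %in% names(measured_optima))
      measured_optima[[key]] else NULL
  if (is.null(rsm_optimum)) {
    o <- optimize_surface(rsm_model)
    rsm_settings <- o$settings
    rsm_pred <- o$value
  } else {
    rsm_settings <- as.numeric(rsm_optimum)
    rsm_pred <- predict(rsm_model, rsm_optimum)
  }
  optima <- opt_row("RSM", rsm_settings, rsm_pred, measured_at("rsm"))
  if (!is.null(ga_result))
    optima <- rbind(optima, opt_row("ANN+GA", ga_result$best_individual,
                                    ga_result$best_fitness,
                                    measured_at("ann")))
  structure(list(metrics = metrics, optima = optima, per_run = per_run),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, digits = 4, ...) {
  cat("Model comparison metrics\n")
  m <- x$metrics
  m[-1] <- lapply(m[-1], signif, digits)
  print(m, row.names = FALSE)
  cat("\nOptimum conditions\n")
  o <- x$optima
  o[-1] <- lapply(o[-1], signif, digits)
  print(o, row.names = FALSE)
  invisible(x)
}

#' Write a comparison report to CSV files
#'
#' @param report A `comparison_report`.
#' @param dir Output directory (created if needed); writes `metrics.csv`,
#'   `optima.csv` and `per_run.csv`.
#' @return `dir`, invisibly.
#' @export
write_report_csv <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$optima, file.path(dir, "optima.csv"),
                   row.names = FALSE)
  utils::write.csv(report$per_run, file.path(dir, "per_run.csv"),
                   row.names = FALSE)
  invisible(dir)
}
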