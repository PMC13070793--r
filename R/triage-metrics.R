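## The core computation: apply a configuration to the cohorts (per-study OR
## rule), build the pseudo confusion matrix under an assumed detectable
## cancer prevalence, and derive the full metric panel.
##
## Model: cohort 1 is all cancer-positive, so sensitivity = tp1/n1 is
## observed. Cohort 2 has no per-study ground truth; pPos = round(pi * n2)
## modelled positives are allocated, tp2 = pPos * sensitivity of them assumed
## flagged, and the remaining (n2 - pPos) modelled negatives minus the false
## positives give the true negatives. tp2/fn2/fp/tn stay unrounded reals;
## integers appear only in display output.

#' Flag studies under a triage configuration
#'
#' A study is flagged when any selected finding is present (logical OR over
#' the selected columns); with `includeCritical = TRUE` on the configuration,
#' the catalogue's CRITICAL findings are unioned into the rule.
#'
#' @param matrix a [CohortMatrix-class] aligned to `catalogue`.
#' @param config a [TriageConfiguration-class]; every selected finding must
#'   exist in the catalogue.
#' @param catalogue the [FindingCatalogue-class].
#' @return logical vector of length `nStudies(matrix)`, in study order.
#' @export
flagStudies <- function(matrix, config, catalogue) {
  unknown <- setdiff(config@selected, catalogue@finding)
  if (length(unknown))
    cxrStop(sprintf("selected finding(s) not in catalogue: %s",
                    paste(unknown, collapse = ", ")))
  sel <- config@selected
  if (config@includeCritical)
    sel <- union(sel, catalogue@finding[catalogue@priorityClass == "CRITICAL"])
  if (length(sel) == 0L)
    return(stats::setNames(rep(FALSE, nStudies(matrix)), studyIds(matrix)))
  flags <- rowSums(matrix@presence[, sel, drop = FALSE]) > 0L
  stats::setNames(as.logical(flags), studyIds(matrix))
}

#' Pseudo confusion matrix from aggregate counts
#'
#' The count-level entry point: everything the model needs is the observed
#' flag counts in the two cohorts and the assumed prevalence, so published
#' aggregate counts can be evaluated directly without study-level data.
#'
#' @param tp1 flagged studies in the cancer cohort.
#' @param n1 cancer-cohort size (>= 1).
#' @param flagged2 flagged studies in the referral cohort.
#' @param n2 referral-cohort size (>= 1).
#' @param pi assumed detectable-cancer prevalence in [0, 1); default 0.01.
#' @return a [PseudoConfusion-class] object.
#' @export
pseudoConfusionFromCounts <- function(tp1, n1, flagged2, n2, pi = 0.01) {
  if (!isScalarNumber(pi) || pi < 0 || pi >= 1)
    cxrStop("pi must lie in [0, 1)")
  if (!isScalarNumber(n1) || n1 < 1) cxrStop("n1 must be >= 1")
  if (!isScalarNumber(n2) || n2 < 1) cxrStop("n2 must be >= 1")
  if (tp1 < 0 || tp1 > n1) cxrStop("tp1 must lie in [0, n1]")
  if (flagged2 < 0 || flagged2 > n2) cxrStop("flagged2 must lie in [0, n2]")
  sens <- tp1 / n1
  pPos <- roundHalfUp(pi * n2)
  tp2 <- pPos * sens
  fn2 <- pPos - tp2
  fp <- flagged2 - tp2
  if (fp < 0)
    cxrStop(sprintf(
      paste0("assumed prevalence pi = %g implies %.2f modelled true positives, ",
             "more than the %g studies actually flagged in the referral cohort; ",
             "pi is inconsistent with the observed flag rate"),
      pi, tp2, flagged2), class = "cxr_model_error")
  tn <- (n2 - pPos) - fp
  new("PseudoConfusion",
      tp1 = as.numeric(tp1), fn1 = as.numeric(n1 - tp1), n1 = as.numeric(n1),
      flagged2 = as.numeric(flagged2), n2 = as.numeric(n2), pi = pi,
      pPos = pPos, tp2 = tp2, fn2 = fn2, fp = fp, tn = tn)
}

#' Pseudo confusion matrix from cohort data
#'
#' Flags both cohorts under the configuration and delegates to
#' [pseudoConfusionFromCounts()].
#'
#' @inheritParams flagStudies
#' @param cancer cancer-cohort [CohortMatrix-class] (all studies
#'   cancer-positive by design).
#' @param referral referral-cohort [CohortMatrix-class] (cancer status
#'   unknown; modelled via `pi`).
#' @param pi assumed detectable-cancer prevalence in [0, 1).
#' @return a [PseudoConfusion-class] object.
#' @export
pseudoConfusion <- function(cancer, referral, config, catalogue, pi = 0.01) {
  if (nStudies(cancer) < 1L) cxrStop("cancer cohort must have >= 1 study")
  tp1 <- sum(flagStudies(cancer, config, catalogue))
  flagged2 <- sum(flagStudies(referral, config, catalogue))
  pseudoConfusionFromCounts(tp1, nStudies(cancer), flagged2,
                            nStudies(referral), pi)
}

#' Wald confidence interval for a binomial proportion
#'
#' Normal-approximation interval p +/- z * sqrt(p (1 - p) / n), clamped to
#' [0, 1].
#'
#' @param p observed proportion in [0, 1].
#' @param n denominator (>= 1).
#' @param level confidence level in (0, 1); default 0.95.
#' @return numeric (low, high).
#' @export
waldCi <- function(p, n, level = 0.95) {
  if (!isScalarNumber(p) || p < 0 || p > 1) cxrStop("p must lie in [0, 1]")
  if (!isScalarNumber(n) || n < 1) cxrStop("n must be >= 1")
  if (!isScalarNumber(level) || level <= 0 || level >= 1)
    cxrStop("level must lie in (0, 1)")
  z <- stats::qnorm((1 + level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(max(0, p - half), min(1, p + half))
}

#' Full metric panel from a pseudo confusion matrix
#'
#' Sensitivity (and FNR) come from cohort 1; specificity, PPV, NPV, FPR and
#' the number-needed-to-report figures from the modelled cohort-2 cells.
#' Confidence intervals are Wald, on (sensitivity, n1) and on
#' (specificity, n2 - pPos). PPV and nnrPos are NA when no modelled true
#' positives exist; nnrNeg is NA when no modelled false negatives exist.
#'
#' @param pc a [PseudoConfusion-class] object.
#' @param ciLevel confidence level for the intervals; default 0.95.
#' @param name configuration name carried onto the result.
#' @return a [StrategyMetrics-class] object.
#' @export
computeMetrics <- function(pc, ciLevel = 0.95, name = "configuration") {
  sens <- pc@tp1 / pc@n1
  negDen <- pc@tn + pc@fp  # = n2 - pPos, the modelled negatives
  spec <- if (negDen > 0) pc@tn / negDen else 1
  ppv <- if (pc@tp2 > 0) pc@tp2 / (pc@tp2 + pc@fp) else NA_real_
  npv <- if (pc@tn + pc@fn2 > 0) pc@tn / (pc@tn + pc@fn2) else NA_real_
  new("StrategyMetrics",
      name = name,
      sensitivity = sens, specificity = spec,
      ppv = ppv, npv = npv,
      fpr = 1 - spec, fnr = 1 - sens,
      sensitivityCi = waldCi(sens, pc@n1, ciLevel),
      specificityCi = waldCi(spec, max(1, negDen), ciLevel),
      pctFlagged1 = pc@tp1 / pc@n1,
      pctFlagged2 = pc@flagged2 / pc@n2,
      nnrPos = if (pc@tp2 > 0) (pc@tp2 + pc@fp) / pc@tp2 else NA_real_,
      nnrNeg = if (pc@fn2 > 0) (pc@tn + pc@fn2) / pc@fn2 else NA_real_,
      ciLevel = ciLevel, confusion = pc)
}

#' Evaluate one configuration end to end
#'
#' Convenience wrapper: [pseudoConfusion()] then [computeMetrics()].
#'
#' @inheritParams pseudoConfusion
#' @param ciLevel confidence level for the intervals.
#' @return a [StrategyMetrics-class] object.
#' @export
evaluateStrategy <- function(cancer, referral, config, catalogue,
                             pi = 0.01, ciLevel = 0.95) {
  pc <- pseudoConfusion(cancer, referral, config, catalogue, pi)
  computeMetrics(pc, ciLevel, name = config@name)
}

#' Compare several configurations side by side
#'
#' @inheritParams pseudoConfusion
#' @param configs list of [TriageConfiguration-class] objects (>= 1).
#' @param ciLevel confidence level for the intervals.
#' @return list of [StrategyMetrics-class], named by configuration name.
#' @export
compareStrategies <- function(cancer, referral, catalogue, configs,
                              pi = 0.01, ciLevel = 0.95) {
  if (length(configs) < 1L) cxrStop("at least one configuration required")
  out <- lapply(configs, function(cfg)
    evaluateStrategy(cancer, referral, cfg, catalogue, pi, ciLevel))
  names(out) <- vapply(configs, function(cfg) cfg@name, character(1))
  out
}

## -- report rendering --------------------------------------------------------

#' One metrics record as a flat data.frame row
#'
#' Proportions are reported both as full-precision values and as display
#' percentages (2 dp, half away from zero); the modelled cohort-2 cells are
#' additionally rounded to integers for presentation.
#'
#' @param metrics a [StrategyMetrics-class] object.
#' @return one-row data.frame with fixed column names.
#' @export
metricsRecord <- function(metrics) {
  pc <- metrics@confusion
  data.frame(
    strategy = metrics@name,
    n_selected = NA_integer_,  # filled by metricsTable when configs known
    sensitivity = metrics@sensitivity,
    sensitivity_ci_low = metrics@sensitivityCi[1],
    sensitivity_ci_high = metrics@sensitivityCi[2],
    specificity = metrics@specificity,
    specificity_ci_low = metrics@specificityCi[1],
    specificity_ci_high = metrics@specificityCi[2],
    ppv = metrics@ppv, npv = metrics@npv,
    fpr = metrics@fpr, fnr = metrics@fnr,
    pct_flagged1 = metrics@pctFlagged1,
    pct_flagged2 = metrics@pctFlagged2,
    nnr_pos = metrics@nnrPos, nnr_neg = metrics@nnrNeg,
    tp1 = pc@tp1, fn1 = pc@fn1, n1 = pc@n1,
    flagged2 = pc@flagged2, n2 = pc@n2, pi = pc@pi, p_pos = pc@pPos,
    tp2_display = roundHalfUp(pc@tp2), fn2_display = roundHalfUp(pc@fn2),
    fp_display = roundHalfUp(pc@fp), tn_display = roundHalfUp(pc@tn),
    sensitivity_pct = roundHalfUp(100 * metrics@sensitivity, 2),
    specificity_pct = roundHalfUp(100 * metrics@specificity, 2),
    ppv_pct = roundHalfUp(100 * metrics@ppv, 2),
    npv_pct = roundHalfUp(100 * metrics@npv, 2),
    fpr_pct = roundHalfUp(100 * metrics@fpr, 2),
    fnr_pct = roundHalfUp(100 * metrics@fnr, 2),
    nnr_pos_display = roundHalfUp(metrics@nnrPos),
    nnr_neg_display = roundHalfUp(metrics@nnrNeg),
    row.names = NULL)
}

#' Tabulate metrics for several strategies
#'
#' @param metricsList list of [StrategyMetrics-class] (e.g. from
#'   [compareStrategies()]).
#' @param configs optional list of matching [TriageConfiguration-class]
#'   objects used to fill the `n_selected` column.
#' @return data.frame, one row per strategy.
#' @export
metricsTable <- function(metricsList, configs = NULL) {
  df <- do.call(rbind, lapply(metricsList, metricsRecord))
  if (!is.null(configs))
    df$n_selected <- vapply(configs, length, integer(1))
  df
}

#' Write a metrics report as CSV and JSON
#'
#' @param table data.frame from [metricsTable()].
#' @param csvPath,jsonPath output paths; either may be NULL to skip.
#' @return invisibly, the table.
#' @export
writeMetricsReport <- function(table, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath))
    utils::write.csv(table, csvPath, row.names = FALSE, na = "NA")
  if (!is.null(jsonPath))
    jsonlite::write_json(table, jsonPath, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  invisible(table)
}
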