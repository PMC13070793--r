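## Sensitivity sweeps: over the assumed cancer prevalence (flag counts held
## fixed, only the modelling changes) and over the prevalence-ratio
## selection threshold (the configuration itself changes).

#' Sweep the assumed cancer prevalence
#'
#' Recomputes the metric panel at each prevalence value with the observed
#' flag counts held fixed; only the modelled allocation of positives in the
#' referral cohort changes, so sensitivity and the flagged fractions are
#' constant across the sweep.
#'
#' @inheritParams pseudoConfusion
#' @param piValues strictly increasing prevalences, each in [0, 1).
#' @param ciLevel confidence level for the intervals.
#' @return a [SweepResult-class] with `parameterKind = "prevalence"`.
#' @export
prevalenceSweep <- function(cancer, referral, config, catalogue,
                            piValues, ciLevel = 0.95) {
  checkSweepValues(piValues, "piValues")
  if (any(piValues < 0 | piValues >= 1)) cxrStop("each pi must lie in [0, 1)")
  tp1 <- sum(flagStudies(cancer, config, catalogue))
  flagged2 <- sum(flagStudies(referral, config, catalogue))
  metrics <- lapply(piValues, function(p) {
    pc <- tryCatch(
      pseudoConfusionFromCounts(tp1, nStudies(cancer), flagged2,
                                nStudies(referral), p),
      error = function(e) e)
    if (inherits(pc, "condition"))
      cxrStop(sprintf("at pi = %g: %s", p, conditionMessage(pc)),
              class = "cxr_model_error")
    computeMetrics(pc, ciLevel, name = config@name)
  })
  new("SweepResult", parameterKind = "prevalence",
      parameter = as.numeric(piValues), metrics = metrics)
}

#' Sweep the prevalence-ratio selection threshold
#'
#' For each threshold t, builds the configuration
#' `selectByRatio(table, classes, t)` and evaluates it at a fixed assumed
#' prevalence. Raising the threshold shrinks the selection, so the flagged
#' fraction and sensitivity are non-increasing in t.
#'
#' @inheritParams pseudoConfusion
#' @param classes priority classes eligible for selection.
#' @param thresholds strictly increasing positive ratio thresholds.
#' @param ciLevel confidence level for the intervals.
#' @return a [SweepResult-class] with `parameterKind = "ratio_threshold"`.
#' @export
ratioThresholdSweep <- function(cancer, referral, catalogue,
                                classes = "HIGH", thresholds,
                                pi = 0.01, ciLevel = 0.95) {
  checkSweepValues(thresholds, "thresholds")
  if (any(thresholds <= 0)) cxrStop("thresholds must be positive")
  table <- prevalenceRatioTable(cancer, referral, catalogue)
  metrics <- lapply(thresholds, function(t) {
    cfg <- selectByRatio(table, classes, t)
    evaluateStrategy(cancer, referral, cfg, catalogue, pi, ciLevel)
  })
  new("SweepResult", parameterKind = "ratio_threshold",
      parameter = as.numeric(thresholds), metrics = metrics)
}

checkSweepValues <- function(values, what) {
  if (length(values) < 1L || anyNA(values))
    cxrStop(sprintf("%s must be a non-empty numeric vector", what))
  if (is.unsorted(values, strictly = TRUE))
    cxrStop(sprintf("%s must be strictly increasing", what))
  invisible(values)
}

#' Flatten a sweep result to a data.frame
#'
#' One row per parameter value with the column layout
#' `parameter,sensitivity,specificity,ppv,npv,fpr,fnr,pct_flagged2,nnr_pos`.
#'
#' @param sweep a [SweepResult-class].
#' @return data.frame.
#' @export
sweepTable <- function(sweep) {
  rows <- lapply(seq_along(sweep@parameter), function(i) {
    m <- sweep@metrics[[i]]
    data.frame(parameter = sweep@parameter[i],
               sensitivity = m@sensitivity, specificity = m@specificity,
               ppv = m@ppv, npv = m@npv, fpr = m@fpr, fnr = m@fnr,
               pct_flagged2 = m@pctFlagged2, nnr_pos = m@nnrPos,
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Write a sweep result to CSV
#'
#' @param sweep a [SweepResult-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeSweepCsv <- function(sweep, path) {
  utils::write.csv(sweepTable(sweep), path, row.names = FALSE, na = "NA")
  invisible(path)
}
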