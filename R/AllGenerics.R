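#' @rdname FindingCatalogue-class
#' @param object,x a package object.
#' @param ... unused.
#' @export
setGeneric("findingNames", function(x) standardGeneric("findingNames"))

#' @rdname FindingCatalogue-class
#' @export
setGeneric("priorityClass", function(x) standardGeneric("priorityClass"))

#' @rdname CohortMatrix-class
#' @export
setGeneric("studyIds", function(x) standardGeneric("studyIds"))

#' @rdname CohortMatrix-class
#' @export
setGeneric("cohortLabel", function(x) standardGeneric("cohortLabel"))

#' @rdname CohortMatrix-class
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))

#' @rdname CohortMatrix-class
#' @export
setGeneric("nStudies", function(x) standardGeneric("nStudies"))

#' @rdname TriageConfiguration-class
#' @export
setGeneric("selectedFindings", function(x) standardGeneric("selectedFindings"))

## -- accessors ---------------------------------------------------------------

#' @rdname FindingCatalogue-class
#' @export
setMethod("findingNames", "FindingCatalogue", function(x) x@finding)

#' @rdname CohortMatrix-class
#' @export
setMethod("findingNames", "CohortMatrix", function(x) colnames(x@presence))

#' @rdname FindingCatalogue-class
#' @export
setMethod("priorityClass", "FindingCatalogue", function(x) {
  stats::setNames(x@priorityClass, x@finding)
})

#' @rdname FindingCatalogue-class
#' @export
setMethod("length", "FindingCatalogue", function(x) length(x@finding))

#' @rdname CohortMatrix-class
#' @export
setMethod("studyIds", "CohortMatrix", function(x) rownames(x@presence))

#' @rdname CohortMatrix-class
#' @export
setMethod("cohortLabel", "CohortMatrix", function(x) x@label)

#' @rdname CohortMatrix-class
#' @export
setMethod("presenceMatrix", "CohortMatrix", function(x) x@presence)

#' @rdname CohortMatrix-class
#' @export
setMethod("nStudies", "CohortMatrix", function(x) nrow(x@presence))

#' @rdname CohortMatrix-class
#' @export
setMethod("dim", "CohortMatrix", function(x) dim(x@presence))

#' @rdname TriageConfiguration-class
#' @export
setMethod("selectedFindings", "TriageConfiguration", function(x) x@selected)

#' @rdname TriageConfiguration-class
#' @export
setMethod("length", "TriageConfiguration", function(x) length(x@selected))

## -- show methods ------------------------------------------------------------

#' @rdname FindingCatalogue-class
#' @export
setMethod("show", "FindingCatalogue", function(object) {
  tab <- table(factor(object@priorityClass, levels = PRIORITY_CLASSES))
  cat(sprintf("FindingCatalogue with %d findings (%s)\n",
              length(object@finding),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  head_n <- utils::head(object@finding, 5)
  cat("  ", paste(head_n, collapse = ", "),
      if (length(object@finding) > 5) ", ..." else "", "\n", sep = "")
})

#' @rdname CohortMatrix-class
#' @export
setMethod("show", "CohortMatrix", function(object) {
  m <- object@presence
  cat(sprintf("CohortMatrix '%s': %d studies x %d findings (%.2f%% cells positive)\n",
              object@label, nrow(m), ncol(m),
              if (length(m)) 100 * mean(m) else 0))
})

#' @rdname TriageConfiguration-class
#' @export
setMethod("show", "TriageConfiguration", function(object) {
  cat(sprintf("TriageConfiguration '%s': %d selected finding(s)%s\n",
              object@name, length(object@selected),
              if (object@includeCritical) " + CRITICAL stream" else ""))
  if (length(object@selected))
    cat("  ", paste(utils::head(object@selected, 8), collapse = ", "),
        if (length(object@selected) > 8) ", ..." else "", "\n", sep = "")
})

#' @rdname PseudoConfusion-class
#' @export
setMethod("show", "PseudoConfusion", function(object) {
  cat(sprintf("PseudoConfusion (pi = %g, modelled positives = %g)\n",
              object@pi, object@pPos))
  cat(sprintf("  cohort 1 (observed): TP %g / FN %g of n1 = %g\n",
              object@tp1, object@fn1, object@n1))
  cat(sprintf("  cohort 2 (modelled): TP %.2f  FN %.2f  FP %.2f  TN %.2f of n2 = %g\n",
              object@tp2, object@fn2, object@fp, object@tn, object@n2))
})

#' @rdname StrategyMetrics-class
#' @export
setMethod("show", "StrategyMetrics", function(object) {
  cat(sprintf("StrategyMetrics '%s'\n", object@name))
  cat(sprintf("  sensitivity %s%% (%s-%s%%)  specificity %s%% (%s-%s%%)\n",
              fmtPct(object@sensitivity),
              fmtPct(object@sensitivityCi[1]), fmtPct(object@sensitivityCi[2]),
              fmtPct(object@specificity),
              fmtPct(object@specificityCi[1]), fmtPct(object@specificityCi[2])))
  cat(sprintf("  PPV %s%%  NPV %s%%  FPR %s%%  FNR %s%%\n",
              fmtPct(object@ppv), fmtPct(object@npv),
              fmtPct(object@fpr), fmtPct(object@fnr)))
  cat(sprintf("  flagged: %s%% of cohort 1, %s%% of cohort 2;  NNR+ %s  NNR- %s\n",
              fmtPct(object@pctFlagged1), fmtPct(object@pctFlagged2),
              ifelse(is.na(object@nnrPos), "NA", sprintf("%.0f", roundHalfUp(object@nnrPos))),
              ifelse(is.na(object@nnrNeg), "NA", sprintf("%.0f", roundHalfUp(object@nnrNeg)))))
})

#' @rdname SweepResult-class
#' @export
setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult over %s (%d points: %s)\n",
              object@parameterKind, length(object@parameter),
              paste(signif(object@parameter, 4), collapse = ", ")))
})

#' @rdname SyntheticSpec-class
#' @export
setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: n1 = %g, n2 = %g, %d findings, seed = %g\n",
              object@n1, object@n2, nrow(object@findings), object@seed))
})
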