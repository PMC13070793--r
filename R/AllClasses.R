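#' @import methods
NULL

#' Priority classes recognised in a finding catalogue
#'
#' CRITICAL findings always warrant urgent reporting regardless of cancer
#' association; HIGH findings are clinically significant candidates for
#' cancer-directed prioritisation; STANDARD findings are never prioritised.
#'
#' @export
PRIORITY_CLASSES <- c("CRITICAL", "HIGH", "STANDARD")

#' FindingCatalogue: the universe of AI-detectable findings
#'
#' An ordered catalogue of finding names, each carrying exactly one priority
#' class. The catalogue order is canonical: all cohort matrices are aligned
#' to it on load, and all deterministic orderings (selections, tie-breaks)
#' follow it.
#'
#' @slot finding character vector of unique, non-empty finding names.
#' @slot priorityClass character vector, one of CRITICAL/HIGH/STANDARD per
#'   finding.
#' @seealso [readCatalogue()]
#' @export
setClass("FindingCatalogue",
  representation(finding = "character", priorityClass = "character"))

setValidity("FindingCatalogue", function(object) {
  f <- object@finding
  cl <- object@priorityClass
  if (length(f) < 1L) return("catalogue must contain at least one finding")
  if (length(cl) != length(f)) return("finding and priorityClass lengths differ")
  if (anyNA(f) || any(!nzchar(f))) return("finding names must be non-empty")
  if (anyDuplicated(f)) {
    return(sprintf("duplicate finding name(s): %s",
                   paste(unique(f[duplicated(f)]), collapse = ", ")))
  }
  bad <- setdiff(unique(cl), PRIORITY_CLASSES)
  if (length(bad)) {
    return(sprintf("unknown priority class token(s): %s (allowed: %s)",
                   paste(bad, collapse = ", "),
                   paste(PRIORITY_CLASSES, collapse = ", ")))
  }
  TRUE
})

#' CohortMatrix: binary study-by-finding presence matrix for one cohort
#'
#' Rows are studies (chest X-rays), columns are AI findings in catalogue
#' order; entries are strictly 0/1 (finding absent/present). Missing values
#' are a contract violation, never imputed.
#'
#' @slot label cohort label, e.g. "cancer" or "referral".
#' @slot presence integer matrix in \{0,1\} with study ids as rownames and
#'   finding names as colnames.
#' @seealso [readCohortCsv()], [generateCohorts()]
#' @export
setClass("CohortMatrix",
  representation(label = "character", presence = "matrix"))

setValidity("CohortMatrix", function(object) {
  if (!isScalarString(object@label)) return("label must be a single non-empty string")
  m <- object@presence
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    return("presence matrix must have unique finding colnames")
  if (ncol(m) < 1L) return("presence matrix must have at least one finding column")
  if (nrow(m) > 0L) {
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
      return("presence matrix must have unique study_id rownames")
    if (anyNA(m)) return("presence matrix contains missing values")
    if (!all(m == 0L | m == 1L)) return("presence matrix entries must be 0 or 1")
  }
  TRUE
})

#' TriageConfiguration: a flagging rule over findings
#'
#' A study is flagged for prioritisation when any selected finding is present
#' (logical OR). When `includeCritical` is TRUE the CRITICAL-class findings
#' of the catalogue are unioned into the rule at flagging time; the default
#' FALSE treats CRITICAL findings as a separate always-prioritise stream that
#' does not enter cancer-metric computation.
#'
#' @slot name configuration name, e.g. "strategy1".
#' @slot selected character vector of selected finding names.
#' @slot includeCritical logical scalar.
#' @export
setClass("TriageConfiguration",
  representation(name = "character", selected = "character",
                 includeCritical = "logical"))

setValidity("TriageConfiguration", function(object) {
  if (!isScalarString(object@name)) return("name must be a single non-empty string")
  if (anyNA(object@selected)) return("selected findings must not contain NA")
  if (anyDuplicated(object@selected)) return("selected findings must be unique")
  if (length(object@includeCritical) != 1L || is.na(object@includeCritical))
    return("includeCritical must be TRUE or FALSE")
  TRUE
})

#' PseudoConfusion: observed cohort-1 counts plus modelled cohort-2 counts
#'
#' Cohort 1 (all cancer-positive) yields observed tp1/fn1 and hence
#' sensitivity = tp1/n1. Cohort 2 has no per-study ground truth; a fixed
#' detectable-cancer prevalence pi allocates pPos = round(pi * n2) modelled
#' positives, of which tp2 = pPos * sensitivity are assumed captured by the
#' flag. The modelled cell counts tp2/fn2/fp/tn are kept as unrounded reals;
#' integer rounding is display-only.
#'
#' @slot tp1,fn1,n1 observed cohort-1 counts (tp1 + fn1 = n1).
#' @slot flagged2,n2 observed referral-cohort flag count and size.
#' @slot pi assumed detectable-cancer prevalence in [0, 1).
#' @slot pPos modelled positive count round(pi * n2).
#' @slot tp2,fn2,fp,tn modelled real-valued cohort-2 cells summing to n2.
#' @seealso [pseudoConfusion()], [pseudoConfusionFromCounts()]
#' @export
setClass("PseudoConfusion",
  representation(tp1 = "numeric", fn1 = "numeric", n1 = "numeric",
                 flagged2 = "numeric", n2 = "numeric", pi = "numeric",
                 pPos = "numeric", tp2 = "numeric", fn2 = "numeric",
                 fp = "numeric", tn = "numeric"))

setValidity("PseudoConfusion", function(object) {
  sl <- c("tp1", "fn1", "n1", "flagged2", "n2", "pi", "pPos",
          "tp2", "fn2", "fp", "tn")
  for (s in sl) {
    v <- slot(object, s)
    if (!isScalarNumber(v)) return(sprintf("slot %s must be a finite scalar", s))
  }
  if (object@tp1 + object@fn1 != object@n1) return("tp1 + fn1 must equal n1")
  if (object@pi < 0 || object@pi >= 1) return("pi must lie in [0, 1)")
  if (object@fp < 0)
    return("negative modelled false positives: pi inconsistent with flag rate")
  tot <- object@tp2 + object@fn2 + object@fp + object@tn
  if (abs(tot - object@n2) > 1e-8 * max(1, object@n2))
    return("modelled cohort-2 cells must sum to n2")
  TRUE
})

#' StrategyMetrics: the full metric panel for one configuration
#'
#' Sensitivity and its complement FNR are observed in cohort 1; specificity,
#' PPV, NPV, FPR and the number-needed-to-report figures are modelled in
#' cohort 2 under the assumed prevalence. PPV/nnrPos are NA when tp2 = 0,
#' nnrNeg is NA when fn2 = 0 (undefined, not an error).
#'
#' @slot name configuration name.
#' @slot sensitivity,specificity,ppv,npv,fpr,fnr proportions in [0, 1].
#' @slot sensitivityCi,specificityCi length-2 numeric (low, high), clamped to
#'   [0, 1].
#' @slot pctFlagged1,pctFlagged2 flagged fractions in each cohort.
#' @slot nnrPos,nnrNeg chest X-rays reported per cancer detected in the
#'   AI-positive / AI-negative stream.
#' @slot ciLevel confidence level used for the intervals.
#' @slot confusion the underlying [PseudoConfusion-class] object.
#' @seealso [computeMetrics()]
#' @export
setClass("StrategyMetrics",
  representation(name = "character",
                 sensitivity = "numeric", specificity = "numeric",
                 ppv = "numeric", npv = "numeric",
                 fpr = "numeric", fnr = "numeric",
                 sensitivityCi = "numeric", specificityCi = "numeric",
                 pctFlagged1 = "numeric", pctFlagged2 = "numeric",
                 nnrPos = "numeric", nnrNeg = "numeric",
                 ciLevel = "numeric", confusion = "PseudoConfusion"))

setValidity("StrategyMetrics", function(object) {
  props <- c("sensitivity", "specificity", "fpr", "fnr",
             "pctFlagged1", "pctFlagged2")
  for (s in props) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < -1e-12 || v > 1 + 1e-12)
      return(sprintf("slot %s must be a proportion in [0, 1]", s))
  }
  for (s in c("ppv", "npv")) {  # NA marks an undefined value (e.g. tp2 = 0)
    v <- slot(object, s)
    if (length(v) != 1L || (!is.na(v) && (v < -1e-12 || v > 1 + 1e-12)))
      return(sprintf("slot %s must be NA or a proportion in [0, 1]", s))
  }
  for (s in c("sensitivityCi", "specificityCi")) {
    ci <- slot(object, s)
    if (length(ci) != 2L || anyNA(ci)) return(sprintf("%s must be (low, high)", s))
    if (ci[1] > ci[2] + 1e-12) return(sprintf("%s low exceeds high", s))
    if (ci[1] < -1e-12 || ci[2] > 1 + 1e-12)
      return(sprintf("%s must be clamped to [0, 1]", s))
  }
  if (abs(object@fnr - (1 - object@sensitivity)) > 1e-12)
    return("fnr must equal 1 - sensitivity exactly")
  if (abs(object@fpr - (1 - object@specificity)) > 1e-12)
    return("fpr must equal 1 - specificity exactly")
  TRUE
})

#' SweepResult: metrics along a swept parameter
#'
#' @slot parameterKind "prevalence" (assumed cancer prevalence pi) or
#'   "ratio_threshold" (prevalence-ratio selection cutoff).
#' @slot parameter strictly increasing numeric vector of parameter values.
#' @slot metrics list of [StrategyMetrics-class], one per parameter value.
#' @seealso [prevalenceSweep()], [ratioThresholdSweep()]
#' @export
setClass("SweepResult",
  representation(parameterKind = "character", parameter = "numeric",
                 metrics = "list"))

setValidity("SweepResult", function(object) {
  if (!object@parameterKind %in% c("prevalence", "ratio_threshold"))
    return("parameterKind must be 'prevalence' or 'ratio_threshold'")
  p <- object@parameter
  if (length(p) < 1L || anyNA(p)) return("parameter values must be non-empty, non-NA")
  if (is.unsorted(p, strictly = TRUE)) return("parameter values must be strictly increasing")
  if (length(object@metrics) != length(p))
    return("one metrics entry per parameter value required")
  if (!all(vapply(object@metrics, is, logical(1), "StrategyMetrics")))
    return("metrics must all be StrategyMetrics")
  TRUE
})

#' SyntheticSpec: parameters of the correlated-binary cohort generator
#'
#' One row per finding: target marginal prevalence in the cancer cohort
#' (prev1) and referral cohort (prev2), and a loading in [-1, 1] coupling the
#' finding to a per-study latent severity factor (one-factor Gaussian copula;
#' loading 0 gives independence).
#'
#' @slot n1,n2 cohort sizes (cancer, referral).
#' @slot findings data.frame with columns finding, priority_class, prev1,
#'   prev2, loading.
#' @slot seed integer RNG seed pinning the output byte-for-byte.
#' @seealso [generateCohorts()], [specFromPrevalence()]
#' @export
setClass("SyntheticSpec",
  representation(n1 = "numeric", n2 = "numeric", findings = "data.frame",
                 seed = "numeric"))

setValidity("SyntheticSpec", function(object) {
  if (!isScalarNumber(object@n1) || object@n1 < 1 || object@n1 != round(object@n1))
    return("n1 must be a positive integer")
  if (!isScalarNumber(object@n2) || object@n2 < 1 || object@n2 != round(object@n2))
    return("n2 must be a positive integer")
  if (!isScalarNumber(object@seed) || object@seed != round(object@seed))
    return("seed must be an integer")
  f <- object@findings
  need <- c("finding", "priority_class", "prev1", "prev2", "loading")
  if (!all(need %in% names(f)))
    return(sprintf("findings must have columns: %s", paste(need, collapse = ", ")))
  if (nrow(f) < 1L) return("at least one finding required")
  if (anyDuplicated(f$finding)) return("finding names must be unique")
  if (!all(f$priority_class %in% PRIORITY_CLASSES))
    return("priority_class values must be CRITICAL/HIGH/STANDARD")
  if (anyNA(f$prev1) || any(f$prev1 < 0 | f$prev1 > 1)) return("prev1 must lie in [0, 1]")
  if (anyNA(f$prev2) || any(f$prev2 < 0 | f$prev2 > 1)) return("prev2 must lie in [0, 1]")
  if (anyNA(f$loading) || any(abs(f$loading) > 1)) return("loadings must lie in [-1, 1]")
  TRUE
})
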