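## Per-finding prevalence in each cohort, the cancer:referral prevalence
## ratio, and ratio-threshold finding selection.

#' Per-finding prevalence in one cohort
#'
#' @param matrix a [CohortMatrix-class] with at least one study.
#' @return data.frame with columns `finding`, `count` (positive studies) and
#'   `proportion` (count / n studies), one row per finding in matrix order.
#' @export
findingPrevalence <- function(matrix) {
  n <- nStudies(matrix)
  if (n < 1L) cxrStop("prevalence undefined for an empty cohort (0 studies)")
  counts <- colSums(matrix@presence)
  data.frame(finding = findingNames(matrix),
             count = as.integer(counts),
             proportion = as.numeric(counts) / n,
             row.names = NULL)
}

#' Prevalence-ratio table across the two cohorts
#'
#' For each catalogue finding, the proportion positive in the cancer cohort
#' (prev1), in the referral cohort (prev2), and their ratio prev1/prev2 —
#' the key finding-selection metric. A finding present in cancers but absent
#' from referrals gets ratio `Inf` (maximally discriminative); a finding
#' absent from both gets `NaN` (uninformative, never selected by threshold).
#'
#' @param cancer,referral [CohortMatrix-class] objects aligned to `catalogue`.
#' @param catalogue the [FindingCatalogue-class].
#' @param continuityCorrection add 0.5 to all four counts before forming the
#'   ratio (off by default; raw ratios are the standard output).
#' @return data.frame with columns `finding, priority_class, count1, n1,
#'   prev1, count2, n2, prev2, ratio`, one row per catalogue finding in
#'   catalogue order.
#' @export
prevalenceRatioTable <- function(cancer, referral, catalogue,
                                 continuityCorrection = FALSE) {
  for (m in list(cancer, referral)) {
    if (!identical(findingNames(m), catalogue@finding))
      cxrStop(sprintf("cohort '%s' columns are not aligned to the catalogue",
                      cohortLabel(m)))
  }
  p1 <- findingPrevalence(cancer)
  p2 <- findingPrevalence(referral)
  n1 <- nStudies(cancer)
  n2 <- nStudies(referral)
  if (continuityCorrection) {
    ratio <- ((p1$count + 0.5) / (n1 + 1)) / ((p2$count + 0.5) / (n2 + 1))
  } else {
    ratio <- p1$proportion / p2$proportion  # Inf when prev2 = 0; NaN for 0/0
  }
  data.frame(finding = catalogue@finding,
             priority_class = catalogue@priorityClass,
             count1 = p1$count, n1 = n1, prev1 = p1$proportion,
             count2 = p2$count, n2 = n2, prev2 = p2$proportion,
             ratio = ratio, row.names = NULL)
}

#' Sort a prevalence table by ratio, descending
#'
#' `Inf` ratios rank first, `NaN` last; ties keep catalogue (input) order so
#' reports are reproducible.
#'
#' @param table a prevalence-ratio table from [prevalenceRatioTable()].
#' @return the re-ordered table.
#' @export
sortByRatio <- function(table) {
  key <- table$ratio
  key[is.nan(key)] <- -Inf
  table[order(-key, seq_len(nrow(table))), , drop = FALSE]
}

#' Select findings by priority class and prevalence-ratio threshold
#'
#' The mechanism behind ratio-based strategies: keep findings whose priority
#' class is in `classes` and whose ratio strictly exceeds `minRatio`
#' (ties at the threshold are excluded; `Inf` always qualifies, `NaN` never
#' does). Result order is catalogue (table) order.
#'
#' @param table a prevalence-ratio table.
#' @param classes character vector of priority classes to consider
#'   (default "HIGH").
#' @param minRatio positive ratio threshold (default 5).
#' @param name name for the resulting configuration.
#' @return a [TriageConfiguration-class]; an empty selection is valid.
#' @export
selectByRatio <- function(table, classes = "HIGH", minRatio = 5,
                          name = sprintf("ratio_gt_%g", minRatio)) {
  if (!isScalarNumber(minRatio) && !identical(minRatio, Inf))
    cxrStop("minRatio must be a single positive number")
  if (minRatio <= 0) cxrStop("minRatio must be positive")
  keep <- table$priority_class %in% classes &
    !is.nan(table$ratio) & table$ratio > minRatio
  TriageConfiguration(table$finding[keep], name = name)
}

#' Write a prevalence-ratio table to CSV
#'
#' Special ratio values are serialised as the tokens `inf` and `nan`.
#'
#' @param table a prevalence-ratio table.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writePrevalenceCsv <- function(table, path) {
  out <- table
  r <- out$ratio
  out$ratio <- ifelse(is.nan(r), "nan", ifelse(is.infinite(r), "inf",
                                               format(r, digits = 15)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a prevalence-ratio table written by [writePrevalenceCsv()]
#'
#' @param path CSV path.
#' @return the table with numeric `ratio` (`Inf`/`NaN` restored).
#' @export
readPrevalenceCsv <- function(path) {
  if (!file.exists(path)) cxrStop(sprintf("table file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                        colClasses = c(ratio = "character"))
  df$ratio <- vapply(df$ratio, function(x) {
    switch(x, inf = Inf, nan = NaN, as.numeric(x))
  }, numeric(1), USE.NAMES = FALSE)
  df
}
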