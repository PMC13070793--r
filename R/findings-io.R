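## Reading, validating and writing the finding catalogue and cohort
## matrices. The binary data contract is enforced here so every downstream
## module can assume clean 0/1 matrices aligned to the catalogue.

#' Construct a finding catalogue
#'
#' @param finding character vector of unique finding names (order is
#'   canonical for the whole analysis).
#' @param priorityClass character vector of CRITICAL/HIGH/STANDARD, one per
#'   finding.
#' @return a [FindingCatalogue-class] object.
#' @examples
#' FindingCatalogue(c("solitary_lung_mass", "pneumothorax"),
#'                  c("HIGH", "CRITICAL"))
#' @export
FindingCatalogue <- function(finding, priorityClass) {
  new("FindingCatalogue", finding = as.character(finding),
      priorityClass = as.character(priorityClass))
}

#' Construct a cohort matrix
#'
#' @param presence numeric/integer/logical matrix with entries 0/1, study ids
#'   as rownames, finding names as colnames.
#' @param label cohort label.
#' @return a [CohortMatrix-class] object.
#' @export
CohortMatrix <- function(presence, label) {
  storage.mode(presence) <- "integer"
  new("CohortMatrix", label = label, presence = presence)
}

#' Construct a triage configuration
#'
#' @param selected character vector of finding names whose presence flags a
#'   study.
#' @param name configuration name.
#' @param includeCritical union the catalogue's CRITICAL findings into the
#'   flagging rule (default FALSE: CRITICAL findings form a separate
#'   always-prioritise stream outside cancer-metric computation).
#' @return a [TriageConfiguration-class] object.
#' @export
TriageConfiguration <- function(selected, name = "configuration",
                                includeCritical = FALSE) {
  new("TriageConfiguration", name = name,
      selected = as.character(selected), includeCritical = includeCritical)
}

#' Read a finding catalogue from CSV or JSON
#'
#' CSV files need the two columns `finding,priority_class`; JSON files hold
#' an array of objects with the same two keys. Class tokens are
#' case-sensitive (CRITICAL/HIGH/STANDARD). File order is preserved and
#' becomes the canonical column order for all cohort matrices.
#'
#' @param path path to a `.csv` or `.json` catalogue file.
#' @return a [FindingCatalogue-class] object.
#' @export
readCatalogue <- function(path) {
  if (!file.exists(path)) cxrStop(sprintf("catalogue file not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (!is.data.frame(df)) cxrStop("JSON catalogue must be an array of objects")
  } else {
    df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8")
  }
  need <- c("finding", "priority_class")
  if (!all(need %in% names(df)))
    cxrStop(sprintf("catalogue must have columns %s; found: %s",
                    paste(need, collapse = ","), paste(names(df), collapse = ",")))
  bad <- which(!df$priority_class %in% PRIORITY_CLASSES)
  if (length(bad))
    cxrStop(sprintf("unknown priority class '%s' at row %d of %s",
                    df$priority_class[bad[1]], bad[1], path))
  FindingCatalogue(df$finding, df$priority_class)
}

#' Write a finding catalogue to CSV
#'
#' @param catalogue a [FindingCatalogue-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeCatalogueCsv <- function(catalogue, path) {
  df <- data.frame(finding = catalogue@finding,
                   priority_class = catalogue@priorityClass)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a binary cohort matrix from CSV
#'
#' The file must have header `study_id,<finding_1>,...,<finding_K>` with
#' `study_id` first, cells strictly "0" or "1" (no blanks, no true/false),
#' and unique study ids. The finding columns must be exactly the catalogue's
#' name set in any order; columns are re-ordered to catalogue order.
#'
#' @param path path to the cohort CSV.
#' @param catalogue the [FindingCatalogue-class] defining the expected
#'   columns and their canonical order.
#' @param label cohort label stored on the result.
#' @return a [CohortMatrix-class] object.
#' @export
readCohortCsv <- function(path, catalogue, label) {
  if (!file.exists(path)) cxrStop(sprintf("cohort file not found: %s", path))
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  if (length(names(df)) < 1L || names(df)[1] != "study_id")
    cxrStop(sprintf("first column of %s must be study_id", path))
  cols <- setdiff(names(df), "study_id")
  missing <- setdiff(catalogue@finding, cols)
  extra <- setdiff(cols, catalogue@finding)
  if (length(missing) || length(extra))
    cxrStop(sprintf(
      "cohort columns do not match catalogue in %s; missing: [%s]; extra: [%s]",
      path, paste(missing, collapse = ", "), paste(extra, collapse = ", ")))
  dupIds <- unique(df$study_id[duplicated(df$study_id)])
  if (length(dupIds))
    cxrStop(sprintf("duplicate study_id in %s: %s", path,
                    paste(dupIds, collapse = ", ")))
  values <- as.matrix(df[, catalogue@finding, drop = FALSE])
  bad <- which(!(values == "0" | values == "1"), arr.ind = TRUE)
  if (nrow(df) > 0L && nrow(bad)) {
    i <- bad[1, 1]; j <- bad[1, 2]
    cxrStop(sprintf(
      "non-binary cell '%s' at data row %d, column '%s' of %s (only 0/1 allowed)",
      values[i, j], i, catalogue@finding[j], path))
  }
  m <- matrix(as.integer(values), nrow = nrow(df),
              ncol = length(catalogue@finding),
              dimnames = list(df$study_id, catalogue@finding))
  CohortMatrix(m, label = label)
}

#' Write a cohort matrix to CSV
#'
#' Writes the `study_id,<finding...>` layout accepted by [readCohortCsv()];
#' write-then-read is the identity on study ids, finding names and values,
#' and the output is byte-stable for a given matrix.
#'
#' @param matrix a [CohortMatrix-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeMatrixCsv <- function(matrix, path) {
  m <- matrix@presence
  df <- data.frame(study_id = rownames(m) %||% character(0),
                   as.data.frame(m), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
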