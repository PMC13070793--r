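## Configuration search: the named strategies (ratio-threshold selection,
## all-HIGH, and a clinically curated list read from file), plus an explicit
## sensitivity-vs-workload frontier search over candidate finding subsets.
## The frontier search generalises the manual strategy refinement into a
## reproducible procedure; it is an extension beyond the published workflow
## and is labelled as such in the documentation.

#' Build one of the named prioritisation strategies
#'
#' * `strategy1`: HIGH-class findings with prevalence ratio strictly
#'   greater than 5 (specificity-maximising).
#' * `strategy2`: all HIGH-class findings (sensitivity-maximising).
#' * `strategy3_file`: a clinically curated finding list read from
#'   `strategy3Path` — clinical consensus is an input, not a computation.
#'
#' @param catalogue the [FindingCatalogue-class].
#' @param table prevalence-ratio table from [prevalenceRatioTable()]
#'   (needed for `strategy1`; ignored otherwise).
#' @param which one of "strategy1", "strategy2", "strategy3_file".
#' @param strategy3Path file with one finding name per line; blank lines and
#'   `#` comments are skipped.
#' @param minRatio ratio threshold for `strategy1` (default 5).
#' @return a [TriageConfiguration-class].
#' @export
namedStrategy <- function(catalogue, table = NULL,
                          which = c("strategy1", "strategy2", "strategy3_file"),
                          strategy3Path = NULL, minRatio = 5) {
  which <- match.arg(which)
  switch(which,
    strategy1 = {
      if (is.null(table)) cxrStop("strategy1 requires a prevalence-ratio table")
      selectByRatio(table, classes = "HIGH", minRatio = minRatio,
                    name = "strategy1")
    },
    strategy2 = TriageConfiguration(
      catalogue@finding[catalogue@priorityClass == "HIGH"], name = "strategy2"),
    strategy3_file = {
      if (is.null(strategy3Path)) cxrStop("strategy3_file requires a path")
      sel <- readStrategyList(strategy3Path)
      unknown <- setdiff(sel, catalogue@finding)
      if (length(unknown))
        cxrStop(sprintf("strategy-3 list names unknown finding(s): %s",
                        paste(unknown, collapse = ", ")))
      # catalogue order for reproducible reports
      TriageConfiguration(catalogue@finding[catalogue@finding %in% sel],
                          name = "strategy3")
    })
}

#' Read a finding-list file (one name per line, # comments allowed)
#'
#' @param path file path.
#' @return character vector of finding names.
#' @export
readStrategyList <- function(path) {
  if (!file.exists(path)) cxrStop(sprintf("strategy list not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}

#' Write a strategy finding list
#'
#' @param config a [TriageConfiguration-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeStrategyList <- function(config, path) {
  writeLines(config@selected, path)
  invisible(path)
}

## Shared by the frontier searches: per-finding flag columns restricted to
## the candidate set, so subset evaluation is a cheap column-OR.
frontierContext <- function(cancer, referral, catalogue, candidates) {
  unknown <- setdiff(candidates, catalogue@finding)
  if (length(unknown))
    cxrStop(sprintf("candidate finding(s) not in catalogue: %s",
                    paste(unknown, collapse = ", ")))
  cand <- catalogue@finding[catalogue@finding %in% candidates]  # catalogue order
  list(cand = cand,
       m1 = presenceMatrix(cancer)[, cand, drop = FALSE] > 0L,
       m2 = presenceMatrix(referral)[, cand, drop = FALSE] > 0L,
       n1 = nStudies(cancer), n2 = nStudies(referral))
}

frontierEval <- function(ctx, idx) {
  if (length(idx) == 0L) return(c(sens = 0, wl = 0))
  c(sens = sum(rowSums(ctx$m1[, idx, drop = FALSE]) > 0L) / ctx$n1,
    wl = sum(rowSums(ctx$m2[, idx, drop = FALSE]) > 0L) / ctx$n2)
}

frontierPoint <- function(ctx, idx) {
  ev <- frontierEval(ctx, idx)
  data.frame(n_findings = length(idx),
             findings = paste(ctx$cand[idx], collapse = ";"),
             sensitivity = ev[["sens"]], pct_flagged2 = ev[["wl"]],
             row.names = NULL)
}

## Pareto filter: maximise sensitivity, minimise workload. Exact duplicates
## on both coordinates collapse to the smallest subset (then first in
## enumeration order).
paretoFilter <- function(points) {
  ord <- order(points$pct_flagged2, -points$sensitivity, points$n_findings)
  points <- points[ord, , drop = FALSE]
  bestSens <- -Inf
  keep <- logical(nrow(points))
  for (i in seq_len(nrow(points))) {
    if (points$sensitivity[i] > bestSens + 1e-15) {
      keep[i] <- TRUE
      bestSens <- points$sensitivity[i]
    }
  }
  out <- points[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exhaustive sensitivity-workload frontier over candidate subsets
#'
#' Enumerates all 2^k subsets of the candidate findings, evaluates cancer
#' sensitivity (cohort 1) and flagged fraction (referral cohort) for each,
#' and returns the Pareto-optimal set: no returned configuration is beaten
#' on sensitivity by another with equal or lower workload.
#'
#' @inheritParams pseudoConfusion
#' @param candidates character vector of candidate finding names.
#' @param maxCandidates refuse enumeration beyond this many candidates
#'   (default 20; use [greedyFrontier()] for larger sets).
#' @return data.frame with columns `n_findings, findings` (";"-joined,
#'   catalogue order), `sensitivity, pct_flagged2`, sorted by workload
#'   ascending (sensitivity non-decreasing).
#' @export
exhaustiveFrontier <- function(cancer, referral, catalogue, candidates,
                               maxCandidates = 20) {
  ctx <- frontierContext(cancer, referral, catalogue, candidates)
  k <- length(ctx$cand)
  if (k > maxCandidates)
    cxrStop(sprintf(
      "%d candidates exceed maxCandidates = %d (2^k enumeration); use greedyFrontier",
      k, maxCandidates))
  subsets <- lapply(0:(2^k - 1), function(code) which(bitwAnd(code, 2^(0:(k - 1))) > 0))
  points <- do.call(rbind, lapply(subsets, function(idx) frontierPoint(ctx, idx)))
  paretoFilter(points)
}

#' Greedy forward-selection frontier
#'
#' Starts from the empty configuration and repeatedly adds the candidate
#' finding maximising the sensitivity gain per unit of added referral
#' workload (gain ratio; the workload denominator is floored at one referral
#' study, 1/n2, so zero-workload findings are always taken first). Stops
#' when the workload budget would be exceeded or no finding adds
#' sensitivity. Ties break by catalogue order, so the path is deterministic
#' and independent of candidate input order. The greedy path is not
#' guaranteed Pareto-optimal; compare with [exhaustiveFrontier()] on small
#' candidate sets.
#'
#' @inheritParams exhaustiveFrontier
#' @param workloadBudget maximum flagged fraction of the referral cohort,
#'   in (0, 1].
#' @return data.frame as in [exhaustiveFrontier()], one row per accepted
#'   finding, in acceptance order (workload non-decreasing).
#' @export
greedyFrontier <- function(cancer, referral, catalogue, candidates,
                           workloadBudget = 1) {
  if (!isScalarNumber(workloadBudget) ||
      workloadBudget <= 0 || workloadBudget > 1)
    cxrStop("workloadBudget must lie in (0, 1]")
  ctx <- frontierContext(cancer, referral, catalogue, candidates)
  eps <- 1 / ctx$n2
  chosen <- integer(0)
  path <- list()
  remaining <- seq_along(ctx$cand)
  cur <- frontierEval(ctx, chosen)
  repeat {
    if (length(remaining) == 0L) break
    best <- NULL
    bestScore <- 0
    for (j in remaining) {  # candidates in catalogue order -> first best wins ties
      ev <- frontierEval(ctx, c(chosen, j))
      dSens <- ev[["sens"]] - cur[["sens"]]
      dWl <- ev[["wl"]] - cur[["wl"]]
      if (dSens <= 0 || ev[["wl"]] > workloadBudget) next
      score <- dSens / max(dWl, eps)
      if (score > bestScore + 1e-15) {
        bestScore <- score
        best <- j
      }
    }
    if (is.null(best)) break
    chosen <- c(chosen, best)
    remaining <- setdiff(remaining, best)
    cur <- frontierEval(ctx, chosen)
    path[[length(path) + 1L]] <- frontierPoint(ctx, sort(chosen))
  }
  if (length(path) == 0L)
    return(data.frame(n_findings = integer(0), findings = character(0),
                      sensitivity = numeric(0), pct_flagged2 = numeric(0)))
  out <- do.call(rbind, path)
  rownames(out) <- NULL
  out
}

#' Write a frontier to CSV
#'
#' @param frontier data.frame from [exhaustiveFrontier()] or
#'   [greedyFrontier()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeFrontierCsv <- function(frontier, path) {
  utils::write.csv(frontier, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
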