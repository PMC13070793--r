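# Named strategies and the sensitivity/workload frontier search.

# Independent full-enumeration oracle, written against the raw matrices.
oracleFrontier <- function(cancer, referral, candidates) {
  m1 <- presenceMatrix(cancer)
  m2 <- presenceMatrix(referral)
  points <- list()
  for (code in 0:(2^length(candidates) - 1)) {
    idx <- which(as.logical(bitwAnd(code, 2^(seq_along(candidates) - 1))))
    sel <- candidates[idx]
    sens <- if (length(sel)) mean(apply(m1[, sel, drop = FALSE] == 1, 1, any)) else 0
    wl <- if (length(sel)) mean(apply(m2[, sel, drop = FALSE] == 1, 1, any)) else 0
    points[[code + 1]] <- c(sens = sens, wl = wl, size = length(sel))
  }
  pts <- do.call(rbind, points)
  # keep points not dominated by any other (higher sens at <= workload)
  keep <- vapply(seq_len(nrow(pts)), function(i) {
    !any((pts[, "sens"] > pts[i, "sens"] + 1e-15 &
            pts[, "wl"] <= pts[i, "wl"] + 1e-15) |
           (pts[, "sens"] >= pts[i, "sens"] - 1e-15 &
              pts[, "wl"] < pts[i, "wl"] - 1e-15))
  }, logical(1))
  unique(pts[keep, c("sens", "wl"), drop = FALSE])
}

test_that("named strategies have the expected sizes on the full demo fixture", {
  fx <- demoFixture(2, "full")
  tab <- prevalenceRatioTable(fx$cancer, fx$referral, fx$catalogue)

  s1 <- namedStrategy(fx$catalogue, tab, "strategy1")
  s2 <- namedStrategy(fx$catalogue, which = "strategy2")
  expect_length(s1, 18L)
  expect_length(s2, 41L)
  expect_true(all(selectedFindings(s1) %in% selectedFindings(s2)))

  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# curated demo list", fx$strategy3), path)
  s3 <- namedStrategy(fx$catalogue, which = "strategy3_file", strategy3Path = path)
  expect_length(s3, 32L)
  # selection is reported in catalogue order regardless of file order
  expect_identical(selectedFindings(s3),
                   findingNames(fx$catalogue)[findingNames(fx$catalogue) %in%
                                                fx$strategy3])

  writeLines(c(fx$strategy3, "not_a_real_finding"), path)
  expect_error(namedStrategy(fx$catalogue, which = "strategy3_file",
                             strategy3Path = path), "not_a_real_finding")
})

test_that("strategy-list files support comments and blank lines", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# header", "", "pleural_effusion  ", "consolidation # inline"),
             path)
  expect_identical(readStrategyList(path), c("pleural_effusion", "consolidation"))
})

test_that("exhaustive frontier matches brute-force enumeration", {
  # single candidate: frontier within {empty, singleton}
  cat1 <- tinyCatalogue(1)
  c1 <- makeCohort(matrix(c(1, 1, 0, 0)), cat1, "cancer")
  c2 <- makeCohort(matrix(c(1, 0, 0, 0, 0)), cat1, "referral")
  fr <- exhaustiveFrontier(c1, c2, cat1, "finding_1")
  expect_lte(nrow(fr), 2L)
  expect_true(all(fr$n_findings %in% c(0L, 1L)))

  # two findings flagging disjoint cancer studies: union dominates at the
  # summed workload
  cat2 <- tinyCatalogue(2)
  c1 <- makeCohort(rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1), c(0, 0), c(0, 0)),
                   cat2, "cancer")
  c2 <- makeCohort(rbind(c(1, 0), c(0, 1), c(0, 0), c(0, 0)), cat2, "referral")
  fr2 <- exhaustiveFrontier(c1, c2, cat2, findingNames(cat2))
  union <- fr2[fr2$n_findings == 2, ]
  expect_equal(union$sensitivity, 4 / 6)
  expect_equal(union$pct_flagged2, 2 / 4)

  # k = 8 random fixture against the independent 2^8 scan
  set.seed(17)
  cat8 <- tinyCatalogue(8)
  c1 <- randomCohort(40, cat8, p = 0.25, label = "cancer")
  c2 <- randomCohort(60, cat8, p = 0.10, label = "referral")
  fr8 <- exhaustiveFrontier(c1, c2, cat8, findingNames(cat8))
  oracle <- oracleFrontier(c1, c2, findingNames(cat8))
  got <- unique(cbind(sens = fr8$sensitivity, wl = fr8$pct_flagged2))
  expect_equal(got[order(got[, "wl"], got[, "sens"]), , drop = FALSE],
               oracle[order(oracle[, "wl"], oracle[, "sens"]), , drop = FALSE])

  expect_error(exhaustiveFrontier(c1, c2, cat8, findingNames(cat8),
                                  maxCandidates = 4), "greedyFrontier")
})

test_that("frontier points are mutually non-dominated and sorted", {
  set.seed(23)
  cat6 <- tinyCatalogue(6)
  c1 <- randomCohort(30, cat6, p = 0.3, label = "cancer")
  c2 <- randomCohort(50, cat6, p = 0.15, label = "referral")
  fr <- exhaustiveFrontier(c1, c2, cat6, findingNames(cat6))
  expect_true(all(diff(fr$pct_flagged2) >= 0))
  expect_true(all(diff(fr$sensitivity) > 0))
  for (i in seq_len(nrow(fr))) {
    dominated <- any(fr$sensitivity > fr$sensitivity[i] + 1e-15 &
                       fr$pct_flagged2 <= fr$pct_flagged2[i] + 1e-15)
    expect_false(dominated)
  }
})

test_that("greedy frontier respects budget, order-invariance and the oracle", {
  set.seed(41)
  cat8 <- tinyCatalogue(8)
  c1 <- randomCohort(40, cat8, p = 0.25, label = "cancer")
  c2 <- randomCohort(60, cat8, p = 0.15, label = "referral")

  # infeasible budget (below any single finding's flag rate) -> empty path
  minRate <- min(colMeans(presenceMatrix(c2)))
  stopifnot(minRate > 0)
  none <- greedyFrontier(c1, c2, cat8, findingNames(cat8),
                         workloadBudget = minRate / 2)
  expect_equal(nrow(none), 0L)

  # unconstrained: terminal sensitivity equals the full candidate set's
  full <- greedyFrontier(c1, c2, cat8, findingNames(cat8), workloadBudget = 1)
  allSens <- mean(apply(presenceMatrix(c1) == 1, 1, any))
  expect_equal(full$sensitivity[nrow(full)], allSens)
  expect_true(all(diff(full$pct_flagged2) >= 0))

  # permutation-invariant in candidate order
  perm <- greedyFrontier(c1, c2, cat8, sample(findingNames(cat8)),
                         workloadBudget = 1)
  expect_identical(perm, full)

  # each greedy point is on or below the exhaustive frontier; report the gap
  exact <- exhaustiveFrontier(c1, c2, cat8, findingNames(cat8))
  gaps <- vapply(seq_len(nrow(full)), function(i) {
    best <- max(exact$sensitivity[exact$pct_flagged2 <= full$pct_flagged2[i] + 1e-12])
    best - full$sensitivity[i]
  }, numeric(1))
  expect_true(all(gaps >= -1e-12))
  expect_lt(max(gaps), 0.25)  # greedy is heuristic; bound the observed gap
})

test_that("zero-workload findings are taken before costly ones", {
  cat3 <- tinyCatalogue(3)
  # finding_3 captures a cancer study but never flags a referral
  c1 <- makeCohort(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 0, 1)),
                   cat3, "cancer")
  c2 <- makeCohort(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 0), c(0, 0, 0)),
                   cat3, "referral")
  path <- greedyFrontier(c1, c2, cat3, findingNames(cat3), workloadBudget = 1)
  expect_identical(path$findings[1], "finding_3")
  expect_equal(path$pct_flagged2[1], 0)
})
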