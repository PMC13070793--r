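# Flagging, the pseudo confusion matrix under an assumed prevalence, and
# the metric panel.

test_that("study flagging is an OR over selected findings", {
  cat <- tinyCatalogue(3, classes = c("CRITICAL", "HIGH", "HIGH"))
  m <- makeCohort(rbind(c(1, 0, 0), c(0, 0, 1), c(0, 0, 0)), cat)

  none <- TriageConfiguration(character(0))
  expect_identical(unname(flagStudies(m, none, cat)), rep(FALSE, 3))

  single <- TriageConfiguration("finding_1")
  expect_identical(unname(flagStudies(m, single, cat)), c(TRUE, FALSE, FALSE))

  # includeCritical unions the CRITICAL set into the rule
  high <- TriageConfiguration("finding_3", includeCritical = TRUE)
  expect_identical(unname(flagStudies(m, high, cat)), c(TRUE, TRUE, FALSE))

  expect_error(flagStudies(m, TriageConfiguration("no_such"), cat), "no_such")
})

test_that("flagging equals a brute-force OR oracle on random small cohorts", {
  set.seed(123)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    n <- sample(1:10, 1)
    cat <- tinyCatalogue(k)
    m <- randomCohort(n, cat, p = runif(1, 0.1, 0.6))
    sel <- sample(findingNames(cat), sample(0:k, 1))
    cfg <- TriageConfiguration(sel)
    expect_identical(unname(flagStudies(m, cfg, cat)),
                     bruteForceFlags(m, sel))
  }
})

test_that("pseudo confusion follows the assumed-prevalence model", {
  # 1% of 13,802 referrals -> 138 modelled positives
  pc <- pseudoConfusionFromCounts(1164, 1282, 1490, 13802, 0.01)
  expect_equal(pc@pPos, 138)

  # hand arithmetic from the stated formulas (strategy-1 counts)
  sens <- 1164 / 1282
  expect_equal(pc@tp2, 138 * sens)              # ~125.30
  expect_equal(pc@fn2, 138 - 138 * sens)        # ~12.70
  expect_equal(pc@fp, 1490 - 138 * sens)        # ~1364.70
  expect_equal(pc@tn, (13802 - 138) - (1490 - 138 * sens))  # ~12299.30
  expect_equal(pc@tp2 + pc@fn2 + pc@fp + pc@tn, 13802)

  # no-positives limit
  pc0 <- pseudoConfusionFromCounts(1164, 1282, 1490, 13802, 0)
  expect_equal(pc0@tp2, 0)
  expect_equal(pc0@fn2, 0)
  expect_equal(pc0@fp, 1490)
  expect_equal(pc0@tn, 13802 - 1490)

  # pi inconsistent with the observed flag rate fails loudly
  expect_error(pseudoConfusionFromCounts(100, 100, 5, 1000, 0.5),
               "inconsistent with the observed flag rate",
               class = "cxr_model_error")
})

test_that("matrix-based and count-based confusion agree", {
  cc <- countCohorts(tp1 = 37, n1 = 50, flagged2 = 21, n2 = 200)
  pc <- pseudoConfusion(cc$cancer, cc$referral, cc$config, cc$catalogue, 0.02)
  expect_equal(pc@tp1, 37)
  expect_equal(pc@flagged2, 21)
  ref <- pseudoConfusionFromCounts(37, 50, 21, 200, 0.02)
  expect_equal(pc@tp2, ref@tp2)
  expect_equal(pc@tn, ref@tn)
})

test_that("metric panel formulas and undefined markers", {
  # perfect triage: flags exactly the modelled positives
  pc <- pseudoConfusionFromCounts(100, 100, 10, 1000, 0.01)
  m <- computeMetrics(pc)
  expect_equal(m@sensitivity, 1)
  expect_equal(m@specificity, 1)
  expect_equal(m@ppv, 1)
  expect_equal(m@npv, 1)

  # pi = 0: no modelled positives -> PPV and NNR+ undefined, not an error
  m0 <- computeMetrics(pseudoConfusionFromCounts(80, 100, 50, 1000, 0))
  expect_true(is.na(m0@ppv))
  expect_true(is.na(m0@nnrPos))
  expect_true(is.na(m0@nnrNeg))  # fn2 = 0 too
  expect_equal(m0@specificity, (1000 - 50 - 0) / 1000)
})

test_that("Wald interval matches closed form and clamps", {
  ci <- waldCi(0.5, 100, 0.95)
  expect_equal(round(ci, 3), c(0.402, 0.598))

  expect_equal(waldCi(0, 50), c(0, 0))
  expect_equal(waldCi(1, 50), c(1, 1))

  # hand-computed: p = 12299/13664 = 0.9001025, half-width = 0.0050281
  ci2 <- waldCi(12299 / 13664, 13664, 0.95)
  expect_equal(round(ci2, 4), c(0.8951, 0.9051))

  expect_error(waldCi(1.2, 10), "\\[0, 1\\]")
  expect_error(waldCi(0.5, 0), ">= 1")
})

test_that("prevalence sweep holds flag counts fixed and annotates failures", {
  cc <- countCohorts(tp1 = 90, n1 = 100, flagged2 = 60, n2 = 500)
  sweep <- prevalenceSweep(cc$cancer, cc$referral, cc$config, cc$catalogue,
                           c(0.005, 0.01, 0.02))
  tab <- sweepTable(sweep)
  expect_equal(tab$parameter, c(0.005, 0.01, 0.02))
  # sensitivity and flagged fraction depend only on the data, not pi
  expect_length(unique(tab$sensitivity), 1L)
  expect_length(unique(tab$pct_flagged2), 1L)

  # single point equals the direct computation
  single <- prevalenceSweep(cc$cancer, cc$referral, cc$config, cc$catalogue, 0.01)
  direct <- evaluateStrategy(cc$cancer, cc$referral, cc$config, cc$catalogue, 0.01)
  expect_equal(sweepTable(single)$specificity, direct@specificity)
  expect_equal(sweepTable(single)$npv, direct@npv)

  # an infeasible pi is reported with the offending value
  expect_error(
    prevalenceSweep(cc$cancer, cc$referral, cc$config, cc$catalogue,
                    c(0.01, 0.5)),
    "at pi = 0.5", class = "cxr_model_error")

  expect_error(
    prevalenceSweep(cc$cancer, cc$referral, cc$config, cc$catalogue,
                    c(0.02, 0.01)),
    "strictly increasing")
})

test_that("ratio-threshold sweep shrinks selections monotonically", {
  fx <- demoFixture(5, "test")
  sweep <- ratioThresholdSweep(fx$cancer, fx$referral, fx$catalogue,
                               classes = "HIGH", thresholds = c(1, 2, 5, 10),
                               pi = 0.01)
  tab <- sweepTable(sweep)
  expect_true(all(diff(tab$pct_flagged2) <= 1e-12))
  expect_true(all(diff(tab$sensitivity) <= 1e-12))

  # brute-force recomputation per threshold on a small table
  table <- prevalenceRatioTable(fx$cancer, fx$referral, fx$catalogue)
  for (i in seq_along(sweep@parameter)) {
    t <- sweep@parameter[i]
    keep <- table$finding[table$priority_class == "HIGH" &
                            !is.nan(table$ratio) & table$ratio > t]
    flags1 <- bruteForceFlags(fx$cancer, keep)
    expect_equal(sweep@metrics[[i]]@sensitivity,
                 sum(flags1) / nStudies(fx$cancer))
  }

  # threshold below every ratio selects the whole eligible class
  lowest <- selectByRatio(table, "HIGH",
                          min(table$ratio[is.finite(table$ratio)]) / 2)
  expect_identical(selectedFindings(lowest),
                   table$finding[table$priority_class == "HIGH"])
})

test_that("strategy comparison preserves superset monotonicity", {
  fx <- demoFixture(8, "test")
  high <- findingNames(fx$catalogue)[priorityClass(fx$catalogue) == "HIGH"]
  a <- TriageConfiguration(high[1:3], name = "A")
  b <- TriageConfiguration(high[1:6], name = "B")
  res <- compareStrategies(fx$cancer, fx$referral, fx$catalogue, list(a, b))
  expect_named(res, c("A", "B"))
  expect_gte(res$B@sensitivity, res$A@sensitivity)
  expect_gte(res$B@pctFlagged2, res$A@pctFlagged2)
  expect_gte(res$B@pctFlagged1, res$A@pctFlagged1)

  # one configuration: identical to the direct evaluation
  solo <- compareStrategies(fx$cancer, fx$referral, fx$catalogue, list(a))
  direct <- evaluateStrategy(fx$cancer, fx$referral, a, fx$catalogue)
  expect_equal(solo$A@specificity, direct@specificity)

  tab <- metricsTable(res, list(a, b))
  expect_equal(tab$n_selected, c(3L, 6L))
  expect_equal(nrow(tab), 2L)
})

test_that("panel invariants hold on randomized inputs", {
  set.seed(31)
  for (rep in 1:25) {
    n1 <- sample(20:200, 1)
    n2 <- sample(200:2000, 1)
    tp1 <- sample(0:n1, 1)
    pi <- runif(1, 0, 0.05)
    # keep flagged2 above the modelled positives so the model is feasible
    minFlag <- ceiling(round(pi * n2) * tp1 / n1)
    flagged2 <- minFlag + sample.int(n2 - minFlag + 1, 1) - 1
    pc <- pseudoConfusionFromCounts(tp1, n1, flagged2, n2, pi)
    expect_equal(pc@tp2 + pc@fn2 + pc@fp + pc@tn, n2)
    m <- computeMetrics(pc)
    expect_identical(m@fnr, 1 - m@sensitivity)
    expect_identical(m@fpr, 1 - m@specificity)
    if (!is.na(m@ppv)) expect_equal(m@nnrPos * m@ppv, 1)
    expect_true(m@sensitivityCi[1] <= m@sensitivity &&
                  m@sensitivity <= m@sensitivityCi[2])
    expect_true(m@specificityCi[1] <= m@specificity &&
                  m@specificity <= m@specificityCi[2])
  }
})

test_that("metrics reports render to CSV and JSON with display rounding", {
  pc <- pseudoConfusionFromCounts(1164, 1282, 1490, 13802, 0.01)
  tab <- metricsTable(list(computeMetrics(pc, name = "strategy1")))
  expect_equal(tab$tp2_display, 125)
  expect_equal(tab$fn2_display, 13)
  expect_equal(tab$fp_display, 1365)
  expect_equal(tab$tn_display, 12299)
  expect_equal(tab$sensitivity_pct, 90.80)
  expect_equal(tab$nnr_pos_display, 12)

  csv <- withr::local_tempfile(fileext = ".csv")
  json <- withr::local_tempfile(fileext = ".json")
  writeMetricsReport(tab, csv, json)
  backCsv <- read.csv(csv)
  backJson <- jsonlite::fromJSON(json)
  expect_equal(backCsv$specificity_pct, 90.01)
  expect_equal(backJson$specificity_pct, 90.01)
  expect_equal(backJson$strategy, "strategy1")
})
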