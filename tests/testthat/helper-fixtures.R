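# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

tinyCatalogue <- function(k = 3, classes = rep("HIGH", k),
                          names = sprintf("finding_%d", seq_len(k))) {
  FindingCatalogue(names, classes)
}

# Cohort from an explicit 0/1 matrix, columns named after the catalogue.
makeCohort <- function(values, catalogue, label = "cohort",
                       prefix = substr(label, 1, 1)) {
  m <- as.matrix(values)
  dimnames(m) <- list(sprintf("%s%03d", prefix, seq_len(nrow(m))),
                      findingNames(catalogue))
  CohortMatrix(m, label)
}

randomCohort <- function(n, catalogue, p = 0.3, label = "cohort") {
  k <- length(catalogue)
  makeCohort(matrix(rbinom(n * k, 1, p), nrow = n), catalogue, label)
}

# Degenerate single-finding cohorts realising exact aggregate flag counts,
# so published count-level results can be pushed through the full
# matrix-based pipeline.
countCohorts <- function(tp1, n1, flagged2, n2) {
  catalogue <- FindingCatalogue("flagging_finding", "HIGH")
  cancer <- makeCohort(matrix(rep(c(1L, 0L), c(tp1, n1 - tp1))),
                       catalogue, "cancer")
  referral <- makeCohort(matrix(rep(c(1L, 0L), c(flagged2, n2 - flagged2))),
                         catalogue, "referral")
  list(catalogue = catalogue, cancer = cancer, referral = referral,
       config = TriageConfiguration("flagging_finding", name = "counts"))
}

# Independent brute-force flagging oracle: per-study any() over selected
# columns, written without the package's vectorised path.
bruteForceFlags <- function(matrix, selected) {
  m <- presenceMatrix(matrix)
  vapply(seq_len(nrow(m)), function(i) {
    any(vapply(selected, function(f) m[i, f] == 1L, logical(1)))
  }, logical(1))
}
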