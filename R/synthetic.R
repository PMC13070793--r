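## Correlated binary cohort simulator. Each study draws one latent severity
## factor z ~ N(0, 1); finding f with loading l_f is present iff
##
##   l_f * z + sqrt(1 - l_f^2) * e_f  <=  qnorm(target prevalence),
##
## with e_f independent standard normal — a one-factor Gaussian-copula
## threshold model. Marginals hit their targets exactly in expectation for
## any loading; positive loadings make findings co-occur on the same
## (sicker) studies, mirroring the clinical pattern that drives multi-
## finding studies. RNG: Mersenne-Twister with inversion normals, seeded
## once per generation call, cancer cohort drawn before referral.

#' Construct a synthetic-cohort specification
#'
#' @param findings data.frame with columns `finding`, `priority_class`,
#'   `prev1` (target marginal in the cancer cohort), `prev2` (target in the
#'   referral cohort) and `loading` in [-1, 1].
#' @param n1,n2 cohort sizes (cancer, referral).
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return a [SyntheticSpec-class] object.
#' @export
SyntheticSpec <- function(findings, n1, n2, seed) {
  new("SyntheticSpec", n1 = as.numeric(n1), n2 = as.numeric(n2),
      findings = as.data.frame(findings), seed = as.numeric(seed))
}

#' Generate a pair of correlated binary cohorts
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with elements `cancer` and `referral`, both
#'   [CohortMatrix-class] objects aligned to the spec's finding order; study
#'   ids are `c1_0001...` / `c2_0001...`.
#' @export
generateCohorts <- function(spec) {
  validObject(spec)
  set.seed(spec@seed %% .Machine$integer.max, kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  cancer <- drawCohort(spec@n1, spec@findings, spec@findings$prev1, "c1")
  referral <- drawCohort(spec@n2, spec@findings, spec@findings$prev2, "c2")
  list(cancer = CohortMatrix(cancer, "cancer"),
       referral = CohortMatrix(referral, "referral"))
}

drawCohort <- function(n, findings, prev, prefix) {
  k <- nrow(findings)
  l <- findings$loading
  z <- stats::rnorm(n)
  e <- matrix(stats::rnorm(n * k), nrow = n, ncol = k)
  x <- outer(z, l) + sweep(e, 2, sqrt(1 - l^2), `*`)
  thresh <- stats::qnorm(prev)  # -Inf at prev 0, +Inf at prev 1
  m <- matrix(0L, nrow = n, ncol = k,
              dimnames = list(sprintf("%s_%05d", prefix, seq_len(n)),
                              findings$finding))
  m[sweep(x, 2, thresh, `<=`)] <- 1L
  m
}

#' Derive a synthetic spec from an observed prevalence table
#'
#' Target marginals are set to the table's prev1/prev2, so generated cohorts
#' are "shaped like this site": recomputing the prevalence table on the
#' output recovers the input marginals up to binomial sampling error.
#'
#' @param table prevalence-ratio table from [prevalenceRatioTable()].
#' @param n1,n2 cohort sizes for the generated data.
#' @param defaultLoading latent-factor loading applied to every finding
#'   (default 0.35).
#' @param seed integer seed.
#' @return a [SyntheticSpec-class] object.
#' @export
specFromPrevalence <- function(table, n1, n2, defaultLoading = 0.35, seed) {
  SyntheticSpec(
    data.frame(finding = table$finding,
               priority_class = table$priority_class,
               prev1 = table$prev1, prev2 = table$prev2,
               loading = defaultLoading),
    n1 = n1, n2 = n2, seed = seed)
}

#' Read a synthetic spec from YAML or JSON
#'
#' Top-level keys `n1`, `n2`, `seed` and `findings` (array of records with
#' the [SyntheticSpec()] columns).
#'
#' @param path spec file path (`.yaml`/`.yml`/`.json`).
#' @return a [SyntheticSpec-class] object.
#' @export
readSyntheticSpec <- function(path) {
  if (!file.exists(path)) cxrStop(sprintf("spec file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("n1", "n2", "seed", "findings")
  if (!all(need %in% names(raw)))
    cxrStop(sprintf("spec must have keys: %s", paste(need, collapse = ", ")))
  f <- raw$findings
  if (!is.data.frame(f)) {
    # column map (yaml::write_yaml layout) or an array of records
    if (is.list(f) && !is.null(names(f))) {
      f <- as.data.frame(f)
    } else {
      f <- do.call(rbind, lapply(f, as.data.frame))
    }
  }
  SyntheticSpec(f, n1 = raw$n1, n2 = raw$n2, seed = raw$seed)
}

#' Write a synthetic spec to YAML
#'
#' @param spec a [SyntheticSpec-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeSyntheticSpec <- function(spec, path) {
  yaml::write_yaml(list(n1 = spec@n1, n2 = spec@n2, seed = spec@seed,
                        findings = spec@findings), path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Demo fixture. The finding names below mix terms used for chest X-ray AI
## findings with clearly labelled illustrative placeholders; the catalogue,
## classes and prevalences are ILLUSTRATIVE demo data, not any vendor's real
## finding list or any site's measured prevalences.

demoCatalogueFrame <- function(scale = c("full", "test")) {
  scale <- match.arg(scale)
  highStrong <- c(  # HIGH class, strongly cancer-associated in the demo
    "solitary_lung_mass", "inferior_mediastinal_mass", "superior_mediastinal_mass",
    "diffuse_upper_airspace_opacity", "diffuse_airspace_opacity",
    "cavitating_mass_with_content", "cavitating_mass", "hilar_lymphadenopathy",
    "multiple_masses_or_nodules", "solitary_nodule", "peribronchial_cuffing",
    "lung_collapse", "segmental_collapse", "pleural_mass",
    "rib_destructive_lesion", "focal_airspace_opacity", "lobar_airspace_opacity",
    "mediastinal_widening")
  highMild <- c(  # HIGH class, weakly discriminative in the demo
    "pleural_effusion", "loculated_pleural_effusion", "interstitial_thickening",
    "diffuse_interstitial_thickening", "consolidation", "linear_atelectasis",
    "bronchiectasis", "pulmonary_fibrosis", "apical_fibrosis",
    "pleural_thickening", "calcified_nodule", "granuloma",
    "hiatus_hernia", "cardiomegaly", "pericardial_effusion",
    "elevated_hemidiaphragm", "diaphragmatic_eventration",
    "kyphosis", "osteopaenia", "spinal_arthritis",
    "diffuse_spinal_osteophytes", "rib_fracture_old", "shoulder_arthritis")
  critical <- c(
    "pneumothorax", "tension_pneumothorax", "pneumomediastinum",
    "pneumoperitoneum", "misplaced_nasogastric_tube", "misplaced_central_line",
    "subcutaneous_emphysema", "large_pleural_effusion_critical",
    "acute_rib_fracture", "flail_segment", "widened_paratracheal_stripe",
    "acute_aortic_syndrome")
  nStd <- if (scale == "full") 124L - length(c(highStrong, highMild, critical)) else 9L
  standard <- sprintf("illustrative_standard_finding_%02d", seq_len(nStd))
  if (scale == "test") {
    highStrong <- highStrong[1:5]
    highMild <- highMild[1:3]
    critical <- critical[1:3]
  }
  data.frame(
    finding = c(critical, highStrong, highMild, standard),
    priority_class = c(rep("CRITICAL", length(critical)),
                       rep("HIGH", length(highStrong) + length(highMild)),
                       rep("STANDARD", length(standard))),
    group = c(rep("critical", length(critical)),
              rep("high_strong", length(highStrong)),
              rep("high_mild", length(highMild)),
              rep("standard", length(standard))))
}

#' Deterministic demo fixture
#'
#' Generates an illustrative catalogue plus cancer and referral cohorts. At
#' `scale = "full"` the shape is 1,282 x 124 and 13,802 x 124 and the demo
#' prevalences are calibrated with wide margins so the three named
#' strategies select 18 (HIGH with ratio > 5), 41 (all HIGH) and 32
#' (curated list) findings for any seed; at `scale = "test"` a small
#' 150 x 20 / 400 x 20 fixture is produced for fast pipelines.
#'
#' @param seed integer seed; identical seeds reproduce the fixture
#'   byte-for-byte.
#' @param scale "full" or "test".
#' @return list with elements `catalogue` ([FindingCatalogue-class]),
#'   `cancer`, `referral` ([CohortMatrix-class]), `strategy3` (character
#'   vector of curated finding names) and `spec` (the
#'   [SyntheticSpec-class] used).
#' @export
demoFixture <- function(seed = 20260101, scale = c("full", "test")) {
  scale <- match.arg(scale)
  frame <- demoCatalogueFrame(scale)
  prev <- switch(scale,
    full = list(critical = c(0.050, 0.020), high_strong = c(0.120, 0.008),
                high_mild = c(0.060, 0.030), standard = c(0.100, 0.080)),
    test = list(critical = c(0.080, 0.040), high_strong = c(0.350, 0.030),
                high_mild = c(0.150, 0.080), standard = c(0.120, 0.100)))
  frame$prev1 <- vapply(frame$group, function(g) prev[[g]][1], numeric(1))
  frame$prev2 <- vapply(frame$group, function(g) prev[[g]][2], numeric(1))
  frame$loading <- 0.35
  sizes <- switch(scale, full = c(1282, 13802), test = c(150, 400))
  spec <- SyntheticSpec(frame[, c("finding", "priority_class",
                                  "prev1", "prev2", "loading")],
                        n1 = sizes[1], n2 = sizes[2], seed = seed)
  cohorts <- generateCohorts(spec)
  highStrong <- frame$finding[frame$group == "high_strong"]
  highMild <- frame$finding[frame$group == "high_mild"]
  # curated demo list: all strongly-associated HIGH findings plus the first
  # clinically plausible additions from the mild group (32 at full scale)
  nExtra <- if (scale == "full") 14L else 2L
  strategy3 <- c(highStrong, utils::head(highMild, nExtra))
  list(catalogue = FindingCatalogue(frame$finding, frame$priority_class),
       cancer = cohorts$cancer, referral = cohorts$referral,
       strategy3 = strategy3, spec = spec)
}
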