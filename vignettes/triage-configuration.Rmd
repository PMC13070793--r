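---
title: "Configuring chest X-ray AI triage from shadow-mode data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Configuring chest X-ray AI triage from shadow-mode data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cxrtriage)
```

## The problem

Chest X-ray AI systems used for worklist triage emit, for every study, a
binary presence/absence call for each finding in a fixed catalogue (up to
124 findings for current systems). Before such a system can reorder a
reporting worklist, the deploying site must decide *which* findings should
escalate a study — a configuration choice, not a model property. `cxrtriage`
implements a data-driven workflow for making and evaluating that choice when
the target condition is lung cancer:

1. run the AI in shadow mode (outputs hidden from clinicians) over a general
   referral population, and over a retrospective cohort of confirmed,
   radiographically visible cancers;
2. rank findings by how much more prevalent they are among cancers than
   among referrals;
3. evaluate candidate configurations by the fraction of cancers they capture
   and the reporting workload they create, with cohort-2 accuracy metrics
   modelled under an assumed cancer prevalence.

## The model

### Flagging

A triage configuration is a subset $S$ of catalogue findings. Study $i$ with
binary finding vector $x_i$ is flagged iff $\max_{f \in S} x_{if} = 1$ (an
OR rule). CRITICAL-class findings (pneumothorax and the like) form a
separate always-prioritise stream: by default they are *not* unioned into
$S$ when computing cancer metrics, and `includeCritical = TRUE` exists for
modelling the combined live rule.

### The prevalence ratio

For finding $f$, with prevalence $p_{1f}$ in the cancer cohort and $p_{2f}$
in the referral cohort, the selection metric is the ratio
$r_f = p_{1f} / p_{2f}$. Conventions: $r_f = \infty$ when $p_{2f} = 0 <
p_{1f}$ (maximally discriminative, sorted first) and undefined (`NaN`) when
both are 0 (uninformative, never selected). Threshold selection is strict
($r_f > t$), so ties at the threshold are excluded. An optional
continuity-corrected ratio (add 0.5 to the four counts) is available but off
by default; the raw ratio is the standard output. No per-finding hypothesis
test is computed: the ranking is descriptive and feeds a clinical review,
not an inferential claim.

### The pseudo confusion matrix

Every cancer-cohort study is cancer-positive by construction, so
$\mathrm{sensitivity} = \mathrm{TP}_1 / n_1$ is observed directly. The
referral cohort has no per-study ground truth; instead a fixed detectable
cancer prevalence $\pi$ (default 1%) is assumed, giving
$P = \operatorname{round}(\pi n_2)$ modelled positives. These are allocated
proportionally to the observed sensitivity:

$$\mathrm{TP}_2 = P \cdot \mathrm{sens}, \quad
  \mathrm{FN}_2 = P - \mathrm{TP}_2, \quad
  \mathrm{FP} = \mathrm{flagged}_2 - \mathrm{TP}_2, \quad
  \mathrm{TN} = (n_2 - P) - \mathrm{FP},$$

from which specificity $= \mathrm{TN}/(\mathrm{TN}+\mathrm{FP})$, PPV, NPV,
FPR and the number-needed-to-report figures
($\mathrm{NNR}^+ = \mathrm{flagged}_2/\mathrm{TP}_2$, the CXRs reported in
the AI-positive stream per cancer found, and its AI-negative analogue)
follow. Two numerical choices matter and were fixed deliberately:

* **Only $P$ is rounded to an integer; the four cells stay real-valued.**
  Rounding the cells first visibly distorts PPV, NPV and NNR at realistic
  sizes; integer cells appear only in display output (`*_display` columns,
  half-away-from-zero).
* **Model guard.** If $\mathrm{TP}_2 > \mathrm{flagged}_2$ — the assumed
  prevalence implies more modelled cancers among flags than flags exist —
  the computation fails loudly (a distinct error class, CLI exit code 3)
  rather than emitting a negative FP.

Confidence intervals are Wald: $p \pm z_{(1+\gamma)/2}\sqrt{p(1-p)/n}$,
clamped to $[0,1]$, with $n_1$ for sensitivity and $n_2 - P$ (the modelled
negatives) for specificity. Wilson or exact intervals would be defensible
alternatives; Wald was chosen because it is the convention in the
spreadsheet-based tools this package formalises, and because published
configuration reports of this kind print Wald-consistent bounds. Display
note: a quantity computed at full precision can round differently from a
value recomputed from already-rounded cells (e.g. a specificity CI bound, or
an NNR in the third decimal); all package output rounds the full-precision
value, half away from zero.

These are **modelled (pseudo) metrics**: everything involving cohort 2
depends linearly on the single assumption $\pi$, which is why
`prevalenceSweep()` exists — it recomputes the panel across a $\pi$ grid
with the observed flag counts held fixed. Sensitivity and the flagged
fractions are structurally invariant across that sweep; only the modelled
allocation changes. `ratioThresholdSweep()` varies the selection threshold
instead, tracing the intrinsic trade-off between cancer capture and the
fraction of referrals prioritised.

## Named strategies and the frontier search

Three named configurations mirror the standard workflow: `strategy1`
(HIGH-class findings with ratio $> 5$; specificity-leaning), `strategy2`
(all HIGH findings; sensitivity-leaning) and `strategy3` (a clinically
curated list, read from a file — expert consensus is an *input* here, not a
computation). Beyond these, the package adds an explicit search, as an
extension of the manual refinement step:

* `exhaustiveFrontier()` enumerates all $2^k$ subsets of up to 20 candidate
  findings and returns the Pareto set on (sensitivity, fraction of referrals
  flagged). Workload is measured on the referral cohort only — the cancer
  cohort is enriched and says nothing about live workload.
* `greedyFrontier()` scales past 20 candidates by forward selection,
  maximising sensitivity gain per unit of added workload; the workload
  denominator is floored at one referral study ($1/n_2$) so findings that
  add capture at zero workload are always taken first. Ties break by
  catalogue order, making the path deterministic and invariant to candidate
  input order. The greedy path is a heuristic, not guaranteed optimal; the
  test suite measures its gap against the exhaustive frontier on small
  candidate sets instead of claiming optimality.

## The synthetic cohort generator

Shadow-mode exports cannot be redistributed, so the package ships a
generator that emulates their shape: two cohorts of correlated binary
vectors with cohort-specific marginal prevalences. Study $i$ draws one
latent severity factor $z_i \sim N(0,1)$; finding $f$ with loading
$\lambda_f \in [-1,1]$ is present iff

$$\lambda_f z_i + \sqrt{1-\lambda_f^2}\, e_{if} \le \Phi^{-1}(p_f),$$

with $e_{if}$ independent standard normal — a one-factor Gaussian-copula
threshold model. Marginals hit their targets exactly in expectation for any
loading; positive loadings make findings co-occur on the same (sicker)
studies. A single factor was preferred over a full copula correlation
matrix: it matches the clinically plausible structure (generally unwell,
often older patients accumulate findings — the mechanism that also makes
degenerative bone findings correlate with cancer cohorts) while staying
identifiable from the few statistics anyone can publish. Age and sex are not
modelled explicitly; their confounding effect is represented only through
this loading-induced co-occurrence, which is a documented limitation.
Loadings are free parameters with default 0.35 — a moderate co-occurrence
level chosen once as clinically plausible; no published per-finding
co-occurrence data exist to calibrate against. One behavioural subtlety:
the probability a study shows $\ge 2$ findings rises with the loading for
rare findings, but is non-monotone for common ones (at marginal prevalence
0.3 and four findings it peaks near loading 0.5), because strong coupling
also concentrates *absences*.

RNG discipline: Mersenne-Twister with inversion normals, seeded once per
generation call, cancer cohort drawn before referral — fixtures regenerate
byte-for-byte from the seed on any platform.

`demoFixture()` bundles an illustrative 124-finding catalogue (12 CRITICAL,
41 HIGH, 71 STANDARD; names mix real chest X-ray finding vocabulary with
labelled placeholders) and cohorts of 1,282 cancers and 13,802 referrals at
full scale. Demo prevalences are set with wide margins around the ratio-5
threshold (true ratios ≈ 15 for the strongly cancer-associated HIGH
findings vs ≈ 2 for the rest) so the named strategies select 18, 41 and 32
findings deterministically for any seed. The test-scale fixture (150 × 20 /
400 × 20) keeps full pipelines under a minute. The catalogue, classes and
prevalences are illustrative demo data, not any vendor's finding list or
any site's measured prevalences.

## What passing tests do and do not show

The suite verifies: the strict binary I/O contract; ratio conventions and
threshold selection against enumeration; flagging against a brute-force OR
oracle; the pseudo-confusion arithmetic against hand-computed values and a
published three-strategy panel reproduced from its aggregate counts;
conservation ($\mathrm{TP}_2+\mathrm{FN}_2+\mathrm{FP}+\mathrm{TN}=n_2$) and
the exact identities $\mathrm{FNR} = 1-\mathrm{sens}$,
$\mathrm{FPR} = 1-\mathrm{spec}$, $\mathrm{NNR}^+ \cdot \mathrm{PPV} = 1$ on
randomized inputs; frontier results against an independent $2^8$ scan;
generator marginals against binomial error bounds and pairwise co-occurrence
against a numerically integrated bivariate-normal orthant probability.
Problem sizes in the default run are desk-scale (cohorts up to 40,000 × 5
synthetic studies, candidate sets of 8); they exercise every code path at
sizes where independent oracles are exact.

None of this validates the *clinical* assumptions: that the assumed
prevalence matches a given referral population, that a registry-linked
cancer cohort transfers across sites, or that a configuration tuned on one
region's data generalises — evaluating a configuration on the same cohorts
used to choose it is calibration, not validation. The package computes the
modelled quantities; their interpretation carries those caveats.
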