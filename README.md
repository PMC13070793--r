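# cxrtriage

Configuration and evaluation of chest X-ray AI triage from shadow-mode
exports, aimed at faster lung cancer detection.

Chest X-ray AI systems used for worklist triage output a binary
presence/absence call per study for each finding in a fixed catalogue.
Deploying sites must choose in advance which findings escalate a study for
urgent reporting. `cxrtriage` is for the imaging-network analysts and
clinical-AI teams making that choice: it turns two shadow-mode CSV exports —
a retrospective cohort of confirmed, radiographically visible cancers and a
prospective general referral cohort — into ranked findings, evaluated
configurations and workload trade-off curves.

## The method

For finding $f$ with prevalence $p_{1f}$ among cancers and $p_{2f}$ among
referrals, findings are ranked by the **prevalence ratio**
$r_f = p_{1f}/p_{2f}$; a configuration is a finding subset $S$, and a study
is flagged iff any finding in $S$ is present. Sensitivity is observed in
the cancer cohort ($\mathrm{sens} = \mathrm{TP}_1/n_1$). The referral
cohort has no per-study ground truth, so cohort-2 metrics are **modelled**
under an assumed detectable-cancer prevalence $\pi$ (default 1%):

$$P = \operatorname{round}(\pi n_2),\qquad
\mathrm{TP}_2 = P\cdot\mathrm{sens},\qquad
\mathrm{FP} = \mathrm{flagged}_2 - \mathrm{TP}_2,\qquad
\mathrm{TN} = (n_2 - P) - \mathrm{FP},$$

giving pseudo specificity, PPV, NPV, FPR and number-needed-to-report
(CXRs reported per cancer detected) with Wald confidence intervals. The
package adds prevalence and ratio-threshold sensitivity sweeps, exhaustive
and greedy Pareto-frontier search over candidate finding sets, a one-factor
Gaussian-copula simulator for correlated binary cohorts, and a CLI. See the
methods vignette (`vignettes/triage-configuration.Rmd`) for assumptions and
numerical choices.

## Worked example

Published aggregate counts are enough to evaluate a configuration — here a
curated 32-finding HIGH-class set that flagged 1,229 of 1,282 cancers and
2,987 of 13,802 referrals:

```r
library(cxrtriage)
pc <- pseudoConfusionFromCounts(tp1 = 1229, n1 = 1282,
                                flagged2 = 2987, n2 = 13802, pi = 0.01)
pc
#> PseudoConfusion (pi = 0.01, modelled positives = 138)
#>   cohort 1 (observed): TP 1229 / FN 53 of n1 = 1282
#>   cohort 2 (modelled): TP 132.29  FN 5.71  FP 2854.71  TN 10809.29 of n2 = 13802
computeMetrics(pc, name = "curated_high")
#> StrategyMetrics 'curated_high'
#>   sensitivity 95.87% (94.78-96.96%)  specificity 79.11% (78.43-79.79%)
#>   PPV 4.43%  NPV 99.95%  FPR 20.89%  FNR 4.13%
#>   flagged: 95.87% of cohort 1, 21.64% of cohort 2;  NNR+ 23  NNR- 1896
```

Reading: the rule captures 95.87% of confirmed cancers; under the 1%
prevalence assumption, 23 flagged CXRs must be reported to encounter one
cancer in the AI-positive stream, and a non-flagged CXR is cancer-free with
modelled probability 99.95% (the safety metric).

With study-level data the same panel is computed from matrices. The
built-in demo fixture emulates the full problem shape (illustrative
catalogue and prevalences, not any vendor's or site's real data):

```r
fx <- demoFixture(seed = 20260101, scale = "full")
fx$catalogue
#> FindingCatalogue with 124 findings (CRITICAL: 12, HIGH: 41, STANDARD: 71)
#>   pneumothorax, tension_pneumothorax, pneumomediastinum, pneumoperitoneum, misplaced_nasogastric_tube, ...
tab <- prevalenceRatioTable(fx$cancer, fx$referral, fx$catalogue)
head(sortByRatio(tab)[, c("finding", "priority_class", "prev1", "prev2", "ratio")], 3)
#>                  finding priority_class     prev1       prev2    ratio
#> 13    solitary_lung_mass           HIGH 0.1107644 0.006013621 18.41892
#> 23 peribronchial_cuffing           HIGH 0.1271451 0.007535140 16.87362
#> 22       solitary_nodule           HIGH 0.1146646 0.007100420 16.14899
selectByRatio(tab, classes = "HIGH", minRatio = 5, name = "ratio_gt_5")
#> TriageConfiguration 'ratio_gt_5': 18 selected finding(s)
#>   solitary_lung_mass, inferior_mediastinal_mass, superior_mediastinal_mass, ...
```

## Command line

The installed script wraps the same functions
(`system.file("cli", "cxrtriage.R", package = "cxrtriage")`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "cxrtriage.R", package = "cxrtriage"))')
Rscript $CLI simulate --demo test --seed 7 --out demo
Rscript $CLI prevalence --catalogue demo/catalogue.csv \
    --cancer demo/cancer.csv --referral demo/referral.csv --out demo
Rscript $CLI evaluate --catalogue demo/catalogue.csv \
    --cancer demo/cancer.csv --referral demo/referral.csv \
    --strategies strategy1,strategy2,strategy3 \
    --strategy3-list demo/strategy3.txt --out demo
```

Subcommands: `prevalence`, `evaluate`, `sweep-prevalence`, `sweep-ratio`,
`optimise`, `simulate`. Exit codes: 0 success, 2 validation/usage error,
3 modelling error (e.g. an assumed prevalence inconsistent with the
observed flag rate). Logs go to stderr, data to files.

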