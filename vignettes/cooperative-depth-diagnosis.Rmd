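---
title: "Cooperative AI-endoscopist diagnosis of invasion depth: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cooperative AI-endoscopist diagnosis of invasion depth: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depthfusion)
```

## The clinical problem

Early gastric cancer confined to the mucosa (M) is a candidate for
endoscopic submucosal dissection; cancer invading the submucosa (SM)
generally is not. The preoperative M-versus-SM call therefore decides
between endoscopic resection and a far more invasive gastrectomy, yet
endoscopists reach only about 70% accuracy on it. `depthfusion`
implements a decision-level cooperation scheme between a probabilistic
image classifier ("the AI") and a panel of endoscopists: each source
issues a binary depth call with a *confidence level*, and a fixed
decision table fuses the two. SM is the positive class in every
statistic.

## Sources and their confidence

**The AI.** The classifier's softmax-style output `p_sm` in [0, 1] is
dichotomised at 0.5. Its *diagnostic probability* is the probability of
the chosen class, `q = max(p_sm, 1 - p_sm)`; `q > 0.75` is high
confidence, otherwise low. Two boundary conventions are ours to fix
because a continuous score leaves them open: the half-open band
`(0.5, 0.75]` is read as low confidence (a hole between 0.50 and 0.51
is not implementable for a continuous probability), and `p_sm = 0.5`
exactly defaults to the *negative* class M with low confidence, so a
coin-flip score never inflates SM calls; `stratify_ai(ties = "SM")`
flips that convention.

**The panel.** An odd panel of raters votes M/SM per case; the panel's
label is the strict majority and its confidence is high exactly when
the vote is unanimous. Panels of size one are allowed (always
unanimous) — useful for testing and degenerate designs.

## The fusion table

For each case the two (label, confidence) pairs are fused:

1. labels agree — the shared label is final;
2. labels differ at different confidence — the higher-confidence source
   wins;
3. labels differ at the same confidence — a *mismatch*: mismatch 1 when
   the AI says SM and the panel M, mismatch 2 the reverse.

Mismatches are resolved by one of four fixed patterns: I (AI wins
both), II (panel wins mismatch 1, AI mismatch 2), III (AI wins
mismatch 1, panel mismatch 2), IV (panel wins both). `select_pattern()`
scores all four on training data and keeps the F1-best; ties break to
the lowest-numbered pattern so output is deterministic. The table does
not distinguish high/high from low/low disagreement — a mismatch is
defined by the label pair alone. Whether the training-side AI
probabilities come from a leave-one-out harness or a refit model is the
caller's choice; out-of-sample (LOO) scores are the recommended and
documented default since in-sample scores are optimistically biased.

F1 is the harmonic mean of sensitivity and PPV,
`2·sens·PPV/(sens + PPV)`, computed internally in the equivalent count
form `2tp/(2tp + fp + fn)`: identical where both are defined, 0 when
there are no true positives but errors exist, and `NA` only when tp,
fp, fn are all zero. Any ratio with a zero denominator is reported as
`NA`, never silently 0 — a cohort with no positive calls should not
look like a perfect one.

## Panel selection

`select_best_panel()` reproduces the marker-combination search: all
`choose(n, k)` odd subsets of the rater pool are enumerated in
lexicographic id order, each subset's majority vote is scored, and the
F1-best subset wins (lexicographic tie-break). The module accepts any
odd `k` over any pool, not only 3-of-4 experts, since combinations of
markers are worth examining in general.

## Rebuilding published tables from operating points

Per-case reads for the original study are not deposited, but every
printed table row is an operating point (sensitivity, specificity) on a
cohort of known balanced class sizes (250/250 internal, 100/100 test).
`confusion_from_operating_point()` inverts each row to integer counts —
`tp = round(sens · n_pos)` with half rounded away from zero, since the
printed percentages are conventionally rounded half-up — after which
`metrics_from_confusion()` reproduces accuracy, PPV, NPV and F1 to the
last printed digit. Comparisons are made at one unit in the last
printed digit (±0.05 percentage points, ±0.0005 for F1). On a balanced
design this reconstruction also enforces
`accuracy = (sens + spec)/2` exactly, a useful internal-consistency
check; the one published cell that fails it (the cooperation column's
test NPV, printed 70.2 where the column's own sensitivity/specificity
force 76.9) is treated as a typesetting error and not reproduced.

## Confidence-strata comparison

`confidence_strata()` cross-tabulates correct/incorrect against
high/low confidence and applies the Pearson chi-square test for 2×2
tables (`chi_square_2x2()`), computed from the closed form
`n(ad − bc)² / ((a+b)(c+d)(a+c)(b+d))` on 1 df. No continuity
correction is applied by default — the uncorrected Pearson statistic is
the plain reading of "chi-square test" — and `correct = TRUE` enables
the Yates correction for users who prefer it. If a stratum is empty the
table is still returned and the test is omitted.

## Leave-one-out harness

`leave_one_out()` is generic over any classifier expressed as a
`fit(data, seed)` / `predict_proba(state, newdata)` pair: n folds, case
i never in its own training set, predictions pooled in input order,
then metrics and strata. Folds run sequentially with per-fold seeds
derived deterministically from the master seed, so reports are
bit-reproducible. The package ships only simple reference classifiers
(prescored column, logistic, nearest centroid, constant, prevalence,
and a memorising *leakage canary* whose LOO predictions must all be
exactly 0.5) — a convolutional network's weights are not reproducible
at desk scale, while the evaluation protocol around it is, and the
protocol is what this package implements. `evaluate_holdout()` is the
train/test counterpart with case-id disjointness enforced.

## The synthetic cohort generator

`generate_cohort()` provides case-level data with the statistical
structure the analysis assumes, so the whole pipeline is testable
without images.

**AI score.** A binormal latent: `s ~ N(0, 1)` for M and `N(delta, 1)`
for SM, thresholded at `t`, with `t = qnorm(spec)` and
`delta = qnorm(spec) + qnorm(sens)` (`calibrate_binormal()`), so the
target operating point holds exactly in expectation. The reported
probability is the equal-prior posterior recentred at the threshold,
`p_sm = plogis(delta·(s − t))`: a strictly monotone transform of `s`
that puts the `p_sm = 0.5` boundary exactly at `s = t`, because the
downstream dichotomisation is implicitly at 0.5 and calibration must
land there.

**Rater votes.** A one-factor latent model: per case a shared factor
`c ~ N(0,1)`; rater r sees `u_r = sqrt(rho)·c + sqrt(1−rho)·e_r` and
votes SM when `u_r` exceeds the class-specific quantile matching its
target (sensitivity on SM cases, 1 − specificity on M cases). Since
`u_r` is marginally standard normal for every `rho`, per-rater
operating points are exact in expectation at any correlation; `rho`
only moves inter-rater agreement (identical votes at `rho = 1` for
raters sharing an operating point). A single shared factor was chosen
over a full copula: one interpretable parameter, exact marginals. The
true inter-rater correlation of the study is unreported, so `rho` is a
free parameter; the default 0.5 is a moderate value typical of reader
studies and claims no fidelity to the original panel.

**Presets.** `paper_preset("training_like")` is 250 SM/250 M, AI at
(0.76, 0.78), raters A–D at their published per-rater operating points,
38% of SM cases annotated SM1. `paper_preset("test_like")` is 100/100,
AI at (0.74, 0.71), and a three-rater panel: only the panel-level
operating point (0.52, 0.88) is published for the test cohort, so each
synthetic rater carries that point with a high default correlation
(`rho = 0.8`) — the majority vote of identically calibrated raters
approaches the members' common operating point as `rho → 1` and equals
it at 1, whereas independent raters would overshoot the specificity.

**Covariates.** Tumour diameter is lognormal (median 22 mm, log-sd
0.45, about a quarter of lesions above 30 mm) and histology is 65/35
differentiated/undifferentiated; both are annotations by default.
`covariate_effect > 0` shifts the AI latent of *large or
undifferentiated truth-M* lesions toward SM — mimicking the documented
failure mode in which large undifferentiated intramucosal lesions are
confidently miscalled SM — and deliberately leaves rater votes
untouched. The default is 0 so that calibration stays exact unless the
effect is requested. The SM1/SM2 split (95/155 training-like, 26/74
test-like) is purely annotational: the method is binary M-vs-SM.

**What the generator does not emulate.** Real endoscopic reads are
driven by shared image features, so rater errors correlate with lesion
difficulty and with the AI's errors; here the AI score and the rater
factor are independent given the class. Passing tests therefore show
the *procedure* is correct and well calibrated, not that its measured
advantage transfers to any particular clinical cohort.

## Problem sizes and numerical choices

Calibration checks in the test suite use 50 000 cases per class per
correlation value (binomial SE ≈ 0.002, compared at 3 SEs); end-to-end
checks run the full pipeline at the study's own 500-case training
scale. Tie-breaks are everywhere deterministic (lowest-numbered
pattern, lexicographic subset). Degenerate inputs fail loudly before
computation: even panels, one-class cohorts for F1 selection,
single-class LOO training folds (reported with the fold index),
out-of-range probabilities, and malformed CSV cells (reported with row
and column).

## Worked example

```{r example}
train <- generate_cohort(paper_preset("training_like", seed = 1))
test  <- generate_cohort(paper_preset("test_like", seed = 2))
report <- run_pipeline(train, test, k = 3)
report
report$strata_ai$table
```

## Limitations

The generator's operating points are expectations, so any single
cohort fluctuates binomially around them; the published tables are
reproduced exactly only through operating-point reconstruction, not
through simulation. Confidence intervals for the diagnostic metrics and
ROC/AUC analysis are out of scope, as is anything involving the images
themselves or the network that scored them.
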