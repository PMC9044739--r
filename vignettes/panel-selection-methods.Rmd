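---
title: "Selecting a serum protein panel for recurrence risk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting a serum protein panel for recurrence risk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prmstrat)
```

## The problem

Men with clinically localized prostate cancer and moderately elevated PSA
(2–10 ng/ml) are hard to stratify: PSA and biopsy Gleason grade predict
biochemical recurrence after prostatectomy only imperfectly. Serum is an
attractive complement — secreted, mostly N-glycosylated tissue proteins
leak into blood and can be quantified in a multiplexed way by targeted
mass spectrometry (parallel reaction monitoring, PRM) long before
clinical-grade immunoassays exist for them. `prmstrat` implements the
full analysis chain for such a screen: transition-level PRM quantities →
a spike-in-normalized protein matrix → an exhaustive, paired,
bootstrap-cross-validated search over small marker panels → a final
random-forest risk score whose low/high stratification is judged with
ROC, DeLong, Kaplan–Meier, and likelihood-ratio statistics. Because the
real sera and instrument files cannot ship with an R package, a
synthetic-cohort generator reproduces the statistical structure the
analysis relies on, which makes every stage testable end to end.

## Quantitation model

A PRM report is a long table of chromatographic peak areas, one row per
(sample, protein, peptide, precursor charge, transition). Quantities are
rolled up in two fixed steps:

1. **Precursor**: the summed area of the four most prominent transitions
   of that precursor in that sample; if fewer than four were observed,
   all observed transitions are summed. "Most prominent" is decided per
   sample; ties at the fourth place break by transition id, so the
   roll-up is deterministic (a tie at the fourth-largest area cannot
   change the sum, only the bookkeeping of which ids were used).
2. **Protein**: the sum of all its precursor quantities. Charge states
   of one peptide count as distinct precursors; since both steps are
   sums, grouping them differently would not change the protein total.

Missing never becomes zero: a precursor with no observed transition, or a
protein with no observed precursor, stays missing.

Every protein quantity is then divided by the same sample's quantity of
the bovine A1AG spike-in, an exogenous glycoprotein added before sample
processing. Whatever multiplicative efficiency factor a sample picked up
during enrichment and digestion applies equally to the spike-in, so the
ratio cancels it; in the generator this is exact when measurement noise
is switched off, which the tests exploit. Other spike-ins (e.g. a bovine
fetuin-B) are carried as QC columns but never used for normalization.

## Preprocessing

The completed matrix fed to the model search is produced in a fixed
order: outlier removal, presence filtering, imputation.

* **Outliers** are detected per protein with a
  regression-on-order-statistics rule: the central band of sorted log
  quantities (default the 10–90% plotting positions, $p_i = i/(N+1)$) is
  regressed on standard normal quantiles, giving a robust log-normal
  location/scale fit that ignores the tails. A value is flagged when the
  expected number of observations at least as extreme under that fit,
  $N \cdot P(\text{more extreme})$, falls below a threshold (default 1
  expected observation, either tail). Flagged cells become missing;
  whole samples are never dropped. With fewer than 10 observed values,
  or a zero-spread degenerate fit, nothing is flagged. The rule runs on
  the normalized matrix — normalization removes a per-sample nuisance
  factor that would otherwise masquerade as biological spread.
* **Presence filter**: a protein is kept only if observed in *strictly
  more* than two-thirds of samples. The boundary matters: with 78
  samples, 53 present (53/78 > 2/3) passes and 52 (= 2/3 exactly) is
  dropped.
* **Imputation** is single (one completed matrix feeds the search) and
  uses chained random forests: missing cells start at their protein's
  observed median, then for a fixed number of sweeps (default 5) each
  incomplete protein is regressed on all the others with a
  random forest and its missing cells are replaced by the forest
  predictions, proteins ordered least-missing first. The procedure is
  deterministic under its seed, never alters observed cells, and flags
  imputed cells in the table's state matrix.

No scaling is applied anywhere: random forests are invariant to
monotone transforms of individual features, and the suite asserts that
rescaling an input column leaves every fold AUC unchanged.

## The panel search

With $p$ candidate proteins and a maximum panel size $k$, every subset
of size $1..k$ is enumerated and joined with the clinical base features
(always PSA; optionally biopsy Gleason). For 21 candidates and $k = 5$
that is $\sum_{j=1}^{5}\binom{21}{j} = 27{,}895$ models; the scaled
study in `analysis/` uses 12 candidates and $k = 3$ (298 models) so a
full run finishes in about a minute.

Every model is scored under **one shared bootstrap plan**: $F$ resamples
(default 50; 20 in the scaled study) of the cohort drawn with
replacement, each paired with its out-of-bag complement as the test set.
A fold whose out-of-bag set lacks an outcome class is redrawn. Per fold,
a random-forest classifier (recurrence vs no recurrence; default 200
trees, 100 in the scaled study; all other hyperparameters at package
defaults, i.e. $\sqrt{p}$ features per split and fully grown trees)
is fit on the resample and its out-of-bag samples are scored with the
recurrence-class probability; the fold AUC is the Mann–Whitney statistic
of those scores. Forest seeds derive from (plan seed, fold, model
label), so results are bit-reproducible and independent of evaluation
order.

Models are ranked by **median fold AUC**. Because every model saw the
identical folds, the best model can be compared with each other model by
a two-sided *paired* t-test on the fold AUC vectors; after Bonferroni
correction over the number of comparisons, every model with adjusted
$p \ge \alpha$ (default 0.05) is *statistically equivalent* to the best.
Two degenerate cases are fixed by convention: an identical fold vector
(all differences zero) is equivalent, and a constant non-zero shift is
not. Rather than trusting the single best model — an unstable object
under bootstrap noise — the **feature prevalence** across the
equivalence set (the fraction of member models containing each protein,
base features excluded, ties broken lexicographically) nominates the
final panel: features that appear in essentially all statistically
indistinguishable top models are the stable signal.

## The risk model and its evaluation

The final classifier is a random forest on the top-prevalence proteins
plus PSA and biopsy Gleason (entering as an ordinal integer, not
one-hot). A cutoff on the predicted score is chosen to maximize Youden's
$J = \text{sensitivity} + \text{specificity} - 1$ over the observed
scores, taking the lowest maximizer on ties; patients with
score > cutoff are high risk. $J$ depends only on score ranks, so the
stratification is invariant to monotone transforms of the score. The
evaluation stage applies the training-derived model and cutoff without
refitting.

Evaluation statistics are implemented in the package rather than
wrapped, with installed reference implementations used as independent
cross-checks in the test suite:

* **AUC** in its Mann–Whitney form (ties count one half), with a DeLong
  standard error for single-cohort estimates; across CV folds the
  package reports the percentile spread of fold AUCs instead, and labels
  the two accordingly.
* **DeLong's test** for two correlated ROC curves, from the covariance
  of placement values; a zero-variance comparison (e.g. a score compared
  with itself) returns $p = 1$ with a warning.
* **Kaplan–Meier** product-limit curves per risk group; censored times
  reduce the risk set without steps.
* The **likelihood-ratio test** from a proportional-hazards model with
  the single binary group covariate, maximizing the Breslow partial
  likelihood (a one-dimensional, concave problem solved by golden-section
  search to $10^{-10}$); the statistic $2(\ell(\hat\beta)-\ell(0))$ is
  referred to $\chi^2_1$. Ties are handled by the Breslow approximation.
  An estimate running to the search boundary (complete separation, which
  a strongly separating training-set stratification can produce) is
  clamped and reported with a warning.

## What the generator emulates — and what it does not

The synthetic cohort reproduces the features the analysis depends on:

* log-normal protein abundances (log2 basis) with fixed per-peptide and
  per-transition response weights, a per-sample multiplicative batch
  factor (log2 sd `batch_sigma`, default 0.5), and a per-measurement
  log2 residual; one `noise_sigma` (default 0.5) drives both the
  sample-level biological residual and the transition-level measurement
  residual, so setting it to zero silences every variance source at
  once;
* a spike-in reference present and complete in every sample, exactly
  proportional to the batch factor;
* two informative proteins whose log2 mean is *lower* by `effect_log2`
  in patients who later recur — the direction reported for
  extracellular-matrix markers of aggressiveness — with a default of 1
  log2 unit chosen as a tunable, deliberately moderate effect (the
  univariate separation is far from complete), not as anyone's estimate
  of a real effect size;
* abundance-dependent missingness (values below a protein's
  `mnar_quantile` censored with probability `mnar_prob`) plus
  independent MCAR dropout, applied at the protein–sample level:
  low-abundance proteins drop out of whole samples, as in real PRM
  panels where a third of monitored candidates may go unquantified;
* clinical covariates with realistic ranges — PSA within the 2–10 ng/ml
  inclusion window, biopsy Gleason 6–10 enriched for high grades among
  recurrence cases via a shared latent aggressiveness, an NCCN-style
  category 1–4 derived deterministically from PSA/Gleason/stage-proxy by
  a low/high composite rule (the real composite algorithm is not public,
  so a deterministic surrogate is used) — and event times that are
  truncated-exponential within the follow-up horizon for recurrence
  cases, uniform censoring otherwise (~40% recurrence by default).

It does **not** emulate retention-time drift, interference or integration
errors in peak areas, correlated protein modules, cohort/site effects
beyond the single batch factor, or continuous post-operative PSA
trajectories. Consequently, a passing suite demonstrates that the
machinery is correct and recovers planted structure under realistic
noise, missingness, and batch variation — it cannot certify performance
on real sera, where feature correlations and assay artifacts are richer.

## Numerical and design choices

* Seeds: one global seed hashes (32-bit FNV) into per-stage, per-fold,
  and per-model seeds, so runs are bit-reproducible while forests stay
  independent; any evaluation order yields identical results.
* Bootstrap out-of-bag sets are the test sets ("bootstrapped
  cross-validation" leaves the test set unstated; out-of-bag is the
  standard completion and is fixed here).
* The degenerate paired-t conventions and the lowest-maximizer cutoff
  tie-break are stated above; both exist purely for determinism.
* The presence filter is strict (`>`), read literally from "over
  two-thirds".
* The outlier rule's fit band (10–90%) and expected-count threshold (1)
  are exposed in `preprocess_config()` since no canonical values exist.
* Problem sizes in `analysis/` and the tests (78–200 patients, 12
  proteins, $k \le 3$, 20 folds, 100 trees) are scaled-down analogues
  chosen so a complete study runs in minutes on a laptop while keeping
  every qualitative property of the full-size search; the enumeration
  arithmetic for the full 21-candidate, 5-plex search is checked
  exactly.
* In-sample training AUC of the final forest is optimistic (often 1.0);
  the honest performance number is the out-of-bag median AUC from the
  search stage, and the evaluation stage exists to apply a *fixed* model
  to a cohort, which is only meaningful on data not used for training.

## Known limitations

* The equivalence set's size is sensitive to fold count and cohort size;
  with few folds the paired t-test has little power and the set grows.
* Single imputation understates uncertainty from missingness; the search
  treats the completed matrix as data, as the original procedure does.
* The Breslow tie approximation is mildly biased with heavy ties; with
  monthly follow-up granularity this is negligible.
* The DeLong normal reference is asymptotic; with very few events the
  type-I error drifts, which the calibration tests bound at n = 100.
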