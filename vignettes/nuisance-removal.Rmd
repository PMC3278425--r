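---
title: "Removing nuisance variability before biomarker classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Removing nuisance variability before biomarker classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nuisancer)
```

## The problem

Diagnostic classification features — neuropsychological test scores,
volumetric imaging biomarkers — depend not only on disease but on covariates
of no diagnostic interest: age, gender, education, weight, vital signs. A
70-year-old control can have the hippocampal volume of a 55-year-old
patient. Left in the data, this *nuisance variability* widens the
within-group distributions and erodes classification accuracy. `nuisancer`
implements three remedies and the evaluation machinery to compare them
fairly:

* **Data correction** — fit, within a healthy reference group, a linear
  regression of each classification feature on the chosen nuisance
  features, and subtract the fitted effect from *every* subject
  (`fit_nuisance_model()`, `correct_features()`). This is the adjustment
  ANCOVA makes, applied as an explicit pre-processing step.
* **Data stratification** — for each target subject, train the classifier
  only on subjects whose nuisance values all lie within a threshold of the
  target's values (`make_rule()`, `stratify()`).
* **Combination** — stratify the training set per subject, then correct the
  selected subset with the model fitted on the *full* training set's
  reference group (`stratify_then_correct()`).

## The correction model

For classification feature $c_i$ and nuisance features $s_1,\dots,s_k$, the
reference-group subjects define an ordinary-least-squares fit

$$c_i(n) \approx b_i + \sum_j a_{ij}\, s_j(n),$$

and every subject (all groups) is replaced by the residual
$\hat c_i(n) = c_i(n) - b_i - \sum_j a_{ij} s_j(n)$. Fitting only on the
reference group is the crux: that group carries no disease-related
variability, so the slopes estimate the *normal* covariate effect and the
disease signal is untouched. Two consequences are testable exactly:

* the reference group has mean zero in every corrected feature (OLS
  residuals are centered), and
* refitting on already-corrected reference data returns a null model.

Design choices, made where the method statement is genuinely open:

* **Multiple nuisances** are handled by one *joint* multiple regression per
  feature, not sequential single-covariate passes: joint OLS is
  order-independent and matches the ANCOVA antecedent.
* **No post-correction offset**: corrected values are residuals. Adding the
  reference mean back would only translate every subject equally, and
  classification is translation-invariant; leaving it off makes the
  zero-mean property directly checkable.
* **Missing values**: reference subjects missing the feature or any
  involved nuisance are dropped from that feature's fit (complete case per
  feature, avoiding imputation bias inside the model). At correction time a
  missing nuisance regressor is imputed with the stored reference-group
  mean, so a present feature value is never lost to a missing covariate.
* **Binary/ordinal nuisances** (gender, smoking) enter as 0/1 or integer
  regressors. Correction suits continuous features best; ordinal features
  are corrected too, with the caveat that small shifts rarely change their
  classification behaviour.

## The stratification rule

A subject enters the training subset for target $n$ when
$|s_j - s_j(n)| \le th_j$ for *every* rule nuisance, with
$th_j = \alpha \cdot \mathrm{sd}(s_j)$ computed over the whole dataset.
Boundary ties are included ($\le$). Defaults: $\alpha = 1$ (the value that
gave the best average results in the motivating study) and a whole-set
fallback when a study group would drop below `min_group_size = 10`
training subjects.

Choices to be aware of:

* **sd convention**: sample standard deviation ($n-1$); at realistic sample
  sizes the population/sample difference is immaterial, but it is pinned
  down here for reproducibility.
* **Whole-dataset thresholds**: $th_j$ is a global scale parameter, not a
  per-split statistic, and is deliberately not recomputed per training
  fold; the target subject contributes one row to a standard deviation over
  hundreds, which is not subject-level leakage.
* **Fallback reading**: the fallback fires when *either* study group falls
  below the minimum — a classifier needs both groups populated. The
  conjunctive reading ("both below") is available via
  `make_rule(fallback = "both")`.
* Non-ordered categorical nuisances are not supported in the rule; binary
  features must be 0/1-coded. For a balanced binary nuisance, $\alpha = 1$
  admits only same-category subjects (threshold just above 0.5, opposite
  category at distance 1).

The combination method fits the correction model on the full training set,
not the stratified subset: stratified subsets can be too small for stable
regression, and under the linearity assumption the same coefficients apply
in every stratum.

## The classifier stack

The evaluation pipeline holds the classifier fixed and simple so that
accuracy differences are attributable to the nuisance handling:

1. **Pre-selection** (`preselect_features()`): drop features with more than
   10% missing values or a pooled two-sample t-test p-value above a
   threshold between the two study groups. Pre-selection runs once on the
   full dataset — replicating the original design — which is a known
   optimistic-bias choice; it affects all methods equally and so does not
   distort their comparison.
2. **Imputation**: training-set means, computed within the training portion
   only.
3. **SMOTE balancing** (`smote_balance()`): synthetic minority subjects
   interpolated toward one of k = 5 nearest minority neighbours (the
   original algorithm's default) until the study groups are equal, so a
   majority-class shortcut cannot masquerade as accuracy.
4. **Stepwise selection** (`stepwise_select()`): forward entry at partial-F
   p < 0.05, backward removal at p > 0.10, iterated to a fixed point —
   the classic stepwise-regression recipe.
5. **Linear regression classifier** (`train_classifier()`): OLS of the
   0/1-coded label on the selected features, thresholded at 0.5 (the
   balanced prior after SMOTE). Ties go to the class coded 1; when stepwise
   selection retains nothing, the intercept-only score 0.5 combined with
   the tie rule yields a constant, deterministic prediction — documented
   rather than randomized, so runs are exactly reproducible.

## Evaluation

`make_cv_plan()` draws `n_repeats` (default 100) random 90/10 splits of the
pair-eligible subjects *once*; every method and nuisance subset is
evaluated on the same splits, so per-repeat accuracies pair positionally
and `paired_compare()` can apply the paired t-test (two-sided, significance
at p < 0.05). Reference-group subjects outside the pair are always training
material and never classified. The repeated-CV paired t-test is known to
violate independence assumptions across repeats; it is implemented as the
standard recipe it is, and its p-values should be read as descriptive.

`run_method()` executes the per-split pipeline; for stratification and
combination, one classifier is trained per test subject, with a pure cache
keyed on the selected subject set (identical subsets reuse one fit; the
SMOTE seed is derived per repeat, so caching cannot change results — and
the `alpha` $\to \infty$ limit reproduces the original method bit for bit).
`search_nuisance_subsets()` enumerates every non-empty nuisance subset
(capped at 12 features), and `best_by_size()` / `autoplot()` show the best
accuracy as a function of subset size.

## What the synthetic generators emulate

`simulate_interaction()` reproduces the four canonical nuisance-feature
interaction types:

| Type | Structure | Appropriate remedy |
|------|-----------|--------------------|
| 0 | no relation | none needed |
| 1 | nuisance predicts group membership | none — the "nuisance" is a classification feature and must not be corrected or stratified on |
| 2 | shared linear relation $c = f(s)$ | correction (or stratification) |
| 3 | separation grows with the nuisance; reference flat | stratification only |

`simulate_hippocampus()` adds an ADNI-like scenario: volume declining
linearly with age, a female offset, and a negative disease shift, with
defaults in plausible cubic-millimetre magnitudes (baseline 4300, −25/year,
−250 for females, −600 for disease, residual sd 400, ages 55–90).

Numeric defaults are the package's own calibration — the taxonomy carries
no published parameters:

* the age-like nuisance is uniform on 55–90 years (the ADNI recruitment
  span), noise sd 1 so shifts read in within-group sd units;
* Type 2 uses slope 0.1 per nuisance unit and group separation 1.5 sd,
  placing single-feature original-data accuracy near 0.70 with visible
  headroom (corrected data reach ≈ 0.78);
* Type 3 experiments use separation 4 sd at the top of the nuisance range
  (groups nearly overlap at the young end) — a steep but plausible
  atrophy-like gradient that isolates the mechanism stratification
  exploits;
* the parameter-recovery experiments draw the nuisance uniform on 0–10 so
  both slope *and* intercept are estimated within the data range rather
  than by long extrapolation;
* all generator noise is Gaussian.

Passing tests on these generators demonstrate the algorithms' contracts —
zero-mean correction, rule-exact stratification, ordering of methods by
interaction type — not performance on clinical data: real datasets mix
interaction types, have non-Gaussian and ordinal features, and their
nuisance effects need not be linear.

## Numerical choices and degenerate inputs

* Zero-variance nuisance in the reference group: an error (the regression
  denominator vanishes), as is a collinear nuisance set.
* Fewer reference subjects than nuisances + 2: an error (no degrees of
  freedom).
* Stepwise selection skips constant candidates silently and collinear
  candidates with a warning; `max_steps = 100` guards against cycling.
* A score exactly at the decision threshold is assigned the class coded 1.
* Paired comparison of identical accuracy vectors reports an undefined
  (`NA`) p-value rather than a fabricated one.
* Problem sizes in the test-suite experiments are scaled (20 CV repeats,
  300 subjects per group, 20 experiment replicates) — large enough that
  the method orderings are stable across seeds, small enough to run
  routinely.

## Worked example

```{r, eval = FALSE}
library(nuisancer)

ds <- simulate_interaction(2, n_per_group = 300, seed = 42)
pair <- group_pair("A", "B", reference = "ref")
plan <- make_cv_plan(ds, pair, n_repeats = 20, seed = 42)

orig <- run_method(ds, pair, "original", plan = plan)
corr <- run_method(ds, pair, "correction", "age", plan = plan)
paired_compare(corr, orig)

plot_method_comparison(orig, corr)
```

## Known limitations

* Linear correction only; polynomial or interaction terms are out of scope
  (the motivating work found cross-terms performed worse).
* Interaction types are *assumed*, not detected from data; choosing the
  method per feature pair automatically is future work.
* Accuracy is the only evaluation metric (no AUC/sensitivity/specificity),
  and no multiple-testing correction is applied across the subset search.
* The stratification rule needs ordered nuisances; non-ordered categorical
  covariates would need hand-chosen thresholds.
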