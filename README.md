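# fairpost

Benchmarks for **post-processing bias mitigation** in binary clinical risk
classifiers. Post-processing methods adjust a *trained* model's scores or
predicted labels — no retraining, no access to raw training data — to shrink
group disparities such as unequal detection of at-risk patients. This
package is for researchers and practitioners who need to know *which* of
these methods to trust *under which data conditions*: scarce representation
of the disadvantaged group, extreme class imbalance, hard vs easy
classification tasks, and the presence of other, untreated protected
attributes.

## What it computes

For a dataset $D = (A, X, Y)$ with binary class $Y$ (1 = favorable) and
binary protected attribute $A$ (0 = unprivileged), fairness is measured by

- equal opportunity difference $\mathrm{EOp} = |TPR_0 - TPR_1|$, and
- equalized odds difference
  $\mathrm{EOd} = \tfrac12\big(|FPR_0 - FPR_1| + |TPR_0 - TPR_1|\big)$,

alongside accuracy, balanced accuracy and F1. The package provides:

- **`simulate_dataset()`** — a synthetic biased-data generator: features
  drawn from class-conditional bivariate Gaussians (favorable class mean
  $(2, 2+s)$, covariance $[[5,1],[1,5]]$; unfavorable class mean
  $(-2, -(2+s))$, covariance $[[10,1],[1,3]]$) with $A = \mathrm{sgn}(x_0)$,
  so the unprivileged group is structurally depleted in the favorable class.
  The shift $s$ controls class separability.
- **`plan_ugr()` / `resample_to_ugr()`** — class-balanced subsampling to a
  target unprivileged-group rate, with cell-wise prefix nesting across
  targets.
- **`fit_policy()` / `apply_policy()`** — seven debiasing methods behind one
  policy interface: calibrated score mixing (`cpp`), equalized-odds label
  flipping (`epp`), reject-option relabeling (`roc`), sensitivity-guided
  thresholds (`psta`), confusion-tensor flipping (`fact`), smoothed
  group-specific thresholds (`gstar`) and multiaccuracy boosting (`mab`,
  which never sees the protected attribute). Policies serialize to JSON and
  replay exactly.
- **`build_baseline()` / `classify_region()`** — a mutation-based reference
  trade-off curve and the win-win / good / poor / inverted / lose-lose
  classification of mitigation outcomes, including a 90%
  performance-retention sub-region for clinical settings.
- **`run_benchmark()`** with `change_table()`, `untreated_impact()`,
  `spearman_attr_corr()`, `correlation_vs_impact()` and
  `proportion_over_baseline()` — the full cross-validated experiment
  grid and its summary tables.

## Worked example

Simulate the medium-separation biased design, train a logistic model,
fit a reject-option policy on the training predictions, and evaluate on a
held-out fold:

```r
library(fairpost)

ds     <- simulate_dataset(synth_config(s = 0, n_per_class = 1000, seed = 1))
folds  <- make_cv_folds(ds, k = 5, seed = 1)
train  <- dataset_subset(ds, setdiff(1:2000, folds[[1]]))

adapter <- adapter_logistic()
model   <- adapter$fit(train$features, train$labels)
ctx     <- fit_context(adapter$predict(model, train$features),
                       train$labels, train$protected$A)
policy  <- fit_policy("roc", ctx)
policy
#> <decision_policy: flip_region>
#> List of 1
#>  $ margin: num 0.23

scores <- adapter$predict(model, ds$features[folds[[1]], ])
test   <- grouped_scores(scores, ds$labels[folds[[1]]],
                         ds$protected$A[folds[[1]]])

test$predicted_label <- threshold_labels(scores)   # unmitigated
round(fairness_report(test), 3)
#>    acc  bacc    f1   eop   eod
#>  0.858 0.857 0.856 0.172 0.249

test$predicted_label <- apply_policy(policy, test) # after mitigation
round(fairness_report(test), 3)
#>   acc bacc    f1   eop  eod
#>  0.83 0.83 0.825 0.013 0.02
```

The unmitigated model detects at-risk members of the unprivileged group far
less often (a 17-point true-positive-rate gap). Relabeling predictions in a
0.23-wide margin around the decision boundary closes the gap to about one
point, at a cost of roughly three accuracy points — a point that
`classify_region()` would place in the *good* trade-off region relative to
the mutation baseline.

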