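---
title: "Benchmarking post-processing bias mitigation: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking post-processing bias mitigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairpost)
```

## The problem

Clinical risk classifiers frequently miss at-risk patients from some
demographic groups more often than from others. Post-processing debiasing
methods repair a *trained* model's scores or labels — without retraining —
to shrink such group disparities. Whether a given method helps, and at what
cost to predictive performance, depends heavily on properties of the data:
how separable the classes are, how prevalent the favorable outcome is, and
how well the disadvantaged ("unprivileged") group is represented.

`fairpost` provides a controlled laboratory for that question: a synthetic
biased-data generator whose bias structure is fully known, seven
post-processing methods behind one fit/apply policy interface, the standard
group-fairness metrics, a mutation-based reference trade-off curve, and a
cross-validated benchmark harness.

## The synthetic generator

A dataset is $D = (A, X, Y)$ with binary class $Y$ (1 = favorable outcome),
two-dimensional features $X = (x_0, x_1)$, and binary protected attribute
$A$ (0 = unprivileged). Features are drawn class-conditionally:

$$X \mid Y{=}1 \sim \mathcal N\!\left(\binom{2}{2+s},
\begin{pmatrix}5 & 1\\ 1 & 5\end{pmatrix}\right), \qquad
X \mid Y{=}0 \sim \mathcal N\!\left(\binom{-2}{-(2+s)},
\begin{pmatrix}10 & 1\\ 1 & 3\end{pmatrix}\right),$$

and $A = \operatorname{sgn}(x_0)$. The separation shift $s$ (unitless;
$-1$, $0$, $+1$ for hard, medium, easy tasks) moves the class means apart
along $x_1$ only, so group composition is unaffected by $s$. Because the
class means differ in $x_0$, the $x_0 < 0$ group is scarce in the
favorable class and abundant in the unfavorable one: the marginal tail
probabilities at $s = 0$ are $\Phi(-2/\sqrt5) \approx 0.187$ for $Y = 1$
and $\Phi(2/\sqrt{10}) \approx 0.736$ for $Y = 0$. This is the structural
bias every method is evaluated against. Sample estimates of these two
fractions at $n = 1000$ per class are what `scripts/acceptance.R` reports.

Conventions fixed once and documented:

* $x_0 = 0$ maps to the privileged group — a probability-zero event under
  the continuous model, resolved to the larger group.
* The unprivileged group is coded $A = 0$ because under the generator its
  favorable rate is lowest.
* The default dataset size is 1000 rows per class (2000 total), the size
  used throughout the attribute-imbalance design.

## Controlled group representation

`plan_ugr()` and `resample_to_ugr()` subsample a dataset to a target
unprivileged-group rate (UGR) while keeping classes exactly balanced. Two
constraints (class balance, target rate) leave one degree of freedom — how
unprivileged rows split across classes — which we resolve by demanding
equal unprivileged counts in both classes ($u_1 = u_0$), the maximally
symmetric choice. The plan search decrements the total $m$ in steps of 2
from the largest even total until all four (group, class) cell demands fit
their supplies; demanded counts round half-up, so the achieved rate is
within $1/m$ of the target.

Each cell receives one fixed seeded permutation and all demanded counts are
taken as prefixes, so training sets at different UGR targets are nested
*cell-wise*: the rows a cell contributes at a smaller demand are always a
subset of those at a larger demand. Whole-set nesting across UGR levels is
impossible in general — privileged cell demands *shrink* as the target UGR
grows while unprivileged demands grow — so cell-wise prefix nesting is the
strongest subset guarantee any such design can make, and it is the one we
test by set inclusion on row identifiers.

## Metrics

With per-group true/false positive rates $TPR_g$, $FPR_g$:

* Equal opportunity difference: $EOp = |TPR_0 - TPR_1|$.
* Equalized odds difference: $EOd = \tfrac12(|FPR_0-FPR_1| + |TPR_0-TPR_1|)$.
* Performance: accuracy, pooled balanced accuracy $(TPR+TNR)/2$, and F1 for
  the favorable class. F1 with zero predicted positives is defined as 0
  with a warning; balanced accuracy is pooled, not group-averaged, because
  it is treated as a global performance measure.
* Undefined group rates (a group with no positives, say) raise errors
  rather than silently returning 0 — a disparity computed from an undefined
  rate is meaningless.

Cliff's $\delta$ (pairwise dominance in $[-1,1]$, computed through the
midrank identity rather than pair enumeration; $|\delta| \ge 0.428$ flagged
as a large effect) quantifies before/after shifts, and pairwise Spearman
correlations between protected attributes use the asymptotic
$t$ approximation for p-values — binary attributes always carry ties, so
exact null distributions do not apply.

## The seven policies

All methods are fit on a validation set of scored instances and return a
serializable `decision_policy`; deterministic policies are idempotent,
randomized ones (mixing, label flipping) draw from a seeded stream.

* **CPP** — calibrated score mixing. Only one of the generalized
  false-negative/false-positive costs can be equalized for calibrated
  scores; the default equalizes the false-negative cost (recall-preserving,
  so at-risk cases are not missed), mixing the lower-cost group's scores
  with its base-rate constant predictor at the closed-form rate. The FPR
  variant is available via `cpp_cost = "fpr"` but is not the tested default.
* **EPP** — equalized-odds label flipping: four conditional flip
  probabilities minimizing expected error subject to exact equality of
  post-policy TPR and FPR across groups. The feasible set is the unit box
  cut by two hyperplanes; with a linear objective the optimum is found
  exactly by vertex enumeration (all-constant mixings are always feasible,
  so the program is never empty). No external LP solver is involved, and
  the enumeration is itself checked against grid oracles in the tests.
* **ROC** — reject-option relabeling in a symmetric margin around the 0.5
  boundary, unprivileged to favorable and privileged to unfavorable. The
  smallest margin on a 0.01 grid bringing validation EOp inside the band
  (default 0.05, the conventional default in existing toolkits) is chosen;
  failing that, the margin minimizing EOp.
* **PSTA** — sensitivity-guided thresholds: privileged threshold fixed at
  0.5; the unprivileged threshold moves over the sorted unique validation
  scores to align unprivileged TPR with the whole-population TPR, subject
  to the unprivileged FPR staying within a ceiling of the population FPR
  plus 0.10. The ceiling value is this package's choice of "acceptable";
  it is configurable (`fpr_ceiling`).
* **FACT** — confusion-tensor flipping: the same four flip rates, now
  minimizing expected error plus $\lambda \cdot$ EOp violation
  ($\lambda = 1$ by default). The objective is convex piecewise-linear, so
  its exact minimum sits at a box vertex or on the kink hyperplane; both
  candidate sets are enumerated. $\lambda \to 0$ recovers the identity
  policy.
* **GSTAR** — per-group thresholds minimizing error plus $\lambda \cdot$
  EOd estimated from kernel-smoothed group- and class-conditional score
  CDFs (Gaussian kernel, Silverman bandwidth — standard and deterministic).
  A grid over empirical scores seeds a Nelder-Mead refinement.
* **MAB** — multiaccuracy boosting: the only method that never sees the
  protected attribute. Each round fits a ridge-regression auditor to the
  residuals (label minus score) over the raw features; if either
  auditor-signed region's mean residual magnitude exceeds `mab_alpha`
  (0.01), scores get an additive logit correction of `mab_eta` (0.1) times
  the auditor prediction. Rounds are accepted only if they strictly shrink
  the detected region's residual magnitude; at most `mab_rounds` (50)
  rounds. All are configurable; the auditor class and step size are this
  package's defaults, as the method family prescribes none.

Ties at any threshold resolve as score $\ge \theta \to$ favorable,
everywhere.

## The trade-off baseline and its regions

A mitigation outcome is judged against a mutation baseline: for each degree
$d \in \{0.1, \dots, 1.0\}$, a uniformly chosen fraction $d$ of the
unmitigated predictions is replaced by the majority label (50 trials per
degree; the mutation target is the majority class, the dominant strategy of
the framework this construction follows). Mean (fairness, performance) per
degree plus the unmitigated origin form a polyline; at $d = 1$ the
predictor is constant, so EOp is exactly 0 and accuracy equals the majority
proportion — a closed-form anchor the tests check. Points are classified
relative to the origin: **win-win** (both strictly better), **inverted**
(performance up, fairness not), **lose-lose** (neither better), and, when
fairness improves but performance does not, **good** if the point lies on
or above the polyline at its fairness value, else **poor**. Equality on
fairness counts as not improved and equality on performance as not worsened
— the conservative reading under which a method must land strictly above
the baseline to be called effective. The good region splits at a
performance-retention line: retaining at least `healthcare_factor` (default
0.9, configurable up to 0.99 for high-stakes uses) of the origin
performance marks the stricter sub-region (`good-2.2`) that clinical use
cases care about. Interpolation along the polyline is linear with flat
extrapolation beyond its fairness range.

## Benchmark protocol

`run_benchmark()` runs stratified 5-fold cross-validation per dataset,
protected attribute, model adapter and method. Within each fold the
training portion may be resampled to a target UGR; **the test fold is never
resampled**, so test sets stay identical across representation scenarios.
Policies are fit, by default, on the full training predictions: at
UGR = 0.1 the resampled training set contains only a few dozen unprivileged
rows, and reserving a further calibration split (available via
`calib_frac`) leaves group-rate estimates with single-digit counts — fits
then collapse to no-ops out of pure noise. Randomized policies are applied
10 times and their metrics averaged. Fold metrics are computed per fold
first and changes averaged afterwards; absolute and relative changes are
averaged separately (which can rank methods differently — a property the
tests construct explicitly), and relative changes with baseline magnitude
below $10^{-6}$ are excluded from relative means with a reported count.

Imbalance strata follow fixed interval maps: favorable-class proportion in
$[0, 0.25)$, $[0.25, 0.75)$, $[0.75, 1]$ and unprivileged-group rate in
$[0, 0.20)$, $[0.20, 0.50)$, $[0.50, 1]$, each low/medium/high with
half-open boundaries exactly as printed.

All randomness descends from one master seed through named substreams
(`substream_seed`), so fold assignment, resampling, policy fitting and
mutation trials are individually reproducible and independent of execution
order.

## What the synthetic checks do and do not show

The generator emulates the key axes of real clinical datasets — class
separability, favorable-class proportion, unprivileged representation, and
(via constructed second attributes) correlation between protected
attributes — under exactly known bias. It does not emulate feature-rich
tabular records, measurement noise, label error, or covariate shift, so a
method's good behavior here is necessary, not sufficient, evidence for
real-world use.

The directional check of the fairness-targeting methods (reject-option and
sensitivity-guided thresholding reducing held-out EOp under scarce
unprivileged representation) is run on class-balanced $s = 0$ data with
3000 rows per class, five folds, and the per-fold mean over five
training-resample replicates. The replicate average is a variance
reduction: a single 400-row test fold holds only a few dozen unprivileged
positives, and its realized baseline disparity occasionally lands near zero
by chance, in which case *any* correction fitted on biased training
evidence looks harmful on that one fold. The sign of the method effect is
the claim under test, so the comparison is made at a problem size where the
sign, not the noise, dominates. Generator defaults are untouched by this
choice.

## Numerical choices and degenerate inputs

* Exact LP/piecewise-linear optima via vertex enumeration; tolerance
  $10^{-9}$ on bound feasibility, $10^{-8}$ on constraint residuals.
* Threshold and margin searches operate on sorted unique empirical scores
  (GSTAR caps each group's candidate axis at 60 quantiles before
  refinement).
* Policy JSON uses 17 significant digits, which round-trips IEEE doubles
  exactly — thresholds are often set to exact score values, and lossy
  printing could flip a label on replay.
* Degenerate validation sets (an empty group-class cell) refuse to fit;
  undefined rates raise typed errors; the benchmark records NA metrics for
  test folds where an evaluation attribute degenerates.
* Cliff's large-effect flag is boundary-inclusive up to $10^{-12}$ to
  absorb rank-arithmetic rounding at the printed 0.428 threshold.

## Limitations

Only binary class and binary protected attributes are supported; no
pre-/in-processing methods; no multi-attribute joint debiasing (single
attributes are treated, spillover onto the others is measured); model
adapters ship for regularized logistic regression and gradient-boosted
trees only, though anything emitting class-1 probabilities plugs in. The
benchmark's real-data conclusions depend on datasets the user supplies via
`load_tabular()`; nothing is bundled.
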