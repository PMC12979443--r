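---
title: "Synchronous feature selection and hyperparameter optimization with IGKSO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synchronous feature selection and hyperparameter optimization with IGKSO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its methods: the optimizer and
its two improvements, the joint feature/hyperparameter encoding, the
evaluation stack, the Shapley attribution, the synthetic cohort, and the
numerical and design choices behind each — including the places where the
design was genuinely open and what we chose.

## The optimization problem

Wrapper feature selection with simultaneous hyperparameter tuning is a
mixed discrete/continuous search: with `p` candidate features and `q`
tunable hyperparameters there are `2^p` masks crossed with a continuous
configuration space, scored by a noisy, expensive objective
(cross-validated performance). The package attacks it with a continuous
swarm optimizer over the unit box `[0, 1]^(p+q)`: the first `p`
coordinates are a soft feature mask (feature `j` selected when coordinate
`j ≥ 0.5`; if none passes, the largest coordinate is selected — so a
candidate always has at least one feature), and the remaining coordinates
decode to hyperparameters linearly, log-linearly, by rounding, or by
category index, per the declared kind of each hyperparameter.

## The baseline optimizer and the two improvements

`igkso()` is a population minimizer over a box. One generation of the
baseline dynamics (`variant = "gkso"`) applies, per individual, one of
three moves, accepted greedily (kept only on strict improvement, which
also makes the best-so-far curve non-increasing — the elitism invariant
the tests assert):

1. **Hunting movement**: a step toward the population best plus a social
   differential term between two random peers,
   `x′ = x + C ⊙ F[(best − x) + a(x_{r1} − x_{r2})]`, where `F ~ U(0.4,
   0.9)` per individual, `C` is a binomial crossover mask (rate 0.9, at
   least one coordinate), and `a` decays linearly over the run. The sparse
   coordinate updates keep a usable acceptance rate in high dimension; the
   decaying social term hands the run over from exploration to
   exploitation.
2. **Foraging** (probability 0.2): a sparse Gaussian perturbation around
   the best whose scale is the forager's own per-coordinate distance to
   it, so refinement sharpens automatically as the swarm contracts.
3. **Self-protection** (coordinate rate `0.02·(1 − t/T)`): a uniform
   in-box coordinate reset, active early, vanishing late.

The published description of this optimizer family names the predatory
phases but not their equations, so these dynamics are this package's own
parameterization, deliberately isolated behind one internal function
(`gkso_step`) so the two documented improvements can be tested
independently of the baseline's exact form:

- **Bernoulli chaotic initialization** (`init_population(chaotic = TRUE)`):
  each individual's coordinates follow an orbit of the piecewise-linear
  shift map `x ← x/(1−λ)` for `x ≤ 1−λ`, else `(x−(1−λ))/λ`, with a random
  start and ≥ 20 burn-in steps, mapped affinely onto the bounds. The map is
  mixing (the tests check no empty decile over 1,000 orbit points).
  `λ = 0.4` by default — a common choice for this map; the source
  description gives no value — exposed as `bernoulli_lambda`.
- **Spiral-flight mutation** (`spiral_flight_mutate()`): per dimension
  `x′ = |best − x|·e^{bl}·cos(2πl) + best` with one `l ~ U(−1, 1)` per
  mutation call and shape constant `b = 1` (the standard logarithmic-spiral
  operator; the source names the operator without writing it). Applied
  with probability `mutation_prob = 0.2` per individual per iteration.

Two acceptance rules for the mutation were tried during development.
Tie-accepting greedy (`≤`) let mutants equal in fitness collapse onto the
best and measurably *hurt* multimodal search (Rastrigin, Ackley) by
destroying diversity; unconditional replacement churned the population to
no benefit. The frozen rule is strict greedy (`<`): a mutant replaces its
individual only on strict improvement. The mutation also draws from its
own seeded substream, so both variants' baseline dynamics consume
identical random sequences and differ only through the initialization and
the accepted mutants. Under this design the improved variant's mean final
best dominated the baseline on the sphere, Rastrigin and Ackley benchmarks
for every disjoint base seed tried.

Boundary handling is clamping (reflection was considered and rejected for
simplicity); a non-finite objective value causes an in-box uniform reset
of that individual rather than an error.

## Cross-validated fitness and the merge phase

`cv_fitness()` scores a candidate by stratified 5-fold cross-validation:
per fold, the learner is trained on the in-fold rows of the *selected*
columns only — standardization statistics included, so no information
leaks from held-out rows — and scored on the held-out rows at threshold
0.5. The objective is the mean held-out F1 (ROC-AUC available via
`objective = "auc"`); F1 is the headline training metric of the motivating
study, and the paper does not name its optimized objective, so F1 was
chosen for consistency. A fold whose training fails contributes the worst
possible value. The fold partition depends only on a seed derived
independently of the optimizer's stream, so fitness is a fixed
deterministic function throughout a run.

A fixed partition avoids noisy-objective pathologies but lets a strong
optimizer overfit the partition: a pure-noise feature occasionally
*strictly* improves the measured F1 of these particular folds, and mask
coordinates of truly neutral features drift freely across the selection
threshold. Both effects inflate noise-feature selection. The merge phase
therefore applies **backward pruning under a one-standard-error rule**
(the same principle as the lasso's `lambda.1se` selection): walking the
selected features from the weakest mask coordinate, a feature is dropped
unless keeping it improves the per-fold fitness by more than one paired
standard error across folds. Informative features survive (their paired
gain is large and consistent); drifted or spuriously helpful noise is
removed. In the package's planted-signal experiment (5 informative
features shifted by 1 SD, 10 noise features, n = 400, logistic learner,
population 20, 40 iterations, 10 seeded runs) this yields informative
selection rates ≥ 0.9 and noise rates ≤ 0.3 — the tests assert ≥ 0.8 and
≤ 0.4. An explicit parsimony penalty (`parsimony`, weight on the selected
fraction) exists but defaults to 0; the pruning is a tie-resolution of the
same objective, not a penalty.

The final model is retrained on all supplied rows with the winning
configuration.

## Base learners and their tuning spaces

Four learners cover four paradigms behind one contract (probability scores
in [0, 1], deterministic given a seed, leakage-safe preprocessing:
continuous features z-scored with training statistics, binary passed
through, categorical one-hot encoded):

| learner | backend | tuned hyperparameters |
|---|---|---|
| `lr` | glmnet | penalty l1/l2, C (log-uniform 0.001–100), max_iter (50–500) |
| `bp` | in-house MLP | hidden layers {50; 100; 50+50}, activation relu/tanh/logistic, learning_rate_init and alpha (log-uniform 1e-4–0.1), batch_size (16–128) |
| `svm` | e1071 | C (log-uniform 0.1–100), kernel linear/rbf/poly, gamma (log-uniform 1e-4–10), degree (2–5, poly only) |
| `xgb` | xgboost | learning_rate (0.01–0.3), max_depth (3–12), min_child_weight (1–10), subsample and colsample_bytree (0.5–1), reg_alpha (0–1), reg_lambda (0–2) |

Values outside these ranges are rejected before any fitting. Notes on the
mappings: the logistic regression's `C` is the inverse regularization
strength, translated to glmnet's `lambda = 1/(C·n)`; the BP network is a
compact in-house multi-layer perceptron (Adam, cross-entropy, L2, seeded,
fixed epoch budget — 500 for final fits, fewer inside CV for speed, no
early stopping) because no pre-installed R backend offers multi-layer
architectures with all three activations; XGBoost runs single-threaded
with a fixed 100 boosting rounds (the tuning table has no tree-count row)
and its own seed parameter. The conditional SVM `degree` is decoded
always but flagged inactive unless the kernel is polynomial.

## Evaluation stack

All conventions are pinned for internal consistency: the positive call is
`score ≥ threshold` everywhere; ROC-AUC is the rank-based Mann–Whitney
concordance with ties counted ½ (identical to exhaustive pairwise
comparison, which the tests run as the oracle); PR-AUC is step-wise
average precision (not trapezoidal, which is optimistic under ties — with
all scores tied it correctly collapses to the prevalence); decision-curve
net benefit is `TP/N − FP/N · p_t/(1−p_t)` on a default grid 0.01–0.99 by
0.01 against the treat-all and treat-none references; calibration uses 10
equal-width bins with the Brier score as the mean squared error of the
probabilities. Degenerate denominators (e.g. no predicted positives)
return 0 with an explicit flag rather than NaN.

## Shapley attribution

`shapley_values()` uses the marginal (interventional) expectation as the
coalition value: features absent from a coalition are replaced, row by
row, by a background sample (recommended: ~100 training rows), and the
value is the mean prediction over those hybrids — the mainstream
tree-explainer convention; whether the motivating study used
path-dependent or interventional expectations is unstated, and the
interventional form is the one with a model-agnostic definition.
Exact mode enumerates all `2^d` coalitions (capped at `d ≤ 12`) and
satisfies efficiency (`base + Σφ = prediction`) to 1e-9, along with the
dummy and symmetry axioms the tests assert. Sampled mode averages marginal
contributions over seeded uniform permutations; each permutation's
contributions telescope exactly, and the per-feature Monte-Carlo standard
error shrinks as `1/√n_perm`. Attributions are computed on the probability
scale. Pairwise interaction tensors are out of scope; interaction
structure is surfaced through `dependence_data()` (per-row feature value,
attribution, and a coloring feature).

## Baseline statistics

`pooled_t_from_summary()` implements the pooled-variance (Student) two
sample t from `mean ± SD, n` summaries — the form that reproduces the
published baseline tables exactly, which is how we know the source used
the pooled rather than Welch form — and `chi_square()` the uncorrected
Pearson statistic (again, the corrected form does not reproduce the
printed values). p-values come from the exact t and χ² distributions. Two
conventions for degenerate input: zero pooled variance with equal means
gives t = 0; with unequal means it is rejected (infinite statistic).
Three published cross-tabulation statistics (employment status,
occupation, living mode of the train/test comparison) do not match the
uncorrected Pearson recomputation of their own printed counts and are
treated as unreproducible rounding/transcription artifacts rather than
targets.

## The synthetic cohort: what it emulates and what it cannot

`generate_cohort()` draws 360 + 181 patients (the published CAF split).
Features with published per-group moments (age, BMI, sex, knee extensor
moment, TUG time, KL grade, WOMAC pain, HADS anxiety) are drawn per group;
features with only whole-cohort summaries (duration, gait speed, WOMAC
stiffness/function, employment, occupation, education, living mode, MRI
findings) are drawn group-independent — the source tables print no group
split for them, and we do not invent one. Continuous features are Gaussian
with rejection resampling into plausible clinical ranges (e.g. TUG > 3 s,
WOMAC pain 0–20), which preserves moments better than clipping; an
infeasible clamp is rejected at schema construction. Features are
independent within group by default: only marginals are published, so any
correlation structure would be an extrapolation.

Consequences worth stating plainly: the generator reproduces *marginal*
group differences, not the joint feature–outcome geometry of the real
cohort. Passing tests therefore demonstrate that the pipeline recovers
separations it was given, not that the published predictive performance
(F1, AUC, Brier on the real test set) is reproduced — it cannot be, and
the package does not claim it. The 15%-band fidelity check compares
scale-normalized statistics (|t|/√10 on a ×10 cohort, since t grows with
√n) and is a ~2σ band for the weakest row at that size.

## Problem sizes and reproducibility

Simulation sizes used by the test suite and acceptance script are chosen
to make each property decisive at interactive runtimes on one CPU: the
optimizer comparison runs the published protocol shape (population 30, 200
iterations) at 10 repetitions per variant; monotonicity is checked on all
23 benchmarks at 50 iterations; feature recovery uses n = 400 with
population 20 × 40 iterations × 10 runs; Shapley exactness uses toy models
up to 8 features with 10–15 background rows. Every stochastic stage —
generator, split, CV partition, optimizer, per-fold learner seeds,
permutation sampling — draws its seed through one deterministic derivation
from the user's seed, so every result in the package is bit-reproducible.

## Known limitations

- The baseline dynamics are a reconstruction; absolute benchmark numbers
  are not comparable to other implementations of the same name, only the
  within-package variant comparison is meaningful.
- A single fixed CV partition makes fitness deterministic but optimizable;
  the one-SE pruning mitigates, not eliminates, partition overfitting.
- The BP learner's epoch budget inside CV is reduced for speed; its CV
  fitness is a slightly pessimistic estimate of its fully trained form.
- Exact Shapley is exponential in features (capped at 12); sampled mode's
  error is quantified but not deterministic.
- No confidence intervals on AUC, no probability calibration of learners,
  no class weighting, no multi-class support.
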