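---
title: "Methods: scoring and surrogate verification of masking policies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and surrogate verification of masking policies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how `deidverify` defines its scores, what the
synthetic-data generator does and does not emulate, and the design and
numerical choices behind the surrogate-model stage. It is the package's
reference for *why* the defaults are what they are.

## 1. The scoring model

A person record carries seven fields: name (three character tokens: one
family name, two given-name tokens), age, mobile phone number,
residential area, illness, ABO blood type and smoking status. A masking
policy chooses, per field, how many characters to replace with `*`.
The policy is encoded as seven integer label codes; for name, age and
phone the two digits of the code are (number of masked characters,
number of exposed characters), so name levels 0–3 map to 03/12/21/30,
age levels 0–2 to 02/11/20, and phone none/partial/full to 08/17/80.
Categorical fields are all-or-nothing (1 kept, 0 hidden): partially
masking a label drawn from a small closed set would still allow exact
grouping, so intermediate levels carry no information.

**Usability** is computed from the codes alone as
`Σ tens·ones + Σ categorical codes`. Two consequences of taking the
digit-product rule literally are worth recording. First, a fully
*unmasked* name (03) or phone (08) contributes zero, the same as a
fully masked one — the rule rewards *partial* exposure. Second, the
attainable maximum over the whole policy space is 14
(`1·2 + 1·1 + 1·7 + 1 + 1 + 1 + 1`), not 15; the confidentiality band
scale tops out at 15, so the two components are nearly but not exactly
symmetric. Both quirks are kept as defined, not "fixed", because the
surrogate-verification question is about the rule as stated.

**Confidentiality** is the deduplication statistic: the number of
distinct masked 7-field tuples divided by the original row count,
times 100. It is banded into `{15, 12, 9, 6, 3, 1, 0}` so that it
shares the 0–15 range of usability. The printed band edges overlap at
the top of the scale, so the package fixes them as half-open
intervals, upper-inclusive in the interior:

* `(0, 20] → 15`, `(20, 40] → 12`, `(40, 60] → 9`, `(60, 80] → 6`
* `(80, 99) → 3`, `[99, 100) → 1`, exactly `100 → 0`.

Exactly 100% gets its own band because it is qualitatively different:
not a single row was collapsed, i.e. the masking did nothing for
privacy. The **final score** is usability plus the band score; it is
the dependent variable of the regression dataset.

## 2. The synthetic cohort generator

Cohorts are drawn from probability tables transcribed from published
Korean national statistics (family-name shares; decade age bands for
the 2015 population; residential-area shares over the 17 first-level
divisions; ABO blood-type shares; a 21.5% smoking rate). The tables
ship in `inst/extdata/demographics.yaml` with the printed values; some
printed vectors sum to 99.5 or 100.2 because each entry was rounded
independently at the source, so `load_demographics()` renormalizes
proportionally and keeps the printed values for reporting. There is no
residual category to absorb the rounding gap, which makes proportional
renormalization the neutral choice.

Choices where the sources are silent, fixed once:

* **Names** are always three tokens. The two given-name tokens are
  drawn uniformly from a fixed alphabet of 100 synthetic syllables —
  no given-name frequency table is published, and only the token
  *count* matters to the masking rules.
* **Ages** are uniform within their decade band; the open-ended
  "100 and over" band is realized as uniform on 100–109.
* **Phones** are `010-` plus eight uniform digits, unique within a
  cohort by rejection sampling (real numbering assigns distinct
  numbers).
* **Illness** is uniform over five labels by construction.
* All fields are sampled **independently**. Real demographic fields
  are correlated (age with illness, region with age structure, smoking
  with sex and age). Passing distributional tests here therefore shows
  the generator matches the published *marginals*, not that any joint
  structure of real data is reproduced. The scoring and surrogate
  machinery is unaffected by this: it consumes masked tuples, whatever
  their joint law.

Determinism: `generate_cohort(n, spec, seed)` seeds a private RNG
stream and restores the caller's state; per-cohort seeds inside
`build_dataset()` are derived as a fixed affine-mod function of the
master seed and the cohort index, kept below 2^31.

## 3. Masking conventions

* Name tokens are masked in the fixed order first given token, second
  given token, family token. The label code is order-free, but the
  deduplication statistic is not: a deterministic order is required
  for reproducibility. The worked labeling example masks a given-name
  token, consistent with this order.
* "Partial" phone masking keeps the `010-` prefix and the *first*
  random digit (`010-7123-4567 → 010-7***-****`), i.e. seven of eight
  random digits masked — following the worked examples for code 17.
* Ages are rendered on two digits within their century (103 renders as
  "03"), so the two-digit masking rules apply uniformly; no separate
  century marker is kept. The 100+ band holds 0.07% of the population,
  so the collision with ages 0–9 is negligible for grouping.
* Masking is monotone by construction: raising any level only replaces
  additional characters, never restores one. The test-suite checks the
  induced monotonicity of the deduplication count on nested policies.

## 4. The regression dataset

`enumerate_policies()` yields the full Cartesian product
`4 × 3 × 3 × 2⁴ = 576` policies in a canonical order (all-unmasked
first). The default design scores all 576 policies against one cohort
each of sizes {100, 500, 1000, 5000} (2304 rows). Rationale: the sizes
span the interesting confidentiality regimes — at n = 100 full masking
gives 1% (deep in the top band) while light masking stays at 100% —
and the whole dataset builds in seconds on a desktop. One replicate
per size keeps the target a deterministic function of
`(n_samples, codes)`, which is what makes exact regeneration and
byte-identical manifest hashes possible. Both the size grid and the
replicate count are arguments, not constants.

Label codes enter the feature matrix as plain integers (3, 12, 21, …),
not one-hot encoded: the codes are ordinal in "amount masked", and the
tree methods split on thresholds, so the numeric treatment is both
faithful to their definition and convenient for interpretation.

## 5. Surrogate models and tuning

Five tree-based regressors are compared: a decision tree (`rpart`,
with complexity pruning disabled so the depth and leaf-size parameters
govern growth), a random forest (`ranger`), and three gradient
boosting variants that deliberately share one engine (`xgboost`) and
differ in tree-growth policy:

* `gbm` — depth-wise, exact greedy splits, shallow trees (depth 3), no
  L2 penalty: the classic gradient-boosting-machine configuration;
* `xgb` — depth-wise with the engine's regularized objective and the
  tuned depth / minimum-child-weight;
* `lgbm` — leaf-wise (best-first) growth on 255-bin feature
  histograms, 31-leaf cap, no L2 penalty: the light-GBM algorithm
  family. For squared loss the hessian is 1 per row, so the engine's
  minimum child weight is exactly the minimum leaf sample count.

Running the boosting variants on one engine makes their comparison a
comparison of *growth policies* rather than of implementations, and
keeps a single code path for prediction and SHAP.

Grid search uses 5-fold cross-validation on the 80% training split,
scored by mean CV RMSE alone (a single objective avoids an undefined
multi-objective rule; R² on the same split is monotone in RMSE anyway
once the fold targets are fixed). Ties break by canonical grid order.
For the boosting methods, all candidate round counts within a
hyperparameter group are evaluated by truncating one model trained at
the largest count — boosting is sequential and deterministic without
subsampling, so truncated predictions are bitwise-identical to
separately trained shorter models (a property the test-suite asserts).

The 80/20 split takes `floor(0.8 n)` training rows of a seeded
permutation (2304 → 1843/461). RMSE and R² are implemented directly
from their definitions and checked against brute-force recomputation
at 1e-9.

Under the default design the tuned boosted surrogates reach held-out
R² ≈ 0.97 (computed by `compare_models()` and the acceptance script).
The residual is interpolation error on the ~20% of policy cells unseen
in training: the target is piecewise-constant in the integer label
space with interactions (usability digit products; band thresholds
crossing with `n_samples`), and tree ensembles do not extrapolate
across unseen cells exactly. Denser designs (replicates, more sizes)
raise R² but were not made the default, which is pinned to the
2304-row study conditions.

## 6. TreeSHAP

The best boosted surrogate is interpreted with TreeSHAP — the exact
Shapley values of the cover-weighted conditional-expectation value
function for trees. The package implements the polynomial-time path
algorithm in C++ (src/treeshap.cpp) operating on the parsed tree dump,
entirely in double precision, and computes the base value and
per-instance predictions by the same double-precision traversal.
Local accuracy — base value plus attribution row-sum equals the
prediction — then holds to ~1e-12, comfortably inside the 1e-6
tolerance the package asserts on every explained instance. (Float32
attribution pipelines drift by a few ULPs of the prediction scale,
around 1e-5 at scores near 30, which is why double precision is a
requirement here, not a nicety.)

Correctness is established two independent ways in the test-suite:
coalition-enumeration Shapley values (all 2^p subsets, p ≤ 4) on small
models, including a duplicated-feature fixture and the closed-form
stump case; and the boosting engine's native float32 attributions at
float tolerance on larger models.

Reported per feature: mean |attribution| (the importance ranking, ties
alphabetical) and the sign of the Spearman correlation between feature
value and attribution (the direction-of-effect trend; `NA` for
constant features or all-zero attributions). Attributions are
evaluated on the held-out test rows: explaining training rows would
conflate memorization with structure. On the default pipeline the
phone-number code carries the largest mean |attribution| — the phone
field dominates deduplication because unmasked phones are unique by
construction.

## 7. Degenerate inputs and numerical edges

* `confidentiality_value()` rejects percentages outside `(0, 100]`;
  a nonempty cohort cannot produce 0%.
* `r_squared()` errors on zero-variance targets rather than returning
  a conventional value.
* Row keys for deduplication join fields with a `\r` separator, which
  cannot appear in any rendered field, so concatenation cannot merge
  distinct tuples.
* The single-leaf (no-split) boosted model is handled explicitly in
  SHAP: all attributions zero, base value equal to the constant
  prediction.
* Phone-space exhaustion (≥ 10^8 phones) errors rather than looping.

## 8. Problem sizes used by the test-suite

Distributional checks use one 200,000-record cohort (±0.5 percentage
points around the configured shares; at n = 200,000 the binomial
standard error of a 20% share is ≈ 0.09 points, so the tolerance sits
at ~5σ). Oracle-equivalence checks use cohorts up to 200 rows against
an O(n²) comparison oracle. The surrogate stage runs on the default
2304-row dataset with the full grids. These sizes are the package's
chosen study conditions; they keep a full test run in the low minutes
on one CPU.

## 9. Known limitations

* Field independence and opaque given-name tokens (see §2): the
  generator matches published marginals only.
* The usability rule's zero contribution for unmasked name/phone and
  its maximum of 14 are properties of the rule as defined, inherited
  deliberately.
* Equal weighting of usability and the confidentiality band in the
  final score is a convention of the scoring rule, not a calibrated
  trade-off.
* SHAP is defined for the boosted surrogates; the decision tree and
  random forest backends are compared on accuracy but not explained.
* Direction trends for weakly attributed features (e.g. cohort size,
  region) are unstable across dataset designs and are reported as
  information, not asserted properties.
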