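---
title: "Logistic tensor regression for paired-visit EHR data: models, training, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logistic tensor regression for paired-visit EHR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltrEHR)
```

## The prediction problem

ltrEHR models a common clinical-forecasting setup: a patient is seen at one
hospital visit, and at the start of the *next* visit — an irregular number of
days later — a binary decision must be predicted (here framed as eligibility
for advanced heart-failure therapies such as transplant or mechanical
circulatory support). Each training sample is one pair of consecutive visits
and carries

* the multiset of medical codes recorded at the first visit (ICD-10-style
  diagnoses, CPT-style procedures, VA-class drugs),
* a short vector of vitals/labs `x` of length `d` (systolic blood pressure,
  heart rate, chloride, sodium by default),
* the elapsed days `t` between the visits, and
* the binary outcome `y` at the second visit.

Codes are mapped into a `D`-dimensional embedding space (word2vec trained on
visits-as-documents), and the visit becomes a matrix `X` of size `M x D`
whose row `m` is the embedding of code `m` if that code was present and zero
otherwise. A patient with `n` consecutive visits contributes `n - 1` pairs,
so samples are clustered within patients; every data split in the package is
therefore patient-wise.

## The two models

**Standard LTR.** A logistic regression on the bilinear contraction of `X`:

$$ P(y = 1 \mid X, x) \;=\; \sigma\!\big([\,u^\top X \;|\; x^\top\,] v + b\big), $$

with one weight `u_m` per medical code, coefficients `v` of length `D + d`,
and intercept `b`. The code weights are shared by the whole population.

**Personalized LTR.** The same contraction applied to the sample Gram matrix
`S = X^\top X` with an embedding-space weight `w` of length `D`:

$$ P(y = 1 \mid X, x) \;=\; \sigma\!\big([\,w^\top S \;|\; x^\top\,] v + b\big). $$

Because `w^\top S = (Xw)^\top X`, each sample induces its own code-weight
vector `u_i = X_i w`: the model has only `D` trainable code parameters, yet
the weight attached to a code varies across patients with the rest of the
visit — an attention mechanism over code embeddings. `forward_personalized()`
implements both routes (`form = "gram"` and `form = "attention"`) and the
test suite asserts their algebraic identity to 1e-10.

Two presentation choices differ from formulations one sometimes sees for
attention classifiers, and both are deliberate. The output nonlinearity is a
sigmoid, because the training loss is a binary cross-entropy and needs
probabilities in (0, 1); a `tanh` output (affinely rescaled into (0, 1)) and
a `tanh` squashing of the derived weights `u_i` are available behind flags
for ablation. And the minimized objective is the standard logistic loss
`mean(log(1 + exp(-y * logit)))` (labels in {-1, +1}) — the sign convention
under which gradient descent actually converges — plus an L1 penalty
`lambda * ||u||_1` (standard) or `lambda * ||w||_1` (personalized) that
pushes the model onto a small set of informative codes. We penalize `w`
rather than the derived `u_i` in the personalized model because `w` is the
trainable object; a flag for penalizing `mean(||u_i||_1)` was considered and
rejected as it couples the penalty to the visit-length distribution.

## What is — and is not — identifiable

The bilinear form makes `(u, v)` jointly non-identified: replacing
`(u_c, e_c^\top v_{1:D})` by `(\kappa u_c, e_c^\top v_{1:D}/\kappa)` changes
nothing. Beyond the global scale and sign, the *direction* of `u` itself is
not pinned down: the likelihood depends on `u` and `v` only through the
per-code products

$$ \alpha_c \;=\; u_c \,\big(e_c^\top v_{1:D}\big), $$

which equal the logit shift caused by code `c` being present (before time
encoding). These **effective code weights** (`effective_code_weights()`) are
invariant, reproducible across refits, and are exactly what the add/remove
perturbation simulation measures; all population-level interpretation and
all recovery validation in this package is therefore phrased in terms of
`alpha`, not the raw factor `u`. The synthetic generator records its own
interpretable `u_effective` alongside the raw parameters for the same
reason. `flip_ltr_sign()` resolves the residual global-sign freedom when a
fit must be aligned with a reference.

## Irregular time: positional encoding

The gap `t` (days, used raw) enters through fixed sine/cosine features,

$$ PE(t, 2j-1) = \sin\!\big(t / 10000^{2j/(D+d)}\big), \qquad
   PE(t, 2j)   = \cos\!\big(t / 10000^{2j/(D+d)}\big), \qquad j = 1, \dots, (D+d)/2, $$

requiring `D + d` even. The encoding is applied **multiplicatively**: column
`k` of `X` is scaled by entry `k`, lab entry `k` by entry `D + k` — the first
`D` positions belong to the embedding columns in embedding order, the last
`d` to the labs in cohort column order. An additive mode (the transformer
convention) is available for ablation. Multiplicative scaling preserves the
zero rows of absent codes exactly, and applying it twice is *not* a no-op;
`apply_pe()` tracks a flag and warns on reapplication.

## Training

`fit_ltr()` runs full-batch Adam (lr default 1e-2) from Kaiming-uniform
initialization (`U(-sqrt(6/fan_in), +sqrt(6/fan_in))`, `fan_in` = the
parameter's input dimension; intercept at zero). The L1 term is handled by a
proximal soft-threshold after each Adam update, with the threshold scaled by
Adam's diagonal preconditioner (`lr * lambda / (sqrt(v_hat) + eps)`), so
penalized coordinates reach *exact* zeros instead of oscillating at the
step-size scale; the exported `ltr_gradient()` keeps the plain subgradient
convention (`sign(.)`, 0 at 0) for anyone who wants the mathematical object.
Numerical safety: the loss uses a stable softplus (no overflow at any
logit), and reported probabilities come from logits clamped at +-30, keeping
them strictly inside (0, 1).

Early stopping evaluates the monitored loss every 25 steps and halts after
20 evaluations without improvement (defaults; `max_steps` 5000). With
`val_fraction > 0` the monitor is a patient-wise validation loss, otherwise
the training objective. `grid_search()` scores every `(lr, lambda)` cell by
validation AUC on an internal patient-wise split and refits the winner on
all data; ties prefer the smaller `lambda`, then the smaller learning rate
(sparser and slower wins). Grid defaults (`lr` in {1e-3, 1e-2}, `lambda` in
{0, 1e-3, 1e-2, 1e-1}) bracket the scale at which the L1 path moves from
dense to empty on cohorts of a few hundred samples.

## Evaluation protocol

`make_fold_plan()` first holds out a fraction (default 0.2) of *patients*,
stratified on the patient-level label (positive if any of the patient's
pairs is positive — the conservative choice for multi-pair patients), then
deals the remaining patients into `k = 10` stratified folds. `run_cv()`
trains on nine folds and scores the tenth; the holdout supports one final
evaluation reported separately. Baselines (logistic regression, linear SVM,
Gaussian naive Bayes, random forest — library implementations with fixed
seeds) consume the `D + d` global-average-pooled representation: the mean
over all `M` rows of `X` including zeros, matching the tensor's definition
(a nonzero-row mean is available behind a flag), concatenated with labs.
With *weight transfer*, the fold's fitted LTR code weights replace the flat
average — a global `u` from the standard model, per-sample `u_i = X_i w`
from the personalized one. SVM scores are raw decision values passed through
a sigmoid rather than Platt scaling, which avoids a nondeterministic
internal cross-validation.

Metrics are accuracy and F1 (`2TP / (FN + 2TP + FP)`) at threshold 0.5,
midrank AUC (the normalized Mann-Whitney statistic) and step-integrated
AUPRC. Model comparison uses Cohen's d on per-fold AUCs with the pooled-SD
denominator; `|d| >= 0.8` is labeled large and 0.5-0.8 moderate.

## The synthetic cohort generator

Real paired-visit EHR cohorts of this kind are not shareable, so the
package ships a generator whose outputs have the statistical structure the
models assume, with the generating process fully recorded:

* **Vocabulary** — unique code strings styled after ICD-10/CPT-4/VA-class
  identifiers, in a 5970 : 2229 : 239 diagnosis : procedure : drug ratio
  (scaled), partitioned into phenotype groups that play the role Phecodes
  play for real ICD codes.
* **Visits** — each visit picks two theme groups and draws ~80% of its
  3 + Poisson(9) codes from them, so same-group codes genuinely co-occur and
  embeddings can learn the grouping.
* **Gaps** — log-normal elapsed days (median 60, sdlog 0.8): heavy-tailed,
  exercising the positional encoding over several octaves.
* **Labs** — drawn per latent severity class with means/SDs echoing an
  advanced-heart-failure cohort (e.g. systolic BP 102.7 +- 15.0 in the
  severe class vs 121.7 +- 22.7 otherwise); the generating model consumes
  them z-scored by fixed pooled constants recorded in the ground truth.
* **Labels** — Bernoulli draws from the standard-LTR forward model
  `sigmoid(sum_present alpha_c + x_z' v_lab + b)`, then flipped with a small
  probability (default 0.05). The per-sample probabilities and the uniform
  draws behind every label are stored, so `noise = 0` labels can be
  regenerated exactly from the recorded truth. A `threshold` label mode
  (`y = 1{p > 0.5}`) provides deterministic, separable labelings for sanity
  checks.

Effective code effects are drawn on a fixed, well-spaced grid (+6.5 down to
+2 over six codes, -4.3 down to -2 over four, at 20% sparsity on `M = 50`)
with an intercept of -2. These values were chosen once so that the
generating model itself discriminates at held-out AUC ~0.92-0.93 under the
recovery conditions used in validation (2000 pairs, 5% label flips — the
flips alone cap attainable AUC near 0.95); weaker effects would make
recovery experiments unable to distinguish estimation failure from an
undiscriminating truth. The spread between adjacent positive effects keeps
the top-of-ranking stable across refits.

What the generator does *not* emulate: real coding intensity (we draw ~12
codes per visit against a small vocabulary, where real visits draw ~10 from
thousands), longitudinal drift across a patient's pairs (pairs from one
patient are exchangeable here), code-code interactions beyond group
co-occurrence, and missingness in labs. Passing tests on these cohorts
demonstrates correctness of the machinery and recoverability under the
model's own assumptions — not clinical performance.

## Numerical and design choices worth knowing

* Duplicate codes at a visit collapse to presence when building `X`
  (`use_counts = TRUE` scales rows by multiplicity instead).
* Codes never seen in the embedding corpus get zero vectors; pairs involving
  zero vectors are excluded from the embedding-quality AUC since cosine is
  undefined there.
* The embedding-quality score treats every unordered pair of diagnosis
  codes as positive iff the two codes share a phenotype group, scored by
  cosine similarity; beyond 200k pairs all positives are kept and negatives
  are subsampled with a seed.
* word2vec training (SGNS default, `D = 100`, full-visit window, 5
  negatives) is an in-package single-threaded implementation with its own
  RNG: same seed, same vectors, bit-for-bit. Codes are shuffled within each
  visit every epoch because a visit has no internal order.
* Lab standardization in `build_tensors()` uses cohort-level means/SDs
  (recorded in attributes). This is a population-constant rescaling akin to
  a unit change; fold-internal re-standardization was judged not worth the
  bookkeeping given the baselines re-standardize their own features.
* Pipeline runs (`run_pipeline()`) are stage-resumable (a stage is skipped
  when its outputs exist) and byte-deterministic given the config's named
  seeds; problem sizes in the bundled demo config (200 codes, 500 pairs,
  `D = 20`) keep a full run within a few CPU minutes.

## Known limitations

Only two-visit pairs are modeled — no longitudinal sequences beyond the
pair. The personalized model's interpretability rests on `u_i = X_i w`,
which inherits any biases of the embedding space. The correlation screen
(`code_label_correlation_screen()`) is report-only: it flags codes that
nearly encode the label but removes nothing, since a removal threshold is a
cohort-level judgment call. Cohen's d on 10 folds is a coarse effect-size
summary, not a significance test.
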