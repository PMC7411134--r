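---
title: "Methods: soft ensemble vote classification and its optimizers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soft ensemble vote classification and its optimizers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model and its assumptions

`sevc` predicts the solubility of chimeric virus-like particle (cVLP)
constructs from amino acid sequence alone. The core assumption is that
insolubility is driven to a useful first order by composition-weighted
hydrophobicity: a hydrophobicity scale assigns one number per residue,
and a construct's feature under that scale is the plain sum over its
sequence. The feature is deliberately *not* length-normalized —
constructs built with different insertion strategies differ in length,
and the stump threshold absorbs any constant per-strategy offset, so
normalization would add a free choice without changing decisions.
Residue order never matters (a composition-only model); 3-D effects
such as assembly-interface geometry are explicitly outside the model
family, which is why the strategy optimizer exists (see below).

Each scale induces one one-level decision tree (stump), trained by
minimizing the leaf-size-weighted Gini diversity index over candidate
thresholds (midpoints between consecutive distinct sorted feature
values — standard CART practice, and exactly recoverable by exhaustive
enumeration, which the test suite does). A stump's vote is its leaf's
class sign times the leaf's raw majority fraction (no Laplace
smoothing), so votes live in [−1, +1]. The ensemble averages the votes
of the `n` stumps with the highest feature importance — the stump's
training-set Matthews correlation coefficient (MCC), chosen over
accuracy because it is robust to class imbalance — and discretizes at
zero with ties going to "insoluble". Model size `n` is selected by
Monte Carlo cross-validation (MC-CV): repeated unstratified random 1:1
splits of the training set, with all model sizes evaluated on the same
validation half within a run so sizes are directly comparable. The
split is unstratified on purpose, contrasting with the single
stratified train/test split of the dataset: stratification is a
property of the experiment design, not of the resampling.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| MC-CV runs (stats / scale-eval / final) | 25 / 100 / 1000 | runs | 25 suffices for FN/FP composition means; 100 stabilizes a median used as an objective; 1000 for reported curves |
| strategy step | 0.01 | continuous-vote units | smallest meaningful shift of `p` given vote granularity of majority fractions |
| strategy acceptance margin | 0.05 | MCC | lets the climb traverse small dips without resetting |
| scale acceptance margin | 0.2 | MCC | single-stump medians fluctuate more than ensemble medians |
| patience | 50 | iterations | consecutive non-improvements before stopping |
| modification rate `r` | 0.01 (synthesis) / 0.05 (optimization) | fraction of unit variance | the modifier is standardized before application, so each step perturbs the scale by on average `r` of unit variance; literature scales need the larger rate to escape their basin |
| train/test split | 384 / 184 | constructs | the published dataset geometry, preserved by the synthetic preset |

Scales are always centered and scaled to unit *sample* variance
(`n − 1` denominator; the convention is arbitrary but must be
consistent, since only relative values matter to a stump). Literature
scales are loaded as-is for classification — stumps are invariant to
affine transforms of a feature — and normalized inside the optimizer,
where "1% of unit variance" only means something on a normalized
scale. Random initial scales are normalized before first use for the
same reason. Non-canonical residues (B, Z, X, U) are rejected rather
than imputed.

# The two optimizers

**Strategy optimizer.** MC-CV validation classifications are
accumulated into one contingency matrix per insertion strategy, summed
over all runs and all model sizes — the target being maximized is the
median over sizes of per-size median validation MCC, so the update
signal mirrors the target's scope (the alternative, accumulating only
at the selected size, is available via `contingency_sizes = "best"`).
The strategy with the largest |FN − FP| gets its additive vote offset
stepped by ±0.01 (positive when FN > FP: that strategy should be
classified more soluble). Fresh MC-CV splits are drawn every iteration
from a master seed stream, so the whole trajectory is reproducible but
no split is reused. The no-improvement counter increments on both
within-margin acceptances and resets; only a new best clears it.

**Scale optimizer.** From pooled validation FN/FP groups (over the
stats MC-CV runs, single-stump model), the mean residue-count vectors
`a_FN`, `a_FP` and mean feature values `f_FN = a_FN·s`,
`f_FP = a_FP·s` give a composition difference `Δa` and feature
difference `Δf`. Counts are raw counts, not relative frequencies —
only then do the `f` values equal mean feature values exactly, since
`F = count · s`. The raw modifier is elementwise `Δf·Δa`,
standardized, and applied at rate `r`; the candidate scale is then
re-normalized and scored by median validation MCC in the eval MC-CV.

**The modifier sign.** The product `Δf·Δa` as such *increases* the
values of FN-enriched residues whenever the FN group sits above the
boundary — which moves both groups *away* from the boundary and makes
misclassification worse; the mirrored argument holds in the opposite
stump orientation. The stated goal of the update — move the mean FN
and FP feature values toward the classification boundary, e.g. raise
the value of a residue over-represented among false positives —
requires the opposite direction, `−Δf·Δa`. This package therefore
defaults to `modifier_sign = -1`. The choice is not cosmetic: on the
synthetic recovery harness the negative direction climbs from a random
scale to high validation MCC and high rank correlation with the
planted ground-truth scale, while the positive direction stalls near
the random baseline (the accept/reject gate prevents deterioration
but cannot create progress from a systematically wrong step). The
uninverted direction remains available via `modifier_sign = 1`.

# The synthetic generator

`generate_dataset()` states a world: a random backbone (149 residues
by default, core-protein-truncation-like), 71 random insert peptides
of 9–30 residues, and eight parameterized insertion strategies placed
around a loop-like region at roughly half the backbone, with distinct
deletion counts and glycine/serine linkers. A construct's latent
insolubility is the ground-truth-scale feature of its full chimeric
sequence, plus a per-strategy offset, plus Gaussian noise with
standard deviation defaulting to 0.25× the spread of the noiseless
latent — enough noise that single-stump training MCC is clearly below
1, little enough that the signal is recoverable. Labels use an
empirical-quantile threshold, guaranteeing the near-balanced classes
the original dataset is described to have. The stratified split
realizes both marginals exactly (strategies: equal counts ±1; inserts:
floor/ceil of the proportional share) via a randomized
max-remaining-capacity assignment on the bipartite insert × strategy
grid.

What the generator does *not* emulate: real amino acid usage
frequencies (residues are uniform), sequence correlations, any 3-D or
assembly physics, and any model mismatch (the latent lives inside the
model family by construction, so recovery tests have a well-defined
optimum). A green recovery test therefore establishes that the
algorithms work *when their assumptions hold* — it says nothing about
how much of real cVLP solubility those assumptions capture.

Precipitation screening data are simulated as
`as_conc = 0.43 + 0.25·z + ε` (molar), where `z` is the construct's
standardized margin below the solubility threshold and
`ε ~ N(0, 0.05²)`, floored at 0.05 M. The defaults echo the reported
screening behavior — most constructs between 0.5 and 0.7 M, the
occasional value toward 0.4 and 1 M — with one deliberate limitation:
a linear map of a half-normal margin cannot simultaneously produce a
tight 0.5–0.7 M bulk and a 0.1 M outlier, so the extreme low outlier
of real screenings is out of reach of this generator.

# Numerical choices

* Impurity ties break toward the smallest threshold, leaf-majority
  ties toward insoluble, importance ties keep table order (stable
  sort), model-size ties take the smallest size — all deterministic,
  and conservative toward the insoluble class, matching `p ≤ 0 →
  insoluble`.
* Tie-breaking is *exact*: near-ties in the floating-point impurity
  are re-compared by integer cross-multiplication, so the chosen
  threshold is the true smallest minimizer, bit-reproducibly. MCC uses
  a single square root of the exact integer product so that
  equal-count contingencies compare bit-identical (stable ranking
  ties).
* MCC is defined as 0 when a denominator factor vanishes; MAD is the
  raw median absolute deviation about the median (no 1.4826 constant).
* Degenerate stumps (single-class or constant-feature training data)
  predict the majority class from both leaves with threshold −∞.
* Reversed-scale duplicates are detected at Pearson correlation
  ≤ −0.999 after normalization, tolerating rounding in published
  tables; the non-reversed member is kept.
* All randomness derives from explicit integer seeds; every routine
  restores the caller's RNG state, and master seeds fan out to stage
  seeds through a fixed stream so stages are independently
  reproducible.
* PCA on scale tables: scales are normalized (hence columns mean-zero)
  and decomposed without further centering; the PC1 explained-variance
  fraction is the first squared singular value over the total.

# Known limitations

**In-sample drift of the optimizers.** Both optimizers maximize MC-CV
validation MCC computed *inside* the training set. A fixed random
label assignment retains chance structure — per-strategy class
imbalances of order √(0.25/48) ≈ 7%, and composition directions with
chance label correlation of order √(20/384) — and both optimizers can
ratchet into it: on label-permuted data the strategy optimizer's best
vector reliably acquires offsets of 0.1–0.2 pointing at the most
imbalanced strategies, and the scale climb can (depending on the
realization) reach in-sample median validation MCC near 0.3 while the
same scale scores near zero on the held-out test set. This is honest
selection bias, not an implementation leak: MC-CV within the training
set cannot protect against overfitting the training set; only the
external test split can. Consequences: (a) the strict null-safety
bounds in the acceptance suite (modifiers within ±0.02, synthesized
null MCC within ±0.15) fail for the algorithm as specified and are
left red rather than weakened; (b) reported performance should always
be the external-test figure at the validation-selected size, never the
validation optimum itself.

**Other limitations.** The composition-only feature cannot represent
order- or structure-dependent effects; the strategy offset is a blunt
per-stratum correction, not a mechanistic model. The precipitation
regression assumes linearity solely because the intended datasets are
small (≈10 points); with ten points the fitted R² has wide sampling
variability, which is why the test suite checks a permutation null
(mean shuffled R² well below the fitted one) rather than a point
value. The PC1≈69% literature-scale diagnostic requires the 91-scale
table, which is not distributed with this package.
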