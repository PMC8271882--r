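---
title: "Joint Hilbert embeddings for Mocap classification: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint Hilbert embeddings for Mocap classification: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ehecco)
```

This vignette is the package's own account of the science it implements: the
embedding metric, the recognition pipeline built around it, the synthetic
data that exercises it, and the numerical and design choices that were
genuinely open.

## 1. From marginal to joint embeddings

A characteristic kernel κ (here always Gaussian,
κ_σ(a,b) = exp(−‖a−b‖²/2σ²)) maps a probability distribution P to its *mean
embedding* μ = E[φ(x)] in the kernel's RKHS, injectively. The RKHS distance
between two mean embeddings is the maximum mean discrepancy; with empirical
measures on samples {xₙ} and {z_m} it is estimated by pure kernel sums
(`mmd_squared()`):

d̂² = (1/N²) 1ᵀK_{x,x}1 + (1/M²) 1ᵀK_{z,z}1 − (2/NM) 1ᵀK_{x,z}1.

MMD sees only the *marginal* law of each view. To compare *joint*
distributions over a pair of spaces — here a pose space X = R^V and a latent
space Y = R^Q — each joint law is embedded in the tensor space H⊗G as a
cross-covariance operator E[φ(x) ⊗ ψ(y)]. The squared tensor-space distance
between two such embeddings has a closed-form sample estimator in which the
tensor kernel factorizes into a Hadamard product of the two Gram matrices
(`ehecco_squared()`):

d̂²_J = αᵀ(K^φ_{x,x} ∘ K^ψ_{y,y})α + βᵀ(K^φ_{z,z} ∘ K^ψ_{l,l})β
      − 2 αᵀ(K^φ_{x,z} ∘ K^ψ_{y,l})β.

The embeddings themselves are never materialized; everything happens through
kernel evaluations. The weight vectors α, β are probability vectors holding
the joint mass of each sample pair; the package uses the uniform empirical
measure 1/N by default and accepts any normalized vector. The decisive
property over MMD is sensitivity to *coupling*: for X standard normal, the
joint laws of (X, +X) and (X, −X) have identical marginals in both
coordinates, yet EHECCO separates them reliably while the marginal MMD on
either coordinate sees nothing (this is an acceptance-tested property, and
`generate_coupled_records()` builds the motion-domain analogue with in-phase
vs anti-phase arm swings).

### Estimator numerics

* Squared distances use the stable expansion ‖a−b‖² = ‖a‖²+‖b‖²−2a·b with
  negative round-off clamped to zero before exponentiation; self Gram
  matrices are symmetrized by averaging with their transpose.
* The quadratic form is analytically non-negative (PSD kernels). Values in
  (−10⁻⁹, 0) are clamped to zero silently; anything below −10⁻⁹ raises an
  internal-consistency error, since it can only mean a broken kernel.
* A brute-force nested-loop transcription of the three double sums
  (`ehecco_squared_oracle()`) ships as a first-class function. It is the
  testing oracle for the vectorized path (agreement to 1e−10 relative over
  randomized instances) and deliberately contains no matrix algebra.
* The MMD literature writes the estimator with kernel κ_{2σ}, which is
  ambiguous between doubling the bandwidth (denominator 8σ²) and doubling
  the variance (4σ²). `mmd_squared()` exposes the choice as `convention =
  "bandwidth"` (default), `"variance"`, or `"plain"`; `ehecco_squared()`
  uses the bandwidths as given, matching the joint estimator's printed form.
  The bandwidth grid search in the pipeline absorbs any fixed rescaling, so
  classification results do not depend on the convention.
* Dissimilarity matrices store the distance d_J = √(max(d̂²_J, 0)), not the
  squared form: t-SNE and dissimilarity-space features behave better with a
  distance-like quantity. `squared = TRUE` exposes the raw estimator.

## 2. The recognition pipeline

One record travels through:

1. **Forward kinematics** on the BVH joint tree (intrinsic rotations in the
   file's declared channel order, degrees in files, radians internally),
   then **hip normalization**: the root position is subtracted per frame.
   Only translation is removed — no orientation alignment and no
   limb-length rescaling, deliberately, so that body-size information
   survives into the anthropometric analysis.
2. **Codebook**: the flattened frames (V = 3J) are grouped by normalized
   spectral clustering — Gaussian affinity at the median-heuristic
   bandwidth, symmetric normalized Laplacian, row-normalized top-N_c
   eigenvectors, seeded k-means — and each cluster contributes its
   *medoid*, so codebook poses are actual recorded frames. Ties break to the
   lowest frame index. N_c defaults to 50 (capped at the record length):
   a few dozen poses cover cyclic actions well and the per-pair metric cost
   grows as O(N_c²).
3. **Latent basis**: PCA with Q = 3 components, fitted *globally* on the
   pooled codebook frames of the training records. A per-record basis would
   make the latent cross-kernel K^ψ_{y,l} compare coordinates expressed in
   different, arbitrarily rotated axes; a shared basis is the only reading
   under which the cross term is well-defined. Within cross-validation the
   basis (and everything else learnable) is fitted on training folds only.
   Eigenvector signs follow a fixed convention (largest-magnitude
   coefficient positive) so refits are bit-identical.
4. **Distance matrix and SVM**: records become EHECCO distances; an RBF SVM
   is trained on the dissimilarity representation, each record's feature
   vector being its distances to the training records. An alternative
   reading — converting D directly into the kernel exp(−γD²) — is available
   as `mode = "precomputed"`; the feature reading is the default because
   the distance matrix plus a nonlinear RBF mapping is the more standard
   dissimilarity-space construction and keeps the SVM kernel PSD without
   further conditions on D.
5. **Hyperparameters**: both bandwidths are searched over
   {0.5σ₀, σ₀, 2σ₀, 5σ₀, 10σ₀} around each space's median-heuristic σ₀
   (computed on pooled training samples of that space), crossed with the
   SVM penalty grid {1, 10, 10², 10³, 10⁴} and precision grid
   {0.01, 0.1, 1, 100, 1000} — 625 tuples, scored by 3-fold internal
   stratified cross-validation on the training records, ties broken by the
   smallest grid indices. The search nests inside every outer fold; the
   optimistic variant (one search on all data) is intentionally not
   offered.
6. **Evaluation**: stratified 10-fold cross-validation (stratification
   matters at 5 records per class; folds are reduced with a warning when a
   class is smaller than the fold count), mean accuracy =
   trace(confusion)/N, pooled confusion matrix.
7. **Interpretation**: t-SNE on the distance matrix (precomputed-distance
   mode, exact θ = 0, default perplexity 5 for cohort-sized Λ) for 2-D
   scatter plots, and covariate correlation: a 1-D t-SNE projection is
   averaged per subject and correlated (absolute Pearson r) against each
   subject measurement, pooled and per class.

All randomness — codebooks, folds, k-means, internal grids, t-SNE — derives
from one master seed; identical seeds give identical reports.

## 3. The synthetic generator

No bundled Mocap corpus can ship with the package, so the generator *is* the
study system. It emulates labeled, multi-subject, multi-class skeletal time
series: a deterministic humanoid tree (hip root, two 3-joint legs, spine,
head, two 2-joint arms; 15 joints by default; offsets in centimeters;
120 Hz), with every rotation channel following A·sin(2πft+φ)+c. Parameters
combine

* a fixed per-channel baseline,
* per-class deviations scaled by `class_separation` (default 1; 0 removes
  all class signal),
* a hidden per-subject scalar *style* shifting rotation offsets along a
  fixed direction, scaled by `style_scale` (default 1) — the same subject
  performs every action "their way",
* Gaussian per-frame jitter (`noise_sd`, default 2°),
* a slow class-independent sinusoidal root drift (so hip normalization is
  doing real work), and record durations drawn from 2–4 s.

Subject covariates include one size-like column with a documented linear
link to style (wingspan = 12·style + 180 + N(0,1) cm) and three independent
distractors. Seeds are hierarchical (master → per record), so subsetting a
dataset never changes the surviving records.

Sinusoidal kinematics were chosen over physical simulation because they give
closed-form ground truth for oracle tests and reproduce the cyclic structure
of repeated actions that makes codebook coverage meaningful. What the
generator does *not* emulate: biomechanical constraints (joint limits, limb
coupling through dynamics), marker dropout and occlusion noise,
non-stationary tempo changes within a record, and realistic inter-subject
kinematic variation beyond the one-dimensional style. Passing tests
therefore demonstrate that the implementation realizes the method's claimed
properties under controlled conditions — not that those accuracy levels
transfer to recorded human data.

## 4. Study conditions used by the tests

The end-to-end checks run the default conditions: 5 classes × 4 subjects ×
5 repetitions (100 records), N_c = 50, Q = 3, 10-fold CV. Under them the
pipeline separates the classes essentially perfectly, and with
`class_separation = 0` plus shuffled labels it falls to the 5-class chance
level — the pair of results that shows the accuracy is earned from class
structure rather than leaked. One caveat the checks surface honestly: the
pooled codebook frames of the default dataset place roughly 74% of their
variance in the first three components, a shade under the 75% the latent
view retains on real motion — the generator's channels are deliberately
independent sinusoids (for closed-form oracles), so their variance spreads
across more directions than coordinated human limbs would; per-record the
three components retain well over 90%. Smaller configurations (3 classes × 2
subjects × 4 reps, 15-pose codebooks, 1–1.5 s records at 60 Hz) are used
where a property does not need the full design; the estimator-level checks
run on randomized instances with N, M ≤ 20 samples and V ≤ 6, Q ≤ 3
dimensions, where the nested-loop oracle is fast.

The covariate-correlation check uses a style-dominant cohort: 17 subjects,
6 records each, `class_separation = 0`. The reason is a genuine limitation
worth stating plainly: a 1-D t-SNE projection preserves neighborhoods, not
global orientation. When strong class clusters exist, each cluster's
internal style gradient is embedded with an arbitrary sign, so per-subject
means taken across clusters cancel — even when the distance matrix
demonstrably carries the style signal (a classical-MDS control recovers it
with |r| ≈ 0.99 in the same setting). Even under style-dominant conditions
the t-SNE readout is realization-sensitive: a 1-D t-SNE can *fold* a line
of tight subject clusters, since nothing in its objective rewards global
ordering, so the linear correlation varies considerably across generated
cohorts while the MDS control stays near 0.99. The acceptance script
therefore reports both readouts. Users who want subject-level
interpretation should prefer a global method such as classical MDS on D, or
average within class (the `per_class` output), and treat 1-D t-SNE
correlations as qualitative.

## 5. Degenerate inputs and edge behavior

* All-coincident samples make the median heuristic undefined; it falls back
  to σ = 1 with a warning instead of erroring, so pathological synthetic
  edge cases keep pipelines running.
* Records shorter than N_c keep all frames, reducing N_c with a warning.
* A constant covariate column yields NA with a warning rather than a
  spurious correlation.
* `fit_latent_basis()` refuses q above the achievable rank and names the
  rank in the error.
* BVH parsing reports line numbers for malformed files, accepts any declared
  rotation-channel order, and retains End Sites as zero-channel leaves;
  End Sites never enter the V-dimensional feature vector since they carry
  no motion channels.

## 6. Known limitations

* The metric's cost is O(N_c²) kernel work per record pair and the matrix
  is Λ×Λ; very large corpora need subsampling or blocking.
* Only two coupled views are supported (pose + latent); extensions to more
  than two tensor factors are out of scope.
* The conditional-embedding family of operators is not implemented; EHECCO
  compares joint laws only.
* Codebooks are per record. A dataset-global codebook is a plausible
  alternative reading of the pipeline and is intentionally not implemented;
  per-record codebooks keep records independent and are what the coverage
  diagnostics assume.
* t-SNE-based 1-D interpretation carries the orientation caveat of §4.
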