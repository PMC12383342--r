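---
title: "Habitat radiomics, 2.5D multi-instance learning and nomogram modelling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat radiomics, 2.5D multi-instance learning and nomogram modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

habitomics implements a complete CT-based prediction pipeline for binary
clinical endpoints such as lymph-node metastasis (LNM) after neoadjuvant
therapy in esophageal squamous cell carcinoma: intratumoral habitat
delineation, a large handcrafted radiomic feature bank, a feature-selection
cascade, 2.5D slice-level learning fused into patient-level multi-instance
(MIL) features, clinicoradiological logistic signatures, a fusion nomogram,
and a full evaluation suite. Because clinical CT cohorts cannot ship with a
package, a synthetic-cohort generator with a known generative model makes
every stage testable end to end.

## Preprocessing

CT intensities are clipped to [−125, 225] HU, the contrast-enhanced
soft-tissue window: values outside it are dominated by air, bone and
artifacts and would destabilize intensity statistics. Volumes are resampled
to 1 mm isotropic voxels (trilinear for the image, nearest-neighbor for the
mask so it stays binary; output grid size is `round(n * spacing / target)`
per axis). Gray levels are discretized with a fixed 5-HU bin width, giving
(225 − (−125))/5 = 70 bins; the bin of value *x* is
`floor((x − clip_lo)/5) + 1`, with the top edge closed so 225 falls in bin
70 rather than an empty 71st bin. Fixed bin *width* (absolute resampling)
keeps one HU meaning per bin across patients, unlike fixed bin counts.

## Habitat delineation

Every in-mask voxel is described by the 19 standard first-order statistics
(energy, total energy, entropy, minimum, 10th/90th percentile, maximum,
mean, median, interquartile range, range, mean absolute deviation, robust
MAD, RMS, SD, skewness, kurtosis, variance, uniformity) of its 3×3×3
neighborhood, restricted to in-mask voxels; entropy and uniformity use the
5-HU bins for consistency with the global discretization. Voxels with fewer
than two in-mask neighbors are flagged and later assigned to the cluster
with the nearest mean HU. The exact composition of the 19-channel local
feature set is our documented choice; only its cardinality is externally
constrained.

Channels are z-scored (population SD) and clustered per patient with
K-means at k = 3 (fixed a priori; no model selection over k). Lloyd
iterations start from deterministic seeds: the feature vectors of the
voxels at the 1/6, 3/6 and 5/6 quantiles of the window-mean-HU channel.
This makes maps reproducible and invariant to voxel ordering, and since
habitats are intensity-ordered structures it places one seed per putative
compartment. Final labels are renumbered by ascending cluster mean HU.
Clustering is per patient: unsupervised cluster identities are not
comparable across patients, which is exactly why downstream aggregation
averages over subregions.

## Handcrafted features

The bank holds 1834 features: 14 geometry + 20 × 18 first-order + 20 × 73
texture.

* **Geometry (14)**, computed once on the mask: mesh and voxel volume,
  surface area, surface/volume ratio, sphericity, maximum 3D diameter,
  three in-plane maximum 2D diameters, three principal axis lengths,
  elongation, flatness. Surface area integrates the gradient magnitude of a
  Gaussian-smoothed (σ = 1.5 voxel) mask indicator — accurate for the
  smooth blob-like shapes of tumors (sphere area within ~0.2%), though it
  rounds sharp corners of artificial shapes. Sphericity is clipped at its
  theoretical maximum of 1 because discretization noise in the volume
  estimate can push a near-perfect digital sphere fractionally above it.
  Maximum diameters use per-slice convex hulls (every extreme point of the
  3D cloud is extreme in its own slice, so this is exact).
* **First-order (18 per derived image)**: the 19 statistics minus total
  energy, which is a voxel-count-scaled duplicate of energy.
* **Texture (73 per derived image)**: GLCM 22, GLRLM 16, GLSZM 16, GLDM 14,
  NGTDM 5, computed from the discretized image (5-HU bins on the original;
  fixed 32 bins on derived images, whose scales are not HU). GLCM and GLRLM
  are evaluated for each of the 13 unique 3D directions and the features
  averaged. The 22 GLCM features exclude sum average and dissimilarity,
  which are deterministic functions of joint average and difference
  average. Degenerate inputs (single gray level, directions with no voxel
  pairs) return defined values — joint entropy 0, maximum probability 1 —
  never errors. Texture matrices are built in compiled code; a plain-R
  reference implementation of every feature family is kept and
  cross-checked in the tests.

The 20-image filter bank: original; 8 sub-bands of a one-level undecimated
separable Haar wavelet; Laplacian-of-Gaussian at σ = 1..6 mm
(σ²-normalized); square, square root, logarithm and exponential of the
range-shifted image; gradient magnitude. Only the counts 18 × 20 and
73 × 20 are externally constrained; the composition is our documented
choice.

**Whole-ROI vs habitat features.** `Intra` features are extracted from the
whole tumor. `Habitat` features extract the full bank from each habitat
subregion (subregions under 10 voxels are excluded) and take the
feature-wise arithmetic mean, which makes the result invariant to habitat
label permutation — the reason averaging is preferred over concatenation
when cluster identities are not comparable across patients.

## Feature-selection cascade

ICC → z-score → Welch t-test → correlation pruning → LASSO, strictly
nested:

1. **ICC(2,1)** (two-way random effects, absolute agreement, single
   measurement) between duplicate segmentations; keep ICC ≥ 0.85
   (inclusive). The habitat and MIL chains skip this stage: duplicate
   segmentations do not give matched cluster identities.
2. **Z-score** with training mean and population SD (the divide-by-*n*
   form); held-out tables are transformed with the training statistics, and
   no test-set statistic influences any selection decision.
3. **Welch t-test** per feature, two-sided; keep p < 0.05 strictly. Welch
   rather than pooled variance because group variances are not assumed
   equal.
4. **Greedy correlation pruning**: while any pair has Pearson |r| > 0.9,
   delete the feature with the most over-threshold partners (ties: larger
   mean |r| with its partners, then lexicographic name). "Most partners" is
   our operationalization of "highest redundancy".
5. **LASSO** on the 0/1 label as a *linear* (MSE) model — matching the
   minimum-mean-squared-error criterion used to pick λ — with 10-fold CV;
   λ* minimizes mean CV MSE and the selection is the nonzero support. If
   everything is shrunk to zero, the first feature to enter the path is
   kept so downstream models stay defined (with a warning).

## 2.5D slice learning and MIL fusion

The central slice maximizes in-mask area (ties to the lower index); slices
at offsets −4, −2, 0, +2, +4 are cropped to the central-slice bounding box
grown 10% per side and squared, HU-clipped, min–max normalized to [−1, 1]
per slice (constant slices map to zeros), and resized to 224 × 224 with
nearest-neighbor interpolation. Offsets beyond the volume reuse the nearest
valid slice.

Backbones are pluggable per-slice classifiers behind a registry. The three
reference backbones are small seeded convolutional classifiers: the slice
is mean-pooled 8×, passed through fixed random zero-mean convolution
filters (8×5×5, 16×5×5, 16×7×7) with ReLU and global mean/max pooling,
plus the pooled image's global mean and SD (zero-mean filters are blind to
the DC level); a logistic head is trained with minibatch SGD, sigmoid
cross-entropy loss and a cosine-decay learning rate. They train on a CPU in
seconds, so the tests exercise the pipeline rather than pretrained weights;
large pretrained architectures can be plugged in through the same
interface. One model is fit per (backbone, offset) pair — 15 under the
default registry — with the patient label as the weak slice label.

Slice outputs are fused per patient: the **predict-likelihood histogram**
(per backbone, the histogram of its five slice probabilities over five
equal-width bins on [0, 1], half-open and closed at the top, plus the count
of positive hard labels at the 0.5 threshold), and **bag-of-words TF-IDF**
(tokens are (backbone, probability-decile) pairs over the 15 outcomes;
idf = ln((1+N)/(1+df)) + 1 fitted on training patients only; rows
L2-normalized). The concatenation is the MIL feature table, which then goes
through the selection cascade (without ICC) and signature fitting like any
radiomic chain.

## Signatures, model zoo and nomogram

The clinicoradiological signature is a univariate logistic screen
(p < 0.05 gate, with a small-ridge fallback under complete separation,
detected by a saturated linear predictor) followed by a multivariate
logistic fit with Wald 95% CIs; the retained set is the jointly significant
variables.

Radiomic signatures are fitted over a model zoo — logistic regression, RBF
SVM, random forest, extremely randomized trees, two gradient-boosted-tree
variants (shallow and deep configurations of the same boosting library,
behind one interface), and a single-hidden-layer perceptron — with
exhaustive grid search maximizing mean AUC over 5 seeded stratified CV
folds, refit at the best hyperparameters, and a Youden-optimal decision
threshold frozen from the training ROC (the threshold convention is our
choice; the evaluation reports it explicitly).

The nomogram is a logistic model over age, treatment, MLNSD and the
Habitat/MIL signature predicted probabilities. Points for variable *i* at
value *x* are `100 · β_i (x − ref_i) / max_j |β_j| range_j` with the
reference at the variable's minimum-risk end of the training range — the
signed form is nonnegative in-range and stays monotone beyond it — so the
largest-leverage variable spans exactly 0–100 and the probability map is an
exact re-parameterization of the logistic model (equal to 1e−9, not an
approximation).

## Evaluation

AUC is the tie-aware Mann–Whitney statistic; its variance comes from the
DeLong structural components, with Wald (default) or logit-transformed 95%
CIs, and the paired DeLong test compares correlated AUCs. Threshold metrics
(accuracy, sensitivity, specificity, PPV, NPV) carry class-stratified
percentile-bootstrap CIs; undefined PPV/NPV are reported as missing.
Calibration uses binned observed-vs-predicted curves with 1000 stratified
bootstrap resamples and the Hosmer–Lemeshow test on deciles of risk with
χ² = Σ (O−E)²/(E(1−E/n)) and g − 2 degrees of freedom; the g − 2 rule is
calibrated for probabilities fitted on the same data, which is how the
null-calibration test simulates it. Decision curves report
NB(t) = TP/n − FP/n · t/(1−t) against treat-all and treat-none. All
resampling takes an explicit seed.

## The synthetic cohort

Each phantom tumor is an ellipsoid (largest semi-axis 9–14 mm by default,
minor axes 60–90% of it) in a 64³ volume of 1 mm voxels over a smooth
soft-tissue background (40 ± 15 HU, long-range field). The tumor is layered
along its major axis — the proximal–distal direction of an elongated
esophageal tumor — into a necrotic pole (15 ± 5 HU, smooth texture), a
tumor body (85 ± 12 HU) and an enhancing pole (175 ± 24 HU, rough texture),
each a Gaussian random field with its own correlation length. Layering
means only intensity-adjacent compartments share an interface, and
compartment fields are blended through a Gaussian partial-volume ramp
(σ = 0.9 voxel) emulating scanner blur, so interfaces are ramps rather
than step edges while the ground-truth labels stay crisp. The necrotic
fraction is sampled per patient (18–45% of the volume, cut at volume
quantiles).

Distinct compartment texture *amplitudes* (5/12/24 HU) matter beyond
realism: they make the dispersion channels of the local feature set order
the compartments consistently with intensity, and they place
partial-volume transition windows inside the observed dispersion range
instead of letting them form a spurious "interface habitat".

Per-patient latents drive the label through a logistic model with fixed
standardization constants and an intercept calibrated so the cohort mean
risk equals the configured prevalence (0.3): necrotic-core volume fraction,
enhancing-pole mean intensity (±5 HU SD) and heterogeneity (texture SD
multiplier 0.5–1.0), tumor-body enhancement (±17 HU mean shift), MLNSD,
age, and treatment arm. The default coefficients put the dominant image
signal on tumor-body enhancement. That choice is what gives habitat
analysis a genuine, mechanistically honest advantage over whole-ROI
analysis: a mid-intensity compartment's mean shift cannot be isolated by
any whole-ROI quantile (every whole-ROI statistic mixes compartments with
volume-fraction-dependent weights), while the middle habitat's own mean
reads it directly; likewise single-compartment texture is diluted in
whole-ROI texture statistics. Signals that a whole-ROI quantile *can* read
cleanly (e.g. the brightest compartment's intensity, visible to p90/max)
are deliberately given small weights and variances — with them dominant,
whole-ROI and habitat chains are near-equivalent and the comparison is
uninformative; and because subregion averaging mixes all compartment
means, a large nuisance variance on the brightest compartment would also
drown the habitat readout itself.

Rater variability for ICC testing is simulated by rounds of random
morphological boundary jitter (dilate or erode a random half of the
boundary shell per round), giving Dice monotonically decreasing in the
magnitude parameter. Clinical covariates are sampled from distributions
loosely matched to a thoracic-oncology cohort; only age, treatment and
MLNSD carry label signal.

What the generator does **not** emulate: scanner- and protocol-specific
noise spectra and artifacts, non-ellipsoidal or infiltrative tumor
morphology, anatomically structured mediastinal background, and
inter-feature correlation structures of real tumors. Passing tests
therefore demonstrate correctness and internal validity of the pipeline,
not clinical performance.

## Problem sizes and numerical choices

Tests and the acceptance script run at desk scale, chosen as the smallest
sizes at which each property is identified:

* Habitat-recovery ARI uses ~50 mm tumors (104³ volumes). Partial-volume
  transition bands — not noise — bound achievable ARI: away from a ±2-voxel
  band around compartment interfaces the clustering matches the planted
  truth almost perfectly (interior ARI ≈ 0.99), and the band fraction
  scales inversely with tumor size. ~50 mm is the locally-advanced-tumor
  scale at which the band is small enough for overall ARI ≥ 0.8.
* End-to-end directional comparisons (whole-ROI vs habitat signatures;
  nomogram fusion) run 20 replicates of n = 300 cohorts in 44³ volumes
  with 7–10 mm tumors and the original-image filter bank; a 70/30
  stratified split, the selection cascade per chain, random-forest
  signatures, and the fusion nomogram.
* Label-model recovery uses the latents-only generation mode
  (`generate_cohort(..., images = FALSE)`) at n = 20000, where logistic
  coefficient standard errors are well below the 15% tolerance.
* Statistical null calibrations use 500–2000 Monte Carlo replicates, which
  bound the simulation SE of a 5% rate at well under the ±2% tolerance.

Numerical conventions worth knowing: quantiles are R type 7 everywhere
(including the compiled window statistics); population (divide-by-*n*)
variance in first-order features and z-scores; skewness/kurtosis of
constant regions are defined as 0; K-means uses Lloyd iterations with
deterministic seeding; ties in the central-slice choice go to the lower
index; all stochastic steps take explicit seeds and every output is a pure
function of (inputs, config, seed).

## Known limitations

Feature values are not bit-identical to any specific third-party extractor
(bin-edge and aggregation conventions differ between tools); the reference
backbones are deliberately small and are not a substitute for large
pretrained networks when real images are available; the nomogram's point
scale is anchored to the training range, so out-of-range inputs
extrapolate linearly; and the synthetic cohort's habitat-advantage
mechanism, while chosen to mirror the biology of treatment response, is a
model — directional results on it validate the machinery, not the clinical
claim.
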