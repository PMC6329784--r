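---
title: "Decoding tactile roughness intensity from multivoxel patterns: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding tactile roughness intensity from multivoxel patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

When people feel a rough surface, and when they merely watch someone else
feel it, do the same neural populations encode *how rough* it is? The
analysis implemented here addresses that question with a five-level
roughness design: sandpapers of particle size 0.3, 12, 40, 60 and 100 μm,
each identified by a surface colour, explored by touch in half the scanning
runs and watched on video in the other half. Three searchlight decoding
analyses probe (a) tactile runs, (b) visual runs, and (c) cross-modal
transfer — training the classifier on one modality and testing on the other.
Above-chance cross-modal transfer at a location can only arise if the
pattern-to-intensity mapping there is common to both modalities; that is the
central dissociation the pipeline exists to detect.

Because no public dataset accompanies this design, the package ships a
first-class synthetic-data module. Every stage of the pipeline can therefore
be exercised against known ground truth: signal regions are planted with
known responsiveness (tactile-only, visual-only, shared, or
modality-independent), and the analysis must find exactly the ones its logic
predicts.

## The processing chain

1. **Trial table** (`generate_trial_table`): 3 runs per modality, each 310 s
   — a 10 s baseline then 25 trials of 12 s in five blocks, every block a
   random permutation of the five intensities. Visual trials stimulate for
   the first 3 s of the trial; tactile trials stimulate 9 s in (7 s rest,
   2 s finger placement, 3 s exploration).
2. **Forward model** (`simulate_bold`): voxel time courses are the sum of
   per-trial responses (3 s box-car convolved with the canonical
   double-gamma HRF), a slow cosine drift with random per-voxel phase, and
   AR(1) Gaussian noise. Within a signal region the amplitude of trial $t$
   at voxel $v$ is
   $a_{tv} = g\,c_t + \alpha\, P_{c_t v}$, where $c_t$ is the intensity
   class, $g$ the univariate gain, $\alpha$ the pattern amplitude and $P$ a
   class-by-voxel pattern map drawn once per subject from a standard normal.
   Shared regions reuse one $P$ for both modalities; independent regions
   draw one per modality.
3. **Trial-wise GLM** (`build_trial_design`, `fit_betas`): one regressor per
   trial (150 across the session), a discrete-cosine drift basis with all
   periods above 128 s, and a constant, fitted per run by OLS. The trial
   coefficients (beta series) are the classifier's examples.
4. **Searchlight GNB** (`runwise_cv`, `crossmodal_cv`): a 3×3×3 voxel cube
   slides over the mask; at each centre a 5-class Gaussian Naive Bayes
   classifier with per-feature class means and a *pooled* within-class
   variance is cross-validated run-wise (leave-one-run-out) or across
   modalities (both directions, averaged). Chance (0.2) is subtracted, so
   maps live on $[-0.2, 0.8]$.
5. **Group inference** (`onesample_tmap`, `extract_clusters`,
   `signflip_null`): voxel-wise one-sample t against zero (one-tailed),
   thresholded at $p < 0.001$ with cluster extent $> 50$, and corrected by a
   sign-flipping permutation null of maximum cluster sizes (95th
   percentile).
6. **Behavioral chain** (`normalize_ratings`, `group_dissimilarity`,
   `nonmetric_mds`, `mantel_test`): free-modulus magnitude estimates of
   pairwise dissimilarity are normalized in two steps (geometric-mean
   rescaling, then per-participant min–max), averaged into a 5×5
   ordered-pair dissimilarity matrix, embedded by nonmetric MDS, and
   compared between conditions by Mantel permutation tests.
7. **Region analyses** (`cluster_confusion`, `confusion_behavior_corr`,
   `tvalue_property_corr`): per-cluster confusion matrices pooled over the
   searchlights inside a cluster, correlated (off-diagonal entries) with the
   behavioral similarity matrix; and per-cluster activation levels
   correlated with particle size versus luminance.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| TR | 1.52 | s | acquisition rate of the emulated protocol |
| trial / stimulation / baseline | 12 / 3 / 10 | s | printed block design |
| high-pass cutoff | 128 | s | standard drift cutoff; yields 4 cosine columns on a 310 s run |
| HRF | peak 6, undershoot 16, dispersions 1, ratio 6, length 32 | s | canonical double-gamma |
| searchlight half-width | 1 (3×3×3) | voxels | the decoding neighbourhood |
| `min_voxels` | 10 | voxels | mask-edge searchlights below this are skipped |
| voxel threshold / extent | 0.001 / 50 | — | cluster-forming rule |
| sign-flip permutations | 1000 | — | max-cluster-size null |
| Mantel permutations | 10000 | — | condition-relabelling null |
| `noise_sd` | 14 | signal units | see calibration below |
| `pattern_amp` / `intensity_gain` | 1 / 0.5 | signal units | multivoxel vs univariate signal strength |
| `ar1_rho` | 0.3 | — | minimal temporally correlated noise model |
| rating exponent γ | 0.3 | — | compressive psychophysical axis |

**SNR calibration.** The generator's noise level is anchored to the decoding
accuracies the design is known to produce in practice: with `noise_sd = 14`
and `pattern_amp = 1`, run-wise searchlight accuracy inside a signal region
averages ≈ 0.27 against a 0.2 chance level — the weak-but-reliable regime
typical of single-trial intensity decoding — rather than the near-ceiling
values a casual noise choice produces. Cross-modal accuracy runs somewhat
higher in the shared region because cross-modal training uses all 75
examples of a modality instead of 50.

**Rating exponent.** The latent perceptual axis is $p_i = s_i^{0.3}$ with
$s_i$ the particle size in μm. A compressive power law is the conventional
magnitude-estimation choice and places 100 μm far from the cluster of small
sizes, so the (0.3, 100) pair is always the most dissimilar.

## The recovery phantom

`demo_phantom()` is the reference ground truth for recovery tests: a 24³
grid, ellipsoid mask (semi-axes 11, ≈ 5600 voxels), and four width-7 cube
regions, one per responsiveness type. Two placement rules matter:

* Every pair of regions that one searchlight scheme can co-detect sits at
  Chebyshev distance 11 — a 4-voxel gap — so a cluster plus its one-voxel
  searchlight spill cannot bridge into a neighbour. The tactile-only and
  visual-only regions are never co-detected and need no such budget.
* The *independent* region carries no univariate intensity gain. A mean
  activation ramp over intensity identical in both modalities would itself
  be a cross-modally shared code, and the region exists precisely to show
  that information encoded with unrelated patterns does **not** transfer.
  Its decodability within each modality comes entirely from its two
  unrelated pattern maps.

Cube corners falling outside the ellipsoid are clipped (319 of 343 voxels
survive); the clipped voxel set is the ground truth all overlap measures use.

## Numerical choices

* **Unit-peak HRF.** The sampled kernel is scaled to a maximum of 1 and the
  same regressor-construction code is shared between the forward model and
  the design builder, so noiseless simulation followed by OLS returns the
  generated amplitudes to machine precision (a tested identity).
* **Pooled GNB variance** (one variance per feature, shared across classes)
  is markedly stabler than per-class variances at 10–15 training examples
  per class; variances are floored at $10^{-12}$ times their mean.
  Prediction ties break toward the lowest class index — deterministic and
  testable.
* **Searchlight vectorization.** Class means and pooled variances are
  sufficient statistics per voxel, so they are computed once for the whole
  brain and neighbourhood log-likelihood sums are obtained by one sparse
  matrix product per class — equivalent to fitting a classifier per
  searchlight, at a small fraction of the cost.
* **Sign-flip nulls** recompute t from per-voxel $\sum x$ and $\sum x^2$
  under each flip assignment; component labelling goes through vectorized
  adjacency enumeration and graph connectivity.
* **Drift removal is exact only within the DCT span.** Any drift that is a
  linear combination of the modelled cosines and the constant leaves task
  betas untouched to $10^{-8}$; an off-harmonic slow cosine (e.g. 200 s
  period on a 310 s run) is only approximately spanned and can move trial
  betas by several percent of its amplitude. This is a property of
  cosine-basis high-pass filtering itself, not of this implementation, and
  the property tests assert the exact in-span statement plus a bounded
  off-span leakage.
* **Truncated final tactile trial.** With runs of exactly 310 s and tactile
  stimulation starting 9 s into each trial, the last tactile trial's
  haemodynamic response is mostly unsampled; its regressor is near zero and
  its beta noisy. This is faithful to the emulated design and is the reason
  tactile decoding runs slightly below visual decoding at matched signal.
* **Degenerate inputs.** All-equal ratings per participant, all-zero
  dissimilarities, zero off-diagonal variance in Mantel inputs, empty
  clusters, missing classes in a training fold, and zero between-subject
  variance at a voxel are all explicit errors or flagged sentinels rather
  than silent NaNs.

## Open design points and how they were resolved

* **Mantel null and tail.** The null relabels the five conditions jointly on
  rows and columns of one matrix; the default is one-tailed (positive
  correspondence is the hypothesis) with a two-tailed option. The observed
  statistic is included in the Monte-Carlo count, so $p \ge 1/(n_{perm}+1)$;
  an exhaustive mode enumerates all 120 relabelings and is the oracle for
  the sampled path.
* **MDS flavour.** Kruskal stress is reported, so nonmetric (isotonic) MDS
  is the implementation, run from a classical-scaling start plus random
  restarts (50 by default); ordered-pair matrices are symmetrized as
  $(d+d^\top)/2$ only at the MDS boundary, and kept asymmetric everywhere
  else.
* **Sign-flip scheme.** The default flips each subject's map independently
  with probability 0.5 — the standard exchangeability argument. An
  asymmetric variant (flip probability 0.2, mirroring the 80/20 marginal
  sign probabilities of chance-subtracted accuracies) is exposed as
  `flip_prob` for comparison, but is not an exchangeable null and is not
  used by the calibration tests.
* **Zero ratings** break geometric means; by default they are omitted from
  the mean (an epsilon-substitution option, half the smallest positive
  rating, is provided).
* **Cluster confusion matrices** pool the test predictions of all
  searchlight centres inside the cluster; this uses exactly the decoding
  decisions that made the cluster significant.
* **t-versus-property correlations** pool (voxel, condition) pairs across
  the cluster (n = 5 × cluster size); a cluster-mean variant (n = 5) is
  available where the pooled version's effective sample size would be
  misleading.
* **Trial-wise estimation** fits all 25 trial regressors of a run
  simultaneously (least-squares-all); with 12 s between trials the
  collinearity is mild, and the per-run fits match the run-wise
  cross-validation structure downstream.

## What the synthetic data does and does not emulate

The generator reproduces the statistical structure the analysis assumes:
block-randomized balanced designs, HRF-convolved responses, slow drift,
temporally autocorrelated noise, subject-specific multivoxel patterns that
are stable across runs, and free-modulus ratings on a shared latent axis. It
does **not** emulate anatomy, spatially correlated (smoothed) noise,
physiological cycles, motion, inter-subject anatomical variability, or
non-Gaussian pattern distributions. Passing recovery tests therefore shows
the pipeline's inferential logic is sound and calibrated under its own
assumptions — not that real data meet those assumptions.

## Problem sizes used by the test suite

The suite favours small, repeated simulations: chance calibration uses 8
null subjects on the full 24³ phantom; ROI recovery uses 15 subjects with
200 sign-flip permutations; type-I calibration of the corrected cluster test
uses 200 null datasets of 10 subjects on a 16³ grid with 100 permutations
each and a 0.01 cluster-forming threshold (the coarser threshold keeps the
max-cluster-size null off the degenerate all-zero distribution at this grid
size); Mantel-type error rates use 500 exhaustively enumerated null draws.
These sizes give Monte-Carlo error comfortably inside each test's tolerance.

## Known limitations

* No prewhitening: OLS with AR(1) noise is unbiased (tested) but not
  minimum-variance; the emulated protocol's modelling choice is kept.
* The 18-connectivity default and the 95th-percentile extent rule are
  conventions; both are parameters.
* Cross-modal accuracy is not directly comparable in magnitude to run-wise
  accuracy (different training-set sizes).
* Accuracy maps are analysed with Gaussian random-effects machinery even
  though per-subject accuracies are discrete; with ≥ 10 subjects and 75
  test trials this is harmless, but with very few subjects ties can produce
  zero-variance voxels (flagged with a sentinel).
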