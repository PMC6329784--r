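# roughmvpa

Searchlight decoding of tactile roughness intensities from multivoxel fMRI
patterns — with a synthetic-data generator that makes every stage testable
against known ground truth.

## The problem

Five sandpapers (particle sizes 0.3, 12, 40, 60, 100 μm) are explored by
touch in half of a scanning session and watched on video in the other half.
Three questions follow, each answered by a whole-brain searchlight analysis:

* which local activity patterns discriminate the five intensities during
  **tactile** exploration,
* which do so during **visual** observation, and
* where does a classifier trained on one modality decode the other
  (**cross-modal** transfer) — possible only where the pattern-to-intensity
  code is shared between modalities.

The pipeline is: trial-wise GLM beta series (box-car ⊛ canonical double-gamma
HRF, 128 s discrete-cosine high-pass) → 3×3×3 cube searchlight with a
5-class pooled-variance Gaussian Naive Bayes classifier under run-wise or
cross-modal cross-validation → chance-subtracted accuracy maps → one-sample
random-effects t maps, clusters at voxel *p* < 0.001 and extent > 50,
corrected by a sign-flip max-cluster-size permutation null → per-cluster
confusion matrices correlated with the behaviorally derived similarity
matrix (Mantel-type condition-relabelling tests). The behavioral side
normalizes free-modulus magnitude-estimation ratings (geometric-mean
rescaling, then per-participant min–max), averages them into 5×5
ordered-pair dissimilarity matrices, and embeds them with nonmetric MDS
(Kruskal stress-1).

Because no real data ship with the package, a first-class generator
(`simulate_bold`, `generate_ratings`, `demo_phantom`) produces fMRI-like
volumes and ratings with planted signal regions that are tactile-only,
visual-only, shared, or modality-independent — so the cross-modal logic can
be verified end to end: the independent region decodes within each modality
but must *not* transfer.

## Worked example

```r
library(roughmvpa)

## behavioral chain: ratings -> group dissimilarity -> MDS -> Mantel
ratings <- generate_ratings(n_participants = 15, seed = 1)
d <- group_dissimilarity(normalize_ratings(ratings)$ratings)
round(as.matrix(d), 2)
#>      0.3   12   40   60  100
#> 0.3 0.00 0.28 0.53 0.63 0.73
#> 12  0.26 0.00 0.16 0.26 0.40
#> 40  0.50 0.15 0.00 0.03 0.17
#> 60  0.61 0.24 0.03 0.00 0.08
#> 100 0.77 0.38 0.18 0.08 0.00

nonmetric_mds(d, seed = 1)$stress
#> 7.86e-17                         # 5 points embed exactly in 2-D

learning <- generate_ratings(n_participants = 15, seed = 2)
dl <- group_dissimilarity(normalize_ratings(learning)$ratings)
mantel_test(similarity_from_dissimilarity(d),
            similarity_from_dissimilarity(dl), n_perm = 10000, seed = 3)
#> r = 0.996, p = 0.0077            # same latent axis with and without vision

## imaging chain: one synthetic subject, cross-modal searchlight
phantom <- demo_phantom(seed = 1)          # 24^3 grid, 4 ground-truth regions
trials  <- generate_trial_table(3, seed = 2)   # 6 runs x 25 trials
betas   <- simulate_subject_betas(phantom, trials, seed = 3)
sl      <- crossmodal_cv(betas$tactile, betas$visual)
#> mean raw accuracy: shared region 0.33, independent region 0.21 (chance 0.20)
```

The dissimilarity matrix is compressive in particle size (0.3 vs 100 μm is
the most dissimilar pair), the five points embed in two dimensions with
essentially zero stress, and the two rating sessions — which share one
latent perceptual axis — correlate near unity. In the imaging half, the
cross-modal searchlight is above chance only in the region whose
pattern-to-intensity map is shared between modalities; the region with
unrelated per-modality patterns stays at chance, which is the central
dissociation of the analysis. Group-level inference over many such subjects
(`group_stack`, `signflip_null`, `cluster_table`) turns these maps into
corrected cluster tables, and `run_pipeline(default_config(), out_dir)`
drives the whole chain end to end, writing NIfTI maps, CSV matrices and a
seed-logging manifest.

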