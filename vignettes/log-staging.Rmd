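---
title: "Self-supervised T-staging with LoG filtering and information-bottleneck clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised T-staging with LoG filtering and information-bottleneck clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pathological T-staging of rectal cancer grades how deeply a tumor has
invaded the bowel wall, from T1 (submucosa) to T4 (adjacent organs).
The ground truth comes from biopsy after resection, so most MRI slices
in a clinical archive are unlabeled, while the imaging signal that
separates the stages — invasion depth and boundary texture — is subtle
and easily blurred by slice extraction and augmentation.  `logstage`
implements a pipeline that learns a four-way slice classifier from
unlabeled data: texture enhancement, convolutional features,
information-theoretic clustering, and pseudo-label training.

## Pipeline overview

1. **Slice extraction** (`load_volume()`, `volume_to_slices()`): 3D
   volumes are cut along the axial axis into 2D grayscale rasters.
   Registration and modality fusion are assumed done upstream; slices
   of any MRI modality are treated as independent samples.
2. **LoG enhancement** (`apply_log()`): each slice is filtered with a
   zero-sum Laplacian-of-Gaussian kernel, which suppresses flat
   intensity regions and strengthens boundaries.
3. **Features** (`build_model()`, `extract_features()`): a small CNN
   maps the central crop of each filtered slice to a feature vector.
4. **Clustering** (`sib_cluster()`): features are clustered into four
   groups by a sequential information bottleneck (sIB), maximizing
   `L = I(T;Y) - I(T;X) / lambda`.
5. **Pseudo-label training** (`fit()`): cluster assignments become
   training labels for a few epochs of SGD; steps 3–5 alternate.
6. **Evaluation** (`stage_metrics()`, `roc_curve()`, `kfold_split()`):
   one-vs-rest accuracy, sensitivity, specificity, balanced accuracy
   and AUC, with patient-grouped cross-validation splits.

## LoG filtering

The kernel samples the analytic Laplacian of an unnormalized Gaussian,

$$\mathrm{LoG}(x, y) = \frac{x^2 + y^2 - 2\sigma^2}{\sigma^4}
  \, e^{-(x^2+y^2)/2\sigma^2},$$

on an integer lattice of side $2\lceil 3\sigma\rceil + 1$ (the
conventional $3\sigma$ truncation).  The normalizing coefficient is
omitted, so the kernel value at the origin is $-2/\sigma^2$.  Two
numerical choices matter:

* **Zero-sum correction.**  The continuous LoG integrates to zero but
  its truncated sampling does not; the mean tap is subtracted (with a
  final compensation on the center tap) so that constant images are
  annihilated exactly.  Without this, flat anatomy acquires a spurious
  offset that propagates into every downstream feature.
* **Reflect padding.**  Responses keep the input shape and quarter-turn
  rotations commute with filtering, which stabilizes augmented views.

Edges appear as zero-crossings of the response;
`detect_zero_crossings()` keeps a crossing when the sign flip between
4-neighbors exceeds a strength threshold (default
$0.05\,\max|\mathrm{resp}|$; "strong" vs "weak" is not standardized, so
the fraction is exposed).  Corner-like, scale-stable points can be
scored with `shi_tomasi_score()` (minimum structure-tensor eigenvalue,
5×5 window) and edge-like responses rejected by the
principal-curvature ratio test $\mathrm{tr}^2/\det < (r+1)^2/r$ with
$r = 10$, the canonical default of that test.  The fixed four-level
pyramid (640×480 down to 80×60 by 2×2 averaging) supports multi-scale
use; classification itself trains on LoG-filtered intensity, with
keypoint maps available as optional extra inputs.

The staging preprocessing default is $\sigma = 1.6$ pixels: small
enough to keep thin-wall detail at 64×64, large enough to suppress
pixel noise.  The filtered response is standardized per slice (zero
mean, unit variance) so that the network sees a consistent scale.

## The bottleneck objective and draw-and-merge

Features are turned into a discrete joint distribution: negatives are
clipped, a floor of $10^{-8}$ is added (an all-zero row becomes
uniform rather than undefined), rows are normalized into conditionals
$p(y\mid x)$, and $p(x)$ is uniform.  The clustering objective is

$$\mathcal{L} = I(T; Y) - \lambda^{-1} I(T; X),$$

with $k = 4$ clusters and $\lambda = 100$: information about the
feature coordinates ($Y$) is preserved while the identity of the
individual image ($X$) is compressed.  With uniform $p(x)$ and hard
assignments, $I(T;X)$ reduces to the cluster-mass entropy $H(T)$, so
at $\lambda = 100$ the compression term is at most
$\log(4)/100 \approx 0.014$ nats — a ≤1% correction that breaks ties
without fighting the information term.

Optimization is sequential draw-and-merge: each point in turn is drawn
out as a singleton cluster and re-merged into the cluster with the
smallest *merger cost*, the objective decrease

$$\Delta\mathcal{L}(t) = (p(x) + p(t))\,
  \mathrm{JS}_{w}\!\left[p(y\mid x),\, p(y\mid t)\right]
  - \lambda^{-1} (p(x) + p(t))\, H(w),$$

where $w = (p(x), p(t))/(p(x)+p(t))$.  The compression part uses the
membership-indicator conditionals over $X$; because the drawn point
does not belong to the target cluster, their supports are disjoint and
the Jensen–Shannon divergence collapses to the weight entropy $H(w)$.
Both identities are verified in the test-suite against a from-scratch
objective-difference oracle to $10^{-9}$, which also settles the exact
weighting of the JS term.

Implementation rules that make the procedure well behaved:

* **Monotonicity.**  Re-merging into the argmin cannot lower the
  objective (merging back into the original cluster restores it), so
  the objective trace is non-decreasing; this is asserted on every
  fixture.
* **Stay on ties.**  If the original cluster is within `tol` of the
  minimum cost, the point stays.  Moving on exact ties can cycle
  forever without changing the objective; staying makes "a full pass
  with no reassignment" a reachable stopping state.  Among other
  clusters, ties go to the lowest index (deterministic given the seed).
* **Singleton protection.**  The sole member of a cluster is never
  drawn, so exactly `k` non-empty clusters survive — the cluster count
  never collapses.
* **Restarts.**  Each of 5 restarts (default) starts from a seeded
  random balanced partition and reshuffles the draw order each pass;
  the best objective wins.  On enumerable instances ($k^N \le 6561$)
  the returned objective beats at least 95% of all partitions.

One pass costs $O(N \, k \, D)$; with the desk-scale defaults
($N \le 500$, $D = 64$, $k = 4$) clustering is a negligible fraction
of the round time.

## The alternating loop

Each round clusters the *central crops* of the preprocessed images
(clean, deterministic views) and then trains on *augmented* views
(random crop, flips, right-angle rotations) for `epochs_per_round`
epochs — clean features for clustering, noisy views for gradient
steps.  Two choices deserve explanation:

* **Head reinitialization.**  Cluster indices are arbitrary from round
  to round, so the linear head is reinitialized at each round start
  while the backbone persists — the standard deep-clustering remedy
  for label permutation.  The backbone is trained continuously rather
  than from scratch, which preserves the features the clustering just
  exploited.
* **Optimizer.**  Plain SGD with momentum 0.9 and learning rate 0.003.
  The rate was chosen for stability of the *feature space*: the loop
  fails not by diverging loss but by feature collapse (dead ReLU units
  make all images map to one point, and clustering degenerates).  A
  trivial-solution guard warns whenever one cluster exceeds 70% of the
  samples.

Anonymous clusters are mapped onto stages with the exact Hungarian
assignment (all $k!$ permutations for $k \le 8$) on a labeled subset's
confusion matrix; without labels, clusters are reported as C1–C4.

## The synthetic phantom generator

`generate_phantoms()` emulates exactly the statistical structure the
pipeline is supposed to recover: each image is a ring (a simulated
bowel wall) whose **relative wall thickness** (0.20/0.35/0.52/0.72 of
the outer radius) and **outward boundary irregularity** (sinusoidal
amplitude 0.02/0.05/0.09/0.14) increase monotonically with stage —
a monotone invasion-depth gradient.  Images carry angular wall
texture, i.i.d. Gaussian noise (default sd 0.05 against a wall/lumen
contrast of ~0.65), a random rotation (drawn as the phase of the
angular structure) and ±10% scale jitter.  Class proportions default
to 18/27/35/20% with largest-remainder rounding, so small sets honor
them exactly.  At zero noise the classes are linearly separable in the
scale-invariant radial-profile feature space
(`radial_profile_features()`), giving an oracle classifier with
accuracy 1 — the baseline against which pipeline claims are judged.

What the phantoms deliberately do **not** model: anatomy around the
bowel, modality-specific physics, partial-volume effects, patient-level
correlation between slices, and fuzzy stage boundaries.  Passing the
phantom suite therefore shows that the machinery (filtering, features,
clustering, alternation, mapping, metrics) works as specified on data
with a clean monotone invasion signal; it does not certify clinical
accuracy.

## Problem sizes and test design

The suite runs entirely on synthetic data at sizes chosen so the whole
package is exercised in minutes on one CPU: merger-cost oracles on
$N \le 10$ with full enumeration; recovery fixtures with 200 points in
16 dimensions; end-to-end runs with 200 training and 100 held-out
phantoms, 5 rounds and 5 seeds.  `scripts/acceptance.R` re-runs the
main computation from scratch at the same sizes and writes the
resulting quantities as JSON.

## Known limitations

* The CNNs are deliberately small (tens of thousands of parameters);
  the architecture-robustness axis (`vgg_small`, `resnet_small`,
  `alex_small`) checks interface and behavior, not ImageNet-scale
  capacity.
* With all-identical inputs the information term vanishes and the
  compression term mildly prefers unbalanced clusters, so the training
  loss floor is the pseudo-label entropy rather than $\log 4$ exactly;
  the degenerate case is tested accordingly.
* DICOM support covers uncompressed explicit-VR little-endian
  grayscale slices only.
* `sensitivity`/`specificity` are computed image-level (one-vs-rest),
  the convention under which staging tables are reported; undefined
  ratios (zero denominators) are reported as `NA`, never silently 0.
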