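---
title: "Quantifying temporal dynamics of cells by video feature aggregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying temporal dynamics of cells by video feature aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Live-cell microscopy records two complementary kinds of cellular dynamics: the
deformation of the cell contour (elongation, protrusion, shape change) and the
streaming of cytoplasmic content (directed motion of intracellular cargo,
including the splitting, merging and disappearance of particles). Both carry
information about cell state — for instance, the activation level of
lymphocytes after an immune challenge. `cellvfa` turns a video of a single
tracked cell, plus its per-frame contour, into a fixed-length vector suitable
for classification, and provides the full evaluation protocol around it.

The package assumes segmentation and tracking have already been done: its
inputs are frames plus closed contours (one per frame). Cell segmentation and
video stabilization are deliberately out of scope — they are standard,
replaceable preprocessing, and the contour contract keeps the package
agnostic to how they were obtained.

## Frame-pair dynamic features

For each frame pair `(i, i + Delta)` (interval `Delta`, default 30 frames at
25 fps) three feature groups are computed and concatenated into
`F = {F_DCS, F_MDF, F_ACF}` of length `L + 2R`.

### Contour deformation (`F_DCS`)

Both contours are resampled to `n = 100` points at equal arc length with a
canonical start point. Each point gets a *shape context*: a log-polar
histogram (5 log-radius times 12 angle bins) of the positions of the other
points, with radii normalized by the mean pairwise distance, which makes the
description translation- and scale-invariant. Point pairs are matched by
minimizing the total chi-squared histogram cost with the Hungarian algorithm,
a regularized thin-plate spline (TPS) is fitted to the matched pairs, the
second contour is warped, and the process repeats. The shape-context distance
after each of the `L` iterations — the symmetric mean of minimal chi-squared
costs between the contexts of the reference contour and the warped one — is
recorded; the vector `(D_SC^1, ..., D_SC^L)` is the deformation feature.

Two numerical choices matter here:

* **TPS regularization.** With equal point counts the Hungarian match is a
  bijection, so an *exactly* interpolating TPS would place the warped contour
  onto the reference point-for-point and every distance would be identically
  zero. All iterations therefore use bending-energy regularization
  `lambda0 * (mean pairwise distance)^2` with `lambda0 = 1`, the standard
  choice in shape-context matching. Because the affine part of a TPS is never
  penalized, similarity transforms (translation, uniform scaling, and pure
  dilation between the contours) are still absorbed exactly, so the feature
  responds to genuine local deformation only.
* **Degeneracy tie-breaks.** Near-circular contours make many permutations
  cost-equal; a tiny order-preserving bias (`1e-8`, scaled by circular index
  distance) makes the matching deterministic and rigid in the degenerate
  case, and a perfect (zero-cost) match skips the warp entirely so identical
  contours yield an exactly zero feature. Histogram bin edges are snapped at
  nine decimals before flooring so that points lying numerically on a bin
  boundary bin identically at any image scale.

### Cytoplasmic streaming (`F_MDF`, `F_ACF`)

A dense SIFT image assigns every pixel a 128-dimensional descriptor (4x4
cells of 4x4 px, 8 orientation bins) with a *stabilized* l2 normalization,
`255 * v / (||v|| + 128)`: exact unit normalization would amplify
noise-dominated descriptors of flat regions to full scale, flooding the
matching term with spurious signal, while the stabilizer (half the 8-bit
intensity range) keeps low-contrast descriptors proportionally small. The
movement field `w = (u, v)` between the two SIFT images minimizes the
discrete energy

```
E(w) = sum_p min(||s1_p - s2_{p+w_p}||_1, t)
     + sum_p eta (|u_p| + |v_p|)
     + sum_{(p,q) neighbors} min(alpha |u_p - u_q|, d) + min(alpha |v_p - v_q|, d)
```

with truncated data and (per-component) smoothness terms. The truncations
and displacement weight follow common SIFT-flow practice for 0-255
descriptors (`eta = 0.005*255`, `t = d = 40*255`, search radius 2 per
level). The smoothness weight must be matched to the descriptor scale: with
the stabilized normalization, typical descriptor distances are smaller than
for unnormalized SIFT images, and the conventional weight over-smooths —
smoothly varying streaming fields collapse to zero. The default
`alpha = 0.25*255` was calibrated once by minimizing the mean endpoint
error of the estimated field against the generator's ground-truth streaming
fields on held-out seeds.

The optimizer is coarse-to-fine over descriptor pyramids (2x2 block
averaging, coarsest side at least 8 — averaging descriptors rather than
recomputing SIFT keeps the optimizer usable on directly supplied descriptor
grids). At each level it combines three move types, each of which can only
lower the energy:

1. a uniform-field scan at the coarsest level (a constant field has zero
   smoothness cost, so this is an exact search over global translations);
2. *fusion moves*: the current field is fused with uniform proposals around
   its dominant displacements, each binary fusion solved exactly by min-cut
   (the truncated-linear smoothness is a metric, so the binary subproblem is
   submodular). This lets coherent regions switch displacement jointly,
   which single-pixel updates cannot initiate;
3. red-black ICM sweeps for local polish, accepting strict improvements only
   (so identical inputs return the exactly-zero, globally optimal field).

The returned energy always equals an independent re-evaluation of `E` on the
returned field, and the per-sweep energy trace at the finest level is
non-increasing. The *appearance change field* is the per-pixel Euclidean
norm of `s1_p - s2_{p + w_p}` — the descriptor discrepancy between
*corresponding* points — capturing intensity/texture change (particle
splitting, merging, vanishing) that the movement field alone misses.

Both fields are summarized as orientation histograms over `R` equal sectors
of `[0, 2pi)` by flow angle: each pixel adds its flow magnitude (movement
histogram) or its descriptor discrepancy (appearance histogram) to its
sector. Zero-displacement pixels are skipped (their angle is undefined), and
histograms are restricted to the cell mask dilated by 2 px so background
contributes nothing. No frame-level normalization is applied — the encoding
stage handles scale.

Defaults: `R = 36` when the cytoplasm histograms are used alone; inside the
combined feature `L = R = 10`, keeping the frame-pair dimension at 30.

## Video-wide aggregation

A video yields a temporal sequence of frame-pair features. Three compact
encodings against a codebook learned from *training* sequences only:

* **Fisher vector** (default): diagonal-covariance GMM with `K` components
  (EM with seeded k-means initialization). Component variances are shrunk
  toward the global per-dimension variance with one pseudo-observation (a
  normal-inverse-gamma MAP update): with small codebooks a component easily
  captures a nearly constant feature dimension, and an unshrunk near-zero
  variance makes the Fisher standardization amplify that dimension's noise
  until it dominates the whole encoding. The EM trace reported is the
  penalized log-likelihood, which the MAP iterations make non-decreasing.
  Per component the posterior-weighted first- and second-order residuals
  are concatenated (`2 D K`), then signed-square-root and global l2
  normalization are applied.
* **VLAD-k**: residuals to the `k = 5` nearest of `K` k-means centers
  (`D K`), with per-word intra-l2, then SSR, then global l2 normalization.
* **H-VLAD**: first-, second- and third-order residuals per word against the
  training statistics of that word (`3 D K`), same normalization chain.
  Empty words contribute zero blocks; the skewness block is zero when a word
  holds two or fewer descriptors or has zero variance.

PCA pre-processing is supported (`d_prime`) but defaults to off: the
frame-pair dimension (30) is already small. Sequence order does not affect
these poolings; *temporal pyramid pooling* (TPP) restores coarse temporal
structure by encoding the whole sequence, its halves, and its thirds
(contiguous near-equal windows, earlier windows taking the remainder) and
concatenating the six encodings, with a final l2 normalization.

## Evaluation protocol

`run_experiment()` implements the reference protocol: random splits (default
30) with a fixed number of training videos per class (default 20), codebook
and optional PCA fitted on training frame-pair features only, a linear SVM
(libsvm via e1071) with the penalty selected by stratified fivefold
cross-validation on the training encodings over the grid `2^-5 ... 2^15`
(factor-4 steps), and macro precision / recall / F-score (one-vs-rest per
class, unweighted mean — the averaging convention is the package's choice)
reported as mean +/- sd over splits. `mAP` is the mean per-class accuracy.
The `score_overlap()` diagnostic histograms the SVM decision values of two
classes' training exemplars on a shared binning and reports the summed
bin-wise minimum — a direct view of how discriminative an encoding is;
following its original use it is computed without TPP.

## The synthetic generator

Real reference recordings of stimulated lymphocytes are not publicly
available, so the package ships a generator whose videos exercise every
stage: a star-shaped contour `r(theta, t) = R0 (1 + sum_m a_m(t)
cos(m theta + phi_m))` with smoothly varying mode amplitudes bounded by
`deform_amplitude`; Gaussian-blob particles inside the cell advected by a
smoothed random velocity field (Gaussian-filtered white noise, tapered to
zero at the contour) scaled to a mean interior speed `stream_speed`; and
split/merge/vanish appearance events at a per-particle rate. Optional dim
bystander blobs (emulating red blood cells in a lymphocyte field of view)
can be placed strictly outside the target contour, mirroring recordings in
which the target never overlaps its neighbours. Streaming pairs
are generated by backward warping, so the returned ground-truth field
reproduces frame 2 exactly up to events and noise. Class structure mirrors a
normal / slight / moderate / drastic activation ladder by grading
`deform_amplitude` and `stream_speed`; the grading values are the package's
own choice, since no quantitative class dynamics are published.

What the generator does *not* emulate: phase-contrast optics (halo,
shade-off), segmentation errors (contours are exact), cell translocation,
occlusion or multi-cell interaction, and 3-D streaming projected to 2-D.
Passing tests on synthetic data therefore demonstrate that the machinery
measures what it claims under known ground truth — not that classification
accuracy on any particular real dataset will match.

## Problem sizes used by the validation suite

The test and acceptance runs use desk-scale conditions chosen once: 64x64
frames, 24-frame clips, frame interval 4 (five non-overlapping pairs per
video), FV with `K = 8`, 5 random splits with 10 (two-class) or 8
(four-class) training videos per class, and 20 (two-class) or 12
(four-class) videos per class. The translation-recovery check uses 32x32
textures over 10 seeds with search radius 4.

## Known limitations

* Flow displacements are integer-valued; sub-pixel streaming below ~0.5
  px/frame at the chosen interval is quantized away (raising the interval is
  the intended remedy, as in the reference protocol).
* The deformation feature assumes simple closed contours; self-intersecting
  or fragmented cell outlines are rejected rather than repaired.
* The optimizer guarantees monotone energy descent and strong recovery on
  piecewise-uniform motion, not global optimality of the flow energy.
* With very small codebooks relative to feature diversity, VLAD/H-VLAD can
  produce all-zero encodings (every descriptor on a center); these are
  flagged (`zero_encoding` attribute) and left unnormalized.
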