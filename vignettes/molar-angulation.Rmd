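---
title: "Measuring molar angulation from segmentation masks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring molar angulation from segmentation masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molaraxis)
```

## The problem

The angulation of a mandibular third molar — the angle between its long
axis and a vertical reference — is the main radiographic predictor of
whether the tooth will erupt into function or stay impacted.  Third molars
angled beyond a critical value of 27.0° tend to increase their tilt over
time, so a single measurement on an end-of-treatment panoramic radiograph
carries real prognostic weight, and the clinically interesting calls
cluster in a narrow borderline band, [24.5°, 29.5°], around that
threshold.  Measuring the angle by hand is slow and observer-dependent;
`molaraxis` implements the automated alternative: given a per-tooth binary
segmentation mask, estimate the long axis by iterative regression on the
tooth contour, then classify eruption potential from the angle magnitude.

Segmentation itself (in a clinical deployment, a CNN) is out of scope:
the package consumes masks from label-map PNGs or LabelMe-style polygon
JSON and replaces the upstream model — and the private radiograph data it
requires — with a parametric molar phantom generator, so that every claim
the package makes about its measurement accuracy is checked against known
ground truth.

## Coordinate and angle conventions

All pixel coordinates are 0-based pixel centers, x rightward, y downward.
Angles are measured from the image-vertical axis; a **positive signed
angle means the occlusal (chewing) end of the tooth leans toward +x**.
Left-side molars (FDI 36–38) in the generator tilt positive, right-side
molars (46–48) negative; clinical outputs use the magnitude, which is how
molar angulations are conventionally reported.

## The orientation algorithm

Starting from a seed angle $\theta_0$, each of 10 iterations performs:

1. rotate the tooth contour by $-\theta_{k-1}$ about its centroid, so the
   current estimate becomes vertical;
2. censor the occlusal surface and the roots, keeping the fraction
   $[0.15, 0.55]$ of the contour's vertical extent — a section of crown
   and cervix whose mesial and distal walls run nearly parallel to the
   long axis;
3. split the retained points into left and right chains (row-wise extreme
   points) and fit each chain by least squares of $x$ on $y$ — the
   near-vertical geometry makes $x$-on-$y$ the well-conditioned choice;
4. correct the estimate: $\theta_k = \theta_{k-1} -
   \tfrac{1}{2}(\alpha_L + \alpha_R)$, where $\alpha = \arctan(dx/dy)$ is
   a side line's slope angle.

The sign in step 4 deserves a note: with y growing downward, a wall whose
*axis orientation* is $+\varphi$ (top toward +x) has slope
$dx/dy = -\tan\varphi$, so the mean slope angle must be subtracted to add
the mean line *orientation* to the estimate.  Averaging the two sides
cancels the first-order effect of symmetric crown taper, which is what
lets a section that includes some tapering crown still estimate the axis.

Numerical choices that matter:

* **Sub-pixel contours, resampled densely.**  The contour is traced once
  from the mask (largest connected component) and resampled at ~0.25 px
  spacing.  Without this, rotated integer-rounded rows frequently contain
  a point from only one side of the tooth, and the row-splitting rule
  (single-point rows feed both chains) then contaminates a chain with
  points from the opposite wall — a single such point can bias a side fit
  by several degrees.
* **Band-edge hygiene.**  Rows only partially covered by the censor band
  are dropped before side-splitting, for the same reason: a half-covered
  edge row can hold one wall but not the other.
* **Fixed 10 iterations, early stop disabled by default.**  On clean
  contours the update falls below 0.1° well before iteration 10 (the
  convergence tests assert this); the `converged` flag records it.  The
  pivot is the contour centroid; the resulting angle is pivot-invariant.

### Seeding

The seed comes from two reference points, the occlusal-surface midpoint
and the pulp-chamber floor: $\theta_0 = \operatorname{atan2}(x_{occ} -
x_{pulp},\; y_{pulp} - y_{occ})$.  In a clinical pipeline these are
predicted by the segmentation network; the phantom generator therefore
attaches the true pair to each generated tooth.  For masks that arrive
without landmarks, `estimate_landmarks()` provides a geometric fallback:
the centroid of the top 5% of occupied rows, and the centroid of the
35–45% height band.  This heuristic is deliberately simple and is *coarse*
— on tilted teeth its seed can be tens of degrees off, because the top
rows isolate an occlusal corner rather than the occlusal midpoint.  The
refinement loop tolerates this: its basin of attraction is wide, and the
end-to-end tests (which re-read masks from PNG and use only the heuristic)
recover angles across ±60° to within a fraction of a degree.  The
landmark-quality guarantee (seed within 5° of truth) holds for supplied
landmarks, not for the fallback heuristic on strongly tilted teeth.

## The phantom generator

`make_molar_polygon()` builds an upright molar silhouette from explicit
parts: a trapezoid crown (default 44 px wide, 18 px tall) over a
rectangular cervix (30 × 42 px) over 0–2 tapering root prongs (30 px).
The proportions were chosen so that the default censor band falls mostly
on the parallel cervix walls — the feature the algorithm exploits on real
teeth — while still containing some tapered crown, plus:

* `asymmetry` skews the mesial vs distal crown taper (±0.3 max), the main
  realistic source of measurement bias;
* `n_roots = 0` encodes a follicle without root formation (development
  stages A–D), `n_roots = 2` a bifurcated molar;
* vertex jitter (Gaussian, per vertex) and vertex dropout emulate
  imperfect segmentation boundaries.

`sample_scene()` draws a six-tooth mandibular scene on a 420 × 1220 px
canvas: per-position angle magnitudes come from normal models (M1
16.7 ± 5.2°, M2 19.4 ± 6.8°, M3 44.8 ± 11.2°, truncated to [0°, 90°)),
which reproduce the reported distribution of molar angulations on
panoramic radiographs; third molars get a random development stage
(15% A–D, 25% E, 60% F–H — end-of-orthodontic-treatment patients mostly
have root formation under way) that sets their root morphology.  Sizes
vary ±10% around the defaults.  Everything is driven by one integer seed;
the same seed reproduces bit-identical scenes.

What the phantoms do **not** emulate: radiographic texture, overlapping
neighboring anatomy (ramus, canal, second-molar contact), projection
distortion of the panoramic geometry, and CNN-specific segmentation error
modes.  Passing the recovery tests therefore demonstrates that the
*measurement algorithm* is correct and stable given reasonable masks — not
that any particular segmentation model is accurate.

## Validation suite

* **Segmentation metrics** (IoU = TP/(TP+FP+FN), precision, recall,
  pixel-wise; Hausdorff = the maximal Euclidean distance between boundary
  pixel sets).  The Hausdorff is symmetric by default (`directed = FALSE`
  exposes the one-sided variant); whether a published value is directed or
  symmetric is often unstated, and symmetric-boundary is the common
  convention.  Undefined ratios (empty masks) return `NaN` with a warning
  so batch evaluation continues.
* **Error-interval accuracy** at ±1°, ±2.5°, ±5° (inclusive bounds).
* **Bland–Altman**: differences oriented test − reference; limits of
  agreement at bias ± 1.96 × sample SD (n−1).
* **ICC**: two-way random effects, absolute agreement, single measurement
  — the standard inter-observer choice — with the McGraw–Wong F-based 95%
  CI.  Published clinical reports rarely state the exact ICC variant their
  statistics package used, so the model tag is carried on the result
  rather than asserted to match any external tool.

## Eruption classification

`classify_eruption()` calls a third molar *unfavorable* when its angle
magnitude strictly exceeds 27.0° ("greater than" — exactly 27.0° is
favorable), and flags angles in [24.5°, 29.5°] as borderline regardless of
verdict.  Because the clinical reference axis is itself debatable (image
vertical vs the second molar's axis), the table-level interface offers an
`absolute` mode (M3 magnitude as measured) and a `relative` mode (M3 minus
ipsilateral M2 signed angle); outputs are labeled with the mode used.
Development stage is user-supplied metadata (Demirjian letters, shortened
to no-roots / bifurcation / developed-roots); no image-based staging is
attempted.

## Problem sizes and what the checks show

The package's self-validation, mirrored in `scripts/acceptance.R` and the
test suite, uses: 200 single-molar phantoms (angles uniform ±60°,
asymmetry ±0.2) for recovery — noise-free bias is ~0.02° and RMSE ~0.4°,
and with 2 px vertex jitter RMSE stays below 3°; 20 six-tooth scenes
(120 teeth) for the end-to-end pipeline through PNG round-trips and
heuristic seeding, with ≥95% of teeth within ±2.5°; 100 random mask pairs
for exact agreement of the metrics with brute-force oracles; and n = 200
simulated rating tables for ICC parameter recovery.  These sizes keep the
full suite comfortably within a few minutes on a single CPU while leaving
Monte-Carlo error well below the tolerances being asserted.

## Known limitations

* Maxillary teeth and non-molar tooth classes are unsupported.
* The heuristic landmark fallback is unreliable as a *final* answer on
  strongly tilted teeth; it is only a seed, and supplied landmarks
  (JSON, or generator ground truth) are preferred when available.
* Censor-band defaults assume mandibular molar proportions; unusually
  short crowns or very long roots may need `band_top_frac` /
  `band_bottom_frac` adjustments.
* The strict ">" at exactly the critical angle is a convention; clinically
  such a case is borderline anyway and flagged as such.
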