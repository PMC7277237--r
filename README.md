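# molaraxis

Automated measurement of mandibular molar angulation from per-tooth
segmentation masks, for predicting third-molar eruption potential.

On an end-of-treatment panoramic radiograph, the angle between a third
molar's long axis and the vertical is the key predictor of whether the
tooth will erupt or impact: beyond a critical angle of **27.0°**, future
functional eruption becomes unlikely, and calls inside the borderline
interval **[24.5°, 29.5°]** deserve flagging.  `molaraxis` measures that
angle from a binary segmentation mask by an iterative contour-regression
algorithm and provides the full technical and clinical validation tooling
around it — plus a parametric molar-phantom generator so every accuracy
claim is testable against known ground truth without patient data.

## The algorithm

Starting from a landmark-seeded angle θ₀ (occlusal-surface midpoint and
pulp-chamber floor: θ₀ = atan2(x_occ − x_pulp, y_pulp − y_occ)), each of
10 iterations:

1. rotates the tooth contour upright by the current estimate θₖ₋₁;
2. censors the occlusal surface and roots, keeping the `[0.15, 0.55]`
   fraction of the vertical extent (a crown/cervix section whose mesial
   and distal walls run near-parallel to the long axis);
3. fits least-squares lines x = a + b·y to the left and right contour
   chains;
4. updates θₖ = θₖ₋₁ − ½(atan b_L + atan b_R), i.e. adds the mean
   *orientation* of the two side lines.

Averaging the two sides cancels symmetric crown taper; ten iterations
drive the per-iteration update below 0.1° on clean contours.

Also included, mirroring how such a tool is validated:

- **Segmentation metrics**: pixel-wise IoU = TP/(TP+FP+FN), precision,
  recall, and the (symmetric, boundary-based) Hausdorff distance in px.
- **Agreement statistics** for paired angle tables: accuracy within
  ±1°/±2.5°/±5°, Bland–Altman bias and limits of agreement
  (bias ± 1.96 SD), and ICC (two-way random, absolute agreement, single
  measurement, with 95% CI).
- **Eruption calls**: favorable/unfavorable against the 27.0° rule with
  borderline flagging and shortened Demirjian staging (A–D / E / F–H).
- **I/O**: label-map PNG (8-bit, index → FDI code) and LabelMe-style
  polygon JSON readers/writers, angle CSV tables.

## Worked example

```r
library(molaraxis)

sam <- sample_scene(7)            # six-tooth phantom scene, seeded
tab <- measure_scene(sam$scene)   # measure all teeth
merge(phantom_truth_table(sam)[, c("fdi", "true_angle_deg", "stage")],
      tab[, c("fdi", "angle_signed_deg", "converged")], by = "fdi")
#>   fdi true_angle_deg stage angle_signed_deg converged
#> 1  36       11.77414     H         11.81700      TRUE
#> 2  37       12.79942     H         12.40872      TRUE
#> 3  38       40.18232     G         40.28554      TRUE
#> 4  46      -28.59369     H        -28.67612      TRUE
#> 5  47      -11.26195     H        -11.11887      TRUE
#> 6  48      -37.02392     E        -36.70420      TRUE
```

Every measured angle lands within half a degree of the generator's ground
truth (signs follow the package convention: positive = occlusal end
toward image-right, so left- and right-side molars tilt with opposite
signs).  A single tooth exposes the full iteration trace:

```r
res <- refine_orientation(sam$scene$instances[[3]])   # FDI 48
res
#> <orientation_result: initial -35.47 deg -> final -36.70 deg
#>  (|angle| 36.70 deg) in 10 iteration(s), converged>
classify_eruption(res$final_magnitude_deg)$verdict
#> [1] "unfavorable"     # 36.7 deg > 27.0 deg critical angle
```

## Command line

A thin wrapper over the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "molaraxis.R", package = "molaraxis"))')
Rscript $CLI generate --scenes 3 --seed 7 --out scenes/
Rscript $CLI measure --input scenes/ --out angles.csv
Rscript $CLI eval-angles --ref scenes/ground_truth.csv --test angles.csv --out report
Rscript $CLI predict --angles angles.csv --out eruption.csv
```

Subcommands: `generate`, `measure`, `eval-seg`, `eval-angles`, `predict`.
Exit codes: 0 success, 1 I/O error, 2 usage error.  Batch failures are
collected per instance, not fatal.

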