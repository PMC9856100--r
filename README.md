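# renalseg

Joint kidney segmentation and registration for 2D dynamic
contrast-enhanced MR images (DCE-MRI), for image-analysis researchers and
pipeline builders who need an automatic, shape-aware alternative to
register-then-segment workflows.

Segmenting the kidney from every time point of a perfusion sequence is
the prerequisite step of renal-function CAD pipelines, and it is hard:
contrast changes the kidney's brightness across phases, noise is
substantial, and a shape model only helps if it is correctly aligned to
each image.  `renalseg` evolves a level-set contour under a single energy
that couples intensities, a statistical shape prior and the affine
alignment, so segmentation and registration are estimated together:

```
E(φ, A, T) = λ₁ Σ δ_ε(φ)|∇φ|
           + λ₂ [ Σ V_ε(φ) m_B P_B(X̂) + Σ (1 − V_ε(φ)) m_K P_K(X̂) ]
           + λ₃ Σ (V_ε(φ) − V_ε(φ_PK(X̂)))²
```

with `V_ε`/`δ_ε` the smeared Heaviside/Dirac kernels, `m_K`/`m_B` fuzzy
c-means memberships, `P_K`/`P_B` the prior's Bayesian label
probabilities, `φ_PK` the prior's signed-distance representation, and
`X̂ = R H S (X − c) + c + T` the affine map (rotation, shear, scale,
translation) into the prior's frame.  Each iteration evolves the contour
one step, re-estimates the clustering state, and descends the seven
affine parameters.  Defaults follow the reference setting
`(λ₁, λ₂, λ₃, ε, β, γ₁, γ₂, γ₃, γ₄, γ₅) =
(6, 6, 0.1, 1.5, 1, 0.8, 1e−14, 1e−10, 1e−10, 1e−9)`.

The package also ships the Bayesian shape-prior builder (no pixel ever
saturates at probability 0/1), accuracy metrics (Dice, IoU,
95th-percentile Hausdorff distance), a seeded bean-shaped phantom
generator so everything is testable without clinical data, and a small
command line.  See the methods vignette
(`vignettes/renalseg-methods.Rmd`) for the model, the numerical choices
and known limitations.

## Worked example

Build a prior from a synthetic cohort, segment a noisy phantom, score it:

```r
library(renalseg)

spec   <- phantomSpec(seed = 1L)                  # 256x256, noise sd 10
cohort <- generateTrainingCohort(30, spec)        # 30 aligned masks
prior  <- buildShapePrior(lapply(cohort, function(m) m * 1), beta = 1)
prior
#> ShapePriorModel: 256 x 256 grid, N = 30 masks, beta = 1
#>   P(kidney) in [0.03226, 0.9677]; prior shape area = 2840 px

mask <- generateKidneyMask(spec, seed = 42L)      # held-out phantom
img  <- generateDCEImage(mask, spec, seed = 42L)
res  <- segmentKidney(img, prior, segmentationConfig())
res
#> SegmentationResult: 256 x 256, 137 iterations (converged)
#>   kidney area = 3374 px (5.15% of image)
#>   energy: 215353 -> 2145.49
#> AffineParams (image -> prior frame)
#>   theta = 7.3815e-05 rad (0.004229 deg)
#>   scale = (1, 1)  shear = (-3.50545e-06, 3.87605e-06)
#>   translation = (6.37201e-07, -2.07851e-07) px

c(dice = diceCoefficient(segMask(res), mask),
  iou  = iouScore(segMask(res), mask),
  hd95 = hausdorff95(segMask(res), mask))
#>      dice       iou      hd95
#> 0.9788099 0.9584991 2.0000000
```

The prior's probabilities span `[1/31, 30/31]` — the Bayesian estimator's
bounds for a 30-mask cohort.  The energy falls four orders of magnitude
from the border initialization to convergence; Dice 0.979 and a 95%
boundary distance of 2 px against the ground-truth mask are typical for
aligned phantoms at noise sd 10.  The affine estimate stays at the
identity because image and prior are already aligned; for misaligned
images enable the phantom-scale registration mode,
`segmentationConfig(normalizeGradients = TRUE)`.

## Command line

```sh
Rscript inst/scripts/renalseg simulate    --out sim --n 5 --seed 1
Rscript inst/scripts/renalseg build-prior --masks sim/masks --out prior.rds
Rscript inst/scripts/renalseg segment     --image sim/image_001.png --prior prior.rds --out seg
Rscript inst/scripts/renalseg evaluate    --pred seg --truth sim/masks --out metrics.csv
```

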