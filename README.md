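# neuroSegReg

Tools for two problems in 2D brain MR image analysis:

1. **C-SVM tissue segmentation.** Brain MR slices contain white matter (WM),
   gray matter (GM) and cerebrospinal fluid (CSF) inside a skull/background
   envelope. A two-phase region model can separate brain from background but
   cannot produce multi-class labels, while a pixel classifier alone wastes
   effort on the background. neuroSegReg combines the two: a Chan-Vese
   active contour minimizing

   `f(C, g0, g1) = alpha*Length(C) + beta*Area(inside(C))
                  + gamma1*sum_inside (u - g0)^2 + gamma2*sum_outside (u - g1)^2`

   isolates brain tissue, then a Gaussian-kernel soft-margin SVM
   (`k(x, x') = exp(-||x - x'||^2 / (2 sigma^2))`, one-vs-one) labels each
   in-contour pixel as CSF/GM/WM from gray-level co-occurrence (GLCM)
   texture statistics — ASM, contrast, correlation, variance and entropy
   over 7x7 windows at orientations {0, 45, 90, 135} degrees — plus the
   windowed intensity mean.

2. **Rigid registration of brain functional time series.** Small head
   movements between frames are recovered per frame by normalized
   cross-correlation block matching on 4x4 sub-blocks with recursive
   similarity accumulation `B(k) = phi*B(k-1) + d(k)`, Adaboost-weighted
   match reliability, and a weighted orthogonal-Procrustes rigid fit
   (rotation + translation), plus a mode-seeking "fuzzy pixel" clustering
   diagnostic.

Everything is testable without external data: the package ships a seeded
synthetic brain-phantom generator (piecewise-constant tissues, smooth
multiplicative bias field, additive noise, rigid motion series with ground
truth) that emulates simulated T1 acquisitions with 2% noise and 30%
gray-level non-uniformity.

Intended users: image-analysis method developers and students who want a
compact, fully reproducible reference implementation of the
contour-plus-kernel-classifier segmentation pattern and of classical
block-matching rigid registration.

## Worked example

```r
library(neuroSegReg)

## a 96x96 phantom at the standard conditions: 2% noise, 30% non-uniformity
ph <- makeBrainPhantom(phantomSpec(seed = 7))
ph
#> LabeledImage 96 x 96
#>   labels: background=5049 csf=939 gm=1624 wm=1604
#>   intensity range: [-0.0136, 0.9929]

## C-SVM segmentation: Chan-Vese gate + texture SVM (sigma 0.5, C 1000,
## 1500 stratified training pixels), evaluated inside the true brain region
seg <- csvmSegment(intensity(ph), tissueLabels(ph), seed = 7)
overallAccuracy(tissueLabels(seg), tissueLabels(ph), tissueLabels(ph) != 0)
#> SegmentationMetrics: accuracy 0.9028
#>   Dice: 0=0.0000 1=0.8851 2=0.8894 3=0.9344
```

90.3% of brain pixels get the correct tissue label; per-class Dice overlaps
are 0.89 (CSF), 0.89 (GM) and 0.93 (WM). (Class 0 is background, which does
not occur inside the evaluation region.)

```r
## a 20-frame motion series (shifts <= 3 px, rotations <= 2 deg) and its
## recovery; frame 0 is the reference
base <- makeBrainPhantom(phantomSpec(noise_fraction = 0, seed = 7))
ser <- makeMotionSeries(base, n_frames = 20, max_shift_px = 3,
                        max_rot_deg = 2, seed = 11)
res <- registerTimeSeries(ser)
res$transforms[[2]]
#> RigidTransform2D: tx=-1.0802 ty=-3.2279 angle=0.3168 deg (center 47.5, 47.5)
truthTransforms(ser)[[2]]
#> RigidTransform2D: tx=-1.3365 ty=-2.9969 angle=0.0424 deg (center 47.5, 47.5)
mean(sapply(res$diagnostics[-1], function(d) d$tre))
#> [1] 0.1830103
```

The recovered transforms track the ground truth with a mean target
registration error of 0.18 px over a 5x5 probe grid.

## Command line

A thin CLI over the same functions is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "neurosegreg.R", package = "neuroSegReg"))')
Rscript $CLI phantom-gen --size 96x96 --noise 0.02 --bias 0.30 --seed 7 \
        --out phantom.nii --labels labels.png
Rscript $CLI segment --input phantom.nii --train-labels labels.png \
        --n-train 1500 --sigma 0.5 --c 1000 --seed 7 --out seg.png \
        --truth labels.png --report report.json
Rscript $CLI phantom-series --frames 20 --max-shift 3 --max-rot 2 --seed 11 \
        --out series.tif --truth truth.json
Rscript $CLI register --series series.tif --seed 11 --out aligned.tif \
        --transforms est.json --truth truth.json --report reg.json
```

Verbs: `phantom-gen`, `phantom-series`, `segment-cv`, `texture`, `segment`,
`register`, `evaluate`. Every seeded invocation is bit-reproducible. Formats:
NIfTI (`.nii`/`.nii.gz`, lossless doubles), multi-page TIFF (32-bit float),
PNG (8-bit), JSON transforms/reports, YAML config.

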