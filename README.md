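# dixonseg

Automated whole-breast segmentation and breast-density quantification from
fat-water (Dixon) decomposition breast MRI.

## Why

Breast density (BD) — the fibroglandular fraction of the breast — is a
validated breast-cancer risk factor and a surrogate endpoint in prevention
trials. MR-based BD is computed from the per-voxel **fat fraction**
`FF = 100·fat/(fat+water)` inside a whole-breast segmentation:

```
MagDensity = 100 − mean(FF over the breast mask)   [percent]
```

The segmentation is the weak link: automated segmenters historically fail
where the pectoral muscle "juts" into the breast, and segmentation noise
propagates directly into longitudinal density changes. `dixonseg` implements
two fully automated segmenters designed for reproducibility, the MagDensity
measure, and the test-retest statistics used to compare segmenters — plus a
seeded synthetic phantom world with analytically known ground truth that makes
the whole stack testable offline.

**Registration segmenter** (primary): preprocess (fat-water-sum → min-max
normalization → 2D Canny edge enhancement → Otsu → morphological body mask →
sigmoid fat/water combination `SI_C = 1/(1+exp((−SI_W−0.25)/SI_F))` →
midline split with left flip); rank a dictionary of (template image, expert
mask) pairs by normalized mutual information `NMI = (H(A)+H(B))/H(A,B)`;
non-rigidly register the 5 best templates (multi-resolution cubic B-spline
free-form deformation, Parzen-window NMI gradient ascent); warp their masks;
keep voxels present in **≥ 4 of 5** warped masks.

**3D U-Net segmenter** (miniature variant): dual-channel fat/water input,
[conv3³+ReLU+BN]×2 blocks, 2³ max-pool / transposed-conv levels with skip
concatenation, sigmoid head, probability threshold **0.35** + hole filling;
Adam with the published plateau schedule (LR ×0.33 after 50 stagnant epochs,
floor 1e-5, early stop at 200). Implemented in base R matrix algebra and
exercised at phantom scale.

**Statistics**: Δ₂₋₁ summaries, paired MSE, and the two-way single-measure
absolute-agreement ICC(A,1) with the McGraw–Wong F-based 95% CI; a
significance simulation showing how test-retest SD translates into
detectability of a 1% density change.

## Worked example

```r
library(dixonseg)

# a 64x64x48 bilateral phantom with 35% fibroglandular fraction, and a
# 15-template dictionary spanning random sizes, shapes, and densities
ph   <- make_phantom(phantom_spec(seed = 11, density_fraction = 0.35))
dict <- make_dictionary(15, phantom_spec(seed = 100))

res  <- segment_registration(ph$volume, dict)
pred <- pmin(res$right_mask$data + res$left_mask$data, 1)

dice_coefficient(pred, ph$truth$breast_mask_right$data +
                       ph$truth$breast_mask_left$data)
#> [1] 0.932

magdensity(fat_fraction(ph$volume),
           segmentation_mask(pred, spacing = c(2, 2, 2)))$magdensity
#> [1] 36.08        # generator truth: 35.00

res$report$right$template_ids
#> [1] "tpl011" "tpl003" "tpl009" "tpl008" "tpl002"
```

The predicted mask overlaps the ground-truth breast at Dice 0.93 and recovers
the constructed density within ~1 percentage point. The report lists the five
templates chosen by NMI (here 1.543 … 1.510) for each side.

Reproducibility statistics on paired measurements:

```r
p <- paired_measures(1:5, test   = c(20.1, 25.3, 31.2, 35.0, 40.8),
                          retest = c(20.6, 25.1, 30.8, 35.9, 40.2))
icc_a1(p)$icc
#> [1] 0.997        # 95% CI (0.976, 1.000)

power_simulation(n_per_group = 10, true_change = 1, sd = 1.42, reps = 2000,
                 seed = 1)
#> $p_analytic 0.1327   $power_mc 0.305
```

The analytic p of 0.13 at test-retest SD 1.42% reproduces the published
motivating example: tighter segmentation reproducibility (smaller SD) is what
moves a 1% density change into significance.

## Command line

```sh
Rscript inst/cli/dixonseg simulate-phantom --seed 3 --out ph/
Rscript inst/cli/dixonseg simulate-dict --n 15 --out dict/
Rscript inst/cli/dixonseg segment-reg --fat ph/fat.nii.gz --water ph/water.nii.gz \
        --dict dict/ --out-prefix out/case1
Rscript inst/cli/dixonseg density --fat ph/fat.nii.gz --water ph/water.nii.gz \
        --mask out/case1_right_mask.nii.gz --out out/density.json
Rscript inst/cli/dixonseg testretest --table pairs.csv --out stats.json
```

All volumes are single-file NIfTI-1 (`.nii`/`.nii.gz`; images float32, masks
uint8); a minimal reader/writer is built in. Every subcommand writes a
`run_log.json` (timestamp, version, config) beside its outputs.

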