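# fcmseg

Unsupervised lesion segmentation for single-channel medical images (MRI
slices and volumes) by **hard C-means (HCM)** and **fuzzy C-means (FCM)**
clustering of gray values, including a **gray-level-histogram-accelerated
FCM** that clusters the N gray levels weighted by frequency instead of
every pixel. The package is aimed at medical-image-analysis work where an
intensity-based clustering baseline, its validity indices, and its overlap
scores against ground truth need to be computed reproducibly — without a
training set.

## The method

The image is flattened to samples S = {s_1..s_x} (one gray value per
pixel) and partitioned into c clusters with centers w_i via the c × x
membership matrix U = [μ_ig], columns summing to 1:

* HCM minimizes J_HCM = Σ_i Σ_g μ_ig d_ig², μ_ig ∈ {0,1}
  (nearest-center assignment ↔ per-cluster means);
* FCM minimizes J_FCM = Σ_i Σ_g μ_ig^r d_ig² for a fuzzifier r > 1, with
  the standard alternating updates
  μ_ig = [Σ_k (d_ig/d_kg)^{2/(r−1)}]⁻¹ and
  w_i = Σ_g μ_ig^r s_g / Σ_g μ_ig^r;
* the histogram variant regroups the same objective by gray level g with
  frequency weights h(g) — J_H = Σ_g Σ_i μ_ig^r h(g) ‖g − w_i‖² — and is
  *exactly* equivalent to pixel-domain FCM on the quantized image at
  per-iteration cost O(Nc) instead of O(xc).

Fuzzy results are hardened by per-pixel argmax. Evaluation covers the
partition coefficient and partition entropy (crispness indices; for HCM a
soft relaxation at the fitted centers is reported, since a hard partition
trivially scores PC = 1), plus Dice, sensitivity and specificity against a
ground-truth lesion mask. A built-in phantom generator (nested ellipses:
background/organ/lesion, Gaussian plus exact-fraction impulse noise)
provides ground-truthed test images and powers an HCM-vs-FCM
noise-robustness benchmark. See `vignette source in vignettes/` for the
full model account.

## Worked example

```r
library(fcmseg)

ph  <- generate_phantom(phantom_spec(seed = 7, impulse_fraction = 0.02))
seg <- segment_image(ph$image, "fcm", fit_config(c = 3, fuzzifier = 2),
                     truth = ph$lesion)
seg
#> <segmentation: fcm > c = 3  iterations = 10
#>   centers:  29.5698, 120.0073, 211.7917
#>   PC = 0.9856031  PE = 0.0397335
#>   Dice =0.8634157 sensitivity =0.9912748 specificity =0.9900903 (lesion cluster 2)
```

The three centers recover the phantom's tissue means (30/120/200); the
lesion center is pulled to 211.8 by the 2% salt pixels at 255. PC near 1
and PE near 0 say the partition is almost crisp; Dice 0.86 against the
true lesion mask reflects the salt pixels mislabeled as lesion (there is
no spatial regularization, by design).

```r
bm <- run_benchmark(noise_fractions = c(0, 0.02, 0.05), seeds = 1:2)
summarize_benchmark(bm)[, c("algorithm", "noise", "dice_mean",
                            "partition_coefficient_mean", "iterations_mean")]
#>   algorithm noise dice_mean partition_coefficient_mean iterations_mean
#> 1       fcm  0.00    1.0000                     0.9898               5
#> 2       fcm  0.02    0.8621                     0.9856              10
#> 3       fcm  0.05    0.7103                     0.9791              15
#> 4       hcm  0.00    1.0000                     0.9899               1
#> 5       hcm  0.02    0.8621                     0.9853               1
#> 6       hcm  0.05    0.7103                     0.9794               1
```

Segmentation quality degrades smoothly with the corrupted-pixel fraction;
both algorithms segment the clean phantom perfectly.

## Command line

```sh
Rscript inst/cli/fcmseg.R segment --input slice.png --algorithm fcm \
    --clusters 3 --fuzzifier 2 --seed 1 --truth mask.png --output out/
Rscript inst/cli/fcmseg.R benchmark --noise 0,0.01,0.02,0.03,0.04,0.05 \
    --seeds 1,2,3 --output bench/
```

`segment` writes the hardened label map in the input's format plus a flat
JSON metrics record; `benchmark` writes per-record and mean±sd CSVs.
Formats: NIfTI-1 (`.nii`/`.nii.gz`), 8-bit PNG, 16-bit TIFF. A flat
`key = value` config file can supply any flag (`--config run.cfg`; explicit
flags win).

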