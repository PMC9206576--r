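---
title: "Fuzzy and hard C-means segmentation: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy and hard C-means segmentation: models, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcmseg)
```

## The segmentation model

`fcmseg` segments single-channel intensity images (MRI slices or volumes)
by clustering pixel gray values. The image is flattened to a sample set
$S = \{s_1, \dots, s_x\}$, one scalar feature per pixel, and partitioned
into $c$ clusters described by centers $w_1, \dots, w_c$ and a $c \times x$
membership (affiliation) matrix $U = [\mu_{ig}]$ whose columns sum to one.

**Hard C-means (HCM)** is the crisp special case ($\mu_{ig} \in \{0, 1\}$;
k-means on gray values). It minimizes the mean-square-error criterion

$$J_{\mathrm{HCM}}(U, W) = \sum_{i=1}^{c} \sum_{g=1}^{x} \mu_{ig}\,
d_{ig}^2, \qquad d_{ig} = \lVert s_g - w_i \rVert,$$

by alternating nearest-center assignment with per-cluster means.

**Fuzzy C-means (FCM)** relaxes memberships to $[0,1]$ and minimizes

$$J_{\mathrm{FCM}}(U, W) = \sum_{i=1}^{c} \sum_{g=1}^{x} \mu_{ig}^{\,r}\,
d_{ig}^2,$$

where the fuzzifier $r > 1$ controls how soft the partition is. The
alternating updates are the standard stationary-point conditions:

$$\mu_{ig} = \Bigl[\sum_{k=1}^{c} (d_{ig}/d_{kg})^{2/(r-1)}\Bigr]^{-1}
\quad (d_{kg} > 0\ \forall k), \qquad
w_i = \frac{\sum_g \mu_{ig}^{\,r} s_g}{\sum_g \mu_{ig}^{\,r}}.$$

When a sample coincides exactly with one or more centers, unit membership
is placed on the zero-distance center(s), split equally if several — the
standard reading of the two-branch membership rule. A fuzzy result is
converted to a crisp segmentation by *hardening*: per sample, the
maximal-membership cluster wins, ties to the lowest cluster index.

**Histogram acceleration.** Gray values are heavily duplicated in medical
images, so the pixel-domain iteration wastes work. With the image quantized
to $N$ levels and $h(g)$ the probability of level $g$, the objective can be
regrouped by level:

$$J_H(U, W) = \sum_{g=0}^{N-1} \sum_{i=1}^{c} \mu_{ig}^{\,r}\, h(g)\,
\lVert g - w_i \rVert^2, \qquad
w_i = \frac{\sum_g h(g)\, \mu_{ig}^{\,r}\, g}{\sum_g h(g)\,
\mu_{ig}^{\,r}}.$$

Because a pixel's membership depends only on its gray level, this is not an
approximation: `histogram_fcm_fit()` reproduces `fcm_fit()` on the quantized
image exactly (same initialization), at per-iteration cost $O(Nc)$ instead
of $O(xc)$. The test suite asserts that equivalence on random images, and
that the level-domain fit is invariant to pixel count at fixed histogram.
One deliberate correction is baked in: the level-domain objective is
sometimes written with an *unsquared* distance, which would be inconsistent
with the center update above; `fcmseg` uses the squared distance in both
objectives so the center update is the exact stationary point of the
objective it descends. `J_H` equals the pixel objective divided by the
pixel count, a harmless rescaling that leaves the minimizers unchanged.

## Evaluation metrics

*Cluster-validity indices.* The partition coefficient
$V_{pc} = \tfrac1x \sum_{i,g} \mu_{ig}^2 \in [1/c,\,1]$ and partition
entropy $V_{pe} = -\tfrac1x \sum_{i,g} \mu_{ig} \ln \mu_{ig} \in [0,\,\ln c]$
(with $0 \ln 0 = 0$) measure how crisp a fuzzy partition is; these are the
classical indices those names denote. A hard partition trivially scores
$V_{pc} = 1$, $V_{pe} = 0$, which makes the indices useless for comparing
HCM against FCM directly. `fcmseg` therefore also reports **soft HCM
validity**: the indices evaluated on the fuzzy-membership relaxation
(`soft_membership()`, $r = 2$) at the fitted HCM centers, i.e. how crisp the
data look *around those centers*. Benchmark tables use the soft values for
HCM; the trivial hard values remain available via `validity_report()`.

*Overlap metrics.* With $A$ the true lesion region, $C$ the predicted one,
and $B$, $D$ their complements:
$\mathrm{Dice} = |A \cap C| / \tfrac12(|A| + |C|)$,
$\mathrm{Sensitivity} = |A \cap C| / |A|$,
$\mathrm{Specificity} = |B \cap D| / |B|$.
Overlap is computed on hardened masks; in benchmarks the predicted lesion
cluster is the one with maximal Dice against the truth, while on real data
an explicit cluster index can be pinned instead.

## The synthetic phantom

No patient cohort ships with the package, so validation runs on a synthetic
phantom designed to exercise exactly the moving parts above: nested
ellipses — background, organ, and a lesion strictly inside the organ — the
minimal geometry echoing a cystic lesion on a pelvic slice. Defaults,
chosen once: $256 \times 256$ pixels, tissue means $30/120/200$ on a
$0$–$255$ scale (well separated but with overlapping noise tails), additive
Gaussian noise with $\sigma = 5$ as a modest continuous noise floor, and
impulse ("salt-and-pepper") corruption of an exact pixel fraction — the
benchmark's noise axis, swept over $0\%$–$5\%$ — half set to the range
minimum, half to the maximum. Images are rounded to integer gray levels
(8-bit-like), which also makes the $N = 256$ histogram path lossless on
phantoms. The truth label map is never touched by noise.

What the phantom does *not* emulate: Rician noise statistics, bias fields,
partial-volume edges, texture within tissues, or any acquisition physics.
Passing the phantom tests therefore demonstrates correctness of the
optimization and the metrics under controlled contamination — not clinical
segmentation quality on real MRI.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `c` | 3 (pipeline) | number of tissue classes; 3 matches the phantom's background/organ/lesion |
| `fuzzifier` r | 2.0 | the canonical FCM choice; the method is characterised for $r \in (1.1, 5)$ and values outside warn rather than error |
| `tol` | $10^{-5}$ | convergence threshold on the max absolute center change, in intensity units |
| `max_iter` | 300 | iteration cap; fits on the phantom converge in well under 50 cycles |
| `n_levels` N | 256 | histogram resolution; use 4096 for 12-bit MRI |
| `gaussian_sigma` | 5 | phantom noise floor (intensity units) |
| `impulse_fraction` | 0 | corrupted-pixel fraction; benchmark sweeps 0–0.05 |

## Numerical and design choices

* **Initialization.** `"quantile"` (default) places the $c$ starting
  centers at the $(i + 0.5)/c$ type-7 quantiles of the *distinct* observed
  intensities rather than of the raw pixel multiset. This was a deliberate
  choice after the multiset version proved fragile: when background
  occupies ~70% of a lesion image, several multiset quantiles fall into the
  background mode and the fit converges to a merged organ+lesion cluster.
  Support quantiles are invariant to tissue-volume imbalance, deterministic,
  and provably distinct whenever the input has at least $c$ distinct
  values. `"random"` (seeded) draws $c$ distinct observed values, e.g. for
  multi-start searches. Both the pixel- and histogram-domain fits use the
  same routine, so their initializations agree bit-for-bit.
* **Membership stability.** Each distance column is normalized by its
  minimum before exponentiation, so $(d/d_{\min})^{-1/(r-1)} \le 1$ cannot
  overflow even for $r$ close to 1.
* **Monotone descent.** The objective is recorded once per full
  membership+center cycle, where the two-block coordinate-descent argument
  guarantees a non-increasing trace; the tests assert it to $10^{-9}$
  relative tolerance on every fit they run.
* **Ties and degeneracies.** Equidistant HCM assignment goes to the lowest
  cluster index; hardening breaks ties the same way. An HCM cluster left
  empty is re-seeded at the sample farthest from its assigned center
  (keeping $c$ fixed; an empty cluster contributes nothing to the
  objective, so descent is preserved). Inputs with fewer than $c$ distinct
  values, and partitions with an all-zero cluster, raise errors rather than
  returning collapsed fits.
* **Iteration counts, not wall-clock.** The benchmark reports iteration
  counts as the hardware-independent effort measure.

## The noise benchmark

`run_benchmark()` sweeps the default phantom over impulse fractions
0–5% for several replicate seeds, runs HCM and FCM (optionally the
histogram variant), and tabulates one record per (algorithm, noise, seed):
soft-HCM/FCM validity indices, iteration counts, and overlap metrics
against the phantom truth. Two structural facts are worth knowing when
reading its output. First, hardening FCM memberships reduces to the
nearest-center rule, so FCM and HCM label maps — and hence Dice — can
coincide exactly on integer-valued images whenever no gray level falls
between their slightly different decision boundaries. Second, FCM's
$\mu^r$ weighting damps the pull of impulse outliers on its centers, which
is precisely where the two algorithms separate; the same damping leaves
salt pixels marginally farther from their nearest FCM center, so the
soft-index comparison between the two algorithms is a near-tie whose sign
can go either way as the corruption fraction grows. The test suite asserts
the directional comparisons on the default sweep and reports what it finds.

## Problem sizes used by the test suite

The suite validates at scales chosen to keep the full run comfortably
interactive while still exercising every code path: a thousand randomized
small fits for the column-sum invariant; one hundred $24 \times 24$ random
phantoms for monotone descent; exhaustive two-cluster enumeration on up to
8 samples against multi-start HCM; twenty random $64 \times 64$ images for
the histogram/pixel equivalence; and the full $256 \times 256$ default
phantom for parameter recovery and the noise benchmark.

## Known limitations

* Features are scalar gray values; no spatial regularization, so impulse
  noise necessarily produces isolated mislabeled pixels (a median filter or
  spatially-aware FCM variant would be the usual remedy, and both are out
  of scope here).
* Multichannel/multisequence inputs, kernelized variants and GPU execution
  are out of scope.
* The lesion/cluster correspondence on real data must be supplied or
  checked by the user; maximal-Dice matching needs a truth mask.
* FCM converges to a local optimum of a non-convex objective; the
  deterministic initializer makes runs reproducible, not globally optimal.
  Multi-start with `init = "random"` and varying seeds is the supported
  escape hatch.
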