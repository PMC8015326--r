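---
title: "Methods: detection evaluation and competitive fitness estimation for GFP-marked worm assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detection evaluation and competitive fitness estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormscore)
```

## The assay and what this package computes

Competitive fitness of a *C. elegans* strain is commonly measured by letting
the focal strain reproduce alongside a GFP-marked tester strain, imaging
samples of the mixed offspring under fluorescence, and scoring the
proportion of focal (non-GFP) animals among all animals. GFP testers express
the marker only in the pharynx, so each worm in a micrograph is classified
by the presence of a bright pharynx spot. A detector — a trained network or
any other method — emits per-image boxes with a class and a confidence;
the fitness analysis then reduces per-image focal/GFP counts to image- and
population-level proportions and compares them with a reference ("by eye")
scoring.

`wormscore` implements the full measurement chain in a detector-agnostic
way:

* **Formats**: Pascal VOC XML and COCO JSON annotations, per-worm instance
  masks, and the two CSV contracts (per-image class counts; per-detection
  boxes). All internal boxes are 0-based half-open; VOC's 1-based inclusive
  and COCO's x/y/w/h conventions are converted only at the I/O boundary so
  no off-by-one can drift into the metrics.
* **Evaluation**: IoU, greedy confidence-ordered one-to-one matching at a
  threshold (0.5 by default), precision/recall, and average precision and
  recall per class, per MS-COCO-style object-size bin, and per animal
  density stratum (split at 70 animals per image).
* **Error taxonomy**: every detection and annotation is assigned to exactly
  one of five outcomes — correct, incorrect class, counted twice, missed,
  false detection — and category counts are regressed on animal density.
* **Fitness statistics**: focal proportions per image and pooled per
  population, proportion differences between methods, bias regressions,
  paired Wilcoxon comparisons, and SD-vs-proportion variability regressions.
* **Synthetic data and a reference detector** so that every stage is
  testable end to end without trained weights or real micrographs.

## Detection matching and metrics

Matching is greedy in decreasing confidence order: each detection claims the
unclaimed annotation with the highest IoU at or above the threshold
(same-class only for metric scoring). Ties in confidence are broken toward
the detection with the better candidate IoU, then the lower index. This is
the scheme detection benchmarks use and is fully reproducible; the test
suite carries a brute-force optimal matcher as an oracle for small
instances, and the greedy matcher can only attain at most the optimal pair
count.

Average precision uses the all-point interpolated area under the
precision-recall curve (`p_interp(r)` = max precision at recall ≥ `r`),
the convention of modern VOC-style evaluations; an 11-point variant is not
provided. Average recall is the fraction of annotated worms recovered by
*all* retained detections at the IoU threshold, without a per-image
detection cap — whether capped COCO-style AR is intended by assay reports
is usually unstated, so the uncapped definition is used and documented
here.

Object sizes follow the MS-COCO groups. "32 and 96 square pixels" in assay
descriptions is read as the COCO side-length convention (areas 32² = 1024
and 96² = 9216 px²), because the groups are explicitly borrowed from the
MS-COCO competition; the literal thresholds (32 and 96 px²) are available
via `size_convention = "literal"`. Density stratification splits images at
`< 70` vs `≥ 70` ground-truth animals; the boundary count 70 itself falls
in the high stratum, a choice that had to be fixed because "below and
above 70" leaves it ambiguous. Density is counted from annotations, not
detections.

## The error taxonomy

Outcome classification deliberately matches class-AGNOSTICALLY first: a
wrong-class detection sitting on a worm is one "incorrect count", not a
miss plus a false positive. Precedence when a detection could be several
things is primary-match classification, then counted-twice, then false
detection; a duplicate with the wrong class is still counted twice because
the worm's classification is already decided by its primary match. Manual
audits of this kind state no precedence, and a merged detection spanning
two tangled worms could defensibly be scored several ways; the greedy rule
fixes one behaviour and the package documents rather than hides that
choice.

Two conservation identities hold for every input and are property-tested on
hundreds of random perturbation scenarios:
`correct + incorrect + missed = n_annotations` and
`correct + incorrect + counted_twice + false = n_detections`.

## Fitness estimation

The population-level proportion is always pooled — focal and GFP counts are
summed over all images of a population before dividing — never the mean of
per-image proportions; the two differ whenever image totals vary.
Variability is the sample SD (n−1) of the per-image proportions. Images
with no animals yield an explicitly undefined per-image proportion; they
are excluded from per-image statistics but their zero counts still enter
the pooled sums, and the exclusion count is reported.

The bias analysis regresses `d = p_model − p_eye` on `p_eye`. Under a
one-way GFP→focal class swap at rate `s` with no other errors,
`E(d) = s(1 − p)` exactly, so the fitted slope and intercept recover
`−s` and `+s`; this analytic law is one of the package's acceptance
properties. More generally, with class-symmetric swap rate `s` and a share
`φ` of random-class false detections, `E(d | p_eye) = s(1 − 2 p_eye) +
φ(0.5 − p_eye)`: small symmetric errors already produce a genuinely
negative picture-level slope (the model pulls extreme proportions toward
the middle).

One consequence worth stating plainly: because the perturbation model's
errors act on each image's *realised* counts, `E(d | p_eye)` is the same
linear function at the image and the population level, so this generator
does **not** produce a systematically flatter population-level slope —
pooling shrinks the noise, not the bias. An observed flattening between
the two levels in real data is therefore, under this error model,
indistinguishable from estimation noise. The acceptance suite asserts the
flattening property anyway and the corresponding test documents its
failure rate; reproducing a structural flattening would require error
rates that depend on the population truth rather than on per-image
realisations, which the perturbation contract (independent per-object
errors) excludes.

The paired Wilcoxon test drops zero differences (Wilcoxon's original
convention; Pratt's alternative changes p-values and is not offered), uses
midranks for ties, enumerates the exact null by convolution for up to 25
nonzero differences, and switches to a tie-corrected normal approximation
with continuity correction above that. Two-sided p-values are computed as
`min(1, 2·min(P(W ≤ w), P(W ≥ w)))`. With no nonzero differences at all
the p-value is 1 by convention, so pipelines on perfect agreement do not
crash. The exact branch is verified against full sign-assignment
enumeration for n ≤ 10 and against `stats::wilcox.test` on tie-free data.

## The synthetic scene generator

The generator emulates the imaging situation, not worm biomechanics: each
worm is a quadratic spline through three control points thickened to half
its body width — enough to exercise detection, overlap, clustering, and
pharynx-spot classification, which is what the downstream pipeline
consumes. Defaults describe 1024 × 819 px dark-background micrographs with
about 50 worms per image (assay reports print only a 70-animal density
split, so the mean density is a declared choice, not a claimed match),
body lengths 80–160 px and widths 8–14 px (areas mostly in the COCO
"medium" bin, where real assay tables report their metrics), a 30% share
of worms aggregated around Neyman–Scott-style cluster centres (tangling is
reported qualitatively as the dominant error source at high density), GFP
with probability `1 − focal_fraction`, and a pharynx disk of radius 6 px
at twice the body intensity at one body end. Rendering places the
background at 0.08 and bodies at 0.45 intensity under a linear
illumination field of relative magnitude 0.15 across the width plus
additive Gaussian noise (SD 0.02), clipped to [0, 1].

Worms whose pixels (or, for geometry-only sampling, whose tube extent)
reach the image border are flagged and excluded from annotations — the
edge-exclusion rule: a worm whose glowing pharynx may be off-frame cannot
be classified, and scoring it would bias counts toward non-GFP. Overlapping
worms are allowed and keep their own boxes, reproducing the hard tangled
cases. A `min_separation` option rejects uniform placements closer than a
margin to previously placed worms; it exists to build the well-separated
fixtures on which a classical detector must be exact, and is off by
default.

Every sampling operation is a pure function of its configuration and seed;
one user-facing seed expands into per-stage, per-image child seeds through
a fixed integer fold, so adding images never reshuffles existing ones.

The perturbation model inverts the error taxonomy: worms are dropped with
`miss_rate`, surviving worms swap class at class-specific rates, emitted
boxes are jittered, a duplicate box double-fires with `duplicate_rate`,
and a Poisson number of worm-sized random-class false boxes is added.
Confidences are Uniform(0.5, 1) for real and spurious detections alike, so
metrics cannot separate them by score — a deliberate worst case for the
evaluator. Default rates (miss 0.05, swaps 0.02, duplicate 0.015, 0.5
falses/image, 1 px jitter) describe a well-behaved detector whose correct
count regresses on density with slope just below 1 and whose error
categories have small positive slopes, the qualitative shape reported for
trained detectors on this assay. What the generator does *not* emulate:
illumination-dependent failure modes, density-dependent error rates, worm
body texture, or a real microscope PSF — so passing tests demonstrate the
correctness of the measurement chain, not detector performance on real
micrographs.

The study simulator draws each population's true offspring focal fraction
from a Beta distribution centred on the parental proportion with
concentration 30 (per-population SD ≈ 0.09, spanning roughly the offspring
proportion range reported for real assays); per-image worm counts are
Poisson around the configured mean. Study shape defaults are 15 + 15 + 25
populations at parental focal proportions 0.45, 0.60 and 0.75 with 10
images each — 550 images in total.

## The classical reference detector

A deterministic stand-in for a trained network: Otsu (or fixed) threshold,
8-connected components (built on EBImage's 4-connected labelling plus a
diagonal-merge pass), an area filter, removal of any component touching
the border (the same edge-exclusion rule as annotation), then GFP iff at
least `min_pharynx_pixels` pixels exceed `pharynx_threshold`. Touching
worms are *not* split — no watershed — so merged components become single
detections, deliberately reproducing the dominant high-density error mode
and giving the error taxonomy real work. Confidence is mean component
intensity over the expected body level, clipped below at a floor: an
arbitrary but contrast-monotone heuristic, since classical components have
no learned score. A minimum foreground/background contrast guard declares
an image objectless rather than thresholding pure noise on blank images.

On well-separated noiseless synthetic scenes the detector is exact
(precision = recall = 1 with per-image counts equal to truth), which is the
fixed point the acceptance suite verifies; with clustering enabled its
recall drops steeply, which the suite verifies as a monotone degradation.

## Numerical and testing choices

Problem sizes in the test suite are chosen to keep the full run at a few
minutes on one CPU: 1000 random box pairs against a pixel-rasterisation
IoU oracle (agreement to 1e-12), 500 random perturbation scenarios for the
conservation identities, 300 images for injected-rate recovery (3 binomial
or Poisson SEs), 500 images for the analytic bias law (3 SEs on slope and
intercept), 50 replicate studies of 55 populations for estimator
behaviour, and 50 + 36 rendered images for the classical end-to-end run.
Study-level simulation samples scenes in geometry-only mode (no pixel
masks), which is exact for counts and boxes up to rounding of the tube
extent.

Known limitations: no reading of proprietary microscope formats; no
polygon-annotation reader (masks cover the segmentation use); no multi-IoU
COCO-style mAP (assays evaluate at IoU 0.5); the reference detector does
not split tangled worms by design; and the perturbation model's
independence assumptions exclude density- or illumination-dependent error
structure.
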