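---
title: "Segmenting H&E tissue with a purple-pink colour transform: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting H&E tissue with a purple-pink colour transform: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HEtissue)
```

## The model

Haematoxylin stains nuclei blue-purple and eosin stains cytoplasm and stroma
pink, so H&E tissue pixels have both `R > G` and `B > G`. With channels
normalized to `[0, 1]`, the package computes

$$T = \mathrm{ReLU}(R - G) \odot \mathrm{ReLU}(B - G),$$

per pixel, where $\mathrm{ReLU}(x) = \max(x, 0)$ and $\odot$ is element-wise
multiplication. The representation has three exact algebraic properties that
the whole method rests on (all are enforced as tests):

* **Achromatic zeroing.** Any pixel with $R = G = B$ maps to exactly 0 —
  white glass, grey scanner blobs, black pen, dark bounding boxes.
* **Green-dominance zeroing.** Any pixel with $G \ge R$ or $G \ge B$ maps to
  exactly 0 — blue and green pens ($G \ge R$), red and orange pens
  ($G \ge B$).
* **Positivity on tissue.** Purple-pink pixels are strictly positive.

Consequently $T$ is bimodal: a large spike *exactly at zero* (background and
artefacts) and a positive tissue mode. A single Otsu threshold on $T$ then
separates them. A pixel is tissue iff $T$ is **strictly greater** than the
threshold; since the threshold is never below the first bin edge, the exact
zeros can never be labelled tissue, which is what makes the artefact
rejection unconditional for achromatic and green-dominant artefacts. The
deliberate limitation: pink pen has the same colour as eosin, is positive in
$T$, and is retained — the package reproduces this failure rather than
patching it, because it is a property of the representation.

The baseline for comparison is the conventional pipeline: Otsu on the
greyscale luminance, with tissue *below* the threshold (tissue is darker
than background). We adopt Rec. 601 weights ($0.299, 0.587, 0.114$), the
de-facto greyscale conversion in imaging libraries; nothing downstream is
sensitive to the small difference from Rec. 709.

## The Otsu solver

Otsu's criterion picks the histogram boundary maximizing the between-class
variance $\sigma_b^2 = w_0 w_1 (\mu_0 - \mu_1)^2$, equivalently minimizing
the within-class variance (the equivalence is asserted on random histograms
in the tests). Design choices, all recorded in the output report:

* **Bin count 256** by default. Otsu's criterion is classically stated on
  256 grey levels; $T$ is continuous, so a bin count must be chosen.
* **Histogram domain `[0, max(values)]`**, not `[0, 1]`. Realistic eosin
  colours give $T \approx 0.05$; unit-range bins would collapse all tissue
  into a few bins next to the zero spike. Binning to the observed maximum
  makes the solver scale-free (the affine-covariance test checks this).
* **Tie rule: midpoint of the maximizing run.** Flat maxima are not an edge
  case here — every empty bin in the valley between the zero spike and the
  tissue mode produces an exact tie — so ties are resolved by returning the
  midpoint of the contiguous maximizing range of boundaries (Otsu's
  averaging suggestion), which is deterministic and symmetric. Ties are
  detected at a relative tolerance of $10^{-10}$ to absorb
  last-ulp differences in the cumulative sums.
* **Degenerate histograms** (all mass in one bin, e.g. an all-white overview
  where $T \equiv 0$): no two-class split exists, so the segmenters return
  an all-`FALSE` mask and warn, never an arbitrary cut.
* **Class means use bin midpoints.** The solver maximizes the criterion *of
  the histogram*. The brute-force test oracle therefore evaluates the same
  discrete objective — every value represented at its bin midpoint — but
  exhaustively and naively (explicit per-class means at every boundary, no
  cumulative-sum recurrence), so the two implementations are independent
  while solving the same optimization and must agree exactly. An oracle
  computing class means from the raw values instead would optimize a
  slightly different objective whose argmax can shift by one bin on smooth
  data; we measured such one-bin disagreements on ~16% of uniform samples,
  which is expected behaviour of two different estimators, not an
  implementation defect.

All computation is in double precision; maps are stored as base R numeric
arrays (R has no single-precision type; at the 2048-px overview default the
memory cost is a few tens of MB at worst).

## The synthetic slide generator

The generator exists so that every pipeline property is testable with known
per-class ground truth (tissue, background, pen, box, scanner — five masks
that partition the raster; artefacts drawn over tissue claim their pixels).
It emulates the *colour structure* of a scanned H&E overview, which is the
only thing the method reads:

* **Background**: per-pixel achromatic grey with level $U(0.92, 0.99)$ —
  bright, slightly noisy glass.
* **Tissue colour model**: $R \sim U(0.75, 0.95)$, $G \sim U(0.45, 0.65)$,
  $B \sim U(G + 0.05, 0.85)$, plus per-pixel brightness jitter
  ($\sigma = 0.02$) added *equally to all three channels* and clipped to
  $[0, 1]$. Shared-channel jitter is the deliberate interpretation: additive
  noise that is independent per channel would violate $B > G$ for a few
  percent of draws near the narrow end of the $B - G$ gap, whereas
  brightness jitter preserves the channel ordering exactly under clipping,
  so every tissue sample provably has $T > 0$. The same construction makes
  blue/green/black/red/orange pen samples provably $T = 0$.
* **Within-slide colour coherence**: one base colour is drawn per slide and
  modulated by a smooth multiplicative brightness field (±10%, kernel width
  8% of the short side) plus the shared jitter. This mirrors real sections,
  where staining intensity varies smoothly but hue is consistent across a
  slide. It is load-bearing: filling tissue pixels i.i.d. from the colour
  model spreads $T$ over more than an order of magnitude
  ($\approx 0.005$–$0.2$), destroying the bimodality, and in a prototype
  Otsu then cut into the tissue mode (recall $\approx 0.6$). Real overviews
  are bimodal because stain hue is consistent; the generator reproduces
  that mechanism rather than the artefactual i.i.d. extreme.
* **Tissue shape**: irregular blobs — a random centre and radius
  (12–20% of the short side) modulated by Gaussian-smoothed noise (kernel
  width 5% of the short side). No nuclear or glandular texture; the method
  never looks at texture.
* **Pen strokes**: random 3-point polylines of configurable width, routed
  across the tissue by default (pens split tissue on real slides). Pink pen
  strokes reuse the slide's own tissue base colour, because the real-world
  failure mode is pen that matches the eosin on that slide. Orange pens are
  modelled with $B < G$; real orange inks could conceivably approach
  $B \approx G$, and this range is a modelling choice that guarantees their
  rejection is exercised through the $B - G$ factor.
* **Bounding box**: a 3-px dark grey frame inset from the border;
  **scanner artefacts**: dark grey irregular blobs or rows of small
  text-like rectangles. All achromatic.

What the generator does **not** emulate: chromatic aliasing at tissue
boundaries, scanner-specific colour casts, stain fading, coverslip edges,
tissue folds, and JPEG compression artefacts. Passing the synthetic suite
therefore demonstrates the colour-separation logic under the stated colour
model, not performance on any particular scanner's output.

Suites are reproducible: per-slide seeds are derived from a master seed, and
a slide is a pure function of its `SlideSpec`. Fixtures round-trip through
8-bit PNG; quantization is monotone, so it cannot move a pixel across the
$T = 0$ boundary (this is asserted in the tests).

## Evaluation

The qualitative success rubric — all tissue segmented, all background
rejected, all bounding boxes rejected, all artefacts rejected — is
operationalised quantitatively: a segmentation succeeds iff tissue recall
$\ge 0.95$ and each non-tissue class inclusion $\le 0.01$. Absolutes are not
attainable on rasters with soft edges, and a single-observer judgement is
replaced by these proxies deliberately; the thresholds are reported next to
every verdict and are arguments of `evaluateSlide()`. Dice against the truth
tissue mask is reported alongside. The standard comparison
(`compareMethods()`) runs both methods on a suite of 30 clean / 15 pen / 15
scanner+box slides of 256×256 px — small enough to evaluate in seconds on
one core, large enough that strokes, boxes and blobs are tens to thousands
of pixels each.

`cubeMembership()` enumerates an RGB lattice and applies the transform at
every point; the member set is exactly $\{(r,g,b): r > g, b > g\}$, with
closed-form count $\sum_{g=0}^{n-1}(n-1-g)^2$ at resolution $n$ — the test
suite checks the enumeration against both the closed form and a literal
triple loop.

## Interfaces and conventions

Coordinates are row-major, origin top-left; 1-based inside R, 0-based in
files. Masks are written as 8-bit single-channel PNGs (0/255); reports,
sidecars and manifests are JSON with a `schemaVersion` field. Overview
extraction reads flat PNG/JPEG/TIFF or multi-page pyramidal TIFF, picking
the smallest level at least as large as the requested overview size
(default 2048 px on the longer side — small enough for interactive use,
large enough to retain multi-pixel pen strokes) and downscaling bilinearly;
masks can be re-expanded to source resolution by nearest-neighbour
replication for patch pipelines. Alpha channels are composited over white
before use, matching scanner padding. The CLI exit contract is 0 success,
1 any per-file failure, 2 usage error; logs go to stderr, results to files.

## Known limitations

* The method is specific to stains that render tissue purple-pink; other
  stains need a different representation.
* Pink pen is indistinguishable from eosin by construction and is retained.
* Faint eosin at the resolution limit can fall under the threshold when a
  slide's $T$ mode is extremely narrow; no morphological cleanup is applied
  by default (an optional minimum-object-size filter exists but is off, as
  the core method uses none).
* The luminance baseline is implemented for comparison, not as a
  recommendation.
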