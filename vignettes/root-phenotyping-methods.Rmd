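---
title: "Methods: quantitative in situ root phenotyping from scanner image series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative in situ root phenotyping from scanner image series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rhizotrack analyzes time series of flatbed-scanner images of roots grown
against the transparent face of a soil-filled rhizotron. This vignette
explains the models and procedures behind each stage, the parameters that
matter, the design choices made where several designs were defensible, and
what the synthetic-data validation does and does not establish about real
images.

## Physical calibration

Every physical quantity derives from the scanner resolution: a pixel spans
`25.4 / dpi` mm. The package works at two resolution grades: a morphology
grade (1200 dpi in the field protocol) for root traits, growth dynamics and
root lifespan, and a hair grade (4800 dpi) on which individual root hairs
resolve. The hair threshold is configurable (`hair_dpi_threshold`, default
4800 dpi); hair quantification refuses to run below it rather than return
numbers dominated by resolution artifacts.

## Segmentation

Two segmenters produce the binary root mask.

The **classical baseline** flattens illumination by subtracting a
large-kernel local mean, keeps pixels brighter than the local mean by
`thr_offset` (default 0.12 on a 0–1 scale), applies morphological opening
(disc of 3 px) and drops components below `min_area_px` (default 20 px). It
is deterministic and fast, but by construction it can only find tissue that
is *brighter* than its surroundings: senescent (dark brown) roots and
bright mineral grains are its systematic failure modes.

The **trainable segmenter** is a small convolutional encoder–decoder. The
encoder stacks 3×3 convolution + ReLU + 2×2 average-pooling stages (default
widths 8 and 16, total downsampling ×4). At the bottleneck an atrous
spatial pyramid pooling (ASPP) block runs parallel 3×3 convolutions at
dilation rates 1, 2 and 4 and fuses them with a 1×1 convolution; the
parallel dilations give the bottleneck a multi-scale receptive field around
thin structures without extra downsampling. The decoder upsamples
exclusively by sub-pixel convolution (pixel shuffle): a 1×1 convolution
expands channels to `r² × C`, which are reshaped into an `r`-fold finer
grid. Sub-pixel upsampling is used at *every* decoder stage, so the product
of the upsampling factors equals the encoder's downsampling factor by
construction; compared with bilinear or transposed-convolution upsampling it
avoids interpolation blur exactly where thin-root continuity is decided.
The loss is mean pixel-wise binary cross-entropy plus a Dice term (weight
1 by default): cross-entropy supplies well-scaled per-pixel gradients,
while the Dice term counteracts the extreme background/foreground imbalance
of root images. Optimization is Adam at learning rate 0.01 for 10 epochs of
48 batches × 8 foreground-balanced 64-px patches, with flip and 90°
rotation augmentation only. One seed controls initialization, patch
sampling and augmentation, making training bit-reproducible. Higher
learning rates were observed to collapse the small network into an
all-background prediction (dead ReLUs), which is why the default is
conservative and the schedule relies on more steps rather than a hotter
optimizer.

Inference tiles frames larger than the training patch with 25% overlap and
stitches tile centres, which suppresses border artifacts of valid-region
convolution. Lowering the probability threshold can only grow the mask
(monotonicity), which the tests assert.

All convolution forward/backward kernels are implemented in C++ within the
package; the network is small enough that a desk-scale training run takes
on the order of two minutes on one CPU core.

## Skeleton-based morphology

Traits are measured on the medial axis of the mask:

* **Thinning** uses the Guo–Hall two-subiteration scheme. The more common
  Zhang–Suen scheme was implemented first and rejected after it was found
  to erode certain tapered diagonal ribbons to almost nothing — a failure
  mode a root-image tool cannot afford, since laterals are exactly such
  ribbons.
* **Local radius** at a skeleton node is the Euclidean distance transform
  minus half a pixel (pixel-centre-to-boundary distance): on a ribbon of
  width 5 px the centre row then reads radius 2.5 px, which is the value a
  continuous medial axis would give.
* **Edges** connect 8-neighbouring skeleton pixels with nominal weights 1
  and √2. Diagonal edges that shortcut an orthogonally connected corner are
  dropped so staircases are not double-counted.
* **Root length (RL)** is *not* the raw edge-weight sum: on oblique paths
  the {1, √2} weights over-count by up to ~8% (worst near 22.5°), and
  thinning adds staircase jitter. Instead each maximal degree-2 chain is
  resampled every 5 nodes and chord lengths are summed. This estimator is
  within ~1% of the true length at every orientation; the raw edge list is
  retained in the `skeleton_graph` for callers that want it.
* **Average diameter (AD)** is the mean node diameter (2 × radius);
  **surface area (RSA)** and **volume (RV)** treat each edge as a cylinder
  of the local mean radius, which follows tapering roots more faithfully
  than the global `π × AD × RL` approximation.
* **Root length density** is `RLD = RL / (A × DOF)` with `A` the observed
  frame area and `DOF` the depth of soil imaged against the panel
  (default 0.25 cm). RL and A are kept in cm and cm² throughout, giving
  RLD in cm/cm³.
* Spur branches shorter than `prune_len_mm` (default 0.5 mm) are pruned;
  when hairs must survive skeletonization the hair module uses no pruning
  and separates hairs by width instead.

## Growth dynamics

The net growth rate of root length density between consecutive
observations is `RLD_NGR = (RLD_n − RLD_{n−1}) / d`, with `d` the actual
elapsed days — daily imaging gives `d = 1`, but gaps are honoured rather
than assumed away. Negative values indicate net senescence. No smoothing is
applied to exported rates; the telescoping identity
`Σ NGR·d = RLD_last − RLD_first` therefore holds exactly and is asserted in
the tests. Individual roots are tracked by overlapping connected components
from one registered frame to the next (previous component dilated by a
margin defines the next search region); elongation and diameter-change
rates are finite differences of the tracked component's skeleton
measurements.

## Root hairs

At hair-grade resolution, hairs are thin skeleton branches rooted on the
much wider axis. Separation is by local width: nodes at least
`axis_min_width_mm` (0.08 mm) wide form the axis; branch components thinner
than `hair_max_width_mm` (0.04 mm) with path length inside a plausibility
band (0.05–1.5 mm) count as hairs. Because the medial axis grows a short
internal branch toward every hair attachment, the axis subgraph is pruned
of spurs shorter than ~1.3 local radii before its length is measured, and
all lengths use the chain-resampling estimator described above. Density is
reported per mm of axis skeleton — the field reports hair density in
varying units, so the denominator is documented rather than assumed
universal. A sampling helper reproduces the manual protocol of measuring a
handful (default 5) of randomly selected hairs alongside the full-population
mean.

## Lifespans and survival analysis

A root's lifespan is the number of days between its first appearance and
the day its appearance turns senescent; a hair's, between appearance and
distortion. Operationally:

* **Registration**: integer-pixel translation per frame maximizing the
  normalized cross-correlation with the first frame (scanner-fixed pots
  justify translation-only registration). Peaks below a confidence floor
  leave the frame unshifted with a warning.
* **Root senescence** is brightness-based: the median brightness of the
  subject's root pixels falls below `live_min_brightness` (default 0.6);
  the boundary value counts as live. This mirrors the visual criterion that
  live roots are white and senescent roots dark brown or black.
* **Hair distortion** is shape-based: tortuosity (skeleton path length /
  endpoint chord) above 1.5 counts as distorted ("twisted and bent"). A
  semicircle has tortuosity π/2 ≈ 1.571 and is therefore classified
  distorted at the default — a useful analytic anchor for the threshold.
* **Censoring**: subjects still alive at the last frame are right-censored
  there. How the original field protocol handled still-living roots at the
  end of its observation window is not stated in public descriptions;
  right-censoring at the last frame is this package's documented choice and
  is what the Kaplan–Meier machinery expects.

The **Kaplan–Meier estimator** `S(t) = Π (1 − d_i/n_i)` is implemented from
first principles (the `survival` package serves only as an independent
cross-check in the tests, where the two agree to 1e−12 on exhaustively
enumerated small samples). The median lifespan is the smallest event time
with `S(t) ≤ 0.5` (with a 1e−9 tolerance so a cumulative product equal to
one half within float error counts), and is undefined when the curve never
reaches 0.5. Group comparison reports the difference of medians and the
standard one-degree-of-freedom log-rank test.

## The synthetic rhizotron generator

Every quantitative claim in the test suite is scored against synthetic
scenes with exact ground truth. The generator grows a schematic taproot
system as piecewise-linear polylines: regularly spaced, strictly
side-alternating first-order laterals (phyllotaxis-like patterning),
Poisson second-order laterals, per-step heading jitter with a mild
gravitropic pull, and linear base-to-tip diameter tapers. A root emerging
on day `e` with rate `r` shows `min(r·(t − e + 1), full length)` mm on day
`t`, so total root length, per-root lengths and length-weighted mean
diameter all have closed forms. Laterals branch from the parent *surface*
(not centreline) and new roots steer to keep at least `min_clearance_mm`
(1 mm) from previously grown roots: both choices exist so that the rendered
mask and the closed-form truth describe the same object — crossings and
junction double-counting would otherwise put an irreducible bias between
oracle and measurement. The taproot persists through the horizon;
exponential lifespans (default mean 35 d at field scale) apply to laterals,
whose hairs carry their own exponential lifespans (default mean 25 d).

Rendering emulates a scanner's view: dark speckled soil (value-noise
texture plus occasional bright mineral grains — deliberate false-positive
bait for the classical thresholder), near-white live roots, smooth dark
senescent roots whose mean brightness stays between live tissue and soil,
per-day sensor noise, and hairs only at hair-grade dpi. Distorted hairs
curl into a sinusoid with tortuosity ≈ 1.9, safely above the 1.5 threshold.
One seed fixes soil, geometry and noise; renders are bit-reproducible.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: occlusion of roots by soil particles, root
decay textures ("folded epidermis"), water films and condensation on the
panel, illumination drift between scans, overlapping root mats in older
plants, and 3-D geometry projected into the soil slab. Results on real
rhizotron imagery depend on retraining the segmenter on real annotated
frames; the architecture and every downstream measurement are unchanged by
that substitution.

## Validation problem sizes

The test and acceptance runs use desk-scale versions of the study
conditions, chosen once: a 30 × 45 mm scanned window at 300 dpi over a
12-day horizon, taproot 3 mm/day, six first-order laterals at 2 mm/day,
lateral lifespans exponential with mean 6 d (so emergence, senescence and
censoring all occur within the horizon); hair scenes use an 8 × 8 mm window
at 4800 dpi with hairs at 3 per mm, lengths 0.2–0.9 mm. The segmenter
trains for 10 epochs on 20 frames from 10 scenes and is evaluated on 10
frames from 5 unseen scenes. Survival checks use n = 300 exponential
lifespans per replicate (medians averaged over 10 replicates, since a
single sample's median has ~8% sampling error) and 100 two-group
replicates at n = 200/group for log-rank power.

## Known limitations

* Root systems denser than the clearance assumption (heavily overlapping
  mats) break the one-component-per-root logic of tracking and event
  extraction; the package measures what is visible, as any 2-D method must.
* Hair length recovery degrades for hairs that grow against their parent
  root or cross a neighbour (partial occlusion); counts and density are
  robust well before lengths are.
* `AD` averages node diameters uniformly along the skeleton, so it is a
  length-weighted mean diameter, not an area-weighted one.
* The registration model is translation-only; rotating or flexing pots
  violate it and would need a richer transform.
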