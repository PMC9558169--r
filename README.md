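# rhizotrack

Quantitative *in situ* root phenotyping from rhizotron scanner image time
series.

Roots grown against the transparent face of a soil-filled rhizotron can be
imaged repeatedly and non-destructively with a flatbed scanner. Turning
those image series into numbers is the hard part: the soil background is
cluttered, roots are thin and fade from white to brown as they senesce, and
root hairs only resolve at very high resolution. rhizotrack is an R
toolkit for the full analysis chain:

* **Catalog & calibration** — per-pot daily series parsed from file names
  (`pot03_d014_1200dpi.png`), pixels converted to mm via `25.4 / dpi`.
* **Segmentation** — a deterministic threshold baseline, and a small
  trainable encoder–decoder with atrous spatial pyramid pooling (ASPP) and
  a sub-pixel convolution (pixel-shuffle) decoder, implemented from first
  principles with backpropagation and Adam in R/C++ inside the package.
* **Morphology** — skeleton-based total root length (RL, cm), average
  diameter (AD, mm), surface area (RSA, cm²), volume (RV, cm³), and root
  length density `RLD = RL / (A × DOF)` (cm/cm³), where `A` is the observed
  frame area and `DOF` the imaged soil depth (default 0.25 cm).
* **Dynamics** — net growth rate `RLD_NGR = (RLD_n − RLD_{n−1}) / d`
  (negative values mean net senescence), plus per-root elongation and
  diameter-change rates from component tracking.
* **Root hairs** — hair count, length and per-mm density from
  hair-resolution masks, separated from the axis by local skeleton width.
* **Lifespans** — emergence/senescence events across the registered series
  (roots brown by brightness, hairs distort by tortuosity), right-censored
  at the last frame, summarized by a from-scratch Kaplan–Meier estimator
  with median lifespans and log-rank group comparison.
* **Synthetic rhizotron generator** — seeded scenes with exact ground
  truth (polyline skeletons, diameters, hair annotations, emergence and
  senescence days) that back every quantitative claim in the test suite.

## Worked example

Grow a synthetic root system, render its daily frames, and measure traits
and growth dynamics against the known truth:

```r
library(rhizotrack)

params <- rsa_params(frame_width_mm = 30, frame_height_mm = 45,
                     horizon_days = 12, taproot_rate_mm_per_day = 3,
                     lateral1_rate_mm_per_day = 2, n_lateral1 = 6,
                     root_lifespan_mean_days = 6, hair_density_per_mm = 0,
                     sow_xy_mm = c(15, 4))
truth <- grow_root_system(params, seed = 42)
#> root_system_truth: 9 roots (1 taproot, 6 lateral1, 2 lateral2), horizon 12 d, seed 42

sim <- generate_series(truth, days = 1:12, render_config(dpi = 300, seed = 7))
traits <- traits_for_series(sim$series, sim$masks, prune_len_mm = 1)
round(head(traits, 4), 3)
#>   day RL_cm AD_mm RSA_cm2 RV_cm3 RLD_cm_per_cm3
#> 1   1 0.595 1.140   0.213  0.006          0.176
#> 2   2 1.115 1.025   0.355  0.009          0.330
#> 3   3 1.636 0.965   0.488  0.013          0.485
#> 4   4 2.426 0.866   0.650  0.016          0.719
```

Day 1 shows only the emerging taproot (hence the large mean diameter);
lateral emergence then drives RL up while AD falls. The measured RL at day
12 (12.46 cm here) sits within a few percent of the generator's closed-form
truth (12.29 cm). Net growth rate of root length density:

```r
dyn <- rld_ngr(traits)
round(tail(dyn, 3), 4)
#>    day RLD_cm_per_cm3 d RLD_NGR_cm_per_cm3_day
#> 10  10         2.9034 1                 0.3600
#> 11  11         3.3390 1                 0.4356
#> 12  12         3.6933 1                 0.3543
```

Lifespans of the generated roots, summarized by the product-limit curve:

```r
km <- kaplan_meier(truth_events(truth))
km
#> survival_curve: 3 event times, median lifespan 5 d
#>   time n_risk n_event n_censored  survival
#> 1    4      6       2          0 0.6666667
#> 2    5      4       1          0 0.5000000
#> 3    9      2       1          0 0.2500000
```

Half of the event-bearing roots had senesced by day 5; subjects still alive
at day 12 are right-censored. On real data the same calls run on masks from
`threshold_segment()` or a trained `predict_mask()`, with events extracted
by `extract_events()` over `align_series()`-registered frames.

## Command line

A thin CLI over the same functions lives at `exec/rhizotrack`:

```sh
Rscript exec/rhizotrack simulate --in data/sim --seed 4
Rscript exec/rhizotrack run --in data/sim --out results/run1 --seed 4
Rscript exec/rhizotrack run --in data/sim --out results/run2 --skip hairs,lifespan
```

`run` executes catalog → segment → traits → dynamics → [hairs] → lifespan
and writes CSV tables, PNG masks and a manifest (package version, config
hash, seeds) sufficient to reproduce the run byte-for-byte.

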