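---
title: "Quantifying metabolic glycan labeling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying metabolic glycan labeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoquant)
```

## The measurement problem

In metabolic oligosaccharide engineering (MOE), cells are fed an unnatural
monosaccharide (for example an azide-tagged ManNAc analog) that the sialic
acid pathway converts and installs on glycoconjugates. A click reaction
then attaches a detectable probe to the incorporated reporter. Three
readouts quantify how well a given analog is incorporated:

1. **Confocal imaging.** Sialylation happens in the Golgi, so the probe
   signal (fluorescent streptavidin bound to a clicked biotin probe) is
   partitioned into *in-Golgi* and *out-of-Golgi* pools using a Golgi
   marker (TGN46) channel. The statistic of interest is the integrated
   density (IntDen) of the reporter in each pool: the plain sum of raw grey
   values over the region, which at unit pixel calibration equals
   mean × area. A high in-Golgi IntDen relative to the negative control
   indicates efficient transfer of the modified sugar onto glycoconjugates;
   the out-of-Golgi pool tracks trafficking to the membrane and recycling
   compartments.
2. **Flow cytometry.** Cell-surface labeling is summarized as the mean
   fluorescence intensity (MFI) of the gated single-cell population, and
   reported relative to the negative control:
   relative MFI = MFI(analog) / MFI(control).
3. **Western blot densitometry.** Whole-lane biotin signal is normalized to
   the Ponceau-red total-protein stain and expressed relative to a
   designated reference lane:
   Rel. Int. = (biotin/Ponceau)~lane~ / (biotin/Ponceau)~reference~.

In every readout the **negative control** is the same biological object:
cells fed the *natural* sugar (ManNAc) and carried through the identical
click/staining protocol, so that any signal they show is nonspecific probe
binding. The imaging threshold, the unspecific MFI, and the "ns" baseline
of the significance tests all derive from it.

## The imaging pipeline

For each condition the stages are:

1. **Background threshold.** All reporter-channel pixels of the
   condition's negative-control images are pooled and a cutoff is taken,
   by default the 99.5th percentile (type-7 quantile); `mean + k·SD`
   (default k = 3) is available as an alternative. The percentile rule is
   robust to non-Gaussian background and has a direct self-consistency
   property: applied back to the controls it leaves at most 0.5 % of
   pixels foreground, which is below any plausible cell-size filter.
2. **Whole-cell ROIs.** The binary foreground is `reporter > cutoff` —
   cells are found on the *thresholded reporter channel*, not the nucleus
   channel, as the ImageJ-macro-style workflow this emulates does.
   The mask is cleaned by a morphological closing (disc of radius 2 px),
   hole filling (bright membrane rings therefore yield complete cell
   disks), removal of objects below 500 px, and 4-connected labeling.
   Optionally, touching cells are split by propagation from
   nucleus-channel Otsu seeds. Cells touching the border are kept by
   default (configurable).
3. **Golgi ROIs.** The TGN46 marker channel is thresholded *within* the
   cell ROIs, by default with Otsu's method computed on the in-cell
   histogram (an adaptive rule avoids introducing a second manual
   threshold); components below 20 px are discarded.
4. **Partition and measurement.** For each cell, `in_golgi` is the
   intersection of the cell ROI with the Golgi mask and `out_golgi` is the
   remainder, so area and IntDen are conserved *exactly*:
   IntDen(in) + IntDen(out) = IntDen(whole cell). Min/max/mean grey values
   and IntDen are measured on the **raw** reporter channel — the threshold
   only defines geometry. Thresholding the measured values as well would
   bias means and break conservation.
5. **Aggregation.** The image is the replication unit: per-cell IntDen is
   averaged within an image, then the condition mean and sample SD (n − 1)
   are taken over image-level values, with SD reported only when at least
   two images exist. Per-cell aggregation is also available, but
   image-level is what is reported.
6. **Significance.** Analog vs control image-level IntDen per region,
   unpaired two-tailed t-test (classical equal-variance Student by
   default, Welch by flag), with the star tiering
   `*** p ≤ 0.005, ** p ≤ 0.01, * p ≤ 0.05, ns otherwise` (boundaries
   inclusive). No multiple-testing correction is applied, matching the
   reporting convention this package reproduces.

Two reporting details are deliberate:

* A cell whose Golgi mask is empty keeps all three rows in the measurement
  table, the empty region carrying `area_px = 0`, `intden = 0` and NA
  min/max/mean, with the affected cells flagged. This keeps the
  table shape predictable and conservation exact.
* For significance testing, an image in which *no* cell passes the size
  filter contributes an image-level IntDen of 0 — absence of detectable
  signal, not missing data. Condition summaries, in contrast, report NA
  with a flag in that case rather than a silent zero, because a summary
  mean of zero would be indistinguishable from a measured zero. A null
  experiment (labeled images identical to controls) therefore ends in a
  degenerate zero-variance comparison, which is reported as `ns` with
  p = NA and an explanatory note.

## Fraction recovery as a validation statistic

`estimate_golgi_fraction()` background-corrects the two regional means
(`B = max(0, mean IntDen − background·mean area)`) and returns
`B_in / (B_in + B_out)`. It exists to close the validation loop against the
synthetic generator: when a known fraction of the reporter budget is
planted in the Golgi, the pipeline should return it. It is not a
biological quantity of the wet-lab assay, and it requires the background
rate per pixel to be known (in synthetic scenes it is; on real data it
would have to be estimated from the controls).

## The synthetic scene generator

Because no public imaging dataset accompanies the assay, validation rests
on a forward model with planted truth:

* **Geometry.** `n_cells` (default 6) elliptical cells with semi-major
  axes 25–40 px are placed without overlap (rejection sampling, failure
  after 1000 consecutive attempts) on a 512 × 512 field; each has a
  nucleus (radius fraction 0.4, slightly offset), a 2-px membrane annulus,
  and a perinuclear Golgi crescent hugging the nucleus sized to 5 % of the
  non-nuclear cell area. Golgi geometry is chosen for visual plausibility;
  quantification correctness does not depend on its shape.
* **Reporter forward model.** Each cell receives an expected reporter
  budget (default 5·10⁵ counts) split `f_golgi : membrane_frac :
  remainder` over Golgi, membrane and diffuse cytoplasm, uniformly within
  each compartment; the nucleus carries no reporter signal (streptavidin
  labeling of sialoglycoconjugates is secretory/membrane-bound). By
  construction the per-cell expected signal sums to the budget exactly,
  which is what makes planted-fraction recovery a sharp test.
* **Noise.** Observed pixels are Poisson draws of the expected rate plus
  additive Gaussian read noise (SD 2 counts), quantized to integer counts
  and clipped to [0, 65535] — the standard two-knob fluorescence detector
  model. Defaults (background 2 counts/px, nonspecific in-cell control
  level 4 counts/px) put the dimmest labeled compartment at a
  signal-to-noise ratio well above 5, the regime in which planted-fraction
  recovery is expected to be accurate to ±0.05.
* **Controls.** A control scene with the same seed reuses the *identical*
  geometry (the geometry is drawn before any pixel noise) and replaces the
  reporter expectation with the uniform nonspecific level inside cells.
* **Cytometry.** Event tables draw FSC/SSC from normal clusters
  (main population 5·10⁵ ± 5·10⁴ / 2·10⁵ ± 3·10⁴), fluorescence from a
  lognormal (meanlog log 500, sdlog 0.5) whose mean is scaled by the
  planted fold; debris sits near zero FSC and doublets at about twice the
  main cluster. Planted folds of 2–40 cover the range such experiments
  report.
* **Lanes.** Planted biotin/Ponceau ratios with mean-one multiplicative
  lognormal noise on the non-reference lanes, and varying Ponceau loadings
  so the normalization is actually exercised.

What the generator does **not** emulate — and what passing tests therefore
do not establish on real data: optical blur (no PSF convolution, so
segmentation boundaries are sharper than reality), z-structure, uneven
illumination, spectral bleed-through between channels, autofluorescence
gradients, cell shape irregularity beyond ellipses, and manual-gate
geometry in cytometry. Results on synthetic scenes validate the *computations*;
they do not certify segmentation accuracy on real micrographs.

## Numerical and design choices

* Grey values are never rescaled; 8/16-bit unsigned input is represented
  as doubles internally. Channels are stored one-per-page in TIFF, which
  round-trips 16-bit integers exactly. Multi-sample (RGB) pages and
  z-stacks are rejected rather than projected, since per-image
  quantification assumes a single plane.
* Percentile = type-7 quantile (R's default interpolation), stated once
  and used everywhere (thresholds, gates).
* Matrix indexing is 1-based (row, column), row-major in the R sense;
  masks always share the image shape.
* The FSC debris floor is the 2 % sample quantile *capped at half the
  median FSC*. An uncapped quantile floor trims ~2 % of a debris-free
  population on every application, so re-gating would never stabilize;
  with the cap, re-applying the gate removes well under 2 % more events.
  The robust z-score cut (|z| > 2.5 on FSC or SSC, median/MAD with
  SD-consistent scaling, z ≡ 0 when MAD = 0) removes doublets and
  outliers. The full rule is recorded in every `gate_result` for audit.
* MFI is the arithmetic mean, not geometric — "mean fluorescence
  intensity" with no log transform.
* The t-test defaults to the classical pooled-variance Student variant;
  "unpaired two-tailed t-test" without qualification is resolved toward
  the textbook default, with Welch one flag away and the variant echoed
  in all outputs.
* The control threshold could be pooled per condition or re-derived per
  image; this implementation pools per condition, which is more stable
  with few control images. Likewise it measures per-cell ROIs (with a
  single merged ROI conceptually available through summing, since IntDen
  is additive over disjoint regions).
* FCS binary parsing is out of scope; event tables enter as CSV with
  instrument-style column names (`FSC-A`, `SSC-A`, `FL1-A`/`FL2-A`).
  Band/lane extraction from gel scans is likewise out of scope — lane
  densities enter as numbers; the defined computation is the
  normalization.

## Problem sizes used by the test-suite

Unit tests run single-module checks on 256 × 256 scenes with 3 cells to
stay quick; the validation suite uses the default 512 × 512, 6-cell
conditions: 20 scenes for conservation, 20 seeds per planted fraction
f ∈ {0.1, 0.3, 0.6, 0.9} (with `membrane_frac = min(0.2, (1 − f)/2)` so the
compartment shares stay feasible at high f), 10 seeds per planted MFI fold
∈ {2, 3, 10, 40} at 10⁴ events, and 10⁴ replicates for the empirical size
of the t-test. `scripts/acceptance.R` recomputes the same quantities from
scratch at 10 seeds per condition.

## A worked example

```{r example, eval = FALSE}
library(glycoquant)

# a labeled scene with 60% of the reporter planted in the Golgi,
# and its matched negative control (identical geometry)
p   <- scene_params(f_golgi = 0.6, seed = 5)
sc  <- generate_scene(p)
ctl <- generate_control_scene(p)

thr   <- derive_background_threshold(list(ctl$field))
cells <- segment_cells(sc$field, thr)
golgi <- segment_golgi(sc$field, cells)
tab   <- quantify_field(sc$field, partition_all_cells(cells, golgi))
su    <- summarize_condition(list(list(meta = sc$field$meta, table = tab)))

estimate_golgi_fraction(su[su$region == "in_golgi", ],
                        su[su$region == "out_golgi", ],
                        background_per_px = p$background_level)
#> [1] 0.5992489
```

## Known limitations

* Segmentation is intensity-threshold based; heavily confluent cultures
  or dim, spatially varying labeling would need seeded splitting at least
  (`use_nuclei_seeds = TRUE`) and possibly a different segmentation
  front-end. The module boundaries allow swapping one in.
* The automatic FSC/SSC gate is a reproducible *stand-in* for a manual
  dot-plot gate, not a reconstruction of any particular operator's gate;
  no attempt is made to reproduce instrument-specific raw MFI values.
* `sd_intden` follows the "at least two images" replication convention;
  with exactly two images the SD estimate is itself very noisy, and the
  t-tests inherit that (correctly) through their degrees of freedom.
* Colocalization coefficients (Pearson/Manders) are intentionally absent:
  the partition statistic answers a different, budget-accounting question.
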