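# glycoquant

Reproducible quantification for metabolic oligosaccharide engineering
(MOE) experiments, in which cells are fed unnatural monosaccharide analogs
(azide- or alkyne-tagged ManNAc or sialic acid) and the incorporated
reporter is revealed by click chemistry. The package reimplements, as
tested R functions, the three quantitative readouts such studies rely on:

1. **Confocal in/out-of-Golgi partitioning.** A background threshold is
   derived from the reporter channel of negative-control images (cells fed
   the natural sugar, so any streptavidin signal is nonspecific binding):
   by default the 99.5th percentile of the pooled control pixels. Cells
   are segmented on the thresholded reporter channel, Golgi ROIs come from
   the TGN46 marker channel (Otsu within cells), and each cell is split
   into `in_golgi` / `out_golgi` regions. The reported statistic is the
   integrated density, IntDen = Σ grey values (= mean × area at unit pixel
   calibration), measured on the **raw** channel so that
   IntDen(in) + IntDen(out) = IntDen(whole cell) exactly. Aggregation
   treats the image as the replication unit (mean over cells per image,
   then mean ± SD over images).
2. **Flow-cytometry relative MFI.** Events are gated on FSC/SSC (quantile
   debris floor + robust median/MAD outlier cut, the rule recorded for
   audit), the mean fluorescence intensity is the arithmetic mean of the
   gated events, and conditions are reported as
   relative MFI = MFI(analog) / MFI(ManNAc control).
3. **Blot densitometry.** Relative lane intensity
   Rel. Int. = (biotin/Ponceau)_lane ÷ (biotin/Ponceau)_reference, with
   the reference lane exactly 1.

Significance uses the unpaired two-tailed t-test (Student by default,
Welch by flag) with the star tiering `*** p ≤ 0.005`, `** p ≤ 0.01`,
`* p ≤ 0.05`, `ns` otherwise.

Because no public imaging dataset accompanies this assay family, the
package ships a ground-truthed synthetic generator: three-channel
fluorescence fields (nuclei / Golgi marker / reporter) with a planted
in-Golgi fraction of the reporter budget and Poisson + read-noise pixel
statistics, matched negative-control fields with identical geometry,
cytometry event tables with planted fold-changes plus debris/doublets, and
lane tables with planted ratios. Every pipeline stage is validated by
recovering what was planted. See the vignette
(`vignettes/quantifying-glyco-labeling.Rmd`) for the full model and design
rationale.

## Worked example

Generate a labeled scene with 60 % of the reporter budget planted in the
Golgi, quantify it against its matched negative control, and recover the
planted fraction:

```r
library(glycoquant)

p   <- scene_params(f_golgi = 0.6, seed = 5)
sc  <- generate_scene(p)
ctl <- generate_control_scene(p)          # same geometry, nonspecific signal

thr <- derive_background_threshold(list(ctl$field))
#> <threshold_model> condition synthetic: cutoff 9 (percentile 99.5, 262144 control px)
cells <- segment_cells(sc$field, thr)
#> <cell_label_map> 6 cell(s), min area 500 px
golgi <- segment_golgi(sc$field, cells)
tab   <- quantify_field(sc$field, partition_all_cells(cells, golgi))
su    <- summarize_condition(list(list(meta = sc$field$meta, table = tab)))
su
#>   condition_id    region mean_intden sd_intden n_images n_cells mean_area_px
#> 1    synthetic  in_golgi      299695        NA        1       6       117.00
#> 2    synthetic out_golgi      205718        NA        1       6      2725.83

estimate_golgi_fraction(su[su$region == "in_golgi", ],
                        su[su$region == "out_golgi", ],
                        background_per_px = p$background_level)
#> [1] 0.5992489      # planted: 0.6
```

The mean in-Golgi IntDen (299 695) is the average, over cells, of the
summed raw reporter counts inside the Golgi mask; after subtracting the
expected background (2 counts/px × mean area) the in-Golgi share of the
signal is 0.599 — the planted 0.6 to three decimals.

The cytometry and blot paths work the same way:

```r
a <- generate_event_table(n_main = 1e4, n_debris = 500, n_doublets = 500,
                          fold_over_control = 10, seed = 33)
b <- generate_event_table(n_main = 1e4, n_debris = 500, n_doublets = 500,
                          fold_over_control = 1, is_control = TRUE, seed = 34)
ga <- gate_events(a)
#> <gate_result> kept 9881 / 11000 events (89.8%)
relative_mfi(mean_fluorescence(a, ga),
             mean_fluorescence(b, gate_events(b)))
#> [1] 10.0165       # planted fold: 10

round(relative_lane_intensity(
  generate_lane_table(c(1, 0.5, 1.6, 0.8), noise_cv = 0.05, seed = 9)), 3)
#> lane1 lane2 lane3 lane4
#> 1.000 0.481 1.534 0.793

t_test_two_sample(c(2.1, 2.5, 2.9), c(3.9, 4.4, 4.1))
#> <test_result> student t = -5.986, df = 4, p = 0.003915 [***]
```

End-to-end runs are driven by a YAML config (`read_run_config()`,
`run_all()`); `simulate_experiment()` writes a complete demo experiment
with a ready-to-run config, and `inst/cli/glycoquant.R` exposes the stages
as shell subcommands (`simulate`, `quantify-images`, `quantify-flow`,
`densitometry`, `stats`, `run-all`). Outputs are a pure function of config
and seed — reruns are byte-identical.

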