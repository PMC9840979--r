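# strifr

Struggle-response analysis for restrained-fly video.

A fly glued by its thorax to a slide keeps trying to escape: bursts of
flailing alternate with bouts of complete immobility. The balance of
those two states — and how interventions such as optogenetic activation
of serotonergic neurons shift it — is a compact behavioral readout of
action versus behavioral arrest. `strifr` computes that readout from
multi-fly video and wraps it in estimation statistics:

* **detection** — Otsu thresholding, morphological cleaning, connected
  components and size filtering locate each fly in the first frame; a
  fixed square ROI is assigned per fly and joined to arena metadata by
  raster position;
* **motion** — per-fly activity traces as the mean absolute pixel
  difference between consecutive frames within the ROI, denoised with a
  temporal median filter and a minimum-difference noise floor estimated
  from the background *at ROI pixel count*; optogenetic light onset
  detected from background RGB jumps;
* **ethogram** — activity/immobility segmentation under the five-second
  immobility rule (quiescence shorter than 5 s is not immobility);
* **metrics** — total activity and inactivity, epoch counts and mean
  durations, the activity:inactivity ratio
  `R = T_active / T_inactive` (the primary statistic), and the
  struggle speed (mean |I_t − I_{t−2}| over active epochs);
* **estimation** — Glass Δ = (m_e − m_c)/s_c, Cohen's
  d = (m_e − m_c)/s_pooled (paired: mean difference over the SD of the
  pair differences), BCa bootstrap 95% CIs, two-sided permutation
  t-tests with automatic exact enumeration, magnitude bands at
  0.2/0.5/0.8, effect-size matrices across interventions, delta
  regressions with adjusted R², and analytic power via the noncentral
  t distribution;
* **synthetic videos** — programmed alternating behavior rendered as
  jittering disks with optional flash and salt-and-pepper noise, plus
  ground-truth JSON, so the whole pipeline is testable end to end.

Inputs are numbered PNG frame directories or in-memory frame objects,
an arena metadata CSV, and (for the walking paradigm) centroid
trajectory CSVs in calibrated millimetres.

## Worked example

Simulate one six-fly, five-minute assay with 1% pixel noise, run the
pipeline, and look at one fly's metrics:

```r
library(strifr)

programs <- lapply(1:6, function(i)
  sample_program(duration = 300, mean_active = 20, mean_inactive = 10,
                 amplitude = 3, seed = 100 + i, fly_id = i))
spec <- render_spec(frame_size = c(120, 160), fps = 30, n_flies = 6,
                    noise_fraction = 0.01, seed = 7)
video <- render_video(programs, spec)

cfg <- strif_config(fps = 30, n_expected_flies = 6, seed = 1)
run <- run_strif(video$frames, metadata = NULL, cfg)
run$metrics[, c("position", "total_active", "total_inactive", "ratio",
                "n_active_epochs", "strif_speed")]
```

```
  position total_active total_inactive    ratio n_active_epochs strif_speed
1        1     196.5000      103.50000 1.898551               8    27.14455
2        2     162.3333      137.66667 1.179177               9    27.18202
3        3     249.2667       50.73333 4.913272               6    27.67559
4        4     208.0000       92.00000 2.260870               6    27.85772
5        5     212.4667       87.53333 2.427266               8    27.09296
6        6     211.6667       88.33333 2.396226               7    26.93930
```

Each row is one fly over the 300-s assay: fly 3 struggled for 249 s
and was immobile for 51 s (ratio 4.9); fly 2 split its time much more
evenly (ratio 1.2). `strif_speed` is the mean alternating-frame pixel
difference during active epochs (intensity/pixel), a proxy for
flailing vigour. Against the programmed ground truth, every interior
epoch boundary is recovered within a second and state totals agree to
0.13 s:

```r
truth <- program_to_ethogram(programs[[3]])
compare_to_truth(run$ethograms[[3]], truth, tol = 1)
#> $n_boundaries: 10   $n_matched: 10   $state_sequence_equal: TRUE
#> $active_time_error: 0.000429
```

A contrast between two groups of ratios returns the full estimation
bundle:

```r
set.seed(2); ctrl <- rnorm(45, 1.8, 0.6); trt <- rnorm(45, 1.3, 0.6)
effect_contrast(trt, ctrl, label = "Trh>Chrimson:ratio", seed = 1)
#> <effect_result> Trh>Chrimson:ratio
#>   n = 45 vs 45; mean diff = -0.6074 [95CI -0.8882, -0.3155]
#>   Glass delta = -0.889, Cohen's d = -0.885 (large), p_perm = 9.999e-05
```

For optogenetic recordings, `run_optogenetic()` detects the flash,
splits every fly's ethogram into before/after windows and returns
paired contrasts per genotype; `plot_ethogram_raster(..., align_at =
flash_time)` draws the event-aligned raster.

A thin command-line front end lives at `inst/cli/strif.R` with
subcommands `simulate`, `track`, `optogenetic`, `stats` and `regress`.

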