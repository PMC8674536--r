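# gammarep

Stimulus repetition changes primary visual cortex: firing rates decrease
(repetition suppression) while narrowband gamma-band (~30–90 Hz) LFP
responses typically strengthen and shift in peak frequency. `gammarep` is
an R toolkit for asking whether those repetition trajectories are
**stimulus-specific** — whether V1 tracks each image's repetition history
separately even when repetitions are interleaved with other images — and
whether the induced state **persists** across blocks of intervening
stimulation. It is written for electrophysiologists and methods
researchers who want every stage of such an analysis testable against
planted ground truth.

The package pairs a synthetic-data generator (constrained-lag
natural-image sequences, ABA/BBA grating blocks, In/Out location blocks;
multi-site LFP + MUA-envelope signals with controlled repetition
trajectories; eye traces) with the full analysis chain:

* denoised MUA (`compute_dmua`), baseline normalization, epoching,
  re-referencing;
* Hann and DPSS multitaper power spectra (`taper_power`; K = 2TW, so
  250 ms epochs with ±10 Hz smoothing give 5 tapers) and MUA–LFP
  **pairwise phase consistency**
  `PPC = 2/(N(N−1)) Σ_{j<k} cos(θ_j − θ_k)`, computed by its closed form
  and unbiased by observation count;
* per-stimulus gamma-peak detection in 20–190 Hz, permutation validation
  against the 190 ± 8 Hz reference band, site grouping (±16 Hz) and
  peak-aligned averaging;
* early (repetitions 1–4) / late (5–15) OLS slopes, the
  repetition-related change `RRC = r_last / (0.5 (r_last + r_first))`,
  and cross-validated intercept–slope (drive-dependence) correlations
  with a median-split floor-effect control;
* the headline **split-half specificity statistic**: z-scored per-stimulus
  repetition trajectories, concatenated per session in fixed stimulus
  order, correlated across s = 100 random session halves, and tested
  against a stimulus-reshuffling permutation null (1000 iterations,
  two-sided, BH-FDR across frequency or time bins);
* sign-flip and exchange permutation tests (two-sided p floor 0.002 at
  1000 permutations), bootstrap SEMs, block-design regression models, and
  microsaccade/pupil preprocessing.

## Worked example

Simulate eight sessions of an interleaved natural-image experiment with
fully stimulus-specific repetition effects, then run the end-to-end
analysis:

```r
library(gammarep)

truth <- ground_truth(sprintf("img%02d", 1:8), specificity_transfer = 0,
                      seed = 42)
cfg <- dataset1_config(n_stimuli = 8, reps_per_stim = 18, n_sessions = 8,
                       n_sites = 4, s = 100, n_perm = 1000,
                       truth = truth, seed = 42)
report <- run_dataset1_analysis(cfg)

head(report$peaks, 4)
#> # A tibble: 4 × 5
#>   stimulus_id freq_hz  rank     p validated
#>   <chr>         <dbl> <int> <dbl> <lgl>
#> 1 img01            76     1 0.001 TRUE
#> 2 img02            76     1 0.001 TRUE
#> 3 img03            52     1 0.001 TRUE
#> 4 img04            72     1 0.001 TRUE

report$tests
#> # A tibble: 4 × 5
#>   feature segment mean_slope mean_rrc     p
#>   <chr>   <chr>        <dbl>    <dbl> <dbl>
#> 1 dmua    early      -0.304     0.945 0.002
#> 2 dmua    late       -0.0492    0.968 0.002
#> 3 gamma   early       0.0379    1.01  0.108
#> 4 gamma   late        0.0228    1.03  0.002

report$specificity
#> # A tibble: 1 × 5
#>   observed_r     p significant n_animals n_sessions
#>        <dbl> <dbl> <lgl>           <int>      <dbl>
#> 1      0.628 0.002 TRUE                1          8
```

Reading the output: every stimulus's gamma peak was found and validated
against high-frequency activity (p at the permutation floor). Firing
rates (dMUA, as stimulation/baseline ratios) drop steeply over the first
four repetitions (mean slope −0.30 per repetition, RRC 0.95, sign-flip
p = 0.002) and continue to drop slowly thereafter; gamma-band power rises
across late repetitions (slope +0.023, p = 0.002; the early gamma slope
averages near zero here because the planted early slopes vary in sign
across stimuli). The split-half correlation of z-scored trajectories is
r = 0.63 and beats its stimulus-reshuffling null at the two-sided
permutation floor — the repetition trajectories are stimulus-specific, as
planted. `autoplot(report$specificity)` draws the null histogram with the
observed value; `run_block_analysis(block_config(...))` runs the
grating/location block contrasts and regression models instead.

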