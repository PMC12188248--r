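# flyssvep

Analysis of steady-state visually evoked potentials (SSVEPs) recorded
across a 16-channel transect of the *Drosophila* brain under
carrier/deviant ("oddball") visual stimulation, with a forward simulator
that makes every stage testable against known ground truth.

## The problem

Flies watching a 10 Hz flicker (50 ms duty cycle, 20 s trials, 3 s pauses)
produce steady-state evoked potentials throughout the brain. Embedding a
differently coloured deviant flash every fifth event tags a second
frequency (F2 = 2 Hz) on top of the carrier (F1 = 10 Hz). Because flies
sleep during overnight recordings — behavioural quiescence of 5 min or
more — every stimulus event can be labelled by brain region, colour, role
(carrier/deviant), stimulus history, sleep/wake state, position within a
sleep bout, and proboscis-extension context, and the per-event SSVEP
amplitude compared across those labels.

The core quantities, per event:

- `amp_raw = max − min` of the LFP in the 100 ms window after stimulus
  onset (peak-trough amplitude);
- `amp_norm = amp_raw / mean(amp_raw)` over all events of the same colour
  within a fly and channel (carriers and deviants pooled), so
  `mean(amp_norm) ≡ 1` per pool;
- `amp_corrected = amp_norm − m̄_fly`, where `m̄_fly` is the mean of the
  fly's per-group mean normalised amplitudes for the comparison at hand,
  so the group means centre at zero within each fly.

Group tests are one-way ANOVAs on per-fly means (the fly is the unit of
replication) with Bonferroni-corrected pairwise t tests
(`p_adj = min(1, p × n_pairs)`).

The package covers the full path: counterbalanced stimulus schedules
(carrier-only, phasic-deviant, jittering-deviant), a forward simulator
(multichannel LFP + movement + proboscis traces with ground truth),
preprocessing (downsampling, 50 Hz notch, polarity-reversal detection,
re-referencing, region assignment), sleep-bout scoring and one-minute
segmentation, proboscis-spell classification with inter-extension sampling
windows, amplitude extraction and history labelling, F1/F2 power spectra,
and per-fly statistics with report output. See the methods vignette
(`vignettes/flyssvep-methods.Rmd`) for the model and every numerical
choice.

## Worked example

Simulate eight 30-minute flies, run the whole pipeline, and test the
headline contrasts (all numbers below are what this exact code prints):

```r
library(flyssvep)

cfg <- flyssvep_config(n_flies = 8, fly_duration_s = 1800, seed = 7)
out <- run_pipeline(cfg, quiet = TRUE)

dplyr::bind_rows(lapply(out$comparisons, glance))
#> # A tibble: 4 × 6
#>   contrast                            region  n_flies n_groups f_statistic  p_value
#>   <chr>                               <chr>     <int>    <int>       <dbl>    <dbl>
#> 1 carrier_vs_deviant_green_central    central       8        2    333.     3.70e-11
#> 2 wake_vs_sleep_green_carrier_central central       7        2      0.0280 8.70e- 1
#> 3 wake_vs_sleep_green_deviant_central central       7        2     42.5    2.86e- 5
#> 4 segments_green_deviant_central      central       3        7     19.0    5.56e- 6
```

Reading the table: deviant responses are far smaller than history-matched
carrier responses in the central region (row 1); sleep leaves carrier
responses unchanged (row 2, not significant — an exact null in the
simulator) but significantly attenuates central deviant responses
(row 3); and deviant responses differ across the seven bout segments
(row 4, fewer flies because a 30 min recording rarely contains every
segment for every fly).

The frequency-tagging spectrum of a single simulated fly:

```r
rec <- simulate_recording(cfg$sim, duration_s = 460, seed = 1)
sp <- power_spectrum(rec, channel = 9)   # intermediate channel
spectrum_peaks(sp)
#> $f1_hz
#> [1] 10
#>
#> $f2_hz
#> [1] 2
autoplot(sp)
```

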