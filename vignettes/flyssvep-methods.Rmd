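---
title: "Methods: frequency-tagged visual responses across the fly brain, from stimulus schedule to statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency-tagged visual responses across the fly brain, from stimulus schedule to statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyssvep)
```

## The problem this package addresses

A linear 16-channel probe inserted through one eye of a tethered fly records
local field potentials (LFPs) along a transect from the retina to the
central brain while full-field colour flashes are delivered at a fixed
carrier frequency (F1 = 10 Hz, 50% duty cycle) in 20 s trials separated by
3 s pauses. Embedding a differently coloured, low-probability "deviant"
flash every fifth event adds a second tagged frequency (F2 = 2 Hz). Because
the fly also sleeps during overnight recordings, every stimulus event can
be labelled with the animal's behavioural state, and the steady-state
visually evoked potential (SSVEP) amplitude can be compared across stimulus
probability, stimulus history, brain region, sleep/wake state, position
within a sleep bout, and proboscis-extension context.

`flyssvep` implements that entire analysis as composable, data-frame-first
functions, together with a forward simulator that generates synthetic
recordings with known ground truth so that every stage — and the pipeline
as a whole — is testable without any recorded data.

## The amplitude model

The primary metric is the per-event peak-trough amplitude: within a window
after each stimulus onset (default `[0, 100)` ms, one inter-stimulus
interval, so windows never overlap), `amp_raw = max - min` of the LFP,
order-agnostic. Three derived quantities follow:

1. **Normalised amplitude.** Within each fly and channel, all events of one
   colour — carriers and deviants pooled — form a normalisation pool;
   `amp_norm` is the event's proportion of the pool mean, so
   `mean(amp_norm) = 1` holds exactly per (fly, channel, colour). This
   removes between-fly and between-channel scale differences while
   preserving role/state contrasts within a colour.
2. **Corrected amplitude.** For a named comparison, each fly's centre (the
   unweighted mean of its per-group mean normalised amplitudes) is
   subtracted from its records, so the group means average to zero exactly
   within each fly. Contrasts therefore compare distributions centred per
   fly, removing residual individual offsets.
3. **Per-fly group means.** The fly is the unit of replication: statistics
   always run on one mean per fly per group, never on pooled events.

Contrasts are history-matched: the carrier-versus-deviant comparison uses
only first carriers after a deviant versus deviants preceded by a carrier,
so both groups share a colour-transition history and differ only in
probability. Carriers are additionally numbered 1–4 by their position after
the most recent deviant ("carrier order"), and deviants carry the length of
the carrier run preceding them, which selects history-matched subsets of
jittering-deviant trials (runs of exactly four carriers).

Group differences are assessed with a one-way ANOVA on per-fly means,
followed by all pairwise pooled-variance t tests with Bonferroni
multiplication (`p_adj = min(1, p × n_pairs)`; with two groups
F = t² exactly, which the test suite checks). When every group has zero
within-group variance the test is degenerate; the package warns and falls
back to exact equality of group means.

One calibration subtlety deserves a note. With two groups, per-fly
mean-centering forces the corrected group means of each fly to be exact
mirror images (`+d/2`, `−d/2`), so an *unpaired* ANOVA run on corrected
values understates the standard error of the mean difference by √2 and
inflates the false-positive rate (to roughly 15% at a nominal 5%, which
Monte-Carlo on the simulator's exact carrier null confirms). The pipeline
therefore tests per-fly means of the *normalised* amplitude — the per-fly
group differences are identical to the corrected ones, but the shared
per-fly component then adds equal variance to both groups and the unpaired
ANOVA is calibrated or conservative — while corrected amplitudes remain
the comparison-specific values recorded, summarised and plotted.
`flywise_means()` accepts either column, so the corrected-value test is
still available.

## Preprocessing

The chain is fixed: optional downsampling (Fourier anti-aliasing followed
by integer decimation) → line-noise removal (1 Hz-wide spectral notches at
50 Hz and harmonics below Nyquist) → polarity-reversal detection →
re-referencing → region assignment. A recording records which steps it has
seen and refuses to be preprocessed twice. Only the first 6 h of a longer
recording are analysed by default.

Reversal detection averages event-locked responses over one inter-stimulus
interval per channel (up to the first 2000 events), and returns the
channel with the smallest peak-trough amplitude among channels at which the
dominant deflection changes sign between neighbours, breaking ties to the
lower index. Absence of any sign change raises an explicit no-reversal
error — the signature of an insertion without a visual response, which in
practice excludes that fly. Re-referencing subtracts the reversal channel
from the other 15, removing common-mode signal exactly. Analysis regions
are derived arithmetically from the reversal: central = reversal − 8,
intermediate = reversal − 3, peripheral = reversal + 3, clamped into range
with a warning.

## Behaviour scoring

Movement activity is binned (1 s bins) and thresholded; by default the
threshold adapts to the trace scale (20% of the 95th percentile of per-bin
peaks), and both bin and threshold are configuration. Maximal quiescent
runs of at least 5 min become sleep bouts — boundary inclusive, so exactly
300 s of immobility is sleep — and everything else is wake, yielding bouts
that tile the recording with alternating states.

Each sleep bout contributes five labelled one-minute segments (first,
second, middle, second-last and last minute); the immediately preceding
wake bout contributes its middle and final minutes. For a bout of D whole
minutes the middle window starts at minute `floor((D − 1) / 2) + 1`, a
deterministic centring rule under which a 5 min bout yields exactly
minutes 1–5 with no overlap; the priority rule (first/last windows beat
middle ones) only matters if the sleep threshold is configured below 5 min.

Proboscis extensions are threshold crossings of the extension-distance
trace, merged across sub-100 ms gaps. Events whose peaks are within 5 s of
each other in groups of three or more form rhythmic spells; isolated events
longer than 1.5 s are "reaches"; other isolated events are left
unclassified. Spells are split at bout boundaries so each has an
unambiguous wake/sleep context. SSVEPs in proboscis-extension-contextual
analyses are sampled only from the open windows between a spell's
extensions, trimmed by a 50 ms guard and dropped when shorter than one
stimulus period, so the extension epochs themselves never contribute.

## The forward simulator

The simulator is a statistical forward model, not a biophysical one. It
encodes, as configuration:

* a signed per-channel amplitude profile that tapers linearly to zero at
  the polarity-reversal channel (default 12) and inverts beyond it;
* a biphasic evoked kernel (difference of alpha functions, ~15 ms latency,
  span under one inter-stimulus interval, unit peak-trough amplitude) whose
  main lobe dominates, giving the kernel net area and therefore more
  spectral weight at 2 Hz than at its harmonics;
* colour gains (blue 0.8 × green) and a role/state gain table: deviant
  responses smaller than carriers in every region and most so centrally
  (0.7/0.7/0.85), a further ×0.6 attenuation of central deviant responses
  during deep sleep only, and carrier-order gains (0.8, 0.9, 1, 1) outside
  the central group, making the first carrier after a colour change respond
  differently in the optic lobes while the central brain is insensitive to
  carrier order. Carrier gains are state-invariant everywhere, encoding the
  finding that repetitive-stimulus processing is unaffected by sleep. The
  direction of the carrier-order effect is simplified to be
  colour-independent, and deep sleep is defined as the mid-bout minutes
  (minute 3 through the second-last) of each sleep bout;
* alternating wake/sleep bouts drawn from a lognormal model with medians
  11.2 and 12.8 min (sdlog 0.6), a movement trace with per-second activity
  bursts during wake, and a proboscis model that concentrates rhythmic
  extension spells in deep-sleep minutes with occasional wake spells and
  longer singular reaches;
* 1/f background noise per channel plus a 1/f component shared across all
  channels (removable by re-referencing, mimicking synchronized endogenous
  activity), with a 1 Hz high-pass corner reflecting AC-coupled
  acquisition, and 50 Hz line noise.

With the defaults, the evoked response at responsive channels is a few
times the background standard deviation — the regime in which steady-state
responses are visible in single trials. Because the 5-event amplitude cycle
(four graded carriers, then a smaller deviant) is a smooth envelope, its
2 Hz fundamental dominates its harmonics, and the trial-averaged spectrum
of an intermediate channel shows the F1 peak at 10 Hz and the F2 peak at
2 Hz, as the analysis expects. Ground truth records every bout, deep-sleep
interval, proboscis event, and the noise-free per-channel amplitude of
every stimulus event, enabling exact round-trip tests (with all noise set
to zero the measured amplitudes equal truth to within 1e-6 relative).

Jittering-deviant trials displace each nominal deviant position by a
rounded Gaussian offset (default sd = 1 position). Offsets that collide
with or order-swap against an already placed deviant are redrawn (up to 100
times, then the nominal position is kept if admissible); deviants jittered
outside the trial are dropped. Under this rule the gap between consecutive
deviants is modal at 4 carriers with 3 and 5 next most likely, and the mean
gap is ≈3.99 over many trials. The exact collision rule used in the
original experiments is unknown; this one preserves strict ordering and the
stated gap statistics.

One master seed drives everything; per-component and per-fly sub-seeds are
derived deterministically, so `(config, seed)` reproduces a run
bitwise.

### What the simulator does not emulate

Real recordings contain electrode drift, movement artefacts, waveform
nonstationarity, colour-dependent response shapes (not just gains),
arousal-dependent background spectra and imperfect polarity reversals.
Passing round-trip tests on simulated data therefore demonstrates that the
pipeline correctly recovers the structure it is designed to measure — not
that real recordings satisfy that structure. The two gain defaults most
relevant to the headline comparison (deviant attenuation and its deep-sleep
factor) are deliberately round numbers used for parameter-recovery
testing, not estimates of the physiological effect sizes.

## Numerical choices

* Epoch window `[0, 100)` ms; amplitudes are unsigned `max − min`.
* Spectra are single-taper periodograms over each full 20 s trial span
  (0.05 Hz resolution), normalised to unit total power per trial before
  averaging, DC excluded.
* Line-noise notches are 1 Hz wide, applied in the Fourier domain
  (linear-phase, exact passband).
* Downsampling requires an integer factor and uses Fourier anti-aliasing.
* Sleep/wake assignment of an event uses its onset time; the sleep
  boundary is inclusive (`>= 300` s).
* Ties in reversal detection break to the lower channel index; region
  indices clamp into `1..n_channels` with a warning.
* Normalisation pools span the full analysed span of a recording.
* Flies missing a group of a contrast are excluded from that contrast with
  a message, not an error.

## Problem sizes used by the test and acceptance suites

Simulated checks run on deliberately desk-scale problems chosen to keep
the full suite fast while leaving comfortable statistical margins:
recordings of 2–30 min at 200 Hz (the overnight analysis rate; the
simulator generates at the analysis rate directly rather than at the
acquisition rate, since nothing above the analysis band is modelled),
20-trial spectra, 20 seeds for reversal recovery, 10,000 trials for jitter
statistics, and 10 seeds × 8 flies × 30 min for the parameter-recovery
check of the headline contrast. At that scale the deviant deep-sleep
decrement is detected in essentially every run while the matched carrier
contrast — an exact null by construction — stays at its nominal false-positive
rate.

## Worked example

```{r example, eval = FALSE}
library(flyssvep)

cfg <- flyssvep_config(n_flies = 8, fly_duration_s = 1800, seed = 1)
out <- run_pipeline(cfg, out_dir = "flyssvep-report", quiet = TRUE)

# headline contrasts on per-fly corrected amplitudes
lapply(out$comparisons, glance)

# frequency-tagging spectrum of one fly
rec <- simulate_recording(cfg$sim, duration_s = 460, seed = 1)
sp <- power_spectrum(rec, channel = 9)
spectrum_peaks(sp)
autoplot(sp)
```

## Known limitations

* The container format is a directory of Parquet tables plus a JSON
  header; it is lossless and versioned but not a single-file archive.
* The ANOVA family for the seven-segment analysis is the omnibus test plus
  all-pairs Bonferroni within a panel; other family definitions would give
  different adjusted p values.
* The proboscis classifier is threshold-based; it stands in for
  video-based tracking, which is out of scope (the pipeline consumes a 1-D
  extension-distance trace).
* Statistics assume approximately normal per-fly means; with N = 6–8 flies
  this matches the original design but is not robust to heavy outliers.
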