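Package: flyssvep
Title: Steady-State Visually Evoked Potential Analysis for Multichannel Fly Brain Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing steady-state visually evoked potentials
    (SSVEPs) recorded across a 16-channel transect of the Drosophila brain
    under carrier/deviant ("oddball") visual stimulation. Includes a
    counterbalanced stimulus-schedule generator (carrier-only, phasic-deviant
    and jittering-deviant trials), a forward simulator producing multichannel
    local field potentials with movement and proboscis traces and ground-truth
    labels, preprocessing (downsampling, line-noise removal, polarity-reversal
    detection, re-referencing, region assignment), immobility-based sleep-bout
    scoring with one-minute bout segmentation, proboscis-extension spell
    classification, per-event peak-trough amplitude extraction with
    per-colour normalisation and comparison-specific corrected amplitudes,
    frequency-tagging (F1/F2) power spectra, and per-fly group statistics
    with Bonferroni-corrected pairwise tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    arrow,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
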