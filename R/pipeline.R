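DEFAULT_CONTRASTS <- list(
  list(contrast = "carrier_vs_deviant", color = "green", role = NA,
       region = "central"),
  list(contrast = "wake_vs_sleep", color = "green", role = "carrier",
       region = "central"),
  list(contrast = "wake_vs_sleep", color = "green", role = "deviant",
       region = "central"),
  list(contrast = "segments", color = "green", role = "deviant",
       region = "central"))

#' Build a validated pipeline run configuration
#'
#' Collects every tunable threshold of the simulator, preprocessing,
#' behaviour scoring, amplitude extraction and statistics stages into one
#' list, so a run is fully specified by `(config, seed)`.
#'
#' @param n_flies Number of simulated flies (default 8).
#' @param fly_duration_s Recording duration per fly, seconds (default 1800).
#' @param seed Master seed; per-fly and per-component sub-seeds are derived
#'   deterministically from it.
#' @param sim A [sim_config()].
#' @param preprocessing List: `target_fs` (`NULL` keeps the simulated
#'   rate), `base_hz`, `max_span_s`.
#' @param behavior List: `min_sleep_s`, `bin_s`, `threshold` (`NULL` =
#'   adaptive), `pe_threshold`, `spell_gap_s`, `min_spell_events`,
#'   `reach_min_duration_s`.
#' @param ssvep List: `window_s` (amplitude window after onset).
#' @param stats List: `alpha`.
#' @param contrasts List of contrast specs, each a list with elements
#'   `contrast`, `color`, `role`, `region`.
#' @return A list of class `"flyssvep_config"`. Unknown keys in any
#'   section are rejected.
#' @export
flyssvep_config <- function(n_flies = 8, fly_duration_s = 1800, seed = 1,
                            sim = sim_config(), preprocessing = list(),
                            behavior = list(), ssvep = list(),
                            stats = list(), contrasts = DEFAULT_CONTRASTS) {
  merge_checked <- function(defaults, user, section) {
    extra <- setdiff(names(user), names(defaults))
    if (length(extra) > 0) {
      abort_flyssvep(
        sprintf("unknown %s key(s): %s", section,
                paste(extra, collapse = ", ")),
        "flyssvep_invalid_config")
    }
    utils::modifyList(defaults, user)
  }
  structure(
    list(
      n_flies = as.integer(n_flies),
      fly_duration_s = fly_duration_s,
      seed = as.integer(seed),
      sim = sim,
      preprocessing = merge_checked(
        list(target_fs = NULL, base_hz = 50, max_span_s = 6 * 3600),
        preprocessing, "preprocessing"),
      behavior = merge_checked(
        list(min_sleep_s = 300, bin_s = 1, threshold = NULL,
             pe_threshold = 0.3, spell_gap_s = 5, min_spell_events = 3,
             reach_min_duration_s = 1.5),
        behavior, "behavior"),
      ssvep = merge_checked(list(window_s = c(0, 0.1)), ssvep, "ssvep"),
      stats = merge_checked(list(alpha = 0.05), stats, "stats"),
      contrasts = contrasts),
    class = "flyssvep_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys map to the arguments of [flyssvep_config()]; the `sim`
#' section maps to [sim_config()] arguments. Unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A [flyssvep_config()] list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("n_flies", "fly_duration_s", "seed", "sim", "preprocessing",
             "behavior", "ssvep", "stats", "contrasts")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    abort_flyssvep(sprintf("unknown config key(s): %s",
                           paste(extra, collapse = ", ")),
                   "flyssvep_invalid_config")
  }
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_config, raw$sim)
  do.call(flyssvep_config, raw)
}

#' Process one recording through behaviour scoring and amplitude extraction
#'
#' Runs the preprocessing chain, scores sleep/wake bouts from the movement
#' trace, segments them into labelled minutes, detects and classifies
#' proboscis events, extracts per-event amplitudes on the three region
#' channels, and attaches the history/state/segment/PE-context labels.
#'
#' @param rec A raw [new_recording()].
#' @param config A [flyssvep_config()].
#' @return A list: `records` (labelled amplitude table), `bouts`,
#'   `segments`, `pe`, `channel_map`, `rec` (the preprocessed recording).
#' @export
process_fly <- function(rec, config = flyssvep_config()) {
  pp <- preprocess_recording(
    rec, target_fs = config$preprocessing$target_fs %||% rec$fs,
    base_hz = config$preprocessing$base_hz,
    max_span_s = config$preprocessing$max_span_s)
  beh <- config$behavior
  activity <- quantify_movement(pp$rec$movement, pp$rec$fs,
                                bin_s = beh$bin_s,
                                threshold = beh$threshold)
  bouts <- score_bouts(activity, min_sleep_s = beh$min_sleep_s)
  segments <- segment_bouts(bouts)
  pe <- classify_pe(
    detect_pe_events(pp$rec$proboscis, pp$rec$fs,
                     threshold = beh$pe_threshold),
    spell_gap_s = beh$spell_gap_s,
    min_spell_events = beh$min_spell_events,
    reach_min_duration_s = beh$reach_min_duration_s,
    bouts = bouts)
  records <- compute_amplitudes(pp$rec, pp$channel_map,
                                window_s = config$ssvep$window_s)
  hist <- label_history(pp$rec$events)
  records <- dplyr::left_join(
    records,
    hist[c("trial_id", "seq_index", "prev_color", "prev_role",
           "carrier_order", "carrier_run")],
    by = c("trial_id", "seq_index"))
  records <- label_state(records, bouts, segments, pe)
  list(records = records, bouts = bouts, segments = segments, pe = pe,
       channel_map = pp$channel_map, rec = pp$rec)
}

#' Run the full simulation-to-statistics pipeline
#'
#' Simulates `n_flies` recordings (per-fly sub-seeds derived from the
#' master seed), processes each through preprocessing, behaviour scoring
#' and amplitude extraction, normalises amplitudes per fly/channel/colour,
#' then fits every configured contrast on per-fly corrected-amplitude
#' means. Identical `(config, seed)` give identical outputs.
#'
#' @param config A [flyssvep_config()].
#' @param out_dir Optional report directory passed to [build_report()].
#' @param quiet Suppress per-fly progress messages.
#' @return A list: `records` (all flies, labelled and normalised), `bouts`,
#'   `comparisons` (named list of [omnibus_test()] results), `config`.
#' @export
run_pipeline <- function(config = flyssvep_config(), out_dir = NULL,
                         quiet = FALSE) {
  all_records <- list(); all_bouts <- list()
  for (k in seq_len(config$n_flies)) {
    fly_id <- sprintf("fly%02d", k)
    if (!quiet) message("simulating and processing ", fly_id)
    rec <- simulate_recording(config$sim, config$fly_duration_s,
                              seed = derive_seed(config$seed, 100 + k),
                              fly_id = fly_id)
    res <- tryCatch(process_fly(rec, config), flyssvep_error = function(e) {
      message(fly_id, " excluded: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    all_records[[fly_id]] <- res$records
    all_bouts[[fly_id]] <- dplyr::mutate(res$bouts, fly_id = fly_id,
                                         .before = 1)
  }
  if (length(all_records) == 0) {
    abort_flyssvep("no fly produced usable records.",
                   "flyssvep_insufficient_data")
  }
  records <- normalize_amplitudes(dplyr::bind_rows(all_records))
  bouts <- dplyr::bind_rows(all_bouts)

  comparisons <- list()
  for (cs in config$contrasts) {
    nm <- paste(c(cs$contrast, cs$color, cs$role, cs$region)[
      !vapply(list(cs$contrast, cs$color, cs$role, cs$region),
              function(x) is.null(x) || is.na(x), logical(1))],
      collapse = "_")
    cmp <- tryCatch({
      r <- records[records$region == cs$region, ]
      sel <- select_contrast(r, cs$contrast,
                             color = if (is.null(cs$color) ||
                                         is.na(cs$color)) NULL else cs$color,
                             role = cs$role %||% "deviant")
      corr <- corrected_amplitude(sel)
      # test per-fly means of the normalised amplitude: per-fly differences
      # equal the corrected ones, but the unpaired ANOVA stays calibrated
      # (mean-centred two-group values are exactly anticorrelated, which
      # would understate the unpaired standard error)
      omnibus_test(flywise_means(corr, value = "amp_norm"),
                   contrast = nm, region = cs$region)
    }, flyssvep_error = function(e) {
      message("contrast ", nm, " skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(cmp)) comparisons[[nm]] <- cmp
  }
  if (!is.null(out_dir)) {
    build_report(comparisons, bouts = bouts, dir = out_dir,
                 manifest = list(seed = config$seed,
                                 n_flies = config$n_flies,
                                 fly_duration_s = config$fly_duration_s,
                                 package_version =
                                   as.character(utils::packageVersion("flyssvep"))))
  }
  list(records = records, bouts = bouts, comparisons = comparisons,
       config = config)
}
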