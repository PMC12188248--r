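#' Per-fly group means for a contrast
#'
#' The fly is the unit of replication: every statistical test runs on one
#' mean per fly per group. Flies with an empty group cell are dropped with
#' a message.
#'
#' @param records Output of [corrected_amplitude()] (columns `fly_id`,
#'   `group`, `amp_corrected`).
#' @param value Column to average (default `"amp_corrected"`).
#' @return A tibble: `fly_id`, `group`, `mean_amp`.
#' @export
flywise_means <- function(records, value = "amp_corrected") {
  out <- dplyr::summarise(
    dplyr::group_by(records, .data$fly_id, .data$group),
    mean_amp = mean(.data[[value]]), .groups = "drop")
  n_groups <- length(unique(out$group))
  counts <- table(out$fly_id)
  incomplete <- names(counts)[counts < n_groups]
  if (length(incomplete) > 0) {
    message(sprintf("dropping %d fly/flies with empty cells: %s",
                    length(incomplete), paste(incomplete, collapse = ", ")))
    out <- out[!out$fly_id %in% incomplete, ]
  }
  if (dplyr::n_distinct(out$fly_id) < 2) {
    abort_flyssvep("fewer than 2 flies remain; cannot test.",
                   "flyssvep_insufficient_data")
  }
  out
}

#' One-way ANOVA with Bonferroni-corrected pairwise comparisons
#'
#' Omnibus one-way analysis of variance of the per-fly group means across
#' group labels, followed by all pairwise pooled-variance t tests with
#' Bonferroni multiplication (`p_adj = min(1, p * n_pairs)`). Deterministic
#' given the means. When every group has zero within-group variance the
#' test is degenerate: a warning is raised and the p value falls back to
#' exact equality of the group means (1 if all equal, 0 otherwise).
#'
#' @param fly_means Output of [flywise_means()].
#' @param contrast Optional contrast name stored on the result.
#' @param region Optional region label stored on the result.
#' @return An object of class `"flyssvep_comparison"`: a list with
#'   `contrast`, `region`, `n_flies`, `groups`, `f_statistic`, `p_value`,
#'   `pairwise` (tibble: `group_a`, `group_b`, `estimate`, `p_raw`,
#'   `p_bonferroni`, `significant`) and `fly_means`.
#' @export
omnibus_test <- function(fly_means, contrast = NA_character_,
                         region = NA_character_) {
  fly_means$group <- factor(fly_means$group)
  groups <- levels(fly_means$group)
  if (length(groups) < 2) {
    abort_flyssvep("at least 2 groups are required.",
                   "flyssvep_insufficient_data")
  }
  counts <- table(fly_means$group)
  if (any(counts < 2)) {
    abort_flyssvep("at least 2 flies per group are required.",
                   "flyssvep_insufficient_data")
  }
  within_var <- stats::aggregate(mean_amp ~ group, data = fly_means,
                                 FUN = stats::var)$mean_amp
  gmeans <- stats::aggregate(mean_amp ~ group, data = fly_means,
                             FUN = mean)$mean_amp
  if (all(within_var < .Machine$double.eps)) {
    warning("degenerate test: zero within-group variance in every group; ",
            "falling back to exact equality of group means.", call. = FALSE)
    equal <- max(gmeans) - min(gmeans) < .Machine$double.eps
    f_stat <- if (equal) 0 else Inf
    p_val <- if (equal) 1 else 0
  } else {
    fit <- stats::aov(mean_amp ~ group, data = fly_means)
    tab <- summary(fit)[[1]]
    f_stat <- tab[["F value"]][1]
    p_val <- tab[["Pr(>F)"]][1]
  }
  pairs <- utils::combn(groups, 2)
  n_pairs <- ncol(pairs)
  pairwise <- purrr::map_dfr(seq_len(n_pairs), function(k) {
    a <- fly_means$mean_amp[fly_means$group == pairs[1, k]]
    b <- fly_means$mean_amp[fly_means$group == pairs[2, k]]
    p <- if (stats::var(a) + stats::var(b) < .Machine$double.eps) {
      if (abs(mean(a) - mean(b)) < .Machine$double.eps) 1 else 0
    } else {
      stats::t.test(a, b, var.equal = TRUE)$p.value
    }
    tibble::tibble(group_a = pairs[1, k], group_b = pairs[2, k],
                   estimate = mean(a) - mean(b), p_raw = p,
                   p_bonferroni = min(1, p * n_pairs))
  })
  pairwise$significant <- pairwise$p_bonferroni < 0.05
  structure(
    list(contrast = contrast, region = region,
         n_flies = dplyr::n_distinct(fly_means$fly_id), groups = groups,
         f_statistic = f_stat, p_value = p_val, pairwise = pairwise,
         fly_means = fly_means),
    class = "flyssvep_comparison")
}

#' @export
print.flyssvep_comparison <- function(x, ...) {
  cat(sprintf("<flyssvep_comparison> %s%s: F = %.3g, p = %.3g (N = %d flies)\n",
              if (is.na(x$contrast)) "" else x$contrast,
              if (is.na(x$region)) "" else paste0(" [", x$region, "]"),
              x$f_statistic, x$p_value, x$n_flies))
  print(x$pairwise)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the pairwise comparisons of a fitted contrast
#'
#' @param x A [omnibus_test()] result.
#' @param ... Unused.
#' @return One row per pairwise comparison.
#' @export
tidy.flyssvep_comparison <- function(x, ...) {
  dplyr::mutate(x$pairwise, contrast = x$contrast, region = x$region,
                .before = 1)
}

#' One-row summary of a fitted contrast
#'
#' @param x A [omnibus_test()] result.
#' @param ... Unused.
#' @return A one-row tibble with the omnibus statistics.
#' @export
glance.flyssvep_comparison <- function(x, ...) {
  tibble::tibble(contrast = x$contrast, region = x$region,
                 n_flies = x$n_flies, n_groups = length(x$groups),
                 f_statistic = x$f_statistic, p_value = x$p_value)
}

#' Box-plot summary statistics
#'
#' Median, quartiles and 1.5 x interquartile-range whisker limits, the
#' summary drawn in every figure.
#'
#' @param x Numeric vector.
#' @return A one-row tibble: `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`, `n`.
#' @export
box_stats <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  tibble::tibble(median = q[2], q1 = q[1], q3 = q[3],
                 whisker_low = q[1] - 1.5 * iqr,
                 whisker_high = q[3] + 1.5 * iqr, n = length(x))
}

#' Write a machine-readable analysis report
#'
#' Renders the per-contrast comparison table, per-group box-plot summary
#' statistics, bout-duration table, optional spectra and a run manifest
#' into a report directory, with ggplot figures for each section present.
#'
#' @param comparisons List of [omnibus_test()] results (at least one).
#' @param bouts Optional combined bout table (with a `fly_id` column).
#' @param spectra Optional [power_spectrum()] result (or combined tibble).
#' @param dir Output directory.
#' @param manifest Optional named list (seeds, config hash, ...) written to
#'   `manifest.json`.
#' @return `dir`, invisibly.
#' @export
build_report <- function(comparisons, bouts = NULL, spectra = NULL,
                         dir = "flyssvep-report", manifest = list()) {
  if (length(comparisons) == 0) {
    abort_flyssvep("at least one comparison is required.",
                   "flyssvep_invalid_argument")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fig_dir <- file.path(dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE)

  comp_tbl <- dplyr::bind_rows(purrr::map(comparisons, tidy))
  omni_tbl <- dplyr::bind_rows(purrr::map(comparisons, glance))
  utils::write.csv(comp_tbl, file.path(dir, "comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(omni_tbl, file.path(dir, "omnibus.csv"), row.names = FALSE)

  group_stats <- dplyr::bind_rows(purrr::map(comparisons, function(cmp) {
    dplyr::reframe(dplyr::group_by(cmp$fly_means, .data$group),
                   box_stats(.data$mean_amp)) |>
      dplyr::mutate(contrast = cmp$contrast, region = cmp$region,
                    .before = 1)
  }))
  utils::write.csv(group_stats, file.path(dir, "group_stats.csv"),
                   row.names = FALSE)

  for (cmp in comparisons) {
    p <- autoplot.flyssvep_comparison(cmp)
    nm <- sprintf("comparison_%s_%s.png",
                  cmp$contrast %||% "contrast", cmp$region %||% "all")
    try(ggplot2::ggsave(file.path(fig_dir, nm), p, width = 5, height = 4,
                        dpi = 120), silent = TRUE)
  }
  if (!is.null(bouts) && nrow(bouts) > 0) {
    utils::write.csv(bouts, file.path(dir, "bouts.csv"), row.names = FALSE)
    try(ggplot2::ggsave(file.path(fig_dir, "bout_durations.png"),
                        plot_bout_durations(bouts), width = 6, height = 3,
                        dpi = 120), silent = TRUE)
  }
  if (!is.null(spectra) && nrow(spectra) > 0) {
    utils::write.csv(spectra, file.path(dir, "spectra.csv"),
                     row.names = FALSE)
    try(ggplot2::ggsave(file.path(fig_dir, "spectrum.png"),
                        autoplot.flyssvep_spectrum(spectra), width = 5,
                        height = 3.5, dpi = 120), silent = TRUE)
  } else {
    writeLines("no spectra were supplied for this run.",
               file.path(dir, "spectra_NOTE.txt"))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
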