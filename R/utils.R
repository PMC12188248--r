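# Internal helpers shared across modules.

`%||%` <- rlang::`%||%`

STIM_COLORS <- c("green", "blue")

#' @keywords internal
#' @noRd
abort_flyssvep <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "flyssvep_error"), ...)
}

# Deterministic 32-bit sub-seed derivation so each simulator component gets
# its own reproducible stream from one master seed. Kept below 2^31.
derive_seed <- function(seed, offset) {
  s <- (as.numeric(seed) %% 2147483647)
  as.integer((s * 48271 + 7919 * as.numeric(offset)) %% 2147483647)
}

# Row-wise max/min over the columns of a matrix without apply() overhead.
row_max <- function(m) Reduce(pmax, as.data.frame(m))
row_min <- function(m) Reduce(pmin, as.data.frame(m))

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    abort_flyssvep(sprintf("`%s` must be a single positive number.", name),
                   "flyssvep_invalid_spec")
  }
  invisible(x)
}

assert_color <- function(x, name) {
  if (!is.character(x) || length(x) != 1 || !x %in% STIM_COLORS) {
    abort_flyssvep(
      sprintf("`%s` must be one of %s.", name,
              paste0('"', STIM_COLORS, '"', collapse = ", ")),
      "flyssvep_invalid_spec")
  }
  invisible(x)
}

other_color <- function(color) setdiff(STIM_COLORS, color)
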