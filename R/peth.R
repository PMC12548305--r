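# Peri-event time histograms around pulse onsets and z-scored population
# summaries.

# Pooled bin counts of `times` relative to every onset whose window
# contains them.  Window and bin are in seconds; bins are half-open
# [left, right).  Fully vectorized; a spike inside two overlapping windows
# (window span wider than the pulse period) is counted in both.
pooled_bin_counts <- function(times, onsets, window_s, bin_s) {
  n_bins <- as.integer(round((window_s[2] - window_s[1]) / bin_s))
  i0 <- count_below(times, onsets + window_s[1])
  i1 <- count_below(times, onsets + window_s[2])
  n_per <- i1 - i0
  if (!sum(n_per)) return(integer(n_bins))
  idx <- sequence(n_per, from = i0 + 1L)
  rel <- times[idx] - rep(onsets, n_per)
  bins <- floor((rel - window_s[1]) / bin_s + 1e-9) + 1L
  bins <- bins[bins >= 1L & bins <= n_bins]  # guards float edge cases
  tabulate(bins, n_bins)
}

#' Compute a peri-event time histogram (PETH)
#'
#' Spike counts in uniform bins of time relative to pulse onset, pooled over
#' all pulses.  Bins are half-open: a spike at relative time `t` falls in
#' the bin with left edge `<= t <` right edge.  When the window is wider
#' than the pulse period (the default 75-ms window at 20 Hz), a spike is
#' counted relative to every pulse whose window contains it.
#'
#' @param train a [spike_train()].
#' @param pulse_onsets a [stim_protocol()] or numeric onset vector (seconds).
#' @param window_ms two-element window around onset in ms, e.g. `c(-25, 50)`.
#' @param bin_ms bin width in ms; must divide the window span.
#' @return an object of class `peth` with fields `unit_id`, `bin_edges_ms`,
#'   `counts`, `n_pulses`, `bin_ms`, `rate_hz` (counts / (pulses x bin
#'   width)), and `z` (filled by [zscore_peth()]).
#' @export
compute_peth <- function(train, pulse_onsets, window_ms = c(-25, 50),
                         bin_ms = 1) {
  stopifnot_param(inherits(train, "spike_train"), "train must be a spike_train")
  onsets <- as_onsets(pulse_onsets)
  if (!length(onsets)) of_stop("invalid_parameter", "no pulses to align to")
  stopifnot_param(length(window_ms) == 2L && window_ms[1] < window_ms[2],
                  "window_ms must be an increasing pair")
  span <- window_ms[2] - window_ms[1]
  n_bins <- span / bin_ms
  stopifnot_param(abs(n_bins - round(n_bins)) < 1e-9,
                  "bin_ms (%g) must divide the window span (%g ms)",
                  bin_ms, span)
  counts <- pooled_bin_counts(train$times, onsets, window_ms / 1000,
                              bin_ms / 1000)
  structure(list(unit_id = train$unit_id,
                 bin_edges_ms = seq(window_ms[1], window_ms[2], by = bin_ms),
                 counts = counts, n_pulses = length(onsets),
                 bin_ms = bin_ms,
                 rate_hz = counts / (length(onsets) * bin_ms / 1000),
                 z = NULL, flat_baseline = FALSE),
            class = "peth")
}

#' @export
print.peth <- function(x, ...) {
  cat(sprintf("<peth> unit '%s': %d bins of %g ms over [%g, %g) ms, %d pulses%s\n",
              x$unit_id, length(x$counts), x$bin_ms, x$bin_edges_ms[1],
              x$bin_edges_ms[length(x$bin_edges_ms)], x$n_pulses,
              if (is.null(x$z)) "" else ", z-scored"))
  invisible(x)
}

#' z-score a PETH against pre-onset baseline bins
#'
#' `z = (rate - mean(baseline rates)) / sd(baseline rates)` per bin, with
#' the baseline taken from pre-onset bins by default — stimulus-free at
#' train starts and the conventional normalization for population heatmaps.
#' A unit with zero baseline variance gets `z = 0` everywhere and is flagged
#' (`flat_baseline`).
#'
#' @param peth a [compute_peth()] result.
#' @param baseline_ms two-element range of baseline bins in ms; must lie
#'   inside the PETH window and be disjoint from `test_window_ms`.
#' @param test_window_ms the detection window the baseline must not touch.
#' @return the `peth` with `z` filled.
#' @export
zscore_peth <- function(peth, baseline_ms = c(-25, 0),
                        test_window_ms = c(0, 12)) {
  stopifnot_param(inherits(peth, "peth"), "peth must be a peth object")
  stopifnot_param(length(baseline_ms) == 2L && baseline_ms[1] < baseline_ms[2],
                  "baseline_ms must be an increasing pair")
  if (baseline_ms[2] > test_window_ms[1] && baseline_ms[1] < test_window_ms[2]) {
    of_stop("invalid_parameter",
            "baseline [%g, %g) ms overlaps the test window [%g, %g) ms",
            baseline_ms[1], baseline_ms[2], test_window_ms[1],
            test_window_ms[2])
  }
  edges <- peth$bin_edges_ms
  left <- edges[-length(edges)]
  right <- edges[-1]
  base <- which(left >= baseline_ms[1] - 1e-9 & right <= baseline_ms[2] + 1e-9)
  stopifnot_param(length(base) >= 1L,
                  "baseline range [%g, %g) ms contains no whole PETH bin",
                  baseline_ms[1], baseline_ms[2])
  mu <- mean(peth$rate_hz[base])
  s <- sd(peth$rate_hz[base])
  if (!is.finite(s) || s == 0) {
    peth$z <- rep(0, length(peth$counts))
    peth$flat_baseline <- TRUE
  } else {
    peth$z <- (peth$rate_hz - mu) / s
    peth$flat_baseline <- FALSE
  }
  peth
}

#' Assemble a population matrix of z-scored PETHs
#'
#' Rows are units: significant responders first, ordered by the latency of
#' their first significant bin (ties by unit id), then non-responders by
#' unit id.  The partition index is the number of responders — the row
#' below which the heatmap's responder block ends.
#'
#' @param peths list of z-scored [peth] objects.
#' @param calls list of [response_call] objects for the same units.
#' @return an object of class `population_matrix` with fields `z` (units x
#'   bins matrix), `unit_order`, `partition_index`, `bin_edges_ms`.
#' @export
population_matrix <- function(peths, calls) {
  p_ids <- vapply(peths, `[[`, character(1), "unit_id")
  c_ids <- vapply(calls, `[[`, character(1), "unit_id")
  if (!setequal(p_ids, c_ids) || length(p_ids) != length(c_ids)) {
    of_stop("invalid_parameter",
            "peths and calls must cover the same unit set")
  }
  calls <- calls[match(p_ids, c_ids)]
  stopifnot_param(all(vapply(peths, function(p) !is.null(p$z), logical(1))),
                  "all peths must be z-scored (run zscore_peth first)")
  responsive <- vapply(calls, `[[`, logical(1), "responsive")
  first_bin <- vapply(calls, function(cl) {
    if (length(cl$significant_bins)) min(cl$significant_bins) else Inf
  }, double(1))
  ord <- c(which(responsive)[order(first_bin[responsive], p_ids[responsive])],
           which(!responsive)[order(p_ids[!responsive])])
  z <- do.call(rbind, lapply(peths[ord], `[[`, "z"))
  rownames(z) <- p_ids[ord]
  structure(list(z = z, unit_order = p_ids[ord],
                 partition_index = sum(responsive),
                 bin_edges_ms = peths[[1]]$bin_edges_ms),
            class = "population_matrix")
}

#' @export
print.population_matrix <- function(x, ...) {
  cat(sprintf("<population_matrix> %d units x %d bins, %d responders first\n",
              nrow(x$z), ncol(x$z), x$partition_index))
  invisible(x)
}
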