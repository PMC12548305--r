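# S3 containers shared across the pipeline: spike trains, stimulation
# protocols, recording sets.

#' Construct a spike train
#'
#' A single sorted unit's spike times in seconds from recording start,
#' together with the recording span.  Duplicated timestamps are legal (two
#' threshold crossings can quantize to one sample) but are reported.
#'
#' @param times numeric vector of spike times in seconds, ascending, `>= 0`.
#' @param duration recording duration in seconds; all times must be below it.
#' @param unit_id identifier for the unit.
#' @return an object of class `spike_train` with fields `unit_id`, `times`,
#'   `duration`.
#' @export
spike_train <- function(times, duration, unit_id = "u1") {
  stopifnot_param(is.numeric(times), "spike times must be numeric")
  stopifnot_param(is.numeric(duration) && length(duration) == 1L && duration > 0,
                  "duration must be a single positive number")
  times <- as.double(times)
  stopifnot_param(all(is.finite(times)) || length(times) == 0L,
                  "spike times must be finite")
  stopifnot_param(length(times) == 0L || min(times) >= 0,
                  "spike times must be non-negative")
  stopifnot_param(is_sorted(times), "spike times must be sorted ascending")
  stopifnot_param(length(times) == 0L || max(times) < duration,
                  "all spike times must be < duration (last = %g, duration = %g)",
                  if (length(times)) max(times) else NA_real_, duration)
  if (anyDuplicated(times)) {
    message(sprintf("spike_train '%s': %d duplicated timestamp(s) retained",
                    unit_id, sum(duplicated(times))))
  }
  structure(list(unit_id = as.character(unit_id), times = times,
                 duration = as.double(duration)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit '%s': %d spikes over %.1f s (%.2f Hz)\n",
              x$unit_id, length(x$times), x$duration,
              length(x$times) / x$duration))
  invisible(x)
}

#' Construct a recording set
#'
#' A collection of simultaneously recorded units from one site (animal x
#' penetration), with the acquisition sampling rate and the animal's group.
#'
#' @param trains list of [spike_train()] objects with unique `unit_id`s.
#' @param sampling_rate acquisition rate in Hz.
#' @param site_id identifier of the recording site.
#' @param group_label `"ChR2"` or `"control"`.
#' @return an object of class `recording_set`.
#' @export
recording_set <- function(trains, sampling_rate, site_id = "site1",
                          group_label = c("ChR2", "control")) {
  group_label <- match.arg(group_label)
  stopifnot_param(is.list(trains) &&
                    all(vapply(trains, inherits, logical(1), "spike_train")),
                  "trains must be a list of spike_train objects")
  ids <- vapply(trains, `[[`, character(1), "unit_id")
  stopifnot_param(!anyDuplicated(ids),
                  "unit_ids must be unique within a recording set")
  stopifnot_param(is.numeric(sampling_rate) && sampling_rate > 0,
                  "sampling_rate must be positive")
  structure(list(trains = trains, sampling_rate = as.double(sampling_rate),
                 site_id = as.character(site_id), group_label = group_label),
            class = "recording_set")
}

#' @export
print.recording_set <- function(x, ...) {
  cat(sprintf("<recording_set> site '%s' (%s): %d units @ %g Hz\n",
              x$site_id, x$group_label, length(x$trains), x$sampling_rate))
  invisible(x)
}

#' Construct a stimulation protocol
#'
#' Light-pulse onset times plus the train/pulse geometry.  Within a train,
#' consecutive onsets are separated by exactly `1/pulse_rate`; trains are
#' separated by `inter_train_gap` and no pulse precedes `baseline_s`.
#'
#' @param pulse_onsets pulse onset times in seconds, strictly ascending.
#' @param train_id integer train membership per pulse.
#' @param pulse_width pulse duration in seconds; must be below `1/pulse_rate`.
#' @param pulse_rate within-train pulse rate in Hz.
#' @param train_spec numeric train durations in seconds (presentation order).
#' @param inter_train_gap gap between train offset and next train onset, s.
#' @param baseline_s pre-stimulation baseline in seconds.
#' @param total_duration recording span in seconds.
#' @return an object of class `stim_protocol`.
#' @export
stim_protocol <- function(pulse_onsets, train_id, pulse_width, pulse_rate,
                          train_spec, inter_train_gap, baseline_s,
                          total_duration) {
  pulse_onsets <- as.double(pulse_onsets)
  stopifnot_param(!is.unsorted(pulse_onsets, strictly = TRUE),
                  "pulse onsets must be strictly ascending")
  stopifnot_param(pulse_rate > 0, "pulse_rate must be positive")
  stopifnot_param(pulse_width > 0 && pulse_width < 1 / pulse_rate,
                  "pulse_width must lie in (0, 1/pulse_rate)")
  stopifnot_param(length(pulse_onsets) == 0L || min(pulse_onsets) >= baseline_s,
                  "no pulse onset may precede the baseline period")
  stopifnot_param(length(train_id) == length(pulse_onsets),
                  "train_id must have one entry per pulse")
  structure(list(pulse_onsets = pulse_onsets,
                 train_id = as.integer(train_id),
                 pulse_width = as.double(pulse_width),
                 pulse_rate = as.double(pulse_rate),
                 train_spec = as.double(train_spec),
                 inter_train_gap = as.double(inter_train_gap),
                 baseline_s = as.double(baseline_s),
                 total_duration = as.double(total_duration)),
            class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(paste0("<stim_protocol> %d pulses @ %g Hz (width %g ms), ",
                     "%d trains of %s s, baseline %g s, total %g s\n"),
              length(x$pulse_onsets), x$pulse_rate, 1000 * x$pulse_width,
              length(x$train_spec),
              paste(x$train_spec, collapse = "/"), x$baseline_s,
              x$total_duration))
  invisible(x)
}

as_onsets <- function(protocol) {
  if (inherits(protocol, "stim_protocol")) return(protocol$pulse_onsets)
  stopifnot_param(is.numeric(protocol), "expected a stim_protocol or onsets")
  as.double(protocol)
}
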