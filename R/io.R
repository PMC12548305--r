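# Readers/writers for the formats the pipeline touches: NeuroSuite-style
# .res/.clu spike files, pulse-event CSVs with a key = value geometry
# config, and per-animal freezing CSVs.  Readers are strict: malformed rows
# raise errors, they are never coerced silently.

read_integer_lines <- function(path, what) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  vals <- suppressWarnings(as.numeric(lines))
  bad <- which(!is.finite(vals) | vals != floor(vals))
  if (length(bad)) {
    of_stop("format_error", "%s '%s': non-integer token at line %d ('%s')",
            what, path, bad[1], lines[bad[1]])
  }
  vals
}

#' Read a NeuroSuite .res/.clu spike file pair
#'
#' `.res` holds one integer sample index per spike; `.clu` holds a first
#' line with the number of clusters followed by one cluster id per spike.
#' Spike times are `sample_index / sampling_rate` seconds.  Clusters 0 and 1
#' (artifact and multi-unit by convention) are excluded by default.
#'
#' @param res_path,clu_path file paths.
#' @param sampling_rate acquisition rate in Hz.  The default corresponds to
#'   a 32,556 samples/s acquisition system.
#' @param exclude_clusters integer cluster ids dropped before building units.
#' @param duration recording span in seconds; defaults to just past the last
#'   spike.
#' @param site_id,group_label recording-set annotations.
#' @return a [recording_set()] with one [spike_train()] per retained cluster
#'   (unit ids `"clu<k>"`), empty (with a warning) if no cluster survives.
#' @export
read_res_clu <- function(res_path, clu_path, sampling_rate = 32556,
                         exclude_clusters = c(0L, 1L), duration = NULL,
                         site_id = "site1", group_label = "ChR2") {
  stopifnot_param(sampling_rate > 0, "sampling_rate must be positive")
  res <- read_integer_lines(res_path, ".res")
  clu <- read_integer_lines(clu_path, ".clu")
  if (length(clu) != length(res) + 1L) {
    of_stop("format_error",
            ".clu must have one header line plus one id per spike: %d ids for %d spikes",
            length(clu) - 1L, length(res))
  }
  ids <- as.integer(clu[-1L])
  times <- res / sampling_rate
  ord <- order(times)
  times <- times[ord]
  ids <- ids[ord]
  keep <- !(ids %in% exclude_clusters)
  if (is.null(duration)) {
    duration <- if (length(times)) max(times) + 1 / sampling_rate else 1
  }
  units <- sort(unique(ids[keep]))
  if (!length(units)) {
    warning("no units retained after cluster exclusion")
    return(recording_set(list(), sampling_rate, site_id, group_label))
  }
  trains <- lapply(units, function(u) {
    spike_train(times[keep & ids == u], duration, sprintf("clu%d", u))
  })
  recording_set(trains, sampling_rate, site_id, group_label)
}

#' Write spike trains as a NeuroSuite .res/.clu pair
#'
#' Times are quantized to integer sample indices (`round(t * rate)`); the
#' round trip through [read_res_clu()] preserves times to within half a
#' sample.  Units are written as clusters 2, 3, ... (0/1 reserved).
#'
#' @param trains list of [spike_train()] objects.
#' @param res_path,clu_path output paths.
#' @param sampling_rate acquisition rate in Hz.
#' @return invisibly, the cluster id assigned to each train.
#' @export
write_res_clu <- function(trains, res_path, clu_path, sampling_rate = 32556) {
  stopifnot_param(sampling_rate > 0, "sampling_rate must be positive")
  all_t <- unlist(lapply(trains, `[[`, "times"))
  clu_of <- rep(seq_along(trains) + 1L,
                vapply(trains, function(x) length(x$times), integer(1)))
  ord <- order(all_t)
  samples <- round(all_t[ord] * sampling_rate)
  writeLines(format(samples, scientific = FALSE, trim = TRUE), res_path)
  writeLines(c(as.character(length(trains) + 2L),
               as.character(clu_of[ord])), clu_path)
  invisible(seq_along(trains) + 1L)
}

#' Write pulse onsets as a two-column CSV
#'
#' @param protocol a [stim_protocol()].
#' @param path output CSV path (columns `onset_s`, `train_id`).
#' @param config_path optional path for a key = value geometry sidecar
#'   (pulse_rate, pulse_width, inter_train_gap, baseline_s, total_duration).
#' @export
write_events_csv <- function(protocol, path, config_path = NULL) {
  stopifnot_param(inherits(protocol, "stim_protocol"),
                  "protocol must be a stim_protocol")
  write.csv(data.frame(onset_s = protocol$pulse_onsets,
                       train_id = protocol$train_id),
            path, row.names = FALSE, quote = FALSE)
  if (!is.null(config_path)) {
    writeLines(c(sprintf("pulse_rate = %.10g", protocol$pulse_rate),
                 sprintf("pulse_width = %.10g", protocol$pulse_width),
                 sprintf("inter_train_gap = %.10g", protocol$inter_train_gap),
                 sprintf("baseline_s = %.10g", protocol$baseline_s),
                 sprintf("total_duration = %.10g", protocol$total_duration)),
               config_path)
  }
  invisible(path)
}

# Parse a flat "key = value" config file (TOML-style scalars only).
read_kv_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_][A-Za-z0-9_.]*)\\s*=\\s*(.+?)\\s*$", lines))
  bad <- which(vapply(kv, length, integer(1)) != 3L)
  if (length(bad)) {
    of_stop("format_error", "config '%s': cannot parse line %d", path, bad[1])
  }
  vals <- lapply(kv, function(m) {
    v <- m[3]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else gsub('^"|"$', "", v)
  })
  setNames(vals, vapply(kv, `[[`, character(1), 2))
}

#' Read a pulse-event CSV into a stimulation protocol
#'
#' @param path CSV with header and columns `onset_s`, `train_id`.  Unsorted
#'   onsets are sorted with a warning; negative onsets are an error.
#' @param config_path optional key = value sidecar supplying the geometry;
#'   explicit arguments below override it.
#' @param pulse_rate,pulse_width,inter_train_gap,baseline_s geometry fields
#'   (see [stim_protocol()]); defaults are used for fields found in neither
#'   place.
#' @return a [stim_protocol()].
#' @export
read_events_csv <- function(path, config_path = NULL, pulse_rate = NULL,
                            pulse_width = NULL, inter_train_gap = NULL,
                            baseline_s = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("onset_s", "train_id") %in% names(df))) {
    of_stop("format_error",
            "events CSV must have columns onset_s, train_id (found: %s)",
            paste(names(df), collapse = ", "))
  }
  if (nrow(df) && any(df$onset_s < 0)) {
    of_stop("format_error", "negative pulse onset at row %d",
            which(df$onset_s < 0)[1])
  }
  if (is.unsorted(df$onset_s)) {
    warning("pulse onsets were not sorted; sorting")
    df <- df[order(df$onset_s), , drop = FALSE]
  }
  cfg <- if (!is.null(config_path)) read_kv_config(config_path) else list()
  pick <- function(arg, key, default) {
    if (!is.null(arg)) arg else if (!is.null(cfg[[key]])) cfg[[key]] else default
  }
  rate <- pick(pulse_rate, "pulse_rate", 20)
  onsets <- df$onset_s
  baseline <- pick(baseline_s, "baseline_s",
                   if (nrow(df)) min(onsets) else 0)
  total <- if (!is.null(cfg$total_duration)) cfg$total_duration else {
    if (nrow(df)) max(onsets) + 30 else baseline
  }
  stim_protocol(pulse_onsets = onsets, train_id = df$train_id,
                pulse_width = pick(pulse_width, "pulse_width", 0.010),
                pulse_rate = rate,
                train_spec = as.double(tapply(onsets, df$train_id, length)) / rate,
                inter_train_gap = pick(inter_train_gap, "inter_train_gap", 30),
                baseline_s = baseline, total_duration = total)
}

#' Read and validate a freezing-table CSV
#'
#' Required columns: `animal_id`, `group`, `stage`, `percent_freezing`.
#' Percentages must lie in `[0, 100]` and `(animal_id, stage)` pairs must be
#' unique (add a `session` column to disambiguate repeated stages).
#'
#' @param path CSV path.
#' @param stage_vocabulary optional character vector; stages outside it are
#'   an error (use [protocol_stages()] for the standard vocabularies).
#' @return a validated freezing-table data.frame.
#' @export
read_freezing_csv <- function(path, stage_vocabulary = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_freezing(df, stage_vocabulary)
}

#' Validate a freezing table
#'
#' @param df data.frame with columns `animal_id`, `group`, `stage`,
#'   `percent_freezing` (optionally `session`).
#' @param stage_vocabulary optional allowed stage labels.
#' @return the validated data.frame, invisibly unchanged.
#' @export
validate_freezing <- function(df, stage_vocabulary = NULL) {
  need <- c("animal_id", "group", "stage", "percent_freezing")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    of_stop("format_error", "freezing table missing column(s): %s",
            paste(miss, collapse = ", "))
  }
  bad <- which(!is.finite(df$percent_freezing) | df$percent_freezing < 0 |
                 df$percent_freezing > 100)
  if (length(bad)) {
    of_stop("validation_error",
            "percent_freezing outside [0, 100] at row %d (animal %s, stage %s: %g)",
            bad[1], df$animal_id[bad[1]], df$stage[bad[1]],
            df$percent_freezing[bad[1]])
  }
  key <- if ("session" %in% names(df)) {
    paste(df$animal_id, df$session, df$stage)
  } else {
    paste(df$animal_id, df$stage)
  }
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    of_stop("validation_error", "duplicated (animal, stage) pair: %s", d)
  }
  if (!is.null(stage_vocabulary)) {
    unk <- setdiff(unique(df$stage), stage_vocabulary)
    if (length(unk)) {
      of_stop("validation_error", "unknown stage label(s): %s (expected: %s)",
              paste(unk, collapse = ", "),
              paste(stage_vocabulary, collapse = ", "))
    }
  }
  df
}

#' Write a freezing table as CSV
#'
#' @param df freezing-table data.frame (validated before writing).
#' @param path output path.
#' @export
write_freezing_csv <- function(df, path) {
  validate_freezing(df)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
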