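# Pipeline orchestration: population-level detection, end-to-end report
# runs, and run manifests.  Every stochastic stage derives its seed from
# the master seed via child_seed(), so a whole run is reproducible from a
# single integer.

#' Run the responsiveness test on every unit of a population
#'
#' @param trains list of [spike_train()] objects.
#' @param protocol a [stim_protocol()] or onset vector.
#' @param config a [jitter_config()]; its seed is re-derived per unit from
#'   `seed`.
#' @param seed master seed for the surrogate draws.
#' @param classify type responsive units (see [detect_response()]).
#' @return list of [response_call] objects, one per train.
#' @export
detect_population <- function(trains, protocol, config = jitter_config(),
                              seed = 1, classify = TRUE) {
  lapply(seq_along(trains), function(i) {
    cfg <- config
    cfg$seed <- child_seed(seed, i)
    detect_response(trains[[i]], protocol, cfg, classify = classify)
  })
}

#' Convert response calls to a data.frame
#'
#' @param calls list of [response_call] objects.
#' @return data.frame with columns `unit_id`, `responsive`, `response_type`,
#'   `first_sig_bin_ms`.
#' @export
calls_as_df <- function(calls) {
  data.frame(
    unit_id = vapply(calls, `[[`, character(1), "unit_id"),
    responsive = vapply(calls, `[[`, logical(1), "responsive"),
    response_type = vapply(calls, `[[`, character(1), "response_type"),
    first_sig_bin_ms = vapply(calls, function(cl) {
      if (length(cl$significant_bins)) min(cl$significant_bins) else NA_real_
    }, double(1)),
    stringsAsFactors = FALSE)
}

#' Write a run manifest
#'
#' Records the master seed, the package version and the run parameters as
#' JSON next to the run's outputs, so any run can be reproduced from its
#' manifest alone.
#'
#' @param out_dir output directory.
#' @param params named list of run parameters.
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, params) {
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    c(list(package = "optofear",
           version = as.character(packageVersion("optofear"))), params),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' End-to-end report run on synthetic data
#'
#' Generates a stimulation protocol, a ground-truth spike population and a
#' freezing table, runs detection, chance calibration and the behavioral
#' comparisons, and writes CSV outputs plus a manifest into `out_dir`.
#' Numeric outputs are byte-identical across runs with the same seed.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed.
#' @param n_units number of simulated units.
#' @param n_shuffles ISI-shuffle replicates for the chance estimate.
#' @param protocol_name behavioral protocol for the freezing arm.
#' @return invisibly, a list with the in-memory results (`calls_df`,
#'   `summary`, `shuffle`, `behavior`, `pooling`).
#' @export
run_report <- function(out_dir, seed = 1, n_units = 50, n_shuffles = 10,
                       protocol_name = "ABA") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  protocol <- gen_protocol(seed = child_seed(seed, 1L))
  pop <- gen_population(n_units, frac_excited = 0.08, frac_inhibited = 0.04,
                        protocol, seed = child_seed(seed, 2L))
  calls <- detect_population(pop$trains, protocol, seed = child_seed(seed, 3L))
  cdf <- calls_as_df(calls)
  cdf$true_class <- vapply(pop$ground_truth, `[[`, character(1), "class")
  write.csv(cdf, file.path(out_dir, "calls.csv"), row.names = FALSE)
  summ <- summarize_population(calls)
  shuffle <- chance_fraction(pop$trains, protocol, n_shuffles = n_shuffles,
                             seed = child_seed(seed, 4L))
  write.csv(data.frame(replicate = seq_len(n_shuffles),
                       chance_fraction = shuffle$chance_fractions),
            file.path(out_dir, "chance.csv"), row.names = FALSE)
  summary_df <- data.frame(
    n_units = summ$total, responsive = summ$responsive,
    fraction = summ$fraction,
    excited = summ$by_type[["excited"]],
    inhibited_rebound = summ$by_type[["inhibited_rebound"]],
    observed_fraction = shuffle$observed_fraction,
    chance_fraction = mean(shuffle$chance_fractions),
    corrected_fraction = shuffle$observed_fraction -
      mean(shuffle$chance_fractions))
  write.csv(summary_df, file.path(out_dir, "summary.csv"), row.names = FALSE)

  tbl <- gen_freezing_dataset(freezing_spec(seed = child_seed(seed, 5L)),
                              protocol_name)
  write_freezing_csv(tbl, file.path(out_dir, "freezing.csv"))
  pooling <- pool_controls_check(tbl)
  behavior <- if (pooling$pooled) {
    timecourse_compare(pooling$table)
  } else {
    NULL
  }
  if (!is.null(behavior)) {
    write.csv(behavior, file.path(out_dir, "behavior_stats.csv"),
              row.names = FALSE)
  }
  write.csv(pooling$comparisons, file.path(out_dir, "control_pooling.csv"),
            row.names = FALSE)
  write_manifest(out_dir, list(subcommand = "report", seed = seed,
                               n_units = n_units, n_shuffles = n_shuffles,
                               protocol_name = protocol_name))
  invisible(list(calls_df = cdf, summary = summary_df, shuffle = shuffle,
                 behavior = behavior, pooling = pooling))
}
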