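# Synthetic-data generators: stimulation protocols, ground-truth spike
# populations, and freezing tables with the group structure the behavioral
# statistics assume.  All generators are pure functions of (parameters,
# seed).

#' Generate a pulse-train stimulation protocol
#'
#' One trial: a silent baseline followed by 20 Hz pulse trains of several
#' durations presented once each in seed-determined random order, separated
#' by a fixed inter-train gap.  The defaults reproduce the acute-experiment
#' design: trains of 0.5, 1, 5 and 15 s at 20 Hz (430 pulses in total) after
#' a 5-min baseline, 30 s apart.
#'
#' @param train_spec numeric vector of train durations in seconds.
#' @param pulse_rate within-train pulse rate, Hz.
#' @param pulse_width pulse duration, seconds.  The pulse width is not used
#'   to place onsets but bounds response latencies downstream.
#' @param inter_train_gap seconds between the end of a train and the next
#'   train's first pulse.
#' @param baseline_s pre-stimulation baseline, seconds.
#' @param seed integer seed controlling the train order.
#' @return a [stim_protocol()].  `total_duration` extends one gap past the
#'   last train so offset-locked analyses have room.
#' @export
#' @examples
#' p <- gen_protocol(seed = 1)
#' length(p$pulse_onsets)  # 430
gen_protocol <- function(train_spec = c(0.5, 1, 5, 15), pulse_rate = 20,
                         pulse_width = 0.010, inter_train_gap = 30,
                         baseline_s = 300, seed = 1) {
  stopifnot_param(length(train_spec) >= 1L && all(train_spec > 0),
                  "train durations must be positive")
  stopifnot_param(pulse_rate > 0, "pulse_rate must be positive")
  stopifnot_param(pulse_width > 0 && pulse_width < 1 / pulse_rate,
                  "pulse_width must be < 1/pulse_rate")
  stopifnot_param(inter_train_gap >= 0 && baseline_s >= 0,
                  "gap and baseline must be non-negative")
  set.seed(child_seed(seed, 0L))
  order_idx <- sample.int(length(train_spec))
  durations <- train_spec[order_idx]
  onsets <- vector("list", length(durations))
  ids <- vector("list", length(durations))
  start <- baseline_s
  for (i in seq_along(durations)) {
    n <- round(durations[i] * pulse_rate)
    onsets[[i]] <- start + (seq_len(n) - 1) / pulse_rate
    ids[[i]] <- rep.int(i, n)
    start <- start + durations[i] + inter_train_gap
  }
  stim_protocol(pulse_onsets = unlist(onsets), train_id = unlist(ids),
                pulse_width = pulse_width, pulse_rate = pulse_rate,
                train_spec = durations, inter_train_gap = inter_train_gap,
                baseline_s = baseline_s, total_duration = start)
}

#' Generate a background spike train (gamma renewal process)
#'
#' Inter-spike intervals are gamma distributed with mean `1/rate` and shape
#' `isi_shape`; shape 1 is a Poisson process, shape below 1 gives bursty
#' trains (ISI coefficient of variation `1/sqrt(shape)`).
#'
#' @param rate mean firing rate, Hz (`rate = 0` yields an empty train).
#' @param duration recording span, seconds.
#' @param isi_shape gamma shape of the ISI distribution, positive.
#' @param seed integer seed.
#' @param unit_id identifier for the generated unit.
#' @return a [spike_train()] truncated to `[0, duration)`.
#' @export
gen_background_train <- function(rate, duration, isi_shape = 1, seed = 1,
                                 unit_id = "u1") {
  stopifnot_param(rate >= 0, "rate must be non-negative")
  stopifnot_param(duration > 0, "duration must be positive")
  stopifnot_param(isi_shape > 0, "isi_shape must be positive")
  if (rate == 0) return(spike_train(numeric(0), duration, unit_id))
  set.seed(child_seed(seed, 0L))
  scale <- 1 / (rate * isi_shape)
  n_guess <- ceiling(rate * duration + 4 * sqrt(rate * duration) + 25)
  times <- cumsum(rgamma(n_guess, shape = isi_shape, scale = scale))
  while (length(times) && times[length(times)] < duration) {
    times <- c(times, times[length(times)] +
                 cumsum(rgamma(n_guess, shape = isi_shape, scale = scale)))
  }
  spike_train(times[times < duration], duration, unit_id)
}

#' Describe a ground-truth unit
#'
#' The latent response class and parameters of one simulated unit, kept for
#' detector scoring.  `"excited"` units add a short-latency spike after pulse
#' onsets; `"inhibited_rebound"` units lose background spikes during the
#' pulse and add a rebound spike just after pulse offset; `"none"` units are
#' pure background (probability forced to 0, suppression factor to 1).
#'
#' @param unit_id identifier.
#' @param class one of `"none"`, `"excited"`, `"inhibited_rebound"`.
#' @param response_latency seconds from pulse onset (excited) or from pulse
#'   offset (rebound) to the injected spike.
#' @param per_pulse_response_prob probability an individual pulse evokes the
#'   injected spike.
#' @param suppression_factor multiplicative within-pulse rate factor in
#'   `[0, 1]` for inhibited units (0 = complete silencing).
#' @param background_rate background firing rate, Hz.
#' @param isi_shape gamma ISI shape of the background process.
#' @return an object of class `ground_truth_unit`.
#' @export
ground_truth_unit <- function(unit_id, class = c("none", "excited",
                                                 "inhibited_rebound"),
                              response_latency = 0.0015,
                              per_pulse_response_prob = 0.3,
                              suppression_factor = 0.2,
                              background_rate = 5, isi_shape = 1) {
  class <- match.arg(class)
  if (class == "none") {
    per_pulse_response_prob <- 0
    suppression_factor <- 1
  }
  stopifnot_param(per_pulse_response_prob >= 0 && per_pulse_response_prob <= 1,
                  "per_pulse_response_prob must be in [0, 1]")
  stopifnot_param(suppression_factor >= 0 && suppression_factor <= 1,
                  "suppression_factor must be in [0, 1]")
  stopifnot_param(response_latency >= 0, "response_latency must be >= 0")
  stopifnot_param(background_rate >= 0 && isi_shape > 0,
                  "background_rate must be >= 0 and isi_shape > 0")
  structure(list(unit_id = as.character(unit_id), class = class,
                 response_latency = response_latency,
                 per_pulse_response_prob = per_pulse_response_prob,
                 suppression_factor = suppression_factor,
                 background_rate = background_rate, isi_shape = isi_shape),
            class = "ground_truth_unit")
}

#' Inject ground-truth responses into a background train
#'
#' Excited units: with `per_pulse_response_prob`, one extra spike at
#' `onset + response_latency` plus truncated-positive Normal latency noise
#' (SD `latency_sd`), keeping injected responses mostly within one 1-ms bin.
#' Inhibited-rebound units: background spikes inside each pulse are deleted
#' with probability `1 - suppression_factor`, and with
#' `per_pulse_response_prob` one rebound spike is added uniformly within
#' `(offset, offset + rebound_span]` — inside the 12-ms test window for a
#' 10-ms pulse.
#'
#' @param train background [spike_train()].
#' @param protocol [stim_protocol()] sharing the train's time axis.
#' @param ground_truth a [ground_truth_unit()].
#' @param seed integer seed for the per-pulse Bernoulli draws and noise.
#' @param latency_sd SD of the excited-latency noise, seconds.
#' @param rebound_span span after pulse offset receiving rebound spikes, s.
#' @return a [spike_train()] with responses injected, re-sorted.
#' @export
inject_responses <- function(train, protocol, ground_truth, seed = 1,
                             latency_sd = 0.0002, rebound_span = 0.002) {
  stopifnot_param(inherits(train, "spike_train"), "train must be a spike_train")
  stopifnot_param(inherits(protocol, "stim_protocol"),
                  "protocol must be a stim_protocol")
  stopifnot_param(inherits(ground_truth, "ground_truth_unit"),
                  "ground_truth must be a ground_truth_unit")
  gt <- ground_truth
  if (gt$class == "none") return(train)
  period <- 1 / protocol$pulse_rate
  stopifnot_param(gt$response_latency < period,
                  "response latency (%g s) must be below the pulse period (%g s)",
                  gt$response_latency, period)
  set.seed(child_seed(seed, 0L))
  onsets <- protocol$pulse_onsets
  times <- train$times
  evoked <- runif(length(onsets)) < gt$per_pulse_response_prob
  if (gt$class == "excited") {
    lat <- gt$response_latency +
      rnorm_trunc_pos(sum(evoked), sd = latency_sd,
                      lower = -gt$response_latency)
    times <- c(times, onsets[evoked] + lat)
  } else {  # inhibited_rebound
    idx <- findInterval(times, onsets)
    d <- times - onsets[pmax(idx, 1L)]
    inside <- idx > 0L & d >= 0 & d < protocol$pulse_width
    drop <- inside & (runif(length(times)) < (1 - gt$suppression_factor))
    times <- times[!drop]
    rebound <- onsets[evoked] + protocol$pulse_width +
      runif(sum(evoked), 0, rebound_span)
    times <- c(times, rebound)
  }
  times <- sort(times)
  times <- times[times < train$duration]
  spike_train(times, train$duration, train$unit_id)
}

# Normal(0, sd) noise truncated to be > lower (rejection sampling).
rnorm_trunc_pos <- function(n, sd, lower) {
  if (n == 0L) return(numeric(0))
  x <- rnorm(n, sd = sd)
  bad <- which(x <= lower)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), sd = sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}

#' Generate a ground-truth spike population
#'
#' Draws `n_units` background trains over the protocol span and injects
#' responses into exact class counts: `round(frac_excited * n_units)` excited
#' units, `round(frac_inhibited * n_units)` inhibited-rebound units, the rest
#' untouched.  Class assignment is a seed-determined permutation.
#'
#' @param n_units number of units.
#' @param frac_excited,frac_inhibited class fractions in `[0, 1]`, summing to
#'   at most 1.
#' @param protocol [stim_protocol()] defining the time axis.
#' @param background_params list with elements `rate_range` (Hz bounds the
#'   per-unit background rate is drawn from), `isi_shape`, `response_prob`,
#'   `latency` (s), `suppression_factor`.
#' @param seed integer master seed.
#' @return list with `trains` (list of [spike_train()]) and `ground_truth`
#'   (list of [ground_truth_unit()], same order).
#' @export
gen_population <- function(n_units, frac_excited, frac_inhibited, protocol,
                           background_params = list(), seed = 1) {
  stopifnot_param(n_units >= 1, "n_units must be at least 1")
  stopifnot_param(frac_excited >= 0 && frac_excited <= 1 &&
                    frac_inhibited >= 0 && frac_inhibited <= 1,
                  "class fractions must lie in [0, 1]")
  stopifnot_param(frac_excited + frac_inhibited <= 1,
                  "class fractions must sum to at most 1")
  stopifnot_param(inherits(protocol, "stim_protocol"),
                  "protocol must be a stim_protocol")
  bp <- modifyList(list(rate_range = c(2, 8), isi_shape = 1,
                        response_prob = 0.3, latency = 0.0015,
                        suppression_factor = 0.2), background_params)
  n_exc <- round(frac_excited * n_units)
  n_inh <- round(frac_inhibited * n_units)
  classes <- rep("none", n_units)
  set.seed(child_seed(seed, 0L))
  picks <- sample.int(n_units, n_exc + n_inh)
  classes[picks[seq_len(n_exc)]] <- "excited"
  if (n_inh > 0) classes[picks[n_exc + seq_len(n_inh)]] <- "inhibited_rebound"
  rates <- runif(n_units, bp$rate_range[1], bp$rate_range[2])
  trains <- vector("list", n_units)
  gts <- vector("list", n_units)
  for (i in seq_len(n_units)) {
    uid <- sprintf("u%03d", i)
    gt <- ground_truth_unit(uid, classes[i],
                            response_latency = bp$latency,
                            per_pulse_response_prob = bp$response_prob,
                            suppression_factor = bp$suppression_factor,
                            background_rate = rates[i],
                            isi_shape = bp$isi_shape)
    bg <- gen_background_train(rates[i], protocol$total_duration,
                               isi_shape = bp$isi_shape,
                               seed = child_seed(seed, 2L * i), unit_id = uid)
    trains[[i]] <- inject_responses(bg, protocol, gt,
                                    seed = child_seed(seed, 2L * i + 1L))
    gts[[i]] <- gt
  }
  list(trains = trains, ground_truth = gts)
}

# ---------------------------------------------------------------------------
# Freezing tables

# Stage vocabulary and laser annotation per behavioral protocol.  ABCA: cued
# conditioning, extinction in B, renewal tests in C then A with the laser on
# during each pre-CS baseline.  ABA: single renewal test in A.  contextual:
# context-only conditioning and a 6-min recall with laser during the first
# four minutes.
protocol_stage_table <- function(protocol_name) {
  tabs <- list(
    ABCA = data.frame(
      stage = c("conditioning", "extinction_first", "extinction_last",
                "renewalC_baseline", "renewalC_CS",
                "renewalA_baseline", "renewalA_CS"),
      laser = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
      stringsAsFactors = FALSE),
    ABA = data.frame(
      stage = c("conditioning", "extinction_first", "extinction_last",
                "baseline_laser", "CS"),
      laser = c(FALSE, FALSE, FALSE, TRUE, FALSE),
      stringsAsFactors = FALSE),
    contextual = data.frame(
      stage = c("baseline", "ITI", paste0("recall_minute_", 1:6)),
      laser = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
      stringsAsFactors = FALSE)
  )
  if (!protocol_name %in% names(tabs)) {
    of_stop("invalid_parameter",
            "unknown protocol '%s'; valid protocols: %s", protocol_name,
            paste(names(tabs), collapse = ", "))
  }
  tabs[[protocol_name]]
}

#' Stage vocabulary of a behavioral protocol
#'
#' @param protocol_name `"ABCA"`, `"ABA"` or `"contextual"`.
#' @return data.frame with columns `stage` and `laser` (whether the laser is
#'   on during that stage for stimulated animals).
#' @export
protocol_stages <- function(protocol_name) protocol_stage_table(protocol_name)

default_stage_means <- function(protocol_name) {
  switch(protocol_name,
         ABCA = c(conditioning = 60, extinction_first = 75,
                  extinction_last = 40, renewalC_baseline = 50,
                  renewalC_CS = 55, renewalA_baseline = 55, renewalA_CS = 50),
         ABA = c(conditioning = 60, extinction_first = 75,
                 extinction_last = 40, baseline_laser = 55, CS = 50),
         contextual = c(baseline = 10, ITI = 55,
                        setNames(rep(60, 6), paste0("recall_minute_", 1:6))))
}

#' Specify a synthetic freezing-table effect structure
#'
#' Three groups: stimulated `ChR2` animals and two controls (`control_GFP`,
#' virus control; `control_nolaser`, stimulation control) that share
#' identical stage means — the structure under which control pooling is
#' legitimate.  At laser-on stages the ChR2 mean is shifted down by
#' `laser_stage_delta`.
#'
#' @param group_sizes named counts for `ChR2`, `control_GFP`,
#'   `control_nolaser`.
#' @param stage_means named percent-freezing means per stage; `NULL` uses the
#'   protocol defaults.
#' @param stage_sd between-animal SD of percent freezing.
#' @param laser_stage_delta percent-freezing reduction applied to ChR2 at
#'   laser-on stages.
#' @param seed integer seed.
#' @return an object of class `freezing_spec`.
#' @export
freezing_spec <- function(group_sizes = c(ChR2 = 10, control_GFP = 9,
                                          control_nolaser = 9),
                          stage_means = NULL, stage_sd = 10,
                          laser_stage_delta = 20, seed = 1) {
  stopifnot_param(all(c("ChR2", "control_GFP", "control_nolaser") %in%
                        names(group_sizes)),
                  "group_sizes must name ChR2, control_GFP, control_nolaser")
  stopifnot_param(all(group_sizes >= 0), "group sizes must be non-negative")
  stopifnot_param(stage_sd >= 0, "stage_sd must be non-negative")
  structure(list(group_sizes = group_sizes, stage_means = stage_means,
                 stage_sd = stage_sd, laser_stage_delta = laser_stage_delta,
                 seed = seed),
            class = "freezing_spec")
}

#' Generate a synthetic per-animal, per-stage freezing table
#'
#' Per-animal stage values are drawn Normal(group stage mean, `stage_sd`)
#' and clipped to `[0, 100]`; ChR2 means at laser-on stages are shifted by
#' `-laser_stage_delta`.  The two control groups share stage means exactly.
#'
#' @param spec a [freezing_spec()].
#' @param protocol_name `"ABCA"`, `"ABA"` or `"contextual"`.
#' @return a freezing table: data.frame with columns `animal_id`, `group`,
#'   `stage`, `percent_freezing`.
#' @export
gen_freezing_dataset <- function(spec = freezing_spec(),
                                 protocol_name = "ABA") {
  stopifnot_param(inherits(spec, "freezing_spec"),
                  "spec must be a freezing_spec")
  stages <- protocol_stage_table(protocol_name)
  means <- spec$stage_means
  if (is.null(means)) means <- default_stage_means(protocol_name)
  missing_stage <- setdiff(stages$stage, names(means))
  stopifnot_param(length(missing_stage) == 0L,
                  "stage_means missing stages: %s",
                  paste(missing_stage, collapse = ", "))
  set.seed(child_seed(spec$seed, 0L))
  rows <- list()
  counter <- 0L
  for (grp in c("ChR2", "control_GFP", "control_nolaser")) {
    n <- spec$group_sizes[[grp]]
    if (n == 0) next
    for (a in seq_len(n)) {
      counter <- counter + 1L
      aid <- sprintf("%s_%02d", grp, a)
      mu <- means[stages$stage]
      if (grp == "ChR2") mu <- mu - spec$laser_stage_delta * stages$laser
      val <- rnorm(nrow(stages), mean = mu, sd = spec$stage_sd)
      val <- pmin(pmax(val, 0), 100)
      rows[[counter]] <- data.frame(animal_id = aid, group = grp,
                                    stage = stages$stage,
                                    percent_freezing = val,
                                    stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
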