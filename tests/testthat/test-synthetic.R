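test_that("protocol geometry: counts, spacing, baseline, determinism", {
  p <- gen_protocol(seed = 3)
  expect_equal(length(p$pulse_onsets), 430)
  expect_equal(sort(as.vector(table(p$train_id))), c(10, 20, 100, 300))
  # pulse counts conserved: per-train counts sum to the onset count
  expect_equal(sum(table(p$train_id)), length(p$pulse_onsets))
  expect_true(all(diff(p$pulse_onsets) > 0))
  within <- split(p$pulse_onsets, p$train_id)
  for (tr in within) {
    if (length(tr) > 1) expect_equal(diff(tr), rep(1 / 20, length(tr) - 1))
  }
  expect_gte(min(p$pulse_onsets), p$baseline_s)
  expect_lt(p$pulse_width, 1 / p$pulse_rate)
  expect_identical(p$pulse_onsets, gen_protocol(seed = 3)$pulse_onsets)
  expect_false(identical(p$train_spec, gen_protocol(seed = 4)$train_spec) &&
                 identical(p$pulse_onsets, gen_protocol(seed = 4)$pulse_onsets))
})

test_that("single 1-s train at 20 Hz after 300-s baseline spans 300.0-300.95 s", {
  p <- gen_protocol(train_spec = 1, baseline_s = 300, seed = 1)
  expect_equal(length(p$pulse_onsets), 20)
  expect_equal(p$pulse_onsets[1], 300.0)
  expect_equal(p$pulse_onsets[20], 300.95)
})

test_that("protocol rejects invalid geometry", {
  expect_error(gen_protocol(train_spec = c(1, -1)), "positive")
  expect_error(gen_protocol(pulse_rate = 0), "positive")
  expect_error(gen_protocol(pulse_width = 0.06), "pulse_width")
})

test_that("background train matches renewal-process expectations", {
  expect_length(gen_background_train(0, 100, seed = 1)$times, 0)
  # mean count over seeds vs the Poisson oracle (rate x duration)
  counts <- vapply(1:300, function(s) {
    length(gen_background_train(5, 600, isi_shape = 1, seed = s)$times)
  }, double(1))
  se <- sqrt(3000 / 300)  # Poisson variance / n seeds
  expect_lt(abs(mean(counts) - 3000), 3 * se)
  # bursty trains have larger ISI CV; oracle: gamma CV = 1/sqrt(shape)
  cv <- function(shape, s) {
    isi <- diff(gen_background_train(5, 600, isi_shape = shape, seed = s)$times)
    sd(isi) / mean(isi)
  }
  cvs_b <- vapply(1:20, function(s) cv(0.3, s), double(1))
  cvs_p <- vapply(1:20, function(s) cv(1, s), double(1))
  expect_gt(mean(cvs_b), mean(cvs_p))
  expect_lt(abs(mean(cvs_b) - 1 / sqrt(0.3)), 0.2)
  expect_lt(abs(mean(cvs_p) - 1), 0.1)
})

test_that("response injection follows the ground-truth class contract", {
  p <- toy_protocol(train_spec = c(0.5, 1, 5, 15), baseline_s = 300)
  bg <- gen_background_train(5, p$total_duration, seed = 11)
  none <- ground_truth_unit("u1", "none")
  expect_identical(inject_responses(bg, p, none, seed = 1)$times, bg$times)
  # excited at prob 1 on an empty background: one spike ~latency after each onset
  empty <- spike_train(numeric(0), p$total_duration)
  exc <- ground_truth_unit("u1", "excited", response_latency = 0.0015,
                           per_pulse_response_prob = 1)
  out <- inject_responses(empty, p, exc, seed = 2)
  expect_length(out$times, 430)
  rel <- out$times - p$pulse_onsets[findInterval(out$times, p$pulse_onsets)]
  expect_true(all(rel > 0 & rel < 0.0015 + 6 * 0.0002))
  # full suppression removes every within-pulse background spike
  inh <- ground_truth_unit("u1", "inhibited_rebound", suppression_factor = 0,
                           per_pulse_response_prob = 0)
  sup <- inject_responses(bg, p, inh, seed = 3)
  idx <- findInterval(sup$times, p$pulse_onsets)
  d <- sup$times - p$pulse_onsets[pmax(idx, 1)]
  expect_false(any(idx > 0 & d >= 0 & d < p$pulse_width))
  # rebound spikes land within 2 ms of pulse offset
  reb <- ground_truth_unit("u1", "inhibited_rebound", suppression_factor = 1,
                           per_pulse_response_prob = 1)
  out2 <- inject_responses(empty, p, reb, seed = 4)
  rel2 <- out2$times - p$pulse_onsets[findInterval(out2$times, p$pulse_onsets)]
  expect_true(all(rel2 > p$pulse_width & rel2 <= p$pulse_width + 0.002))
  # latency must stay below the pulse period
  late <- ground_truth_unit("u1", "excited", response_latency = 0.06,
                            per_pulse_response_prob = 1)
  expect_error(inject_responses(bg, p, late, seed = 1), "latency")
})

test_that("population generator hits exact class counts, deterministically", {
  p <- toy_protocol()
  pop <- gen_population(25, 0.08, 0.04, p, seed = 5)
  cls <- vapply(pop$ground_truth, `[[`, character(1), "class")
  expect_equal(sum(cls == "excited"), 2)
  expect_equal(sum(cls == "inhibited_rebound"), 1)
  expect_equal(sum(cls == "none"), 22)
  pop2 <- gen_population(25, 0.08, 0.04, p, seed = 5)
  expect_identical(cls, vapply(pop2$ground_truth, `[[`, character(1), "class"))
  expect_identical(pop$trains[[1]]$times, pop2$trains[[1]]$times)
  pop0 <- gen_population(10, 0, 0, p, seed = 1)
  expect_true(all(vapply(pop0$ground_truth, `[[`, character(1), "class") == "none"))
  expect_error(gen_population(10, 0.8, 0.4, p), "sum")
  expect_error(gen_population(10, -0.1, 0, p), "\\[0, 1\\]")
})

test_that("freezing tables honor stage means, laser delta, and clipping", {
  # sd 0: every animal equals its group stage mean, ChR2 shifted at laser stages
  tbl <- gen_freezing_dataset(freezing_spec(stage_sd = 0,
                                            laser_stage_delta = 20), "ABA")
  stages <- protocol_stages("ABA")
  means <- tapply(tbl$percent_freezing, list(tbl$group, tbl$stage), unique)
  for (s in stages$stage) {
    expect_equal(means["control_GFP", s], means["control_nolaser", s])
    expected_shift <- if (stages$laser[stages$stage == s]) 20 else 0
    expect_equal(means["control_GFP", s] - means["ChR2", s], expected_shift)
  }
  # delta 0: no group shift anywhere
  tbl0 <- gen_freezing_dataset(freezing_spec(stage_sd = 0,
                                             laser_stage_delta = 0), "ABA")
  m0 <- tapply(tbl0$percent_freezing, list(tbl0$group, tbl0$stage), unique)
  expect_true(all(abs(m0["ChR2", ] - m0["control_GFP", ]) < 1e-12))
  # values clipped to [0, 100]
  hi <- freezing_spec(stage_means = NULL, stage_sd = 40, seed = 2)
  tblh <- gen_freezing_dataset(hi, "ABA")
  expect_true(all(tblh$percent_freezing >= 0 & tblh$percent_freezing <= 100))
  expect_error(gen_freezing_dataset(freezing_spec(), "XYZ"),
               "ABCA, ABA, contextual")
})
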