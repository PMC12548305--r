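test_that("surrogate matrix geometry, empty train, and displacement bounds", {
  p <- toy_protocol()
  cfg <- jitter_config(seed = 2)
  empty <- spike_train(numeric(0), p$total_duration)
  surr <- jitter_surrogates(empty, p, cfg)
  expect_equal(dim(surr), c(100, 12))
  expect_true(all(surr == 0))
  # displacement magnitudes lie in [1, 10] ms, both signs occur; count conserved
  set.seed(1)
  times <- sort(runif(500, 0, 50))
  jt <- optofear:::jitter_spikes(times, cfg)
  expect_length(jt, 500)
  mag <- abs(jt - times) * 1000
  expect_true(all(mag >= 1 - 1e-9 & mag <= 10 + 1e-9))
  expect_true(any(jt > times) && any(jt < times))
  cfg_pos <- jitter_config(jitter_sign = "positive", seed = 2)
  jt2 <- optofear:::jitter_spikes(times, cfg_pos)
  expect_true(all(jt2 > times))
  expect_error(jitter_config(n_surrogates = 1), "at least 2")
  expect_warning(jitter_surrogates(random_train(1), p,
                                   jitter_config(n_surrogates = 10)),
                 "unstable")
})

test_that("detection is deterministic and calls obvious cases correctly", {
  p <- gen_protocol(seed = 1)
  cfg <- jitter_config(seed = 5)
  zero <- spike_train(numeric(0), p$total_duration)
  expect_false(detect_response(zero, p, cfg)$responsive)
  # injected excited unit: significant bin at its latency
  bg <- gen_background_train(5, p$total_duration, seed = 12)
  gt <- ground_truth_unit("u1", "excited", response_latency = 0.0015,
                          per_pulse_response_prob = 0.5)
  tr <- inject_responses(bg, p, gt, seed = 13)
  call <- detect_response(tr, p, cfg)
  expect_true(call$responsive)
  expect_true(1 %in% call$significant_bins)
  expect_equal(call$response_type, "excited")
  call2 <- detect_response(tr, p, cfg)
  expect_identical(call, call2)
  # inhibited-rebound unit: suppressed during pulse, rebound at offset
  gti <- ground_truth_unit("u2", "inhibited_rebound",
                           per_pulse_response_prob = 0.5,
                           suppression_factor = 0.1)
  tri <- inject_responses(gen_background_train(8, p$total_duration, seed = 14),
                          p, gti, seed = 15)
  calli <- detect_response(tri, p, cfg)
  expect_true(calli$responsive)
  expect_equal(calli$response_type, "inhibited_rebound")
  expect_gte(min(calli$significant_bins), 10)
})

test_that("positive-only jitter mode also detects a locked response", {
  p <- gen_protocol(seed = 1)
  cfg <- jitter_config(jitter_sign = "positive", seed = 6)
  bg <- gen_background_train(5, p$total_duration, seed = 22)
  gt <- ground_truth_unit("u1", "excited", per_pulse_response_prob = 0.5)
  tr <- inject_responses(bg, p, gt, seed = 23)
  expect_true(detect_response(tr, p, cfg)$responsive)
})

test_that("typing rule: latency split and suppression requirement", {
  onsets <- seq(10, 10.45, by = 0.05)
  cfg <- jitter_config()
  mk_call <- function(bins) {
    structure(list(unit_id = "u", responsive = TRUE, significant_bins = bins,
                   response_type = "none", thresholds = rep(0, 12),
                   observed = rep(0, 12), bin_ms = 1),
              class = "response_call")
  }
  # suppressed peth: no spikes during pulses, steady spikes elsewhere
  base_times <- sort(unlist(lapply(onsets, function(o) o - c(0.020, 0.015, 0.005))))
  pe_sup <- compute_peth(spike_train(base_times, 20), onsets)
  expect_equal(classify_type(mk_call(1), pe_sup, cfg), "excited")
  expect_equal(classify_type(mk_call(c(10, 11)), pe_sup, cfg),
               "inhibited_rebound")
  # within-pulse rate >= baseline: late bin is still excited
  dense <- sort(c(base_times, unlist(lapply(onsets, function(o) o + c(0.002, 0.005, 0.008)))))
  pe_dense <- compute_peth(spike_train(dense, 20), onsets)
  expect_equal(classify_type(mk_call(11), pe_dense, cfg), "excited")
  notresp <- mk_call(numeric(0))
  notresp$responsive <- FALSE
  expect_error(classify_type(notresp, pe_sup, cfg), "non-responsive")
})

test_that("detection rate is monotone in per-pulse response probability", {
  p <- gen_protocol(seed = 2)
  probs <- c(0.05, 0.1, 0.2, 0.4)
  n_rep <- 60
  rate <- sapply(seq_along(probs), function(j) {
    hits <- vapply(seq_len(n_rep), function(r) {
      bg <- gen_background_train(5, p$total_duration, seed = 1000 * j + r)
      gt <- ground_truth_unit("u", "excited",
                              per_pulse_response_prob = probs[j])
      tr <- inject_responses(bg, p, gt, seed = 2000 * j + r)
      detect_response(tr, p, jitter_config(seed = 3000 * j + r),
                      classify = FALSE)$responsive
    }, logical(1))
    mean(hits)
  })
  se <- sqrt(pmax(rate * (1 - rate), 0.25 / n_rep) / n_rep)
  for (j in 2:4) {
    expect_gte(rate[j], rate[j - 1] - 2 * (se[j] + se[j - 1]))
  }
  # and the strongest condition detects essentially always
  expect_gte(rate[4], 0.9)
})

test_that("population summary partitions and validates", {
  p <- toy_protocol()
  mk <- function(id, resp, type) {
    structure(list(unit_id = id, responsive = resp,
                   significant_bins = if (resp) 1 else numeric(0),
                   response_type = type), class = "response_call")
  }
  calls <- list(mk("a", TRUE, "excited"), mk("b", TRUE, "inhibited_rebound"),
                mk("c", FALSE, "none"), mk("d", TRUE, "excited"))
  s <- summarize_population(calls)
  expect_equal(s$responsive, 3)
  expect_equal(s$total, 4)
  expect_equal(s$fraction, 0.75)
  expect_equal(sum(s$by_type), s$responsive)
  expect_error(summarize_population(list()), "non-empty")
})
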