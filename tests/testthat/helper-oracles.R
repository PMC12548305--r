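# Shared fixtures and independent oracles used across the suite.

# A small protocol (short baseline keeps background trains small).
toy_protocol <- function(train_spec = c(0.5, 1), baseline_s = 10, seed = 1) {
  gen_protocol(train_spec = train_spec, baseline_s = baseline_s, seed = seed)
}

# Brute-force PETH oracle: double loop over pulses and spikes, half-open
# bins.  Independent of the package's vectorized binning.
peth_oracle <- function(times, onsets, window_ms, bin_ms) {
  n_bins <- round((window_ms[2] - window_ms[1]) / bin_ms)
  counts <- integer(n_bins)
  for (o in onsets) {
    for (t in times) {
      rel <- (t - o) * 1000
      if (rel >= window_ms[1] && rel < window_ms[2]) {
        b <- floor((rel - window_ms[1]) / bin_ms + 1e-9) + 1
        counts[b] <- counts[b] + 1L
      }
    }
  }
  counts
}

# Exact two-sided signed-rank p by full enumeration of sign patterns.
signrank_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  # two-sided: fold around the null mean n(n+1)/4
  mu <- n * (n + 1) / 4
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-12)
}

# Pooled-variance two-sample t and p, from the closed form.
pooled_t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2,
       p = 2 * pt(abs(t), n1 + n2 - 2, lower.tail = FALSE))
}

# Permutation p-value for a difference in means (oracle for the pooled t
# under exchangeability).
perm_p_oracle <- function(a, b, n_perm = 1e5, seed = 1) {
  set.seed(seed)
  x <- c(a, b)
  n1 <- length(a)
  obs <- abs(mean(a) - mean(b))
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(x), n1)
    if (abs(mean(x[idx]) - mean(x[-idx])) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}

random_train <- function(seed, rate = 5, duration = 60) {
  gen_background_train(rate, duration, isi_shape = runif(1, 0.4, 2),
                       seed = seed, unit_id = sprintf("r%d", seed))
}
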