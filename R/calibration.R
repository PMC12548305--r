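# Chance-level calibration of the jitter test by ISI-order shuffling, and
# the paired signed-rank comparison of observed vs chance responsive
# proportions across recording sites.

#' Shuffle the order of a train's inter-spike intervals
#'
#' Randomly permutes the ISI sequence while keeping the first spike time
#' fixed, so the ISI multiset, the spike count, and the first and last
#' spike times are preserved exactly.  This preserves the unit's firing
#' statistics and burst structure while destroying the temporal alignment
#' of spikes to the stimulation, which makes it the appropriate global null
#' for the detector's hit rate.  Trains with fewer than 3 spikes are
#' returned unchanged (0 or 1 permutable ISIs).
#'
#' @param train a [spike_train()].
#' @param seed integer seed.
#' @return a [spike_train()].
#' @export
shuffle_isi <- function(train, seed = 1) {
  stopifnot_param(inherits(train, "spike_train"), "train must be a spike_train")
  n <- length(train$times)
  if (n < 3L) return(train)
  set.seed(child_seed(seed, 0L))
  isi <- diff(train$times)
  out <- train
  out$times <- train$times[1] + cumsum(c(0, sample(isi)))
  # guard against float drift past the recording end
  out$times[n] <- train$times[n]
  out
}

#' Estimate the detector's chance hit rate by ISI shuffling
#'
#' Runs [detect_response()] on the unshuffled trains (the observed
#' fraction), then repeats the identical analysis on `n_shuffles`
#' ISI-shuffled copies of the whole population, recording the responsive
#' fraction of each replicate.  Shuffle and surrogate seeds are derived
#' from `seed` with a counter, so replicate `k` is reproducible in
#' isolation.
#'
#' @param trains non-empty list of [spike_train()] objects.
#' @param protocol a [stim_protocol()] or onset vector.
#' @param config a [jitter_config()].
#' @param n_shuffles number of shuffle replicates (>= 1).
#' @param seed master seed.
#' @param site_id label carried into the result.
#' @return an object of class `shuffle_result`: `site_id`,
#'   `observed_fraction`, `chance_fractions` (length `n_shuffles`),
#'   `n_shuffles`, `n_units`, and `observed_calls`.
#' @export
chance_fraction <- function(trains, protocol, config = jitter_config(),
                            n_shuffles = 100, seed = 1, site_id = "site1") {
  stopifnot_param(is.list(trains) && length(trains) >= 1L,
                  "trains must be a non-empty list")
  stopifnot_param(n_shuffles >= 1, "n_shuffles must be at least 1")
  n_units <- length(trains)
  detect_frac <- function(tr_list, seed_base) {
    resp <- vapply(seq_along(tr_list), function(i) {
      cfg <- config
      cfg$seed <- child_seed(seed_base, i)
      detect_response(tr_list[[i]], protocol, cfg, classify = FALSE)$responsive
    }, logical(1))
    mean(resp)
  }
  obs_calls <- lapply(seq_along(trains), function(i) {
    cfg <- config
    cfg$seed <- child_seed(child_seed(seed, 0L), i)
    detect_response(trains[[i]], protocol, cfg, classify = FALSE)
  })
  observed <- mean(vapply(obs_calls, `[[`, logical(1), "responsive"))
  chance <- vapply(seq_len(n_shuffles), function(k) {
    rep_seed <- child_seed(seed, k)
    shuffled <- lapply(seq_along(trains), function(i) {
      shuffle_isi(trains[[i]], seed = child_seed(rep_seed, i))
    })
    detect_frac(shuffled, child_seed(rep_seed, 0L))
  }, double(1))
  structure(list(site_id = site_id, observed_fraction = observed,
                 chance_fractions = chance, n_shuffles = n_shuffles,
                 n_units = n_units, observed_calls = obs_calls),
            class = "shuffle_result")
}

#' @export
print.shuffle_result <- function(x, ...) {
  cat(sprintf(paste0("<shuffle_result> site '%s': observed fraction %.3f, ",
                     "chance %.3f +/- %.3f (%d shuffles, %d units)\n"),
              x$site_id, x$observed_fraction, mean(x$chance_fractions),
              sd(x$chance_fractions), x$n_shuffles, x$n_units))
  invisible(x)
}

#' Paired comparison of observed vs chance responsive proportions
#'
#' Wilcoxon signed-rank test on the paired differences (observed - chance),
#' one pair per recording site.  Zero differences are dropped (standard
#' practice); with all differences zero the test is degenerate and `p = 1`
#' is returned with a warning.  The exact small-sample null distribution is
#' used below 26 non-zero pairs, the tie-corrected normal approximation
#' otherwise.  A sign-test variant is available.
#'
#' The exact null is computed by a generating-function recursion over the
#' (tie-averaged) ranks, so tied differences — routine when comparing
#' proportions over a handful of sites — still get an exact permutation p
#' rather than a normal fallback.
#'
#' @param per_site_observed,per_site_chance paired numeric vectors (equal
#'   length; 5 or more pairs recommended).
#' @param method `"signed_rank"` (default) or `"sign"`.
#' @return list with `statistic` (V, the positive-rank sum), `p_value`,
#'   `n_pairs` (non-zero pairs used), `method`.
#' @export
signrank_compare <- function(per_site_observed, per_site_chance,
                             method = c("signed_rank", "sign")) {
  method <- match.arg(method)
  stopifnot_param(length(per_site_observed) == length(per_site_chance),
                  "paired vectors must have equal length")
  stopifnot_param(length(per_site_observed) >= 1L, "need at least one pair")
  d <- per_site_observed - per_site_chance
  d <- d[d != 0]
  if (!length(d)) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = NA_real_, p_value = 1, n_pairs = 0L,
                method = method))
  }
  n <- length(d)
  if (method == "sign") {
    ht <- stats::binom.test(sum(d > 0), n, p = 0.5)
    return(list(statistic = sum(d > 0), p_value = ht$p.value,
                n_pairs = n, method = method))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n < 26) {
    p <- signrank_exact_p(r, v)
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - n * (n + 1) / 4) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  }
  list(statistic = v, p_value = p, n_pairs = n, method = method)
}

# Exact two-sided signed-rank p over the 2^n equiprobable sign patterns,
# via the generating function of the positive-rank sum.  Ranks are doubled
# so midranks from ties become integers.
signrank_exact_p <- function(r, v_obs) {
  r2 <- as.integer(round(2 * r))
  f <- numeric(sum(r2) + 1L)  # f[k + 1] = #patterns with 2V = k
  f[1] <- 1
  for (w in r2) {
    g <- f
    g[(w + 1L):length(f)] <- g[(w + 1L):length(f)] + f[seq_len(length(f) - w)]
    f <- g
  }
  v2 <- seq_along(f) - 1
  mu2 <- sum(r2) / 2
  sum(f[abs(v2 - mu2) >= abs(2 * v_obs - mu2) - 1e-9]) / sum(f)
}
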