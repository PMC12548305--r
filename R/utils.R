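# Internal helpers: seed derivation, validation, classed errors.

of_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "optofear_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = NULL)
  ))
}

stopifnot_param <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) of_stop("invalid_parameter", fmt, ...)
}

#' Derive a child seed from a master seed
#'
#' All stochastic stages of the pipeline draw their seeds from a single
#' master seed through this function, so any stage (e.g. shuffle replicate
#' `k`) is reproducible in isolation.  A Lehmer-style step keeps results in
#' the 32-bit signed integer range.
#'
#' @param seed master seed (non-negative integer).
#' @param index counter distinguishing the consumers (non-negative integer).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, index) {
  stopifnot_param(is.numeric(seed) && length(seed) == 1L && seed >= 0,
                  "seed must be a single non-negative number")
  stopifnot_param(is.numeric(index) && length(index) == 1L && index >= 0,
                  "index must be a single non-negative number")
  m <- 2147483647  # 2^31 - 1, prime
  s <- ((as.double(seed) %% m) * 48271 + (as.double(index) + 1) * 7919) %% m
  as.integer(s %% (m - 2) + 1)
}

# Number of spike times strictly below x (times sorted ascending).
count_below <- function(times, x) {
  findInterval(x, times, left.open = TRUE)
}

is_sorted <- function(x) !is.unsorted(x, strictly = FALSE)
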