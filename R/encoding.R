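#' Construct a spike train
#'
#' A spike train records, for each of `n` neurons, the ordered timesteps
#' (1-based, within `1..T`) at which the neuron fired.
#'
#' @param times List of strictly increasing integer vectors, one per neuron.
#' @param n Number of neurons.
#' @param T Number of timesteps.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, n, T) {
  n <- as.integer(n); T <- as.integer(T)
  if (length(times) != n) stop("times must have one entry per neuron")
  times <- lapply(times, function(ts) {
    ts <- as.integer(ts)
    if (length(ts) && (is.unsorted(ts, strictly = TRUE) || ts[1] < 1L ||
                       ts[length(ts)] > T))
      stop("spike timesteps must be strictly increasing within 1..T")
    ts
  })
  structure(list(times = times, n = n, T = T), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat("<spike_train> ", x$n, " neuron(s), T = ", x$T, ", ",
      sum(spike_counts(x)), " spike(s)\n", sep = "")
  invisible(x)
}

#' Per-neuron spike counts
#' @param train A [spike_train()].
#' @return Integer vector of length `train$n`.
#' @export
spike_counts <- function(train) {
  vapply(train$times, length, integer(1))
}

# invert neuron -> timesteps into timestep -> spiking neuron ids
spikes_by_step <- function(train) {
  out <- vector("list", train$T)
  ns <- rep.int(seq_len(train$n), spike_counts(train))
  ts <- unlist(train$times, use.names = FALSE)
  if (length(ts)) out[] <- unname(split(ns, factor(ts, levels = seq_len(train$T))))
  else out[] <- list(integer(0))
  out
}

#' Encode intensities as Poisson (Bernoulli-per-timestep) spike trains
#'
#' Each input neuron spikes independently at every timestep with probability
#' `min(1, intensity * rate_scale)` — the standard rate encoding used when
#' static inputs are presented to a rate-coded spiking network.
#'
#' @param intensity Non-negative numeric vector, one value per input neuron.
#' @param T Number of timesteps.
#' @param rate_scale Multiplier from intensity to per-timestep spike
#'   probability.
#' @param seed Integer seed; encoding is reproducible given the seed.
#' @return A [spike_train()] over `length(intensity)` neurons.
#' @examples
#' poisson_encode(c(0, .5, 1), T = 20, seed = 1)
#' @export
poisson_encode <- function(intensity, T, rate_scale = 1, seed = 1L) {
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (rate_scale <= 0) stop("rate_scale must be > 0")
  n <- length(intensity); T <- as.integer(T)
  p <- pmin(1, intensity * rate_scale)
  with_seed(derive_seed(seed, 101L), {
    u <- matrix(runif(n * T), nrow = T, ncol = n)
  })
  fire <- sweep(u, 2L, p, `<`) | matrix(rep(p >= 1, each = T), T, n)
  spike_train(lapply(seq_len(n), function(i) which(fire[, i])), n = n, T = T)
}

#' Encode intensities through an analog integrate-and-fire front end
#'
#' Each intensity is applied as a constant current: the input neuron's
#' membrane potential is incremented by the intensity once per timestep and
#' the neuron fires (strictly) above `v_th`, with subtract- or zero-reset.
#' An intensity of 0.4 against `v_th = 1` therefore first fires at the
#' third timestep (potential 0.4, 0.8, 1.2).
#'
#' @inheritParams poisson_encode
#' @param v_th Threshold of the front-end neurons.
#' @param reset `"subtract"` or `"zero"`.
#' @return A [spike_train()].
#' @export
analog_encode <- function(intensity, T, v_th = 1, reset = c("subtract", "zero")) {
  if (any(intensity < 0)) stop("intensities must be non-negative")
  reset <- match.arg(reset)
  n <- length(intensity); T <- as.integer(T)
  v_th <- rep_len(v_th, n)
  times <- vector("list", n)
  v <- numeric(n)
  fire_mat <- matrix(FALSE, T, n)
  for (t in seq_len(T)) {
    v <- v + intensity
    f <- v > v_th
    fire_mat[t, ] <- f
    v[f] <- if (reset == "subtract") v[f] - v_th[f] else 0
  }
  spike_train(lapply(seq_len(n), function(i) which(fire_mat[, i])), n = n, T = T)
}

## ---- seeding ----------------------------------------------------------
## All randomness fans out from one master seed into named substreams so
## that e.g. re-clustering or a different lane count never reshuffles the
## encoding draws. Substream seeds stay below 2^31 - 1.

derive_seed <- function(seed, stream) {
  ((as.double(seed) %% 2147483647) * 48271 + as.double(stream)) %% 2147483647
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
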