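#' Specify a per-neuron outgoing-weight distribution
#'
#' Synthetic networks draw each presynaptic neuron's outgoing weights from
#' one of three families. `"two_point"` is the heavy-tailed default that
#' emulates trained networks, where the per-neuron maximum outgoing weight
#' is an outlier at roughly five times the median: weights are jittered
#' uniformly around a median `m` and one synapse per neuron is set to
#' `max_median_ratio * m`. For `"uniform"` and `"lognormal"`, supplying
#' `max_median_ratio` applies a per-neuron power transform that pins the
#' realized max/median ratio to the target while keeping the median fixed.
#'
#' @param family `"two_point"`, `"uniform"` or `"lognormal"`.
#' @param median Target median weight magnitude.
#' @param max_median_ratio Target per-neuron max/median ratio (`NULL` to
#'   leave the family's natural tail).
#' @param spread Relative half-width of the two-point jitter.
#' @param min,max Bounds for the uniform family.
#' @param meanlog,sdlog Lognormal parameters.
#' @param p_inhibitory Probability that a synapse is inhibitory (sign
#'   flipped; magnitudes are unaffected).
#' @return An object of class `weight_dist_spec`.
#' @export
weight_dist_spec <- function(family = c("two_point", "uniform", "lognormal"),
                             median = 0.1, max_median_ratio = 5,
                             spread = 0.4, min = 0, max = 1,
                             meanlog = log(0.1), sdlog = 0.5,
                             p_inhibitory = 0) {
  family <- match.arg(family)
  if (median <= 0) stop("config error: median must be > 0")
  if (!is.null(max_median_ratio) && max_median_ratio < 1)
    stop("config error: max_median_ratio must be >= 1")
  if (p_inhibitory < 0 || p_inhibitory > 1)
    stop("config error: p_inhibitory must be in [0, 1]")
  if (family == "uniform" && (min < 0 || max <= min))
    stop("config error: uniform family needs 0 <= min < max")
  structure(list(family = family, median = median,
                 max_median_ratio = max_median_ratio, spread = spread,
                 min = min, max = max, meanlog = meanlog, sdlog = sdlog,
                 p_inhibitory = p_inhibitory),
            class = "weight_dist_spec")
}

draw_neuron_weights <- function(dist, n) {
  w <- switch(dist$family,
    two_point = {
      m <- dist$median
      base <- m * runif(n, 1 - dist$spread, 1 + dist$spread)
      if (!is.null(dist$max_median_ratio) && n >= 2L) {
        i <- which.max(base)
        base[i] <- dist$max_median_ratio * median(base[-i])
      }
      base
    },
    uniform = runif(n, dist$min, dist$max),
    lognormal = rlnorm(n, dist$meanlog, dist$sdlog))
  if (!is.null(dist$max_median_ratio) && dist$family != "two_point" && n >= 3L) {
    med <- median(w); mx <- max(w)
    if (mx > med && med > 0) {
      a <- log(dist$max_median_ratio) / log(mx / med)
      w <- med * (w / med)^a
    }
  }
  if (dist$p_inhibitory > 0)
    w <- w * ifelse(runif(n) < dist$p_inhibitory, -1, 1)
  w
}

#' Generate a synthetic feed-forward network
#'
#' Builds dense layers of the given sizes with per-presynaptic-neuron
#' weights drawn from `dist`, reproducibly under `seed`. The default
#' heavy-tailed distribution emulates the outgoing-weight statistics of
#' trained networks (per-neuron max around five times the median), which
#' is the regime where cluster-max normalization pays off.
#'
#' @param layer_sizes Integer vector of at least two sizes
#'   (input, hidden..., output).
#' @param dist A [weight_dist_spec()].
#' @param seed Integer seed.
#' @param v_th Threshold voltage, recycled over layers.
#' @param bias Bias, recycled over layers.
#' @param name Network name.
#' @return An [network_spec()] object.
#' @examples
#' net <- generate_network(c(8, 6, 3), seed = 1)
#' @export
generate_network <- function(layer_sizes, dist = weight_dist_spec(),
                             seed = 1L, v_th = 1, bias = 0,
                             name = "synthetic") {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L))
    stop("layer_sizes must give at least two sizes >= 1")
  v_th <- rep_len(v_th, length(layer_sizes) - 1L)
  bias <- rep_len(bias, length(layer_sizes) - 1L)
  with_seed(derive_seed(seed, 500L), {
    layers <- lapply(seq_len(length(layer_sizes) - 1L), function(l) {
      n_in <- layer_sizes[l]; n_out <- layer_sizes[l + 1L]
      W <- t(vapply(seq_len(n_in),
                    function(i) draw_neuron_weights(dist, n_out),
                    numeric(n_out)))
      if (n_out == 1L) W <- matrix(W, nrow = n_in)
      layer_spec(n_in, n_out, weights = W, bias = bias[l], v_th = v_th[l])
    })
    network_spec(layers, name = name,
                 metadata = list(seed = as.character(seed),
                                 dist = dist$family))
  })
}

#' The two-source, one-target toy network
#'
#' Two spiking source neurons feed a single integrate-and-fire target
#' through weights `w13` and `w23` — the minimal circuit on which the
#' convergence of probabilistic average potentiation to the synaptic
#' weights can be watched directly.
#'
#' @param w13,w23 Synaptic weights from sources 1 and 2 to the target.
#' @param v_th Target threshold.
#' @return An [network_spec()] object with one dense 2-to-1 layer.
#' @export
toy_two_source <- function(w13 = 0.5, w23 = 0.6, v_th = 1) {
  network_spec(list(layer_spec(2L, 1L, weights = matrix(c(w13, w23), 2L, 1L),
                               v_th = v_th)),
               name = "two-source-toy")
}

#' Generate a batch of stimulus intensity vectors
#'
#' @param n_stimuli Number of stimuli.
#' @param n_inputs Input-layer size.
#' @param seed Integer seed.
#' @param min,max Intensity range.
#' @return A numeric matrix, one row per stimulus.
#' @export
make_stimuli <- function(n_stimuli, n_inputs, seed = 1L, min = 0, max = 1) {
  with_seed(derive_seed(seed, 600L), {
    matrix(runif(n_stimuli * n_inputs, min, max), nrow = n_stimuli)
  })
}

agreement_run <- function(net, stimuli, modes, config, seed, ref_preds) {
  preds <- integer(nrow(stimuli))
  updates <- numeric(nrow(stimuli))
  for (s in seq_len(nrow(stimuli))) {
    run <- run_inference(net, stimuli[s, ], modes = modes, config = config,
                         seed = derive_seed(seed, 700L + s))
    preds[s] <- run$prediction
    updates[s] <- sum(vapply(run$layers,
                             function(lr) lr$stats$synaptic_updates,
                             numeric(1)))
  }
  list(agreement = mean(preds == ref_preds), mean_updates = mean(updates),
       preds = preds)
}

baseline_predictions <- function(net, stimuli, config, seed) {
  vapply(seq_len(nrow(stimuli)), function(s)
    run_inference(net, stimuli[s, ], modes = "deterministic", config = config,
                  seed = derive_seed(seed, 700L + s))$prediction,
    integer(1))
}

#' Sweep the number of synaptic clusters
#'
#' For each cluster count `B`, runs probabilistic inference on every
#' stimulus and reports the mean synaptic updates per inference, the
#' fraction of stimuli whose prediction agrees with the deterministic
#' baseline on the same stimulus and encoding seed (the offline surrogate
#' for accuracy degradation), and the closed-form expected updates per
#' spike summed over all presynaptic neurons. With `B` equal to the
#' fan-out size, probabilistic propagation is identical to the baseline
#' and agreement is exactly 1.
#'
#' @param net An [network_spec()].
#' @param stimuli Matrix of intensities, one row per stimulus
#'   (see [make_stimuli()]).
#' @param B_values Integer vector of cluster counts.
#' @param config A [run_config()]; its `B` is overridden per sweep point.
#' @param seed Master seed.
#' @return A tibble of class `snn_sweep` with columns `B`, `mean_updates`,
#'   `agreement`, `expected_updates_per_spike`.
#' @export
sweep_clusters <- function(net, stimuli, B_values, config = run_config(),
                           seed = 1L) {
  if (any(B_values < 1L)) stop("B values must be >= 1")
  bsl <- baseline_predictions(net, stimuli, config, seed)
  rows <- lapply(B_values, function(B) {
    cfg <- config; cfg$B <- as.integer(B)
    res <- agreement_run(net, stimuli, "probabilistic", cfg, seed, bsl)
    exp_upd <- sum(vapply(net$layers, function(ly)
      sum(expected_updates(
        build_cluster_tables(resolve_fanout(ly), B, cfg$K,
                             normalizer = cfg$normalizer),
        method = if (cfg$method == "histogram") "discretized" else "continuous")),
      numeric(1)))
    tibble::tibble(B = as.integer(B), mean_updates = res$mean_updates,
                   agreement = res$agreement,
                   expected_updates_per_spike = exp_upd)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("snn_sweep_clusters", "snn_sweep", class(out))
  out
}

#' Sweep the cumulative-histogram resolution
#'
#' For each bin count `K`, runs histogram-method probabilistic inference on
#' every stimulus and reports agreement with the deterministic baseline,
#' mean updates per inference, and the memory overhead of the tables. The
#' ensemble-averaged agreement trend is non-decreasing in `K`; the
#' overhead is strictly increasing in `K`.
#'
#' @inheritParams sweep_clusters
#' @param K_values Integer vector of bin counts.
#' @return A tibble of class `snn_sweep` with columns `K`, `agreement`,
#'   `mean_updates`, `memory_overhead`.
#' @export
sweep_bins <- function(net, stimuli, K_values, config = run_config(),
                       seed = 1L) {
  if (any(K_values < 1L)) stop("K values must be >= 1")
  bsl <- baseline_predictions(net, stimuli, config, seed)
  rows <- lapply(K_values, function(K) {
    cfg <- config; cfg$K <- as.integer(K); cfg$method <- "histogram"
    res <- agreement_run(net, stimuli, "probabilistic", cfg, seed, bsl)
    tibble::tibble(K = as.integer(K), agreement = res$agreement,
                   mean_updates = res$mean_updates,
                   memory_overhead = memory_overhead(net, cfg$B, K,
                                                     cfg$storage))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("snn_sweep_bins", "snn_sweep", class(out))
  out
}
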