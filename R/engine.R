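#' One integrate-and-fire evaluation step
#'
#' Adds the bias to the membrane potential, compares strictly against the
#' threshold, and on firing resets either by subtracting the threshold
#' (default; the standard choice for rate-coded networks converted from
#' analog ones, as it preserves residual drive) or to zero. Pure
#' integrate-and-fire: no leak, no refractory period.
#'
#' @param v Membrane potential(s) before bias.
#' @param bias Bias added at every evaluation step.
#' @param v_th Threshold voltage (> 0); firing requires `v + bias > v_th`.
#' @param reset `"subtract"` or `"zero"`.
#' @return A list with `v` (post-step potentials) and `spiked` (logical).
#' @examples
#' if_neuron_step(0.9, 0.2, 1)   # fires, residual 0.1
#' @export
if_neuron_step <- function(v, bias, v_th, reset = c("subtract", "zero")) {
  reset <- match.arg(reset)
  v2 <- v + bias
  sp <- v2 > v_th
  v2[sp] <- if (reset == "subtract") v2[sp] - rep_len(v_th, length(v2))[sp] else 0
  list(v = v2, spiked = sp)
}

#' Deterministic propagation of one spike
#'
#' Every postsynaptic membrane potential in the spiking neuron's fan-out is
#' incremented by the signed synaptic weight. Each synaptic update costs
#' two memory reads (weight and postsynaptic state) and one write.
#'
#' @param neuron Spiking presynaptic neuron index.
#' @param fanout A [resolve_fanout()] object.
#' @param v Membrane potentials of the postsynaptic layer.
#' @return A list: updated `v`, `updates`, `reads`, `writes`.
#' @export
propagate_deterministic <- function(neuron, fanout, v) {
  tg <- fanout$targets[[neuron]]
  w <- fanout$weights[[neuron]]
  n <- length(tg)
  if (n) v[tg] <- v[tg] + w
  list(v = v, updates = n, reads = 2L * n, writes = n)
}

new_stats_env <- function(n_lanes, n_spikes_cap, record_trace) {
  e <- new.env(parent = emptyenv())
  e$spikes <- 0L
  e$updates <- 0
  e$reads <- c(weight = 0, state = 0, index = 0, tp_table = 0, w_max = 0)
  e$writes <- 0
  e$trace <- if (record_trace) matrix(0, n_spikes_cap, n_lanes) else NULL
  e$row <- 0L
  e
}

finalize_stats <- function(e, lanes_cfg, keep_trace = TRUE) {
  trace <- if (!is.null(e$trace) && e$row > 0L) e$trace[seq_len(e$row), , drop = FALSE] else NULL
  cyc_s <- cyc_a <- NA_real_
  lane_updates <- rep(0, lanes_cfg$n_lanes)
  if (!is.null(trace)) {
    lane_updates <- colSums(trace)
    cyc_s <- simulate_schedule(trace, lanes_cfg, "sync")
    cyc_a <- simulate_schedule(trace, lanes_cfg, "async")
  }
  structure(list(spikes = e$spikes, synaptic_updates = e$updates,
                 reads = e$reads, writes = e$writes,
                 lane_updates = lane_updates,
                 cycles_sync = cyc_s, cycles_async = cyc_a,
                 lane_trace = if (keep_trace) trace else NULL),
            class = "propagation_stats")
}

#' @export
print.propagation_stats <- function(x, ...) {
  cat("<propagation_stats> spikes=", x$spikes, " updates=", x$synaptic_updates,
      " reads=", sum(x$reads), " writes=", x$writes,
      " cycles(sync/async)=", x$cycles_sync, "/", x$cycles_async, "\n", sep = "")
  invisible(x)
}

#' Evaluate one layer for all timesteps
#'
#' Layer-major, event-driven evaluation: the layer is run for all `T`
#' timesteps before its successor is touched. Within a timestep the
#' controller first serves every input spike arriving at that timestep
#' (propagation phase), then evaluates all postsynaptic neurons — bias add,
#' strict threshold comparison, reset — pushing the ids of firing neurons
#' into the layer's output spike record (spike-generation phase).
#'
#' In `"deterministic"` mode every spike updates the full fan-out with the
#' stored weights. In `"probabilistic"` mode each spike draws one random
#' threshold per synaptic cluster (continuous uniform on `[0, w_max]` for
#' the scan method; discrete uniform over the `K` histogram thresholds for
#' the histogram method) and updates only the first `t_p` rank-ordered
#' targets, each by `sign * w_max` of its cluster.
#'
#' @param layer A [layer_spec()] object.
#' @param input A [spike_train()] over `layer$n_in` neurons.
#' @param mode `"deterministic"` or `"probabilistic"`.
#' @param config A [run_config()]; `config$timesteps` is used as `T` unless
#'   the input train is longer.
#' @param seed Integer master seed (only probabilistic mode draws from it).
#' @param layer_index Used to derive the layer's RNG substream.
#' @return A list of class `snn_layer_run`: `output` spike train, `stats`
#'   ([simulate_schedule()]-ready counters), `v_final`, and the
#'   potentiation matrix `M` when `config$track_potentiation` is set.
#' @export
run_layer <- function(layer, input, mode = c("deterministic", "probabilistic"),
                      config = run_config(), seed = 1L, layer_index = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(layer, "snn_layer"), inherits(input, "spike_train"))
  if (input$n != layer$n_in)
    stop("input train has ", input$n, " neurons, layer expects ", layer$n_in)
  T <- input$T
  fo <- resolve_fanout(layer)
  L <- config$lanes$n_lanes
  by_step <- spikes_by_step(input)
  n_input_spikes <- sum(spike_counts(input))
  st <- new_stats_env(L, n_input_spikes, config$record_lane_trace)
  track <- config$track_potentiation
  M <- if (track) matrix(0, layer$n_in, layer$n_out) else NULL

  v <- numeric(layer$n_out)
  rec <- matrix(FALSE, T, layer$n_out)
  bias <- layer$bias; v_th <- layer$v_th
  subtract <- config$reset == "subtract"

  if (mode == "deterministic") {
    det_lane <- lapply(vapply(fo$targets, length, integer(1)),
                       lane_work_det, n_lanes = L)
    for (t in seq_len(T)) {
      for (i in by_step[[t]]) {
        tg <- fo$targets[[i]]; w <- fo$weights[[i]]
        n <- length(tg)
        if (n) {
          v[tg] <- v[tg] + w
          if (track) M[i, tg] <- M[i, tg] + w
        }
        st$spikes <- st$spikes + 1L
        st$updates <- st$updates + n
        st$reads[["weight"]] <- st$reads[["weight"]] + n
        st$reads[["state"]] <- st$reads[["state"]] + n
        st$writes <- st$writes + n
        if (!is.null(st$trace)) {
          st$row <- st$row + 1L
          st$trace[st$row, ] <- det_lane[[i]]
        }
      }
      v <- v + bias
      sp <- v > v_th
      rec[t, ] <- sp
      v[sp] <- if (subtract) v[sp] - v_th[sp] else 0
    }
  } else {
    tables <- build_cluster_tables(fo, config$B, config$K,
                                   normalizer = config$normalizer)
    K <- config$K
    histo <- config$method == "histogram"
    b_effs <- vapply(tables, function(cl)
      if (isTRUE(attr(cl, "inert"))) 0L else length(cl), integer(1))
    map_cache <- lapply(seq_len(max(b_effs, 1L)),
                        function(b) map_clusters_to_lanes(b, L))
    with_seed(derive_seed(seed, 300L + layer_index), {
      for (t in seq_len(T)) {
        for (i in by_step[[t]]) {
          st$spikes <- st$spikes + 1L
          cl <- tables[[i]]
          Bi <- b_effs[i]
          lane_vec <- numeric(L)
          if (Bi > 0L) {
            tp_vec <- integer(Bi); ns_vec <- integer(Bi)
            examined <- 0L
            for (b in seq_len(Bi)) {
              cb <- cl[[b]]
              if (histo) {
                k <- floor(runif(1) * K)
                tp <- cb$tp[k + 1L]
              } else {
                r <- runif(1) * cb$wmax
                tp <- cb$nsyn - findInterval(r, cb$asc)
                examined <- examined + min(tp + 1L, cb$nsyn)
              }
              tp_vec[b] <- tp; ns_vec[b] <- cb$nsyn
              if (tp > 0L) {
                idx <- cb$targets[seq_len(tp)]
                upd <- cb$signs[seq_len(tp)] * cb$wmax
                v[idx] <- v[idx] + upd
                if (track) M[i, idx] <- M[i, idx] + upd
              }
            }
            tot <- sum(tp_vec)
            st$updates <- st$updates + tot
            st$reads[["w_max"]] <- st$reads[["w_max"]] + Bi
            if (histo) st$reads[["tp_table"]] <- st$reads[["tp_table"]] + Bi
            else st$reads[["weight"]] <- st$reads[["weight"]] + examined
            st$reads[["index"]] <- st$reads[["index"]] + tot
            st$reads[["state"]] <- st$reads[["state"]] + tot
            st$writes <- st$writes + tot
            lane_vec <- lane_work_prob(tp_vec, ns_vec, map_cache[[Bi]], L)
          }
          if (!is.null(st$trace)) {
            st$row <- st$row + 1L
            st$trace[st$row, ] <- lane_vec
          }
        }
        v <- v + bias
        sp <- v > v_th
        rec[t, ] <- sp
        v[sp] <- if (subtract) v[sp] - v_th[sp] else 0
      }
    })
  }

  out <- spike_train(lapply(seq_len(layer$n_out), function(j) which(rec[, j])),
                     n = layer$n_out, T = T)
  structure(list(output = out,
                 stats = finalize_stats(st, config$lanes),
                 v_final = v, M = M, C_in = spike_counts(input),
                 input_weights_fanout = if (track) fo else NULL,
                 mode = mode, layer_index = layer_index),
            class = "snn_layer_run")
}

#' Run inference through a feed-forward network
#'
#' Encodes the stimulus (Poisson or analog integrate-and-fire front end, or
#' an explicit [spike_train()]), evaluates the layers in order — each for
#' all `T` timesteps, with per-layer choice between deterministic and
#' probabilistic propagation — and classifies by the output layer's spike
#' counts. Ties are broken by the larger final membrane potential, then by
#' the lower neuron index.
#'
#' @param net An [network_spec()] object.
#' @param stimulus Non-negative intensity vector of length `n_in` of the
#'   first layer, or a [spike_train()].
#' @param modes `"deterministic"`, `"probabilistic"`, or a character vector
#'   with one mode per layer.
#' @param config A [run_config()].
#' @param seed Master seed; encoding and every layer draw from derived
#'   substreams, so runs are fully reproducible.
#' @return An object of class `snn_run`: `prediction`, `spike_counts` of
#'   the output layer, `layers` (list of [run_layer()] results), plus the
#'   config and seed for provenance.
#' @export
run_inference <- function(net, stimulus, modes = "deterministic",
                          config = run_config(), seed = 1L) {
  stopifnot(inherits(net, "snn_network"))
  n_layers <- length(net$layers)
  if (length(modes) == 1L) modes <- rep(modes, n_layers)
  if (length(modes) != n_layers)
    stop("modes must have one entry per layer (", n_layers, ")")
  modes <- vapply(modes, function(m)
    match.arg(m, c("deterministic", "probabilistic")), character(1))

  if (inherits(stimulus, "spike_train")) {
    train <- stimulus
    if (train$n != net$layers[[1]]$n_in)
      stop("stimulus spike train size mismatch: ", train$n, " vs ",
           net$layers[[1]]$n_in)
  } else {
    if (length(stimulus) != net$layers[[1]]$n_in)
      stop("stimulus size mismatch: ", length(stimulus), " vs ",
           net$layers[[1]]$n_in)
    train <- if (config$encoding == "poisson")
      poisson_encode(stimulus, T = config$timesteps,
                     rate_scale = config$rate_scale,
                     seed = derive_seed(seed, 7L))
    else analog_encode(stimulus, T = config$timesteps, reset = config$reset)
  }

  layer_runs <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    layer_runs[[l]] <- run_layer(net$layers[[l]], train, mode = modes[l],
                                 config = config, seed = seed, layer_index = l)
    train <- layer_runs[[l]]$output
  }
  counts <- spike_counts(train)
  v_fin <- layer_runs[[n_layers]]$v_final
  best <- which(counts == max(counts))
  if (length(best) > 1L) best <- best[v_fin[best] == max(v_fin[best])]
  prediction <- min(best)

  structure(list(prediction = prediction, spike_counts = counts,
                 layers = layer_runs, modes = modes, config = config,
                 seed = seed, input_train = NULL),
            class = "snn_run")
}

#' @export
print.snn_run <- function(x, ...) {
  cat("<snn_run> ", length(x$layers), " layer(s), prediction = ",
      x$prediction, "\n", sep = "")
  cat("  output spike counts:", x$spike_counts, "\n")
  invisible(x)
}

#' Per-synapse potentiation ledger
#'
#' For a layer run with `track_potentiation` enabled, returns the
#' accumulated potentiation `M` of each postsynaptic neuron by each
#' presynaptic neuron, the presynaptic spike count `C`, and the average
#' potentiation `M / C`. Under deterministic propagation the average equals
#' the synaptic weight exactly whenever `C >= 1`; under probabilistic
#' propagation it converges to the weight as `C` grows (unbiased
#' estimator, standard error shrinking as `1/sqrt(C)`).
#'
#' @param layer_run A [run_layer()] result with tracking enabled (or an
#'   [run_inference()] result, with `layer` selecting which layer).
#' @param layer Layer index when an `snn_run` is given.
#' @return A tibble with columns `pre`, `post`, `weight`, `spikes`,
#'   `potentiation`, `mean_potentiation`.
#' @export
potentiation_ledger <- function(layer_run, layer = 1L) {
  if (inherits(layer_run, "snn_run")) layer_run <- layer_run$layers[[layer]]
  if (is.null(layer_run$M))
    stop("run was not executed with track_potentiation = TRUE")
  M <- layer_run$M
  C <- layer_run$C_in
  fo <- layer_run$input_weights_fanout
  rows <- do.call(rbind, lapply(seq_len(nrow(M)), function(i) {
    tg <- fo$targets[[i]]
    if (!length(tg)) return(NULL)
    data.frame(pre = i, post = tg, weight = fo$weights[[i]],
               spikes = C[i], potentiation = M[i, tg])
  }))
  out <- tibble::as_tibble(rows)
  out$mean_potentiation <- ifelse(out$spikes > 0,
                                  out$potentiation / out$spikes, NA_real_)
  out
}
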