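#' Lane-array configuration
#'
#' The accelerator model serves each spike's synaptic updates across an
#' array of parallel lanes. Cost per lane is
#' `updates * cycles_per_update + cycles_per_spike_overhead` per spike.
#'
#' @param n_lanes Number of lanes (default 16).
#' @param queue_depth Per-lane spike queue depth for asynchronous serving;
#'   `Inf` for unbounded.
#' @param cycles_per_update Cycles per synaptic update (default 1).
#' @param cycles_per_spike_overhead Fixed dispatch overhead per spike per
#'   lane, in cycles (default 1).
#' @return An object of class `lane_config`.
#' @export
lane_config <- function(n_lanes = 16L, queue_depth = Inf,
                        cycles_per_update = 1, cycles_per_spike_overhead = 1) {
  n_lanes <- as.integer(n_lanes)
  if (n_lanes < 1L) stop("config error: n_lanes must be >= 1")
  if (!(is.infinite(queue_depth) || queue_depth >= 1))
    stop("config error: queue_depth must be >= 1 or Inf")
  if (cycles_per_update < 0 || cycles_per_spike_overhead < 0)
    stop("config error: cycle costs must be >= 0")
  structure(list(n_lanes = n_lanes, queue_depth = queue_depth,
                 cycles_per_update = cycles_per_update,
                 cycles_per_spike_overhead = cycles_per_spike_overhead),
            class = "lane_config")
}

#' Energy model configuration
#'
#' A linear, unit-agnostic energy model: total energy is the dot product of
#' the run's counters with these per-event costs. Defaults are skewed
#' toward memory (reads and writes an order of magnitude above the update
#' arithmetic), reflecting that memory dominates energy on spiking-network
#' hardware; all values are user-settable.
#'
#' @param read,write Energy per memory read / write (any category).
#' @param update_op Energy per synaptic-update arithmetic operation.
#' @return An object of class `energy_config`.
#' @export
energy_config <- function(read = 1, write = 1, update_op = 0.1) {
  if (read < 0 || write < 0 || update_op < 0)
    stop("config error: energies must be >= 0")
  structure(list(read = read, write = write, update_op = update_op),
            class = "energy_config")
}

#' Storage model configuration
#'
#' Bit widths used by [memory_overhead()]: baseline weight storage versus
#' the probabilistic tables (rank-ordered target indices, termination-point
#' tables, per-cluster maxima). `sharing = TRUE` stores tables once per
#' shared kernel pattern in locally connected layers.
#'
#' @param bits_weight,bits_index,bits_tp,bits_wmax Bits per stored entry.
#' @param sharing Share tables across neurons with identical kernel
#'   patterns in local layers.
#' @return An object of class `storage_config`.
#' @export
storage_config <- function(bits_weight = 16, bits_index = 16, bits_tp = 16,
                           bits_wmax = 16, sharing = FALSE) {
  if (min(bits_weight, bits_index, bits_tp, bits_wmax) <= 0)
    stop("config error: bit widths must be > 0")
  structure(list(bits_weight = bits_weight, bits_index = bits_index,
                 bits_tp = bits_tp, bits_wmax = bits_wmax,
                 sharing = isTRUE(sharing)),
            class = "storage_config")
}

#' Map synaptic clusters to lanes
#'
#' With `B == n_lanes` the mapping is one cluster per lane. With
#' `B < n_lanes`, lanes form `B` contiguous groups (sizes differing by at
#' most one) and each group splits its cluster's rank range. With
#' `B > n_lanes`, each lane serves up to `ceil(B / n_lanes)` clusters
#' sequentially.
#'
#' @param B Number of clusters.
#' @param n_lanes Number of lanes.
#' @return A list of integer vectors: `lanes[[b]]` are the lane ids serving
#'   cluster `b`.
#' @export
map_clusters_to_lanes <- function(B, n_lanes) {
  B <- as.integer(B); n_lanes <- as.integer(n_lanes)
  if (B < 1L || n_lanes < 1L) stop("B and n_lanes must be >= 1")
  if (B >= n_lanes) {
    lane_of <- ceiling(seq_len(B) * n_lanes / B)
    lapply(seq_len(B), function(b) lane_of[b])
  } else {
    grp <- ceiling(seq_len(n_lanes) * B / n_lanes)  # contiguous lane groups
    lapply(seq_len(B), function(b) which(grp == b))
  }
}

# split n items contiguously among m servers, sizes differing <= 1:
# returns the count of the first t items landing on each server.
split_head_count <- function(n, m, t) {
  if (m == 1L) return(min(n, t))
  bounds <- floor(seq_len(m) * n / m)        # cumulative sizes
  starts <- c(0, bounds[-m])
  pmax(0L, pmin(bounds, t) - starts)
}

# per-lane update counts for one spike.
# det: fanout size n split contiguously over all lanes.
# prob: per-cluster termination points tp, cluster sizes ns, mapping.
lane_work_det <- function(n, n_lanes) {
  as.numeric(split_head_count(n, n_lanes, n))
}

lane_work_prob <- function(tp, ns, mapping, n_lanes) {
  out <- numeric(n_lanes)
  for (b in seq_along(tp)) {
    lanes <- mapping[[b]]
    if (length(lanes) == 1L) out[lanes] <- out[lanes] + tp[b]
    else out[lanes] <- out[lanes] + split_head_count(ns[b], length(lanes), tp[b])
  }
  out
}

#' Simulate synchronous or asynchronous spike serving
#'
#' Given the per-spike, per-lane synaptic-update counts of a run, computes
#' the makespan in cycles under two serving disciplines. Synchronous: the
#' controller serves one spike at a time and waits for the slowest lane
#' before dispatching the next, so idle bubbles accumulate whenever lanes
#' draw unequal termination points. Asynchronous: each lane consumes spikes
#' from its own queue as soon as it is free; with unbounded queues the
#' makespan is the maximum per-lane total, and a bounded queue stalls the
#' producer when any lane's queue is full.
#'
#' @param work Numeric matrix, one row per spike, one column per lane:
#'   synaptic updates performed by that lane for that spike.
#' @param cfg A [lane_config()].
#' @param mode `"sync"` or `"async"`.
#' @return Total cycles (numeric scalar).
#' @examples
#' w <- rbind(c(3, 1), c(1, 3))
#' cfg <- lane_config(n_lanes = 2, cycles_per_spike_overhead = 0)
#' simulate_schedule(w, cfg, "sync")   # 6
#' simulate_schedule(w, cfg, "async")  # 4
#' @export
simulate_schedule <- function(work, cfg = lane_config(),
                              mode = c("sync", "async")) {
  mode <- match.arg(mode)
  work <- as.matrix(work)
  if (ncol(work) != cfg$n_lanes)
    stop("work matrix must have one column per lane (", cfg$n_lanes, ")")
  if (any(work < 0) || any(!is.finite(work))) stop("malformed work vector")
  if (nrow(work) == 0L) return(0)
  cost <- work * cfg$cycles_per_update + cfg$cycles_per_spike_overhead
  if (mode == "sync") return(sum(apply(cost, 1L, max)))
  if (is.infinite(cfg$queue_depth)) return(max(colSums(cost)))
  # bounded queue: producer dispatches spike s once every lane holds < depth
  d <- cfg$queue_depth
  n <- nrow(work); L <- ncol(work)
  finish <- matrix(0, n, L)
  for (s in seq_len(n)) {
    t_disp <- if (s > d) max(finish[s - d, ]) else 0
    for (l in seq_len(L)) {
      start <- max(t_disp, if (s > 1L) finish[s - 1L, l] else 0)
      finish[s, l] <- start + cost[s, l]
    }
  }
  max(finish[n, ])
}

#' Linear energy estimate from run counters
#'
#' @param stats A `propagation_stats` object (or anything with `reads`,
#'   `writes` and `synaptic_updates` fields).
#' @param e An [energy_config()].
#' @return Energy (numeric scalar, arbitrary units).
#' @export
energy_estimate <- function(stats, e = energy_config()) {
  sum(stats$reads) * e$read + stats$writes * e$write +
    stats$synaptic_updates * e$update_op
}

#' Memory overhead of the probabilistic tables
#'
#' Ratio of the bits added by probabilistic propagation (rank-ordered
#' target-index tables, `K`-entry termination-point tables and per-cluster
#' maxima) to the bits of baseline weight storage. `K = 0` disables the
#' termination-point tables (scan method), leaving the index tables and
#' cluster maxima. With `sharing` enabled, locally connected layers store
#' one table set per kernel pattern (channel) instead of one per
#' presynaptic neuron, while dense layers are unaffected.
#'
#' @param net An [network_spec()] object.
#' @param B Clusters per neuron.
#' @param K Histogram bins (0 disables termination tables).
#' @param storage A [storage_config()].
#' @return Overhead fraction (numeric scalar).
#' @export
memory_overhead <- function(net, B = 8L, K = 50L, storage = storage_config()) {
  stopifnot(inherits(net, "snn_network"))
  if (K < 0) stop("K must be >= 0")
  base_bits <- 0; extra_bits <- 0
  for (ly in net$layers) {
    if (ly$connectivity == "dense") {
      base_bits <- base_bits + length(ly$weights) * storage$bits_weight
      per_neuron_syn <- rep.int(ly$n_out, ly$n_in)
      n_tables <- ly$n_in
      syn_per_table <- per_neuron_syn[1]
    } else {
      base_bits <- base_bits + length(ly$weights) * storage$bits_weight
      fo <- resolve_fanout(ly)
      sizes <- vapply(fo$targets, length, integer(1))
      if (storage$sharing) {
        # one table set per channel: the kernel pattern is shared
        sizes <- rep.int(ly$kernel, ly$channels)
      }
      b_eff <- pmin(B, pmax(sizes, 1L))
      extra_bits <- extra_bits + sum(sizes) * storage$bits_index +
        sum(b_eff) * (K * storage$bits_tp + storage$bits_wmax)
      next
    }
    b_eff <- pmin(B, syn_per_table)
    extra_bits <- extra_bits +
      n_tables * (syn_per_table * storage$bits_index +
                  b_eff * (K * storage$bits_tp + storage$bits_wmax))
  }
  if (base_bits == 0) stop("zero baseline weight storage: overhead undefined")
  extra_bits / base_bits
}
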