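#' Build per-neuron synaptic cluster tables
#'
#' Probabilistic spike propagation partitions each presynaptic neuron's
#' outgoing synapses into `B` synaptic clusters — contiguous blocks of
#' postsynaptic indices whose sizes differ by at most one. Within a cluster
#' the synapses are sorted by weight magnitude (descending, ties broken by
#' ascending postsynaptic index), and the cluster's maximum magnitude
#' `w_max` is the probability normalizer: a spike propagates on synapse `j`
#' with probability `|w_j| / w_max`, realized by drawing one uniform
#' threshold `r` on `[0, w_max]` per cluster per spike and propagating on
#' every synapse with `|w_j| > r`. Because the magnitudes are sorted, the
#' propagated synapses are exactly the first `t_p` ranks (the termination
#' point).
#'
#' For the cumulative-histogram method, each cluster also stores a `K`-entry
#' lookup `tp_table` with `tp_table[k+1] = #\{|w_j| > k * w_max / K\}` for
#' `k = 0..K-1`, i.e. the termination point at each of the `K` discrete
#' thresholds, so `t_p` costs a single table read and the weights never
#' need to be fetched during propagation. The discrete threshold set
#' includes 0 (full propagation reachable) and excludes `w_max` (whose
#' success probability is zero for every synapse); a synapse whose weight
#' equals `w_max` therefore propagates with probability 1 in both schemes.
#'
#' Zero-magnitude synapses are pruned at build time: they can never
#' propagate. If a neuron has fewer than `B` outgoing synapses the
#' effective cluster count is its fan-out size (singleton clusters).
#'
#' @param fanout An [resolve_fanout()] object.
#' @param B Number of synaptic clusters per presynaptic neuron (>= 1).
#' @param K Number of cumulative-histogram bins (>= 1).
#' @param normalizer `"cluster_max"` (default) normalizes by each cluster's
#'   maximum magnitude; `"unit"` keeps the plain weight-as-probability
#'   interpretation (`p = w`, applied update `sign * 1`), which requires
#'   all magnitudes `<= 1` and is the slow-converging scheme that
#'   cluster-max normalization accelerates.
#' @return An object of class `cluster_tables`: a list with one entry per
#'   presynaptic neuron, each a list of clusters holding `mags` (descending),
#'   `asc` (the same magnitudes ascending, for binary search), `signs`,
#'   `targets` (rank-ordered postsynaptic indices), `wmax`, `nsyn`, `tp`.
#' @export
build_cluster_tables <- function(fanout, B = 8L, K = 50L,
                                 normalizer = c("cluster_max", "unit")) {
  stopifnot(inherits(fanout, "snn_fanout"))
  normalizer <- match.arg(normalizer)
  B <- as.integer(B); K <- as.integer(K)
  if (B < 1L) stop("B must be >= 1")
  if (K < 1L) stop("K must be >= 1")
  neurons <- lapply(seq_len(fanout$n_in), function(i) {
    w <- fanout$weights[[i]]; tg <- fanout$targets[[i]]
    keep <- w != 0
    w <- w[keep]; tg <- tg[keep]
    n <- length(w)
    if (n == 0L) return(structure(list(), inert = TRUE))
    b_eff <- min(B, n)
    grp <- ceiling(seq_len(n) * b_eff / n)   # contiguous blocks, sizes differ <= 1
    lapply(seq_len(b_eff), function(b) {
      sel <- grp == b
      wb <- w[sel]; tb <- tg[sel]
      ord <- order(-abs(wb), tb)             # stable: magnitude desc, index asc
      mags <- abs(wb)[ord]
      if (normalizer == "unit" && mags[1] > 1)
        stop("unit normalizer requires all weight magnitudes <= 1")
      wmax <- if (normalizer == "unit") 1 else mags[1]
      tp <- vapply(0:(K - 1L),
                   function(k) sum(mags > k * wmax / K), integer(1))
      list(mags = mags, asc = rev(mags), signs = sign(wb)[ord],
           targets = tb[ord], wmax = wmax, nsyn = length(mags), tp = tp)
    })
  })
  structure(neurons, class = "cluster_tables", B = B, K = K,
            n_out = fanout$n_out)
}

#' Cluster-max-normalized propagation probability
#'
#' The probability that a spike propagates on a synapse of magnitude `w`
#' in a cluster with maximum magnitude `w_max` is `w / w_max`: the success
#' probability of the Bernoulli trial `w > r` with `r` uniform on
#' `[0, w_max]`.
#'
#' @param w Weight magnitude(s), `0 <= w <= w_max`.
#' @param w_max Cluster maximum magnitude, `> 0`.
#' @return Probability in `[0, 1]`, vectorized over `w`.
#' @examples
#' propagation_probability(0.2, 1)   # 0.2
#' @export
propagation_probability <- function(w, w_max) {
  if (length(w_max) != 1L || !is.finite(w_max) || w_max <= 0)
    stop("degenerate cluster: w_max must be a single value > 0")
  if (any(w < 0) || any(w > w_max))
    stop("weight magnitudes must lie in [0, w_max]")
  w / w_max
}

#' Termination point by scanning sorted magnitudes
#'
#' Given a cluster's magnitudes sorted in non-increasing order and a drawn
#' threshold `r`, the termination point `t_p` is the number of leading
#' entries strictly greater than `r` — the rank of the smallest weight in
#' the cluster exceeding `r`. All synapses past `t_p` are skipped.
#'
#' @param sorted_mags Non-increasing numeric vector of magnitudes.
#' @param r Threshold(s) in `[0, w_max]`; vectorized.
#' @return Integer termination point(s).
#' @export
termination_scan <- function(sorted_mags, r) {
  n <- length(sorted_mags)
  if (n == 0L) return(rep.int(0L, length(r)))
  n - findInterval(r, rev(sorted_mags))   # count strictly greater than r
}

#' Termination point by cumulative-histogram lookup
#'
#' Returns the precomputed termination point of cluster `b` of `neuron` at
#' discrete threshold index `k` (0-based, `0 <= k < K`). Equals
#' [termination_scan()] at `r = k * w_max / K` by construction; the lookup
#' costs one memory read instead of a weight scan.
#'
#' @param tables A [build_cluster_tables()] object.
#' @param neuron Presynaptic neuron index (1-based).
#' @param b Cluster index (1-based).
#' @param k Bin index, 0-based.
#' @return Integer termination point.
#' @export
termination_lookup <- function(tables, neuron, b, k) {
  K <- attr(tables, "K")
  if (any(k < 0L) || any(k >= K)) stop("bin index k out of range [0, K)")
  tables[[neuron]][[b]]$tp[k + 1L]
}

#' Closed-form expected synaptic updates per spike
#'
#' Under continuous thresholds the expected number of propagated synapses
#' per spike from a neuron is `sum_b sum_j |w_j| / w_max(b)` (linearity over
#' per-synapse Bernoulli trials); under the `K`-bin discretization it is the
#' mean of each cluster's termination-point table. Discretized expectations
#' are never smaller than continuous ones (each synapse's discretized
#' probability is `ceil(K p) / K >= p`).
#'
#' @param tables A [build_cluster_tables()] object.
#' @param method `"continuous"` or `"discretized"`.
#' @return Numeric vector: expected updates per spike, one per presynaptic
#'   neuron.
#' @export
expected_updates <- function(tables, method = c("continuous", "discretized")) {
  method <- match.arg(method)
  vapply(tables, function(cl) {
    if (isTRUE(attr(cl, "inert"))) return(0)
    sum(vapply(cl, function(b) {
      if (method == "continuous") sum(b$mags) / b$wmax else mean(b$tp)
    }, numeric(1)))
  }, numeric(1))
}

# draw per-cluster termination points for n spikes of one neuron;
# vectorized across spikes. Returns a matrix n_spikes x n_clusters.
draw_tp_matrix <- function(clusters, n_spikes,
                           method = c("scan", "histogram"), K = NULL) {
  method <- match.arg(method)
  B <- length(clusters)
  out <- matrix(0L, n_spikes, B)
  for (b in seq_len(B)) {
    cl <- clusters[[b]]
    if (method == "scan") {
      r <- runif(n_spikes) * cl$wmax
      out[, b] <- termination_scan(cl$mags, r)
    } else {
      k <- floor(runif(n_spikes) * K)
      out[, b] <- cl$tp[k + 1L]
    }
  }
  out
}

#' Monte-Carlo synaptic updates per spike for one neuron
#'
#' Repeatedly draws per-cluster thresholds (continuous for the scan method,
#' discrete-uniform over the `K` histogram bins for the histogram method)
#' and returns the realized number of synaptic updates for each simulated
#' spike. This is the same draw-and-terminate path the engine uses,
#' vectorized for estimator studies.
#'
#' @param tables A [build_cluster_tables()] object.
#' @param neuron Presynaptic neuron index.
#' @param n_spikes Number of simulated spikes.
#' @param method `"scan"` (continuous thresholds) or `"histogram"`.
#' @param seed Integer seed.
#' @return Integer vector of length `n_spikes`.
#' @export
simulate_updates_per_spike <- function(tables, neuron, n_spikes,
                                       method = c("scan", "histogram"),
                                       seed = 1L) {
  method <- match.arg(method)
  clusters <- tables[[neuron]]
  if (isTRUE(attr(clusters, "inert"))) return(rep.int(0L, n_spikes))
  with_seed(derive_seed(seed, 211L), {
    tp <- draw_tp_matrix(clusters, n_spikes, method, K = attr(tables, "K"))
  })
  as.integer(rowSums(tp))
}
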