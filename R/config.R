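#' Run configuration
#'
#' Collects every tunable of a simulation run: timesteps, clustering and
#' histogram resolution, propagation method, neuron reset rule, input
#' encoding, and the lane / energy / storage sub-configurations of the
#' accelerator cost model. Defaults follow the regime the method targets:
#' `B = 8` clusters per neuron, `K = 50` histogram bins, 16 lanes,
#' subtract-reset integrate-and-fire neurons.
#'
#' @param timesteps Timesteps `T` per layer evaluation.
#' @param B Synaptic clusters per presynaptic neuron.
#' @param K Cumulative-histogram bins.
#' @param method `"histogram"` (termination lookup) or `"scan"`
#'   (sorted-weight early termination with continuous thresholds).
#' @param normalizer `"cluster_max"` or `"unit"`; see
#'   [build_cluster_tables()].
#' @param reset `"subtract"` (reset by subtraction of `v_th`) or `"zero"`.
#' @param encoding `"poisson"` or `"analog"` input encoding.
#' @param rate_scale Intensity-to-probability multiplier for Poisson
#'   encoding.
#' @param lanes A [lane_config()].
#' @param energy An [energy_config()].
#' @param storage A [storage_config()].
#' @param record_lane_trace Keep the per-spike lane-work trace (needed for
#'   cycle counts).
#' @param track_potentiation Accumulate the per-synapse potentiation ledger.
#' @return An object of class `run_config`.
#' @export
run_config <- function(timesteps = 100L, B = 8L, K = 50L,
                       method = c("histogram", "scan"),
                       normalizer = c("cluster_max", "unit"),
                       reset = c("subtract", "zero"),
                       encoding = c("poisson", "analog"),
                       rate_scale = 1,
                       lanes = lane_config(),
                       energy = energy_config(),
                       storage = storage_config(),
                       record_lane_trace = TRUE,
                       track_potentiation = FALSE) {
  method <- match.arg(method); reset <- match.arg(reset)
  normalizer <- match.arg(normalizer); encoding <- match.arg(encoding)
  timesteps <- as.integer(timesteps); B <- as.integer(B); K <- as.integer(K)
  if (timesteps < 1L) stop("config error: timesteps must be >= 1")
  if (B < 1L) stop("config error: B must be >= 1")
  if (K < 1L) stop("config error: K must be >= 1")
  if (rate_scale <= 0) stop("config error: rate_scale must be > 0")
  structure(list(timesteps = timesteps, B = B, K = K, method = method,
                 normalizer = normalizer,
                 reset = reset, encoding = encoding, rate_scale = rate_scale,
                 lanes = lanes, energy = energy, storage = storage,
                 record_lane_trace = isTRUE(record_lane_trace),
                 track_potentiation = isTRUE(track_potentiation)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> T=", x$timesteps, " B=", x$B, " K=", x$K,
      " method=", x$method, " reset=", x$reset, " encoding=", x$encoding,
      " lanes=", x$lanes$n_lanes, "\n", sep = "")
  invisible(x)
}

#' Write / read a run configuration as structured text
#'
#' The YAML round trip is exact (`read_run_config(write_run_config(cfg))`
#' equals `cfg`), and unknown keys in a file are rejected with the
#' offending key named.
#'
#' @param cfg A [run_config()].
#' @param path File path.
#' @return `write_run_config()` the path, invisibly; `read_run_config()` a
#'   `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  flat <- unclass(cfg)
  flat$lanes <- unclass(flat$lanes)
  flat$energy <- unclass(flat$energy)
  flat$storage <- unclass(flat$storage)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("config error: unknown key(s): ", paste(bad, collapse = ", "))
  args <- raw
  if (!is.null(args$lanes)) args$lanes <- do.call(lane_config, args$lanes)
  if (!is.null(args$energy)) args$energy <- do.call(energy_config, args$energy)
  if (!is.null(args$storage)) args$storage <- do.call(storage_config, args$storage)
  do.call(run_config, args)
}
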