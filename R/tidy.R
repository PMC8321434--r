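#' Tidy a network inference run
#'
#' One row per layer with the propagation counters: spikes served,
#' synaptic updates, memory reads by category, writes, and the cycle
#' counts under synchronous and asynchronous spike serving.
#'
#' @param x An [run_inference()] result.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.snn_run <- function(x, ...) {
  rows <- lapply(seq_along(x$layers), function(l) {
    s <- x$layers[[l]]$stats
    tibble::tibble(layer = l, mode = x$modes[l], spikes = s$spikes,
                   synaptic_updates = s$synaptic_updates,
                   reads_weight = s$reads[["weight"]],
                   reads_state = s$reads[["state"]],
                   reads_index = s$reads[["index"]],
                   reads_tp_table = s$reads[["tp_table"]],
                   reads_w_max = s$reads[["w_max"]],
                   writes = s$writes,
                   cycles_sync = s$cycles_sync,
                   cycles_async = s$cycles_async)
  })
  dplyr::bind_rows(rows)
}

#' One-row summary of a network inference run
#'
#' @param x An [run_inference()] result.
#' @param ... Unused.
#' @return A tibble with the prediction, totals over layers, and the
#'   energy estimate under the run's energy configuration.
#' @export
glance.snn_run <- function(x, ...) {
  td <- tidy(x)
  reads <- sum(td$reads_weight + td$reads_state + td$reads_index +
                 td$reads_tp_table + td$reads_w_max)
  energy <- sum(vapply(x$layers, function(lr)
    energy_estimate(lr$stats, x$config$energy), numeric(1)))
  tibble::tibble(prediction = x$prediction,
                 spikes = sum(td$spikes),
                 synaptic_updates = sum(td$synaptic_updates),
                 reads = reads, writes = sum(td$writes),
                 cycles_sync = sum(td$cycles_sync),
                 cycles_async = sum(td$cycles_async),
                 energy = energy)
}

#' Raster plot of a spike train
#'
#' @param object A [spike_train()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spike_train <- function(object, ...) {
  df <- tibble::tibble(
    neuron = rep.int(seq_len(object$n), spike_counts(object)),
    timestep = unlist(object$times, use.names = FALSE))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timestep, y = .data$neuron)) +
    ggplot2::geom_point(shape = "|", size = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "timestep", y = "neuron") +
    ggplot2::theme_minimal()
}

#' Plot a cluster or bin sweep
#'
#' For a cluster sweep, agreement with the deterministic baseline and mean
#' synaptic updates per inference against `B`; for a bin sweep, agreement
#' and memory overhead against `K`.
#'
#' @param object A [sweep_clusters()] or [sweep_bins()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.snn_sweep <- function(object, ...) {
  xvar <- if ("B" %in% names(object)) "B" else "K"
  yvars <- intersect(c("agreement", "mean_updates", "memory_overhead",
                       "expected_updates_per_spike"), names(object))
  long <- tidyr_pivot(object, xvar, yvars)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = xvar, y = NULL) +
    ggplot2::theme_minimal()
}

# minimal long-format reshape (avoids a tidyr dependency for one call)
tidyr_pivot <- function(df, xvar, yvars) {
  dplyr::bind_rows(lapply(yvars, function(v)
    tibble::tibble(x = df[[xvar]], metric = v, value = df[[v]])))
}

#' Potentiation-convergence plot
#'
#' Plots the per-synapse average potentiation from a [potentiation_ledger()]
#' against the true synaptic weights; points on the diagonal indicate the
#' unbiased-estimator regime.
#'
#' @param ledger A [potentiation_ledger()] tibble.
#' @return A ggplot object.
#' @export
plot_potentiation <- function(ledger) {
  ggplot2::ggplot(ledger,
                  ggplot2::aes(x = .data$weight, y = .data$mean_potentiation)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "synaptic weight", y = "average potentiation") +
    ggplot2::theme_minimal()
}
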