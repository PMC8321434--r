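#' Define one feed-forward layer
#'
#' A layer connects `n_in` presynaptic neurons to `n_out` postsynaptic
#' integrate-and-fire neurons. Dense layers carry one weight per
#' (presynaptic, postsynaptic) pair; locally connected layers share a 1-D
#' kernel that is slid across the input with a stride, with `channels`
#' independent kernels producing `channels` output maps.
#'
#' Weights are stored unnormalized and may be negative (inhibitory
#' synapses). Propagation probabilities are always computed on weight
#' magnitudes relative to per-cluster maxima, so no global rescaling to
#' \[0, 1\] is ever applied; the applied update carries the synapse's sign.
#'
#' @param n_in Number of presynaptic neurons.
#' @param n_out Number of postsynaptic neurons. For `"local"` connectivity
#'   this must equal `n_positions * channels`, where
#'   `n_positions = floor((n_in - kernel) / stride) + 1`.
#' @param weights Dense: an `n_in x n_out` numeric matrix. Local: a
#'   `kernel x channels` numeric matrix of shared kernel weights.
#' @param bias Numeric scalar or length-`n_out` vector added to every
#'   postsynaptic membrane potential at each evaluation step.
#' @param v_th Threshold voltage, scalar or length-`n_out`; must be > 0.
#' @param connectivity `"dense"` or `"local"`.
#' @param kernel,stride,channels Local-connectivity geometry (1-D).
#' @return An object of class `snn_layer`.
#' @examples
#' layer_spec(2, 3, weights = matrix(c(.1, .2, .3, .4, .5, .6), 2, 3, byrow = TRUE))
#' @export
layer_spec <- function(n_in, n_out, weights, bias = 0, v_th = 1,
                       connectivity = c("dense", "local"),
                       kernel = NULL, stride = NULL, channels = NULL) {
  connectivity <- match.arg(connectivity)
  n_in <- as.integer(n_in)
  n_out <- as.integer(n_out)
  if (n_in < 1L || n_out < 1L) stop("layer sizes must be >= 1")
  weights <- as.matrix(weights)
  if (!all(is.finite(weights))) stop("all synapse weights must be finite")
  if (connectivity == "dense") {
    if (!identical(dim(weights), c(n_in, n_out)))
      stop("dense layer requires an n_in x n_out weight matrix (got ",
           nrow(weights), " x ", ncol(weights), ")")
  } else {
    if (is.null(kernel) || is.null(stride) || is.null(channels))
      stop("local connectivity requires kernel, stride and channels")
    kernel <- as.integer(kernel); stride <- as.integer(stride)
    channels <- as.integer(channels)
    if (kernel < 1L || stride < 1L || channels < 1L || kernel > n_in)
      stop("inconsistent kernel/stride/size for local layer: kernel=", kernel,
           " stride=", stride, " n_in=", n_in)
    n_pos <- (n_in - kernel) %/% stride + 1L
    if (n_out != n_pos * channels)
      stop("local layer n_out (", n_out, ") must equal positions*channels (",
           n_pos * channels, ")")
    if (!identical(dim(weights), c(kernel, channels)))
      stop("local layer requires a kernel x channels weight matrix")
  }
  bias <- rep_len(as.numeric(bias), n_out)
  v_th <- rep_len(as.numeric(v_th), n_out)
  if (any(!is.finite(v_th)) || any(v_th <= 0)) stop("v_th must be finite and > 0")
  structure(
    list(n_in = n_in, n_out = n_out, connectivity = connectivity,
         weights = weights, bias = bias, v_th = v_th,
         kernel = kernel, stride = stride, channels = channels),
    class = "snn_layer")
}

#' Assemble layers into a feed-forward network
#'
#' @param layers List of [layer_spec()] objects; layer `l`'s `n_in` must
#'   equal layer `l-1`'s `n_out`.
#' @param name Network name, stored in the container manifest.
#' @param metadata Named character list of free-form annotations.
#' @return An object of class `snn_network`.
#' @export
network_spec <- function(layers, name = "network", metadata = list()) {
  if (length(layers) < 1L) stop("a network needs at least one layer")
  for (l in seq_along(layers)) {
    if (!inherits(layers[[l]], "snn_layer"))
      stop("layers[[", l, "]] is not a layer_spec object")
    if (l > 1L && layers[[l]]$n_in != layers[[l - 1L]]$n_out)
      stop("layer ", l, " input size (", layers[[l]]$n_in,
           ") does not match layer ", l - 1L, " output size (",
           layers[[l - 1L]]$n_out, ")")
  }
  structure(list(layers = layers, name = as.character(name),
                 metadata = metadata),
            class = "snn_network")
}

#' @export
print.snn_network <- function(x, ...) {
  cat("<snn_network> '", x$name, "': ", length(x$layers), " layer(s)\n", sep = "")
  for (l in seq_along(x$layers)) {
    ly <- x$layers[[l]]
    cat(sprintf("  [%d] %s %d -> %d (%d synapses)\n", l, ly$connectivity,
                ly$n_in, ly$n_out, n_synapses(ly)))
  }
  invisible(x)
}

#' Number of synapses in a layer
#'
#' For dense layers this is `n_in * n_out`; for local layers it is the sum
#' of per-presynaptic-neuron fan-out sizes implied by the kernel footprint.
#' @param layer A [layer_spec()] object.
#' @return Integer synapse count.
#' @export
n_synapses <- function(layer) {
  if (layer$connectivity == "dense") return(layer$n_in * layer$n_out)
  fo <- resolve_fanout(layer)
  sum(vapply(fo$targets, length, integer(1)))
}

#' Resolve the fan-out of every presynaptic neuron in a layer
#'
#' The fan-out of presynaptic neuron `i` is the ordered set of
#' (postsynaptic index, weight) pairs its spikes reach; spike propagation
#' iterates over exactly this set. The ordering is ascending postsynaptic
#' index, which makes fan-out resolution pure and reproducible.
#'
#' @param layer A [layer_spec()] object.
#' @return An object of class `snn_fanout`: a list with `targets` and
#'   `weights` (each a list with one vector per presynaptic neuron),
#'   `n_in`, `n_out` and `n_syn`.
#' @export
resolve_fanout <- function(layer) {
  stopifnot(inherits(layer, "snn_layer"))
  if (layer$connectivity == "dense") {
    targets <- rep(list(seq_len(layer$n_out)), layer$n_in)
    weights <- lapply(seq_len(layer$n_in), function(i) unname(layer$weights[i, ]))
  } else {
    k <- layer$kernel; s <- layer$stride; ch <- layer$channels
    n_pos <- (layer$n_in - k) %/% s + 1L
    targets <- vector("list", layer$n_in)
    weights <- vector("list", layer$n_in)
    for (i in seq_len(layer$n_in)) {
      # positions p (1-based) whose footprint [ (p-1)s+1, (p-1)s+k ] covers i
      p_lo <- max(1L, ceiling((i - k) / s) + 1L)
      p_hi <- min(n_pos, (i - 1L) %/% s + 1L)
      if (p_lo > p_hi) { targets[[i]] <- integer(0); weights[[i]] <- numeric(0); next }
      pos <- p_lo:p_hi
      off <- i - (pos - 1L) * s            # kernel row, 1..k
      # output index = (c-1)*n_pos + p, channels outermost
      tg <- as.integer(outer(pos, (seq_len(ch) - 1L) * n_pos, `+`))
      wt <- as.numeric(layer$weights[cbind(rep(off, ch),
                                           rep(seq_len(ch), each = length(pos)))])
      ord <- order(tg)
      targets[[i]] <- tg[ord]; weights[[i]] <- wt[ord]
    }
  }
  structure(list(targets = targets, weights = weights,
                 n_in = layer$n_in, n_out = layer$n_out,
                 n_syn = sum(vapply(targets, length, integer(1)))),
            class = "snn_fanout")
}

## ---- container format -------------------------------------------------
## Single-file JSON container, format version 1. Doubles are serialized as
## decimal strings with 17 significant digits so that save -> load is an
## exact round trip and repeated saves are byte-identical.

fmt_dbl <- function(x) sprintf("%.17g", as.numeric(x))

#' Save / load a network container
#'
#' Writes the network to a single JSON file holding a manifest (format
#' version, name, metadata, layer shapes and connectivity) plus the weight,
#' bias and threshold arrays. Numeric values are stored as 17-significant-
#' digit decimal strings, so `load_network(save_network(net))` reproduces
#' the network exactly and the file bytes are deterministic.
#'
#' @param net An [network_spec()] object.
#' @param path File path.
#' @return `save_network()` returns `path` invisibly; `load_network()`
#'   returns the `snn_network`.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "snn_network"))
  layers <- lapply(net$layers, function(ly) {
    out <- list(n_in = ly$n_in, n_out = ly$n_out,
                connectivity = ly$connectivity,
                weights_dim = dim(ly$weights),
                weights = fmt_dbl(ly$weights),
                bias = fmt_dbl(ly$bias),
                v_th = fmt_dbl(ly$v_th))
    if (ly$connectivity == "local")
      out <- c(out, list(kernel = ly$kernel, stride = ly$stride,
                         channels = ly$channels))
    out
  })
  obj <- list(format = "spikeprop-network", version = 1L,
              name = net$name, metadata = net$metadata, layers = layers)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE,
                                     simplifyDataFrame = FALSE),
                  error = function(e) stop("malformed network container: ",
                                           conditionMessage(e), call. = FALSE))
  if (!identical(obj$format, "spikeprop-network"))
    stop("malformed network container: missing or wrong 'format' field")
  if (is.null(obj$layers) || length(obj$layers) == 0L)
    stop("malformed network container: no 'layers'")
  layers <- lapply(seq_along(obj$layers), function(l) {
    ol <- obj$layers[[l]]
    for (f in c("n_in", "n_out", "connectivity", "weights", "bias", "v_th",
                "weights_dim"))
      if (is.null(ol[[f]]))
        stop("malformed network container: layer ", l, " missing field '", f, "'")
    w <- matrix(as.numeric(ol$weights), nrow = ol$weights_dim[1],
                ncol = ol$weights_dim[2])
    layer_spec(ol$n_in, ol$n_out, weights = w, bias = as.numeric(ol$bias),
               v_th = as.numeric(ol$v_th), connectivity = ol$connectivity,
               kernel = ol$kernel, stride = ol$stride, channels = ol$channels)
  })
  md <- obj$metadata
  if (length(md) == 0L) md <- list()
  network_spec(layers, name = obj$name, metadata = md)
}
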