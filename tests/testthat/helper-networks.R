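# small random fixtures, all built in code

random_small_net <- function(seed, n_layers = 2, size_range = 3:8,
                             median = 0.3) {
  sizes <- withr::with_seed(seed,
    sample(size_range, n_layers + 1, replace = TRUE))
  generate_network(sizes,
                   dist = weight_dist_spec(median = median, spread = 0.5),
                   seed = seed)
}

random_cluster_table <- function(seed, n_max = 64, K_max = 32) {
  withr::with_seed(seed, {
    n <- sample(1:n_max, 1)
    K <- sample(1:K_max, 1)
    w <- runif(n, 0.01, 1)
    fo <- resolve_fanout(layer_spec(1, n, matrix(w, 1)))
    list(tables = build_cluster_tables(fo, B = 1, K = K), weights = w, K = K)
  })
}

# brute-force termination-point oracle: count of weights strictly above r
brute_count_above <- function(weights, r) sum(abs(weights) > r)
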