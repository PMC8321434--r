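test_that("cluster construction partitions, sorts and tabulates as specified", {
  fo <- resolve_fanout(layer_spec(1, 4, matrix(c(.5, 1.0, .25, .75), 1)))
  tab <- build_cluster_tables(fo, B = 2, K = 4)
  cl <- tab[[1]]
  expect_length(cl, 2)
  expect_equal(cl[[1]]$mags, c(1.0, .5))
  expect_equal(cl[[1]]$targets, c(2L, 1L))
  expect_equal(cl[[1]]$wmax, 1.0)
  expect_equal(cl[[2]]$mags, c(.75, .25))
  expect_equal(cl[[2]]$targets, c(4L, 3L))
  expect_equal(cl[[2]]$wmax, .75)

  # termination table over thresholds {0, .3, .6} for mags {.9,.6,.3}
  fo3 <- resolve_fanout(layer_spec(1, 3, matrix(c(.9, .6, .3), 1)))
  tab3 <- build_cluster_tables(fo3, B = 1, K = 3)
  expect_equal(tab3[[1]][[1]]$tp, c(3L, 2L, 1L))

  # all-equal weights: every threshold below w_max, full propagation
  foe <- resolve_fanout(layer_spec(1, 5, matrix(rep(.4, 5), 1)))
  tabe <- build_cluster_tables(foe, B = 1, K = 7)
  expect_equal(tabe[[1]][[1]]$tp, rep(5L, 7))

  # empty fan-out -> inert table
  lyl <- layer_spec(5, 2, matrix(1, 2, 1), connectivity = "local",
                    kernel = 2, stride = 2, channels = 1)
  tabl <- build_cluster_tables(resolve_fanout(lyl), B = 2, K = 3)
  expect_true(isTRUE(attr(tabl[[5]], "inert")))
})

test_that("cluster-table invariants hold on random instances", {
  for (seed in 1:20) {
    rc <- random_cluster_table(seed)
    cl <- rc$tables[[1]][[1]]
    expect_true(all(diff(cl$mags) <= 0))
    expect_true(all(cl$tp >= 0 & cl$tp <= cl$nsyn))
    expect_true(all(diff(cl$tp) <= 0))          # non-increasing in k
    expect_equal(cl$tp[1], sum(cl$mags > 0))    # k = 0 threshold
    expect_equal(cl$wmax, cl$mags[1])
  }
})

test_that("propagation probability is the cluster-max-normalized magnitude", {
  expect_equal(propagation_probability(1, 1), 1.0)
  expect_equal(propagation_probability(0, 1), 0.0)
  # cluster max five times the median: median synapse propagates at 0.2
  expect_equal(propagation_probability(0.1, 0.5), 0.2)
  expect_error(propagation_probability(0.1, 0), "degenerate")
  expect_error(propagation_probability(2, 1), "\\[0, w_max\\]")
})

test_that("scan termination point counts leading magnitudes above the threshold", {
  expect_equal(termination_scan(c(1.0, .5, .2), .4), 2L)
  expect_equal(termination_scan(c(1.0, .5, .2), 1.0), 0L)
  expect_equal(termination_scan(c(1.0, .5, .2), 0), 3L)
  # ties at the threshold are excluded (strict comparison)
  expect_equal(termination_scan(c(.5, .5, .2), .5), 0L)

  withr::with_seed(99, {
    for (rep in 1:1000) {
      n <- sample(1:30, 1)
      w <- runif(n)
      r <- runif(1)
      expect_equal(termination_scan(sort(w, decreasing = TRUE), r),
                   brute_count_above(w, r))
    }
  })
})

test_that("histogram lookup equals the scan at every discrete threshold", {
  for (seed in 1:200) {
    rc <- random_cluster_table(seed, n_max = 40, K_max = 16)
    cl <- rc$tables[[1]][[1]]
    K <- rc$K
    for (k in 0:(K - 1)) {
      r_k <- k * cl$wmax / K
      expect_identical(termination_lookup(rc$tables, 1, 1, k),
                       termination_scan(cl$mags, r_k))
    }
  }
  rc <- random_cluster_table(1)
  expect_error(termination_lookup(rc$tables, 1, 1, rc$K), "out of range")
  # K = 1: the single threshold is 0, every spike propagates everywhere
  fo <- resolve_fanout(layer_spec(1, 6, matrix(runif(6, .1, 1), 1)))
  t1 <- build_cluster_tables(fo, B = 1, K = 1)
  expect_equal(termination_lookup(t1, 1, 1, 0), 6L)
})

test_that("expected updates per spike match the closed form", {
  fo <- resolve_fanout(layer_spec(1, 3, matrix(c(.9, .6, .3), 1)))
  tab <- build_cluster_tables(fo, B = 1, K = 3)
  expect_equal(expected_updates(tab, "continuous"), 2.0)
  expect_equal(expected_updates(tab, "discretized"), 2.0)

  # all weights equal: exactly n_syn in both schemes
  foe <- resolve_fanout(layer_spec(1, 4, matrix(rep(.7, 4), 1)))
  tabe <- build_cluster_tables(foe, B = 1, K = 5)
  expect_equal(expected_updates(tabe, "continuous"), 4)
  expect_equal(expected_updates(tabe, "discretized"), 4)
})

test_that("discretization never lowers propagation probabilities, gap below 1/K", {
  for (seed in 1:25) {
    rc <- random_cluster_table(seed, n_max = 32, K_max = 16)
    cl <- rc$tables[[1]][[1]]
    K <- rc$K
    p_cont <- cl$mags / cl$wmax
    # per-synapse discretized probability: share of bins whose threshold lies below
    p_disc <- vapply(cl$mags, function(m)
      sum(m > (0:(K - 1)) * cl$wmax / K) / K, numeric(1))
    expect_true(all(p_disc >= p_cont - 1e-12))
    expect_true(all(p_disc - p_cont < 1 / K + 1e-12))
    expect_gte(expected_updates(rc$tables, "discretized"),
               expected_updates(rc$tables, "continuous") - 1e-12)
  }
})

test_that("expected updates are non-decreasing under refining partitions", {
  withr::with_seed(5, {
    w <- runif(32, .01, 1)
  })
  fo <- resolve_fanout(layer_spec(1, 32, matrix(w, 1)))
  eu <- vapply(c(1, 2, 4, 8, 16, 32), function(B)
    expected_updates(build_cluster_tables(fo, B = B, K = 8), "continuous"),
    numeric(1))
  expect_true(all(diff(eu) >= -1e-12))
  expect_equal(eu[length(eu)], 32)   # singleton clusters: everything propagates
})

test_that("singleton clusters reproduce the deterministic engine bit-for-bit", {
  net <- random_small_net(61)
  stim <- rep(0.5, net$layers[[1]]$n_in)
  cfg_d <- run_config(timesteps = 20)
  for (method in c("histogram", "scan")) {
    cfg_p <- run_config(timesteps = 20, B = 64, K = 6, method = method)
    rd <- run_inference(net, stim, "deterministic", cfg_d, seed = 8)
    rp <- run_inference(net, stim, "probabilistic", cfg_p, seed = 8)
    expect_identical(rp$prediction, rd$prediction)
    for (l in seq_along(net$layers))
      expect_identical(rp$layers[[l]]$output, rd$layers[[l]]$output)
    expect_equal(tidy(rp)$synaptic_updates, tidy(rd)$synaptic_updates)
  }
})

test_that("per-synapse potentiation is an unbiased estimate of the weight", {
  withr::with_seed(3, {
    w <- runif(12, 0.05, 1)
  })
  ly <- layer_spec(1, 12, matrix(w, 1), v_th = 1e9)
  net <- network_spec(list(ly))
  C <- 5000L
  cfg <- run_config(B = 3, method = "scan", track_potentiation = TRUE)
  run <- run_inference(net, spike_train(list(seq_len(C)), 1, C),
                       "probabilistic", cfg, seed = 12)
  led <- potentiation_ledger(run)
  tab <- build_cluster_tables(resolve_fanout(ly), B = 3, K = 50)
  # map each synapse to its cluster w_max
  wmax_of <- numeric(12)
  for (cl in tab[[1]]) wmax_of[cl$targets] <- cl$wmax
  p <- w / wmax_of
  se <- wmax_of * sqrt(p * (1 - p) / C)
  expect_true(all(abs(led$mean_potentiation - led$weight) <= 4 * se + 1e-12))
})

test_that("Monte-Carlo updates per spike agree with the closed form", {
  rc <- random_cluster_table(7, n_max = 24, K_max = 12)
  for (method in c("scan", "histogram")) {
    u <- simulate_updates_per_spike(rc$tables, 1, 20000, method, seed = 4)
    expected <- expected_updates(rc$tables,
      if (method == "scan") "continuous" else "discretized")
    se <- stats::sd(u) / sqrt(length(u))
    expect_lt(abs(mean(u) - expected), 4 * se + 1e-9)
  }
})
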