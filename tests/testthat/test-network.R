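# Communication-network cluster analysis and behavioural metrics.

edge_graph <- function(edges, n) {
  structure(list(edges = edges, n = n, ids = seq_len(n),
                 timestamp = NA_integer_), class = "comm_graph")
}

# minimal sim_result scaffold for metric tests
fake_result <- function(times, pos, att, state, init_att, final_state,
                        arrival = NULL, comm = comm_params()) {
  n <- length(init_att)
  structure(list(
    times = times, pos = pos, att = att, state = state,
    arrival = arrival %||% rep(NA_real_, n),
    final_state = final_state, init_attitudes = init_att,
    config = list(comm = comm, retain_evacuated_influence = FALSE)
  ), class = "sim_result")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("SCC extraction handles trivial graphs", {
  g <- edge_graph(data.frame(from = integer(0), to = integer(0)), 5)
  cl <- extract_clusters(g)
  expect_equal(sort(unname(cl$membership)), 1:5) # all singletons
  expect_true(all(cl$clusters$size == 1))

  # 3-cycle plus an isolated node
  g <- edge_graph(data.frame(from = c(1, 2, 3), to = c(2, 3, 1)), 4)
  cl <- extract_clusters(g)
  expect_setequal(cl$clusters$size, c(3, 1))
  expect_equal(length(unique(cl$membership[1:3])), 1)
})

test_that("SCC partition matches the reachability oracle on random digraphs", {
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(10:30, 1)
    e <- random_digraph(n)
    g <- edge_graph(e, n)
    cl <- extract_clusters(g)
    oracle <- oracle_scc(e, n)
    expect_equal(canon_partition(cl$membership), canon_partition(oracle))
    # partition property: sizes sum to n
    expect_equal(sum(cl$clusters$size), n)
  }
})

test_that("cluster centres and mean attitudes summarise the members", {
  pos <- rbind(c(0, 0), c(2, 0), c(1, 3), c(50, 50))
  att <- c(0.2, 0.4, 0.6, -0.5)
  g <- edge_graph(data.frame(from = c(1, 2, 3), to = c(2, 3, 1)), 4)
  cl <- extract_clusters(g, positions = pos, attitudes = att)
  big <- cl$clusters[cl$clusters$size == 3, ]
  expect_equal(big$x, 1)
  expect_equal(big$y, 1)
  expect_equal(big$mean_attitude, 0.4)
})

test_that("large/small group split counts evacuating members inclusively", {
  # 12 co-located evacuating agents (one SCC) + 3 isolated evacuees
  pos <- rbind(matrix(rep(c(10, 10), each = 12), 12),
               c(100, 100), c(200, 200), c(300, 300))
  att <- c(rep(0.6, 12), rep(0.9, 3))
  st <- rep(1L, 15)
  res <- fake_result(times = 0, pos = list(pos), att = list(att),
                     state = list(st), init_att = att, final_state = st)
  ts <- group_size_timeseries(res, size_threshold = 10)
  expect_equal(ts$large, 12)
  expect_equal(ts$small, 3)
  expect_equal(ts$evacuating, 15)

  # threshold is inclusive: a cluster of exactly 10 counts as large
  pos10 <- matrix(rep(c(5, 5), each = 10), 10)
  att10 <- rep(0.7, 10)
  res10 <- fake_result(0, list(pos10), list(att10), list(rep(1L, 10)),
                       att10, rep(1L, 10))
  expect_equal(group_size_timeseries(res10, 10)$large, 10)

  # nobody evacuating
  res0 <- fake_result(0, list(pos10), list(att10), list(rep(0L, 10)),
                      att10, rep(0L, 10))
  ts0 <- group_size_timeseries(res0, 10)
  expect_equal(c(ts0$large, ts0$small), c(0, 0))
})

test_that("cluster trajectories filter by attitude sign and size", {
  pos <- rbind(matrix(rep(c(10, 10), each = 5), 5),
               matrix(rep(c(60, 60), each = 4), 4),
               c(120, 120))
  att <- c(rep(0.6, 5), rep(-0.4, 4), 0.9)
  st <- c(rep(1L, 5), rep(0L, 4), 1L)
  res <- fake_result(0, list(pos), list(att), list(st), att, st)
  pos_tr <- cluster_trajectories(res, "positive", min_size = 2)
  expect_equal(nrow(pos_tr), 1)
  expect_equal(pos_tr$size, 5)
  expect_equal(pos_tr$mean_attitude, 0.6)
  neg_tr <- cluster_trajectories(res, "negative", min_size = 2)
  expect_equal(nrow(neg_tr), 1)
  expect_equal(neg_tr$size, 4)
  # singletons excluded at min_size = 2: the lone 0.9 agent appears nowhere
  expect_false(any(pos_tr$size == 1))
  expect_equal(max_negative_cluster(res), 4)
})

test_that("evacuated-attitude histogram and moderate band behave at the edges", {
  att <- c(-0.5, 0.3, 0.9, 0.6)
  res <- fake_result(0, list(matrix(0, 4, 2)), list(att), list(rep(0L, 4)),
                     init_att = att, final_state = c(0L, 0L, 2L, 2L))
  h <- evacuated_attitude_histogram(res)
  expect_equal(sum(h$counts), 2)
  expect_equal(h$band_fraction, 0.5) # 0.6 in band, 0.9 out
  expect_error(evacuated_attitude_histogram(res, bin_width = 0.3), "divide")

  # nobody evacuated: all-zero histogram
  res0 <- fake_result(0, list(matrix(0, 4, 2)), list(att), list(rep(0L, 4)),
                      init_att = att, final_state = rep(0L, 4))
  h0 <- evacuated_attitude_histogram(res0)
  expect_true(all(h0$counts == 0))
  expect_true(is.nan(h0$band_fraction))

  # all evacuated agents very positive: band fraction zero
  res1 <- fake_result(0, list(matrix(0, 4, 2)), list(att), list(rep(0L, 4)),
                      init_att = c(0.9, 0.95, 0.85, 0.99),
                      final_state = rep(2L, 4))
  expect_equal(evacuated_attitude_histogram(res1)$band_fraction, 0)
})

test_that("frozen-attitude runs match the analytic conditional band share", {
  # mu = 0: evacuated set == {A0 >= 0.5}, so the moderate-band share
  # estimates P(0.5 <= A <= 0.8 | A >= 0.5) = 0.6 under Uniform(-1, 1)
  cfg <- tiny_config("root", n_agents = 400, horizon = 400, seed = 8,
                     comm = comm_params(mu = 0))
  res <- run_simulation(cfg)
  h <- evacuated_attitude_histogram(res)
  n_ev <- h$n_evacuated
  expect_equal(n_ev, sum(res$init_attitudes >= 0.5))
  expect_lt(abs(h$band_fraction - 0.6), 3 * sqrt(0.6 * 0.4 / n_ev))
})

test_that("behaviour-change ratio counts dissuaded high-attitude agents", {
  att <- c(0.6, 0.7, 0.3, -0.2)
  res <- fake_result(0, list(matrix(0, 4, 2)), list(att), list(rep(0L, 4)),
                     init_att = att, final_state = c(2L, 0L, 2L, 0L))
  expect_equal(behaviour_change_ratio(res), 0.5) # one of two high failed
  res_low <- fake_result(0, list(matrix(0, 4, 2)), list(att), list(rep(0L, 4)),
                         init_att = rep(-0.5, 4), final_state = rep(0L, 4))
  expect_error(behaviour_change_ratio(res_low), "no agent")
})

test_that("time normalisation divides by the last arrival", {
  att <- rep(0.9, 3)
  res <- fake_result(c(0, 50, 100), NULL, NULL, NULL, att,
                     final_state = rep(2L, 3),
                     arrival = c(20, 100, 60))
  expect_equal(normalise_time(res), c(0, 0.5, 1))
  res_none <- fake_result(0, NULL, NULL, NULL, att, rep(0L, 3))
  expect_error(normalise_time(res_none), "no agent evacuated")
})
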