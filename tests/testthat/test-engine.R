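# Coupled simulation engine and stochastic ensembles.

test_that("decoupled limits give complete or zero evacuation", {
  # unanimous intent, no communication: everyone walks out and arrives
  cfg <- tiny_config("grid", n_agents = 30, horizon = 400, seed = 1,
                     comm = comm_params(epsilon_fn = function(A) rep(0, length(A))))
  res <- run_simulation(cfg, init_attitudes = rep(1, 30))
  expect_equal(completion_ratio(res), 1.0)
  expect_true(all(!is.na(res$arrival)))
  expect_true(all(res$arrival <= cfg$horizon))

  # unanimous refusal, no leaders: nobody moves, run exits at a fixed point
  res0 <- run_simulation(cfg, init_attitudes = rep(-1, 30))
  expect_equal(completion_ratio(res0), 0.0)
  expect_true(res0$ended_early)
})

test_that("frozen attitudes reproduce the analytic completion fraction", {
  # mu = 0: decisions are fixed by the initial draw; completion equals the
  # empirical P(A >= 0.5), which estimates 0.25 under Uniform(-1, 1)
  cfg <- tiny_config("root", n_agents = 400, horizon = 400, seed = 8,
                     comm = comm_params(mu = 0))
  res <- run_simulation(cfg)
  frac_high <- mean(res$init_attitudes >= 0.5)
  expect_equal(completion_ratio(res), frac_high, tolerance = 1e-12)
  # binomial 3-sigma band around the analytic 0.25
  expect_lt(abs(frac_high - 0.25), 3 * sqrt(0.25 * 0.75 / 400))
  expect_equal(behaviour_change_ratio(res), 0)
})

test_that("completion ratio counts evacuated agents and is monotone in time", {
  cfg <- tiny_config("root", n_agents = 60, horizon = 300, seed = 4)
  res <- run_simulation(cfg)
  evac_counts <- vapply(res$state, function(s) sum(s == 2L), numeric(1))
  expect_true(all(diff(evac_counts) >= 0))
  expect_equal(completion_ratio(res),
               sum(res$final_state == 2L) / cfg$n_agents)
  expect_true(all(res$arrival <= cfg$horizon, na.rm = TRUE))
  # states only take the three defined codes
  expect_true(all(unlist(res$state) %in% 0:2))
})

test_that("relative difference follows the definition and rejects zero base", {
  expect_equal(relative_difference(0.4, 0.4), 0)
  expect_equal(relative_difference(0.3, 0.1), 200)
  expect_equal(relative_difference(c(0.2, 0.6), c(0.1, 0.3)), c(100, 100))
  expect_error(relative_difference(0.3, 0), "undefined")
})

test_that("ensembles are reproducible and summaries match the runs", {
  cfg <- tiny_config("root", n_agents = 50, horizon = 150, seed = 12)
  e1 <- run_ensemble(cfg, 4, mode = "attitudes")
  e2 <- run_ensemble(cfg, 4, mode = "attitudes")
  expect_identical(e1$metrics, e2$metrics)
  expect_equal(nrow(e1$metrics), 4)
  # single-run ensemble: degenerate summary
  e3 <- run_ensemble(cfg, 1, mode = "attitudes")
  expect_equal(e3$summary$median, e3$metrics$completion[1])
  expect_equal(e3$summary$q1, e3$summary$q3)
  # box summary recomputable from per-run values
  s <- box_stats(e1$metrics$completion)
  expect_equal(s$median, unname(quantile(e1$metrics$completion, 0.5)))
})

test_that("median_run reproduces the lower-median completion case", {
  cfg <- tiny_config("root", n_agents = 50, horizon = 150, seed = 12)
  ens <- run_ensemble(cfg, 5, mode = "attitudes")
  med <- median_run(ens)
  expect_equal(completion_ratio(med), sort(ens$metrics$completion)[3])
  ens4 <- run_ensemble(cfg, 4, mode = "attitudes")
  med4 <- median_run(ens4)
  expect_equal(completion_ratio(med4), sort(ens4$metrics$completion)[2])
})

test_that("leader-mode ensembles fix attitudes and draw exact leader counts", {
  cfg <- tiny_config("root", n_agents = 50, horizon = 100, seed = 3)
  base <- run_simulation(cfg)
  cfg$leader_fraction <- 0.1
  ens <- run_ensemble(cfg, 3, mode = "leaders", base_run = base,
                      keep_results = TRUE)
  expect_true(all(ens$metrics$n_leaders == 5))
  for (r in ens$results) {
    expect_identical(r$init_positions, base$init_positions)
    # non-leader agents keep the base initial attitudes; leaders are pinned
    nl <- setdiff(seq_len(50), r$leaders)
    expect_equal(r$init_attitudes[nl], base$init_attitudes_raw[nl])
    expect_true(all(r$init_attitudes[r$leaders] == cfg$comm$leader_attitude))
    expect_true(all(r$final_att[r$leaders] == cfg$comm$leader_attitude))
  }
  # leader assignment differs between runs (sampling, not fixed)
  expect_false(identical(ens$results[[1]]$leaders, ens$results[[2]]$leaders))
  expect_error(run_ensemble(cfg, 2, mode = "leaders"), "base_run")
})

test_that("the ten-percent leader case with 5000 agents gets exactly 500 every run", {
  city <- tiny_root_city()
  cfg <- precompute_navigation(
    sim_config(city, n_agents = 5000, leader_fraction = 0.10, horizon = 2,
               record_interval = 1, seed = 21))
  base <- run_simulation(sim_config(city, n_agents = 5000, horizon = 2,
                                    record_interval = 1, seed = 21,
                                    nav = cfg$nav))
  ens <- run_ensemble(cfg, 3, mode = "leaders", base_run = base,
                      keep_results = TRUE)
  expect_true(all(ens$metrics$n_leaders == 500))
  for (r in ens$results) {
    expect_length(r$leaders, 500)
    expect_false(any(duplicated(r$leaders)))
  }
})

test_that("unreachable starting cells trigger a warning", {
  city <- tiny_grid_city()
  # a cost table that walls buildings off completely is impossible (costs
  # are finite), so fabricate unreachability by sending destinations to an
  # enclosed all-water pocket: instead, check the warning path directly via
  # a field with infinite cells
  cfg <- tiny_config("grid", n_agents = 10, horizon = 1, seed = 2)
  cfg$nav$cumcost[] <- Inf
  expect_warning(run_simulation(cfg), "unreachable")
})
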