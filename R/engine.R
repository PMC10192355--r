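#' Simulation configuration
#'
#' Bundles an urban model with the communication and movement parameters and
#' the experiment settings of a single run.
#'
#' @param urban An `urban_model`.
#' @param n_agents Number of agents (default 500 at desk scale).
#' @param comm A `comm_params` object.
#' @param move A `move_params` object.
#' @param leader_fraction Fraction of agents made leading evacuees; the
#'   count is exact: `round(leader_fraction * n_agents)` every run.
#' @param horizon Simulated seconds (default 1800).
#' @param record_interval Seconds between recorded snapshots (default 5).
#' @param seed Master seed for the run.
#' @param restrict_to_inundation Restrict initial placement to inundation
#'   -zone buildings; default `TRUE` for grid-style cities (mirroring
#'   placement in the inundated part of a coastal plain), `FALSE` otherwise.
#' @param retain_evacuated_influence Keep evacuated agents as influence
#'   sources in the communication graph (default `FALSE`: arrival removes an
#'   agent from both communication and movement).
#' @param nav Optional precomputed `nav_field`; computed from `urban` on
#'   first use otherwise (see [precompute_navigation()]).
#' @param cost_table Land-use costs for the navigation field.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(urban, n_agents = 500, comm = comm_params(),
                       move = move_params(), leader_fraction = 0,
                       horizon = 1800, record_interval = 5, seed = 1L,
                       restrict_to_inundation = NULL,
                       retain_evacuated_influence = FALSE,
                       nav = NULL, cost_table = default_cost_table()) {
  stopifnot(inherits(urban, "urban_model"), n_agents >= 1,
            inherits(comm, "comm_params"), inherits(move, "move_params"),
            leader_fraction >= 0, leader_fraction <= 1, horizon > 0,
            record_interval > 0)
  restrict_to_inundation <- restrict_to_inundation %||% (urban$style == "grid")
  structure(list(
    urban = urban, n_agents = as.integer(n_agents), comm = comm, move = move,
    leader_fraction = leader_fraction, horizon = horizon,
    record_interval = record_interval, seed = as.integer(seed),
    restrict_to_inundation = restrict_to_inundation,
    retain_evacuated_influence = retain_evacuated_influence,
    nav = nav, cost_table = cost_table
  ), class = "sim_config")
}

#' Precompute and attach the navigation field to a configuration
#'
#' Ensemble drivers reuse one field across runs; call this once to avoid
#' recomputing the Dijkstra field per run.
#'
#' @param config A `sim_config`.
#' @return The configuration with `nav` filled in.
#' @export
precompute_navigation <- function(config) {
  if (is.null(config$nav))
    config$nav <- navigation_for_city(config$urban, config$cost_table)
  config
}

# derive sub-seeds (placement, attitudes, leaders) from a run seed
derive_seeds <- function(seed, k = 3L) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

#' Run one coupled evacuation simulation
#'
#' The main loop advances physical movement every `dt`; every
#' `comm_interval` seconds the directed communication graph is rebuilt among
#' non-evacuated agents, attitudes are updated synchronously, and the
#' evacuation decision (`A >= threshold`) is re-evaluated in both
#' directions. Evacuating agents follow the navigation field under the
#' social-force model; agents reaching a destination become `evacuated` and
#' leave both movement and communication. Fully reproducible given
#' `config$seed`.
#'
#' @param config A `sim_config`.
#' @param init_attitudes Optional fixed initial attitude vector (otherwise
#'   sampled Uniform(-1, 1) from the run seed).
#' @param init_positions Optional fixed initial positions (otherwise placed
#'   inside buildings from the run seed).
#' @param leader_idx Optional fixed leader index set (otherwise sampled
#'   without replacement from the run seed).
#' @return A list of class `sim_result`: snapshot `times`, lists `pos`,
#'   `att`, `state` (0 idle, 1 evacuating, 2 evacuated), `arrival` times
#'   (`NA` if never), `final_*` fields, plus the initial conditions and the
#'   configuration.
#' @export
run_simulation <- function(config, init_attitudes = NULL,
                           init_positions = NULL, leader_idx = NULL) {
  stopifnot(inherits(config, "sim_config"))
  config <- precompute_navigation(config)
  n <- config$n_agents
  seeds <- derive_seeds(config$seed)

  pos <- init_positions %||%
    place_agents(config$urban, n, config$restrict_to_inundation, seeds[1])
  A0 <- init_attitudes %||% sample_initial_attitudes(n, seeds[2])
  stopifnot(nrow(pos) == n, length(A0) == n)
  n_lead <- round(config$leader_fraction * n)
  leader_idx <- leader_idx %||% assign_leaders(n, n_lead, seeds[3])
  leader <- rep(FALSE, n)
  leader[leader_idx] <- TRUE
  A_start <- A0
  A_start[leader] <- config$comm$leader_attitude

  nav <- config$nav
  cc0 <- nav$cumcost[cbind(
    pmin(pmax(floor(pos[, 1] / nav$resolution), 0), nrow(nav$cumcost) - 1) + 1,
    pmin(pmax(floor(pos[, 2] / nav$resolution), 0), ncol(nav$cumcost) - 1) + 1)]
  if (any(!is.finite(cc0)))
    warning(sum(!is.finite(cc0)),
            " agent(s) start on cells unreachable from any destination")

  cm <- config$comm; mv <- config$move
  raw <- cpp_run_sim(
    config$urban$landuse, nav$cumcost, nav$dir_x, nav$dir_y,
    nav$destinations, nav$resolution,
    pos, A_start, leader,
    cm$epsilon_fn, cm$mu, cm$radius, cm$comm_interval, cm$threshold,
    mv$v0, mv$tau_alpha, mv$dt, mv$force_k, mv$force_tau0, mv$agent_radius,
    mv$force_cutoff, mv$overshoot_cap, mv$arrival_radius,
    config$horizon, config$record_interval,
    config$retain_evacuated_influence)

  structure(list(
    times = raw$times, pos = raw$pos, att = raw$att, state = raw$state,
    arrival = raw$arrival, final_pos = raw$final_pos,
    final_vel = raw$final_vel, final_att = raw$final_att,
    final_state = raw$final_state, t_end = raw$t_end,
    ended_early = raw$ended_early,
    init_positions = pos, init_attitudes = A_start,
    init_attitudes_raw = A0, leaders = leader_idx, config = config
  ), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result>", x$config$n_agents, "agents,",
      length(x$times), "snapshots to t =", x$t_end, "s\n")
  cat("  completion:", round(completion_ratio(x), 3),
      " leaders:", length(x$leaders), "\n")
  invisible(x)
}

#' Evacuation completion ratio
#'
#' Fraction of agents in state `evacuated` at the end of the run.
#'
#' @param result A `sim_result`.
#' @return A fraction in `[0, 1]`.
#' @export
completion_ratio <- function(result) {
  mean(result$final_state == 2L)
}

#' Relative difference between two completion ratios
#'
#' `(a - b) / b * 100`, in percent.
#'
#' @param ratio_a,ratio_b Ratios; `ratio_b` must be nonzero.
#' @return Percent difference (vectorised).
#' @export
relative_difference <- function(ratio_a, ratio_b) {
  if (any(ratio_b == 0)) stop("relative difference undefined for ratio_b = 0")
  (ratio_a - ratio_b) / ratio_b * 100
}

#' Box-plot summary statistics
#'
#' Median, quartiles (linear-interpolation percentile rule, `type = 7`),
#' whiskers at the most extreme values within 1.5 IQR of the box, and
#' fliers beyond the whiskers.
#'
#' @param x Numeric vector.
#' @return A list with `median`, `q1`, `q3`, `iqr`, `whisker_lo`,
#'   `whisker_hi`, `fliers`, `n`.
#' @export
box_stats <- function(x) {
  x <- x[!is.na(x)]
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_lim <- q[1] - 1.5 * iqr; hi_lim <- q[3] + 1.5 * iqr
  inside <- x >= lo_lim & x <= hi_lim
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
       whisker_lo = if (any(inside)) min(x[inside]) else q[1],
       whisker_hi = if (any(inside)) max(x[inside]) else q[3],
       fliers = sort(x[!inside]), n = length(x))
}

default_run_metrics <- function(result) {
  bc <- tryCatch(behaviour_change_ratio(result), error = function(e) NA_real_)
  c(completion = completion_ratio(result),
    n_evacuated = sum(result$final_state == 2L),
    last_arrival = if (any(!is.na(result$arrival)))
      max(result$arrival, na.rm = TRUE) else NA_real_,
    behaviour_change = bc)
}

#' Run a stochastic ensemble of simulations
#'
#' Two experimental designs:
#'
#' * `mode = "attitudes"`: each run redraws initial positions, attitudes and
#'   (if any) leader assignment from an independent seed derived from the
#'   master seed.
#' * `mode = "leaders"`: initial positions and attitudes are fixed to those
#'   of a base run (typically the median completion case of an attitudes
#'   ensemble, see [median_run()]) and only the leading-evacuee assignment
#'   is redrawn, with the exact leader count every run.
#'
#' @param config A `sim_config`; its `seed` is the ensemble master seed.
#' @param n_runs Number of runs (the full-scale experiment uses 120).
#' @param mode `"attitudes"` or `"leaders"`.
#' @param base_run A `sim_result` supplying fixed positions/attitudes for
#'   `mode = "leaders"`; its non-leader initial attitudes are reused
#'   (required in that mode).
#' @param metrics_fn Optional `function(sim_result) -> named numeric` of
#'   extra per-run metrics (e.g. network metrics).
#' @param keep_results Keep the full `sim_result` objects (memory-heavy;
#'   default `FALSE`).
#' @return A list of class `ensemble_result`: `metrics` (per-run
#'   data.frame), `summary` ([box_stats()] of completion), `run_seeds`,
#'   `mode`, `config`, and `results` when kept.
#' @export
run_ensemble <- function(config, n_runs, mode = c("attitudes", "leaders"),
                         base_run = NULL, metrics_fn = NULL,
                         keep_results = FALSE) {
  mode <- match.arg(mode)
  stopifnot(n_runs >= 1)
  config <- precompute_navigation(config)
  set.seed(config$seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  if (mode == "leaders" && is.null(base_run))
    stop("mode = 'leaders' requires a base_run supplying fixed attitudes")

  rows <- vector("list", n_runs)
  results <- if (keep_results) vector("list", n_runs) else NULL
  for (r in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- run_seeds[r]
    res <- if (mode == "attitudes") {
      run_simulation(cfg)
    } else {
      run_simulation(cfg,
                     init_attitudes = base_run$init_attitudes_raw,
                     init_positions = base_run$init_positions)
    }
    m <- default_run_metrics(res)
    if (!is.null(metrics_fn)) m <- c(m, metrics_fn(res))
    rows[[r]] <- c(run = r, seed = run_seeds[r], n_leaders = length(res$leaders), m)
    if (keep_results) results[[r]] <- res
  }
  metrics <- as.data.frame(do.call(rbind, rows))
  structure(list(metrics = metrics, summary = box_stats(metrics$completion),
                 run_seeds = run_seeds, mode = mode, config = config,
                 results = results),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  s <- x$summary
  cat("<ensemble_result>", nrow(x$metrics), "runs, mode:", x$mode, "\n")
  cat(sprintf("  completion median %.3f [Q1 %.3f, Q3 %.3f]\n",
              s$median, s$q1, s$q3))
  invisible(x)
}

#' Re-run the ensemble's median completion case
#'
#' Identifies the run whose completion ratio is the ensemble median (the
#' lower median for even `n_runs`) and re-executes it, returning the full
#' `sim_result`. Its initial attitudes and positions are what
#' `mode = "leaders"` ensembles hold fixed.
#'
#' @param ensemble An `ensemble_result` with `mode = "attitudes"`.
#' @return A `sim_result`.
#' @export
median_run <- function(ensemble) {
  m <- ensemble$metrics
  ord <- order(m$completion)
  pick <- ord[ceiling(length(ord) / 2)]  # lower median for even n
  cfg <- ensemble$config
  cfg$seed <- m$seed[pick]
  run_simulation(cfg)
}
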