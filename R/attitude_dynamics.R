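#' Attitude-dependent bounded-confidence function
#'
#' Returns a function `eps(A)` of the linear form
#' `eps_base + eps_slope * (1 + A) / 2`: the acceptance window widens with
#' the receiver's attitude. Agents inclined to evacuate stay attentive to
#' surrounding opinions (they can be reinforced by fellow evacuees but also
#' dissuaded by reluctant neighbourhoods), whereas entrenched negative
#' agents are close-minded and hard to move -- the asymmetry that lets
#' reluctant districts suppress evacuation and makes trusted leading
#' evacuees disproportionately effective. This functional form is a
#' modelling assumption of the package; any nonnegative function of the
#' attitude vector may be substituted.
#'
#' @param eps_base Window width at `A = -1` (default 0.1).
#' @param eps_slope Additional width gained toward `A = 1` (default 0.8).
#' @return A vectorised function mapping attitudes to acceptance widths.
#' @export
epsilon_linear <- function(eps_base = 0.1, eps_slope = 0.8) {
  stopifnot(eps_base >= 0, eps_slope >= 0)
  function(A) eps_base + eps_slope * (1 + A) / 2
}

#' Communication-model parameters
#'
#' @param mu Update gain in (0, 1]; fraction of the mean accepted attitude
#'   difference applied per communication step (default 0.9, modelling rapid
#'   conformity to surrounding opinion during an emergency).
#' @param radius Communication radius in metres (default 15).
#' @param epsilon_fn Bounded-confidence function `eps(A)`; default
#'   [epsilon_linear()].
#' @param comm_interval Physical seconds between communication steps
#'   (default 1).
#' @param threshold Evacuation-decision attitude: agents with `A >= threshold`
#'   evacuate, and stop if they fall below it (default 0.5).
#' @param leader_attitude Constant attitude of leading evacuees (default 0.7).
#' @return A list of class `comm_params`.
#' @export
comm_params <- function(mu = 0.9, radius = 15, epsilon_fn = epsilon_linear(),
                        comm_interval = 1, threshold = 0.5,
                        leader_attitude = 0.7) {
  stopifnot(mu >= 0, mu <= 1, radius > 0, is.function(epsilon_fn),
            comm_interval > 0, threshold > -1, threshold < 1,
            leader_attitude >= -1, leader_attitude <= 1)
  structure(list(mu = mu, radius = radius, epsilon_fn = epsilon_fn,
                 comm_interval = comm_interval, threshold = threshold,
                 leader_attitude = leader_attitude),
            class = "comm_params")
}

#' Bounded-confidence indicator
#'
#' 1 when the attitude difference is strictly within the receiver's
#' acceptance window (`|A_i - A_j| < eps_i`), else 0. The inequality is
#' strict, so a difference exactly at the window boundary blocks interaction.
#'
#' @param A_i Receiver attitude(s).
#' @param A_j Sender attitude(s).
#' @param eps_i Receiver acceptance width(s).
#' @return Integer 0/1 vector.
#' @export
indicator <- function(A_i, A_j, eps_i) {
  as.integer(abs(A_i - A_j) < eps_i)
}

#' Build the directed communication graph at a snapshot
#'
#' An edge `j -> i` (sender to receiver) exists iff the two agents are within
#' the communication radius (inclusive), `j != i`, and
#' `|A_i - A_j| < eps(A_i)`. The graph is directed because the acceptance
#' window depends on the receiver's attitude.
#'
#' @param positions `n x 2` matrix of agent positions (metres).
#' @param A Attitude vector of length `n`.
#' @param params A `comm_params` object.
#' @param timestamp Optional communication-step index stored on the graph.
#' @param ids Optional original agent ids for the `n` rows (default
#'   `seq_len(n)`), used when the graph is built on a subset of agents.
#' @return A list of class `comm_graph`: `edges` (data.frame `from`, `to` in
#'   original ids), `n`, `ids`, `timestamp`.
#' @export
build_communication_graph <- function(positions, A, params = comm_params(),
                                      timestamp = NA_integer_,
                                      ids = NULL) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 2)
  n <- nrow(positions)
  stopifnot(length(A) == n)
  ids <- ids %||% seq_len(n)
  eps <- params$epsilon_fn(A)
  pr <- cpp_radius_pairs(positions, params$radius)
  from <- integer(0); to <- integer(0)
  if (nrow(pr) > 0) {
    i <- pr[, 1]; j <- pr[, 2]
    d <- abs(A[i] - A[j])
    ij <- d < eps[i]  # j influences i
    ji <- d < eps[j]  # i influences j
    from <- c(j[ij], i[ji])
    to <- c(i[ij], j[ji])
  }
  structure(list(edges = data.frame(from = ids[from], to = ids[to]),
                 n = n, ids = ids, timestamp = timestamp),
            class = "comm_graph")
}

#' @export
print.comm_graph <- function(x, ...) {
  cat("<comm_graph>", x$n, "agents,", nrow(x$edges), "directed edges",
      if (!is.na(x$timestamp)) paste0("(t_s = ", x$timestamp, ")"), "\n")
  invisible(x)
}

#' Synchronous bounded-confidence attitude update
#'
#' Applies one communication step: each non-leader agent moves a fraction
#' `mu` toward the mean attitude of its accepted in-neighbours
#' (`A_i' = A_i + mu * mean_j(A_j - A_i)` over senders `j` with an edge
#' `j -> i`). Agents with no accepted in-neighbours, and leading evacuees,
#' are unchanged. Results are clamped to `[-1, 1]` (a no-op for `mu <= 1`,
#' kept as a numerical guard).
#'
#' @param A Attitude vector.
#' @param graph A `comm_graph` built from the current attitudes/positions.
#' @param mu Update gain.
#' @param leader_mask Logical vector marking leading evacuees (optional).
#' @return Updated attitude vector.
#' @export
update_attitudes <- function(A, graph, mu, leader_mask = NULL) {
  n <- length(A)
  leader_mask <- leader_mask %||% rep(FALSE, n)
  out <- A
  e <- graph$edges
  if (nrow(e) > 0) {
    diff <- A[e$from] - A[e$to]
    s <- rowsum(diff, e$to)
    cnt <- rowsum(rep(1, nrow(e)), e$to)
    idx <- as.integer(rownames(s))
    out[idx] <- A[idx] + mu * s[, 1] / cnt[, 1]
  }
  out[leader_mask] <- A[leader_mask]
  pmin(1, pmax(-1, out))
}

#' Evacuation decision rule
#'
#' An agent evacuates while its attitude is at or above the threshold
#' (`A >= threshold`, inclusive); it stops evacuating as soon as the
#' attitude drops below. The rule is re-applied at every communication step,
#' so behaviour change operates in both directions.
#'
#' @param A Attitude vector.
#' @param threshold Decision threshold (default 0.5).
#' @return Logical vector of evacuating flags.
#' @export
decide <- function(A, threshold = 0.5) {
  A >= threshold
}
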