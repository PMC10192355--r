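#' Extract communication clusters (strongly connected components)
#'
#' A cluster is a strongly connected component of the directed communication
#' graph: every member can reach every other along accepted-influence edges.
#' Agents with no edges form singleton clusters.
#'
#' @param graph A `comm_graph`.
#' @param positions Optional positions of the graph's agents (rows matching
#'   `graph$ids`) for cluster centres.
#' @param attitudes Optional attitudes for cluster mean attitudes.
#' @return A list: `membership` (cluster id per agent, named by agent id)
#'   and `clusters`, a data.frame with `cluster`, `size` and, when provided,
#'   `x`, `y` (mean member position) and `mean_attitude`.
#' @export
extract_clusters <- function(graph, positions = NULL, attitudes = NULL) {
  n <- graph$n
  # vertices are the graph's agents; edges are in original ids
  id_index <- match(graph$edges$from, graph$ids)
  id_index_to <- match(graph$edges$to, graph$ids)
  g <- igraph::make_empty_graph(n = n, directed = TRUE)
  if (nrow(graph$edges) > 0)
    g <- igraph::add_edges(g, rbind(id_index, id_index_to))
  comp <- igraph::components(g, mode = "strong")
  membership <- as.integer(comp$membership)
  names(membership) <- graph$ids
  cl <- data.frame(cluster = seq_len(comp$no),
                   size = as.integer(comp$csize))
  if (!is.null(positions)) {
    if (is.null(dim(positions))) positions <- matrix(positions, ncol = 2)
    cl$x <- as.numeric(tapply(positions[, 1], membership, mean))
    cl$y <- as.numeric(tapply(positions[, 2], membership, mean))
  }
  if (!is.null(attitudes))
    cl$mean_attitude <- as.numeric(tapply(attitudes, membership, mean))
  list(membership = membership, clusters = cl)
}

# agents present in the communication graph at snapshot k: non-evacuated,
# plus evacuated ones when the run retained their influence; or only the
# currently evacuating agents (for convoy/group-size analyses)
snapshot_graph <- function(result, k, evacuating_only = FALSE) {
  st <- result$state[[k]]
  keep <- if (evacuating_only) st == 1L
          else if (result$config$retain_evacuated_influence) rep(TRUE, length(st))
          else st != 2L
  ids <- which(keep)
  build_communication_graph(result$pos[[k]][ids, , drop = FALSE],
                            result$att[[k]][ids],
                            result$config$comm,
                            timestamp = k, ids = ids)
}

#' Large-group vs small-group composition of evacuating agents
#'
#' At each recorded snapshot, rebuilds the communication graph restricted to
#' the currently evacuating agents (clusters of closely communicating
#' evacuees), extracts SCC clusters, and splits the evacuating agents into
#' members of large clusters (cluster size at or above `size_threshold`) and
#' the rest.
#'
#' @param result A `sim_result`.
#' @param size_threshold Minimum cluster size of a large group (default 10,
#'   inclusive).
#' @return A data.frame with `time`, `large`, `small`, `evacuating`,
#'   `large_share` (`NA` when nobody is evacuating).
#' @export
group_size_timeseries <- function(result, size_threshold = 10) {
  stopifnot(size_threshold >= 2)
  out <- lapply(seq_along(result$times), function(k) {
    st <- result$state[[k]]
    gr <- snapshot_graph(result, k, evacuating_only = TRUE)
    evac_total <- sum(st == 1L)
    large <- 0L
    if (gr$n > 0) {
      cl <- extract_clusters(gr)
      sizes <- cl$clusters$size[cl$membership]
      large <- sum(sizes >= size_threshold)
    }
    data.frame(time = result$times[k], large = large,
               small = evac_total - large, evacuating = evac_total,
               large_share = if (evac_total > 0) large / evac_total else NA_real_)
  })
  do.call(rbind, out)
}

#' Trajectories of positive- or negative-attitude clusters
#'
#' Per snapshot, extracts SCC clusters and keeps those whose mean member
#' attitude classifies them as positive (mean at or above the decision
#' threshold) or negative (mean below 0), subject to a minimum size.
#' Cluster centres are mean member positions.
#'
#' @param result A `sim_result`.
#' @param sign `"positive"` or `"negative"`.
#' @param min_size Minimum cluster size to report (default 2).
#' @param threshold Positive-classification threshold (default the run's
#'   decision threshold).
#' @return A data.frame `time`, `cluster`, `x`, `y`, `size`,
#'   `mean_attitude`.
#' @export
cluster_trajectories <- function(result, sign = c("positive", "negative"),
                                 min_size = 2, threshold = NULL) {
  sign <- match.arg(sign)
  threshold <- threshold %||% result$config$comm$threshold
  out <- lapply(seq_along(result$times), function(k) {
    gr <- snapshot_graph(result, k)
    if (gr$n == 0) return(NULL)
    cl <- extract_clusters(gr,
                           positions = result$pos[[k]][gr$ids, , drop = FALSE],
                           attitudes = result$att[[k]][gr$ids])
    cc <- cl$clusters
    sgn_ok <- if (sign == "positive") cc$mean_attitude >= threshold
              else cc$mean_attitude < 0
    keep <- cc$size >= min_size & sgn_ok
    if (!any(keep)) return(NULL)
    data.frame(time = result$times[k], cluster = cc$cluster[keep],
               x = cc$x[keep], y = cc$y[keep], size = cc$size[keep],
               mean_attitude = cc$mean_attitude[keep])
  })
  out <- do.call(rbind, out)
  out %||% data.frame(time = numeric(0), cluster = integer(0), x = numeric(0),
                      y = numeric(0), size = integer(0),
                      mean_attitude = numeric(0))
}

#' Largest negative-attitude cluster observed in a run
#'
#' Convenience metric: the maximum size over all snapshots of clusters with
#' negative mean attitude. Large negative clusters mark neighbourhoods that
#' reinforce non-evacuation.
#'
#' @param result A `sim_result`.
#' @param min_size Minimum size considered (default 1).
#' @return Integer (0 when no negative cluster ever appears).
#' @export
max_negative_cluster <- function(result, min_size = 1) {
  tr <- cluster_trajectories(result, "negative", min_size = min_size)
  if (nrow(tr) == 0) 0L else max(tr$size)
}

#' Initial-attitude histogram of evacuated agents
#'
#' Bins the initial attitudes of the agents that completed evacuation, and
#' reports the fraction of them whose initial attitude lay in the moderate
#' band `[0.2, 0.8]` -- the group whose evacuation depends on social
#' reinforcement rather than strong prior intent.
#'
#' @param result A `sim_result`.
#' @param bin_width Histogram bin width over `[-1, 1]`; must divide 2
#'   evenly (default 0.1).
#' @param band Attitude band for the summary fraction (default
#'   `c(0.2, 0.8)`, inclusive).
#' @return A list: `breaks`, `counts`, `band_fraction` (`NaN` when nobody
#'   evacuated), `n_evacuated`.
#' @export
evacuated_attitude_histogram <- function(result, bin_width = 0.1,
                                         band = c(0.2, 0.8)) {
  k <- 2 / bin_width
  if (abs(k - round(k)) > 1e-9) stop("bin_width must divide 2 evenly")
  breaks <- seq(-1, 1, by = bin_width)
  a0 <- result$init_attitudes[result$final_state == 2L]
  counts <- if (length(a0))
    as.integer(table(cut(a0, breaks, include.lowest = TRUE)))
  else integer(length(breaks) - 1L)
  list(breaks = breaks, counts = counts,
       band_fraction = if (length(a0))
         mean(a0 >= band[1] & a0 <= band[2]) else NaN,
       n_evacuated = length(a0))
}

#' Behaviour-change ratio
#'
#' Among agents whose initial attitude was at or above `high_threshold`
#' (they initially intended to evacuate), the fraction that nonetheless
#' failed to complete evacuation by the end of the run -- i.e. were
#' dissuaded by negative-attitude surroundings.
#'
#' @param result A `sim_result`.
#' @param high_threshold Initial-attitude cut (default 0.5).
#' @return A fraction in `[0, 1]`.
#' @export
behaviour_change_ratio <- function(result, high_threshold = 0.5) {
  high <- result$init_attitudes >= high_threshold
  if (!any(high))
    stop("no agent has initial attitude >= ", high_threshold)
  mean(result$final_state[high] != 2L)
}

#' Normalise a run's time axis by its last arrival
#'
#' Divides times by the run's last arrival time, mapping the evacuation to
#' `[0, 1]` so runs over different travel distances can be compared.
#'
#' @param result A `sim_result` with at least one evacuated agent.
#' @param times Times to normalise (default the snapshot times).
#' @return Numeric vector of normalised times.
#' @export
normalise_time <- function(result, times = result$times) {
  if (all(is.na(result$arrival)))
    stop("no agent evacuated; time normalisation undefined")
  times / max(result$arrival, na.rm = TRUE)
}
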