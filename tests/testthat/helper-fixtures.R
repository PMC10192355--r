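# Small fixture cities and independent oracles used across the test files.

tiny_grid_city <- function(seed = 1, extent = 120, ...) {
  generate_city(city_params("grid", extent = extent, street_spacing = 40,
                            seed = seed, ...))
}

tiny_root_city <- function(seed = 1, extent = 160, ...) {
  generate_city(city_params("root", extent = extent, branch_count = 3,
                            seed = seed, ...))
}

tiny_config <- function(style = "grid", seed = 1, n_agents = 30,
                        horizon = 300, ...) {
  city <- if (style == "grid") tiny_grid_city(seed) else tiny_root_city(seed)
  precompute_navigation(sim_config(city, n_agents = n_agents,
                                   horizon = horizon, record_interval = 5,
                                   seed = seed, ...))
}

# Independent least-cost oracle: the raster lattice as an igraph, shortest
# paths from a super-source attached to all destination cells with
# zero-weight edges.
oracle_nav_cost <- function(cost, dest_cells, res, connectivity = 8) {
  nx <- nrow(cost); ny <- ncol(cost)
  idx <- function(ix, iy) ix + nx * (iy - 1L) # 1-based
  dirs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8)
    dirs <- c(dirs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (d in dirs) {
    ix <- seq_len(nx); iy <- seq_len(ny)
    ix2 <- ix + d[1]; iy2 <- iy + d[2]
    okx <- ix2 >= 1 & ix2 <= nx; oky <- iy2 >= 1 & iy2 <= ny
    g <- expand.grid(ix = ix[okx], iy = iy[oky])
    step <- res * sqrt(sum(d^2))
    from <- c(from, idx(g$ix, g$iy))
    to <- c(to, idx(g$ix + d[1], g$iy + d[2]))
    w <- c(w, step * 0.5 * (cost[cbind(g$ix, g$iy)] +
                            cost[cbind(g$ix + d[1], g$iy + d[2])]))
  }
  super <- nx * ny + 1L
  from <- c(from, rep(super, nrow(dest_cells)))
  to <- c(to, idx(dest_cells[, 1] + 1L, dest_cells[, 2] + 1L))
  w <- c(w, rep(0, nrow(dest_cells)))
  g <- igraph::make_directed_graph(rbind(from, to), n = super)
  d <- igraph::distances(g, v = super, weights = w, mode = "out")[1, ]
  matrix(d[seq_len(nx * ny)], nx, ny)
}

# Brute-force SCC oracle: boolean transitive closure, then mutual
# reachability classes.
oracle_scc <- function(edges, n) {
  R <- diag(TRUE, n)
  if (nrow(edges) > 0)
    R[cbind(edges$from, edges$to)] <- TRUE
  repeat {
    R2 <- (R %*% R) > 0 | R
    if (all(R2 == R)) break
    R <- R2
  }
  mutual <- R & t(R)
  membership <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (membership[i] == 0L) {
      next_id <- next_id + 1L
      membership[mutual[i, ]] <- next_id
    }
  }
  membership
}

random_digraph <- function(n, p = 0.08) {
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs[runif(nrow(pairs)) < p, ]
}

# normalise an SCC membership vector to a canonical labelling
canon_partition <- function(m) as.integer(factor(m, levels = unique(m)))
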