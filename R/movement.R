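#' Pedestrian-movement parameters
#'
#' Constants of the social-force movement model: acceleration is relaxation
#' toward the desired velocity plus anticipatory collision-avoidance forces.
#' Defaults are standard pedestrian-dynamics values and are documented
#' modelling assumptions.
#'
#' @param v0 Preferred walking speed, m/s (default 1.33).
#' @param tau_alpha Velocity relaxation time, s (default 0.5).
#' @param dt Integration step, s (default 0.1; must be well below
#'   `tau_alpha`).
#' @param force_k Interaction-force strength (default 1.5).
#' @param force_tau0 Time-to-collision decay scale, s (default 3).
#' @param agent_radius Body radius, m (default 0.3).
#' @param force_cutoff Projected collisions further ahead than this many
#'   seconds exert no force (default 10).
#' @param overshoot_cap Hard speed cap as a multiple of `v0` (default 1.3).
#' @param arrival_radius Distance to a destination at which evacuation
#'   completes, m (default 2).
#' @return A list of class `move_params`.
#' @export
move_params <- function(v0 = 1.33, tau_alpha = 0.5, dt = 0.1,
                        force_k = 1.5, force_tau0 = 3, agent_radius = 0.3,
                        force_cutoff = 10, overshoot_cap = 1.3,
                        arrival_radius = 2) {
  stopifnot(v0 > 0, tau_alpha > 0, dt > 0, force_k >= 0, force_tau0 > 0,
            agent_radius > 0, force_cutoff > 0, overshoot_cap >= 1,
            arrival_radius > 0)
  if (dt > tau_alpha / 2)
    stop("dt must be well below tau_alpha for a stable explicit-Euler step")
  structure(list(v0 = v0, tau_alpha = tau_alpha, dt = dt, force_k = force_k,
                 force_tau0 = force_tau0, agent_radius = agent_radius,
                 force_cutoff = force_cutoff, overshoot_cap = overshoot_cap,
                 arrival_radius = arrival_radius),
            class = "move_params")
}

#' Anticipatory collision-avoidance force between two agents
#'
#' The force agent `j` exerts on agent `i`. The time to collision `tau_c`
#' solves `|d + v_rel t| = 2 r` by linear extrapolation of the relative
#' motion (`d` the separation, `r` the body radius). If a collision is
#' projected within the cutoff, the force has magnitude
#' `k / tau_c^2 * exp(-tau_c / tau0)` and pushes `i` along the predicted
#' separation at contact; otherwise it is zero. Overlapping pairs use a
#' `tau_c` floor of one integration step.
#'
#' @param pos_i,vel_i Position and velocity of the receiving agent.
#' @param pos_j,vel_j Position and velocity of the other agent.
#' @param params A `move_params` object.
#' @return Length-2 force (acceleration) vector on agent `i`.
#' @export
interaction_force <- function(pos_i, vel_i, pos_j, vel_j, params) {
  d <- pos_j - pos_i
  v <- vel_j - vel_i
  rr <- 2 * params$agent_radius
  a <- sum(v * v)
  b <- sum(d * v)
  cc <- sum(d * d) - rr^2
  tau_floor <- params$dt
  if (cc <= 0) {
    tau_c <- tau_floor
  } else {
    if (a < 1e-12 || b >= 0) return(c(0, 0))
    disc <- b^2 - a * cc
    if (disc <= 0) return(c(0, 0))
    tau_c <- (-b - sqrt(disc)) / a
    if (tau_c <= 0 || tau_c > params$force_cutoff) return(c(0, 0))
    tau_c <- max(tau_c, tau_floor)
  }
  s <- -(d + v * tau_c)
  sn <- sqrt(sum(s * s))
  if (sn < 1e-12) return(c(0, 0))
  mag <- params$force_k / tau_c^2 * exp(-tau_c / params$force_tau0)
  mag * s / sn
}

#' One explicit-Euler step of the social-force movement model
#'
#' Reference (R-level) implementation of a single movement step, matching
#' the compiled engine: evacuating agents relax toward `v0` times the
#' navigation field's desired direction; non-evacuating agents relax toward
#' rest; all agents receive pairwise anticipatory forces; speed is capped at
#' `v0 * overshoot_cap`; moves into building or water cells (from outside
#' them) or out of the domain are resolved by cancelling the blocked
#' displacement component and sliding along the wall.
#'
#' @param positions `n x 2` matrix (metres).
#' @param velocities `n x 2` matrix (m/s).
#' @param evacuating Logical vector of evacuating flags.
#' @param nav A `nav_field`, or `NULL` for free space with zero desired
#'   direction everywhere.
#' @param params A `move_params` object.
#' @param landuse Optional land-use raster for wall handling (`NULL`
#'   disables walls; the domain boundary then still applies if `nav` is
#'   given).
#' @return List with updated `positions` and `velocities`.
#' @export
step_movement <- function(positions, velocities, evacuating, nav, params,
                          landuse = NULL) {
  n <- nrow(positions)
  stopifnot(nrow(velocities) == n, length(evacuating) == n)
  dt <- params$dt
  vmax <- params$v0 * params$overshoot_cap

  e0 <- matrix(0, n, 2)
  if (!is.null(nav) && any(evacuating))
    e0[evacuating, ] <- desired_direction(nav, positions[evacuating, , drop = FALSE])

  # walls: the field crosses buildings at high cost, movement cannot; when
  # the steepest-descent neighbour is not enterable, re-aim at the cheapest
  # enterable neighbour (wall following), matching the compiled engine
  if (!is.null(landuse) && !is.null(nav)) {
    resn <- nav$resolution
    nxc <- nrow(landuse); nyc <- ncol(landuse)
    cell_blocked <- function(cx, cy, cur_code) {
      if (cx < 1 || cx > nxc || cy < 1 || cy > nyc) return(TRUE)
      code <- landuse[cx, cy]
      (code == LU_CODES[["building"]] && cur_code != LU_CODES[["building"]]) ||
        (code == LU_CODES[["water"]] && cur_code != LU_CODES[["water"]])
    }
    # evacuating agents may enter a building cell when that strictly
    # descends the cost field (the raster over-blocks narrow gaps)
    cell_enterable <- function(cx, cy, cur_code, cum_here) {
      if (!cell_blocked(cx, cy, cur_code)) return(TRUE)
      cx >= 1 && cx <= nxc && cy >= 1 && cy <= nyc &&
        landuse[cx, cy] == LU_CODES[["building"]] &&
        nav$cumcost[cx, cy] < cum_here
    }
    for (i in which(evacuating)) {
      if (all(e0[i, ] == 0)) next
      ix <- min(max(floor(positions[i, 1] / resn), 0), nxc - 1) + 1
      iy <- min(max(floor(positions[i, 2] / resn), 0), nyc - 1) + 1
      cur_code <- landuse[ix, iy]
      cum_here <- nav$cumcost[ix, iy]
      sx <- sign(e0[i, 1]); sy <- sign(e0[i, 2])
      if (cell_enterable(ix + sx, iy + sy, cur_code, cum_here)) next
      best <- Inf; bdx <- 0; bdy <- 0
      for (dy2 in -1:1) for (dx2 in -1:1) {
        if (dx2 == 0 && dy2 == 0) next
        if (!cell_enterable(ix + dx2, iy + dy2, cur_code, cum_here)) next
        cval <- nav$cumcost[ix + dx2, iy + dy2]
        if (cval < best) { best <- cval; bdx <- dx2; bdy <- dy2 }
      }
      e0[i, ] <- if (is.finite(best)) c(bdx, bdy) / sqrt(bdx^2 + bdy^2) else c(0, 0)
    }
  }

  # anticipatory forces need relative motion: pairs of resting
  # (non-evacuating, zero-velocity) agents exert nothing on each other
  moving <- evacuating | rowSums(velocities^2) > 1e-12
  forces <- matrix(0, n, 2)
  if (n > 1 && params$force_k > 0) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j || (!moving[i] && !moving[j])) next
        forces[i, ] <- forces[i, ] +
          interaction_force(positions[i, ], velocities[i, ],
                            positions[j, ], velocities[j, ], params)
      }
    }
  }

  acc <- (params$v0 * e0 - velocities) / params$tau_alpha + forces
  vel <- velocities + acc * dt
  sp <- sqrt(rowSums(vel^2))
  over <- sp > vmax
  vel[over, ] <- vel[over, ] * (vmax / sp[over])

  pos <- positions
  res <- if (!is.null(landuse)) {
    if (!is.null(nav)) nav$resolution else 1
  } else NULL
  code_at <- function(x, y) {
    nxc <- nrow(landuse); nyc <- ncol(landuse)
    ix <- pmin(pmax(floor(x / res), 0), nxc - 1) + 1
    iy <- pmin(pmax(floor(y / res), 0), nyc - 1) + 1
    landuse[ix, iy]
  }
  blocked <- function(x, y, cur_code, evac_i = FALSE, cum_cur = Inf) {
    if (!is.null(landuse)) {
      ext_x <- nrow(landuse) * res; ext_y <- ncol(landuse) * res
      if (x < 0 || y < 0 || x >= ext_x || y >= ext_y) return(TRUE)
      code <- code_at(x, y)
      if (code == LU_CODES[["building"]] && cur_code != LU_CODES[["building"]]) {
        # descending cut-through for evacuating agents
        if (evac_i && !is.null(nav)) {
          cx <- min(max(floor(x / res), 0), nrow(landuse) - 1) + 1
          cy <- min(max(floor(y / res), 0), ncol(landuse) - 1) + 1
          if (nav$cumcost[cx, cy] < cum_cur) return(FALSE)
        }
        return(TRUE)
      }
      if (code == LU_CODES[["water"]] && cur_code != LU_CODES[["water"]])
        return(TRUE)
    }
    FALSE
  }
  for (i in seq_len(n)) {
    nxp <- pos[i, 1] + vel[i, 1] * dt
    nyp <- pos[i, 2] + vel[i, 2] * dt
    cur <- if (!is.null(landuse)) code_at(pos[i, 1], pos[i, 2]) else 0L
    cum_cur <- if (!is.null(nav) && !is.null(landuse)) {
      cx <- min(max(floor(pos[i, 1] / nav$resolution), 0), nrow(landuse) - 1) + 1
      cy <- min(max(floor(pos[i, 2] / nav$resolution), 0), ncol(landuse) - 1) + 1
      nav$cumcost[cx, cy]
    } else Inf
    evac_i <- evacuating[i]
    if (!blocked(nxp, nyp, cur, evac_i, cum_cur)) {
      pos[i, ] <- c(nxp, nyp)
    } else if (!blocked(nxp, pos[i, 2], cur, evac_i, cum_cur)) {
      pos[i, 1] <- nxp; vel[i, 2] <- 0
    } else if (!blocked(pos[i, 1], nyp, cur, evac_i, cum_cur)) {
      pos[i, 2] <- nyp; vel[i, 1] <- 0
    } else {
      vel[i, ] <- 0
    }
  }
  list(positions = pos, velocities = vel)
}

#' Evacuation-completion test
#'
#' TRUE for positions within `arrival_radius` (inclusive) of any
#' destination.
#'
#' @param positions `n x 2` matrix or length-2 point.
#' @param destinations Matrix of destination points.
#' @param arrival_radius Arrival distance in metres (default 2).
#' @return Logical vector.
#' @export
check_completion <- function(positions, destinations, arrival_radius = 2) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 2)
  if (is.null(dim(destinations))) destinations <- matrix(destinations, ncol = 2)
  vapply(seq_len(nrow(positions)), function(i) {
    d <- sqrt((destinations[, 1] - positions[i, 1])^2 +
              (destinations[, 2] - positions[i, 2])^2)
    any(d <= arrival_radius)
  }, logical(1))
}
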