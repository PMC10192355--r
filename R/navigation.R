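#' Default land-use traversal costs
#'
#' Dimensionless cost multipliers per metre of travel through each land-use
#' category: road 1, building 4000, water 8000, other 2000. Roads are thus
#' vastly preferred; buildings and water act as near-barriers that remain
#' crossable in principle (agents start indoors).
#'
#' @return Named numeric vector over categories `other, road, building, water`.
#' @export
default_cost_table <- function() {
  c(other = 2000, road = 1, building = 4000, water = 8000)
}

#' Build a traversal-cost raster from a land-use raster
#'
#' @param landuse Integer matrix of category codes (0 other, 1 road,
#'   2 building, 3 water).
#' @param cost_table Named numeric vector giving the cost per category;
#'   defaults to [default_cost_table()]. All costs must be strictly positive.
#' @return Numeric matrix of per-cell costs, same shape as `landuse`.
#' @export
build_cost_map <- function(landuse, cost_table = default_cost_table()) {
  if (length(landuse) == 0) stop("empty land-use raster")
  if (!all(names(LU_CODES) %in% names(cost_table)))
    stop("cost_table must name all categories: ",
         paste(names(LU_CODES), collapse = ", "))
  if (any(cost_table <= 0)) stop("costs must be strictly positive")
  if (!all(landuse %in% LU_CODES))
    stop("unknown land-use category code(s): ",
         paste(setdiff(unique(landuse), LU_CODES), collapse = ", "))
  lookup <- numeric(length(LU_CODES))
  lookup[LU_CODES + 1L] <- cost_table[names(LU_CODES)]
  cost <- matrix(lookup[landuse + 1L], nrow(landuse), ncol(landuse))
  cost
}

#' Compute a least-cost navigation field from destinations
#'
#' Runs a multi-source Dijkstra over the raster's cell lattice: the value of
#' a cell is the minimum cumulative cost to reach any destination, where the
#' edge weight between adjacent cells is the step length (`res`, or
#' `res * sqrt(2)` diagonally) times the arithmetic mean of the two cell
#' costs. The desired-direction layer points from each cell toward its
#' lowest-cumulative-cost neighbour (unit vectors; zero at destination and
#' unreachable cells).
#'
#' @param cost Numeric cost matrix from [build_cost_map()].
#' @param destinations Matrix of destination points (metres), one per row.
#' @param resolution Cell size in metres.
#' @param connectivity 4 or 8 (default) neighbourhood.
#' @return A list of class `nav_field`: `cumcost`, `dir_x`, `dir_y`,
#'   `resolution`, `destinations`, `connectivity`.
#' @export
compute_navigation_field <- function(cost, destinations, resolution = 1,
                                     connectivity = 8) {
  if (length(cost) == 0) stop("empty cost raster")
  if (is.null(dim(destinations))) destinations <- matrix(destinations, ncol = 2)
  if (nrow(destinations) < 1) stop("at least one destination required")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  nx <- nrow(cost); ny <- ncol(cost)
  ix <- floor(destinations[, 1] / resolution)
  iy <- floor(destinations[, 2] / resolution)
  if (any(ix < 0 | ix >= nx | iy < 0 | iy >= ny))
    stop("destination outside the raster")
  f <- cpp_nav_field(cost, cbind(as.integer(ix), as.integer(iy)),
                     resolution, as.integer(connectivity))
  structure(list(cumcost = f$cumcost, dir_x = f$dir_x, dir_y = f$dir_y,
                 resolution = resolution, destinations = destinations,
                 connectivity = connectivity),
            class = "nav_field")
}

#' Navigation field for an urban model
#'
#' Convenience wrapper: cost map from the model's land-use raster, then the
#' least-cost field from its destinations.
#'
#' @param urban An `urban_model`.
#' @param cost_table Per-category costs, see [build_cost_map()].
#' @param connectivity 4 or 8.
#' @return A `nav_field`.
#' @export
navigation_for_city <- function(urban, cost_table = default_cost_table(),
                                connectivity = 8) {
  cost <- build_cost_map(urban$landuse, cost_table)
  compute_navigation_field(cost, urban$destinations, urban$resolution,
                           connectivity)
}

#' Desired movement direction at given positions
#'
#' Looks up the navigation field's steepest-descent direction for the cell
#' containing each position. Destination cells (and unreachable cells) give
#' the zero vector.
#'
#' @param field A `nav_field`.
#' @param position A length-2 point or an `n x 2` matrix (metres).
#' @return An `n x 2` matrix of unit (or zero) direction vectors.
#' @export
desired_direction <- function(field, position) {
  if (is.null(dim(position))) position <- matrix(position, ncol = 2)
  res <- field$resolution
  nx <- nrow(field$cumcost); ny <- ncol(field$cumcost)
  if (any(position[, 1] < 0 | position[, 1] > nx * res |
          position[, 2] < 0 | position[, 2] > ny * res))
    stop("position outside the domain")
  ix <- pmin(pmax(floor(position[, 1] / res), 0), nx - 1) + 1
  iy <- pmin(pmax(floor(position[, 2] / res), 0), ny - 1) + 1
  cbind(field$dir_x[cbind(ix, iy)], field$dir_y[cbind(ix, iy)])
}

#' @export
print.nav_field <- function(x, ...) {
  fin <- is.finite(x$cumcost)
  cat("<nav_field>", nrow(x$cumcost), "x", ncol(x$cumcost), "cells @",
      x$resolution, "m,", nrow(x$destinations), "destination(s)\n")
  cat("  reachable:", round(100 * mean(fin), 1), "%  max cumcost:",
      signif(max(x$cumcost[fin]), 4), "\n")
  invisible(x)
}
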