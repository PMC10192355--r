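#' Parameters for a synthetic urban model
#'
#' Builds the parameter set consumed by [generate_city()]. Two styles are
#' supported, capturing the structural contrast between a coastal-plain city
#' and a ria-valley city:
#'
#' * `"grid"`: a dense Manhattan lattice of narrow orthogonal streets with
#'   contiguous building blocks, the coast along one side and few
#'   destinations on the inland edge (flow-dispersing structure).
#' * `"root"`: a sparser branching network -- a trunk road at the valley
#'   mouth splitting into wider branches that climb inland, buildings strung
#'   along the roads, and one destination at each branch tip
#'   (flow-gathering structure).
#'
#' Defaults are desk-scale (500 m, 2 vs 6 destinations); they are tunable
#' configuration, not claims of fidelity to any real city.
#'
#' @param style `"grid"` or `"root"`.
#' @param extent Domain side length in metres (square domain).
#' @param resolution Raster cell size in metres (default 1).
#' @param street_spacing Grid style: distance between parallel streets (m).
#' @param branch_count Root style: number of main branches (= default
#'   destination count).
#' @param branch_angle Root style: half-opening angle of the branch fan,
#'   degrees from the inland direction.
#' @param road_width Road width in metres. Root default is wider than grid
#'   (sparser structure with wider roads).
#' @param building_coverage Building density control in `[0, 1]`: fraction of
#'   each block lot covered (grid) or of the roadside corridor length
#'   occupied (root).
#' @param n_destinations Number of evacuation destinations. For the root
#'   style `NULL` (default) means one per branch tip.
#' @param inundation_depth_fraction Fraction of the domain depth adjacent to
#'   the coast edge treated as the inundation zone (used for agent placement
#'   restriction and destination siting; no hydrodynamics).
#' @param coast_side Which boundary edge faces the sea: `"S"`, `"N"`, `"W"`
#'   or `"E"`.
#' @param water_width Width (m) of a sea strip along the coast edge rendered
#'   as water cells; 0 disables it.
#' @param village_houses Root style: houses per roadside in the compact
#'   village at the base of each branch (the convoy-forming settlements);
#'   the rest of each branch carries isolated detached houses.
#' @param seed Integer seed controlling the generator's jitter.
#' @return A list of class `city_params`.
#' @export
city_params <- function(style = c("grid", "root"),
                        extent = 500,
                        resolution = 1,
                        street_spacing = 50,
                        branch_count = 6,
                        branch_angle = 55,
                        road_width = NULL,
                        building_coverage = NULL,
                        n_destinations = NULL,
                        inundation_depth_fraction = NULL,
                        coast_side = "S",
                        water_width = 0,
                        village_houses = 6L,
                        seed = 1L) {
  style <- match.arg(style)
  road_width <- road_width %||% switch(style, grid = 6, root = 12)
  building_coverage <- building_coverage %||% switch(style, grid = 0.6, root = 0.65)
  inundation_depth_fraction <- inundation_depth_fraction %||%
    switch(style, grid = 0.35, root = 0.4)
  if (style == "grid") n_destinations <- n_destinations %||% 2L
  if (style == "root") {
    n_destinations <- n_destinations %||% as.integer(branch_count)
    if (n_destinations > branch_count)
      stop("root style: n_destinations cannot exceed branch_count")
  }
  stopifnot(
    extent > 0, resolution > 0, village_houses >= 0,
    street_spacing > 0, branch_count >= 1, branch_angle > 0,
    road_width > 0, building_coverage >= 0, building_coverage <= 1,
    n_destinations >= 1,
    inundation_depth_fraction > 0, inundation_depth_fraction < 1,
    water_width >= 0
  )
  if (!coast_side %in% c("S", "N", "W", "E"))
    stop("coast_side must be one of 'S', 'N', 'W', 'E'")
  if (extent / resolution < 10)
    stop("degenerate extent: domain must span at least 10 cells")
  structure(list(
    style = style, extent = extent, resolution = resolution,
    street_spacing = street_spacing, branch_count = as.integer(branch_count),
    branch_angle = branch_angle, road_width = road_width,
    building_coverage = building_coverage,
    n_destinations = as.integer(n_destinations),
    inundation_depth_fraction = inundation_depth_fraction,
    coast_side = coast_side, water_width = water_width,
    village_houses = as.integer(village_houses),
    seed = as.integer(seed)
  ), class = "city_params")
}

# mark raster cells whose centre lies within halfw of segment p1--p2
mark_segment <- function(landuse, p1, p2, halfw, res, code = LU_CODES[["road"]]) {
  nx <- nrow(landuse); ny <- ncol(landuse)
  xlo <- max(1L, floor((min(p1[1], p2[1]) - halfw) / res) + 1L)
  xhi <- min(nx, floor((max(p1[1], p2[1]) + halfw) / res) + 1L)
  ylo <- max(1L, floor((min(p1[2], p2[2]) - halfw) / res) + 1L)
  yhi <- min(ny, floor((max(p1[2], p2[2]) + halfw) / res) + 1L)
  if (xlo > xhi || ylo > yhi) return(landuse)
  ix <- xlo:xhi; iy <- ylo:yhi
  cx <- (ix - 0.5) * res; cy <- (iy - 0.5) * res
  px <- outer(cx, rep(1, length(cy))); py <- outer(rep(1, length(cx)), cy)
  dx <- p2[1] - p1[1]; dy <- p2[2] - p1[2]
  len2 <- dx * dx + dy * dy
  if (len2 < 1e-12) {
    t <- 0
    qx <- p1[1]; qy <- p1[2]
    d2 <- (px - qx)^2 + (py - qy)^2
  } else {
    t <- pmin(1, pmax(0, ((px - p1[1]) * dx + (py - p1[2]) * dy) / len2))
    qx <- p1[1] + t * dx; qy <- p1[2] + t * dy
    d2 <- (px - qx)^2 + (py - qy)^2
  }
  sel <- d2 <= halfw^2
  sub <- landuse[ix, iy, drop = FALSE]
  sub[sel] <- code
  landuse[ix, iy] <- sub
  landuse
}

# stamp an axis-aligned rectangle (x1,y1)-(x2,y2) if all its cells are free
stamp_rect <- function(landuse, rect, res, only_if_free = TRUE) {
  nx <- nrow(landuse); ny <- ncol(landuse)
  xlo <- floor(rect[1] / res) + 1L; xhi <- ceiling(rect[3] / res)
  ylo <- floor(rect[2] / res) + 1L; yhi <- ceiling(rect[4] / res)
  if (xlo < 1L || ylo < 1L || xhi > nx || yhi > ny) return(NULL)
  # cells whose centre is inside the rectangle
  ix <- xlo:xhi; iy <- ylo:yhi
  cx <- (ix - 0.5) * res; cy <- (iy - 0.5) * res
  ix <- ix[cx >= rect[1] & cx <= rect[3]]
  iy <- iy[cy >= rect[2] & cy <= rect[4]]
  if (!length(ix) || !length(iy)) return(NULL)
  sub <- landuse[ix, iy, drop = FALSE]
  if (only_if_free && any(sub != LU_CODES[["other"]])) return(NULL)
  sub[] <- LU_CODES[["building"]]
  landuse[ix, iy] <- sub
  landuse
}

rect_polygon <- function(rect) {
  matrix(c(rect[1], rect[2], rect[3], rect[2], rect[3], rect[4],
           rect[1], rect[4]), ncol = 2, byrow = TRUE)
}

# snap a point to the centre of its containing cell
snap_to_cell <- function(p, res, n) {
  ix <- pmin(pmax(floor(p[1] / res), 0), n - 1)
  iy <- pmin(pmax(floor(p[2] / res), 0), n - 1)
  c((ix + 0.5) * res, (iy + 0.5) * res)
}

generate_grid_city <- function(p) {
  E <- p$extent; res <- p$resolution
  n <- round(E / res)
  landuse <- matrix(LU_CODES[["other"]], n, n)
  halfw <- p$road_width / 2
  y0 <- p$water_width # land starts above the sea strip (coast frame: south)

  lines_x <- seq(0, E, by = p$street_spacing)
  lines_y <- seq(y0, E, by = p$street_spacing)
  roads <- list()
  for (x in lines_x) {
    landuse <- mark_segment(landuse, c(x, y0), c(x, E), halfw, res)
    roads[[length(roads) + 1L]] <- matrix(c(x, y0, x, E), 2, 2, byrow = TRUE)
  }
  for (y in lines_y) {
    landuse <- mark_segment(landuse, c(0, y), c(E, y), halfw, res)
    roads[[length(roads) + 1L]] <- matrix(c(0, y, E, y), 2, 2, byrow = TRUE)
  }

  # buildings: each block is subdivided into lots; one jittered building per
  # lot with footprint area = coverage * lot area
  buildings <- list()
  if (p$building_coverage > 0) {
    setback <- halfw + 1
    for (bx in seq_len(length(lines_x) - 1L)) {
      for (by in seq_len(length(lines_y) - 1L)) {
        x1 <- lines_x[bx] + setback; x2 <- lines_x[bx + 1L] - setback
        y1 <- lines_y[by] + setback; y2 <- lines_y[by + 1L] - setback
        if (x2 - x1 < 2 * res || y2 - y1 < 2 * res) next
        nlx <- max(1L, floor((x2 - x1) / 12))
        nly <- max(1L, floor((y2 - y1) / 12))
        lw <- (x2 - x1) / nlx; lh <- (y2 - y1) / nly
        side_frac <- sqrt(p$building_coverage)
        for (lx in seq_len(nlx)) {
          for (ly in seq_len(nly)) {
            cx <- x1 + (lx - 0.5) * lw; cy <- y1 + (ly - 0.5) * lh
            jit <- runif(1, 0.9, 1.1)
            bw <- min(lw - res, side_frac * lw * jit)
            bh <- min(lh - res, side_frac * lh * jit)
            rect <- c(cx - bw / 2, cy - bh / 2, cx + bw / 2, cy + bh / 2)
            upd <- stamp_rect(landuse, rect, res)
            if (!is.null(upd)) {
              landuse <- upd
              buildings[[length(buildings) + 1L]] <- rect_polygon(rect)
            }
          }
        }
      }
    }
  }

  # destinations: evenly-spaced street/inland-edge junctions, snapped to the
  # centre of the top road cell of the chosen street columns
  k <- length(lines_x)
  pick <- unique(round(seq(1, k, length.out = p$n_destinations + 2L)))
  pick <- pick[-c(1L, length(pick))]
  if (length(pick) < p$n_destinations)
    pick <- unique(round(seq(2, k - 1L, length.out = p$n_destinations)))
  dest <- t(vapply(lines_x[pick[seq_len(p$n_destinations)]],
                   function(x) snap_to_cell(c(x, E - res / 2), res, n),
                   numeric(2)))
  list(landuse = landuse, buildings = buildings, destinations = dest,
       roads = roads)
}

generate_root_city <- function(p) {
  E <- p$extent; res <- p$resolution
  n <- round(E / res)
  landuse <- matrix(LU_CODES[["other"]], n, n)
  halfw <- p$road_width / 2
  y0 <- p$water_width

  # trunk from the valley mouth at the coast, then a fan of branches whose
  # tips reach the inland edge
  mouth <- c(E / 2, y0)
  junction <- c(E / 2, y0 + 0.3 * (E - y0))
  nb <- p$branch_count
  tip_x <- E * (seq_len(nb) - 0.5) / nb
  tip_x <- junction[1] + (tip_x - junction[1]) *
    min(1, tan(p$branch_angle * pi / 180) * (E - junction[2]) / (E / 2 + 1e-9))
  tips <- cbind(tip_x, E)

  segs <- list(rbind(mouth, junction))
  for (b in seq_len(nb)) {
    # each branch runs junction -> elbow -> tip, giving a root-like bend
    elbow <- junction + 0.55 * (tips[b, ] - junction) +
      c(runif(1, -0.03, 0.03) * E, 0)
    segs[[length(segs) + 1L]] <- rbind(junction, elbow)
    segs[[length(segs) + 1L]] <- rbind(elbow, tips[b, ])
  }
  for (s in segs)
    landuse <- mark_segment(landuse, s[1, ], s[2, ], halfw, res)

  # settlement pattern with two tiers, mirroring a ria-valley town:
  # (i) a compact village lines both roadsides at the base of each branch
  # (houses chained within the communication radius -- when such a village
  # tips positive it evacuates as one group up its branch);
  # (ii) beyond the village, detached houses in two staggered rows sit well
  # back from the carriageway, each beyond communication range of its
  # neighbours and of the road (households decide on their own)
  buildings <- list()
  if (p$building_coverage > 0) {
    bside <- 8
    step <- bside / p$building_coverage
    add_house <- function(ctr) {
      jit <- runif(1, 0.85, 1.1)
      bw <- bside * jit
      rect <- c(ctr[1] - bw / 2, ctr[2] - bw / 2,
                ctr[1] + bw / 2, ctr[2] + bw / 2)
      upd <- stamp_rect(landuse, rect, res)
      if (!is.null(upd)) {
        landuse <<- upd
        buildings[[length(buildings) + 1L]] <<- rect_polygon(rect)
      }
    }
    village_len <- p$village_houses * 12
    for (si in seq_along(segs)) {
      s <- segs[[si]]
      v <- s[2, ] - s[1, ]
      len <- sqrt(sum(v^2))
      if (len < 10) next
      u <- v / len
      perp <- c(-u[2], u[1])
      # villages occupy the start of the two branch segments leaving the
      # junction (not the trunk, which would couple all villages)
      vl <- if (si > 1) min(village_len, 0.6 * len) else 0
      if (vl > 0) {
        for (st in seq(6, vl, by = 12)) {
          base <- s[1, ] + st * u
          for (side in c(-1, 1))
            add_house(base + side * (halfw + 2 + bside / 2) * perp)
        }
      }
      # detached two-row belt on the remainder of the segment
      st0 <- max(vl + step / 2, step / 2)
      if (st0 < len - step / 2) {
        for (st in seq(st0, len - step / 2, by = step)) {
          for (row in c(1, 2)) {
            st_r <- if (row == 1) st else st + step / 2
            if (st_r > len - step / 2) next
            base <- s[1, ] + st_r * u
            for (side in c(-1, 1))
              add_house(base + side *
                          (halfw + 8 + bside / 2 + (row - 1) * (bside + 13)) * perp)
          }
        }
      }
    }
  }

  # destinations: branch tips (evenly chosen when fewer are requested)
  sel <- unique(round(seq(1, nb, length.out = p$n_destinations)))
  dest <- t(vapply(sel, function(b) {
    snap_to_cell(c(tips[b, 1], E - res / 2), res, n)
  }, numeric(2)))
  list(landuse = landuse, buildings = buildings, destinations = dest,
       roads = segs)
}

# map geometry generated in the coast="S" frame onto the requested side
transform_point_from_S <- function(pts, side, E) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  switch(side,
         S = pts,
         N = cbind(pts[, 1], E - pts[, 2]),
         W = cbind(pts[, 2], pts[, 1]),
         E = cbind(E - pts[, 2], pts[, 1]))
}

transform_raster_from_S <- function(m, side) {
  switch(side,
         S = m,
         N = m[, ncol(m):1, drop = FALSE],
         W = t(m),
         E = t(m)[nrow(m):1, , drop = FALSE])
}

#' Generate a synthetic urban model
#'
#' Builds an [`urban_model`][generate_city] from [city_params()]: a land-use
#' raster (categories other/road/building/water), building footprint
#' polygons, evacuation destination points and road centrelines. The
#' generator is deterministic given `params$seed`. Destinations always lie on
#' road cells on the inland boundary, outside the inundation zone.
#'
#' @param params A `city_params` object.
#' @return A list of class `urban_model` with fields `bounds` (xmin, ymin,
#'   xmax, ymax), `resolution`, `landuse` (integer matrix, codes 0 other /
#'   1 road / 2 building / 3 water), `buildings` (list of polygon matrices),
#'   `destinations` (matrix of points), `roads` (list of centreline
#'   matrices), `coast_side`, `inundation_depth_fraction`, `style`, `params`.
#' @examples
#' city <- generate_city(city_params("grid", extent = 200, seed = 1))
#' table(city$landuse)
#' @export
generate_city <- function(params) {
  if (!inherits(params, "city_params")) stop("params must be a city_params object")
  p <- params
  set.seed(p$seed)
  raw <- switch(p$style,
                grid = generate_grid_city(p),
                root = generate_root_city(p))
  E <- p$extent
  landuse <- raw$landuse
  if (p$water_width > 0) {
    iy <- seq_len(max(1L, floor(p$water_width / p$resolution)))
    landuse[, iy] <- LU_CODES[["water"]]
  }
  landuse <- transform_raster_from_S(landuse, p$coast_side)
  buildings <- lapply(raw$buildings, transform_point_from_S,
                      side = p$coast_side, E = E)
  destinations <- transform_point_from_S(raw$destinations, p$coast_side, E)
  roads <- lapply(raw$roads, transform_point_from_S, side = p$coast_side, E = E)

  model <- structure(list(
    bounds = c(0, 0, E, E), resolution = p$resolution,
    landuse = landuse, buildings = buildings,
    destinations = destinations, roads = roads,
    coast_side = p$coast_side,
    inundation_depth_fraction = p$inundation_depth_fraction,
    style = p$style, params = p
  ), class = "urban_model")
  validate_urban(model)
  model
}

# destination-on-road and category-code checks shared by generator and loader
validate_urban <- function(urban) {
  lu <- urban$landuse
  if (!all(lu %in% LU_CODES))
    stop("landuse raster contains unknown category codes")
  for (k in seq_len(nrow(urban$destinations))) {
    d <- urban$destinations[k, ]
    code <- landuse_at(urban, d[1], d[2])
    if (code != LU_CODES[["road"]])
      stop("destination ", k, " does not lie on a road cell")
    if (coast_distance(urban, matrix(d, ncol = 2)) <=
        urban$inundation_depth_fraction * (urban$bounds[3] - urban$bounds[1]))
      stop("destination ", k, " lies inside the inundation zone")
  }
  invisible(urban)
}

#' Land-use category at coordinates
#'
#' @param urban An `urban_model`.
#' @param x,y Coordinate vectors (metres).
#' @return Integer category codes (0 other, 1 road, 2 building, 3 water).
#' @export
landuse_at <- function(urban, x, y) {
  res <- urban$resolution
  nx <- nrow(urban$landuse); ny <- ncol(urban$landuse)
  ix <- pmin(pmax(floor(x / res), 0), nx - 1) + 1
  iy <- pmin(pmax(floor(y / res), 0), ny - 1) + 1
  urban$landuse[cbind(ix, iy)]
}

#' Perpendicular distance of points from the coast edge
#'
#' @param urban An `urban_model`.
#' @param pts An `n x 2` matrix of points (metres).
#' @return Numeric distances from the coast-side boundary.
#' @export
coast_distance <- function(urban, pts) {
  E <- urban$bounds[3]
  switch(urban$coast_side,
         S = pts[, 2], N = E - pts[, 2],
         W = pts[, 1], E = E - pts[, 1])
}

#' @export
print.urban_model <- function(x, ...) {
  lu <- factor(x$landuse, levels = LU_CODES, labels = names(LU_CODES))
  cat("<urban_model> style:", x$style,
      " extent:", x$bounds[3] - x$bounds[1], "m @", x$resolution, "m\n")
  cat("  buildings:", length(x$buildings),
      " destinations:", nrow(x$destinations),
      " coast:", x$coast_side, "\n")
  print(round(prop.table(table(lu)), 3))
  invisible(x)
}

#' Place agents uniformly at random inside buildings
#'
#' Samples initial agent positions uniformly within the building footprints
#' of an urban model, weighting buildings by area. With
#' `restrict_to_inundation = TRUE` only buildings touching the inundation
#' zone (the band of the domain within `inundation_depth_fraction` of the
#' coast edge) are eligible -- mirroring placement restricted to the
#' inundated part of a coastal-plain city.
#'
#' @param urban An `urban_model`.
#' @param n Number of agents.
#' @param restrict_to_inundation Restrict eligible buildings to the
#'   inundation zone.
#' @param seed Integer seed.
#' @return An `n x 2` matrix of positions (metres).
#' @export
place_agents <- function(urban, n, restrict_to_inundation = FALSE, seed = 1L) {
  stopifnot(n >= 1)
  blds <- urban$buildings
  if (!length(blds)) stop("urban model has no buildings")
  if (restrict_to_inundation) {
    depth <- urban$inundation_depth_fraction * (urban$bounds[3] - urban$bounds[1])
    keep <- vapply(blds, function(b) {
      min(coast_distance(urban, b)) <= depth
    }, logical(1))
    blds <- blds[keep]
    if (!length(blds))
      stop("no buildings intersect the inundation zone")
  }
  areas <- vapply(blds, function(b) {
    (max(b[, 1]) - min(b[, 1])) * (max(b[, 2]) - min(b[, 2]))
  }, numeric(1))
  set.seed(seed)
  which_b <- sample.int(length(blds), n, replace = TRUE, prob = areas)
  pos <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    b <- blds[[which_b[i]]]
    # buildings are axis-aligned rectangles: sample the interior directly
    pos[i, 1] <- runif(1, min(b[, 1]) + 1e-6, max(b[, 1]) - 1e-6)
    pos[i, 2] <- runif(1, min(b[, 2]) + 1e-6, max(b[, 2]) - 1e-6)
  }
  pos
}

#' Sample initial evacuation attitudes
#'
#' Attitudes are i.i.d. Uniform(-1, 1): positive values express intention to
#' evacuate, negative values reluctance.
#'
#' @param n Number of agents.
#' @param seed Integer seed.
#' @return Numeric vector of length `n` in `[-1, 1]`.
#' @export
sample_initial_attitudes <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  runif(n, -1, 1)
}

#' Assign leading evacuees by sampling without replacement
#'
#' @param n_agents Total number of agents.
#' @param n_leaders Exact number of leading evacuees (0 allowed).
#' @param seed Integer seed.
#' @return Integer vector of `n_leaders` distinct agent indices.
#' @export
assign_leaders <- function(n_agents, n_leaders, seed = 1L) {
  if (n_leaders < 0 || n_leaders > n_agents)
    stop("n_leaders must be between 0 and n_agents")
  if (n_leaders == 0) return(integer(0))
  set.seed(seed)
  sort(sample.int(n_agents, n_leaders, replace = FALSE))
}
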