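# Synthetic urban generator: structural contracts of the two city styles.

count_street_lines <- function(landuse, margin = 0.9, axis = 1) {
  # count maximal runs of raster columns (axis 1) / rows (axis 2) that are
  # almost entirely road -- these are the straight streets of a grid city
  frac <- if (axis == 1) colMeans(landuse == 1L) else rowMeans(landuse == 1L)
  runs <- rle(frac >= margin)
  sum(runs$values)
}

test_that("grid city produces the expected street lattice and destinations", {
  city <- generate_city(city_params("grid", extent = 500, street_spacing = 50,
                                    n_destinations = 2, seed = 1))
  lu <- city$landuse
  # streets every 50 m across 500 m -> 11 vertical and 11 horizontal lines
  frac_col <- vapply(seq_len(ncol(lu)), function(iy) mean(lu[, iy] == 1L),
                     numeric(1))
  expect_equal(count_street_lines(t(lu)), 11)  # horizontal streets
  expect_equal(count_street_lines(lu), 11)     # vertical streets
  expect_equal(nrow(city$destinations), 2)
  # destinations on the inland (north) edge, on road cells
  expect_true(all(city$destinations[, 2] > 0.95 * 500))
  expect_true(all(landuse_at(city, city$destinations[, 1],
                             city$destinations[, 2]) == 1L))
})

test_that("root city road network is connected with one destination per tip", {
  city <- generate_city(city_params("root", extent = 500, branch_count = 3,
                                    seed = 1))
  expect_gte(nrow(city$destinations), 3)
  # rasterised roads form a single connected component (8-connectivity)
  lu <- city$landuse
  road <- which(lu == 1L, arr.ind = TRUE)
  key <- function(ix, iy) ix + nrow(lu) * iy
  id <- setNames(seq_len(nrow(road)), key(road[, 1], road[, 2]))
  from <- integer(0); to <- integer(0)
  for (d in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    nb <- key(road[, 1] + d[1], road[, 2] + d[2])
    hit <- nb %in% names(id)
    from <- c(from, id[as.character(key(road[hit, 1], road[hit, 2]))])
    to <- c(to, id[as.character(nb[hit])])
  }
  g <- igraph::make_undirected_graph(rbind(from, to), n = nrow(road))
  expect_equal(igraph::components(g)$no, 1)
})

test_that("zero building coverage yields no building cells or polygons", {
  city <- generate_city(city_params("grid", extent = 200,
                                    building_coverage = 0, seed = 1))
  expect_equal(sum(city$landuse == 2L), 0)
  expect_length(city$buildings, 0)
})

test_that("degenerate extents are rejected", {
  expect_error(city_params("grid", extent = 5, resolution = 1), "degenerate")
})

test_that("city generation is deterministic and rasterisation idempotent", {
  a <- generate_city(city_params("root", extent = 200, seed = 7))
  b <- generate_city(city_params("root", extent = 200, seed = 7))
  expect_identical(a$landuse, b$landuse)
  expect_identical(a$buildings, b$buildings)
  expect_identical(a$destinations, b$destinations)
})

test_that("root roads are wider and buildings sparser than grid defaults", {
  grid <- generate_city(city_params("grid", extent = 300, seed = 1))
  root <- generate_city(city_params("root", extent = 300, seed = 1))
  # mean road width ~ road area / total centreline length
  centreline <- function(city) sum(vapply(city$roads, function(s) {
    sum(sqrt(rowSums(diff(s)^2)))
  }, numeric(1)))
  width_g <- sum(grid$landuse == 1L) * grid$resolution^2 / centreline(grid)
  width_r <- sum(root$landuse == 1L) * root$resolution^2 / centreline(root)
  expect_lt(width_g, width_r)
  expect_lt(mean(root$landuse == 2L), mean(grid$landuse == 2L))
})

test_that("agents are placed strictly inside buildings, never on roads or water", {
  city <- tiny_grid_city()
  pos <- place_agents(city, 400, seed = 3)
  expect_equal(nrow(pos), 400)
  inside <- vapply(seq_len(nrow(pos)), function(i) {
    any(vapply(city$buildings, function(b) {
      pos[i, 1] > min(b[, 1]) && pos[i, 1] < max(b[, 1]) &&
        pos[i, 2] > min(b[, 2]) && pos[i, 2] < max(b[, 2])
    }, logical(1)))
  }, logical(1))
  expect_true(all(inside))
  codes <- landuse_at(city, pos[, 1], pos[, 2])
  expect_false(any(codes %in% c(1L, 3L)))
  # determinism
  expect_identical(pos, place_agents(city, 400, seed = 3))
})

test_that("inundation-zone restriction filters buildings and can empty support", {
  city <- tiny_grid_city()
  depth <- city$inundation_depth_fraction * (city$bounds[3] - city$bounds[1])
  pos <- place_agents(city, 200, restrict_to_inundation = TRUE, seed = 1)
  # each point is inside some building that touches the zone; the point
  # itself can exceed the depth by at most one building extent
  expect_true(all(coast_distance(city, pos) <= depth + 20))
  # a city whose inundation band lies below the lowest building
  shore <- generate_city(city_params("grid", extent = 120, street_spacing = 40,
                                     inundation_depth_fraction = 0.02,
                                     seed = 1))
  expect_error(place_agents(shore, 10, restrict_to_inundation = TRUE),
               "inundation")
})

test_that("initial attitudes are Uniform(-1,1), reproducible", {
  a <- sample_initial_attitudes(1e5, seed = 42)
  expect_gte(min(a), -1)
  expect_lte(max(a), 1)
  expect_lt(abs(mean(a)), 0.01)
  expect_identical(a, sample_initial_attitudes(1e5, seed = 42))
  expect_length(sample_initial_attitudes(1, seed = 1), 1)
})

test_that("leader assignment is exact, distinct and validated", {
  l <- assign_leaders(5000, 500, seed = 9)
  expect_length(l, 500)
  expect_false(any(duplicated(l)))
  expect_true(all(l >= 1 & l <= 5000))
  expect_identical(l, assign_leaders(5000, 500, seed = 9))
  expect_length(assign_leaders(100, 0), 0)
  expect_setequal(assign_leaders(10, 10), 1:10)
  expect_error(assign_leaders(10, 11), "between 0 and")
})

test_that("coast_side transforms keep destinations on roads opposite the coast", {
  for (side in c("S", "N", "W", "E")) {
    city <- generate_city(city_params("grid", extent = 120,
                                      street_spacing = 40,
                                      coast_side = side, seed = 1))
    expect_true(all(landuse_at(city, city$destinations[, 1],
                               city$destinations[, 2]) == 1L))
    expect_true(all(coast_distance(city, city$destinations) > 0.9 * 120))
  }
})
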