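# Least-cost navigation fields: cost mapping, closed forms, Dijkstra oracle,
# and descent properties.

test_that("cost map applies the category cost table elementwise", {
  allroad <- matrix(1L, 5, 5)
  expect_true(all(build_cost_map(allroad) == 1))
  lu <- matrix(1L, 4, 4)
  lu[2, 3] <- 3L  # one water cell
  cm <- build_cost_map(lu)
  expect_equal(cm[2, 3], 8000)
  expect_equal(sum(cm == 8000), 1)
  lu[1, 1] <- 2L; lu[4, 4] <- 0L
  cm <- build_cost_map(lu)
  expect_equal(cm[1, 1], 4000)
  expect_equal(cm[4, 4], 2000)
  # override table respected
  cm2 <- build_cost_map(allroad, c(other = 1, road = 7, building = 1, water = 1))
  expect_true(all(cm2 == 7))
})

test_that("cost map rejects unknown categories and empty rasters", {
  expect_error(build_cost_map(matrix(integer(0), 0, 0)), "empty")
  expect_error(build_cost_map(matrix(5L, 2, 2)), "unknown")
  expect_error(build_cost_map(matrix(1L, 2, 2),
                              c(road = 0, building = 1, water = 1, other = 1)),
               "positive")
})

test_that("uniform-cost field equals Manhattan distance at 4-connectivity", {
  cost <- matrix(1, 9, 9)
  dest <- c(4.5, 4.5) # centre of cell (5, 5)
  f <- compute_navigation_field(cost, dest, resolution = 1, connectivity = 4)
  ix <- slice.index(cost, 1); iy <- slice.index(cost, 2)
  manhattan <- abs(ix - 5) + abs(iy - 5)
  expect_equal(f$cumcost, manhattan, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("uniform-cost field equals octile distance at 8-connectivity", {
  cost <- matrix(1, 9, 9)
  res <- 2
  f <- compute_navigation_field(cost, c(9, 9), resolution = res,
                                connectivity = 8)
  ix <- slice.index(cost, 1); iy <- slice.index(cost, 2)
  dx <- abs(ix - 5); dy <- abs(iy - 5)
  octile <- res * (sqrt(2) * pmin(dx, dy) + abs(dx - dy))
  expect_equal(f$cumcost, octile, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("navigation field matches the independent shortest-path oracle", {
  set.seed(11)
  for (rep in 1:5) {
    cost <- matrix(exp(runif(400, 0, 6)), 20, 20)
    dests <- cbind(sample(0:19, 2), sample(0:19, 2))
    f <- compute_navigation_field(cost, (dests + 0.5) * 1.0, resolution = 1)
    oracle <- oracle_nav_cost(cost, dests, res = 1, connectivity = 8)
    expect_equal(f$cumcost, oracle, tolerance = 1e-9)
  }
})

test_that("destination cells are zero and adding a destination never hurts", {
  set.seed(5)
  cost <- matrix(exp(runif(225, 0, 4)), 15, 15)
  f1 <- compute_navigation_field(cost, c(2.5, 2.5))
  expect_equal(f1$cumcost[3, 3], 0)
  f2 <- compute_navigation_field(cost, rbind(c(2.5, 2.5), c(12.5, 12.5)))
  expect_true(all(f2$cumcost <= f1$cumcost + 1e-12))
})

test_that("desired directions descend the field and reach a destination", {
  # single-step descent toward an adjacent destination
  cost <- matrix(1, 7, 7)
  f <- compute_navigation_field(cost, c(3.5, 3.5)) # destination cell (4, 4)
  expect_equal(desired_direction(f, c(4.5, 3.5))[1, ], c(-1, 0)) # east nbr
  expect_equal(desired_direction(f, c(3.5, 3.5))[1, ], c(0, 0))  # at dest
  expect_error(desired_direction(f, c(100, 3)), "outside")

  # greedy descent terminates within n_cells steps on random rasters, with
  # strictly decreasing cumulative cost (no cycles)
  set.seed(21)
  for (rep in 1:3) {
    cost <- matrix(exp(runif(144, 0, 5)), 12, 12)
    dest_cell <- c(sample(0:11, 1), sample(0:11, 1))
    f <- compute_navigation_field(cost, (dest_cell + 0.5))
    for (start in list(c(0.5, 0.5), c(11.5, 0.5), c(5.5, 11.5))) {
      p <- start
      last <- Inf
      for (s in 1:144) {
        ixy <- floor(p) + 1
        cc <- f$cumcost[ixy[1], ixy[2]]
        expect_lt(cc, last)
        last <- cc
        d <- desired_direction(f, p)[1, ]
        if (all(d == 0)) break
        p <- floor(p) + 0.5 + sign(d) # hop to the indicated neighbour centre
      }
      expect_equal(floor(p), dest_cell, ignore_attr = TRUE)
    }
  }
})

test_that("dynamic-programming consistency holds at every non-destination cell", {
  set.seed(33)
  cost <- matrix(exp(runif(100, 0, 4)), 10, 10)
  f <- compute_navigation_field(cost, c(4.5, 7.5))
  cc <- f$cumcost
  for (ix in 1:10) for (iy in 1:10) {
    if (ix == 5 && iy == 8) next
    best <- Inf
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      jx <- ix + dx; jy <- iy + dy
      if (jx < 1 || jx > 10 || jy < 1 || jy > 10) next
      w <- sqrt(dx^2 + dy^2) * 0.5 * (cost[ix, iy] + cost[jx, jy])
      best <- min(best, cc[jx, jy] + w)
    }
    expect_equal(cc[ix, iy], best, tolerance = 1e-9)
  }
})

test_that("destinations outside the raster are rejected", {
  cost <- matrix(1, 10, 10)
  expect_error(compute_navigation_field(cost, c(50, 5)), "outside")
  expect_error(compute_navigation_field(cost, matrix(numeric(0), 0, 2)),
               "destination")
})
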