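test_that("slope corrections reproduce the normalized Tobler walking speeds", {
  expect_equal(tobler_speed(5, 0), 5)
  expect_equal(tobler_speed(5, 0.10), 5 * exp(-0.35))
  expect_equal(tobler_speed(1.67, 0), 1.67)
  # fastest on a slight downhill, slower both ways from there
  expect_gt(tobler_speed(5, -0.05), tobler_speed(5, 0))
  expect_gt(tobler_speed(5, -0.05), tobler_speed(5, -0.3))
  expect_equal(effective_speed(6, 1, 0.10), 5 * exp(-0.35))
  expect_equal(effective_speed(14, 3, 0.25), 50)  # motorized: no correction
  expect_error(effective_speed(11, 1), "barrier")
})

test_that("cycling speed solves the constant-power balance with cap and floor", {
  expect_equal(cycling_speed(10, 0), 10, tolerance = 1e-9)
  expect_lt(cycling_speed(10, 0.05), 10)
  expect_gt(cycling_speed(10, -0.05), 10)
  # steep downhill hits the 1.5x cap
  expect_equal(cycling_speed(10, -0.4), 15)
  # power balance holds at the returned (uncapped) speed
  p <- cycling_params()
  v <- cycling_speed(10, 0.08) / 3.6
  v0 <- 10 / 3.6
  p0 <- 0.5 * p$rho_air * p$cda * v0^3 + p$mass_kg * p$g * p$crr * v0
  expect_equal(0.5 * p$rho_air * p$cda * v^3 +
                 p$mass_kg * p$g * (p$crr + 0.08) * v, p0, tolerance = 1e-6)
  # scenario speed never falls below pushing the bike at walking pace
  expect_gte(effective_speed(16, 2, 0.5), tobler_speed(5, 0.5))
})

test_that("flat uniform landscape yields the hand-computed neighbour times", {
  toy <- flat_toy(3, 3)                 # class 6 walks at 5 km/h, 90 m cells
  origin <- tibble::tibble(id = "A", row = 2L, col = 2L)
  surf <- travel_time_from(origin, toy$cost, toy$dem, 1)
  expect_equal(surf$values[2, 2], 0)
  expect_equal(surf$values[2, 1], 0.09 / 5 * 60)           # 1.08 min axial
  expect_equal(surf$values[1, 1], 0.09 * sqrt(2) / 5 * 60) # diagonal
  expect_equal(attr(surf, "scenario"), 1)
})

test_that("flat-terrain travel time is isotropic: equidistant cells agree to 1e-9", {
  toy <- flat_toy(9, 9)
  origin <- tibble::tibble(id = "A", row = 5L, col = 5L)
  surf <- travel_time_from(origin, toy$cost, toy$dem, 1)
  v <- surf$values
  expect_lt(max(abs(c(v[5, 1] - v[5, 9], v[1, 5] - v[9, 5],
                      v[1, 1] - v[9, 9], v[1, 9] - v[9, 1],
                      v[5, 1] - v[1, 5]))), 1e-9)
})

test_that("walking uphill toward the facility is slower than downhill on the same transect", {
  nr <- 1; nc <- 7
  cost <- new_grid(matrix(6, nr, nc), cell_size = 90, kind = "categorical")
  dem <- new_grid(matrix(seq(1000, 1540, length.out = nc), nr, nc),
                  cell_size = 90, kind = "continuous")    # rises eastward
  origin <- tibble::tibble(id = "A", row = 1L, col = 4L)
  surf <- travel_time_from(origin, cost, dem, 1, cap_minutes = Inf)
  # west cells walk uphill toward the facility, east cells walk downhill
  expect_gt(surf$values[1, 1], surf$values[1, 7])
  expect_gt(surf$values[1, 2], surf$values[1, 6])
})

test_that("water is an absolute barrier: cells cut off by it are unreachable", {
  v <- matrix(6, 5, 5); v[, 3] <- 11
  cost <- new_grid(v, cell_size = 90, kind = "categorical")
  dem <- new_grid(matrix(1000, 5, 5), cell_size = 90, kind = "continuous")
  origin <- tibble::tibble(id = "A", row = 3L, col = 1L)
  surf <- travel_time_from(origin, cost, dem, 1)
  reach <- attr(surf, "reach")
  expect_true(all(is.na(surf$values[, 3:5])))
  expect_true(all(reach[, 4:5] == 3))      # unreachable, not merely capped
  expect_true(all(is.na(reach[, 3])))      # barrier cells carry no code
  # a road bridge across restores reachability
  v[3, 3] <- 16
  cost2 <- new_grid(v, cell_size = 90, kind = "categorical")
  surf2 <- travel_time_from(origin, cost2, dem, 1, cap_minutes = Inf)
  expect_true(is.finite(surf2$values[3, 5]))
})

test_that("times beyond the cap are masked but flagged distinctly", {
  toy <- flat_toy(3, 3, class_code = 3)   # 1 km/h: neighbours cost > 5 min
  origin <- tibble::tibble(id = "A", row = 1L, col = 1L)
  surf <- travel_time_from(origin, toy$cost, toy$dem, 1, cap_minutes = 6)
  expect_equal(sum(!is.na(surf$values)), 3L)  # origin + two axial neighbours
  expect_true(any(attr(surf, "reach") == 2))
  expect_error(travel_time_from(tibble::tibble(id = "B", row = 1L, col = 1L),
                                new_grid(matrix(11, 2, 2), cell_size = 90,
                                         kind = "categorical"),
                                new_grid(matrix(0, 2, 2), cell_size = 90),
                                1), "barrier")
})

test_that("grid-graph Dijkstra matches the exhaustive relaxation oracle on random landscapes", {
  set.seed(20)
  for (i in 1:25) {
    L <- random_landscape(7, 7)
    trav <- arrayInd(which(!(L$cost$values %in% barrier_codes())),
                     dim(L$cost$values))
    o <- trav[sample(nrow(trav), 1), , drop = FALSE]
    origin <- tibble::tibble(id = "A", row = o[1], col = o[2])
    sc <- sample(1:3, 1)
    got <- uncapped_times(origin, L$cost, L$dem, sc)
    want <- oracle_travel_time(L$cost, L$dem, sc, origin)
    want[L$cost$values %in% barrier_codes()] <- NA
    got[is.na(got)] <- Inf; want[is.na(want)] <- Inf
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("Dijkstra agrees with igraph shortest paths as a second, independent check", {
  skip_if_not_installed("igraph")
  set.seed(33)
  L <- random_landscape(10, 10, p_water = 0.05)
  et <- edge_times(L$cost, L$dem, 1)
  nr <- 10; nc <- 10
  edges <- NULL; weights <- NULL
  for (k in 1:8) {
    w <- et$times[[k]]
    idx <- which(!is.na(w), arr.ind = TRUE)
    from <- (idx[, 2] - 1) * nr + idx[, 1]
    to <- (idx[, 2] - 1 + et$offsets[k, 2]) * nr + idx[, 1] + et$offsets[k, 1]
    edges <- rbind(edges, cbind(from, to))
    weights <- c(weights, w[idx])
  }
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  if (igraph::vcount(g) < nr * nc) {
    g <- igraph::add_vertices(g, nr * nc - igraph::vcount(g))
  }
  trav <- arrayInd(which(!(L$cost$values %in% barrier_codes())),
                   dim(L$cost$values))
  origin <- tibble::tibble(id = "A", row = trav[1, 1], col = trav[1, 2])
  d_ig <- igraph::distances(g, v = (origin$col - 1) * nr + origin$row,
                            mode = "out", weights = weights)
  got <- uncapped_times(origin, L$cost, L$dem, 1)
  got[is.na(got)] <- Inf
  expect_equal(as.vector(got), as.vector(d_ig)[seq_len(nr * nc)],
               tolerance = 1e-9)
})

test_that("the accessibility surface is the cellwise minimum and never increases with more facilities", {
  toy <- flat_toy(5, 5)
  a <- travel_time_from(tibble::tibble(id = "A", row = 1L, col = 1L),
                        toy$cost, toy$dem, 1)
  b <- travel_time_from(tibble::tibble(id = "B", row = 5L, col = 5L),
                        toy$cost, toy$dem, 1)
  expect_equal(accessibility_surface(list(a))$values, a$values)
  m <- accessibility_surface(list(a, b))
  expect_equal(m$values, pmin(a$values, b$values, na.rm = TRUE))
  expect_true(all(m$values <= a$values + 1e-12, na.rm = TRUE))
  expect_error(accessibility_surface(list()), "empty")
})

test_that("restricting the transit mask degrades scenario 3 to walking on motorized roads", {
  v <- matrix(6, 3, 5); v[2, ] <- 14      # national road along the middle row
  cost <- new_grid(v, cell_size = 90, kind = "categorical")
  dem <- new_grid(matrix(1000, 3, 5), cell_size = 90, kind = "continuous")
  origin <- tibble::tibble(id = "A", row = 2L, col = 1L)
  fast <- travel_time_from(origin, cost, dem, 3)
  slow <- travel_time_from(origin, cost, dem, 3,
                           transit_mask = matrix(FALSE, 3, 5))
  s1 <- travel_time_from(origin, cost, dem, 1)
  expect_lt(fast$values[2, 5], slow$values[2, 5])
  expect_equal(slow$values, s1$values, tolerance = 1e-9)
})
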