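# Shared fixtures: tiny grids and an independent shortest-path oracle.

# flat, single-class toy landscape (class 6 walks at 5 km/h)
flat_toy <- function(nr = 5, nc = 5, class_code = 6, cell_size = 90,
                     elev = 1000) {
  list(
    cost = new_grid(matrix(class_code, nr, nc), cell_size = cell_size,
                    kind = "categorical"),
    dem = new_grid(matrix(elev, nr, nc), cell_size = cell_size,
                   kind = "continuous")
  )
}

# Independent oracle: exhaustive label-correcting relaxation (Bellman-Ford
# style) over the same edge times, iterated to a fixed point. Shares only
# the edge-cost construction with the implementation, not the search.
oracle_travel_time <- function(cost, dem, scenario, origins,
                               transit_mask = NULL) {
  et <- edge_times(cost, dem, scenario, transit_mask = transit_mask)
  nr <- nrow(cost$values); nc <- ncol(cost$values)
  dist <- matrix(Inf, nr, nc)
  dist[cbind(origins$row, origins$col)] <- 0
  offs <- et$offsets
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (!is.finite(dist[r, c])) next
      for (k in 1:8) {
        rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        w <- et$times[[k]][r, c]
        if (is.na(w)) next
        nd <- dist[r, c] + w
        if (nd < dist[rr, cc] - 1e-12) {
          dist[rr, cc] <- nd
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  dist
}

# random small traversable landscape for oracle-equivalence checks
random_landscape <- function(nr = 8, nc = 8, p_water = 0.1, cell_size = 90) {
  classes <- sample(c(1, 4, 6, 9, 14, 15, 16), nr * nc, replace = TRUE)
  classes[stats::runif(nr * nc) < p_water] <- 11
  cost <- new_grid(matrix(classes, nr, nc), cell_size = cell_size,
                   kind = "categorical")
  dem <- new_grid(matrix(1000 + 80 * stats::rnorm(nr * nc), nr, nc),
                  cell_size = cell_size, kind = "continuous")
  list(cost = cost, dem = dem)
}

# uncapped travel-time values as a matrix (Inf for unreachable)
uncapped_times <- function(origins, cost, dem, scenario, ...) {
  surf <- travel_time_from(origins, cost, dem, scenario,
                           cap_minutes = Inf, ...)
  v <- surf$values
  reach <- attr(surf, "reach")
  v[!is.na(reach) & reach == 3L] <- Inf
  v
}

# small bundle configuration used by the property suites
small_config <- function(seed) {
  synth_config(seed = seed, nrow = 70L, ncol = 70L, n_sectors = 30L,
               total_population = 500000, n_facilities = 30L,
               capacity_mean = 16000,
               n_missing_both = 3L, n_missing_coords = 2L,
               n_missing_capacity = 1L, n_on_water = 2L,
               road_waypoints = c(national = 3L, district = 5L, rural = 10L))
}
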