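test_that("speed table reproduces the scenario speeds per class", {
  expect_equal(speed_for(14, 3)$speed_kmh, 50)       # national, public transport
  expect_equal(speed_for(14, 3)$mode, "motorized")
  expect_equal(speed_for(15, 3)$speed_kmh, 20)       # district
  expect_equal(speed_for(16, 3)$speed_kmh, 5)        # rural: still walking
  expect_equal(speed_for(16, 2)$speed_kmh, 10)       # rural, cycling
  expect_equal(speed_for(16, 2)$mode, "bicycle")
  expect_equal(speed_for(1, 1)$speed_kmh, 1.67)      # mosaic cropland/shrub
  expect_equal(speed_for(4, 1)$speed_kmh, 2.5)
  expect_equal(speed_for(6, 1)$speed_kmh, 5)         # artificial areas
  for (s in 1:3) {
    expect_true(speed_for(11, s)$barrier)            # water: barrier always
    expect_true(speed_for(17, s)$barrier)            # rivers too
  }
  expect_error(speed_for(99, 1), "unknown class")
})

test_that("off-road speeds are scenario-invariant and faster scenarios dominate", {
  tab <- speed_table()
  wide <- tidyr::pivot_wider(tab[!is.na(tab$speed_kmh), c("scenario", "code", "speed_kmh")],
                             names_from = "scenario", values_from = "speed_kmh")
  offroad <- wide[!wide$code %in% c(14:16), ]
  expect_equal(offroad$`2`, offroad$`1`)
  expect_equal(offroad$`3`, offroad$`1`)
  expect_true(all(wide$`2` >= wide$`1`))
  expect_true(all(wide$`3` >= wide$`1`))
})

test_that("cost-surface merge applies landcover < water < rivers < roads precedence", {
  lc <- new_grid(matrix(9, 5, 5), cell_size = 90, kind = "categorical")
  # river flowing down column 3, road crossing along row 3
  river <- new_vector_layer(list(cbind(c(225, 225), c(440, 10))),
                            type = "line")
  road <- new_vector_layer(list(cbind(c(10, 440), c(225, 225))),
                           tibble::tibble(class = "national"), type = "line")
  merged <- merge_cost_surface(lc, rivers = river, roads = road)
  expect_equal(merged$values[3, 3], 14)   # crossing cell is a bridge (road)
  expect_equal(merged$values[1, 3], 17)   # river elsewhere
  expect_equal(merged$values[3, 1], 14)
  expect_equal(merged$values[1, 1], 9)    # untouched landcover

  # identity with no vector features
  expect_identical(merge_cost_surface(lc)$values, lc$values)

  # water polygon burns before rivers/roads
  lake <- new_vector_layer(list(list(cbind(c(0, 450, 450, 0), c(90, 90, 0, 0)))),
                           type = "polygon")
  merged2 <- merge_cost_surface(lc, water = lake)
  expect_true(all(merged2$values[5, ] == 11))
  expect_error(merge_cost_surface(lc, roads = new_vector_layer(
    list(cbind(c(0, 100), c(0, 100))), tibble::tibble(class = "highway"),
    type = "line")), "unknown road class")
})

test_that("road merge outcome does not depend on feature order within the layer", {
  lc <- new_grid(matrix(9, 5, 5), cell_size = 90, kind = "categorical")
  seg <- cbind(c(10, 440), c(225, 225))
  ab <- new_vector_layer(list(seg, seg), tibble::tibble(class = c("national", "rural")),
                         type = "line")
  ba <- new_vector_layer(list(seg, seg), tibble::tibble(class = c("rural", "national")),
                         type = "line")
  expect_identical(merge_cost_surface(lc, roads = ab)$values,
                   merge_cost_surface(lc, roads = ba)$values)
})

test_that("a diagonal road rasterizes to the exact supercover cell set", {
  g <- new_grid(matrix(1, 5, 5), cell_size = 1, origin_y = 5,
                kind = "categorical")
  road <- new_vector_layer(list(cbind(c(0.5, 4.5), c(4.4, 0.4))),
                           tibble::tibble(class = "rural"), type = "line")
  cells <- rasterize_lines(road, g)
  got <- cells[order(cells$row, cells$col), c("row", "col")]
  # enumerated by hand from the u/v boundary crossings of the segment
  expected <- tibble::tibble(
    row = c(1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L),
    col = c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L))
  expect_equal(as.data.frame(got), as.data.frame(expected))
})

test_that("facility cleaning tallies missingness patterns and percentages", {
  n <- 113
  raw <- tibble::tibble(id = sprintf("F%03d", 1:n),
                        x = runif(n, 0, 450), y = runif(n, 0, 450),
                        capacity = 20000, type = "health_centre")
  raw$x[1:9] <- NA; raw$y[1:9] <- NA; raw$capacity[1:9] <- NA   # both
  raw$x[10:16] <- NA; raw$y[10:16] <- NA                         # coords only
  raw$capacity[17:19] <- NA                                      # capacity only
  cost <- new_grid(matrix(9, 5, 5), cell_size = 90, kind = "categorical")
  cl <- clean_facilities(raw, cost)
  r <- glance(cl)
  expect_equal(r$n_included, 94)
  expect_equal(r$pct_included, 83.2)
  expect_equal(r$pct_missing_both, 8.0)
  expect_equal(r$pct_missing_coords_only, 6.2)
  expect_equal(r$pct_missing_capacity_only, 2.7)
  expect_equal(nrow(tidy(cl)), 94)
  expect_equal(r$n_total - r$n_missing_both - r$n_missing_coords_only -
                 r$n_missing_capacity_only, r$n_included)
})

test_that("facilities on water are relocated to the nearest traversable cell, ties by row then column", {
  v <- matrix(11, 3, 3)
  v[1, 2] <- 9; v[3, 2] <- 9
  cost <- new_grid(v, cell_size = 90, kind = "categorical")
  ctr <- cell_to_xy(cost, 2, 2)
  raw <- tibble::tibble(id = "A", x = ctr$x, y = ctr$y, capacity = 100)
  cl <- clean_facilities(raw, cost)
  fac <- tidy(cl)
  expect_true(fac$relocated)
  expect_equal(c(fac$row, fac$col), c(1L, 2L))   # equidistant; lower row wins
  expect_equal(glance(cl)$n_relocated, 1L)
})

test_that("cleaning rejects duplicate ids and non-positive capacities", {
  cost <- new_grid(matrix(9, 3, 3), cell_size = 90, kind = "categorical")
  raw <- tibble::tibble(id = c("A", "A"), x = c(45, 45), y = c(45, 45),
                        capacity = c(10, 10))
  expect_error(clean_facilities(raw, cost), "duplicate")
  raw2 <- tibble::tibble(id = "B", x = 45, y = 45, capacity = 0)
  expect_error(clean_facilities(raw2, cost), "capacity")
})

test_that("reported percentages round half up at one decimal", {
  expect_equal(round_half_up(83.15, 1), 83.2)
  expect_equal(round_half_up(83.25, 1), 83.3)
  expect_equal(round_half_up(-2.25, 1), -2.3)
  expect_equal(round_half_up(100 * 94 / 113, 1), 83.2)
})
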