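make_fractions <- function(codes, weights, exclude = population_exclusion_classes()) {
  structure(tibble::tibble(code = codes, weight = weights),
            class = c("phc_fractions", class(tibble::tibble())),
            exclude = exclude)
}

test_that("density fractions come from single-class sectors by total population / total area", {
  # sector 1: pure class 9, 1000 persons over 10 km^2 (10x10 cells at 1 km)
  labels <- new_grid(matrix(rep(c(1, 2), each = 50), 10, 10),
                     cell_size = 1000, kind = "categorical")
  lc_vals <- matrix(9, 10, 10)
  lc_vals[, 6:10] <- rep(c(9, 1), length.out = 50)  # sector 2 is mixed
  lc <- new_grid(lc_vals, cell_size = 1000, kind = "categorical")
  sectors <- tibble::tibble(id = c(1, 2), population = c(1000, 700))
  fr <- estimate_density_fractions(sectors, labels, lc)
  est <- fr[fr$code == 9, ]
  expect_equal(est$density_per_km2, 1000 / 50)   # 50 km^2 sector
  expect_equal(est$source, "estimated")
  expect_equal(max(fr$weight, na.rm = TRUE), 1)
  # class 1 never occurs alone -> fallback = mean of estimated weights
  expect_equal(fr$weight[fr$code == 1], mean(fr$weight[fr$source == "estimated"]))
})

test_that("class weights average the densities of multiple pure sectors", {
  labels <- new_grid(matrix(rep(1:2, each = 8), 4, 4), cell_size = 1000,
                     kind = "categorical")
  lc <- new_grid(matrix(9, 4, 4), cell_size = 1000, kind = "categorical")
  # both sectors pure class 9, 8 km^2 each: densities 100 and 300
  sectors <- tibble::tibble(id = 1:2, population = c(800, 2400))
  fr <- estimate_density_fractions(sectors, labels, lc)
  expect_equal(fr$density_per_km2[fr$code == 9], 200)
  expect_equal(fr$n_pure_sectors[fr$code == 9], 2L)
})

test_that("estimation fails when no sector is single-class", {
  labels <- new_grid(matrix(1, 2, 2), cell_size = 1000, kind = "categorical")
  lc <- new_grid(matrix(c(9, 1, 9, 1), 2, 2), cell_size = 1000,
                 kind = "categorical")
  sectors <- tibble::tibble(id = 1, population = 10)
  expect_error(estimate_density_fractions(sectors, labels, lc),
               "no single-class sector")
})

test_that("dasymetric redistribution follows the normalized weights", {
  # 900 persons over 2 cells of weight 2 and 1 cell of weight 1 -> 360/360/180
  labels <- new_grid(matrix(1, 1, 3), cell_size = 90, kind = "categorical")
  lc <- new_grid(matrix(c(1, 1, 2), 1, 3), cell_size = 90, kind = "categorical")
  sectors <- tibble::tibble(id = 1, population = 900)
  fr <- make_fractions(c(1, 2), c(2, 1))
  pop <- dasymetric_redistribute(sectors, labels, lc, fr)
  expect_equal(as.vector(pop$values), c(360, 360, 180))

  # uniform case: equal weights spread evenly
  lc_u <- new_grid(matrix(1, 1, 3), cell_size = 90, kind = "categorical")
  pop_u <- dasymetric_redistribute(tibble::tibble(id = 1, population = 1000),
                                   labels, lc_u, make_fractions(1, 0.37))
  expect_equal(as.vector(pop_u$values), rep(1000 / 3, 3))
})

test_that("excluded classes get exactly zero and sector totals are conserved", {
  set.seed(42)
  labels <- new_grid(matrix(sample(1:3, 100, replace = TRUE), 10, 10),
                     cell_size = 90, kind = "categorical")
  lc_vals <- matrix(sample(c(1, 9, 11, 14), 100, replace = TRUE,
                           prob = c(0.4, 0.4, 0.1, 0.1)), 10, 10)
  lc_vals[1, 1:3] <- 9  # make sure every sector keeps an inhabited cell
  lc_vals[5, 1:3] <- 9; lc_vals[9, 1:3] <- 9
  lc <- new_grid(lc_vals, cell_size = 90, kind = "categorical")
  sectors <- tibble::tibble(id = 1:3, population = c(1200, 0, 987))
  fr <- make_fractions(c(1, 9), c(0.5, 1))
  pop <- dasymetric_redistribute(sectors, labels, lc, fr)
  expect_true(all(pop$values[lc$values %in% population_exclusion_classes()] == 0))
  expect_true(all(pop$values >= 0, na.rm = TRUE))
  for (s in 1:3) {
    expect_equal(sum(pop$values[labels$values == s]),
                 sectors$population[s], tolerance = 1e-9)
  }
  expect_equal(sum(pop$values), sum(sectors$population), tolerance = 1e-9)
})

test_that("a sector of only excluded cells is reported unplaceable", {
  labels <- new_grid(matrix(c(1, 1, 2, 2), 2, 2), cell_size = 90,
                     kind = "categorical")
  lc <- new_grid(matrix(c(11, 11, 9, 9), 2, 2), cell_size = 90,
                 kind = "categorical")
  sectors <- tibble::tibble(id = 1:2, population = c(50, 50))
  expect_error(dasymetric_redistribute(sectors, labels, lc,
                                       make_fractions(9, 1)),
               "unplaceable")
})

test_that("with one inhabited class everywhere the result equals areal weighting", {
  set.seed(5)
  labels <- new_grid(matrix(rep(1:4, each = 16), 8, 8), cell_size = 90,
                     kind = "categorical")
  lc <- new_grid(matrix(9, 8, 8), cell_size = 90, kind = "categorical")
  sectors <- tibble::tibble(id = 1:4, population = c(160, 320, 0, 1600))
  pop <- dasymetric_redistribute(sectors, labels, lc, make_fractions(9, 0.8))
  for (s in 1:4) {
    cells <- which(labels$values == s)
    expect_equal(unique(round(pop$values[cells], 9)),
                 round(sectors$population[s] / length(cells), 9))
  }
})

test_that("sector polygons rasterize by cell-center containment", {
  g <- new_grid(matrix(0, 4, 4), cell_size = 100, kind = "continuous")
  left <- list(cbind(c(0, 200, 200, 0, 0), c(0, 0, 400, 400, 0)))
  right <- list(cbind(c(200, 400, 400, 200, 200), c(0, 0, 400, 400, 0)))
  sec <- new_vector_layer(list(left, right), tibble::tibble(id = c(7, 8)),
                          type = "polygon")
  lab <- rasterize_sectors(sec, g)
  expect_true(all(lab$values[, 1:2] == 7))
  expect_true(all(lab$values[, 3:4] == 8))
})
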