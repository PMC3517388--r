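#' Configuration for the synthetic landscape generator
#'
#' Defaults emulate the structure of the study setting the pipeline was
#' designed for: a mountainous province on a 90 m grid (relief 900-3000 m),
#' 97 third-level administrative sectors totalling 2,091,065 inhabitants, a
#' landcover mosaic dominated by cultivated classes, three road classes laid
#' out as connected trees, rivers crossing the domain, one lake acting as a
#' barrier, and 113 primary health facilities with catchment-population
#' capacities of which 9 miss both coordinates and capacity, 7 miss
#' coordinates only, 3 miss capacity only, and 3 sit on water cells. The
#' domain is 120 x 120 cells, a desk-scale stand-in for the real extent.
#'
#' @param seed Integer seed; one global stream drives every draw.
#' @param nrow,ncol Grid shape (>= 20 x 20).
#' @param cell_size Cell size in meters.
#' @param relief_base,relief_amplitude Elevation floor and range (m).
#' @param relief_correlation Terrain correlation length (cells).
#' @param n_sectors Number of Voronoi sectors.
#' @param total_population Sum of sector populations (persons, exact).
#' @param landcover_mixture Named probabilities over inhabited landcover
#'   codes used for patch growth.
#' @param n_landcover_patches Number of landcover patch seeds.
#' @param pure_sector_quota Named integer vector (class code -> number of
#'   sectors forced to that single landcover class) so density-fraction
#'   estimation is always exercised.
#' @param road_waypoints Named integer vector: waypoints per road class; each
#'   class becomes a spanning tree over its waypoints.
#' @param n_rivers Number of rivers crossing the domain north to south.
#' @param lake_fraction Fraction of the domain area occupied by the lake.
#' @param n_facilities Number of facilities in the raw table.
#' @param capacity_mean,capacity_cv Mean and coefficient of variation of the
#'   lognormal catchment-population capacities.
#' @param n_missing_both,n_missing_coords,n_missing_capacity Injected
#'   missingness counts (facilities lacking both fields, coordinates only,
#'   capacity only).
#' @param n_on_water Facilities deliberately placed on lake cells (to
#'   exercise relocation).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L, nrow = 120L, ncol = 120L, cell_size = 90,
                         relief_base = 900, relief_amplitude = 2100,
                         relief_correlation = 15,
                         n_sectors = 97L, total_population = 2091065,
                         landcover_mixture = c(`9` = 0.35, `1` = 0.15,
                                               `7` = 0.10, `2` = 0.08,
                                               `13` = 0.08, `4` = 0.05,
                                               `5` = 0.05, `8` = 0.04,
                                               `10` = 0.04, `12` = 0.03,
                                               `3` = 0.02, `6` = 0.01),
                         n_landcover_patches = 160L,
                         pure_sector_quota = c(`9` = 2L, `1` = 2L, `2` = 1L),
                         road_waypoints = c(national = 4L, district = 6L,
                                            rural = 14L),
                         n_rivers = 2L, lake_fraction = 0.04,
                         n_facilities = 113L,
                         capacity_mean = 20000, capacity_cv = 0.5,
                         n_missing_both = 9L, n_missing_coords = 7L,
                         n_missing_capacity = 3L, n_on_water = 3L) {
  cfg <- as.list(environment())
  if (nrow < 20L || ncol < 20L) stop("grid must be at least 20 x 20", call. = FALSE)
  if (total_population <= 0) stop("total_population must be positive", call. = FALSE)
  if (lake_fraction < 0 || lake_fraction >= 1) {
    stop("lake_fraction must be in [0, 1)", call. = FALSE)
  }
  if (abs(sum(landcover_mixture) - 1) > 1e-6) {
    stop("landcover_mixture must sum to 1", call. = FALSE)
  }
  if (any(!names(landcover_mixture) %in% as.character(c(1:10, 12:13)))) {
    stop("landcover_mixture codes must be inhabited landcover classes", call. = FALSE)
  }
  n_miss <- n_missing_both + n_missing_coords + n_missing_capacity
  if (n_miss + n_on_water > n_facilities) {
    stop("missingness counts plus water placements exceed n_facilities", call. = FALSE)
  }
  if (sum(pure_sector_quota) > n_sectors) {
    stop("pure-sector quota exceeds the number of sectors", call. = FALSE)
  }
  class(cfg) <- "synth_config"
  cfg
}

smooth_field <- function(nr, nc, corr) {
  pad <- ceiling(3 * corr)
  m <- matrix(stats::rnorm((nr + 2 * pad) * (nc + 2 * pad)),
              nr + 2 * pad, nc + 2 * pad)
  k <- stats::dnorm(seq(-pad, pad), sd = corr)
  k <- k / sum(k)
  m <- apply(m, 2, function(col) stats::filter(col, k, sides = 2))
  m <- t(apply(m, 1, function(row) stats::filter(row, k, sides = 2)))
  m[(pad + 1):(pad + nr), (pad + 1):(pad + nc)]
}

nearest_seed_labels <- function(nr, nc, seed_rows, seed_cols) {
  row <- rep(seq_len(nr), times = nc)
  col <- rep(seq_len(nc), each = nr)
  best_d <- rep(Inf, nr * nc)
  lab <- rep(NA_integer_, nr * nc)
  for (i in seq_along(seed_rows)) {
    d <- (row - seed_rows[i])^2 + (col - seed_cols[i])^2
    upd <- d < best_d
    best_d[upd] <- d[upd]
    lab[upd] <- i
  }
  matrix(lab, nr, nc)
}

# largest-remainder rounding: integer vector summing exactly to `total`
apportion <- function(weights, total) {
  raw <- weights / sum(weights) * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

prim_mst <- function(x, y) {
  m <- length(x)
  if (m < 2L) return(matrix(integer(0), 0, 2))
  in_tree <- c(TRUE, rep(FALSE, m - 1))
  d <- (x - x[1])^2 + (y - y[1])^2
  parent <- rep(1L, m)
  edges <- matrix(0L, m - 1, 2)
  for (k in seq_len(m - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(d[cand])]
    edges[k, ] <- c(parent[j], j)
    in_tree[j] <- TRUE
    dn <- (x - x[j])^2 + (y - y[j])^2
    upd <- !in_tree & dn < d
    d[upd] <- dn[upd]
    parent[upd] <- j
  }
  edges
}

circle_polygon <- function(cx, cy, r, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

#' Generate a complete synthetic input bundle
#'
#' Builds, from one seeded random stream, every input the pipeline consumes:
#' a smoothed random-field DEM, a Voronoi sector tessellation with integer
#' populations summing exactly to the configured total, landcover patches
#' from the configured class mixture (with a quota of forced single-class
#' sectors), spanning-tree road networks per class, rivers crossing the
#' domain, one lake polygon, and a raw facility table with capacities,
#' injected missingness and deliberate water placements. The same seed
#' yields an identical bundle.
#'
#' @param config A [synth_config()].
#' @return An object of class `phc_bundle`: list with `config`, `dem`,
#'   `landcover`, `sector_labels`, `sector_table`, `roads`, `rivers`,
#'   `water`, `facilities` (raw table with missingness) and `truth` (the
#'   injected quantities; see [ground_truth()]).
#' @export
generate_landscape <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  nr <- config$nrow; nc <- config$ncol; cs <- config$cell_size
  origin_x <- 0; origin_y <- nr * cs
  template <- new_grid(matrix(0, nr, nc), origin_x = origin_x,
                       origin_y = origin_y, cell_size = cs)

  # --- terrain ---
  f <- smooth_field(nr, nc, config$relief_correlation)
  f <- (f - min(f)) / (max(f) - min(f))
  dem <- new_grid(matrix(round(config$relief_base + config$relief_amplitude * f, 2),
                         nr, nc),
                  origin_x = origin_x, origin_y = origin_y, cell_size = cs,
                  kind = "continuous")

  # --- lake on the western margin (first: sector seeds must stay on land) ---
  area <- (nr * cs) * (nc * cs)
  r_lake <- sqrt(config$lake_fraction * area / pi)
  lake_cx <- origin_x + stats::runif(1, 0.05, 0.15) * nc * cs
  lake_cy <- origin_y - stats::runif(1, 0.35, 0.65) * nr * cs
  water <- new_vector_layer(list(list(circle_polygon(lake_cx, lake_cy, r_lake))),
                            tibble::tibble(name = "lake"), type = "polygon")
  lake_cells <- rasterize_polygons(water, template)
  lake_idx <- (lake_cells$col - 1L) * nr + lake_cells$row
  land <- setdiff(seq_len(nr * nc), lake_idx)

  # --- sectors: Voronoi over land-seeded cells, exact integer populations ---
  sseed <- sample(land, config$n_sectors)
  s_row <- (sseed - 1L) %% nr + 1L
  s_col <- (sseed - 1L) %/% nr + 1L
  sector_labels_m <- nearest_seed_labels(nr, nc, s_row, s_col)
  pops <- apportion(stats::rgamma(config$n_sectors, shape = 2),
                    config$total_population)
  sector_table <- tibble::tibble(id = seq_len(config$n_sectors),
                                 population = pops)
  sector_labels <- new_grid(sector_labels_m * 1, origin_x = origin_x,
                            origin_y = origin_y, cell_size = cs,
                            kind = "categorical")

  # --- landcover: nearest-patch growth + pure-sector quota ---
  pseed <- sample.int(nr * nc, config$n_landcover_patches)
  p_row <- (pseed - 1L) %% nr + 1L
  p_col <- (pseed - 1L) %/% nr + 1L
  p_class <- as.integer(sample(names(config$landcover_mixture),
                               config$n_landcover_patches, replace = TRUE,
                               prob = config$landcover_mixture))
  patch_lab <- nearest_seed_labels(nr, nc, p_row, p_col)
  lc_m <- matrix(p_class[patch_lab], nr, nc)
  quota <- config$pure_sector_quota
  pure_sectors <- tibble::tibble(sector = integer(0), class = integer(0))
  if (length(quota) && sum(quota) > 0) {
    chosen <- sample.int(config$n_sectors, sum(quota))
    cls <- rep(as.integer(names(quota)), times = quota)
    for (i in seq_along(chosen)) {
      lc_m[sector_labels_m == chosen[i]] <- cls[i]
    }
    pure_sectors <- tibble::tibble(sector = chosen, class = cls)
  }
  landcover <- new_grid(lc_m * 1, origin_x = origin_x, origin_y = origin_y,
                        cell_size = cs, kind = "categorical")

  # --- rivers crossing north to south ---
  rivers <- if (config$n_rivers > 0) {
    geoms <- lapply(seq_len(config$n_rivers), function(i) {
      xs <- stats::runif(1, 0.2, 0.8) * nc * cs
      ys <- seq(origin_y, origin_y - nr * cs, length.out = 7)
      xw <- xs + cumsum(c(0, stats::rnorm(6, 0, 0.06 * nc * cs)))
      xw <- pmin(pmax(xw, origin_x + cs), origin_x + (nc - 1) * cs)
      list(cbind(xw, ys))
    })
    new_vector_layer(geoms, tibble::tibble(name = paste0("river", seq_along(geoms))),
                     type = "line")
  } else NULL

  # --- roads: one spanning tree per class ---
  road_geoms <- list(); road_class <- character(0)
  for (cl in names(config$road_waypoints)) {
    m <- config$road_waypoints[[cl]]
    wp <- sample.int(nr * nc, m)
    # keep road waypoints off the lake
    on_lake <- wp %in% ((lake_cells$col - 1L) * nr + lake_cells$row)
    while (any(on_lake)) {
      wp[on_lake] <- sample.int(nr * nc, sum(on_lake))
      on_lake <- wp %in% ((lake_cells$col - 1L) * nr + lake_cells$row)
    }
    w_row <- (wp - 1L) %% nr + 1L
    w_col <- (wp - 1L) %/% nr + 1L
    xy <- cell_to_xy(template, w_row, w_col)
    edges <- prim_mst(xy$x, xy$y)
    for (e in seq_len(nrow(edges))) {
      road_geoms[[length(road_geoms) + 1L]] <-
        list(cbind(xy$x[edges[e, ]], xy$y[edges[e, ]]))
      road_class <- c(road_class, cl)
    }
  }
  roads <- new_vector_layer(road_geoms, tibble::tibble(class = road_class),
                            type = "line")

  # --- facilities near high-density sectors, with injected defects ---
  dens_by_sector <- sector_table$population /
    tabulate(sector_labels_m, nbins = config$n_sectors)
  cell_w <- dens_by_sector[sector_labels_m]
  n_fac <- config$n_facilities
  n_wet <- min(config$n_on_water, length(lake_idx))
  fcell_land <- sample(land, n_fac - n_wet, prob = cell_w[land])
  fcell_wet <- if (n_wet > 0) sample(lake_idx, n_wet) else integer(0)
  fcell <- c(fcell_land, fcell_wet)
  f_row <- (fcell - 1L) %% nr + 1L
  f_col <- (fcell - 1L) %/% nr + 1L
  fxy <- cell_to_xy(template, f_row, f_col)
  jit <- matrix(stats::runif(2 * n_fac, -0.3, 0.3) * cs, ncol = 2)
  sdlog <- sqrt(log(1 + config$capacity_cv^2))
  meanlog <- log(config$capacity_mean) - sdlog^2 / 2
  capacity <- pmax(round(stats::rlnorm(n_fac, meanlog, sdlog) / 10) * 10, 500)
  ftype <- sample(c("health_centre", "health_post", "dispensary"), n_fac,
                  replace = TRUE, prob = c(0.8, 0.1, 0.1))
  fac_full <- tibble::tibble(
    id = sprintf("F%03d", seq_len(n_fac)),
    x = fxy$x + jit[, 1], y = fxy$y + jit[, 2],
    capacity = capacity, type = ftype
  )
  dry <- seq_len(n_fac - n_wet)           # water-placed keep their fields
  defect <- sample(dry, config$n_missing_both + config$n_missing_coords +
                     config$n_missing_capacity)
  ids_both <- defect[seq_len(config$n_missing_both)]
  ids_xy <- defect[config$n_missing_both + seq_len(config$n_missing_coords)]
  ids_cap <- defect[config$n_missing_both + config$n_missing_coords +
                      seq_len(config$n_missing_capacity)]
  facilities <- fac_full
  facilities$x[c(ids_both, ids_xy)] <- NA_real_
  facilities$y[c(ids_both, ids_xy)] <- NA_real_
  facilities$capacity[c(ids_both, ids_cap)] <- NA_real_

  cell_km2 <- (cs / 1000)^2
  truth <- list(
    sector_table = sector_table,
    pure_sectors = dplyr::mutate(
      pure_sectors,
      population = sector_table$population[.data$sector],
      area_km2 = tabulate(sector_labels_m, nbins = config$n_sectors)[.data$sector] * cell_km2,
      density_per_km2 = .data$population / .data$area_km2
    ),
    facilities_full = fac_full,
    missing_both_ids = fac_full$id[ids_both],
    missing_coords_ids = fac_full$id[ids_xy],
    missing_capacity_ids = fac_full$id[ids_cap],
    on_water_ids = if (n_wet > 0) fac_full$id[n_fac - n_wet + seq_len(n_wet)] else character(0),
    lake_cells = lake_cells[, c("row", "col")],
    bundle_id = sprintf("phc-bundle-seed-%d", config$seed)
  )
  structure(list(config = config, dem = dem, landcover = landcover,
                 sector_labels = sector_labels, sector_table = sector_table,
                 roads = roads, rivers = rivers, water = water,
                 facilities = facilities, truth = truth),
            class = "phc_bundle")
}

#' @export
print.phc_bundle <- function(x, ...) {
  cat(sprintf("<phc_bundle seed %d> %d x %d cells, %d sectors (%s persons), %d facilities\n",
              x$config$seed, x$config$nrow, x$config$ncol,
              nrow(x$sector_table),
              format(sum(x$sector_table$population), big.mark = ","),
              nrow(x$facilities)))
  invisible(x)
}

#' Injected ground truth of a synthetic bundle
#'
#' Returns the quantities the generator injected — realized per-class
#' densities of the forced single-class sectors, the identities of
#' facilities with injected missing fields or water placement, and the
#' complete facility table — for parameter-recovery tests.
#'
#' @param bundle A `phc_bundle` from [generate_landscape()].
#' @return The truth record (list).
#' @export
ground_truth <- function(bundle) {
  if (!inherits(bundle, "phc_bundle") || is.null(bundle$truth$bundle_id)) {
    stop("not a generated bundle", call. = FALSE)
  }
  bundle$truth
}

#' Write / read a bundle as plain-text files
#'
#' Grids go to ESRI ASCII, vector layers to GeoJSON, tables to CSV and the
#' truth record to JSON, the same formats the pipeline consumes.
#'
#' @param bundle A `phc_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir` (invisibly) for `write_bundle()`; a `phc_bundle` for
#'   `read_bundle()`.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_grid(bundle$dem, file.path(dir, "dem.asc"))
  write_grid(bundle$landcover, file.path(dir, "landcover.asc"))
  write_grid(bundle$sector_labels, file.path(dir, "sectors.asc"))
  utils::write.csv(bundle$sector_table, file.path(dir, "sectors.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$facilities, file.path(dir, "facilities.csv"),
                   row.names = FALSE)
  write_vector(bundle$roads, file.path(dir, "roads.geojson"))
  if (!is.null(bundle$rivers)) {
    write_vector(bundle$rivers, file.path(dir, "rivers.geojson"))
  }
  write_vector(bundle$water, file.path(dir, "water.geojson"))
  tr <- bundle$truth
  tr$lake_cells <- as.data.frame(tr$lake_cells)
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  cfg <- unclass(bundle$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cfg$landcover_mixture <- unlist(cfg$landcover_mixture)
  cfg$pure_sector_quota <- unlist(cfg$pure_sector_quota)
  cfg$road_waypoints <- unlist(cfg$road_waypoints)
  config <- do.call(synth_config, cfg)
  tr <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  tr$sector_table <- tibble::as_tibble(tr$sector_table)
  tr$pure_sectors <- tibble::as_tibble(tr$pure_sectors)
  tr$facilities_full <- tibble::as_tibble(tr$facilities_full)
  tr$lake_cells <- tibble::as_tibble(tr$lake_cells)
  rivers_path <- file.path(dir, "rivers.geojson")
  structure(list(
    config = config,
    dem = read_grid(file.path(dir, "dem.asc"), "continuous"),
    landcover = read_grid(file.path(dir, "landcover.asc"), "categorical"),
    sector_labels = read_grid(file.path(dir, "sectors.asc"), "categorical"),
    sector_table = tibble::as_tibble(utils::read.csv(file.path(dir, "sectors.csv"))),
    roads = read_vector(file.path(dir, "roads.geojson")),
    rivers = if (file.exists(rivers_path)) read_vector(rivers_path) else NULL,
    water = read_vector(file.path(dir, "water.geojson")),
    facilities = tibble::as_tibble(utils::read.csv(file.path(dir, "facilities.csv"))),
    truth = tr
  ), class = "phc_bundle")
}
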