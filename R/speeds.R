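#' Landcover, road and river class codes of the cost surface
#'
#' The merged cost surface uses 13 generic landcover classes (codes 1-13,
#' water bodies = 11), three road classes reflecting the national road
#' classification (14 national, 15 district, 16 rural/feeder) and a river
#' class (17). Water and rivers are barriers for travel; roads double as
#' bridges where they cross rivers.
#'
#' @return A tibble with columns `code`, `name`, `category` (one of
#'   `landcover`, `road`, `river`, `water`).
#' @export
landcover_classes <- function() {
  tibble::tribble(
    ~code, ~name, ~category,
    1L, "Mosaic: Cropland/Shrub and/or Grass Cover", "landcover",
    2L, "Open/Closed Evergreen/Deciduous Shrub Cover", "landcover",
    3L, "Regularly Flooded Shrub and/or Herbaceous", "landcover",
    4L, "Sparse Herbaceous or Shrub Cover", "landcover",
    5L, "Tree Cover: Broadleaved, Deciduous, Open", "landcover",
    6L, "Artificial and Associated Areas", "landcover",
    7L, "Mosaic: Cropland/Tree Cover/Other Natural Vegetation", "landcover",
    8L, "Tree Cover: Needle-leaved, Evergreen", "landcover",
    9L, "Cultivated and Managed Areas", "landcover",
    10L, "Mosaic: Tree Cover/Other Natural Vegetation", "landcover",
    11L, "Water bodies", "water",
    12L, "Tree Cover: Broadleaved, Evergreen", "landcover",
    13L, "Herbaceous Cover, Closed-Open", "landcover",
    14L, "National Roads", "road",
    15L, "District Roads", "road",
    16L, "Rural/Feeder Roads", "road",
    17L, "Rivers", "river"
  )
}

WATER_CODE <- 11L
ROAD_CODES <- c(national = 14L, district = 15L, rural = 16L)
RIVER_CODE <- 17L

#' Scenario speed model (flat-surface speeds per class)
#'
#' Flat-surface travel speeds in km/h per cost-surface class for the three
#' travel scenarios: scenario 1 walking only; scenario 2 walking off-road and
#' cycling (10 km/h) on all roads; scenario 3 walking off-road and on
#' rural/feeder roads, public (motorized) transport on national (50 km/h) and
#' district (20 km/h) roads. Water bodies and rivers are barriers (speed 0)
#' in every scenario. Off-road walking speeds are identical across scenarios.
#'
#' @return A tibble with columns `scenario`, `code`, `speed_kmh` (`NA` for
#'   barriers), `mode` (`walk`, `bicycle`, `motorized`, or `NA` for
#'   barriers).
#' @export
speed_table <- function() {
  walk <- c(`1` = 1.67, `2` = 1.67, `3` = 1, `4` = 2.5, `5` = 1.25, `6` = 5,
            `7` = 1.67, `8` = 1.67, `9` = 1.67, `10` = 1.25, `12` = 1,
            `13` = 1.67)
  lc <- tibble::tibble(code = as.integer(names(walk)),
                       speed_kmh = unname(walk), mode = "walk")
  barrier <- tibble::tibble(code = c(WATER_CODE, RIVER_CODE),
                            speed_kmh = NA_real_, mode = NA_character_)
  roads <- list(
    `1` = tibble::tibble(code = unname(ROAD_CODES), speed_kmh = 5,
                         mode = "walk"),
    `2` = tibble::tibble(code = unname(ROAD_CODES), speed_kmh = 10,
                         mode = "bicycle"),
    `3` = tibble::tibble(code = unname(ROAD_CODES),
                         speed_kmh = c(50, 20, 5),
                         mode = c("motorized", "motorized", "walk"))
  )
  dplyr::bind_rows(lapply(1:3, function(s) {
    dplyr::bind_rows(lc, barrier, roads[[as.character(s)]]) |>
      dplyr::mutate(scenario = s, .before = 1)
  })) |>
    dplyr::arrange(.data$scenario, .data$code)
}

#' Look up the flat-surface speed and mode for a class under a scenario
#'
#' @param cell_class Integer class code(s) from [landcover_classes()].
#' @param scenario Scenario id, 1, 2 or 3.
#' @param speeds Speed table (defaults to [speed_table()]).
#' @return A tibble with columns `code`, `speed_kmh`, `mode`, `barrier`.
#'   Barriers (water, rivers) have `speed_kmh = NA` and `barrier = TRUE`.
#' @examples
#' speed_for(14, 3)  # national road under public transport: 50 km/h
#' @export
speed_for <- function(cell_class, scenario, speeds = speed_table()) {
  stopifnot(length(scenario) == 1L, scenario %in% 1:3)
  tab <- speeds[speeds$scenario == scenario, ]
  idx <- match(cell_class, tab$code)
  if (anyNA(idx)) {
    stop("unknown class code(s): ",
         paste(unique(cell_class[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(code = as.integer(cell_class),
                 speed_kmh = tab$speed_kmh[idx],
                 mode = tab$mode[idx],
                 barrier = is.na(tab$speed_kmh[idx]))
}

barrier_codes <- function(speeds = speed_table()) {
  unique(speeds$code[is.na(speeds$speed_kmh)])
}
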