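#' Rasterize sector polygons to a sector-label grid
#'
#' Each cell is assigned to the sector polygon containing its center, so the
#' label grid is a partition and downstream mass-conservation checks are
#' exact. Cells inside no sector are `NA` (outside the study area).
#'
#' @param sectors Polygon `phc_vector` with an `id` attribute column.
#' @param grid Alignment template `phc_grid`.
#' @return A categorical `phc_grid` of sector ids.
#' @export
rasterize_sectors <- function(sectors, grid) {
  stopifnot("id" %in% names(sectors))
  cells <- rasterize_polygons(sectors, grid)
  lab <- matrix(NA_real_, nrow(grid$values), ncol(grid$values))
  lab[cbind(cells$row, cells$col)] <- sectors$id[cells$feature]
  new_grid(lab, origin_x = grid$origin_x, origin_y = grid$origin_y,
           cell_size = grid$cell_size, nodata = grid$nodata,
           kind = "categorical")
}

#' Default exclusion classes for population mapping
#'
#' Water bodies, rivers and the three road classes carry zero population in
#' the dasymetric redistribution (people live neither on water nor on the
#' roadway), although roads remain traversable in the cost surface.
#'
#' @return Integer vector of excluded class codes.
#' @export
population_exclusion_classes <- function() {
  c(WATER_CODE, RIVER_CODE, unname(ROAD_CODES))
}

#' Estimate per-landcover density weights by empirical sampling
#'
#' Sectors whose non-excluded cells are occupied by a single inhabited
#' landcover class are isolated; for each, the population density is the
#' sector total divided by the total sector area. The weight of a class is
#' the mean density over its single-class sectors, rescaled so the largest
#' weight is 1. Classes never observed alone receive a fallback weight (the
#' mean of the estimated weights by default).
#'
#' @param sector_table Tibble with columns `id`, `population`.
#' @param sector_labels Categorical `phc_grid` of sector ids (aligned to
#'   `landcover`).
#' @param landcover Merged categorical `phc_grid`.
#' @param exclude Class codes carrying zero population
#'   ([population_exclusion_classes()] by default).
#' @param fallback `"mean"` (mean of estimated weights) or a single numeric
#'   weight applied to unobserved classes.
#' @return An object of class `phc_fractions`: tibble with columns `code`,
#'   `name`, `density_per_km2` (`NA` where fallback), `weight`,
#'   `n_pure_sectors`, `source`; the exclusion set is kept in
#'   `attr(, "exclude")`.
#' @export
estimate_density_fractions <- function(sector_table, sector_labels, landcover,
                                       exclude = population_exclusion_classes(),
                                       fallback = "mean") {
  stop_unaligned(sector_labels, landcover, "sector labels and landcover")
  lab <- as.vector(sector_labels$values)
  lc <- as.vector(landcover$values)
  keep <- !is.na(lab) & !is.na(lc)
  cell_km2 <- (landcover$cell_size / 1000)^2
  df <- tibble::tibble(sector = lab[keep], class = lc[keep])
  per_sector <- df |>
    dplyr::group_by(.data$sector) |>
    dplyr::summarise(
      area_km2 = dplyr::n() * cell_km2,
      inhabited = list(unique(.data$class[!(.data$class %in% exclude)])),
      .groups = "drop"
    ) |>
    dplyr::mutate(pure_class = purrr::map_dbl(
      .data$inhabited, ~ if (length(.x) == 1L) .x else NA_real_))
  pure <- per_sector |>
    dplyr::filter(!is.na(.data$pure_class)) |>
    dplyr::left_join(sector_table, by = c(sector = "id")) |>
    dplyr::mutate(density = .data$population / .data$area_km2)
  classes <- landcover_classes() |>
    dplyr::filter(!(.data$code %in% exclude), .data$category == "landcover")
  est <- pure |>
    dplyr::group_by(code = as.integer(.data$pure_class)) |>
    dplyr::summarise(density_per_km2 = mean(.data$density),
                     n_pure_sectors = dplyr::n(), .groups = "drop")
  out <- classes |>
    dplyr::left_join(est, by = "code") |>
    dplyr::mutate(n_pure_sectors = dplyr::coalesce(.data$n_pure_sectors, 0L),
                  source = ifelse(is.na(.data$density_per_km2),
                                  "fallback", "estimated"))
  if (all(out$source == "fallback")) {
    stop("no single-class sector found for any inhabited class; cannot estimate density fractions",
         call. = FALSE)
  }
  mx <- max(out$density_per_km2, na.rm = TRUE)
  out$weight <- out$density_per_km2 / mx
  fb <- if (identical(fallback, "mean")) {
    mean(out$weight, na.rm = TRUE)
  } else if (is.numeric(fallback) && length(fallback) == 1L) {
    fallback
  } else stop("`fallback` must be \"mean\" or a single numeric weight", call. = FALSE)
  out$weight[is.na(out$weight)] <- fb
  out <- out[, c("code", "name", "density_per_km2", "weight",
                 "n_pure_sectors", "source")]
  structure(out, class = c("phc_fractions", class(out)), exclude = exclude)
}

fraction_weight_lookup <- function(fractions) {
  exclude <- attr(fractions, "exclude")
  w <- stats::setNames(fractions$weight, fractions$code)
  list(weight = w, exclude = exclude)
}

#' Dasymetric redistribution of sector populations onto the grid
#'
#' Distributes each sector's population over its cells proportionally to the
#' landcover density weight of each cell (equal cell areas, so the area share
#' is implicit in the cell count). Excluded classes receive exactly zero.
#' Per-sector cell sums reproduce the sector totals (pycnophylactic
#' property) to machine precision.
#'
#' @inheritParams estimate_density_fractions
#' @param fractions A `phc_fractions` object from
#'   [estimate_density_fractions()], or any tibble with `code` and `weight`
#'   plus an `exclude` attribute.
#' @return A continuous `phc_grid` of persons per cell (`NA` outside all
#'   sectors).
#' @export
dasymetric_redistribute <- function(sector_table, sector_labels, landcover,
                                    fractions) {
  stop_unaligned(sector_labels, landcover, "sector labels and landcover")
  lk <- fraction_weight_lookup(fractions)
  lab <- sector_labels$values
  lc <- landcover$values
  w <- matrix(0, nrow(lc), ncol(lc))
  known <- !is.na(lc)
  codes <- unique(lc[known])
  unknown <- setdiff(codes, c(as.numeric(names(lk$weight)), lk$exclude))
  if (length(unknown)) {
    stop("no density weight for class code(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (cd in setdiff(codes, lk$exclude)) {
    w[known & lc == cd] <- lk$weight[[as.character(cd)]]
  }
  pop <- matrix(NA_real_, nrow(lc), ncol(lc))
  for (i in seq_len(nrow(sector_table))) {
    sid <- sector_table$id[i]
    p <- sector_table$population[i]
    idx <- which(!is.na(lab) & lab == sid)
    if (!length(idx)) next
    ws <- w[idx]
    tot <- sum(ws)
    if (tot == 0 && p > 0) {
      stop(sprintf("sector %s consists entirely of excluded cells; its population is unplaceable", sid),
           call. = FALSE)
    }
    pop[idx] <- if (tot > 0) p * ws / tot else 0
  }
  new_grid(pop, origin_x = landcover$origin_x, origin_y = landcover$origin_y,
           cell_size = landcover$cell_size, nodata = landcover$nodata,
           kind = "continuous")
}
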