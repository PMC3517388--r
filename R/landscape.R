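#' Round half up, as used in reported percentages
#'
#' Base R's `round()` rounds half to even; reported percentages here use the
#' conventional half-up rule (e.g. 83.15 -> 83.2 at one decimal).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

pct1 <- function(count, total) round_half_up(100 * count / total, 1)

#' Merge landcover, water bodies, rivers and roads into one cost surface
#'
#' Burns the vector layers into the categorical landcover grid with fixed
#' precedence landcover < water < rivers < roads. Roads are burned last so a
#' road cell crossing a river stays a road: the crossing acts as a bridge.
#' Water bodies and rivers become barrier cells (untraversable in every
#' scenario).
#'
#' @param landcover Categorical `phc_grid` of landcover codes (1-13).
#' @param rivers Optional line `phc_vector` of rivers.
#' @param roads Optional line `phc_vector` of roads with a `class` attribute
#'   column in `c("national", "district", "rural")`.
#' @param water Optional polygon `phc_vector` of water bodies (lakes).
#' @return A categorical `phc_grid` aligned to `landcover` whose codes come
#'   from [landcover_classes()].
#' @export
merge_cost_surface <- function(landcover, rivers = NULL, roads = NULL, water = NULL) {
  stopifnot(is_grid(landcover), landcover$kind == "categorical")
  out <- landcover$values
  if (!is.null(water) && nrow(water)) {
    cells <- rasterize_polygons(water, landcover)
    out[cbind(cells$row, cells$col)] <- WATER_CODE
  }
  if (!is.null(rivers) && nrow(rivers)) {
    cells <- rasterize_lines(rivers, landcover)
    out[cbind(cells$row, cells$col)] <- RIVER_CODE
  }
  if (!is.null(roads) && nrow(roads)) {
    if (!"class" %in% names(roads)) {
      stop("roads layer needs a `class` attribute", call. = FALSE)
    }
    bad <- setdiff(unique(roads$class), names(ROAD_CODES))
    if (length(bad)) {
      stop("unknown road class: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    cells <- rasterize_lines(roads, landcover)
    # class priority (national > district > rural), not feature order,
    # decides cells shared by several road features
    prio <- c(rural = 1L, district = 2L, national = 3L)
    ord <- order(prio[roads$class[cells$feature]])
    cells <- cells[ord, , drop = FALSE]
    codes <- ROAD_CODES[roads$class[cells$feature]]
    out[cbind(cells$row, cells$col)] <- codes
  }
  new_grid(out, origin_x = landcover$origin_x, origin_y = landcover$origin_y,
           cell_size = landcover$cell_size, nodata = landcover$nodata,
           kind = "categorical")
}

#' Clean the raw facility table against the cost surface
#'
#' Applies the inclusion rules of the analysis: facilities missing
#' coordinates and/or catchment-population capacity are excluded, tallied by
#' missingness pattern; included facilities that land on barrier cells
#' (water, rivers) or outside the grid are relocated to the nearest
#' traversable cell (Euclidean distance between the facility point and cell
#' centers, ties broken by ascending row then column). Percentages are
#' reported to one decimal, rounded half up.
#'
#' @param raw Tibble/data frame with columns `id`, `x`, `y`, `capacity` and
#'   optionally `type`; `NA` marks missing values.
#' @param cost_surface Merged categorical `phc_grid` (see
#'   [merge_cost_surface()]).
#' @param speeds Speed table; only its barrier classes are used.
#' @return An object of class `phc_clean`: a list with `facilities` (tibble
#'   of included facilities with grid cell, relocation flag) and `report`
#'   (one-row tibble of counts and percentages). `tidy()` returns the
#'   facility tibble, `glance()` the report.
#' @export
clean_facilities <- function(raw, cost_surface, speeds = speed_table()) {
  raw <- tibble::as_tibble(raw)
  stopifnot(all(c("id", "x", "y", "capacity") %in% names(raw)))
  if (anyDuplicated(raw$id)) stop("duplicate facility ids", call. = FALSE)
  if (any(!is.na(raw$capacity) & raw$capacity <= 0)) {
    stop("facility capacity must be > 0", call. = FALSE)
  }
  miss_xy <- is.na(raw$x) | is.na(raw$y)
  miss_cap <- is.na(raw$capacity)
  n_total <- nrow(raw)
  n_both <- sum(miss_xy & miss_cap)
  n_xy <- sum(miss_xy & !miss_cap)
  n_cap <- sum(!miss_xy & miss_cap)
  fac <- raw[!miss_xy & !miss_cap, , drop = FALSE]
  if (!"type" %in% names(fac)) fac$type <- NA_character_

  barrier <- barrier_codes(speeds)
  v <- cost_surface$values
  traversable <- !is.na(v) & !(v %in% barrier)
  cell <- xy_to_cell(cost_surface, fac$x, fac$y)
  on_barrier <- is.na(cell$row) | !traversable[cbind(cell$row, cell$col)]
  on_barrier[is.na(on_barrier)] <- TRUE
  n_reloc <- sum(on_barrier)
  if (n_reloc > 0) {
    tr <- which(traversable, arr.ind = TRUE)
    if (nrow(tr) == 0L) stop("cost surface has no traversable cell", call. = FALSE)
    ctr <- cell_to_xy(cost_surface, tr[, 1], tr[, 2])
    for (i in which(on_barrier)) {
      d2 <- (ctr$x - fac$x[i])^2 + (ctr$y - fac$y[i])^2
      j <- order(d2, tr[, 1], tr[, 2])[1]
      cell$row[i] <- tr[j, 1]; cell$col[i] <- tr[j, 2]
      fac$x[i] <- ctr$x[j]; fac$y[i] <- ctr$y[j]
    }
  }
  facilities <- tibble::tibble(
    id = fac$id, x = fac$x, y = fac$y,
    row = cell$row, col = cell$col,
    capacity = fac$capacity, type = fac$type,
    relocated = on_barrier
  )
  report <- tibble::tibble(
    n_total = n_total,
    n_missing_both = n_both,
    n_missing_coords_only = n_xy,
    n_missing_capacity_only = n_cap,
    n_included = n_total - n_both - n_xy - n_cap,
    n_relocated = n_reloc,
    pct_missing_both = pct1(n_both, n_total),
    pct_missing_coords_only = pct1(n_xy, n_total),
    pct_missing_capacity_only = pct1(n_cap, n_total),
    pct_included = pct1(n_total - n_both - n_xy - n_cap, n_total)
  )
  structure(list(facilities = facilities, report = report), class = "phc_clean")
}

#' @export
print.phc_clean <- function(x, ...) {
  r <- x$report
  cat(sprintf("<phc_clean> %d of %d facilities included (%.1f%%), %d relocated off barriers\n",
              r$n_included, r$n_total, r$pct_included, r$n_relocated))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.phc_clean <- function(x, ...) x$facilities

#' @export
glance.phc_clean <- function(x, ...) x$report
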