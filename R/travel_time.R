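#' Slope-corrected walking speed (normalized Tobler function)
#'
#' The canonical hiking function `6 * exp(-3.5 * |s + 0.05|)` km/h peaks on a
#' slight downhill and evaluates to `6 * exp(-0.175)` (about 5.04 km/h) on
#' flat ground. Class speeds in the scenario table are flat-surface speeds,
#' so the function is rescaled: at slope 0 the effective speed equals the
#' class base speed exactly.
#'
#' @param base_kmh Flat-surface walking speed of the landcover class (km/h).
#' @param slope Rise over run in the direction of motion (unitless; uphill
#'   positive).
#' @return Effective walking speed in km/h.
#' @examples
#' tobler_speed(5, 0)      # 5
#' tobler_speed(5, 0.10)   # 5 * exp(-0.35)
#' @export
tobler_speed <- function(base_kmh, slope) {
  base_kmh * exp(-3.5 * abs(slope + 0.05)) / exp(-3.5 * 0.05)
}

#' Cycling slope-speed model parameters
#'
#' Cycling speed is modelled with a constant-power balance: the rider's
#' power, calibrated so the flat speed equals the scenario base speed
#' (10 km/h), is spent against gravity along the slope, rolling resistance
#' and aerodynamic drag. Uphill/downhill speeds solve
#' `0.5*rho*CdA*v^3 + m*g*(Crr + s)*v = P0` for `v`. Downhill speed is capped
#' at `downhill_cap_factor` times the flat speed (a loaded utility bicycle on
#' rough rural roads is not ridden at terminal velocity), and the effective
#' scenario speed never drops below the walking (push) speed on the same
#' slope.
#'
#' @param mass_kg Rider plus bicycle and load mass.
#' @param g Gravitational acceleration (m/s^2).
#' @param crr Rolling resistance coefficient.
#' @param rho_air Air density (kg/m^3).
#' @param cda Effective frontal area times drag coefficient (m^2).
#' @param downhill_cap_factor Maximum speed as a multiple of the flat speed.
#' @return A named list of parameters.
#' @export
cycling_params <- function(mass_kg = 90, g = 9.81, crr = 0.008,
                           rho_air = 1.2, cda = 0.5,
                           downhill_cap_factor = 1.5) {
  list(mass_kg = mass_kg, g = g, crr = crr, rho_air = rho_air, cda = cda,
       downhill_cap_factor = downhill_cap_factor)
}

#' Slope-corrected cycling speed (constant-power balance)
#'
#' @inheritParams tobler_speed
#' @param base_kmh Flat-surface cycling speed (km/h).
#' @param params See [cycling_params()].
#' @return Cycling speed in km/h (capped downhill; not floored — the walking
#'   floor is applied at the scenario level).
#' @export
cycling_speed <- function(base_kmh, slope, params = cycling_params()) {
  n <- max(length(base_kmh), length(slope))
  base <- rep_len(base_kmh, n); s <- rep_len(slope, n)
  v0 <- base / 3.6
  a <- 0.5 * params$rho_air * params$cda
  b0 <- params$mass_kg * params$g * params$crr
  p0 <- a * v0^3 + b0 * v0                      # calibrated rider power (W)
  b <- params$mass_kg * params$g * (params$crr + s)
  # unique positive root of a*v^3 + b*v - p0 on the increasing branch
  v <- pmax(v0, sqrt(pmax(-b / (3 * a), 0)) * 1.1 + 0.1)
  for (k in 1:80) {
    f <- a * v^3 + b * v - p0
    v <- v - f / (3 * a * v^2 + b)
    v <- pmax(v, 1e-6)
  }
  out <- pmin(v * 3.6, params$downhill_cap_factor * base)
  out[is.na(base) | is.na(s)] <- NA_real_
  out
}

# internal vectorized effective speed; barrier -> NA
eff_speed_vec <- function(base, mode_code, slope, params, push_base_kmh) {
  v <- rep(NA_real_, length(base))
  w <- which(mode_code == 1L)
  if (length(w)) v[w] <- tobler_speed(base[w], slope[w])
  b <- which(mode_code == 2L)
  if (length(b)) {
    v[b] <- pmax(cycling_speed(base[b], slope[b], params),
                 tobler_speed(push_base_kmh, slope[b]))
  }
  m <- which(mode_code == 3L)
  if (length(m)) v[m] <- base[m]
  v
}

#' Effective travel speed for a class, scenario and slope
#'
#' Applies the mode-specific slope correction to the flat-surface class
#' speed: walking uses the normalized Tobler function, cycling the
#' constant-power model floored at the walking (push) speed, motorized
#' travel is slope-independent. Slope is rise over run in the patient's
#' direction of motion (toward the facility).
#'
#' @inheritParams speed_for
#' @param slope Rise/run along the direction of motion (recycled).
#' @param params Cycling model parameters ([cycling_params()]).
#' @param push_base_kmh Flat walking speed used when pushing the bicycle.
#' @return Numeric vector of speeds in km/h.
#' @export
effective_speed <- function(cell_class, scenario, slope = 0,
                            speeds = speed_table(), params = cycling_params(),
                            push_base_kmh = 5) {
  look <- speed_for(cell_class, scenario, speeds)
  if (any(look$barrier)) {
    stop("barrier class has no travel speed: ",
         paste(unique(look$code[look$barrier]), collapse = ", "), call. = FALSE)
  }
  n <- max(nrow(look), length(slope))
  mode_code <- c(walk = 1L, bicycle = 2L, motorized = 3L)[look$mode]
  eff_speed_vec(rep_len(look$speed_kmh, n), rep_len(mode_code, n),
                rep_len(slope, n), params, push_base_kmh)
}

grid_offsets <- function() {
  cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
        dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
}

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  r_lo <- max(1L, 1L + dr); r_hi <- min(nr, nr + dr)
  c_lo <- max(1L, 1L + dc); c_hi <- min(nc, nc + dc)
  if (r_lo > r_hi || c_lo > c_hi) return(out)
  rs <- r_lo:r_hi
  cs <- c_lo:c_hi
  out[rs - dr, cs - dc] <- m[rs, cs]
  out
}

#' Anisotropic edge travel times on the 8-connected grid graph
#'
#' For expansion from cell A to neighbour B (distance `d` = cell size, or
#' `sqrt(2)` times it on diagonals) the patient moves B to A, so the slope is
#' `(elev(A) - elev(B)) / d`. The edge time is the half-cell harmonic form
#' `d/2 * (1/v_B + 1/v_A)` with each endpoint's speed taken from its own
#' class at that slope. Barrier endpoints yield no edge.
#'
#' @param cost Merged categorical cost-surface `phc_grid`.
#' @param dem Continuous elevation `phc_grid` (m), aligned to `cost`.
#' @inheritParams effective_speed
#' @param transit_mask Optional logical matrix (same shape): where `FALSE`,
#'   motorized classes fall back to walking at `push_base_kmh` (used to
#'   restrict public transport to one district).
#' @return List with `times` (8 matrices of minutes, expansion direction
#'   A->neighbour; `NA` = no edge) and `offsets`.
#' @keywords internal
#' @export
edge_times <- function(cost, dem, scenario, speeds = speed_table(),
                       params = cycling_params(), transit_mask = NULL,
                       push_base_kmh = 5) {
  stop_unaligned(cost, dem, "cost surface and DEM")
  tab <- speeds[speeds$scenario == scenario, ]
  mx <- max(tab$code)
  base_lut <- rep(NA_real_, mx); mode_lut <- rep(NA_integer_, mx)
  base_lut[tab$code] <- tab$speed_kmh
  mode_lut[tab$code] <- c(walk = 1L, bicycle = 2L, motorized = 3L)[tab$mode]
  lc <- cost$values
  bad <- !is.na(lc) & !(lc %in% tab$code)
  if (any(bad)) {
    stop("cost surface contains unknown class code(s): ",
         paste(unique(lc[bad]), collapse = ", "), call. = FALSE)
  }
  idx <- ifelse(is.na(lc), NA_integer_, lc)
  base <- matrix(base_lut[idx], nrow(lc), ncol(lc))
  mode <- matrix(mode_lut[idx], nrow(lc), ncol(lc))
  if (!is.null(transit_mask)) {
    stopifnot(all(dim(transit_mask) == dim(lc)))
    off <- mode == 3L & !transit_mask
    off[is.na(off)] <- FALSE
    base[off] <- push_base_kmh
    mode[off] <- 1L
  }
  cs_km <- cost$cell_size / 1000
  elev <- dem$values
  times <- vector("list", 8L)
  offs <- grid_offsets()
  for (k in 1:8) {
    dr <- offs[k, 1]; dc <- offs[k, 2]
    d_m <- cost$cell_size * sqrt(sum(c(dr, dc)^2))
    d_km <- cs_km * sqrt(sum(c(dr, dc)^2))
    elev_b <- shift_mat(elev, dr, dc)
    s <- (elev - elev_b) / d_m                 # patient moves B -> A
    v_a <- eff_speed_vec(as.vector(base), as.vector(mode), as.vector(s),
                         params, push_base_kmh)
    v_b <- eff_speed_vec(as.vector(shift_mat(base, dr, dc)),
                         as.vector(shift_mat(mode, dr, dc)),
                         as.vector(s), params, push_base_kmh)
    t <- (d_km / 2) * (1 / v_a + 1 / v_b) * 60
    times[[k]] <- matrix(t, nrow(lc), ncol(lc))
  }
  list(times = times, offsets = offs)
}

run_dijkstra <- function(et, origin_rows, origin_cols, nr, nc) {
  emat <- do.call(cbind, lapply(et$times, as.vector))
  origins0 <- as.integer((origin_cols - 1L) * nr + (origin_rows - 1L))
  d <- grid_dijkstra_cpp(emat, origins0, nr, nc,
                         as.integer(et$offsets[, 1]),
                         as.integer(et$offsets[, 2]))
  matrix(d, nr, nc)
}

#' Travel-time surface toward a set of origin facilities
#'
#' Multi-source least-cost search (Dijkstra) over the 8-connected grid graph
#' with anisotropic edge times ([edge_times()]): every cell gets the minimum
#' travel time in minutes toward the nearest origin. Times above the cap
#' (default 60 minutes) and unreachable cells become `NA`; the two cases are
#' distinguished in the `reach` attribute (1 = within cap, 2 = beyond cap,
#' 3 = unreachable, `NA` = barrier/nodata cell).
#'
#' @param origins Tibble with `row`, `col` columns (e.g. cleaned facilities),
#'   all on traversable cells.
#' @inheritParams edge_times
#' @param cap_minutes Maximum permitted travel time (minutes).
#' @param precomputed Optional result of [edge_times()] to reuse across
#'   facilities.
#' @return A continuous `phc_grid` of minutes with attributes `scenario`,
#'   `cap_minutes` and `reach`.
#' @export
travel_time_from <- function(origins, cost, dem, scenario, cap_minutes = 60,
                             speeds = speed_table(), params = cycling_params(),
                             transit_mask = NULL, push_base_kmh = 5,
                             precomputed = NULL) {
  et <- precomputed %||% edge_times(cost, dem, scenario, speeds, params,
                                    transit_mask, push_base_kmh)
  if (nrow(origins) == 0L) stop("no origin facilities", call. = FALSE)
  v <- cost$values
  barrier <- is.na(v) | v %in% barrier_codes(speeds)
  if (any(barrier[cbind(origins$row, origins$col)])) {
    stop("origin facility on a barrier/nodata cell; clean facilities first",
         call. = FALSE)
  }
  nr <- nrow(v); nc <- ncol(v)
  d <- run_dijkstra(et, origins$row, origins$col, nr, nc)
  reach <- matrix(NA_integer_, nr, nc)
  reach[!barrier] <- 3L
  reach[is.finite(d)] <- 2L
  reach[is.finite(d) & d <= cap_minutes] <- 1L
  vals <- d
  vals[!is.finite(vals) | vals > cap_minutes] <- NA_real_
  out <- new_grid(vals, origin_x = cost$origin_x, origin_y = cost$origin_y,
                  cell_size = cost$cell_size, nodata = cost$nodata,
                  kind = "continuous")
  attr(out, "scenario") <- scenario
  attr(out, "cap_minutes") <- cap_minutes
  attr(out, "reach") <- reach
  out
}

#' Per-facility travel-time surfaces sharing one edge-cost computation
#'
#' @param facilities Cleaned facility tibble (`id`, `row`, `col`).
#' @inheritParams travel_time_from
#' @return Named list (by facility id) of travel-time `phc_grid`s.
#' @export
travel_time_surfaces <- function(facilities, cost, dem, scenario,
                                 cap_minutes = 60, speeds = speed_table(),
                                 params = cycling_params(),
                                 transit_mask = NULL, push_base_kmh = 5) {
  et <- edge_times(cost, dem, scenario, speeds, params, transit_mask,
                   push_base_kmh)
  out <- lapply(seq_len(nrow(facilities)), function(i) {
    travel_time_from(facilities[i, ], cost, dem, scenario, cap_minutes,
                     speeds, params, transit_mask, push_base_kmh,
                     precomputed = et)
  })
  names(out) <- as.character(facilities$id)
  out
}

#' Cellwise-minimum accessibility surface over facilities
#'
#' @param per_facility_surfaces Non-empty list of travel-time surfaces of the
#'   same scenario and alignment.
#' @return A travel-time `phc_grid`: per cell, the minimum over facilities;
#'   `NA` only where all inputs are `NA`.
#' @export
accessibility_surface <- function(per_facility_surfaces) {
  if (length(per_facility_surfaces) == 0L) {
    stop("empty surface list", call. = FALSE)
  }
  first <- per_facility_surfaces[[1]]
  sc <- attr(first, "scenario")
  for (s in per_facility_surfaces[-1]) {
    stop_unaligned(first, s, "travel-time surfaces")
    if (!identical(attr(s, "scenario"), sc)) {
      stop("surfaces mix scenarios", call. = FALSE)
    }
  }
  vals <- Reduce(function(a, b) pmin(a, b, na.rm = TRUE),
                 lapply(per_facility_surfaces, function(s) s$values))
  out <- new_grid(vals, origin_x = first$origin_x, origin_y = first$origin_y,
                  cell_size = first$cell_size, nodata = first$nodata,
                  kind = "continuous")
  attr(out, "scenario") <- sc
  attr(out, "cap_minutes") <- attr(first, "cap_minutes")
  out
}
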