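#' Run the full accessibility and coverage pipeline
#'
#' Executes the stages end to end on an input bundle: facility cleaning
#' against the merged cost surface, dasymetric population mapping, one
#' anisotropic travel-time surface per facility and scenario, sequential
#' capacity-constrained catchment allocation, and the per-scenario coverage
#' report. All tunable parameters are recorded in a provenance block, and
#' identical inputs yield identical results.
#'
#' @param bundle A `phc_bundle` (from [generate_landscape()] or
#'   [read_bundle()]).
#' @param scenarios Subset of `1:3`.
#' @param cap_minutes Travel-time cap in minutes.
#' @param order Facility processing order (default: cleaned-table order).
#' @param transit_mask Optional logical matrix restricting motorized travel.
#' @param speeds Scenario speed table.
#' @param params Cycling model parameters.
#' @param out_dir Optional directory; when given, intermediate rasters and
#'   the report files are written there.
#' @return An object of class `phc_run`: list with `coverage` (row-bound
#'   `phc_coverage` tibble), `catchments` (per scenario), `clean`,
#'   `fractions`, `population`, `cost_surface`, `accessibility` (per
#'   scenario) and `provenance`.
#' @export
run_pipeline <- function(bundle, scenarios = 1:3, cap_minutes = 60,
                         order = NULL, transit_mask = NULL,
                         speeds = speed_table(), params = cycling_params(),
                         out_dir = NULL) {
  stopifnot(all(scenarios %in% 1:3), length(scenarios) >= 1L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  cost <- stage("merge", merge_cost_surface(bundle$landcover, bundle$rivers,
                                            bundle$roads, bundle$water))
  clean <- stage("clean", clean_facilities(bundle$facilities, cost, speeds))
  fractions <- stage("fractions", estimate_density_fractions(
    bundle$sector_table, bundle$sector_labels, cost))
  population <- stage("popmap", dasymetric_redistribute(
    bundle$sector_table, bundle$sector_labels, cost, fractions))
  catchments <- list(); accessibility <- list(); reports <- list()
  for (s in scenarios) {
    key <- paste0("s", s)
    surfaces <- stage(paste0("traveltime_", key), travel_time_surfaces(
      clean$facilities, cost, bundle$dem, s, cap_minutes, speeds, params,
      transit_mask))
    accessibility[[key]] <- accessibility_surface(surfaces)
    ct <- stage(paste0("catchment_", key), allocate_catchments(
      clean$facilities, surfaces, population, cap_minutes, order))
    catchments[[key]] <- ct
    reports[[key]] <- coverage_report(ct, population,
                                      clean$report$n_included)
  }
  coverage <- dplyr::bind_rows(reports)
  class(coverage) <- c("phc_coverage", class(tibble::tibble()))
  provenance <- list(
    config = if (!is.null(bundle$config)) unclass(bundle$config) else NULL,
    scenarios = scenarios, cap_minutes = cap_minutes,
    cycling = params, facility_order = order %||% "input",
    transit_mask = if (is.null(transit_mask)) "whole domain" else "custom"
  )
  provenance$hash <- rlang::hash(provenance)
  run <- structure(list(coverage = coverage, catchments = catchments,
                        clean = clean, fractions = fractions,
                        population = population, cost_surface = cost,
                        accessibility = accessibility,
                        provenance = provenance),
                   class = "phc_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

format_report_csv <- function(coverage) {
  rows <- tibble::tibble(measure = c(
    "population_covered", "population_underserved",
    "facilities_max_travel_time", "facilities_max_capacity"))
  for (i in seq_len(nrow(coverage))) {
    r <- coverage[i, ]
    rows[[paste0("scenario_", r$scenario)]] <- c(
      sprintf("%.0f (%.1f%%)", r$population_covered, r$pct_covered),
      sprintf("%.0f (%.1f%%)", r$population_underserved, r$pct_underserved),
      sprintf("%d (%.1f%%)", r$n_facilities_max_travel_time,
              r$pct_facilities_max_travel_time),
      sprintf("%d (%.1f%%)", r$n_facilities_max_capacity,
              r$pct_facilities_max_capacity))
  }
  rows
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_grid(run$cost_surface, file.path(out_dir, "cost_surface.asc"))
  write_grid(run$population, file.path(out_dir, "population.asc"))
  for (key in names(run$accessibility)) {
    write_grid(run$accessibility[[key]],
               file.path(out_dir, sprintf("traveltime_%s.asc", key)))
    write_grid(run$catchments[[key]]$labels,
               file.path(out_dir, sprintf("catchments_%s.asc", key)))
    utils::write.csv(run$catchments[[key]]$results,
                     file.path(out_dir, sprintf("facility_log_%s.csv", key)),
                     row.names = FALSE)
  }
  utils::write.csv(format_report_csv(run$coverage),
                   file.path(out_dir, "report.csv"), row.names = FALSE)
  jsonlite::write_json(
    c(list(provenance = run$provenance[c("hash", "scenarios", "cap_minutes")]),
      as.list(run$coverage)),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(as.list(tibble::as_tibble(run$fractions)),
                       file.path(out_dir, "fractions.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(run$clean$report, file.path(out_dir, "facility_cleaning.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.phc_run <- function(x, ...) {
  cat("<phc_run>\n")
  r <- x$coverage
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  scenario %d: %.1f%% covered, %.1f%% underserved; %d/%d facilities at capacity\n",
                r$scenario[i], r$pct_covered[i], r$pct_underserved[i],
                r$n_facilities_max_capacity[i], r$n_included_facilities[i]))
  }
  invisible(x)
}

#' @export
tidy.phc_run <- function(x, ...) tibble::as_tibble(x$coverage)

#' @export
glance.phc_run <- function(x, ...) {
  r <- x$coverage
  tibble::tibble(
    total_population = r$total_population[1],
    n_included_facilities = r$n_included_facilities[1],
    n_scenarios = nrow(r),
    best_scenario = r$scenario[which.max(r$pct_covered)],
    best_pct_covered = max(r$pct_covered)
  )
}
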