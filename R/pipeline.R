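#' Full run configuration
#'
#' Aggregates every knob of the pipeline: region generation, road model,
#' temporal PMFs, incident count, drone spec, GA settings, sweep/plateau
#' settings, cost/workload inputs, and the master seed from which every
#' stage seed is derived.
#'
#' @param master_seed Integer master seed (mandatory).
#' @param region A [region_config()].
#' @param road A [road_model()].
#' @param pmf A [temporal_pmf()].
#' @param n_incidents Incidents to simulate (default 10,000).
#' @param spec A [drone_spec()].
#' @param ga A [ga_config()] (its `seed` is overridden by the derived
#'   stage seed).
#' @param k_max Sweep upper bound on network size.
#' @param plateau_threshold Relative-improvement plateau threshold.
#' @param blue_light_factor Ambulance blue-light multiplier.
#' @param cost Named list `unit_cost`, `maintenance_rate`,
#'   `lifespan_years` for [cost_model()].
#' @param annual_events,operators_per_station Workload inputs.
#' @return A list of class `run_config`.
#' @export
run_config <- function(master_seed,
                       region = region_config(),
                       road = road_model(),
                       pmf = temporal_pmf(),
                       n_incidents = 10000,
                       spec = drone_spec(),
                       ga = ga_config(k = 5),
                       k_max = 8,
                       plateau_threshold = 0.02,
                       blue_light_factor = 0.75,
                       cost = list(unit_cost = 15000,
                                   maintenance_rate = 0.20,
                                   lifespan_years = 4),
                       annual_events = 1400,
                       operators_per_station = 2) {
  if (missing(master_seed)) stop("master_seed is required", call. = FALSE)
  structure(
    list(master_seed = as.integer(master_seed), region = region,
         road = road, pmf = pmf, n_incidents = n_incidents, spec = spec,
         ga = ga, k_max = k_max, plateau_threshold = plateau_threshold,
         blue_light_factor = blue_light_factor, cost = cost,
         annual_events = annual_events,
         operators_per_station = operators_per_station),
    class = "run_config"
  )
}

#' Derive a reproducible per-stage seed from the master seed
#'
#' Hashes the stage name into an offset so stages can be rerun
#' independently yet reproducibly.
#'
#' @param master_seed Integer master seed.
#' @param stage Stage name (character).
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(master_seed, stage) {
  codes <- utf8ToInt(stage)
  offset <- sum(codes * seq_along(codes) * 131)
  as.integer((abs(master_seed) + offset * 10007) %% 2147483629)
}

#' Read a run configuration from YAML
#'
#' Recognised top-level keys mirror the [run_config()] arguments; nested
#' maps mirror [region_config()], [road_model()], [drone_spec()],
#' [ga_config()] and the cost list. Missing keys keep their defaults;
#' `master_seed` is mandatory.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$master_seed)) {
    stop("config must set master_seed", call. = FALSE)
  }
  build <- function(fun, args) do.call(fun, args %||% list())
  pmf_args <- list()
  if (!is.null(y$pmf$day_csv)) pmf_args$day_pmf <- read_pmf_csv(y$pmf$day_csv)
  if (!is.null(y$pmf$hour_csv)) pmf_args$hour_pmf <- read_pmf_csv(y$pmf$hour_csv)
  ga_args <- y$ga %||% list()
  if (is.null(ga_args$k)) ga_args$k <- 5
  ga_args$seed <- ga_args$seed %||% 1L
  args <- list(
    master_seed = y$master_seed,
    region = build(region_config, lapply(y$region, unlist)),
    road = build(road_model, lapply(y$road, unlist)),
    pmf = build(temporal_pmf, pmf_args),
    spec = build(drone_spec, y$drone),
    ga = build(ga_config, ga_args)
  )
  for (key in c("n_incidents", "k_max", "plateau_threshold",
                "blue_light_factor", "annual_events",
                "operators_per_station")) {
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  }
  if (!is.null(y$cost)) args$cost <- y$cost
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full simulation-and-optimisation pipeline
#'
#' Chains every stage from one configuration and master seed: generate the
#' region, simulate incidents, evaluate the baseline (no drones), sweep
#' network sizes and pick the plateau, optimise the final network, evaluate
#' the after scenario, and assemble the report tables (coverage, responder
#' mix, per-trust summary, Wilcoxon test, cost, workload). When `out_dir`
#' is given all interface files are written there.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory for the CSV/GeoJSON artefacts.
#' @param quiet Suppress progress messages.
#' @return A list of class `drone_run` with the region, incidents, before
#'   and after records, GA fit, sweep curve, chosen k, and report tables.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  ms <- config$master_seed
  say("master seed: ", ms)

  region <- generate_region(config$region, derive_seed(ms, "region"))
  say("region: ", nrow(region$trusts), " trusts, ",
      nrow(region$facilities), " facilities")

  incidents <- generate_incidents(region, config$n_incidents, config$pmf,
                                  derive_seed(ms, "incidents"))
  say("incidents: ", nrow(incidents))

  before <- simulate_responses(incidents, region, character(0),
                               config$road, config$spec,
                               config$blue_light_factor)

  cfg <- config$ga
  cfg$seed <- derive_seed(ms, "sweep")
  curve <- sweep_bases(incidents, region, config$k_max, cfg,
                       config$road, config$spec, config$blue_light_factor)
  k_star <- select_plateau(curve, config$plateau_threshold)
  say("plateau network size: ", k_star)

  cfg$k <- as.integer(k_star)
  cfg$seed <- derive_seed(ms, "optimize")
  fit <- evolve(incidents, region, cfg, config$road, config$spec,
                config$blue_light_factor)
  say("optimised mean response: ",
      format(fit$best_fitness_min, digits = 5), " min")

  after <- simulate_responses(incidents, region, fit$best_ids,
                              config$road, config$spec,
                              config$blue_light_factor)

  report <- list(
    coverage = dplyr::full_join(
      dplyr::rename(coverage_table(before), fraction_before = "fraction"),
      dplyr::rename(coverage_table(after), fraction_after = "fraction"),
      by = "threshold_min"
    ),
    mix_before = responder_mix(before),
    mix_after = responder_mix(after),
    trust = trust_summary(before, after),
    wilcoxon = wilcoxon_signed_rank(before$winner_min, after$winner_min),
    cost_total = cost_model(k_star, config$cost$unit_cost,
                            config$cost$maintenance_rate,
                            config$cost$lifespan_years),
    workload = workload(config$annual_events, k_star,
                        config$operators_per_station)
  )

  run <- structure(
    list(config = config, region = region, incidents = incidents,
         before = before, after = after, sweep = curve, k_star = k_star,
         ga = fit, report = report),
    class = "drone_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.drone_run <- function(x, ...) {
  cat("<drone_run>", nrow(x$incidents), "incidents,",
      x$k_star, "drone bases selected\n")
  cat("mean response before:", format(mean_response(x$before), digits = 5),
      "min; after:", format(mean_response(x$after), digits = 5), "min\n")
  invisible(x)
}

#' Write all pipeline artefacts to a directory
#'
#' Region GeoJSON + facilities CSV, incidents CSV, before/after response
#' CSVs, best-network CSV (`rank,facility_id,lat,lon`), fitness-history CSV
#' (`generation,best_fitness_min,mean_fitness_min`), sweep CSV
#' (`k,best_fitness_min`), and the report tables.
#'
#' @param run A `drone_run`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_region(run$region, out_dir)
  write_incidents(run$incidents, file.path(out_dir, "incidents.csv"))
  write_responses(run$before, file.path(out_dir, "responses_before.csv"))
  write_responses(run$after, file.path(out_dir, "responses_after.csv"))

  fac <- run$region$facilities
  best <- tibble::tibble(rank = seq_along(run$ga$best_ids),
                         facility_id = run$ga$best_ids) |>
    dplyr::left_join(fac[, c("facility_id", "lat", "lon")],
                     by = "facility_id")
  readr::write_csv(best, file.path(out_dir, "best_network.csv"))
  readr::write_csv(run$ga$history, file.path(out_dir, "fitness_history.csv"))
  readr::write_csv(run$sweep[, c("k", "best_fitness_min")],
                   file.path(out_dir, "sweep.csv"))
  readr::write_csv(run$report$coverage, file.path(out_dir, "coverage.csv"))
  readr::write_csv(
    dplyr::bind_rows(
      dplyr::mutate(run$report$mix_before, scenario = "before"),
      dplyr::mutate(run$report$mix_after, scenario = "after")
    ),
    file.path(out_dir, "responder_mix.csv")
  )
  readr::write_csv(run$report$trust, file.path(out_dir, "trust_summary.csv"))
  invisible(out_dir)
}
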