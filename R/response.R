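#' Drone performance specification
#'
#' @param speed_kmh Cruise speed in km/h (default 100).
#' @param range_km Maximum one-way flight distance in km (default 12); a
#'   base farther than this from an incident is excluded. The range check
#'   is inclusive at exactly `range_km`.
#' @return A list of class `drone_spec`.
#' @export
drone_spec <- function(speed_kmh = 100, range_km = 12) {
  if (speed_kmh <= 0 || range_km <= 0) {
    stop("drone speed and range must be > 0", call. = FALSE)
  }
  structure(list(speed_kmh = speed_kmh, range_km = range_km),
            class = "drone_spec")
}

# Precompute everything a chromosome evaluation needs:
#  - ambulance and AED times per incident (base-set independent)
#  - an incident x candidate-base matrix of drone flight times, Inf where
#    the base is out of range or the flight path crosses a no-fly zone.
response_context <- function(incidents, region, road = road_model(),
                             spec = drone_spec(), blue_light_factor = 0.75,
                             overhead = c(ambulance = 0, public_aed = 0,
                                          drone = 0)) {
  validate_region(region)
  stopifnot(inherits(road, "road_model"), inherits(spec, "drone_spec"))
  n <- nrow(incidents)
  fac <- region$facilities
  stations <- fac[fac$kind == "ambulance_station", ]
  aeds <- fac[fac$kind == "public_aed", ]
  cands <- fac[fac$kind == "candidate_base", ]
  cands <- cands[order(cands$facility_id), ]
  R <- region$earth_radius_km

  speed_min_per_km <- 60 * road$circuity / road$base_speed_kmh
  mult <- road$hourly_multiplier[incidents$hour + 1]

  amb_min <- rep(Inf, n)
  if (nrow(stations) > 0 && n > 0) {
    d <- haversine_matrix(incidents$lat, incidents$lon,
                          stations$lat, stations$lon, R)
    amb_min <- blue_light_factor *
      apply(d, 1, min) * speed_min_per_km * mult +
      overhead[["ambulance"]]
  }
  aed_min <- rep(Inf, n)
  if (nrow(aeds) > 0 && n > 0) {
    d <- haversine_matrix(incidents$lat, incidents$lon, aeds$lat, aeds$lon, R)
    aed_min <- 2 * apply(d, 1, min) * speed_min_per_km * mult +
      overhead[["public_aed"]]
  }

  drone_min_mat <- matrix(Inf, n, nrow(cands),
                          dimnames = list(NULL, cands$facility_id))
  if (nrow(cands) > 0 && n > 0) {
    d <- haversine_matrix(incidents$lat, incidents$lon, cands$lat, cands$lon, R)
    feasible <- d <= spec$range_km
    if (nrow(region$no_fly_zones) > 0) {
      for (z in seq_len(nrow(region$no_fly_zones))) {
        zn <- region$no_fly_zones[z, ]
        for (j in seq_len(nrow(cands))) {
          idx <- which(feasible[, j])
          if (!length(idx)) next
          hit <- segment_intersects_disk(
            cands$lat[j], cands$lon[j],
            incidents$lat[idx], incidents$lon[idx],
            zn$lat, zn$lon, zn$radius_km, R
          )
          feasible[idx[hit], j] <- FALSE
        }
      }
    }
    t_fly <- 60 * d / spec$speed_kmh + overhead[["drone"]]
    drone_min_mat[feasible] <- t_fly[feasible]
  }

  list(incident_id = incidents$incident_id, trust_id = incidents$trust_id,
       amb_min = amb_min, aed_min = aed_min,
       drone_min_mat = drone_min_mat,
       candidate_ids = cands$facility_id)
}

# Mean response time (the GA fitness) for one base set, given a context.
context_fitness <- function(ctx, base_ids) {
  mean(context_winner_min(ctx, base_ids))
}

context_winner_min <- function(ctx, base_ids) {
  w <- pmin(ctx$amb_min, ctx$aed_min)
  if (length(base_ids) > 0) {
    sub <- ctx$drone_min_mat[, base_ids, drop = FALSE]
    w <- pmin(w, apply(sub, 1, min))
  }
  w
}

#' Ambulance response time per incident
#'
#' Blue-light time from the nearest ambulance station: road travel time at
#' the incident's hour, reduced by the blue-light factor (default 0.75, the
#' 25% lights-and-sirens reduction).
#'
#' @param incidents Incident tibble (`lat`, `lon`, `hour`).
#' @param region A `region`.
#' @param road A [road_model()].
#' @param blue_light_factor Multiplier on civilian driving time.
#' @return Numeric minutes per incident; `Inf` when no station exists.
#' @export
ambulance_time <- function(incidents, region, road = road_model(),
                           blue_light_factor = 0.75) {
  ctx <- response_context(incidents, region, road,
                          blue_light_factor = blue_light_factor)
  ctx$amb_min
}

#' Bystander public-AED response time per incident
#'
#' Civilian round-trip driving time to the nearest public AED and back (no
#' blue-light reduction).
#'
#' @inheritParams ambulance_time
#' @return Numeric minutes per incident; `Inf` when no AED exists.
#' @export
aed_time <- function(incidents, region, road = road_model()) {
  ctx <- response_context(incidents, region, road)
  ctx$aed_min
}

#' Drone response time per incident
#'
#' Straight-line flight time from the nearest active base that is within
#' flight range and whose path crosses no no-fly zone; `NA` when no base
#' qualifies. Bases are effectively considered in increasing distance order:
#' a farther base with a clear path wins over a nearer blocked one.
#'
#' @param incidents Incident tibble.
#' @param region A `region`.
#' @param active_bases Character vector of candidate-base facility ids.
#' @param spec A [drone_spec()].
#' @return Numeric minutes per incident, `NA` where unavailable.
#' @export
drone_time <- function(incidents, region, active_bases,
                       spec = drone_spec()) {
  ctx <- response_context(incidents, region, spec = spec)
  bad <- setdiff(active_bases, ctx$candidate_ids)
  if (length(bad)) {
    stop("unknown candidate base id: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(active_bases) == 0) return(rep(NA_real_, nrow(incidents)))
  t <- apply(ctx$drone_min_mat[, active_bases, drop = FALSE], 1, min)
  ifelse(is.finite(t), t, NA_real_)
}

#' Simulate the fastest responder for each incident
#'
#' Computes ambulance, bystander-AED and (when `active_bases` is non-empty)
#' drone response times for every incident and selects the fastest available
#' responder. Exact ties are broken in the fixed order ambulance > drone >
#' public AED (professional responder preferred). With no active bases this
#' is the "before" (no drone network) scenario.
#'
#' @param incidents Incident tibble.
#' @param region A `region`.
#' @param active_bases Character vector of active drone-base ids (possibly
#'   empty).
#' @param road A [road_model()].
#' @param spec A [drone_spec()].
#' @param blue_light_factor Ambulance blue-light multiplier (default 0.75).
#' @param overhead Named additive minutes per responder type, default all 0.
#' @return Tibble with `incident_id`, `trust_id`, `ambulance_min`,
#'   `aed_min`, `drone_min` (`NA` when unavailable), `winner`,
#'   `winner_min`.
#' @export
simulate_responses <- function(incidents, region,
                               active_bases = character(0),
                               road = road_model(), spec = drone_spec(),
                               blue_light_factor = 0.75,
                               overhead = c(ambulance = 0, public_aed = 0,
                                            drone = 0)) {
  ctx <- response_context(incidents, region, road, spec,
                          blue_light_factor, overhead)
  bad <- setdiff(active_bases, ctx$candidate_ids)
  if (length(bad)) {
    stop("unknown candidate base id: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(incidents)
  drone_min <- rep(Inf, n)
  if (length(active_bases) > 0 && n > 0) {
    drone_min <- apply(ctx$drone_min_mat[, active_bases, drop = FALSE],
                       1, min)
  }
  if (n > 0 && any(!is.finite(ctx$amb_min) & !is.finite(ctx$aed_min) &
                   !is.finite(drone_min))) {
    stop("some incident has no available responder of any kind",
         call. = FALSE)
  }
  # tie-break order: ambulance, drone, public_aed
  times <- cbind(ambulance = ctx$amb_min, drone = drone_min,
                 public_aed = ctx$aed_min)
  pick <- apply(times, 1, which.min)
  tibble::tibble(
    incident_id = ctx$incident_id,
    trust_id = ctx$trust_id,
    ambulance_min = ifelse(is.finite(ctx$amb_min), ctx$amb_min, NA_real_),
    aed_min = ifelse(is.finite(ctx$aed_min), ctx$aed_min, NA_real_),
    drone_min = ifelse(is.finite(drone_min), drone_min, NA_real_),
    winner = colnames(times)[pick],
    winner_min = times[cbind(seq_len(n), pick)]
  )
}

#' Mean response time over a simulated incident set
#'
#' The arithmetic mean of the winning responder's time — the fitness
#' indicator used by the genetic algorithm.
#'
#' @param records Response tibble from [simulate_responses()].
#' @return Mean of `winner_min` in minutes.
#' @export
mean_response <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    stop("no response records", call. = FALSE)
  }
  mean(records$winner_min)
}

#' Response record CSV round trip
#'
#' Header `incident_id,ambulance_min,aed_min,drone_min,winner,winner_min`;
#' `drone_min` is empty when the drone is unavailable.
#'
#' @param records Response tibble.
#' @param path CSV path.
#' @export
write_responses <- function(records, path) {
  cols <- c("incident_id", "ambulance_min", "aed_min", "drone_min",
            "winner", "winner_min")
  stopifnot(all(cols %in% names(records)))
  readr::write_csv(records[, cols], path, na = "")
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, col_types = "idddcd")
  cols <- c("incident_id", "ambulance_min", "aed_min", "drone_min",
            "winner", "winner_min")
  if (!identical(names(d), cols)) {
    stop("response CSV header must be ", paste(cols, collapse = ","),
         call. = FALSE)
  }
  tibble::as_tibble(d)
}
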