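# Fixtures built in code: small regions used across the suite.

# A compact generated region: 3 trusts, modest facility counts.
tiny_region <- function(seed = 7) {
  generate_region(
    region_config(
      n_trusts = 3, densities = c(900, 200, 120),
      lat_range = c(54.2, 55.0), lon_range = c(-7.6, -5.8),
      residential_per_trust = 4, residential_radius_km = 6,
      n_ambulance = 5, n_aed = 10, n_candidate = 10, n_no_fly = 1
    ),
    seed = seed
  )
}

# A hand-built single-trust region on the equator where degrees of latitude
# and longitude are commensurate, used for exact geometric assertions.
# deg_per_km converts km offsets to degrees on the default sphere.
deg_per_km <- function() 180 / (pi * 6356)

manual_region <- function(facilities, no_fly = NULL, half_width_deg = 2) {
  poly <- tibble::tibble(
    lat = c(-half_width_deg, -half_width_deg, half_width_deg,
            half_width_deg, -half_width_deg),
    lon = c(-half_width_deg, half_width_deg, half_width_deg,
            -half_width_deg, -half_width_deg)
  )
  trusts <- tibble::tibble(
    trust_id = "T01", name = "Trust T01", population_density = 100,
    polygon = list(poly),
    residential = list(tibble::tibble(lat = 0, lon = 0,
                                      radius_km = 2 * 6356 * pi / 180))
  )
  nfz <- if (is.null(no_fly)) {
    tibble::tibble(zone_id = character(), lat = numeric(),
                   lon = numeric(), radius_km = numeric())
  } else {
    no_fly
  }
  structure(
    list(trusts = trusts, facilities = facilities, no_fly_zones = nfz,
         earth_radius_km = 6356),
    class = "region"
  )
}

# facilities helper: place one facility of a kind at a km offset east of the
# origin along the equator.
facility_at_km <- function(id, kind, east_km, north_km = 0) {
  tibble::tibble(facility_id = id, kind = kind,
                 lat = north_km * deg_per_km(),
                 lon = east_km * deg_per_km())
}

# one incident at the origin (equator) at a fixed hour with multiplier 1
origin_incident <- function(hour = 3) {
  tibble::tibble(incident_id = 1L, trust_id = "T01", lat = 0, lon = 0,
                 day = 0L, hour = as.integer(hour))
}

# a flat road model (no congestion) for exact arithmetic
flat_road <- function(circuity = 1.3, speed = 50) {
  road_model(circuity = circuity, base_speed_kmh = speed,
             hourly_multiplier = rep(1, 24))
}

# A rural-like region: residential areas far from the few ambulance
# stations and AEDs, with candidate drone bases sitting on the residential
# centres themselves (well-placed).
rural_region <- function() {
  res <- tibble::tibble(
    lat = c(0.25, -0.25, 0.25, -0.25, 0.0),
    lon = c(0.6, 0.6, 1.2, 1.2, 0.9),
    radius_km = 8
  )
  trusts <- tibble::tibble(
    trust_id = "T01", name = "Rural trust", population_density = 80,
    polygon = list(tibble::tibble(
      lat = c(-0.6, -0.6, 0.6, 0.6, -0.6),
      lon = c(-0.2, 1.6, 1.6, -0.2, -0.2)
    )),
    residential = list(res)
  )
  # responders clustered near the western edge, far from most residences
  fac <- dplyr::bind_rows(
    tibble::tibble(facility_id = c("AMB001", "AMB002"),
                   kind = "ambulance_station",
                   lat = c(0.05, -0.05), lon = c(-0.1, -0.15)),
    tibble::tibble(facility_id = c("AED001", "AED002"),
                   kind = "public_aed",
                   lat = c(0.1, -0.1), lon = c(-0.05, -0.1)),
    tibble::tibble(facility_id = sprintf("CND%03d", 1:5),
                   kind = "candidate_base",
                   lat = res$lat, lon = res$lon)
  )
  structure(
    list(trusts = trusts, facilities = fac,
         no_fly_zones = tibble::tibble(zone_id = character(),
                                       lat = numeric(), lon = numeric(),
                                       radius_km = numeric()),
         earth_radius_km = 6356),
    class = "region"
  )
}

# small GA test instance: incidents + region with n candidate bases
ga_instance <- function(seed, n_candidates = 8, n_incidents = 30) {
  region <- generate_region(
    region_config(
      n_trusts = 2, densities = c(400, 150),
      lat_range = c(54.3, 54.9), lon_range = c(-7.2, -6.0),
      residential_per_trust = 3, residential_radius_km = 7,
      n_ambulance = 2, n_aed = 4, n_candidate = n_candidates, n_no_fly = 0
    ),
    seed = seed
  )
  incidents <- generate_incidents(region, n_incidents, temporal_pmf(),
                                  seed = seed + 1000)
  list(region = region, incidents = incidents)
}
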