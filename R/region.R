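#' Region generation parameters
#'
#' Bundles the knobs for [generate_region()]. The defaults sketch a small
#' country-scale region: five health trusts tiling a roughly 100 x 140 km
#' bounding box, with population densities spanning urban to rural.
#'
#' @param n_trusts Number of trusts (>= 1).
#' @param densities Persons per km^2 per trust; recycled/validated against
#'   `n_trusts`. Used as apportionment weights for incidents.
#' @param lat_range,lon_range Bounding box in decimal degrees.
#' @param residential_per_trust Residential centres per trust (>= 1).
#' @param residential_radius_km Radius of each residential disk.
#' @param n_ambulance,n_aed,n_candidate Facility counts by kind.
#' @param n_no_fly Number of circular no-fly zones.
#' @param no_fly_radius_km No-fly radius in km (default 5).
#' @param earth_radius_km Sphere radius carried by the region.
#' @return A list of class `region_config`.
#' @export
region_config <- function(n_trusts = 5,
                          densities = c(2600, 180, 120, 150, 220),
                          lat_range = c(54.0, 55.3),
                          lon_range = c(-8.2, -5.4),
                          residential_per_trust = 6,
                          residential_radius_km = 6,
                          n_ambulance = 12,
                          n_aed = 30,
                          n_candidate = 40,
                          n_no_fly = 2,
                          no_fly_radius_km = 5,
                          earth_radius_km = EARTH_RADIUS_KM) {
  if (n_trusts < 1) stop("need at least one trust", call. = FALSE)
  densities <- rep_len(densities, n_trusts)
  if (any(densities <= 0)) stop("population densities must be > 0", call. = FALSE)
  if (n_candidate < 1) stop("need at least one candidate drone base", call. = FALSE)
  if (residential_per_trust < 1) {
    stop("each trust needs at least one residential centre", call. = FALSE)
  }
  counts <- c(n_ambulance, n_aed, n_candidate, n_no_fly)
  if (any(counts < 0)) stop("facility/zone counts must be >= 0", call. = FALSE)
  structure(
    list(
      n_trusts = n_trusts, densities = densities,
      lat_range = sort(lat_range), lon_range = sort(lon_range),
      residential_per_trust = residential_per_trust,
      residential_radius_km = residential_radius_km,
      n_ambulance = n_ambulance, n_aed = n_aed, n_candidate = n_candidate,
      n_no_fly = n_no_fly, no_fly_radius_km = no_fly_radius_km,
      earth_radius_km = earth_radius_km
    ),
    class = "region_config"
  )
}

#' Generate a synthetic region
#'
#' Builds a self-contained study region: trust polygons as jittered vertical
#' strips tiling the bounding box (disjoint convex cells), residential
#' centres inside each trust, facilities of three kinds placed near
#' residential centres (emulating high-footfall AED siting), and circular
#' no-fly zones. Deterministic for a fixed seed.
#'
#' @param config A [region_config()].
#' @param seed Integer seed.
#' @return A list of class `region` with elements `trusts` (tibble:
#'   `trust_id`, `name`, `population_density`, list-columns `polygon` and
#'   `residential`), `facilities` (tibble: `facility_id`, `kind`, `lat`,
#'   `lon`), `no_fly_zones` (tibble: `zone_id`, `lat`, `lon`, `radius_km`)
#'   and `earth_radius_km`.
#' @export
generate_region <- function(config = region_config(), seed = 1L) {
  stopifnot(inherits(config, "region_config"))
  set.seed(seed)
  nt <- config$n_trusts
  lonr <- config$lon_range
  latr <- config$lat_range

  # strip boundaries: equal widths jittered, interior cuts kept ordered
  cuts <- seq(lonr[1], lonr[2], length.out = nt + 1)
  if (nt > 1) {
    w <- diff(lonr) / nt
    cuts[2:nt] <- cuts[2:nt] + runif(nt - 1, -0.2 * w, 0.2 * w)
    cuts <- sort(cuts)
  }
  trust_ids <- sprintf("T%02d", seq_len(nt))
  polygons <- purrr::map(seq_len(nt), function(i) {
    tibble::tibble(
      lat = c(latr[1], latr[1], latr[2], latr[2], latr[1]),
      lon = c(cuts[i], cuts[i + 1], cuts[i + 1], cuts[i], cuts[i])
    )
  })

  residential <- purrr::map(seq_len(nt), function(i) {
    # keep centres away from the strip edges so disks stay mostly internal
    lo <- cuts[i] + 0.1 * (cuts[i + 1] - cuts[i])
    hi <- cuts[i + 1] - 0.1 * (cuts[i + 1] - cuts[i])
    tibble::tibble(
      lat = runif(config$residential_per_trust,
                  latr[1] + 0.08 * diff(latr), latr[2] - 0.08 * diff(latr)),
      lon = runif(config$residential_per_trust, lo, hi),
      radius_km = config$residential_radius_km
    )
  })

  trusts <- tibble::tibble(
    trust_id = trust_ids,
    name = paste("Trust", trust_ids),
    population_density = config$densities,
    polygon = polygons,
    residential = residential
  )

  place_near_residential <- function(n, prefix) {
    if (n == 0) {
      return(tibble::tibble(facility_id = character(), kind = character(),
                            lat = numeric(), lon = numeric()))
    }
    centres <- dplyr::bind_rows(residential)
    idx <- sample.int(nrow(centres), n, replace = TRUE)
    # gaussian scatter around the chosen centre, sd = half the disk radius
    sd_deg_lat <- (centres$radius_km[idx] / 2) / (config$earth_radius_km * pi / 180)
    lat <- centres$lat[idx] + rnorm(n, 0, sd_deg_lat)
    lon <- centres$lon[idx] + rnorm(n, 0, sd_deg_lat / cos(centres$lat[idx] * pi / 180))
    lat <- pmin(pmax(lat, latr[1]), latr[2])
    lon <- pmin(pmax(lon, lonr[1]), lonr[2])
    tibble::tibble(
      facility_id = sprintf("%s%03d", prefix, seq_len(n)),
      lat = lat, lon = lon
    )
  }

  facilities <- dplyr::bind_rows(
    dplyr::mutate(place_near_residential(config$n_ambulance, "AMB"),
                  kind = "ambulance_station"),
    dplyr::mutate(place_near_residential(config$n_aed, "AED"),
                  kind = "public_aed"),
    dplyr::mutate(place_near_residential(config$n_candidate, "CND"),
                  kind = "candidate_base")
  )
  facilities <- facilities[, c("facility_id", "kind", "lat", "lon")]

  no_fly <- if (config$n_no_fly > 0) {
    tibble::tibble(
      zone_id = sprintf("NFZ%02d", seq_len(config$n_no_fly)),
      lat = runif(config$n_no_fly, latr[1], latr[2]),
      lon = runif(config$n_no_fly, lonr[1], lonr[2]),
      radius_km = config$no_fly_radius_km
    )
  } else {
    tibble::tibble(zone_id = character(), lat = numeric(), lon = numeric(),
                   radius_km = numeric())
  }

  region <- structure(
    list(trusts = trusts, facilities = facilities, no_fly_zones = no_fly,
         earth_radius_km = config$earth_radius_km),
    class = "region"
  )
  validate_region(region)
  region
}

validate_region <- function(region) {
  stopifnot(inherits(region, "region"))
  if (nrow(region$trusts) < 1) stop("region has no trusts", call. = FALSE)
  if (anyDuplicated(region$facilities$facility_id)) {
    stop("facility ids are not unique", call. = FALSE)
  }
  if (!any(region$facilities$kind == "candidate_base")) {
    stop("region has no candidate drone bases", call. = FALSE)
  }
  bad_kind <- setdiff(unique(region$facilities$kind),
                      c("ambulance_station", "public_aed", "candidate_base"))
  if (length(bad_kind)) {
    stop("unknown facility kind: ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  }
  invisible(region)
}

#' @export
print.region <- function(x, ...) {
  mix <- table(x$facilities$kind)
  cat("<region>", nrow(x$trusts), "trusts,",
      nrow(x$facilities), "facilities (",
      paste(names(mix), mix, sep = "=", collapse = ", "), "),",
      nrow(x$no_fly_zones), "no-fly zones; earth radius",
      x$earth_radius_km, "km\n")
  invisible(x)
}

#' Parametric road travel-time model
#'
#' A stand-in for a live travel-time provider: driving distance is the
#' crow-flies (haversine) distance scaled by a circuity factor, and speed is
#' a free-flow speed divided by an hour-of-day congestion multiplier.
#'
#' @param circuity Road-to-crow-flies distance ratio (>= 1, default 1.3).
#' @param base_speed_kmh Free-flow driving speed (default 50 km/h).
#' @param hourly_multiplier 24 congestion factors (>= 1), hours 0-23. The
#'   default applies mild morning (08-09) and evening (17-18) peaks.
#' @return A list of class `road_model`.
#' @export
road_model <- function(circuity = 1.3, base_speed_kmh = 50,
                       hourly_multiplier = default_hourly_multiplier()) {
  if (circuity < 1) stop("circuity must be >= 1", call. = FALSE)
  if (base_speed_kmh <= 0) stop("base speed must be > 0", call. = FALSE)
  if (length(hourly_multiplier) != 24 || any(hourly_multiplier < 1)) {
    stop("hourly_multiplier must be 24 values >= 1", call. = FALSE)
  }
  structure(
    list(circuity = circuity, base_speed_kmh = base_speed_kmh,
         hourly_multiplier = hourly_multiplier),
    class = "road_model"
  )
}

#' @rdname road_model
#' @export
default_hourly_multiplier <- function() {
  m <- rep(1, 24)
  m[c(8, 9, 17, 18) + 1] <- 1.3
  m[c(7, 10, 16, 19) + 1] <- 1.15
  m
}

#' Road travel time between two points
#'
#' @param lat1,lon1,lat2,lon2 Endpoints in decimal degrees (vectorised).
#' @param hour Hour of day 0-23 (vectorised), indexing the congestion
#'   multiplier.
#' @param road A [road_model()].
#' @param radius_km Earth radius in km.
#' @return Travel time in minutes.
#' @export
road_time_min <- function(lat1, lon1, lat2, lon2, hour,
                          road = road_model(),
                          radius_km = EARTH_RADIUS_KM) {
  stopifnot(inherits(road, "road_model"))
  if (any(hour < 0 | hour > 23 | hour != floor(hour))) {
    stop("hour must be an integer in 0-23", call. = FALSE)
  }
  d_km <- haversine_km(lat1, lon1, lat2, lon2, radius_km)
  speed <- road$base_speed_kmh / road$hourly_multiplier[hour + 1]
  60 * (d_km * road$circuity) / speed
}

# ---- serialization -------------------------------------------------------

#' Write and read a region as GeoJSON + CSV
#'
#' The region is written as `region.geojson` (trust polygons as Polygon
#' features; residential centres and no-fly zones as Point features with a
#' `radius_km` property; GeoJSON coordinate order is `[lon, lat]`) and
#' `facilities.csv` with header `facility_id,kind,lat,lon`.
#'
#' @param region A `region` object.
#' @param dir Output directory (created if needed).
#' @return `write_region()` returns the directory invisibly; `read_region()`
#'   returns a `region`.
#' @export
write_region <- function(region, dir) {
  validate_region(region)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trust_feats <- purrr::pmap(region$trusts, function(trust_id, name,
                                                    population_density,
                                                    polygon, residential) {
    coords <- lapply(seq_len(nrow(polygon)),
                     function(i) c(polygon$lon[i], polygon$lat[i]))
    list(
      type = "Feature",
      properties = list(feature = "trust", trust_id = trust_id, name = name,
                        population_density = population_density),
      geometry = list(type = "Polygon", coordinates = list(coords))
    )
  })
  res_feats <- purrr::pmap(region$trusts, function(trust_id, name,
                                                   population_density,
                                                   polygon, residential) {
    purrr::pmap(residential, function(lat, lon, radius_km) {
      list(
        type = "Feature",
        properties = list(feature = "residential_center", trust_id = trust_id,
                          radius_km = radius_km),
        geometry = list(type = "Point", coordinates = c(lon, lat))
      )
    })
  })
  nfz_feats <- purrr::pmap(region$no_fly_zones, function(zone_id, lat, lon,
                                                         radius_km) {
    list(
      type = "Feature",
      properties = list(feature = "no_fly_zone", zone_id = zone_id,
                        radius_km = radius_km),
      geometry = list(type = "Point", coordinates = c(lon, lat))
    )
  })
  fc <- list(
    type = "FeatureCollection",
    properties = list(earth_radius_km = region$earth_radius_km),
    features = c(trust_feats, purrr::flatten(res_feats), nfz_feats)
  )
  jsonlite::write_json(fc, file.path(dir, "region.geojson"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(region$facilities, file.path(dir, "facilities.csv"))
  invisible(dir)
}

#' @rdname write_region
#' @export
read_region <- function(dir) {
  fc <- jsonlite::read_json(file.path(dir, "region.geojson"))
  feats <- fc$features
  kind_of <- purrr::map_chr(feats, ~ .x$properties$feature)

  trusts <- purrr::map(feats[kind_of == "trust"], function(f) {
    ring <- f$geometry$coordinates[[1]]
    poly <- tibble::tibble(
      lat = purrr::map_dbl(ring, ~ .x[[2]]),
      lon = purrr::map_dbl(ring, ~ .x[[1]])
    )
    tibble::tibble(
      trust_id = f$properties$trust_id,
      name = f$properties$name,
      population_density = f$properties$population_density,
      polygon = list(poly)
    )
  })
  trusts <- dplyr::bind_rows(trusts)

  res <- purrr::map(feats[kind_of == "residential_center"], function(f) {
    tibble::tibble(
      trust_id = f$properties$trust_id,
      lat = f$geometry$coordinates[[2]],
      lon = f$geometry$coordinates[[1]],
      radius_km = f$properties$radius_km
    )
  })
  res <- dplyr::bind_rows(res)
  trusts$residential <- purrr::map(trusts$trust_id, function(id) {
    sub <- res[res$trust_id == id, c("lat", "lon", "radius_km")]
    tibble::as_tibble(sub)
  })

  nfz <- purrr::map(feats[kind_of == "no_fly_zone"], function(f) {
    tibble::tibble(
      zone_id = f$properties$zone_id,
      lat = f$geometry$coordinates[[2]],
      lon = f$geometry$coordinates[[1]],
      radius_km = f$properties$radius_km
    )
  })
  nfz <- if (length(nfz)) dplyr::bind_rows(nfz) else {
    tibble::tibble(zone_id = character(), lat = numeric(), lon = numeric(),
                   radius_km = numeric())
  }

  facilities <- readr::read_csv(file.path(dir, "facilities.csv"),
                                show_col_types = FALSE,
                                col_types = "ccdd")
  region <- structure(
    list(trusts = trusts, facilities = tibble::as_tibble(facilities),
         no_fly_zones = nfz,
         earth_radius_km = fc$properties$earth_radius_km),
    class = "region"
  )
  validate_region(region)
  region
}
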