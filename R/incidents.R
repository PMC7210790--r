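#' Temporal probability mass functions for incident times
#'
#' Day-of-week (Mon = 0 ... Sun = 6) and hour-of-day (0-23) marginal PMFs
#' from which incident times are drawn independently. The shipped defaults
#' are editable placeholders — a mild weekday elevation and a unimodal
#' daytime (09:00-17:00) peak — not observed registry data; replace them
#' with [read_pmf_csv()] when real distributions are available.
#'
#' @param day_pmf 7 non-negative probabilities summing to 1.
#' @param hour_pmf 24 non-negative probabilities summing to 1.
#' @return A list of class `temporal_pmf`.
#' @export
temporal_pmf <- function(day_pmf = default_day_pmf(),
                         hour_pmf = default_hour_pmf()) {
  check_pmf <- function(p, n, what) {
    if (length(p) != n) stop(what, " must have ", n, " entries", call. = FALSE)
    if (any(p < 0)) stop(what, " has negative entries", call. = FALSE)
    if (abs(sum(p) - 1) > 1e-9) {
      stop(what, " must sum to 1 (got ", format(sum(p)), ")", call. = FALSE)
    }
  }
  check_pmf(day_pmf, 7, "day_pmf")
  check_pmf(hour_pmf, 24, "hour_pmf")
  structure(list(day_pmf = day_pmf, hour_pmf = hour_pmf),
            class = "temporal_pmf")
}

#' @rdname temporal_pmf
#' @export
default_day_pmf <- function() {
  w <- c(rep(1.1, 5), rep(0.875, 2)) # Mon-Fri slightly elevated
  w / sum(w)
}

#' @rdname temporal_pmf
#' @export
default_hour_pmf <- function() {
  h <- 0:23
  # daytime hump peaking early afternoon, low overnight floor
  w <- 0.25 + exp(-((h - 13)^2) / (2 * 4.5^2))
  w / sum(w)
}

#' Read a PMF from a two-column CSV
#'
#' Expects header `index,probability` with indices 0..6 (days) or 0..23
#' (hours) in any order.
#'
#' @param path CSV path.
#' @return Numeric probability vector ordered by index.
#' @export
read_pmf_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, col_types = "id")
  if (!all(c("index", "probability") %in% names(d))) {
    stop("PMF CSV must have columns index,probability", call. = FALSE)
  }
  d <- dplyr::arrange(d, .data$index)
  if (!identical(d$index, seq_len(nrow(d)) - 1L)) {
    stop("PMF indices must be 0..", nrow(d) - 1, call. = FALSE)
  }
  d$probability
}

#' Apportion incidents across trusts by population density
#'
#' Largest-remainder (Hamilton) apportionment of `n_total` incidents
#' proportional to each trust's population density. Counts always sum to
#' `n_total`; remainder ties go to the earlier trust.
#'
#' @param trusts Trust tibble with `trust_id` and `population_density`.
#' @param n_total Total incident count (>= 0).
#' @return Tibble with `trust_id` and `n`.
#' @export
allocate_by_density <- function(trusts, n_total) {
  if (is.null(trusts) || nrow(trusts) == 0) {
    stop("trust list is empty", call. = FALSE)
  }
  if (n_total < 0) stop("n_total must be >= 0", call. = FALSE)
  w <- trusts$population_density
  if (any(w <= 0)) stop("population densities must be > 0", call. = FALSE)
  quota <- n_total * w / sum(w)
  base <- floor(quota)
  rem <- n_total - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  tibble::tibble(trust_id = trusts$trust_id, n = as.integer(base))
}

# Uniform rejection sampling of n points inside the trust polygon that also
# fall inside at least one residential disk.
sample_locations <- function(trust_polygon, residential, n,
                             earth_radius_km = EARTH_RADIUS_KM,
                             max_attempts = 10000) {
  if (n == 0) return(tibble::tibble(lat = numeric(), lon = numeric()))
  if (nrow(residential) == 0) {
    stop("trust has no residential centres", call. = FALSE)
  }
  latr <- range(trust_polygon$lat)
  lonr <- range(trust_polygon$lon)
  out_lat <- numeric(0)
  out_lon <- numeric(0)
  attempts <- 0
  batch <- max(64L, 4L * n)
  while (length(out_lat) < n) {
    if (attempts >= max_attempts * n) {
      stop("location sampling failed: residential disks may not overlap ",
           "the trust polygon", call. = FALSE)
    }
    m <- min(batch, max_attempts * n - attempts)
    attempts <- attempts + m
    lat <- runif(m, latr[1], latr[2])
    lon <- runif(m, lonr[1], lonr[2])
    ok <- point_in_polygon(lat, lon, trust_polygon$lat, trust_polygon$lon)
    if (any(ok)) {
      d <- haversine_matrix(lat[ok], lon[ok], residential$lat,
                            residential$lon, earth_radius_km)
      in_res <- apply(d <= matrix(residential$radius_km, nrow(d),
                                  ncol(d), byrow = TRUE), 1, any)
      out_lat <- c(out_lat, lat[ok][in_res])
      out_lon <- c(out_lon, lon[ok][in_res])
    }
  }
  tibble::tibble(lat = out_lat[seq_len(n)], lon = out_lon[seq_len(n)])
}

#' Sample one residential location within a trust
#'
#' Rejection-samples points uniform over the trust polygon, accepting only
#' those inside a residential disk.
#'
#' @param trust One row of the region's trust tibble (a list or one-row
#'   tibble with `polygon` and `residential`).
#' @param earth_radius_km Earth radius in km.
#' @param max_attempts Cap on rejection attempts before erroring.
#' @return One-row tibble with `lat`, `lon`.
#' @export
sample_location <- function(trust, earth_radius_km = EARTH_RADIUS_KM,
                            max_attempts = 10000) {
  poly <- if (is.data.frame(trust$polygon)) trust$polygon else trust$polygon[[1]]
  res <- if (is.data.frame(trust$residential)) trust$residential else trust$residential[[1]]
  sample_locations(poly, res, 1, earth_radius_km, max_attempts)
}

#' Sample a day and hour from a temporal PMF
#'
#' @param pmf A [temporal_pmf()].
#' @param n Number of draws.
#' @return Tibble with integer columns `day` (0-6) and `hour` (0-23); day
#'   and hour are drawn independently from the two marginals.
#' @export
sample_time <- function(pmf, n = 1) {
  stopifnot(inherits(pmf, "temporal_pmf"))
  tibble::tibble(
    day = sample(0:6, n, replace = TRUE, prob = pmf$day_pmf),
    hour = sample(0:23, n, replace = TRUE, prob = pmf$hour_pmf)
  )
}

#' Generate the simulated OHCA incident set
#'
#' Allocates `n_total` incidents across trusts by population density
#' (largest-remainder), samples each incident's location uniformly within
#' its trust's residential areas, and draws day/hour from the temporal PMFs.
#' Deterministic for a fixed seed.
#'
#' @param region A `region`.
#' @param n_total Number of incidents (default 10,000).
#' @param pmf A [temporal_pmf()].
#' @param seed Integer seed.
#' @param max_attempts Rejection-sampling cap per point.
#' @return Tibble with columns `incident_id`, `trust_id`, `lat`, `lon`,
#'   `day`, `hour`.
#' @export
generate_incidents <- function(region, n_total = 10000,
                               pmf = temporal_pmf(), seed = 1L,
                               max_attempts = 10000) {
  validate_region(region)
  if (n_total < 0) stop("n_total must be >= 0", call. = FALSE)
  set.seed(seed)
  alloc <- allocate_by_density(region$trusts, n_total)
  locs <- purrr::map2(seq_len(nrow(region$trusts)), alloc$n, function(i, ni) {
    loc <- sample_locations(region$trusts$polygon[[i]],
                            region$trusts$residential[[i]], ni,
                            region$earth_radius_km, max_attempts)
    loc$trust_id <- rep(region$trusts$trust_id[i], ni)
    loc
  })
  out <- dplyr::bind_rows(locs)
  times <- sample_time(pmf, nrow(out))
  tibble::tibble(
    incident_id = seq_len(nrow(out)),
    trust_id = out$trust_id,
    lat = out$lat, lon = out$lon,
    day = times$day, hour = times$hour
  )
}

#' Incident CSV round trip
#'
#' Header is exactly `incident_id,trust_id,lat,lon,day,hour`.
#'
#' @param incidents Incident tibble.
#' @param path CSV path.
#' @return `write_incidents()` the path invisibly; `read_incidents()` the
#'   tibble.
#' @export
write_incidents <- function(incidents, path) {
  cols <- c("incident_id", "trust_id", "lat", "lon", "day", "hour")
  stopifnot(all(cols %in% names(incidents)))
  readr::write_csv(incidents[, cols], path)
  invisible(path)
}

#' @rdname write_incidents
#' @export
read_incidents <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, col_types = "icddii")
  cols <- c("incident_id", "trust_id", "lat", "lon", "day", "hour")
  if (!identical(names(d), cols)) {
    stop("incident CSV header must be ", paste(cols, collapse = ","),
         call. = FALSE)
  }
  if (nrow(d) && (any(d$day < 0 | d$day > 6) || any(d$hour < 0 | d$hour > 23))) {
    stop("incident day/hour out of range", call. = FALSE)
  }
  tibble::as_tibble(d)
}
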