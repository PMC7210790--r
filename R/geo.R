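#' @importFrom rlang .data
#' @importFrom stats quantile rnorm runif setNames pnorm
#' @importFrom utils combn head
NULL

# Default sphere radius in km. The polar radius is used throughout as the
# working earth model; any function taking `radius_km` accepts an override.
EARTH_RADIUS_KM <- 6356

check_coords <- function(lat, lon, what = "coordinate") {
  if (any(!is.finite(lat)) || any(!is.finite(lon))) {
    stop(what, ": latitude/longitude must be finite numbers", call. = FALSE)
  }
  if (any(lat < -90 | lat > 90)) {
    stop(what, ": latitude out of range [-90, 90]", call. = FALSE)
  }
  if (any(lon < -180 | lon > 180)) {
    stop(what, ": longitude out of range [-180, 180]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Great-circle distance between points on a sphere
#'
#' Haversine distance in kilometres between WGS84 latitude/longitude pairs.
#' All arguments are vectorised and recycled.
#'
#' @param lat1,lon1 Origin latitude/longitude in decimal degrees.
#' @param lat2,lon2 Destination latitude/longitude in decimal degrees.
#' @param radius_km Sphere radius in km (default 6356, the polar radius).
#' @return Numeric vector of distances in km.
#' @examples
#' haversine_km(54.5973, -5.9301, 54.9966, -7.3086) # Belfast -> Derry
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, radius_km = EARTH_RADIUS_KM) {
  stopifnot(radius_km > 0)
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dphi <- (lat2 - lat1) * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  2 * radius_km * asin(sqrt(pmin(a, 1)))
}

# Dense distance matrix (km) between two point sets given as vectors.
haversine_matrix <- function(lat1, lon1, lat2, lon2,
                             radius_km = EARTH_RADIUS_KM) {
  n <- length(lat1)
  m <- length(lat2)
  outer_lat1 <- matrix(lat1, n, m)
  outer_lon1 <- matrix(lon1, n, m)
  outer_lat2 <- matrix(lat2, n, m, byrow = TRUE)
  outer_lon2 <- matrix(lon2, n, m, byrow = TRUE)
  matrix(
    haversine_km(outer_lat1, outer_lon1, outer_lat2, outer_lon2, radius_km),
    n, m
  )
}

#' Test whether points fall inside a polygon
#'
#' Ray-casting point-in-polygon test on longitude/latitude treated as planar
#' coordinates (adequate for the region scales modelled here). Points on the
#' boundary count as inside, so exclusion rules built on this test are
#' conservative.
#'
#' @param lat,lon Point coordinates (vectorised).
#' @param poly_lat,poly_lon Polygon ring vertices; the ring may be open or
#'   explicitly closed (first vertex repeated last).
#' @return Logical vector.
#' @export
point_in_polygon <- function(lat, lon, poly_lat, poly_lon) {
  if (length(poly_lat) != length(poly_lon)) {
    stop("polygon latitude/longitude lengths differ", call. = FALSE)
  }
  # drop an explicit closing vertex
  np <- length(poly_lat)
  if (np >= 2 && poly_lat[1] == poly_lat[np] && poly_lon[1] == poly_lon[np]) {
    poly_lat <- poly_lat[-np]
    poly_lon <- poly_lon[-np]
  }
  if (length(unique(paste(poly_lat, poly_lon))) < 3) {
    stop("degenerate polygon: fewer than 3 distinct vertices", call. = FALSE)
  }
  check_coords(lat, lon, "query point")
  check_coords(poly_lat, poly_lon, "polygon vertex")
  n <- length(lat)
  inside <- logical(n)
  xs <- poly_lon
  ys <- poly_lat
  nv <- length(xs)
  jseq <- c(nv, seq_len(nv - 1))
  eps <- 1e-12
  for (i in seq_len(n)) {
    x <- lon[i]
    y <- lat[i]
    on_edge <- FALSE
    crossings <- FALSE
    for (v in seq_len(nv)) {
      x1 <- xs[jseq[v]]; y1 <- ys[jseq[v]]
      x2 <- xs[v];       y2 <- ys[v]
      # boundary check: point on segment (x1,y1)-(x2,y2)
      cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      if (abs(cross) < eps &&
          x >= min(x1, x2) - eps && x <= max(x1, x2) + eps &&
          y >= min(y1, y2) - eps && y <= max(y1, y2) + eps) {
        on_edge <- TRUE
        break
      }
      if ((y1 > y) != (y2 > y)) {
        xint <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
        if (x < xint) crossings <- !crossings
      }
    }
    inside[i] <- on_edge || crossings
  }
  inside
}

#' Test whether a straight path passes through a circular no-fly zone
#'
#' Projects the segment and the zone centre into a local equirectangular
#' plane centred on the zone (longitude scaled by the cosine of the zone
#' latitude) and checks whether the segment comes within `radius_km` of the
#' centre. Endpoints inside the disk count as intersecting. The planar
#' approximation is appropriate because zone radii (km) are tiny relative to
#' the earth radius.
#'
#' @param lat1,lon1,lat2,lon2 Segment endpoints in decimal degrees
#'   (vectorised over segments).
#' @param zone_lat,zone_lon Zone centre.
#' @param zone_radius_km Zone radius in km (> 0).
#' @param radius_km Earth radius in km.
#' @return Logical vector, one per segment.
#' @export
segment_intersects_disk <- function(lat1, lon1, lat2, lon2,
                                    zone_lat, zone_lon, zone_radius_km,
                                    radius_km = EARTH_RADIUS_KM) {
  stopifnot(zone_radius_km > 0)
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  check_coords(zone_lat, zone_lon, "zone centre")
  deg <- pi / 180
  coslat <- cos(zone_lat * deg)
  # local plane centred on the zone, axes in km
  ax <- (lon1 - zone_lon) * deg * coslat * radius_km
  ay <- (lat1 - zone_lat) * deg * radius_km
  bx <- (lon2 - zone_lon) * deg * coslat * radius_km
  by <- (lat2 - zone_lat) * deg * radius_km
  dx <- bx - ax
  dy <- by - ay
  len2 <- dx^2 + dy^2
  # parameter of the closest point on the segment to the origin
  t <- ifelse(len2 == 0, 0, pmin(1, pmax(0, -(ax * dx + ay * dy) / len2)))
  cx <- ax + t * dx
  cy <- ay + t * dy
  sqrt(cx^2 + cy^2) <= zone_radius_km
}

#' Nearest facility to a point
#'
#' Finds the facility minimising the haversine distance; ties are broken by
#' the lexicographically lowest facility id.
#'
#' @param lat,lon Query point.
#' @param facilities Tibble with columns `facility_id`, `lat`, `lon`.
#' @param radius_km Earth radius in km.
#' @return A one-row tibble with `facility_id` and `distance_km`.
#' @export
nearest_facility <- function(lat, lon, facilities,
                             radius_km = EARTH_RADIUS_KM) {
  if (is.null(facilities) || nrow(facilities) == 0) {
    stop("facility list is empty", call. = FALSE)
  }
  d <- haversine_km(lat, lon, facilities$lat, facilities$lon, radius_km)
  ord <- order(d, facilities$facility_id)
  tibble::tibble(
    facility_id = facilities$facility_id[ord[1]],
    distance_km = d[ord[1]]
  )
}
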