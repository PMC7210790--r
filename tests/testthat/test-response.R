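# Hand-built equatorial region: distances in km map exactly to degree
# offsets, so responder times can be asserted arithmetically.

test_that("ambulance time is blue-light-reduced road time from the nearest station", {
  # station 10 km east: road time = 60 * 10 * 1.3 / 50 = 15.6 min
  region <- manual_region(facility_at_km("AMB001", "ambulance_station", 10))
  region$facilities <- dplyr::bind_rows(
    region$facilities,
    facility_at_km("CND001", "candidate_base", 50)
  )
  inc <- origin_incident()
  rd <- flat_road()
  expect_equal(ambulance_time(inc, region, rd), 0.75 * 15.6,
               tolerance = 1e-9)
  expect_equal(ambulance_time(inc, region, rd, blue_light_factor = 1),
               15.6, tolerance = 1e-9)
  # co-located station
  region$facilities$lon[region$facilities$facility_id == "AMB001"] <- 0
  region$facilities$lat[region$facilities$facility_id == "AMB001"] <- 0
  expect_equal(ambulance_time(inc, region, rd), 0)
})

test_that("bystander AED time is an unreduced round trip", {
  region <- manual_region(dplyr::bind_rows(
    facility_at_km("AED001", "public_aed", 5),
    facility_at_km("CND001", "candidate_base", 50)
  ))
  inc <- origin_incident()
  rd <- flat_road()
  one_way <- 60 * 5 * 1.3 / 50 # 7.8 min
  expect_equal(aed_time(inc, region, rd), 2 * one_way, tolerance = 1e-9)
})

test_that("drone time honours range (inclusive at 12 km) and no-fly zones", {
  fac <- dplyr::bind_rows(
    facility_at_km("AMB001", "ambulance_station", 100),
    facility_at_km("CND001", "candidate_base", 12),     # exactly in range
    facility_at_km("CND002", "candidate_base", 12.01),  # just out
    facility_at_km("CND003", "candidate_base", -8)      # 8 km west
  )
  region <- manual_region(fac, half_width_deg = 2)
  inc <- origin_incident()
  expect_equal(drone_time(inc, region, "CND001"), 7.2, tolerance = 1e-6)
  expect_true(is.na(drone_time(inc, region, "CND002")))
  # blocked nearest base: a 5 km no-fly disk centred 4.9 km north of the
  # westward flight path blocks CND003 but clears the incident (7 km away)
  # and the eastward path; the clear base at 12 km wins -> 60*12/100 = 7.2
  nfz <- tibble::tibble(zone_id = "NFZ01", lat = 4.9 * deg_per_km(),
                        lon = -5 * deg_per_km(), radius_km = 5)
  blocked <- manual_region(fac, no_fly = nfz)
  t_both <- drone_time(inc, blocked, c("CND001", "CND003"))
  expect_equal(t_both, 7.2, tolerance = 1e-6)
  # without the zone the 8 km base is nearer -> 4.8 min
  expect_equal(drone_time(inc, region, c("CND001", "CND003")), 4.8,
               tolerance = 1e-6)
  expect_true(is.na(drone_time(inc, region, character(0))))
})

test_that("the fastest available responder wins with the documented tie-break", {
  fac <- dplyr::bind_rows(
    facility_at_km("AMB001", "ambulance_station", 10),  # 0.75*15.6 = 11.7
    facility_at_km("AED001", "public_aed", 5),          # 15.6 round trip
    facility_at_km("CND001", "candidate_base", 8)       # 4.8 fly
  )
  region <- manual_region(fac)
  inc <- origin_incident()
  rd <- flat_road()
  after <- simulate_responses(inc, region, "CND001", rd)
  expect_identical(after$winner, "drone")
  expect_equal(after$winner_min, 4.8, tolerance = 1e-6)
  before <- simulate_responses(inc, region, character(0), rd)
  expect_identical(before$winner, "ambulance")
  expect_equal(before$winner_min, 11.7, tolerance = 1e-9)
  expect_true(is.na(before$drone_min))
  # exact ties via co-located responders: all three at the incident give
  # time 0; ambulance is preferred, then drone over the public AED
  fac2 <- dplyr::bind_rows(
    facility_at_km("AMB001", "ambulance_station", 0),
    facility_at_km("AED001", "public_aed", 0),
    facility_at_km("CND001", "candidate_base", 0)
  )
  tie <- simulate_responses(origin_incident(), manual_region(fac2),
                            "CND001", rd)
  expect_equal(tie$ambulance_min, tie$drone_min)
  expect_identical(tie$winner, "ambulance")
  fac3 <- fac2[fac2$facility_id != "AMB001", ]
  tie2 <- simulate_responses(origin_incident(), manual_region(fac3),
                             "CND001", rd)
  expect_equal(tie2$aed_min, tie2$drone_min)
  expect_identical(tie2$winner, "drone")
})

test_that("per-responder overheads are additive", {
  fac <- dplyr::bind_rows(
    facility_at_km("AMB001", "ambulance_station", 10),
    facility_at_km("CND001", "candidate_base", 8)
  )
  region <- manual_region(fac)
  rd <- flat_road()
  rec <- simulate_responses(origin_incident(), region, "CND001", rd,
                            overhead = c(ambulance = 2, public_aed = 0,
                                         drone = 1.5))
  expect_equal(rec$ambulance_min, 0.75 * 15.6 + 2, tolerance = 1e-9)
  expect_equal(rec$drone_min, 4.8 + 1.5, tolerance = 1e-6)
})

test_that("with no active bases the winner is never a drone", {
  region <- tiny_region()
  inc <- generate_incidents(region, 100, seed = 12)
  before <- simulate_responses(inc, region)
  expect_true(all(before$winner %in% c("ambulance", "public_aed")))
  expect_true(all(is.na(before$drone_min)))
})

test_that("drone times never exceed the range/speed bound", {
  region <- tiny_region()
  inc <- generate_incidents(region, 150, seed = 13)
  cands <- region$facilities$facility_id[
    region$facilities$kind == "candidate_base"]
  rec <- simulate_responses(inc, region, cands)
  spec <- drone_spec()
  bound <- 60 * spec$range_km / spec$speed_kmh
  expect_true(all(rec$drone_min[!is.na(rec$drone_min)] <= bound + 1e-9))
})

test_that("adding bases never slows any incident (superset monotonicity)", {
  region <- tiny_region()
  inc <- generate_incidents(region, 120, seed = 14)
  cands <- sort(region$facilities$facility_id[
    region$facilities$kind == "candidate_base"])
  set.seed(15)
  for (i in 1:20) {
    a <- sample(cands, 3)
    b <- union(a, sample(setdiff(cands, a), 2))
    ra <- simulate_responses(inc, region, a)
    rb <- simulate_responses(inc, region, b)
    expect_true(all(rb$winner_min <= ra$winner_min + 1e-12))
  }
})

test_that("mean_response averages winner times and rejects empties", {
  rec <- tibble::tibble(winner_min = c(3, 5, 7))
  expect_equal(mean_response(rec), 5)
  expect_equal(mean_response(rec[2, ]), 5)
  expect_error(mean_response(rec[0, ]), "no response records")
})

test_that("response CSV round trip preserves records and unavailable drones", {
  region <- tiny_region()
  inc <- generate_incidents(region, 40, seed = 16)
  cands <- region$facilities$facility_id[
    region$facilities$kind == "candidate_base"][1:2]
  rec <- simulate_responses(inc, region, cands)
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses(rec, path)
  expect_identical(
    readLines(path, n = 1),
    "incident_id,ambulance_min,aed_min,drone_min,winner,winner_min"
  )
  back <- read_responses(path)
  expect_equal(back$winner_min, rec$winner_min, tolerance = 1e-12)
  expect_identical(is.na(back$drone_min), is.na(rec$drone_min))
})
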