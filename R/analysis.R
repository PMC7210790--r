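#' Sweep the drone-network size and record the best-so-far envelope
#'
#' Runs the genetic algorithm for each network size k = 1..`k_max` and
#' stores both the raw best fitness and the monotone best-so-far envelope
#' (a larger network can always include the smaller one, so the true optimum
#' is non-increasing; the envelope smooths GA noise).
#'
#' @param incidents Incident tibble.
#' @param region A `region`.
#' @param k_max Largest network size to try (>= 1).
#' @param cfg_template A [ga_config()] whose `k` is replaced per sweep
#'   point; its seed is offset by k so sweep points are independent.
#' @param road,spec,blue_light_factor Passed to [evolve()].
#' @param candidates Candidate base ids (default: all in region).
#' @return A tibble of class `sweep_curve` with columns `k`,
#'   `raw_fitness_min`, `best_fitness_min` (the envelope) and a list-column
#'   `best_ids`.
#' @export
sweep_bases <- function(incidents, region, k_max,
                        cfg_template = ga_config(k = 1),
                        road = road_model(), spec = drone_spec(),
                        blue_light_factor = 0.75, candidates = NULL) {
  if (k_max < 1) stop("k_max must be >= 1", call. = FALSE)
  rows <- purrr::map(seq_len(k_max), function(k) {
    cfg <- cfg_template
    cfg$k <- as.integer(k)
    cfg$seed <- as.integer((cfg_template$seed + 7919 * k) %% .Machine$integer.max)
    fit <- evolve(incidents, region, cfg, road, spec, blue_light_factor,
                  candidates)
    tibble::tibble(k = k, raw_fitness_min = fit$best_fitness_min,
                   best_ids = list(fit$best_ids))
  })
  out <- dplyr::bind_rows(rows)
  out$best_fitness_min <- cummin(out$raw_fitness_min)
  out <- out[, c("k", "raw_fitness_min", "best_fitness_min", "best_ids")]
  class(out) <- c("sweep_curve", class(out))
  out
}

#' Choose the network size where returns diminish
#'
#' Returns the smallest k after which every further step improves the
#' best-so-far envelope by less than `rel_threshold` (relative improvement
#' (f(k-1) - f(k)) / f(k-1)). Falls back to the largest k when the curve
#' never plateaus.
#'
#' @param curve A [sweep_bases()] result (or tibble with `k` and
#'   `best_fitness_min`).
#' @param rel_threshold Relative-improvement threshold in (0, 1),
#'   default 0.02.
#' @return The chosen k (integer).
#' @export
select_plateau <- function(curve, rel_threshold = 0.02) {
  if (nrow(curve) == 0) stop("empty sweep curve", call. = FALSE)
  if (rel_threshold <= 0 || rel_threshold >= 1) {
    stop("rel_threshold must be in (0, 1)", call. = FALSE)
  }
  f <- curve$best_fitness_min[order(curve$k)]
  ks <- sort(curve$k)
  if (length(f) == 1) return(ks[1])
  rel <- (f[-length(f)] - f[-1]) / f[-length(f)]
  small <- rel < rel_threshold
  # smallest k such that all subsequent steps are below threshold
  for (i in seq_along(ks)) {
    if (i > length(rel) || all(small[i:length(rel)])) return(ks[i])
  }
  ks[length(ks)]
}

#' Fraction of incidents reached within time thresholds
#'
#' For each threshold t, the fraction of incidents whose winning response
#' time is strictly less than t minutes.
#'
#' @param records Response tibble from [simulate_responses()].
#' @param thresholds_min Threshold vector in minutes, default 3..8.
#' @return Tibble with `threshold_min` and `fraction`.
#' @export
coverage_table <- function(records, thresholds_min = 3:8) {
  if (is.null(records) || nrow(records) == 0) {
    stop("no response records", call. = FALSE)
  }
  tibble::tibble(
    threshold_min = thresholds_min,
    fraction = vapply(thresholds_min,
                      function(t) mean(records$winner_min < t), numeric(1))
  )
}

#' Responder mix: counts and shares by winning responder type
#'
#' @param records Response tibble.
#' @return Tibble with `responder`, `count`, `fraction` covering all three
#'   responder types (zero rows included).
#' @export
responder_mix <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    stop("no response records", call. = FALSE)
  }
  lv <- c("ambulance", "public_aed", "drone")
  counts <- table(factor(records$winner, levels = lv))
  tibble::tibble(
    responder = lv,
    count = as.integer(counts),
    fraction = as.integer(counts) / nrow(records)
  )
}

#' Five-number summary of response times
#'
#' Minimum, first quartile, median, third quartile and maximum, with
#' quartiles by linear interpolation between order statistics.
#'
#' @param times_min Numeric vector of minutes (non-empty).
#' @return Named numeric vector `min`, `q1`, `median`, `q3`, `max`.
#' @export
boxplot_stats <- function(times_min) {
  if (length(times_min) == 0 || any(!is.finite(times_min))) {
    stop("times must be a non-empty finite vector", call. = FALSE)
  }
  q <- quantile(times_min, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  setNames(q, c("min", "q1", "median", "q3", "max"))
}

#' Paired Wilcoxon signed-rank test
#'
#' Tests whether paired before/after response times differ. Zero
#' differences are dropped; |differences| are ranked with average ranks for
#' ties; the statistic W is the smaller of the positive and negative rank
#' sums. The two-sided p-value is exact for n <= 25 effective pairs
#' (the full null distribution over all 2^n sign assignments, computed by
#' dynamic programming with doubled ranks so tied half-ranks stay integral)
#' and a normal approximation with tie correction and continuity correction
#' otherwise. When all differences are zero the test is degenerate and
#' p = 1 is returned.
#'
#' @param before,after Equal-length numeric vectors of paired times.
#' @param method `"auto"` (exact for n <= 25, normal beyond), or force
#'   `"exact"` / `"normal"`.
#' @return Tibble with `statistic` (W), `p_value`, `n_effective`,
#'   `method`.
#' @export
wilcoxon_signed_rank <- function(before, after,
                                 method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (length(before) != length(after)) {
    stop("before and after must have equal length", call. = FALSE)
  }
  d <- after - before
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(tibble::tibble(statistic = 0, p_value = 1, n_effective = 0L,
                          method = "degenerate (all differences zero)"))
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  w <- min(w_pos, w_neg)
  use_exact <- switch(method, auto = n <= 25, exact = TRUE, normal = FALSE)
  if (method == "exact" && n > 30) {
    stop("exact enumeration limited to n <= 30", call. = FALSE)
  }

  if (use_exact) {
    # exact null distribution of W+ over all sign assignments
    r2 <- as.integer(round(2 * r)) # doubled ranks are integers even with ties
    total <- sum(r2)
    dist <- numeric(total + 1) # counts over possible doubled sums 0..total
    dist[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), dist[seq_len(total + 1 - ri)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    wp2 <- as.integer(round(2 * w_pos))
    p_le <- sum(dist[seq_len(wp2 + 1)])
    p_ge <- sum(dist[(wp2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }
  tibble::tibble(statistic = w, p_value = p, n_effective = as.integer(n),
                 method = method)
}

#' Per-trust before/after response-time summary
#'
#' Mean response time before and after the drone network per trust, with a
#' paired Wilcoxon signed-rank p-value on the per-incident times.
#'
#' @param before,after Response tibbles from [simulate_responses()] over
#'   the same incidents (matched by `incident_id`), each carrying
#'   `trust_id`.
#' @return Tibble `trust_id`, `n`, `mean_before_min`, `mean_after_min`,
#'   `p_value`.
#' @export
trust_summary <- function(before, after) {
  stopifnot(identical(before$incident_id, after$incident_id))
  merged <- tibble::tibble(
    trust_id = before$trust_id,
    before_min = before$winner_min,
    after_min = after$winner_min
  )
  merged |>
    dplyr::group_by(.data$trust_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_before_min = mean(.data$before_min),
      mean_after_min = mean(.data$after_min),
      p_value = wilcoxon_signed_rank(.data$before_min,
                                     .data$after_min)$p_value,
      .groups = "drop"
    )
}

#' Lifetime cost of a drone network
#'
#' Purchase plus maintenance over the fleet lifespan:
#' `n_drones * unit_cost * (1 + maintenance_rate * lifespan_years)`.
#'
#' @param n_drones Number of drones/bases (>= 0).
#' @param unit_cost Purchase cost per drone (default 15,000).
#' @param maintenance_rate Annual maintenance as a fraction of purchase
#'   price (default 0.20).
#' @param lifespan_years Service life in years (default 4).
#' @return Total cost in the same currency as `unit_cost`.
#' @export
cost_model <- function(n_drones, unit_cost = 15000, maintenance_rate = 0.20,
                       lifespan_years = 4) {
  if (n_drones < 0 || unit_cost < 0 || maintenance_rate < 0 ||
      lifespan_years < 0) {
    stop("cost inputs must be >= 0", call. = FALSE)
  }
  n_drones * unit_cost * (1 + maintenance_rate * lifespan_years)
}

#' Projected drone-station workload
#'
#' @param annual_events OHCA events per year (>= 0).
#' @param n_stations Number of drone stations (>= 1).
#' @param operators_per_station Trained operators per station (>= 1).
#' @return Tibble with `flights_per_station_per_month` and
#'   `flights_per_operator_per_month`.
#' @export
workload <- function(annual_events, n_stations, operators_per_station = 1) {
  if (n_stations < 1) stop("need at least one station", call. = FALSE)
  if (operators_per_station < 1) stop("need at least one operator", call. = FALSE)
  if (annual_events < 0) stop("annual_events must be >= 0", call. = FALSE)
  per_station <- annual_events / (n_stations * 12)
  tibble::tibble(
    flights_per_station_per_month = per_station,
    flights_per_operator_per_month = per_station / operators_per_station
  )
}

# ---- plots ---------------------------------------------------------------

#' Plot time-threshold coverage before vs after the drone network
#'
#' @param before,after Response tibbles.
#' @param thresholds_min Thresholds in minutes.
#' @return A ggplot.
#' @export
plot_coverage <- function(before, after, thresholds_min = 3:8) {
  d <- dplyr::bind_rows(
    dplyr::mutate(coverage_table(before, thresholds_min),
                  scenario = "before"),
    dplyr::mutate(coverage_table(after, thresholds_min), scenario = "after")
  )
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$threshold_min),
                                  .data$fraction, fill = .data$scenario)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "reached in under (minutes)",
                  y = "share of incidents", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the diminishing-returns sweep curve
#'
#' @param curve A [sweep_bases()] result.
#' @param rel_threshold Plateau threshold passed to [select_plateau()].
#' @return A ggplot with the chosen plateau k marked.
#' @export
plot_sweep <- function(curve, rel_threshold = 0.02) {
  k_star <- select_plateau(curve, rel_threshold)
  ggplot2::ggplot(curve, ggplot2::aes(.data$k, .data$best_fitness_min)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = k_star, linetype = "dashed") +
    ggplot2::labs(x = "number of drone bases",
                  y = "best mean response time (min)") +
    ggplot2::theme_minimal()
}

#' Plot winning-responder mix before vs after
#'
#' @param before,after Response tibbles.
#' @return A ggplot.
#' @export
plot_responder_mix <- function(before, after) {
  d <- dplyr::bind_rows(
    dplyr::mutate(responder_mix(before), scenario = "before"),
    dplyr::mutate(responder_mix(after), scenario = "after")
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$responder, .data$count,
                                  fill = .data$scenario)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "incidents won", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Before/after response-time boxplots per trust
#'
#' @param before,after Response tibbles carrying `trust_id`.
#' @return A ggplot.
#' @export
plot_trust_boxplots <- function(before, after) {
  d <- dplyr::bind_rows(
    dplyr::mutate(before, scenario = "before"),
    dplyr::mutate(after, scenario = "after")
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$trust_id, .data$winner_min,
                                  fill = .data$scenario)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = "response time (min)", fill = NULL) +
    ggplot2::theme_minimal()
}
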