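test_that("sweep envelope is monotone and plateau selection matches hand arithmetic", {
  curve <- tibble::tibble(k = 1:3, best_fitness_min = c(10, 10, 10))
  expect_equal(select_plateau(curve), 1)
  # steps: 20% then 1.25% then ~0.13%; at 5% threshold the answer is k = 2
  curve2 <- tibble::tibble(k = 1:4, best_fitness_min = c(10, 8, 7.9, 7.89))
  expect_equal(select_plateau(curve2, rel_threshold = 0.05), 2)
  # strictly steep curve never plateaus
  curve3 <- tibble::tibble(k = 1:4, best_fitness_min = c(10, 5, 2.5, 1.25))
  expect_equal(select_plateau(curve3, rel_threshold = 0.001), 4)
  expect_equal(select_plateau(curve[1, ]), 1)
  expect_error(select_plateau(curve[0, ]), "empty")
  expect_error(select_plateau(curve, rel_threshold = 0), "threshold")
})

test_that("sweep_bases produces a non-increasing envelope bounded by the oracle", {
  inst <- ga_instance(seed = 201, n_candidates = 6, n_incidents = 25)
  cfg <- ga_config(k = 1, population_size = 12, generations = 15, seed = 4)
  curve <- sweep_bases(inst$incidents, inst$region, k_max = 3,
                       cfg_template = cfg)
  expect_equal(curve$k, 1:3)
  expect_true(all(diff(curve$best_fitness_min) <= 1e-12))
  expect_true(all(curve$best_fitness_min <= curve$raw_fitness_min + 1e-12))
  for (k in 1:3) {
    oracle <- brute_force_best(inst$incidents, inst$region, k = k)
    expect_gte(curve$raw_fitness_min[k], oracle$best_fitness_min - 1e-12)
  }
})

test_that("coverage counts incidents strictly under each threshold", {
  rec <- tibble::tibble(winner_min = c(2, 4, 9))
  cov <- coverage_table(rec, c(3, 8))
  expect_equal(cov$fraction, c(1 / 3, 2 / 3))
  expect_equal(coverage_table(tibble::tibble(winner_min = rep(0, 4)))$fraction,
               rep(1, 6))
  # boundary: a time exactly at the threshold is not counted
  expect_equal(coverage_table(tibble::tibble(winner_min = 3), 3)$fraction, 0)
  set.seed(202)
  rnd <- tibble::tibble(winner_min = rexp(100, 1 / 6))
  expect_true(all(diff(coverage_table(rnd)$fraction) >= 0))
  expect_error(coverage_table(rec[0, ]), "no response records")
})

test_that("responder mix counts and normalises over all three types", {
  rec <- tibble::tibble(winner = c("drone", "drone", "ambulance",
                                   "public_aed"))
  mix <- responder_mix(rec)
  expect_equal(mix$fraction[mix$responder == "drone"], 0.5)
  expect_equal(mix$fraction[mix$responder == "ambulance"], 0.25)
  expect_equal(sum(mix$count), 4)
  expect_equal(sum(mix$fraction), 1, tolerance = 1e-9)
  only_amb <- responder_mix(tibble::tibble(winner = rep("ambulance", 3)))
  expect_equal(only_amb$fraction[only_amb$responder == "drone"], 0)
})

test_that("five-number summary uses linear interpolation between order statistics", {
  expect_equal(unname(boxplot_stats(1:9)["median"]), 5)
  expect_equal(unname(boxplot_stats(c(4, 4, 4))), rep(4, 5))
  # [1,2,3,4]: h = (n-1)p + 1 -> q1 at h=1.75 -> 1.75; q3 at h=3.25 -> 3.25
  expect_equal(unname(boxplot_stats(c(1, 2, 3, 4))),
               c(1, 1.75, 2.5, 3.25, 4))
  set.seed(203)
  x <- rnorm(37)
  s <- boxplot_stats(x)
  expect_true(all(diff(s) >= 0))
  expect_error(boxplot_stats(numeric(0)), "non-empty")
})

test_that("Wilcoxon signed-rank matches exact enumeration and the degenerate case", {
  # all-zero differences
  z <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(z$p_value, 1)
  expect_equal(z$n_effective, 0)
  # n = 5, all positive, distinct: W = 0, p = 2/2^5
  w5 <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))
  expect_equal(w5$statistic, 0)
  expect_equal(w5$p_value, 0.0625)
  expect_match(w5$method, "exact")
})

test_that("exact p-values agree with wilcox.test and with the normal approximation", {
  set.seed(204)
  for (i in 1:20) {
    n <- sample(6:25, 1)
    before <- rnorm(n)
    after <- before + rnorm(n, 0.3)
    # continuous data: no ties, wilcox.test exact applies
    mine <- wilcoxon_signed_rank(before, after)
    ref <- wilcox.test(after, before, paired = TRUE, exact = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
  # exact vs normal approximation at n = 25 within 0.01
  set.seed(205)
  for (i in 1:25) {
    before <- rnorm(25)
    after <- before + rnorm(25, 0.2)
    exact <- wilcoxon_signed_rank(before, after, method = "exact")
    approx <- wilcoxon_signed_rank(before, after, method = "normal")
    expect_lt(abs(exact$p_value - approx$p_value), 0.01)
  }
})

test_that("normal-approximation branch tracks wilcox.test with ties", {
  set.seed(206)
  before <- sample(1:10, 40, replace = TRUE)
  after <- before + sample(c(-2, -1, 1, 2, 3), 40, replace = TRUE)
  mine <- wilcoxon_signed_rank(before, after)
  ref <- wilcox.test(after, before, paired = TRUE, exact = FALSE,
                     correct = TRUE)
  expect_match(mine$method, "normal")
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("cost model reproduces the fleet worked example", {
  expect_equal(cost_model(78), 2106000)
  expect_equal(cost_model(0), 0)
  expect_equal(cost_model(10, maintenance_rate = 0), 150000)
  expect_error(cost_model(-1), ">= 0")
})

test_that("workload projection reproduces the per-station and per-operator figures", {
  w1 <- workload(1400, 78)
  expect_equal(w1$flights_per_station_per_month, 1400 / (78 * 12))
  expect_lt(w1$flights_per_station_per_month, 2)
  w2 <- workload(1400, 78, operators_per_station = 2)
  expect_lt(w2$flights_per_operator_per_month, 1)
  expect_equal(workload(0, 10)$flights_per_station_per_month, 0)
  expect_error(workload(100, 0), "station")
})

test_that("before/after tables show the dominance implied by superset monotonicity", {
  region <- rural_region()
  inc <- generate_incidents(region, 300, seed = 207)
  bases <- region$facilities$facility_id[
    region$facilities$kind == "candidate_base"]
  before <- simulate_responses(inc, region)
  after <- simulate_responses(inc, region, bases)
  cov_b <- coverage_table(before)
  cov_a <- coverage_table(after)
  expect_true(all(cov_a$fraction >= cov_b$fraction))
  ts <- trust_summary(before, after)
  expect_true(all(ts$mean_after_min <= ts$mean_before_min + 1e-12))
  mix <- responder_mix(before)
  expect_equal(mix$fraction[mix$responder == "drone"], 0)
})

test_that("report plots build without error", {
  region <- rural_region()
  inc <- generate_incidents(region, 120, seed = 208)
  bases <- region$facilities$facility_id[
    region$facilities$kind == "candidate_base"]
  before <- simulate_responses(inc, region)
  after <- simulate_responses(inc, region, bases)
  expect_s3_class(plot_coverage(before, after), "ggplot")
  expect_s3_class(plot_responder_mix(before, after), "ggplot")
  expect_s3_class(plot_trust_boxplots(before, after), "ggplot")
  curve <- tibble::tibble(k = 1:4, best_fitness_min = c(9, 7, 6.9, 6.89))
  expect_s3_class(plot_sweep(curve), "ggplot")
})
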