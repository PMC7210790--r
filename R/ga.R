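#' Genetic algorithm configuration
#'
#' @param k Chromosome size: the number of drone bases in each candidate
#'   network.
#' @param population_size Chromosomes per generation (default 50).
#' @param generations Number of generations (default 100).
#' @param mutation_rate Probability a crossover child is mutated
#'   (default 0.10).
#' @param elite_count Fittest chromosomes carried over unchanged
#'   (default 2).
#' @param seed Integer seed; mandatory for reproducibility.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(k, population_size = 50, generations = 100,
                      mutation_rate = 0.10, elite_count = 2, seed = 1L) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (population_size < elite_count + 2) {
    stop("population_size must be >= elite_count + 2", call. = FALSE)
  }
  if (mutation_rate < 0 || mutation_rate > 1) {
    stop("mutation_rate must be in [0, 1]", call. = FALSE)
  }
  if (generations < 1) stop("generations must be >= 1", call. = FALSE)
  structure(
    list(k = as.integer(k), population_size = as.integer(population_size),
         generations = as.integer(generations),
         mutation_rate = mutation_rate,
         elite_count = as.integer(elite_count), seed = as.integer(seed)),
    class = "ga_config"
  )
}

new_chromosome <- function(base_ids) sort(base_ids)

#' Initial GA population
#'
#' Each chromosome is a uniform random k-subset of the candidate base ids,
#' drawn without replacement.
#'
#' @param candidates Character vector of candidate base ids.
#' @param cfg A [ga_config()].
#' @return List of chromosomes (sorted character vectors of length `k`).
#' @export
init_population <- function(candidates, cfg) {
  if (cfg$k > length(candidates)) {
    stop("k exceeds the number of candidate bases", call. = FALSE)
  }
  purrr::map(seq_len(cfg$population_size), function(i) {
    new_chromosome(sample(candidates, cfg$k))
  })
}

#' Set-preserving crossover of two drone-base networks
#'
#' The child is a uniform random k-subset of the union of the parents'
#' genes; identical parents reproduce themselves exactly.
#'
#' @param a,b Chromosomes (character vectors) of equal size.
#' @return A chromosome of the same size.
#' @export
crossover <- function(a, b) {
  if (length(a) != length(b)) {
    stop("parents have different chromosome sizes", call. = FALSE)
  }
  u <- union(a, b)
  if (length(u) <= length(a)) return(new_chromosome(a))
  new_chromosome(sample(u, length(a)))
}

#' Mutate a drone-base network
#'
#' With probability `rate`, one uniformly chosen gene is replaced by a
#' uniformly chosen candidate not already present; otherwise the chromosome
#' is returned unchanged. When every candidate is already in the chromosome
#' there is nothing to mutate.
#'
#' @param chrom Chromosome (character vector).
#' @param candidates All candidate base ids.
#' @param rate Mutation probability in \[0, 1\].
#' @return A chromosome of the same size.
#' @export
mutate_chromosome <- function(chrom, candidates, rate = 0.10) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]", call. = FALSE)
  if (runif(1) >= rate) return(chrom)
  pool <- setdiff(candidates, chrom)
  if (!length(pool)) return(chrom)
  out <- chrom
  out[sample.int(length(out), 1)] <- sample(pool, 1)
  new_chromosome(out)
}

#' Optimise drone-base placement with a genetic algorithm
#'
#' Evolves fixed-size sets of candidate drone bases to minimise the mean
#' response time over the incident set. Each generation the population is
#' ranked by fitness; the elites carry over unchanged; consecutive pairs in
#' descending fitness order are crossed over, each child mutated with
#' probability `mutation_rate`; the population is refilled with random
#' chromosomes. Fitness values are cached by base-set, so repeated
#' chromosomes are never re-simulated. The best-ever network is tracked and
#' its fitness is non-increasing across generations.
#'
#' @param incidents Incident tibble.
#' @param region A `region`.
#' @param cfg A [ga_config()].
#' @param road A [road_model()].
#' @param spec A [drone_spec()].
#' @param blue_light_factor Ambulance blue-light multiplier.
#' @param candidates Candidate base ids; defaults to every
#'   `candidate_base` facility in the region.
#' @return An object of class `drone_ga`: `best_ids`, `best_fitness_min`,
#'   `history` (tibble `generation`, `best_fitness_min`,
#'   `mean_fitness_min`), `config`, and `n_incidents`.
#' @seealso [brute_force_best()] for the exhaustive oracle.
#' @export
evolve <- function(incidents, region, cfg, road = road_model(),
                   spec = drone_spec(), blue_light_factor = 0.75,
                   candidates = NULL) {
  stopifnot(inherits(cfg, "ga_config"))
  if (nrow(incidents) == 0) stop("no incidents to optimise over", call. = FALSE)
  ctx <- response_context(incidents, region, road, spec, blue_light_factor)
  if (is.null(candidates)) candidates <- ctx$candidate_ids
  if (cfg$k > length(candidates)) {
    stop("k exceeds the number of candidate bases", call. = FALSE)
  }
  set.seed(cfg$seed)

  cache <- new.env(parent = emptyenv())
  fitness <- function(chrom) {
    key <- paste(chrom, collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- context_fitness(ctx, chrom)
    cache[[key]] <- f
    f
  }

  pop <- init_population(candidates, cfg)
  best_ids <- NULL
  best_fit <- Inf
  history <- vector("list", cfg$generations)

  for (g in seq_len(cfg$generations)) {
    fit <- vapply(pop, fitness, numeric(1))
    ord <- order(fit)
    pop <- pop[ord]
    fit <- fit[ord]
    if (fit[1] < best_fit) {
      best_fit <- fit[1]
      best_ids <- pop[[1]]
    }
    history[[g]] <- tibble::tibble(
      generation = g, best_fitness_min = best_fit,
      mean_fitness_min = mean(fit)
    )

    elites <- pop[seq_len(min(cfg$elite_count, length(pop)))]
    children <- list()
    i <- 1
    while (i + 1 <= length(pop)) {
      child <- crossover(pop[[i]], pop[[i + 1]])
      child <- mutate_chromosome(child, candidates, cfg$mutation_rate)
      children <- c(children, list(child))
      i <- i + 2
    }
    nxt <- c(elites, children)
    while (length(nxt) < cfg$population_size) {
      nxt <- c(nxt, list(new_chromosome(sample(candidates, cfg$k))))
    }
    pop <- nxt[seq_len(cfg$population_size)]
  }

  structure(
    list(best_ids = best_ids, best_fitness_min = best_fit,
         history = dplyr::bind_rows(history), config = cfg,
         n_incidents = nrow(incidents), candidates = candidates),
    class = "drone_ga"
  )
}

#' @export
print.drone_ga <- function(x, ...) {
  cat("<drone_ga> k =", x$config$k, "bases;",
      x$config$generations, "generations, population",
      x$config$population_size, "\n")
  cat("best mean response time:", format(x$best_fitness_min, digits = 5),
      "min\n")
  cat("best network:", paste(x$best_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy the per-generation fitness history of a GA run
#'
#' @param x A `drone_ga` object.
#' @param ... Unused.
#' @return The history tibble (`generation`, `best_fitness_min`,
#'   `mean_fitness_min`).
#' @method tidy drone_ga
#' @export
tidy.drone_ga <- function(x, ...) x$history

#' One-row summary of a GA run
#'
#' @param x A `drone_ga` object.
#' @param ... Unused.
#' @return Tibble with `k`, `best_fitness_min`, `generations`,
#'   `population_size`, `n_incidents`.
#' @method glance drone_ga
#' @export
glance.drone_ga <- function(x, ...) {
  tibble::tibble(
    k = x$config$k,
    best_fitness_min = x$best_fitness_min,
    generations = x$config$generations,
    population_size = x$config$population_size,
    n_incidents = x$n_incidents
  )
}

#' @rdname tidy.drone_ga
#' @param object A `drone_ga` object.
#' @method autoplot drone_ga
#' @export
autoplot.drone_ga <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"generation",
                           names_to = "series", values_to = "fitness_min")
  ggplot2::ggplot(h, ggplot2::aes(.data$generation, .data$fitness_min,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "mean response time (min)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Exhaustive search over all k-subsets of candidate bases
#'
#' The validation oracle for [evolve()]: evaluates every k-subset and
#' returns the global minimiser of mean response time. Ties are broken
#' lexicographically on the sorted base ids. Refuses instances with more
#' than `cap` combinations.
#'
#' @inheritParams evolve
#' @param k Network size.
#' @param cap Maximum number of subsets to enumerate (default 20,000).
#' @return List with `best_ids` and `best_fitness_min`.
#' @export
brute_force_best <- function(incidents, region, k, road = road_model(),
                             spec = drone_spec(), blue_light_factor = 0.75,
                             candidates = NULL, cap = 20000) {
  ctx <- response_context(incidents, region, road, spec, blue_light_factor)
  if (is.null(candidates)) candidates <- ctx$candidate_ids
  candidates <- sort(candidates)
  n <- length(candidates)
  if (k > n) stop("k exceeds the number of candidate bases", call. = FALSE)
  if (choose(n, k) > cap) {
    stop("refusing exhaustive search: C(", n, ", ", k, ") exceeds cap ",
         cap, call. = FALSE)
  }
  combos <- combn(candidates, k, simplify = FALSE)
  fits <- vapply(combos, function(ids) context_fitness(ctx, ids), numeric(1))
  keys <- vapply(combos, paste, character(1), collapse = "|")
  ord <- order(fits, keys)
  list(best_ids = combos[[ord[1]]], best_fitness_min = fits[ord[1]])
}
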