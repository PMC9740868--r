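#' Configuration for the real-coded genetic algorithm
#'
#' Defaults follow the study configuration: population size NP = 50,
#' crossover probability Pc = 0.8, mutation probability Pm = 0.2, individual
#' length L = 4 (one real gene per extraction factor), 100 generations with
#' one elite individual.
#'
#' @param bounds A `L x 2` matrix of per-gene (low, high) bounds; defaults to
#'   the factor box of [sep_factor_space()].
#' @param population_size Number of individuals NP (>= 2).
#' @param crossover_prob Probability Pc of arithmetic crossover per pair.
#' @param mutation_prob Probability Pm of uniform-reset mutation per gene.
#' @param generations Number of generations to run (no early stopping).
#' @param elitism Number of best individuals copied unchanged each generation.
#' @param seed Integer seed.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(bounds = NULL, population_size = 50,
                      crossover_prob = 0.8, mutation_prob = 0.2,
                      generations = 100, elitism = 1, seed = 1L) {
  if (is.null(bounds)) {
    fs <- sep_factor_space()
    bounds <- cbind(fs$low, fs$high)
  }
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2 || !all(is.finite(bounds)) ||
      any(bounds[, 1] >= bounds[, 2]))
    stop("bounds must be a L x 2 matrix of finite (low, high) with low < high")
  if (population_size < 2) stop("population_size must be >= 2")
  if (crossover_prob < 0 || crossover_prob > 1 ||
      mutation_prob < 0 || mutation_prob > 1)
    stop("crossover_prob and mutation_prob must lie in [0, 1]")
  if (elitism < 1 || elitism > population_size)
    stop("elitism must be in 1..population_size")
  structure(list(bounds = bounds, population_size = as.integer(population_size),
                 crossover_prob = crossover_prob, mutation_prob = mutation_prob,
                 generations = as.integer(generations),
                 elitism = as.integer(elitism), seed = as.integer(seed),
                 length = nrow(bounds)),
            class = "ga_config")
}

#' Seeded uniform initial population
#'
#' @param config A [ga_config()].
#' @return A `NP x L` matrix with genes i.i.d. uniform within bounds.
#' @export
ga_init_population <- function(config) {
  NP <- config$population_size
  L <- config$length
  local_rng(config$seed, {
    pop <- matrix(stats::runif(NP * L), NP, L)
    sweep(sweep(pop, 2, config$bounds[, 2] - config$bounds[, 1], "*"),
          2, config$bounds[, 1], "+")
  })
}

clip_to_bounds <- function(pop, bounds) {
  pop <- pmax(pop, matrix(bounds[, 1], nrow(pop), ncol(pop), byrow = TRUE))
  pmin(pop, matrix(bounds[, 2], nrow(pop), ncol(pop), byrow = TRUE))
}

#' Maximize a fitness function by a real-coded genetic algorithm
#'
#' Each generation: evaluate fitness, carry the `elitism` best individuals
#' over unchanged, fill the rest of the population by fitness-proportional
#' (roulette) selection, whole-arithmetic crossover with probability Pc per
#' pair, and per-gene uniform-reset mutation with probability Pm, clipping to
#' the bounds. Roulette weights are min-shifted so negative fitness values are
#' handled; a constant population gets uniform weights. Elitism guarantees a
#' non-decreasing best-fitness trace.
#'
#' @param fitness Function mapping a length-`L` numeric vector to a finite
#'   scalar (larger is better).
#' @param config A [ga_config()].
#' @return An object of class `ga_result`: `best_individual`, `best_fitness`,
#'   `fitness_trace` (per-generation population best) and `generations_run`.
#' @export
#' @examples
#' fit <- fit_quadratic(sep_design())
#' res <- ga_evolve(function(x) predict(fit, x), ga_config(seed = 1))
#' res$best_fitness
ga_evolve <- function(fitness, config = ga_config()) {
  NP <- config$population_size
  L <- config$length
  local_rng(config$seed, {
    pop <- matrix(stats::runif(NP * L), NP, L)
    pop <- sweep(sweep(pop, 2, config$bounds[, 2] - config$bounds[, 1], "*"),
                 2, config$bounds[, 1], "+")
    trace <- numeric(config$generations)
    best_x <- NULL
    best_f <- -Inf
    for (g in seq_len(config$generations)) {
      f <- apply(pop, 1, fitness)
      if (!all(is.finite(f))) {
        bad <- which(!is.finite(f))[1]
        stop("non-finite fitness ", f[bad], " for individual (",
             paste(signif(pop[bad, ], 6), collapse = ", "), ")")
      }
      gen_best <- which.max(f)
      if (f[gen_best] > best_f) {
        best_f <- f[gen_best]
        best_x <- pop[gen_best, ]
      }
      trace[g] <- f[gen_best]
      if (g == config$generations) break

      elite_idx <- order(f, decreasing = TRUE)[seq_len(config$elitism)]
      n_off <- NP - config$elitism
      if (n_off == 0) next  # fully elitist: population frozen

      w <- f - min(f)
      if (sum(w) == 0) w <- rep(1, NP)
      parents <- pop[sample.int(NP, n_off, replace = TRUE, prob = w), ,
                     drop = FALSE]
      if (n_off >= 2) {
        for (i in seq(1, n_off - n_off %% 2, by = 2)) {
          if (stats::runif(1) < config$crossover_prob) {
            alpha <- stats::runif(1)
            p1 <- parents[i, ]; p2 <- parents[i + 1, ]
            parents[i, ] <- alpha * p1 + (1 - alpha) * p2
            parents[i + 1, ] <- alpha * p2 + (1 - alpha) * p1
          }
        }
      }
      mut <- matrix(stats::runif(n_off * L) < config$mutation_prob, n_off, L)
      if (any(mut)) {
        fresh <- matrix(stats::runif(n_off * L), n_off, L)
        fresh <- sweep(sweep(fresh, 2, config$bounds[, 2] - config$bounds[, 1],
                             "*"), 2, config$bounds[, 1], "+")
        parents[mut] <- fresh[mut]
      }
      pop <- rbind(pop[elite_idx, , drop = FALSE],
                   clip_to_bounds(parents, config$bounds))
    }
    structure(list(best_individual = best_x, best_fitness = best_f,
                   fitness_trace = trace,
                   generations_run = config$generations),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("GA result after %d generations: best fitness %.4f\n",
              x$generations_run, x$best_fitness))
  cat("best individual:", paste(signif(x$best_individual, 6), collapse = ", "),
      "\n")
  invisible(x)
}

#' Optimize extraction conditions over a surrogate model
#'
#' Runs the genetic algorithm with the surrogate's predicted protein content
#' as the fitness function, over the factor box, and reports the best
#' conditions in actual units.
#'
#' @param surrogate A trained `neural_surrogate` (or any object with a
#'   `predict` method over 4-factor settings, e.g. an `rsm_fit`).
#' @param config A [ga_config()]; its bounds default to the surrogate's factor
#'   box when `space` is supplied.
#' @param space Optional [factor_space()] providing the bounds.
#' @return A `ga_result` with `best_individual` in actual units (degC, h,
#'   mol/L, mL/g) and `best_fitness` in mg/g.
#' @export
optimize_extraction <- function(surrogate, config = NULL, space = NULL) {
  if (!is.null(space)) {
    bounds <- cbind(space$low, space$high)
    config <- if (is.null(config)) ga_config(bounds = bounds)
              else { config$bounds <- bounds; config$length <- nrow(bounds); config }
  } else if (is.null(config)) {
    config <- ga_config()
  }
  res <- ga_evolve(function(x) predict(surrogate, x), config)
  names(res$best_individual) <-
    if (!is.null(space)) space$names else rownames(config$bounds)
  res
}

#' Write a GA result and its fitness trace
#'
#' @param result A `ga_result`.
#' @param path JSON output path for the result; the per-generation trace goes
#'   to `trace_path` as CSV when given.
#' @param trace_path Optional CSV path.
#' @return `path`, invisibly.
#' @export
write_ga_json <- function(result, path, trace_path = NULL) {
  jsonlite::write_json(
    list(best_individual = result$best_individual,
         best_fitness = result$best_fitness,
         generations_run = result$generations_run),
    path, digits = NA, auto_unbox = TRUE)
  if (!is.null(trace_path))
    utils::write.csv(data.frame(generation = seq_along(result$fitness_trace),
                                best_fitness = result$fitness_trace),
                     trace_path, row.names = FALSE)
  invisible(path)
}
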