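ARCHITECTURES <- c("FCNN", "CNN", "RNN")

#' Genetic-algorithm configuration
#'
#' Defaults follow the architecture-selection setup: population 10, mutation
#' probability 0.2, crossover probability 0.8, tournament selection of size
#' 3, at most 100 fitness evaluations (repeat evaluations of an already-seen
#' assignment count against the budget), elitism of 1.
#'
#' @param population_size individuals per generation.
#' @param mutation_prob per-gene probability of uniform re-assignment.
#' @param crossover_prob probability a child pair is formed by uniform
#'   crossover (otherwise the parents are copied).
#' @param tournament_size individuals drawn per tournament.
#' @param max_evaluations total fitness-evaluation budget.
#' @param elitism number of best individuals copied unchanged.
#' @param seed RNG seed for the whole run.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 10L, mutation_prob = 0.2,
                      crossover_prob = 0.8, tournament_size = 3L,
                      max_evaluations = 100L, elitism = 1L, seed = 1L) {
  stopifnot(population_size >= 1L, tournament_size >= 1L, elitism >= 0L,
            mutation_prob >= 0, mutation_prob <= 1,
            crossover_prob >= 0, crossover_prob <= 1)
  if (max_evaluations < population_size)
    stop("max_evaluations must cover at least the initial population")
  structure(list(population_size = as.integer(population_size),
                 mutation_prob = mutation_prob,
                 crossover_prob = crossover_prob,
                 tournament_size = as.integer(tournament_size),
                 max_evaluations = as.integer(max_evaluations),
                 elitism = as.integer(elitism),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Select per-gene architectures with a generational GA
#'
#' A solution is a length-n vector over \{FCNN, CNN, RNN\}, one architecture
#' per agent. Selection is by tournament, recombination by uniform
#' crossover, mutation by per-gene uniform re-assignment; the best
#' individual of each generation survives unchanged (elitism), so the
#' best-ever fitness is non-decreasing over the run. The run stops when the
#' evaluation budget is exhausted.
#'
#' @param fitness_fn function taking a character vector of architectures and
#'   returning a scalar fitness (higher is better).
#' @param n solution length (number of genes).
#' @param config a [ga_config()].
#' @param init_population optional list of assignments seeded into the
#'   initial population (e.g. the three uniform single-architecture
#'   assignments); the remainder is drawn uniformly at random.
#' @return A list of class `ga_result`: `best` (assignment), `best_fitness`,
#'   `history` (data frame: evaluation index, solution string, fitness,
#'   best-so-far).
#' @export
run_ga <- function(fitness_fn, n, config = ga_config(),
                   init_population = NULL) {
  stopifnot(inherits(config, "ga_config"), n >= 1L)
  set.seed(config$seed)
  pop_size <- config$population_size
  history <- data.frame(evaluation = integer(0), solution = character(0),
                        fitness = numeric(0), best_so_far = numeric(0))
  best <- NULL; best_fit <- -Inf; n_eval <- 0L

  evaluate <- function(sol) {
    stopifnot(length(sol) == n, all(sol %in% ARCHITECTURES))
    f <- fitness_fn(sol)
    n_eval <<- n_eval + 1L
    if (f > best_fit) { best_fit <<- f; best <<- sol }
    history[nrow(history) + 1L, ] <<- list(n_eval, paste(sol, collapse = ","),
                                           f, best_fit)
    f
  }
  random_solution <- function() sample(ARCHITECTURES, n, replace = TRUE)

  pop <- init_population %||% list()
  pop <- lapply(pop, function(s) { stopifnot(length(s) == n); s })
  while (length(pop) < pop_size) pop[[length(pop) + 1L]] <- random_solution()
  pop <- pop[seq_len(pop_size)]
  fit <- vapply(pop, evaluate, numeric(1))

  tournament <- function() {
    idx <- sample.int(pop_size, config$tournament_size, replace = TRUE)
    pop[[idx[which.max(fit[idx])]]]
  }

  while (n_eval < config$max_evaluations) {
    children <- list()
    if (config$elitism > 0L) {
      elite <- order(fit, decreasing = TRUE)[seq_len(config$elitism)]
      children <- pop[elite]
    }
    while (length(children) < pop_size) {
      p1 <- tournament(); p2 <- tournament()
      if (stats::runif(1) < config$crossover_prob) {
        mask <- stats::runif(n) < 0.5
        c1 <- ifelse(mask, p1, p2)
        c2 <- ifelse(mask, p2, p1)
      } else {
        c1 <- p1; c2 <- p2
      }
      for (child in list(c1, c2)) {
        mut <- stats::runif(n) < config$mutation_prob
        if (any(mut)) child[mut] <- sample(ARCHITECTURES, sum(mut), replace = TRUE)
        if (length(children) < pop_size)
          children[[length(children) + 1L]] <- child
      }
    }
    new_fit <- numeric(pop_size)
    for (i in seq_len(pop_size)) {
      if (n_eval >= config$max_evaluations) {
        # budget exhausted mid-generation: keep the already-evaluated prefix
        children <- children[seq_len(i - 1L)]
        new_fit <- new_fit[seq_len(i - 1L)]
        break
      }
      new_fit[i] <- evaluate(children[[i]])
    }
    if (length(children) < pop_size) break
    pop <- children
    fit <- new_fit
  }
  structure(list(best = best, best_fitness = best_fit, history = history,
                 config = config),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("ga_result: best fitness %.6g after %d evaluations\n  best: %s\n",
              x$best_fitness, nrow(x$history), paste(x$best, collapse = " ")))
  invisible(x)
}

#' Fitness of an architecture assignment
#'
#' Builds a fitness function over architecture assignments for a dataset:
#' for assignment S, gene i's agent is trained (or fetched from the cache)
#' with architecture `S[i]`, the resulting environment is simulated from the
#' evaluation target's first m observations over its full length, and the
#' fitness is the negated aggregate mean-squared error against the target
#' (higher is better). The cache is keyed by (gene, architecture), so
#' assignments sharing components share trained agents; a training failure
#' yields `-Inf` with a message.
#'
#' @param ds a normalized `expression_dataset`.
#' @param m window length.
#' @param train_experiments experiment indices used to build supervised sets.
#' @param tuning_budget random-search trials per (gene, architecture); 0
#'   trains the default spec directly.
#' @param seed base RNG seed for training.
#' @param clip simulation output clipping, see [step_aes()].
#' @return A function `f(assignment) -> fitness` with attributes `cache`
#'   (environment of trained agents) and `target` (the evaluation matrix).
#' @export
make_aes_fitness <- function(ds, m, train_experiments = seq_along(ds$experiments),
                             tuning_budget = 0L, seed = 1L, clip = c(0, 1.5)) {
  stopifnot(inherits(ds, "expression_dataset"), ds$normalized)
  target <- evaluation_target(ds)
  n <- n_genes(ds)
  init <- seed_initial_state(t(target), m)
  cache <- new.env(parent = emptyenv())

  get_agent <- function(gene, arch) {
    key <- paste(gene, arch, sep = "/")
    if (!is.null(cache[[key]])) return(cache[[key]])
    sup <- make_supervised(ds, gene, m, experiments = train_experiments)
    agent <- if (tuning_budget > 0L) {
      tune_hyperparameters(arch, sup, budget = tuning_budget,
                           seed = seed + gene)$agent
    } else {
      train_agent(agent_spec(arch), sup, seed = seed + gene)
    }
    cache[[key]] <- agent
    agent
  }

  f <- function(assignment) {
    stopifnot(length(assignment) == n)
    agents <- tryCatch(
      lapply(seq_len(n), function(i) get_agent(i, assignment[i])),
      error = function(e) e)
    if (inherits(agents, "error")) {
      message(sprintf("fitness: training failed (%s); assigning -Inf",
                      conditionMessage(agents)))
      return(-Inf)
    }
    trace <- simulate_aes(agents, init, ncol(target), clip = clip)
    report <- evaluate_aes(trace, target, m)
    -report$err_mse
  }
  attr(f, "cache") <- cache
  attr(f, "target") <- target
  f
}
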