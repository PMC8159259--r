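#' Configuration of the evolutionary search
#'
#' Defaults follow the study conditions used throughout the package: a
#' population of 100 molecules evolved for 30 generations with 10% elitism,
#' 2-way tournament parent selection, crossover for all non-elite children,
#' and a 5% chance each of mutation and recombination per child; initial
#' molecules are scrambled by 500 mutation steps.
#'
#' @param population_size,n_generations,tournament_size,init_mutations
#'   Positive counts.
#' @param elitism_rate Fraction of the population carried over unchanged
#'   (rounded to a whole number of individuals).
#' @param p_mutation,p_recombination Per-child probabilities.
#' @param seed Optional integer seed; the whole run is reproducible given
#'   the seed, space, config and oracle.
#' @param early_stop Stop when the mean fitness improves by less than
#'   `early_stop_tol` over `early_stop_patience` generations (off by
#'   default: a fixed number of generations is the documented behaviour).
#' @param early_stop_tol,early_stop_patience Early-stopping parameters.
#' @return An object of class `azc_ea_config`.
#' @export
ea_config <- function(population_size = 100L, n_generations = 30L,
                      elitism_rate = 0.10, p_mutation = 0.05,
                      p_recombination = 0.05, tournament_size = 2L,
                      init_mutations = 500L, seed = NULL,
                      early_stop = FALSE, early_stop_tol = 1e-4,
                      early_stop_patience = 5L) {
  stopifnot(
    is_count(population_size), is_count(tournament_size),
    is.numeric(n_generations), n_generations >= 0, n_generations == round(n_generations),
    is_prob(elitism_rate), is_prob(p_mutation), is_prob(p_recombination),
    is.numeric(init_mutations), init_mutations >= 0,
    is.logical(early_stop), is_count(early_stop_patience),
    is.numeric(early_stop_tol), early_stop_tol >= 0
  )
  structure(
    list(
      population_size = as.integer(population_size),
      n_generations = as.integer(n_generations),
      elitism_rate = elitism_rate,
      p_mutation = p_mutation,
      p_recombination = p_recombination,
      tournament_size = as.integer(tournament_size),
      init_mutations = as.integer(init_mutations),
      seed = seed,
      early_stop = early_stop,
      early_stop_tol = early_stop_tol,
      early_stop_patience = as.integer(early_stop_patience)
    ),
    class = "azc_ea_config"
  )
}

#' Build a random initial population
#'
#' @param space An [space_definition()].
#' @param config An [ea_config()].
#' @return A tibble with columns `canonical_key` and `mol` (duplicates are
#'   allowed within a population).
#' @export
initialise_population <- function(space, config = ea_config()) {
  stopifnot(inherits(space, "azc_space"), inherits(config, "azc_ea_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  mols <- replicate(config$population_size,
                    random_molecule(space, config$init_mutations),
                    simplify = FALSE)
  tibble(
    canonical_key = vapply(mols, canonical_key, character(1)),
    mol = mols
  )
}

# evaluate any not-yet-cached molecules; the cache guarantees one oracle
# call per unique canonical key.  Oracle errors / NULL results are recorded
# as +Inf fitness.
evaluate_population <- function(pop, oracle, fitness, cache) {
  for (i in seq_len(nrow(pop))) {
    key <- pop$canonical_key[i]
    if (!is.null(get0(key, envir = cache$fit, inherits = FALSE))) next
    props <- tryCatch(oracle(pop$mol[[i]]), error = function(e) NULL)
    fit <- if (is.null(props)) Inf else
      tryCatch(fitness_value(props, fitness), error = function(e) Inf)
    if (length(fit) != 1L || is.na(fit)) fit <- Inf
    assign(key, fit, envir = cache$fit)
    cache$order <- c(cache$order, key)
    if (is.infinite(fit)) cache$failed <- c(cache$failed, key)
  }
  pop$fitness <- vapply(pop$canonical_key,
                        function(k) get(k, envir = cache$fit, inherits = FALSE),
                        numeric(1), USE.NAMES = FALSE)
  pop
}

new_fitness_cache <- function() {
  e <- new.env(parent = emptyenv())
  e$fit <- new.env(parent = emptyenv(), hash = TRUE)
  e$order <- character(0)
  e$failed <- character(0)
  e
}

# deterministic winner of one tournament: fittest of `k` distinct random
# individuals, exact fitness ties broken by canonical key
tournament_pick <- function(pop, k) {
  idx <- sample.int(nrow(pop), min(k, nrow(pop)))
  sub <- pop[idx, ]
  sub <- sub[order(sub$fitness, sub$canonical_key), ]
  sub[1L, ]
}

#' Advance an evaluated population by one generation
#'
#' The top `elitism_rate` of the population (by fitness, ties broken by
#' canonical key) is carried over unchanged; the remainder is filled with
#' children of crossover between tournament-selected parents, each child
#' then mutated with probability `p_mutation` and recombined with
#' probability `p_recombination`.  A failed crossover falls back to copying
#' the parents.  New molecules are evaluated through the shared fitness
#' cache, so no molecule is ever sent to the oracle twice in a run.
#'
#' @param pop An evaluated population tibble (with `fitness`).
#' @param space,config,oracle,fitness As in [run_evolution()].
#' @param cache Internal fitness cache environment; created when omitted.
#' @return The next evaluated population tibble.
#' @export
next_generation <- function(pop, space, config, oracle,
                            fitness = fitness_spec(), cache = NULL) {
  stopifnot(!is.null(pop$fitness))
  if (is.null(cache)) {
    cache <- new_fitness_cache()
    pop <- evaluate_population(pop, oracle, fitness, cache)
  }
  n <- config$population_size
  n_elite <- min(n, max(0L, round(config$elitism_rate * n)))
  ord <- order(pop$fitness, pop$canonical_key)
  elites <- pop[ord[seq_len(n_elite)], c("canonical_key", "mol")]

  kids_key <- character(0)
  kids_mol <- list()
  add_kid <- function(m) {
    kids_mol[[length(kids_mol) + 1L]] <<- m
    kids_key <<- c(kids_key, canonical_key(m))
  }
  while (length(kids_mol) < n - n_elite) {
    pa <- tournament_pick(pop, config$tournament_size)
    pb <- tournament_pick(pop, config$tournament_size)
    kids <- mol_crossover(pa$mol[[1L]], pb$mol[[1L]],
                          min_rings = space$molsize_min,
                          max_rings = space$molsize_max)
    if (is.null(kids)) kids <- list(pa$mol[[1L]], pb$mol[[1L]])
    for (kid in kids) {
      if (length(kids_mol) >= n - n_elite) break
      if (stats::runif(1) < config$p_mutation) {
        kid <- mol_mutation(kid, space$smarts)
      }
      if (stats::runif(1) < config$p_recombination) {
        kid <- mol_recombination(kid)
      }
      add_kid(kid)
    }
  }
  nxt <- dplyr::bind_rows(
    elites,
    tibble(canonical_key = kids_key, mol = kids_mol)
  )
  evaluate_population(nxt, oracle, fitness, cache)
}

#' Run the evolutionary search
#'
#' Builds a random initial population, then creates generations until the
#' configured number is reached (or, optionally, until the mean fitness
#' stalls).  Every unique molecule is evaluated exactly once through a
#' canonical-key fitness cache.
#'
#' @param space An [space_definition()].
#' @param config An [ea_config()].
#' @param oracle A property oracle: a function `azc_mol -> ` one-row
#'   property data frame (see [surrogate_oracle()], [table_oracle()]).
#' @param fitness A [fitness_spec()].
#' @param verbose Print one line per generation?
#' @return An object of class `azc_evo_run`; see [tidy.azc_evo_run()],
#'   [glance.azc_evo_run()] and [autoplot.azc_evo_run()].
#' @examples
#' \donttest{
#' sp <- space_definition()
#' run <- run_evolution(sp, ea_config(population_size = 20, n_generations = 3, seed = 1),
#'                      surrogate_oracle())
#' glance(run)
#' }
#' @export
run_evolution <- function(space, config = ea_config(), oracle = surrogate_oracle(),
                          fitness = fitness_spec(), verbose = FALSE) {
  stopifnot(inherits(space, "azc_space"), inherits(config, "azc_ea_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  cache <- new_fitness_cache()
  pop <- initialise_population(space, ea_config_no_seed(config))
  pop <- evaluate_population(pop, oracle, fitness, cache)

  log_rows <- list()
  pops <- list()
  snapshot <- function(gen, pop) {
    best <- order(pop$fitness, pop$canonical_key)[1L]
    log_rows[[length(log_rows) + 1L]] <<- tibble(
      generation = gen,
      mean_fitness = mean(pop$fitness[is.finite(pop$fitness)]),
      min_fitness = min(pop$fitness),
      best_key = pop$canonical_key[best],
      n_unique_sampled = length(cache$order)
    )
    pops[[length(pops) + 1L]] <<- tibble(
      generation = gen,
      canonical_key = pop$canonical_key,
      fitness = pop$fitness
    )
    if (verbose) {
      inform(sprintf("generation %d: mean %.4f, min %.4f, %d unique sampled",
                     gen, mean(pop$fitness), min(pop$fitness), length(cache$order)))
    }
  }
  snapshot(0L, pop)

  means <- numeric(0)
  for (g in seq_len(config$n_generations)) {
    pop <- next_generation(pop, space, config, oracle, fitness, cache)
    snapshot(g, pop)
    means <- c(means, mean(pop$fitness[is.finite(pop$fitness)]))
    if (config$early_stop && length(means) > config$early_stop_patience) {
      recent <- utils::tail(means, config$early_stop_patience + 1L)
      if (recent[1L] - min(recent[-1L]) < config$early_stop_tol) break
    }
  }

  log <- dplyr::bind_rows(log_rows)
  best_key <- log$best_key[nrow(log)]
  first_seen <- min(log$generation[log$best_key == best_key])
  structure(
    list(
      log = log,
      populations = dplyr::bind_rows(pops),
      evaluated = tibble(
        canonical_key = cache$order,
        fitness = vapply(cache$order,
                         function(k) get(k, envir = cache$fit, inherits = FALSE),
                         numeric(1), USE.NAMES = FALSE)
      ),
      failed = cache$failed,
      best_key = best_key,
      best_fitness = log$min_fitness[nrow(log)],
      best_first_generation = first_seen,
      config = config,
      space = space
    ),
    class = "azc_evo_run"
  )
}

# initialise_population seeds itself from config$seed; inside run_evolution
# the stream is already seeded, so strip the seed to avoid re-seeding
ea_config_no_seed <- function(config) {
  config$seed <- NULL
  config
}

#' @export
print.azc_evo_run <- function(x, ...) {
  cat(sprintf(
    "<azc_evo_run> %d generations, %d unique molecules sampled\n  best: %s (fitness %.4f eV, first seen generation %d)\n",
    max(x$log$generation), nrow(x$evaluated), x$best_key, x$best_fitness,
    x$best_first_generation
  ))
  invisible(x)
}

#' Tidiers and plots for evolutionary runs
#'
#' `tidy()` returns the per-generation log (mean/min fitness, cumulative
#' unique molecules, current best key); `glance()` a one-row run summary;
#' `autoplot()` the fitness trajectory.
#'
#' @param x An `azc_evo_run`.
#' @param ... Unused.
#' @export
tidy.azc_evo_run <- function(x, ...) x$log

#' @rdname tidy.azc_evo_run
#' @export
glance.azc_evo_run <- function(x, ...) {
  tibble(
    n_generations = max(x$log$generation),
    best_key = x$best_key,
    best_fitness = x$best_fitness,
    best_first_generation = x$best_first_generation,
    n_unique_sampled = nrow(x$evaluated),
    n_failed = length(x$failed)
  )
}

#' @rdname tidy.azc_evo_run
#' @param object An `azc_evo_run`.
#' @export
autoplot.azc_evo_run <- function(object, ...) {
  d <- object$log |>
    tidyr::pivot_longer(c("mean_fitness", "min_fitness"),
                        names_to = "series", values_to = "fitness")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$generation, y = .data$fitness,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(
      values = c(mean_fitness = "#777777", min_fitness = "#1b7837"),
      labels = c(mean_fitness = "population mean", min_fitness = "population minimum")
    ) +
    ggplot2::labs(x = "generation", y = "fitness (eV)", colour = NULL) +
    ggplot2::theme_minimal()
}
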