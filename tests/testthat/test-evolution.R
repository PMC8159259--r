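test_that("configuration validates its rates and counts", {
  expect_error(ea_config(population_size = 0))
  expect_error(ea_config(elitism_rate = 1.5))
  expect_error(ea_config(p_mutation = -0.1))
  cfg <- ea_config()
  expect_equal(cfg$population_size, 100L)
  expect_equal(cfg$n_generations, 30L)
  expect_equal(cfg$elitism_rate, 0.10)
  expect_equal(cfg$tournament_size, 2L)
})

test_that("initial populations are sized, in-space and reproducible", {
  sp <- space_definition()
  cfg <- ea_config(population_size = 15, seed = 4)
  p1 <- initialise_population(sp, cfg)
  p2 <- initialise_population(sp, cfg)
  expect_equal(nrow(p1), 15L)
  expect_identical(p1$canonical_key, p2$canonical_key)
  expect_true(all(vapply(p1$mol, ring_count, integer(1)) == 5L))
})

test_that("elitism makes the population minimum non-increasing", {
  sp <- space_definition()
  run <- run_evolution(sp, ea_config(population_size = 24, n_generations = 8, seed = 2),
                       surrogate_oracle())
  expect_true(all(diff(run$log$min_fitness) <= 1e-12))
  expect_true(all(diff(run$log$n_unique_sampled) >= 0))
  # population size is constant in every snapshot
  sizes <- dplyr::count(run$populations, .data$generation)$n
  expect_true(all(sizes == 24L))
})

test_that("selection alone converges a static population to the elite set", {
  # one-ring space: crossover cannot cut single rings and falls back to
  # copying parents; with mutation and recombination off, selection plus
  # elitism can only reshuffle the initial keys
  sp1 <- space_definition(smiles = c("c1ccccc1", "c1ccncc1", "c1ccnnc1"),
                          molsize_min = 1, molsize_max = 1)
  cfg <- ea_config(population_size = 16, n_generations = 12,
                   p_mutation = 0, p_recombination = 0, init_mutations = 20,
                   seed = 8)
  run <- run_evolution(sp1, cfg, surrogate_oracle())
  init_keys <- unique(run$populations$canonical_key[run$populations$generation == 0])
  final <- run$populations[run$populations$generation == 12, ]
  expect_true(all(final$canonical_key %in% init_keys))
  # the best initial molecule dominates the final population
  best0 <- min(run$populations$fitness[run$populations$generation == 0])
  expect_equal(min(final$fitness), best0)
  expect_gte(mean(final$canonical_key == final$canonical_key[which.min(final$fitness)]),
             0.5)
})

test_that("the fitness cache evaluates each unique molecule exactly once", {
  sp <- space_definition()
  calls <- new.env(parent = emptyenv())
  calls$keys <- character(0)
  counting_oracle <- function(m) {
    calls$keys <- c(calls$keys, canonical_key(m))
    surrogate_oracle()(m)
  }
  run <- run_evolution(sp, ea_config(population_size = 12, n_generations = 4, seed = 6),
                       counting_oracle)
  expect_equal(length(calls$keys), length(unique(calls$keys)))
  expect_setequal(calls$keys, run$evaluated$canonical_key)
})

test_that("oracle failures become worst-possible fitness, never elites", {
  sp <- space_definition()
  flaky <- function(m) {
    if (nonlinearity_degree(m) == 0L) stop("refusing linear molecules")
    surrogate_oracle()(m)
  }
  run <- run_evolution(sp, ea_config(population_size = 10, n_generations = 3, seed = 9),
                       flaky)
  expect_true(length(run$failed) > 0 || all(is.finite(run$evaluated$fitness)))
  expect_true(is.finite(run$best_fitness))
})

test_that("runs are fully reproducible and well summarised", {
  sp <- space_definition()
  cfg <- ea_config(population_size = 14, n_generations = 5, seed = 31)
  r1 <- run_evolution(sp, cfg, surrogate_oracle())
  r2 <- run_evolution(sp, cfg, surrogate_oracle())
  expect_identical(r1$log, r2$log)
  expect_identical(r1$evaluated, r2$evaluated)

  # zero generations: only the initial population is logged
  r0 <- run_evolution(sp, ea_config(population_size = 8, n_generations = 0, seed = 1),
                      surrogate_oracle())
  expect_equal(nrow(r0$log), 1L)
  expect_equal(r0$log$n_unique_sampled, length(unique(r0$populations$canonical_key)))

  td <- tidy(r1)
  expect_named(td, c("generation", "mean_fitness", "min_fitness", "best_key",
                     "n_unique_sampled"))
  gl <- glance(r1)
  expect_equal(gl$n_unique_sampled, nrow(r1$evaluated))
  p <- autoplot(r1)
  expect_s3_class(p, "ggplot")
})

test_that("F_B runs favour higher-EA molecules than F_A runs", {
  sp <- space_definition()
  ra <- run_evolution(sp, ea_config(population_size = 20, n_generations = 6, seed = 12),
                      surrogate_oracle(), fitness_spec("F_A"))
  rb <- run_evolution(sp, ea_config(population_size = 20, n_generations = 6, seed = 12),
                      surrogate_oracle(), fitness_spec("F_B"))
  n_final <- function(run) {
    keys <- run$populations$canonical_key[run$populations$generation == 6]
    mean(describe_molecules(lapply(keys, parse_molecule))$n_nitrogens)
  }
  expect_gt(n_final(rb), n_final(ra))
})
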