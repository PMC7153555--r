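test_that("selective death is Bernoulli in the final survival chance", {
  certain <- tibble::tibble(strategy = "NNN", survival = c(1, 1, 0, 0))
  set.seed(2)
  out <- selective_death(certain)
  expect_equal(nrow(out), 2)
  expect_true(all(out$survival == 1))
  n <- 1e4
  frac <- nrow(selective_death(
    tibble::tibble(strategy = "NNN", survival = rep(0.54, n)))) / n
  expect_lt(abs(frac - 0.54), 3 * sqrt(0.54 * 0.46 / n))
})

test_that("reproduction clones survivors up to carrying capacity", {
  set.seed(4)
  lone <- tibble::tibble(strategy = "NNH", survival = 0.2)
  off <- reproduce_prey(lone, 180)
  expect_equal(nrow(off), 180)
  expect_true(all(off$strategy == "NNH"))
  expect_true(all(off$survival == 1))

  # multinomial expectation at a 50/50 parent split
  parents <- tibble::tibble(strategy = rep(c("NNN", "HHH"), each = 50),
    survival = 1)
  means <- replicate(200, sum(reproduce_prey(parents, 180)$strategy == "NNN"))
  se <- sqrt(180 * 0.25) / sqrt(200)
  expect_lt(abs(mean(means) - 90), 4 * se)

  # empty survivor set falls back to the pre-death population
  off2 <- reproduce_prey(lone[0, ], 10, fallback = lone)
  expect_equal(nrow(off2), 10)
  expect_error(reproduce_prey(lone[0, ], 10),
    class = "aposwitch_engine_error")
})

test_that("extinction rescue restores every allowed strategy exactly", {
  set.seed(6)
  allowed <- default_strategies()
  mono <- tibble::tibble(strategy = rep("NNH", 180), survival = 1)
  fixed <- prevent_extinction(mono, allowed)
  tab <- table(fixed$strategy)
  expect_equal(nrow(fixed), 180)
  expect_setequal(names(tab), allowed)
  expect_equal(as.integer(tab[["NNH"]]), 172)
  expect_true(all(tab[setdiff(allowed, "NNH")] == 1))

  # already complete: unchanged
  complete <- tibble::tibble(strategy = rep(allowed, 20), survival = 0.5)
  expect_equal(prevent_extinction(complete, allowed), complete)

  expect_error(
    prevent_extinction(mono[1:5, ], allowed),
    class = "aposwitch_config_error"
  )
})

test_that("turnover injects naive predators at the configured rate", {
  set.seed(8)
  experienced <- tibble::tibble(memory = runif(45, 1, 10))
  all_new <- predator_turnover(experienced, 1)
  expect_true(all(all_new$memory == 0))
  expect_true(all(all_new$replaced))
  none <- predator_turnover(experienced, 0)
  expect_equal(none$memory, experienced$memory)
  expect_false(any(none$replaced))

  # stochastic reading: rate 0.01 on 45 predators averages 0.45/generation
  n_gen <- 2000
  reps <- replicate(n_gen, sum(predator_turnover(experienced, 0.01)$replaced))
  se <- sqrt(45 * 0.01 * 0.99 / n_gen)
  expect_lt(abs(mean(reps) - 0.45), 3 * se)

  # deterministic alternative replaces a fixed rounded number
  det <- predator_turnover(experienced, 0.5, stochastic = FALSE)
  expect_equal(sum(det$replaced), 23) # round(22.5) half away from zero
})

test_that("runs conserve population size and keep all strategies present", {
  cfg <- apo_config(world_size = 6, prey_frequency = 0.5,
    predator_frequency = 0.2, n_generations = 10, generation_length = 10)
  run <- run_simulation(cfg, seed = 42)
  gens <- tidy(run)
  counts <- as.matrix(gens[, paste0("count_", cfg$allowed_strategies)])
  expect_true(all(rowSums(counts) == 18)) # capacity every generation start
  expect_true(all(counts >= 1)) # rescue guarantees presence
  expect_equal(nrow(gens), 10)
  expect_true(run$winner %in% cfg$allowed_strategies)
})

test_that("identical config and seed give bit-identical runs", {
  cfg <- apo_config(world_size = 6, prey_frequency = 0.5,
    predator_frequency = 0.2, n_generations = 5, generation_length = 10)
  a <- run_simulation(cfg, seed = 7)
  b <- run_simulation(cfg, seed = 7)
  expect_identical(a$final_counts, b$final_counts)
  expect_identical(a$winner, b$winner)
  expect_identical(tidy(a), tidy(b))
})

test_that("zero learning speed keeps every memory at zero through a run", {
  cfg <- apo_config(world_size = 6, prey_frequency = 0.5,
    predator_frequency = 0.3, learning_speed = 0, n_generations = 8,
    generation_length = 10)
  run <- run_simulation(cfg, seed = 3)
  expect_true(all(tidy(run)$mean_predator_memory == 0))
})

test_that("tidy and glance views expose records and summary", {
  cfg <- apo_config(world_size = 5, prey_frequency = 0.4,
    predator_frequency = 0.2, n_generations = 4, generation_length = 5)
  run <- run_simulation(cfg, seed = 10)
  g <- glance(run)
  expect_equal(nrow(g), 1)
  expect_equal(g$winner, run$winner)
  expect_equal(g$n_generations, 4)
  expect_true(all(paste0("count_", cfg$allowed_strategies) %in% names(g)))
  lean <- run_simulation(cfg, seed = 10, record_generations = FALSE)
  expect_identical(lean$final_counts, run$final_counts)
  expect_error(tidy(lean))
})
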