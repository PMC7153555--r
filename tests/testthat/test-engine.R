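test_that("perception equations match their closed forms", {
  expect_equal(discovery_chance(0.05, 0), 0.05)
  expect_equal(discovery_chance(0.4, 1), 1)
  expect_equal(discovery_chance(0.4, 0.3), 0.58)
  expect_equal(conditional_stimulus(0.1, 0), 0.1)
  expect_equal(conditional_stimulus(0.1, 1), 1)
  expect_equal(conditional_stimulus(0.1, 0.3), 0.37)
  expect_equal(learned_repulsiveness(0, 0.9), 0)
  expect_equal(learned_repulsiveness(20, 0.1), 1) # clamped
  expect_equal(learned_repulsiveness(5, 0.1), 0.5)
  expect_equal(prey_attractiveness(0, 0), 1)
  expect_equal(prey_attractiveness(1, 0.3), 0)
  expect_equal(prey_attractiveness(0.1, 0.1), 0.81)
  expect_equal(update_motivation(1, 0.81), 0.81)
  expect_equal(update_motivation(0.81, 0.5), 0.405)
})

test_that("per-step prey operations react, charge costs, and take damage", {
  cfg <- apo_config(signaling_penalty = 0.13)
  prey <- tibble::tibble(
    strategy = c("NHH", "NNH", "NNN", "LLL"),
    state = "resting", survival = 1
  )
  reacted <- prey_react(prey, "approached")
  expect_equal(reacted$switched, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(reacted$intensity, c(1, 0, 0, 0.3))
  # switching OFF is also a level change
  back <- prey_react(reacted, "resting")
  expect_equal(back$switched, c(TRUE, FALSE, FALSE, FALSE))

  # NNN pays nothing at rest; LLL pays the intensity-weighted penalty
  paid <- prey_pay_cost(
    tibble::tibble(strategy = c("NNN", "LLL"), state = "resting",
      survival = 1),
    switched = FALSE, config = cfg
  )
  expect_equal(paid$survival, c(1, 1 - 0.13 * 0.3))

  # a switchable prey that just switched pays all three factors
  paid2 <- prey_pay_cost(
    tibble::tibble(strategy = "NHH", state = "approached", survival = 1),
    switched = TRUE, config = apo_config(signaling_penalty = 0.13)
  )
  expect_equal(paid2$survival, (1 - 0.0005) * (1 - 2.03e-4) * (1 - 0.13),
    tolerance = 1e-12)

  hurt <- apply_attack(tibble::tibble(strategy = "NNN", survival = 1), 0.1)
  expect_equal(hurt$survival, 0.9)
  expect_equal(apply_attack(hurt, 0)$survival, 0.9)
  expect_equal(apply_attack(tibble::tibble(survival = 0.809266), 0.4)$survival,
    0.4855596)
})

test_that("taste is felt only by attackers and drives all learning", {
  preds <- tibble::tibble(memory = c(0, 0), motivation = 1,
    unconditional_stimulus = 0)
  felt <- feel(preds, attacked = c(TRUE, FALSE), repulsive_taste = 0.1)
  expect_equal(felt$unconditional_stimulus, c(0.1, 0))
  # increment = speed * us * cs: zero for the non-attacker
  learned <- learn(felt, cs = 1, learning_speed = 1)
  expect_equal(learned$memory, c(0.1, 0))
  expect_equal(learn(felt, cs = 1, learning_speed = 0)$memory, c(0, 0))
  expect_equal(learn(felt, cs = 0.1, learning_speed = 1000)$memory[1], 10)
})

test_that("attack decisions are Bernoulli in the motivation", {
  expect_true(all(decide_attack(rep(1, 50))))
  expect_false(any(decide_attack(rep(0, 50))))
  set.seed(5)
  n <- 1e5
  rate <- mean(decide_attack(rep(0.81, n)))
  se <- sqrt(0.81 * 0.19 / n)
  expect_lt(abs(rate - 0.81), 3 * se)
})

test_that("predator assignment pairs distinct prey without replacement", {
  set.seed(7)
  cfg <- apo_config()
  prey <- build_initial_population(cfg)
  preds <- assign_predators(prey, build_predators(cfg))
  expect_equal(sum(!is.na(preds$target)), 45)
  expect_equal(anyDuplicated(stats::na.omit(preds$target)), 0)
  expect_true(all(preds$motivation == 1))

  # surplus predators idle
  two <- assign_predators(prey[1, ],
    tibble::tibble(memory = c(0, 0), motivation = 1,
      unconditional_stimulus = 0))
  expect_equal(sum(is.na(two$target)), 1)

  # no predators: nothing approached
  none <- assign_predators(prey, tibble::tibble(memory = numeric(),
    motivation = numeric(), unconditional_stimulus = numeric()))
  expect_equal(nrow(none), 0)
})

test_that("the worked reference frame reproduces the hand-computed trace", {
  res <- scenario_frame(trace_scenario())
  tr <- res$trace
  expect_equal(tr$end$survival, 0.436915, tolerance = 1e-5)
  expect_equal(tr$end$memory, 0.2, tolerance = 1e-12)
  expect_equal(tr$step2$motivation, 0.81, tolerance = 1e-12)
  # intermediate stations of the chain
  expect_equal(tr$step1$survival, 1 - 2.03e-4, tolerance = 1e-12)
  expect_equal(tr$step2$cs, 1)
  expect_equal(tr$step2$lr, 0.1, tolerance = 1e-12)
  expect_equal(tr$step2$attractiveness, 0.81, tolerance = 1e-12)
  expect_equal(tr$step2$survival, 0.809266, tolerance = 1e-5)
})

test_that("a slow-learning predator leaves only damage in its wake", {
  sc <- make_single_pair_scenario("NNN", list(learning_speed = 0),
    draw_script = c(TRUE, TRUE, TRUE))
  res <- scenario_frame(sc)
  expect_equal(res$trace$end$survival, 0.9 * 0.6, tolerance = 1e-12)
  expect_equal(res$trace$end$memory, 0)
})

test_that("an undetected pre-attack switcher pays two switching costs", {
  ov <- list(signaling_penalty = 0.1, basal_detectability = 0.4)
  sc <- make_single_pair_scenario("NHH", ov, draw_script = FALSE)
  res <- scenario_frame(sc)
  o <- brute_force_frame(sc)
  expect_equal(res$trace$end$survival, o$end$survival, tolerance = 1e-12)
  # hand expansion: step1 approached at H with switch-on; steps 2-3 resting
  # with a switch-off at step 2
  sc1 <- (1 - 0.0005) * (1 - 2.03e-4) * (1 - 0.1 * 1)
  sc2 <- (1 - 0.0005) * (1 - 2.03e-4) * (1 - 0.1 * 0)
  sc3 <- (1 - 2.03e-4)
  expect_equal(res$trace$end$survival, sc1 * sc2 * sc3, tolerance = 1e-12)
  # predator never attacked: no taste, no learning
  expect_equal(res$trace$end$memory, 0)
})

test_that("detection uses the approached-state intensity (the opportunity cost of hiding)", {
  set.seed(13)
  n <- 2000
  detect_rate <- function(code, bd) {
    sc <- make_single_pair_scenario(code, list(basal_detectability = bd))
    cfg <- sc$config
    hits <- 0
    for (i in seq_len(n)) {
      w <- apo_world(cfg,
        prey = tibble::tibble(strategy = code, state = "resting",
          survival = 1, cell = 1L),
        predators = tibble::tibble(memory = 0, motivation = 1,
          unconditional_stimulus = 0))
      w <- run_frame(w, cfg, trace = TRUE)
      hits <- hits + attr(w, "trace")$step1$detected
    }
    hits / n
  }
  # post-attack switcher hides while approached: detection at the basal floor
  r_post <- detect_rate("NNH", 0.3)
  expect_lt(abs(r_post - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  # pre-attack switcher is already displaying: basal + intensity headroom
  p_pre <- discovery_chance(0.3, 1)
  r_pre <- detect_rate("NHH", 0.3)
  expect_equal(r_pre, 1) # intensity 1 saturates detection
  expect_gt(r_pre, r_post)
})

test_that("a naive predator always attacks a detected prey at step 2", {
  for (code in c("NNN", "NNH", "NHH", "HHH")) {
    sc <- make_single_pair_scenario(code, list(),
      draw_script = c(TRUE, TRUE, TRUE))
    res <- scenario_frame(sc)
    expect_equal(res$trace$step1$motivation, 1)
    expect_true(res$trace$step2$attacked)
  }
})

test_that("frames keep survival non-increasing and memory non-decreasing", {
  set.seed(17)
  cfg <- apo_config(world_size = 6, prey_frequency = 0.8,
    predator_frequency = 0.3)
  w <- apo_world(cfg)
  s_prev <- w$prey$survival
  m_prev <- w$pred$memory
  for (f in 1:50) {
    w <- run_frame(w, cfg)
    expect_true(all(w$prey$survival <= s_prev + 1e-15))
    expect_true(all(w$prey$survival >= 0 & w$prey$survival <= 1))
    expect_true(all(w$pred$memory >= m_prev - 1e-15))
    s_prev <- w$prey$survival
    m_prev <- w$pred$memory
  }
})

test_that("forced draws demand a single pair and a long-enough script", {
  cfg <- apo_config(world_size = 3, prey_frequency = 1,
    predator_frequency = 2 / 9)
  w <- apo_world(cfg)
  expect_error(run_frame(w, cfg, draws = c(TRUE, TRUE, TRUE)),
    class = "aposwitch_fixture_error")
  sc <- make_single_pair_scenario("NNN", list(), draw_script = c(TRUE, TRUE))
  expect_error(scenario_frame(sc), class = "aposwitch_fixture_error")
})
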