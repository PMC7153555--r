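#' Deterministic single-pair micro-scenarios
#'
#' A micro-scenario is a 1-predator x 1-prey world on a 2 x 2 grid together
#' with a forced-draw script: an ordered list of Bernoulli outcomes consumed
#' in place of the RNG (detection, initial attack, subsequent attack, in
#' that order, each consumed only if the interaction reaches it). Scenarios
#' make every stochastic branch of a frame testable exhaustively.
#'
#' @param strategy_code The prey's strategy (any 3-letter code).
#' @param config_overrides Named list of [apo_config()] arguments to
#'   override; the scenario forces `world_size = 2` and frequencies giving
#'   one prey and one predator.
#' @param draw_script Logical vector of forced outcomes.
#' @param memory Initial aversive memory of the predator (default 0).
#' @return An object of class `apo_scenario`.
#' @examples
#' sc <- make_single_pair_scenario("NNH", list(basal_detectability = 0.4),
#'   draw_script = c(TRUE, TRUE, TRUE))
#' scenario_frame(sc)$trace$end$survival
#' @export
make_single_pair_scenario <- function(strategy_code,
                                      config_overrides = list(),
                                      draw_script = c(TRUE, TRUE, TRUE),
                                      memory = 0) {
  strategy_code <- toupper(strategy_code)
  parse_strategy(strategy_code)
  args <- utils::modifyList(
    list(
      world_size = 2, prey_frequency = 0.25, predator_frequency = 0.25,
      allowed_strategies = strategy_code, n_generations = 1,
      generation_length = 1
    ),
    config_overrides
  )
  # the scenario geometry is fixed; overrides may not change it
  args$world_size <- 2
  args$prey_frequency <- 0.25
  args$predator_frequency <- 0.25
  args$allowed_strategies <- strategy_code
  sc <- list(
    config = do.call(apo_config, args),
    strategy_code = strategy_code,
    draws = as.logical(draw_script),
    memory = memory
  )
  class(sc) <- "apo_scenario"
  sc
}

#' Run one engine frame on a scenario
#'
#' @param scenario An `apo_scenario`.
#' @return A list with the post-frame `world` and the full intermediate
#'   `trace` (see [run_frame()]).
#' @export
scenario_frame <- function(scenario) {
  stopifnot(inherits(scenario, "apo_scenario"))
  cfg <- scenario$config
  world <- apo_world(cfg,
    prey = tibble(strategy = scenario$strategy_code, state = "resting",
      survival = 1, cell = 1L),
    predators = tibble(memory = scenario$memory, motivation = 1,
      unconditional_stimulus = 0)
  )
  world <- run_frame(world, cfg, draws = scenario$draws, trace = TRUE)
  list(world = world, trace = attr(world, "trace"))
}

#' Brute-force frame oracle
#'
#' An independent straight-line recomputation of one interaction frame for a
#' single predator-prey pair, written directly from the model equations and
#' sharing no code with the engine. Every intermediate quantity is computed
#' and returned, so the engine can be checked step by step (the equality
#' tolerance used in the tests is 1e-12).
#'
#' @param scenario An `apo_scenario`.
#' @return A nested list with `step1`, `step2`, `step3` and `end` entries
#'   holding the per-step survival, signal intensity, conditional stimulus,
#'   learned repulsiveness, attractiveness, motivation, unconditional
#'   stimulus and memory values.
#' @export
brute_force_frame <- function(scenario) {
  stopifnot(inherits(scenario, "apo_scenario"))
  cfg <- scenario$config
  draws <- as.logical(scenario$draws)
  pos <- 0L
  next_draw <- function() {
    pos <<- pos + 1L
    if (pos > length(draws)) {
      abort("Forced-draw script exhausted in brute_force_frame().",
        class = "aposwitch_fixture_error")
    }
    draws[pos]
  }

  rank_of <- c(N = 1, L = 2, H = 3)
  value_of <- c(N = 0, L = cfg$intensity_L, H = cfg$intensity_H)
  labels <- strsplit(scenario$strategy_code, "", fixed = TRUE)[[1]]
  lab_rest <- labels[1]; lab_app <- labels[2]; lab_att <- labels[3]
  switchable <- !(lab_rest == lab_app && lab_app == lab_att)

  survival <- 1
  memory <- scenario$memory
  us <- 0
  motivation <- 1
  label <- lab_rest

  is_charged <- function(old, new) {
    if (cfg$cost_on_switch_off) old != new else rank_of[[new]] > rank_of[[old]]
  }
  pay <- function(surv, switch_now, intensity) {
    if (switch_now) surv <- surv * (1 - cfg$switching_cost)
    if (switchable) surv <- surv * (1 - cfg$switchability_maintenance_cost)
    surv * (1 - cfg$signaling_penalty * intensity)
  }

  # ---- step 1: the predator arrives; the prey is approached
  sw1 <- label != lab_app
  ch1 <- is_charged(label, lab_app)
  label <- lab_app
  intensity <- value_of[[label]]
  survival <- pay(survival, ch1, intensity)
  p_detect <- cfg$basal_detectability +
    intensity * (1 - cfg$basal_detectability)
  detected <- next_draw()
  cs1 <- lr1 <- attr1 <- NA_real_
  if (detected) {
    cs1 <- cfg$basal_cognitive_cue +
      intensity * (1 - cfg$basal_cognitive_cue)
    lr1 <- min(1, memory * cs1)
    ir1 <- us # zero: nothing tasted yet
    attr1 <- (1 - lr1) * (1 - ir1)
    motivation <- motivation * attr1
  }
  step1 <- list(
    detected = detected, p_detect = p_detect, switched = sw1,
    survival = survival, intensity = intensity, cs = cs1, lr = lr1,
    attractiveness = attr1, motivation = motivation
  )

  # ---- step 2: initial attack or abandonment
  attacked1 <- FALSE
  if (detected) attacked1 <- next_draw()
  if (attacked1) {
    survival <- survival * (1 - cfg$initial_attack_damage)
    us <- cfg$repulsive_taste
  }
  new_label <- if (attacked1) lab_att else lab_rest
  sw2 <- label != new_label
  ch2 <- is_charged(label, new_label)
  label <- new_label
  intensity <- value_of[[label]]
  survival <- pay(survival, ch2, intensity)
  cs2 <- lr2 <- attr2 <- NA_real_
  if (attacked1) {
    cs2 <- cfg$basal_cognitive_cue +
      intensity * (1 - cfg$basal_cognitive_cue)
    memory <- memory + cfg$learning_speed * us * cs2
    lr2 <- min(1, memory * cs2)
    ir2 <- us
    attr2 <- (1 - lr2) * (1 - ir2)
    motivation <- motivation * attr2
  }
  step2 <- list(
    attacked = attacked1, switched = sw2, survival = survival,
    intensity = intensity, us = us, cs = cs2, lr = lr2,
    attractiveness = attr2, motivation = motivation, memory = memory
  )

  # ---- step 3: subsequent attack or abandonment
  attacked2 <- FALSE
  if (attacked1) attacked2 <- next_draw()
  if (attacked2) {
    survival <- survival * (1 - cfg$subsequent_attack_damage)
  }
  new_label <- if (attacked2) lab_att else lab_rest
  sw3 <- label != new_label
  ch3 <- is_charged(label, new_label)
  label <- new_label
  intensity <- value_of[[label]]
  survival <- pay(survival, ch3, intensity)
  cs3 <- NA_real_
  learns <- attacked1 && (attacked2 || cfg$learn_on_step3_abandon)
  if (learns) {
    cs3 <- cfg$basal_cognitive_cue +
      intensity * (1 - cfg$basal_cognitive_cue)
    memory <- memory + cfg$learning_speed * us * cs3
  }
  step3 <- list(
    attacked = attacked2, switched = sw3, survival = survival,
    intensity = intensity, cs = cs3, memory = memory
  )

  list(
    step1 = step1, step2 = step2, step3 = step3,
    end = list(survival = survival, memory = memory,
      motivation = motivation)
  )
}
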