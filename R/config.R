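#' Simulation configuration
#'
#' Builds the full run configuration. Defaults are the reference condition of
#' the package: a 14 x 14 world holding 180 prey (92% occupancy) and 45
#' predators (23%), 50 interaction frames per generation, 500 generations,
#' signal intensities L = 0.3 / H = 1, attack damages 0.1 (initial) and 0.4
#' (subsequent), basal cognitive cue 0.1, repulsive taste 0.1, and the nine
#' admissible strategies. The five experiment variables default to a moderate
#' point of their grids: moderate switchable-signal penalty (switching cost
#' 5e-4, maintenance cost 2.03e-4), basal detectability 0.4, predator
#' turnover 0.25, learning speed 1, signaling penalty 0.13.
#'
#' @param world_size Side length of the square grid (>= 1).
#' @param generation_length Interaction frames per prey generation.
#' @param n_generations Number of prey generations per run.
#' @param prey_frequency,predator_frequency Fractions of grid squares holding
#'   a prey / predator at generation start; prey count may not exceed the
#'   number of squares.
#' @param intensity_L,intensity_H Numeric intensities of the L and H levels.
#' @param initial_attack_damage,subsequent_attack_damage Survival-chance
#'   multipliers `(1 - damage)` applied at the first and second attack.
#' @param basal_cognitive_cue Signal-independent floor of the conditional
#'   stimulus (learnability of the prey's appearance).
#' @param repulsive_taste Unconditional stimulus felt during attacks.
#' @param allowed_strategies Character vector of admissible strategy codes.
#' @param switching_cost Per-use survival cost of changing signal level.
#' @param switchability_maintenance_cost Per-time-step survival cost of
#'   possessing a switchable mechanism.
#' @param basal_detectability Signal-independent floor of the discovery
#'   chance.
#' @param predator_turnover Per-generation probability that a predator is
#'   replaced by a naive one.
#' @param learning_speed Non-negative coefficient of aversive-memory buildup
#'   (no upper bound).
#' @param signaling_penalty Intensity-weighted survival cost of an active
#'   signal (everything other than detectability).
#' @param rng_seed Integer seed used by [run_simulation()] when no explicit
#'   seed is passed.
#' @param allow_shared_targets If `TRUE`, two predators may land on the same
#'   prey in a frame (sampling with replacement). Default `FALSE`: each prey
#'   faces at most one predator per frame.
#' @param cost_on_switch_off Charge the switching cost on any level change,
#'   including switching the signal off after abandonment (default `TRUE`).
#'   The end-of-frame reversion to resting is always free.
#' @param learn_on_step3_abandon If `TRUE` (default), a predator that
#'   attacked initially but abandons at the final step still observes the
#'   prey's current (reverted) intensity and learns from it with the taste it
#'   retains from the initial attack.
#' @param turnover_stochastic If `TRUE` (default), turnover replaces each
#'   predator independently with probability `predator_turnover`; if `FALSE`,
#'   a deterministic `round(rate * n)` predators are replaced.
#' @return An object of class `apo_config` (a named list).
#' @examples
#' cfg <- apo_config(learning_speed = 10, signaling_penalty = 0.01)
#' cfg$learning_speed
#' @export
apo_config <- function(world_size = 14,
                       generation_length = 50,
                       n_generations = 500,
                       prey_frequency = 0.92,
                       predator_frequency = 0.23,
                       intensity_L = 0.3,
                       intensity_H = 1,
                       initial_attack_damage = 0.1,
                       subsequent_attack_damage = 0.4,
                       basal_cognitive_cue = 0.1,
                       repulsive_taste = 0.1,
                       allowed_strategies = default_strategies(),
                       switching_cost = 0.0005,
                       switchability_maintenance_cost = 2.03e-4,
                       basal_detectability = 0.4,
                       predator_turnover = 0.25,
                       learning_speed = 1,
                       signaling_penalty = 0.13,
                       rng_seed = 1L,
                       allow_shared_targets = FALSE,
                       cost_on_switch_off = TRUE,
                       learn_on_step3_abandon = TRUE,
                       turnover_stochastic = TRUE) {
  cfg <- list(
    world_size = as.integer(world_size),
    generation_length = as.integer(generation_length),
    n_generations = as.integer(n_generations),
    prey_frequency = prey_frequency,
    predator_frequency = predator_frequency,
    intensity_L = intensity_L,
    intensity_H = intensity_H,
    initial_attack_damage = initial_attack_damage,
    subsequent_attack_damage = subsequent_attack_damage,
    basal_cognitive_cue = basal_cognitive_cue,
    repulsive_taste = repulsive_taste,
    allowed_strategies = toupper(allowed_strategies),
    switching_cost = switching_cost,
    switchability_maintenance_cost = switchability_maintenance_cost,
    basal_detectability = basal_detectability,
    predator_turnover = predator_turnover,
    learning_speed = learning_speed,
    signaling_penalty = signaling_penalty,
    rng_seed = as.integer(rng_seed),
    allow_shared_targets = isTRUE(allow_shared_targets),
    cost_on_switch_off = isTRUE(cost_on_switch_off),
    learn_on_step3_abandon = isTRUE(learn_on_step3_abandon),
    turnover_stochastic = isTRUE(turnover_stochastic)
  )
  class(cfg) <- "apo_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  fracs <- c(
    "prey_frequency", "predator_frequency", "intensity_L", "intensity_H",
    "initial_attack_damage", "subsequent_attack_damage",
    "basal_cognitive_cue", "repulsive_taste", "switching_cost",
    "switchability_maintenance_cost", "basal_detectability",
    "predator_turnover", "signaling_penalty"
  )
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      abort(sprintf("`%s` must be a single fraction in [0, 1].", f),
        class = "aposwitch_config_error")
    }
  }
  if (cfg$learning_speed < 0) {
    abort("`learning_speed` must be non-negative.",
      class = "aposwitch_config_error")
  }
  if (cfg$world_size < 1 || cfg$generation_length < 1 || cfg$n_generations < 1) {
    abort("world_size, generation_length and n_generations must all be >= 1.",
      class = "aposwitch_config_error")
  }
  if (cfg$intensity_L > cfg$intensity_H) {
    abort("`intensity_L` must not exceed `intensity_H`.",
      class = "aposwitch_config_error")
  }
  parse_strategy(cfg$allowed_strategies) # validates codes
  counts <- derive_counts(cfg$world_size, cfg$prey_frequency,
    cfg$predator_frequency)
  if (counts$n_prey > cfg$world_size^2) {
    abort("Derived prey count exceeds the number of grid squares.",
      class = "aposwitch_config_error")
  }
  invisible(cfg)
}

#' @export
print.apo_config <- function(x, ...) {
  counts <- derive_counts(x$world_size, x$prey_frequency, x$predator_frequency)
  cat(sprintf(
    "<apo_config> %dx%d world, %d prey / %d predators, %d frames x %d generations\n",
    x$world_size, x$world_size, counts$n_prey, counts$n_predators,
    x$generation_length, x$n_generations
  ))
  cat(sprintf(
    "  costs: switch %g, maintenance %g, penalty %g | detectability %g, turnover %g, learning %g\n",
    x$switching_cost, x$switchability_maintenance_cost, x$signaling_penalty,
    x$basal_detectability, x$predator_turnover, x$learning_speed
  ))
  cat("  strategies:", paste(x$allowed_strategies, collapse = " "), "\n")
  invisible(x)
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Derive population sizes from world size and occupancy frequencies
#'
#' Counts are `round(frequency * world_size^2)`, rounding half away from
#' zero. The reference 14 x 14 world with 92% / 23% occupancy yields 180 prey
#' and 45 predators.
#'
#' @inheritParams apo_config
#' @return A one-row tibble with columns `n_prey` and `n_predators`.
#' @examples
#' derive_counts(14, 0.92, 0.23)
#' @export
derive_counts <- function(world_size, prey_frequency, predator_frequency) {
  stopifnot(
    world_size >= 1,
    prey_frequency >= 0, prey_frequency <= 1,
    predator_frequency >= 0, predator_frequency <= 1
  )
  n_cells <- world_size^2
  tibble(
    n_prey = as.integer(round_half_away(prey_frequency * n_cells)),
    n_predators = as.integer(round_half_away(predator_frequency * n_cells))
  )
}

#' Read / write a configuration as a flat YAML document
#'
#' Every field is optional in the file; missing fields take the
#' [apo_config()] defaults. Strategy sets round-trip as character vectors of
#' codes.
#'
#' @param path File path.
#' @param config An `apo_config` object.
#' @return `read_config()` returns an `apo_config`; `write_config()` returns
#'   the config invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(apo_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown configuration field(s): ",
      paste(unknown, collapse = ", ")), class = "aposwitch_config_error")
  }
  do.call(apo_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "apo_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(config)
}
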