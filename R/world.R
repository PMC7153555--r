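#' Build the initial prey population
#'
#' The initial population is a uniform mix of the allowed strategies: each of
#' the `k` allowed strategies receives `floor(n_prey / k)` individuals and
#' the remainder slots are assigned to strategies drawn without replacement
#' uniformly at random. All prey start resting with survival chance 1, each
#' on a distinct random grid square.
#'
#' @param config An [apo_config()].
#' @return A tibble with columns `strategy`, `state`, `survival`, `cell`.
#' @examples
#' set.seed(1)
#' dplyr::count(build_initial_population(apo_config()), strategy)
#' @export
build_initial_population <- function(config) {
  counts <- derive_counts(config$world_size, config$prey_frequency,
    config$predator_frequency)
  n_prey <- counts$n_prey
  codes <- config$allowed_strategies
  k <- length(codes)
  if (k == 0) abort("`allowed_strategies` is empty.",
    class = "aposwitch_config_error")
  if (n_prey > 0 && n_prey < k) {
    abort(sprintf(
      "Cannot seed a uniform mix: %d prey but %d allowed strategies.",
      n_prey, k
    ), class = "aposwitch_config_error")
  }
  base <- rep(codes, each = n_prey %/% k)
  n_rem <- n_prey - length(base)
  extra <- if (n_rem > 0) sample(codes, n_rem, replace = FALSE) else character()
  strategy <- sample(c(base, extra)) # shuffle placement order
  tibble(
    strategy = strategy,
    state = "resting",
    survival = rep(1, n_prey),
    cell = sample.int(config$world_size^2, n_prey)
  )
}

#' Build the predator population
#'
#' All predators start naive: zero aversive memory, no target.
#'
#' @param config An [apo_config()].
#' @return A tibble with columns `memory`, `motivation`,
#'   `unconditional_stimulus`.
#' @examples
#' nrow(build_predators(apo_config()))
#' @export
build_predators <- function(config) {
  counts <- derive_counts(config$world_size, config$prey_frequency,
    config$predator_frequency)
  n <- counts$n_predators
  tibble(
    memory = rep(0, n),
    motivation = rep(1, n),
    unconditional_stimulus = rep(0, n)
  )
}

# --- internal world representation -----------------------------------------
# The frame loop runs over plain vectors; tibbles only at the interface.
# Strategy tables are precomputed: label index (1=N,2=L,3=H) and intensity
# per (strategy, state).

strategy_tables <- function(codes, levels) {
  p <- parse_strategy(codes)
  lv <- signal_labels()
  lab <- cbind(
    match(p$resting, lv), match(p$approached, lv), match(p$attacked, lv)
  )
  list(
    codes = p$code,
    label = lab,                       # k x 3 label index by state
    intensity = matrix(levels[lab], nrow = nrow(lab)), # k x 3
    switchable = !(lab[, 1] == lab[, 2] & lab[, 2] == lab[, 3]),
    level_values = unname(levels)      # length 3, indexed by label
  )
}

#' Assemble a simulation world
#'
#' Builds the internal world state from a configuration (or from explicit
#' prey / predator tibbles). Uses the current RNG state for initial
#' placement; seed externally or via [run_simulation()].
#'
#' @param config An [apo_config()].
#' @param prey,predators Optional tibbles in the formats of
#'   [build_initial_population()] and [build_predators()]; built from the
#'   config when omitted.
#' @return An object of class `apo_world`.
#' @export
apo_world <- function(config, prey = NULL, predators = NULL) {
  stopifnot(inherits(config, "apo_config"))
  if (is.null(prey)) prey <- build_initial_population(config)
  if (is.null(predators)) predators <- build_predators(config)
  levels <- signal_levels(config$intensity_L, config$intensity_H)
  st <- strategy_tables(config$allowed_strategies, levels)
  sidx <- match(toupper(prey$strategy), st$codes)
  if (anyNA(sidx)) {
    abort("Prey carry strategies outside `allowed_strategies`.",
      class = "aposwitch_config_error")
  }
  w <- list(
    strat = st,
    prey = list(
      strategy = sidx,
      state = rep(1L, nrow(prey)),
      level = st$label[cbind(sidx, 1L)],
      survival = as.numeric(prey$survival),
      cell = if ("cell" %in% names(prey)) prey$cell else
        seq_len(nrow(prey))
    ),
    pred = list(
      memory = as.numeric(predators$memory),
      motivation = rep(1, nrow(predators)),
      us = rep(0, nrow(predators)),
      target = rep(NA_integer_, nrow(predators))
    )
  )
  class(w) <- "apo_world"
  w
}

#' @export
print.apo_world <- function(x, ...) {
  cat(sprintf(
    "<apo_world> %d prey (%d strategies), %d predators, mean memory %.3g\n",
    length(x$prey$strategy), length(unique(x$prey$strategy)),
    length(x$pred$memory),
    if (length(x$pred$memory)) mean(x$pred$memory) else 0
  ))
  invisible(x)
}

#' Tidy views of a world's populations
#'
#' @param world An `apo_world`.
#' @return A tibble: one row per prey (strategy code, state, current signal
#'   intensity, survival chance, cell) or per predator (aversive memory,
#'   motivation, unconditional stimulus, target prey index).
#' @export
prey_tibble <- function(world) {
  stopifnot(inherits(world, "apo_world"))
  p <- world$prey
  tibble(
    strategy = world$strat$codes[p$strategy],
    state = threat_states()[p$state],
    intensity = world$strat$level_values[p$level],
    survival = p$survival,
    cell = p$cell
  )
}

#' @rdname prey_tibble
#' @export
predator_tibble <- function(world) {
  stopifnot(inherits(world, "apo_world"))
  q <- world$pred
  tibble(
    memory = q$memory,
    motivation = q$motivation,
    unconditional_stimulus = q$us,
    target = q$target
  )
}
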