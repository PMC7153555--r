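#' Per-step operations on population tables
#'
#' Tidy counterparts of the sub-procedures the frame loop runs internally,
#' for interactive exploration and testing. All take a tibble first and
#' return a tibble.
#'
#' @name steps
NULL

#' @rdname steps
#' @param prey Prey tibble with columns `strategy` and `state` (and
#'   `survival` where costs apply).
#' @param predators Predator tibble (columns `memory`, and where relevant
#'   `motivation`, `unconditional_stimulus`, `target`).
#' @param new_state Threat state(s) to transition to (recycled).
#' @param levels Intensity map from [signal_levels()].
#' @return `prey_react()`: the prey tibble with updated `state` and
#'   `intensity` plus a logical `switched` column (a switch is a change of
#'   level label).
#' @export
prey_react <- function(prey, new_state, levels = signal_levels()) {
  stopifnot(is.data.frame(prey), all(c("strategy", "state") %in% names(prey)))
  p <- parse_strategy(prey$strategy)
  old_label <- as.matrix(p[, threat_states()])[
    cbind(seq_len(nrow(p)), match(prey$state, threat_states()))]
  new_state <- rep_len(new_state, nrow(prey))
  new_label <- as.matrix(p[, threat_states()])[
    cbind(seq_len(nrow(p)), match(new_state, threat_states()))]
  prey$state <- new_state
  prey$intensity <- unname(levels[new_label])
  prey$switched <- new_label != old_label
  prey
}

#' @rdname steps
#' @param switched Logical vector: did each prey just change level?
#' @param config An [apo_config()].
#' @return `prey_pay_cost()`: the prey tibble with `survival` multiplied by
#'   `(1 - switching_cost)` where switched, `(1 - maintenance_cost)` for
#'   every switchable strategy, and `(1 - penalty * intensity)` always.
#' @export
prey_pay_cost <- function(prey, switched, config) {
  stopifnot(is.data.frame(prey), "survival" %in% names(prey))
  intensity <- if ("intensity" %in% names(prey)) {
    prey$intensity
  } else {
    intensity_for_state(prey$strategy, prey$state,
      signal_levels(config$intensity_L, config$intensity_H))
  }
  s <- prey$survival
  switched <- rep_len(switched, length(s))
  s[switched] <- s[switched] * (1 - config$switching_cost)
  sw <- is_switchable(prey$strategy)
  s[sw] <- s[sw] * (1 - config$switchability_maintenance_cost)
  prey$survival <- s * (1 - config$signaling_penalty * intensity)
  prey
}

#' @rdname steps
#' @param damage Attack damage fraction.
#' @return `apply_attack()`: the prey tibble with `survival` multiplied by
#'   `(1 - damage)`.
#' @export
apply_attack <- function(prey, damage) {
  stopifnot(is.data.frame(prey), "survival" %in% names(prey),
    damage >= 0, damage <= 1)
  prey$survival <- prey$survival * (1 - damage)
  prey
}

#' @rdname steps
#' @param motivation Attack probabilities in `[0, 1]`.
#' @return `decide_attack()`: a logical vector of Bernoulli outcomes.
#' @export
decide_attack <- function(motivation) {
  stopifnot(all(motivation >= 0 & motivation <= 1))
  stats::runif(length(motivation)) < motivation
}

#' @rdname steps
#' @param attacked Logical: did each predator attack this frame?
#' @param repulsive_taste Taste fraction felt during attacks.
#' @return `feel()`: the predator tibble with `unconditional_stimulus` set
#'   to the repulsive taste for attackers (unchanged 0 otherwise).
#' @export
feel <- function(predators, attacked, repulsive_taste) {
  stopifnot(is.data.frame(predators))
  if (!"unconditional_stimulus" %in% names(predators)) {
    predators$unconditional_stimulus <- 0
  }
  attacked <- rep_len(attacked, nrow(predators))
  predators$unconditional_stimulus[attacked] <- repulsive_taste
  predators
}

#' @rdname steps
#' @param cs Conditional stimulus each predator currently observes.
#' @param learning_speed Learning-speed coefficient.
#' @return `learn()`: the predator tibble with `memory` incremented by
#'   `learning_speed * unconditional_stimulus * cs` (so predators that never
#'   attacked, whose unconditional stimulus is 0, gain nothing).
#' @export
learn <- function(predators, cs, learning_speed) {
  stopifnot(is.data.frame(predators), "memory" %in% names(predators))
  us <- if ("unconditional_stimulus" %in% names(predators)) {
    predators$unconditional_stimulus
  } else {
    0
  }
  predators$memory <- predators$memory + learning_speed * us * cs
  predators
}

#' @rdname steps
#' @param allow_shared_targets Sample prey with replacement (default
#'   `FALSE`: each prey faces at most one predator; surplus predators idle).
#' @return `assign_predators()`: the predator tibble with a `target` column
#'   (row index into `prey`, `NA` for idle), `motivation` reset to 1 and
#'   `unconditional_stimulus` cleared.
#' @export
assign_predators <- function(prey, predators, allow_shared_targets = FALSE) {
  stopifnot(is.data.frame(prey), is.data.frame(predators))
  n_prey <- nrow(prey)
  n_pred <- nrow(predators)
  target <- rep(NA_integer_, n_pred)
  if (n_pred > 0 && n_prey > 0) {
    if (allow_shared_targets) {
      target <- sample.int(n_prey, n_pred, replace = TRUE)
    } else {
      k <- min(n_pred, n_prey)
      target[seq_len(k)] <- sample.int(n_prey, k)
    }
  }
  predators$target <- target
  predators$motivation <- 1
  predators$unconditional_stimulus <- 0
  predators
}
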