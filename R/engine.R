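#' Predator perception and decision equations
#'
#' The perceptual core of the model, as pure vectorized functions.
#'
#' * `discovery_chance()`: probability that a searching predator detects the
#'   prey. Basal detectability sets the floor and signal intensity fills the
#'   remaining headroom additively:
#'   `bd + intensity * (1 - bd)`.
#' * `conditional_stimulus()`: strength of the appearance cue that mediates
#'   associative learning and recall, same additive form with the basal
#'   cognitive cue as the floor.
#' * `learned_repulsiveness()`: recall of the stored aversion,
#'   `min(1, memory * cs)`; a naive predator (memory 0) has none, and a
#'   sufficiently experienced one saturates at 1 however faint the cue.
#' * `prey_attractiveness()`: `(1 - learned) * (1 - instinctive)`; both
#'   repulsiveness channels must be near 0 for the prey to look worth
#'   attacking.
#' * `update_motivation()`: per-encounter attack probability, initialized at
#'   1 and multiplied by the current attractiveness after each assessment.
#'
#' @param basal_detectability,basal_cognitive_cue,intensity,cs,lr,ir,motivation,attractiveness
#'   Numeric vectors of fractions in `[0, 1]`.
#' @param memory Non-negative aversive memory (unbounded above).
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' discovery_chance(0.4, 0.3) # 0.58
#' conditional_stimulus(0.1, 1) # 1
#' learned_repulsiveness(5, 0.1) # 0.5
#' prey_attractiveness(0.1, 0.1) # 0.81
#' @name perception
NULL

#' @rdname perception
#' @export
discovery_chance <- function(basal_detectability, intensity) {
  basal_detectability + intensity * (1 - basal_detectability)
}

#' @rdname perception
#' @export
conditional_stimulus <- function(basal_cognitive_cue, intensity) {
  basal_cognitive_cue + intensity * (1 - basal_cognitive_cue)
}

#' @rdname perception
#' @export
learned_repulsiveness <- function(memory, cs) {
  pmin(1, memory * cs)
}

#' @rdname perception
#' @export
prey_attractiveness <- function(lr, ir) {
  (1 - lr) * (1 - ir)
}

#' @rdname perception
#' @export
update_motivation <- function(motivation, attractiveness) {
  motivation * attractiveness
}

# --- scripted draw queue ----------------------------------------------------
# A forced-outcome source consumed in place of the RNG for single-pair
# micro-worlds: logical outcomes popped in event order
# (detection, initial attack, subsequent attack).
make_draw_queue <- function(outcomes) {
  stopifnot(is.logical(outcomes))
  env <- new.env(parent = emptyenv())
  env$outcomes <- outcomes
  env$pos <- 0L
  env
}

pop_draws <- function(queue, n) {
  if (n == 0) return(logical())
  if (queue$pos + n > length(queue$outcomes)) {
    abort("Forced-draw script exhausted: the frame required more draws than scripted.",
      class = "aposwitch_fixture_error")
  }
  out <- queue$outcomes[queue$pos + seq_len(n)]
  queue$pos <- queue$pos + n
  out
}

# Bernoulli draws: real RNG, or scripted outcomes when a queue is supplied.
draw_bernoulli <- function(p, queue = NULL) {
  if (is.null(queue)) stats::runif(length(p)) < p else pop_draws(queue, length(p))
}

# Per-generation frame cache: everything that is constant while the prey
# strategy vector does not change.
frame_cache <- function(w, config) {
  sidx <- w$prey$strategy
  k <- length(w$strat$codes)
  lab <- w$strat$label
  lvals <- w$strat$level_values
  sw_flag <- w$strat$switchable[sidx]
  mcfac <- ifelse(sw_flag, 1 - config$switchability_maintenance_cost, 1)
  penfac <- 1 - config$signaling_penalty * lvals # by level label
  list(
    sidx = sidx,
    sw_flag = sw_flag,
    level_rest = lab[sidx], # column 1
    level_app = lab[sidx + k],
    level_att = lab[sidx + 2L * k],
    mcfac = mcfac,
    penfac = penfac,
    rest_fac = mcfac * penfac[lab[sidx]],
    lvals = lvals,
    sc1 = 1 - config$switching_cost
  )
}

#' Run one interaction frame
#'
#' Executes the three time steps of an interaction frame on a world whose
#' prey are all resting: (1) predators move onto random occupied squares,
#' prey react and pay costs, predators search (the single detection check of
#' the frame), observe, analyze and decide; (2) initial attack or
#' abandonment, attack damage, taste, prey reaction and costs, observation,
#' learning, reassessment; (3) subsequent attack or abandonment, damage,
#' reaction and costs, final learning. At frame end all prey revert to
#' resting free of charge.
#'
#' @param world An [apo_world()] with all prey resting.
#' @param config The [apo_config()] the world was built under.
#' @param draws Optional logical vector of forced Bernoulli outcomes consumed
#'   in event order (detection, initial attack, subsequent attack) instead of
#'   the RNG. Only permitted for single-predator, single-prey micro-worlds.
#' @param trace If `TRUE`, attach a `"trace"` attribute recording every
#'   intermediate quantity of the frame (per step: prey survival and
#'   intensity, conditional stimulus, repulsiveness terms, attractiveness,
#'   motivation, memory, detection/attack outcomes).
#' @return The updated world (invisibly carries the trace attribute when
#'   requested).
#' @export
run_frame <- function(world, config, draws = NULL, trace = FALSE) {
  w <- world
  n_prey <- length(w$prey$strategy)
  n_pred <- length(w$pred$memory)
  if (any(w$prey$state != 1L)) {
    abort("run_frame() requires all prey to start the frame resting.",
      class = "aposwitch_engine_error")
  }
  queue <- NULL
  if (!is.null(draws)) {
    if (n_pred != 1L || n_prey != 1L) {
      abort("Forced draws are only supported in 1-predator x 1-prey micro-worlds.",
        class = "aposwitch_fixture_error")
    }
    queue <- make_draw_queue(as.logical(draws))
  }
  cache <- w$cache
  if (is.null(cache)) cache <- w$cache <- frame_cache(w, config)
  tr <- if (trace) list() else NULL

  survival <- w$prey$survival
  level <- cache$level_rest # all prey resting at frame start
  memory <- w$pred$memory
  motivation <- rep(1, n_pred) # new encounter
  us <- rep(0, n_pred)

  # ---- STEP 1: predators-move, prey-react, prey-pay-cost, search,
  # observe, analyze, decide
  target <- rep(NA_integer_, n_pred)
  if (n_pred > 0 && n_prey > 0) {
    if (!is.null(queue)) {
      target[1L] <- 1L
    } else if (config$allow_shared_targets) {
      target <- sample.int(n_prey, n_pred, replace = TRUE)
    } else {
      kk <- min(n_pred, n_prey) # surplus predators idle this frame
      target[seq_len(kk)] <- sample.int(n_prey, kk)
    }
  }
  paired <- which(!is.na(target))
  tp <- target[paired] # approached prey indices (unique unless shared)

  new_level <- level
  new_level[tp] <- cache$level_app[tp]
  switched <- which(new_level != level)
  switched_up <- new_level[switched] > level[switched]
  level <- new_level
  fac <- cache$rest_fac
  if (length(tp) > 0) fac[tp] <- cache$mcfac[tp] * cache$penfac[level[tp]]
  survival <- survival * fac
  charge <- if (config$cost_on_switch_off) switched else switched[switched_up]
  if (length(charge) > 0) survival[charge] <- survival[charge] * cache$sc1

  detected <- rep(FALSE, n_pred)
  if (length(paired) > 0) {
    i_target <- cache$lvals[level[target[paired]]]
    p_detect <- discovery_chance(config$basal_detectability, i_target)
    detected[paired] <- draw_bernoulli(p_detect, queue)
  }
  engaged <- which(detected)
  cs1 <- lr1 <- attr1 <- rep(NA_real_, if (trace) n_pred else 0)
  if (length(engaged) > 0) {
    i_t <- cache$lvals[level[target[engaged]]]
    cs <- conditional_stimulus(config$basal_cognitive_cue, i_t)
    lr <- learned_repulsiveness(memory[engaged], cs)
    att <- prey_attractiveness(lr, us[engaged]) # us still 0: nothing tasted
    motivation[engaged] <- motivation[engaged] * att
    if (trace) { cs1[engaged] <- cs; lr1[engaged] <- lr; attr1[engaged] <- att }
  }
  if (trace) {
    tr$step1 <- list(
      target = target, detected = detected,
      switched = seq_len(n_prey) %in% switched,
      survival = survival, intensity = cache$lvals[level],
      cs = cs1, lr = lr1, attractiveness = attr1, motivation = motivation
    )
  }

  # ---- STEP 2: initial-act, feel, prey-react, prey-pay-cost, observe,
  # learn, analyze, decide
  attacked1 <- rep(FALSE, n_pred)
  if (length(engaged) > 0) {
    attacked1[engaged] <- draw_bernoulli(motivation[engaged], queue)
  }
  attackers <- which(attacked1) # abandoners idle for the rest of the frame
  hit <- integer(0)
  if (length(attackers) > 0) {
    hits <- tabulate(target[attackers], nbins = n_prey)
    hit <- which(hits > 0)
    survival[hit] <- survival[hit] *
      (1 - config$initial_attack_damage)^hits[hit]
    us[attackers] <- config$repulsive_taste # feel
  }
  # prey-react: attacked prey display their attacked level; approached prey
  # whose predator failed or abandoned revert to resting
  new_level <- cache$level_rest
  new_level[hit] <- cache$level_att[hit]
  switched <- which(new_level != level)
  switched_up <- new_level[switched] > level[switched]
  level <- new_level
  fac <- cache$rest_fac
  if (length(hit) > 0) fac[hit] <- cache$mcfac[hit] * cache$penfac[level[hit]]
  survival <- survival * fac
  charge <- if (config$cost_on_switch_off) switched else switched[switched_up]
  if (length(charge) > 0) survival[charge] <- survival[charge] * cache$sc1

  cs2 <- lr2 <- attr2 <- rep(NA_real_, if (trace) n_pred else 0)
  if (length(attackers) > 0) {
    i_t <- cache$lvals[level[target[attackers]]]
    cs <- conditional_stimulus(config$basal_cognitive_cue, i_t)
    memory[attackers] <- memory[attackers] +
      config$learning_speed * us[attackers] * cs
    lr <- learned_repulsiveness(memory[attackers], cs)
    att <- prey_attractiveness(lr, us[attackers])
    motivation[attackers] <- motivation[attackers] * att
    if (trace) {
      cs2[attackers] <- cs; lr2[attackers] <- lr; attr2[attackers] <- att
    }
  }
  if (trace) {
    tr$step2 <- list(
      attacked = attacked1, switched = seq_len(n_prey) %in% switched,
      survival = survival, intensity = cache$lvals[level],
      us = us, cs = cs2, lr = lr2, attractiveness = attr2,
      motivation = motivation, memory = memory
    )
  }

  # ---- STEP 3: subsequent-act, feel, prey-react, prey-pay-cost, observe,
  # learn
  attacked2 <- rep(FALSE, n_pred)
  if (length(attackers) > 0) {
    attacked2[attackers] <- draw_bernoulli(motivation[attackers], queue)
  }
  attackers2 <- which(attacked2)
  hit2 <- integer(0)
  if (length(attackers2) > 0) {
    hits <- tabulate(target[attackers2], nbins = n_prey)
    hit2 <- which(hits > 0)
    survival[hit2] <- survival[hit2] *
      (1 - config$subsequent_attack_damage)^hits[hit2]
  }
  # feel: a subsequent attack carries the same taste already felt
  new_level <- cache$level_rest
  new_level[hit2] <- cache$level_att[hit2]
  switched <- which(new_level != level)
  switched_up <- new_level[switched] > level[switched]
  level <- new_level
  fac <- cache$rest_fac
  if (length(hit2) > 0) {
    fac[hit2] <- cache$mcfac[hit2] * cache$penfac[level[hit2]]
  }
  survival <- survival * fac
  charge <- if (config$cost_on_switch_off) switched else switched[switched_up]
  if (length(charge) > 0) survival[charge] <- survival[charge] * cache$sc1

  learners <- if (config$learn_on_step3_abandon) attackers else attackers2
  cs3 <- rep(NA_real_, if (trace) n_pred else 0)
  if (length(learners) > 0) {
    i_t <- cache$lvals[level[target[learners]]]
    cs <- conditional_stimulus(config$basal_cognitive_cue, i_t)
    memory[learners] <- memory[learners] +
      config$learning_speed * us[learners] * cs
    if (trace) cs3[learners] <- cs
  }
  if (trace) {
    tr$step3 <- list(
      attacked = attacked2, switched = seq_len(n_prey) %in% switched,
      survival = survival, intensity = cache$lvals[level],
      cs = cs3, memory = memory
    )
  }

  # frame end: free reversion to resting
  w$prey$survival <- survival
  w$prey$level <- cache$level_rest
  w$pred$memory <- memory
  w$pred$motivation <- motivation
  w$pred$us <- us
  w$pred$target <- target
  w$cache <- cache
  if (trace) {
    tr$end <- list(survival = survival, memory = memory)
    attr(w, "trace") <- tr
  }
  w
}
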