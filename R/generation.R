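#' Reproduction-stage operations
#'
#' The end-of-generation pipeline: prey survive Bernoulli trials at their
#' final survival chance, the survivors reproduce clonally until the
#' carrying capacity is refilled, strategies that dropped out are rescued,
#' and part of the predator population is replaced by naive individuals.
#'
#' @param prey A prey tibble with at least columns `strategy` and `survival`.
#' @return `selective_death()`: the surviving rows.
#' @examples
#' set.seed(1)
#' prey <- tibble::tibble(strategy = rep("NNH", 6), survival = c(1, 1, 0, 0.5, 0.5, 0.5))
#' nrow(selective_death(prey))
#' @name reproduction
NULL

#' @rdname reproduction
#' @export
selective_death <- function(prey) {
  stopifnot(is.data.frame(prey), "survival" %in% names(prey))
  prey[stats::runif(nrow(prey)) < prey$survival, , drop = FALSE]
}

#' @rdname reproduction
#' @param survivors Tibble of surviving prey (parents).
#' @param capacity Carrying capacity of the next generation.
#' @param fallback Pre-death population to draw parents from when no prey
#'   survived selection (extinction rescue at the whole-population level).
#' @return `reproduce_prey()`: a tibble of `capacity` offspring, clones of
#'   uniformly (with replacement) sampled parents, each with survival 1 and
#'   state `"resting"`.
#' @export
reproduce_prey <- function(survivors, capacity, fallback = NULL) {
  stopifnot(capacity >= 1)
  parents <- if (nrow(survivors) > 0) survivors else fallback
  if (is.null(parents) || nrow(parents) == 0) {
    abort("No survivors and no fallback population to reproduce from.",
      class = "aposwitch_engine_error")
  }
  picks <- sample.int(nrow(parents), capacity, replace = TRUE)
  tibble(
    strategy = parents$strategy[picks],
    state = "resting",
    survival = rep(1, capacity)
  )
}

#' @rdname reproduction
#' @param next_gen Offspring tibble at capacity.
#' @param allowed Character vector of strategy codes that must all be
#'   present.
#' @return `prevent_extinction()`: the repaired tibble — for every allowed
#'   strategy absent from `next_gen` (processed in random order), one
#'   uniformly chosen individual is replaced by a fresh individual of the
#'   missing strategy. Victims are drawn among individuals that are not the
#'   sole representative of an allowed strategy, so every allowed strategy
#'   ends with count >= 1. Total count is conserved.
#' @export
prevent_extinction <- function(next_gen, allowed) {
  stopifnot(is.data.frame(next_gen), "strategy" %in% names(next_gen))
  allowed <- toupper(allowed)
  if (nrow(next_gen) < length(allowed)) {
    abort("Carrying capacity is below the number of allowed strategies.",
      class = "aposwitch_config_error")
  }
  missing <- setdiff(allowed, unique(next_gen$strategy))
  if (length(missing) == 0) return(next_gen)
  if (length(missing) > 1) missing <- sample(missing)
  for (code in missing) {
    counts <- table(next_gen$strategy)
    sole <- names(counts)[counts == 1 & names(counts) %in% allowed]
    eligible <- which(!(next_gen$strategy %in% sole))
    victim <- eligible[sample.int(length(eligible), 1)]
    next_gen$strategy[victim] <- code
    next_gen$survival[victim] <- 1
    if ("state" %in% names(next_gen)) next_gen$state[victim] <- "resting"
  }
  next_gen
}

#' @rdname reproduction
#' @param predators Predator tibble with a `memory` column.
#' @param rate Turnover rate in `[0, 1]`.
#' @param stochastic If `TRUE` (default), each predator is independently
#'   replaced with probability `rate`; if `FALSE`, a deterministic
#'   `round(rate * n)` random predators are replaced.
#' @return `predator_turnover()`: the updated tibble with replaced
#'   individuals reset to zero memory and a logical `replaced` column.
#' @export
predator_turnover <- function(predators, rate, stochastic = TRUE) {
  stopifnot(is.data.frame(predators), "memory" %in% names(predators),
    rate >= 0, rate <= 1)
  n <- nrow(predators)
  replaced <- if (stochastic) {
    stats::runif(n) < rate
  } else {
    out <- rep(FALSE, n)
    k <- as.integer(round_half_away(rate * n))
    if (k > 0) out[sample.int(n, min(k, n))] <- TRUE
    out
  }
  predators$memory[replaced] <- 0
  if ("motivation" %in% names(predators)) predators$motivation[replaced] <- 1
  if ("unconditional_stimulus" %in% names(predators)) {
    predators$unconditional_stimulus[replaced] <- 0
  }
  predators$replaced <- replaced
  predators
}

#' Run a full simulation to a winning strategy
#'
#' Runs `n_generations` prey generations, each of `generation_length`
#' interaction frames followed by the reproduction stage (selective death,
#' clonal refill to capacity, extinction rescue, predator turnover). The
#' winner is the most abundant strategy in the final population; ties are
#' broken uniformly at random and flagged.
#'
#' @param config An [apo_config()].
#' @param seed Integer RNG seed; defaults to `config$rng_seed`. A given
#'   (config, seed) pair is fully deterministic.
#' @param record_generations Keep the per-generation records (default
#'   `TRUE`; disable to save memory in large sweeps).
#' @return An object of class `apo_run` with fields `winner`, `tie`,
#'   `tied_set`, `final_counts` (named integer vector over the allowed
#'   codes), `generations` (tibble of per-generation records), `config`,
#'   `seed`. Use [generics::tidy()] / [generics::glance()] for tabular
#'   views.
#' @examples
#' cfg <- apo_config(world_size = 5, n_generations = 5, generation_length = 5)
#' run <- run_simulation(cfg, seed = 1)
#' run$winner
#' tidy(run)
#' @export
run_simulation <- function(config, seed = config$rng_seed,
                           record_generations = TRUE) {
  stopifnot(inherits(config, "apo_config"))
  set.seed(as.integer(seed))
  counts <- derive_counts(config$world_size, config$prey_frequency,
    config$predator_frequency)
  capacity <- counts$n_prey
  codes <- config$allowed_strategies
  w <- apo_world(config)
  recs <- if (record_generations) vector("list", config$n_generations)

  for (g in seq_len(config$n_generations)) {
    start_counts <- tabulate(w$prey$strategy, nbins = length(codes))
    for (f in seq_len(config$generation_length)) {
      w <- run_frame(w, config)
    }
    # reproduction stage
    prey_now <- tibble(
      strategy = w$strat$codes[w$prey$strategy],
      survival = w$prey$survival
    )
    survivors <- selective_death(prey_now)
    offspring <- if (capacity > 0) {
      prevent_extinction(
        reproduce_prey(survivors, capacity, fallback = prey_now),
        codes
      )
    } else {
      prey_now[0, ]
    }
    mean_memory <- if (length(w$pred$memory)) mean(w$pred$memory) else 0
    pred_next <- predator_turnover(
      tibble(memory = w$pred$memory),
      config$predator_turnover,
      stochastic = config$turnover_stochastic
    )
    if (record_generations) {
      rec <- c(
        list(
          generation = g,
          n_survivors = nrow(survivors),
          mean_predator_memory = mean_memory,
          n_predators_replaced = sum(pred_next$replaced)
        ),
        stats::setNames(as.list(start_counts), paste0("count_", codes))
      )
      recs[[g]] <- rec
    }
    # prey-emerge: next generation activates on fresh random squares
    sidx <- match(offspring$strategy, codes)
    w$prey$strategy <- sidx
    w$prey$state <- rep(1L, capacity)
    w$prey$level <- w$strat$label[cbind(sidx, 1L)]
    w$prey$survival <- rep(1, capacity)
    w$prey$cell <- if (capacity > 0) {
      sample.int(config$world_size^2, capacity)
    } else {
      integer()
    }
    w$pred$memory <- pred_next$memory
    w$pred$motivation <- rep(1, length(pred_next$memory))
    w$pred$us <- rep(0, length(pred_next$memory))
    w$cache <- NULL # strategy vector changed
  }

  final_counts <- stats::setNames(
    tabulate(w$prey$strategy, nbins = length(codes)), codes
  )
  top <- max(final_counts)
  tied_set <- names(final_counts)[final_counts == top]
  tie <- length(tied_set) > 1
  winner <- if (tie) sample(tied_set, 1) else tied_set

  out <- list(
    winner = winner,
    tie = tie,
    tied_set = tied_set,
    final_counts = final_counts,
    generations = if (record_generations) {
      dplyr::bind_rows(lapply(recs, tibble::as_tibble_row))
    } else {
      NULL
    },
    config = config,
    seed = as.integer(seed)
  )
  class(out) <- "apo_run"
  out
}

#' @export
print.apo_run <- function(x, ...) {
  cat(sprintf(
    "<apo_run> winner %s%s after %d generations (seed %d)\n",
    x$winner, if (x$tie) sprintf(" (tie among %s)",
      paste(x$tied_set, collapse = ", ")) else "",
    x$config$n_generations, x$seed
  ))
  cat("  final counts:",
    paste(sprintf("%s=%d", names(x$final_counts), x$final_counts),
      collapse = " "), "\n")
  invisible(x)
}

#' Tidy per-generation records of a run
#'
#' @param x An `apo_run`.
#' @param ... Unused.
#' @return A tibble with one row per generation: `generation`,
#'   `n_survivors`, `mean_predator_memory` (end of generation, before
#'   turnover), `n_predators_replaced`, and one `count_<CODE>` column per
#'   allowed strategy (counts at generation start).
#' @exportS3Method generics::tidy
tidy.apo_run <- function(x, ...) {
  if (is.null(x$generations)) {
    abort("Run was executed with record_generations = FALSE.")
  }
  x$generations
}

#' One-row summary of a run
#'
#' @param x An `apo_run`.
#' @param ... Unused.
#' @return A one-row tibble: `winner`, `tie`, `seed`, `n_generations`, and
#'   final `count_<CODE>` columns.
#' @exportS3Method generics::glance
glance.apo_run <- function(x, ...) {
  dplyr::bind_cols(
    tibble(
      winner = x$winner, tie = x$tie, seed = x$seed,
      n_generations = x$config$n_generations
    ),
    tibble::as_tibble_row(stats::setNames(
      as.list(as.integer(x$final_counts)),
      paste0("count_", names(x$final_counts))
    ))
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
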