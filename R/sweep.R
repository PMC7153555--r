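#' The signal-penalty ladder of the reference experiment
#'
#' Fifty nonzero levels forming a geometric sequence from 0.13 with ratio
#' 0.85 (so the last two nonzero terms are about 5.32e-5 and 4.52e-5),
#' followed by 0: 51 levels in all, strictly decreasing.
#'
#' @return Numeric vector of length 51.
#' @examples
#' head(signal_penalty_levels())
#' @export
signal_penalty_levels <- function() {
  c(0.13 * 0.85^(0:49), 0)
}

#' Joint presets for the penalty of switchable signals
#'
#' Switching cost (per use) and switchability maintenance cost (per time
#' step) co-vary between three states.
#'
#' @return A tibble with columns `level` (`none`, `moderate`, `high`),
#'   `switching_cost` and `maintenance_cost`.
#' @examples
#' switchable_penalty_presets()
#' @export
switchable_penalty_presets <- function() {
  tibble(
    level = c("none", "moderate", "high"),
    switching_cost = c(0, 0.0005, 0.016),
    maintenance_cost = c(0, 2.03e-4, 0.00340)
  )
}

# deterministic per-run seed from (master seed, condition index, repeat);
# kept well below 2^31 so it is a valid set.seed() argument everywhere
derive_run_seed <- function(master_seed, condition_id, repeat_index) {
  h <- (abs(as.numeric(master_seed)) %% 1e6) * 1000003 +
    as.numeric(condition_id) * 131 + as.numeric(repeat_index) * 7919
  as.integer(h %% 2147483647)
}

#' Build a factorial sweep grid
#'
#' Crosses the five experiment variables — switchable-signal penalty level,
#' basal detectability, predator turnover, learning speed and signaling
#' penalty — with a repeat index, and attaches a deterministic per-run seed.
#' The default factor levels form the reference grid: 3 x 4 x 4 x 12 x 51 =
#' 29,376 conditions, 88,128 runs at three repeats.
#'
#' @param master_seed Integer master seed; per-run seeds are a fixed
#'   function of it and the condition coordinates, so any subset of the
#'   sweep is reproducible in isolation.
#' @param repeats Repeats per condition (default 3).
#' @param switch_penalty_levels Character subset of
#'   `switchable_penalty_presets()$level`.
#' @param basal_detectability,predator_turnover,learning_speed,signaling_penalty
#'   Numeric factor levels.
#' @return A tibble with one row per run: `condition_id`,
#'   `switch_penalty_level`, `switching_cost`, `maintenance_cost`, the four
#'   numeric variables, `repeat`, `seed`.
#' @examples
#' nrow(build_grid(1, repeats = 1)) # 29376
#' @export
build_grid <- function(master_seed = 1L, repeats = 3L,
                       switch_penalty_levels = c("none", "moderate", "high"),
                       basal_detectability = c(0.05, 0.15, 0.4, 0.8),
                       predator_turnover = c(0.01, 0.25, 0.7, 1),
                       learning_speed = c(0, 0.01, 0.03, 0.1, 0.3, 1, 3,
                         10, 30, 100, 300, 1000),
                       signaling_penalty = signal_penalty_levels()) {
  stopifnot(repeats >= 1)
  presets <- switchable_penalty_presets()
  bad <- setdiff(switch_penalty_levels, presets$level)
  if (length(bad) > 0) {
    abort(paste0("Unknown switchable-penalty level(s): ",
      paste(bad, collapse = ", ")), class = "aposwitch_config_error")
  }
  conditions <- tidyr::expand_grid(
    switch_penalty_level = switch_penalty_levels,
    basal_detectability = basal_detectability,
    predator_turnover = predator_turnover,
    learning_speed = learning_speed,
    signaling_penalty = signaling_penalty
  )
  conditions$condition_id <- seq_len(nrow(conditions))
  grid <- tidyr::expand_grid(conditions, "repeat" = seq_len(repeats))
  grid <- dplyr::left_join(grid, presets,
    by = c(switch_penalty_level = "level"))
  grid$seed <- derive_run_seed(master_seed, grid$condition_id, grid$`repeat`)
  grid[, c(
    "condition_id", "switch_penalty_level", "switching_cost",
    "maintenance_cost", "basal_detectability", "predator_turnover",
    "learning_speed", "signaling_penalty", "repeat", "seed"
  )]
}

#' A reduced smoke-test grid
#'
#' A 2 x 2 x 2 x 3 x 5 sub-grid of the reference factors (360 runs at three
#' repeats), small enough for routine regression use.
#'
#' @inheritParams build_grid
#' @return A tibble as from [build_grid()].
#' @export
smoke_grid <- function(master_seed = 1L, repeats = 3L) {
  build_grid(
    master_seed = master_seed, repeats = repeats,
    switch_penalty_levels = c("none", "moderate"),
    basal_detectability = c(0.05, 0.4),
    predator_turnover = c(0.25, 1),
    learning_speed = c(0, 1, 100),
    signaling_penalty = c(0.13, 0.03, 0.008, 0.002, 0)
  )
}

#' Execute a sweep grid
#'
#' Runs [run_simulation()] once per grid row. Runs are independent; with
#' `workers > 1` they are dispatched with `parallel::mclapply()`, and
#' results are assembled in grid order regardless of completion order, so
#' the output is invariant to the worker count. A failed run yields a row
#' with `NA` winner and the error message; it does not abort the sweep.
#'
#' @param grid A tibble from [build_grid()] (or any subset of its rows).
#' @param base_config The configuration holding every parameter the grid
#'   does not vary.
#' @param workers Number of parallel workers (default 1).
#' @param n_generations Optional override of `base_config$n_generations`
#'   (e.g. 50 for smoke-scale sweeps).
#' @param checkpoint Optional CSV path: completed rows are appended as the
#'   sweep progresses, and rows already present are not recomputed on a
#'   resumed call.
#' @return A tibble with one row per run: the grid columns, then `winner`,
#'   `tie`, `error`, and `count_<CODE>` for each allowed strategy.
#' @examples
#' g <- smoke_grid(1)[1:2, ]
#' run_sweep(g, apo_config(world_size = 5, generation_length = 5),
#'   n_generations = 3)
#' @export
run_sweep <- function(grid, base_config = apo_config(), workers = 1L,
                      n_generations = NULL, checkpoint = NULL) {
  stopifnot(is.data.frame(grid))
  if (nrow(grid) == 0) return(empty_sweep_result(base_config))
  cfg0 <- base_config
  if (!is.null(n_generations)) cfg0$n_generations <- as.integer(n_generations)
  codes <- cfg0$allowed_strategies

  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- utils::read.csv(checkpoint, check.names = FALSE)
  }
  todo <- seq_len(nrow(grid))
  if (!is.null(done) && nrow(done) > 0) {
    key <- paste(grid$condition_id, grid$`repeat`)
    todo <- todo[!(key %in% paste(done$condition_id, done$`repeat`))]
  }

  one_run <- function(i) {
    row <- grid[i, ]
    res <- tryCatch({
      cfg <- cfg0
      cfg$switching_cost <- row$switching_cost
      cfg$switchability_maintenance_cost <- row$maintenance_cost
      cfg$basal_detectability <- row$basal_detectability
      cfg$predator_turnover <- row$predator_turnover
      cfg$learning_speed <- row$learning_speed
      cfg$signaling_penalty <- row$signaling_penalty
      run <- run_simulation(cfg, seed = row$seed,
        record_generations = FALSE)
      c(
        list(winner = run$winner, tie = run$tie, error = NA_character_),
        stats::setNames(as.list(as.integer(run$final_counts)),
          paste0("count_", codes))
      )
    }, error = function(e) {
      c(
        list(winner = NA_character_, tie = NA, error = conditionMessage(e)),
        stats::setNames(as.list(rep(NA_integer_, length(codes))),
          paste0("count_", codes))
      )
    })
    dplyr::bind_cols(row, tibble::as_tibble_row(res))
  }

  results <- if (workers > 1 && requireNamespace("parallel", quietly = TRUE) &&
    .Platform$OS.type == "unix") {
    parallel::mclapply(todo, one_run, mc.cores = workers,
      mc.preschedule = TRUE)
  } else {
    lapply(todo, one_run)
  }
  new_rows <- dplyr::bind_rows(results)
  out <- if (!is.null(done) && nrow(done) > 0) {
    dplyr::bind_rows(as_tibble(done), new_rows)
  } else {
    new_rows
  }
  out <- dplyr::arrange(out, .data$condition_id, .data$`repeat`)
  if (!is.null(checkpoint)) {
    utils::write.csv(out, checkpoint, row.names = FALSE)
  }
  class(out) <- c("apo_sweep", class(out))
  out
}

empty_sweep_result <- function(config) {
  out <- tibble(
    condition_id = integer(), switch_penalty_level = character(),
    switching_cost = numeric(), maintenance_cost = numeric(),
    basal_detectability = numeric(), predator_turnover = numeric(),
    learning_speed = numeric(), signaling_penalty = numeric(),
    "repeat" = integer(), seed = integer(),
    winner = character(), tie = logical(), error = character()
  )
  for (code in config$allowed_strategies) out[[paste0("count_", code)]] <- integer()
  class(out) <- c("apo_sweep", class(out))
  out
}

#' Write sweep results as CSV
#'
#' Column order is fixed: condition coordinates, repeat, seed, winner, tie,
#' then the per-strategy final counts.
#'
#' @param result An `apo_sweep` tibble from [run_sweep()].
#' @param path Output CSV path.
#' @return The result, invisibly.
#' @export
write_sweep <- function(result, path) {
  count_cols <- grep("^count_", names(result), value = TRUE)
  cols <- c(
    "condition_id", "switch_penalty_level", "switching_cost",
    "maintenance_cost", "basal_detectability", "predator_turnover",
    "learning_speed", "signaling_penalty", "repeat", "seed", "winner",
    "tie", count_cols
  )
  utils::write.csv(as.data.frame(result)[, cols], path, row.names = FALSE)
  invisible(result)
}

#' Read sweep results written by [write_sweep()]
#'
#' @param path CSV path.
#' @return An `apo_sweep` tibble.
#' @export
read_sweep <- function(path) {
  out <- as_tibble(utils::read.csv(path, check.names = FALSE))
  class(out) <- c("apo_sweep", class(out))
  out
}
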