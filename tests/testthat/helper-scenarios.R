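# Shared fixtures: randomized micro-scenario parameters, forced-draw
# combinations, and a trace-vs-oracle comparator.

# The worked reference trace: a post-attack switcher meeting a naive
# predator, detection and both attacks forced. Only the signaling penalty
# (0.1) and basal detectability (0.4) are pinned; everything else is the
# package default.
trace_scenario <- function() {
  make_single_pair_scenario(
    "NNH",
    list(basal_detectability = 0.4, signaling_penalty = 0.1),
    draw_script = c(TRUE, TRUE, TRUE)
  )
}

# random but valid single-pair parameters (no correlation with any seed the
# engine consumes: scenarios are draw-scripted)
random_overrides <- function() {
  l <- runif(1)
  list(
    intensity_L = l,
    intensity_H = runif(1, l, 1),
    basal_detectability = runif(1),
    basal_cognitive_cue = runif(1),
    repulsive_taste = runif(1),
    initial_attack_damage = runif(1, 0, 0.9),
    subsequent_attack_damage = runif(1, 0, 0.9),
    switching_cost = runif(1, 0, 0.1),
    switchability_maintenance_cost = runif(1, 0, 0.02),
    signaling_penalty = runif(1, 0, 0.3),
    learning_speed = runif(1, 0, 5)
  )
}

# all 2^3 forced-outcome combinations (detection, initial, subsequent);
# later draws are simply never consumed when an earlier one is FALSE
all_draw_combos <- function() {
  g <- expand.grid(d = c(FALSE, TRUE), a1 = c(FALSE, TRUE),
    a2 = c(FALSE, TRUE))
  lapply(seq_len(nrow(g)), function(i) c(g$d[i], g$a1[i], g$a2[i]))
}

expect_close <- function(x, y, tol = 1e-12) {
  if (length(x) == 0 && length(y) == 0) return(invisible(TRUE))
  both_na <- is.na(x) & is.na(y)
  expect_equal(is.na(x), is.na(y))
  if (!all(both_na)) {
    expect_lt(max(abs(x[!both_na] - y[!both_na])), tol)
  }
  invisible(TRUE)
}

# compare every intermediate quantity the engine traced against the
# straight-line oracle
expect_trace_matches_oracle <- function(trace, oracle, tol = 1e-12) {
  expect_equal(trace$step1$detected, oracle$step1$detected)
  expect_close(trace$step1$survival, oracle$step1$survival, tol)
  expect_close(trace$step1$intensity, oracle$step1$intensity, tol)
  expect_close(trace$step1$cs, oracle$step1$cs, tol)
  expect_close(trace$step1$lr, oracle$step1$lr, tol)
  expect_close(trace$step1$attractiveness, oracle$step1$attractiveness, tol)
  expect_close(trace$step1$motivation, oracle$step1$motivation, tol)
  expect_equal(trace$step1$switched, oracle$step1$switched)

  expect_equal(trace$step2$attacked, oracle$step2$attacked)
  expect_equal(trace$step2$switched, oracle$step2$switched)
  expect_close(trace$step2$survival, oracle$step2$survival, tol)
  expect_close(trace$step2$intensity, oracle$step2$intensity, tol)
  expect_close(trace$step2$us, oracle$step2$us, tol)
  expect_close(trace$step2$cs, oracle$step2$cs, tol)
  expect_close(trace$step2$lr, oracle$step2$lr, tol)
  expect_close(trace$step2$attractiveness, oracle$step2$attractiveness, tol)
  expect_close(trace$step2$motivation, oracle$step2$motivation, tol)
  expect_close(trace$step2$memory, oracle$step2$memory, tol)

  expect_equal(trace$step3$attacked, oracle$step3$attacked)
  expect_equal(trace$step3$switched, oracle$step3$switched)
  expect_close(trace$step3$survival, oracle$step3$survival, tol)
  expect_close(trace$step3$intensity, oracle$step3$intensity, tol)
  expect_close(trace$step3$cs, oracle$step3$cs, tol)
  expect_close(trace$step3$memory, oracle$step3$memory, tol)

  expect_close(trace$end$survival, oracle$end$survival, tol)
  expect_close(trace$end$memory, oracle$end$memory, tol)
  invisible(TRUE)
}
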