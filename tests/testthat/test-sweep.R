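test_that("the signal-penalty ladder is the documented geometric sequence", {
  p <- signal_penalty_levels()
  expect_length(p, 51)
  expect_equal(p[1:2], c(0.13, 0.1105))
  expect_equal(signif(p[49], 3), 5.32e-5)
  expect_equal(signif(p[50], 3), 4.52e-5)
  expect_equal(p[51], 0)
  expect_true(all(diff(p) < 0)) # strictly decreasing
  ratios <- p[2:50] / p[1:49]
  expect_true(all(abs(ratios - 0.85) < 1e-12))
  expect_true(all(p >= 0 & p <= 0.13))
})

test_that("switchable-signal penalty presets match the three states", {
  presets <- switchable_penalty_presets()
  expect_equal(presets$level, c("none", "moderate", "high"))
  expect_equal(presets$switching_cost, c(0, 0.0005, 0.016))
  expect_equal(presets$maintenance_cost, c(0, 2.03e-4, 0.00340))
})

test_that("the factorial grid has the reference cardinalities", {
  g1 <- build_grid(master_seed = 1, repeats = 1)
  expect_equal(nrow(g1), 29376)
  expect_equal(nrow(build_grid(master_seed = 1, repeats = 3)), 88128)
  expect_equal(max(g1$condition_id), 29376)
  # one mini-plot: all factors pinned but the penalty ladder
  mini <- build_grid(
    master_seed = 1, repeats = 3,
    switch_penalty_levels = "moderate", basal_detectability = 0.4,
    predator_turnover = 0.25, learning_speed = 1
  )
  expect_equal(nrow(mini), 153)
  # seeds are valid 32-bit integers and deterministic in the master seed
  expect_true(all(g1$seed >= 0 & g1$seed < 2^31))
  expect_identical(build_grid(9, 2)$seed, build_grid(9, 2)$seed)
  expect_false(identical(build_grid(1, 1)$seed, build_grid(2, 1)$seed))
})

test_that("sweeps run, tabulate winners, and tolerate empty grids", {
  base <- apo_config(world_size = 4, prey_frequency = 0.6,
    predator_frequency = 0.2, generation_length = 5)
  g <- smoke_grid(3)[1:4, ]
  res <- run_sweep(g, base, n_generations = 3)
  expect_s3_class(res, "apo_sweep")
  expect_equal(nrow(res), 4)
  expect_true(all(res$winner %in% base$allowed_strategies))
  expect_true(all(is.na(res$error)))
  counts <- as.matrix(res[, paste0("count_", base$allowed_strategies)])
  expect_true(all(rowSums(counts) == derive_counts(4, 0.6, 0.2)$n_prey))

  empty <- run_sweep(g[0, ], base)
  expect_equal(nrow(empty), 0)
})

test_that("sweep output is deterministic and invariant to worker count", {
  base <- apo_config(world_size = 4, prey_frequency = 0.6,
    predator_frequency = 0.2, generation_length = 5)
  g <- smoke_grid(11)[seq(1, 60, by = 12), ]
  a <- run_sweep(g, base, n_generations = 3, workers = 1)
  b <- run_sweep(g, base, n_generations = 3, workers = 2)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("sweeps checkpoint and resume without recomputation", {
  base <- apo_config(world_size = 4, prey_frequency = 0.6,
    predator_frequency = 0.2, generation_length = 5)
  g <- smoke_grid(5)[1:4, ]
  ck <- withr::local_tempfile(fileext = ".csv")
  first <- run_sweep(g[1:2, ], base, n_generations = 3, checkpoint = ck)
  expect_true(file.exists(ck))
  full <- run_sweep(g, base, n_generations = 3, checkpoint = ck)
  expect_equal(nrow(full), 4)
  direct <- run_sweep(g, base, n_generations = 3)
  expect_equal(full$winner, direct$winner)
  expect_equal(full$seed, direct$seed)
})

test_that("sweep CSVs round-trip with the documented column order", {
  base <- apo_config(world_size = 4, prey_frequency = 0.6,
    predator_frequency = 0.2, generation_length = 5)
  res <- run_sweep(smoke_grid(2)[1:2, ], base, n_generations = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweep(res, path)
  header <- names(utils::read.csv(path, check.names = FALSE))
  expect_equal(
    header[1:12],
    c("condition_id", "switch_penalty_level", "switching_cost",
      "maintenance_cost", "basal_detectability", "predator_turnover",
      "learning_speed", "signaling_penalty", "repeat", "seed", "winner",
      "tie")
  )
  expect_equal(header[13:21], paste0("count_", base$allowed_strategies))
  back <- read_sweep(path)
  expect_equal(back$winner, res$winner)
})

test_that("phase plots build and render to files", {
  base <- apo_config(world_size = 4, prey_frequency = 0.6,
    predator_frequency = 0.2, generation_length = 5)
  mini_grid <- build_grid(
    master_seed = 4, repeats = 3,
    switch_penalty_levels = "moderate", basal_detectability = 0.4,
    predator_turnover = 0.25, learning_speed = 1,
    signaling_penalty = c(0.13, 0.01, 0)
  )
  res <- run_sweep(mini_grid, base, n_generations = 2)
  p <- plot_mini(res)
  expect_s3_class(p, "ggplot")
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
  # color map is bijective over the nine codes
  pal <- strategy_colors()
  expect_length(pal, 9)
  expect_setequal(names(pal), default_strategies())
  expect_equal(anyDuplicated(pal), 0)

  out <- withr::local_tempdir()
  files <- render_phase_plots(res, out, formats = "png")
  expect_true(length(files) >= 2) # one mini + one meta
  expect_true(all(file.exists(files)))
})
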