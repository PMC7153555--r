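---
title: "Modeling the evolution of switchable aposematic signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the evolution of switchable aposematic signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aposwitch)
```

## The question and the model

Defended prey advertise their unpalatability with warning signals that
predators learn to avoid. A *switchable* signal — normally hidden, fired
when a predator approaches (pre-attack) or only once an attack has begun
(post-attack) — can save most of a permanent signal's running costs, at the
price of building and operating the switching machinery. `aposwitch`
implements an individual-based model of this trade-off: clonal prey
strategies compete over hundreds of generations against a predator
population that acquires aversion by associative learning.

The model deliberately excludes two other benefits switchable displays may
have: startling the predator (deimatism) and any learning-facilitation
effect of the switching act itself. Both channels exist in nature; keeping
them out isolates the cost-saving benefit, which is the question this
package is built to address. Predators do not evolve, prey defense
(repulsive taste) is homogeneous, generations do not overlap, and there is
no mutation — variation is maintained instead by an extinction-rescue rule
(see below).

## Strategies

A strategy is a triple of signal levels over the threat states
resting → approached → attacked, with discrete levels N (intensity 0),
L (default 0.3) and H (default 1). The intensity of N is fixed at 0: a
"none" level that still raised detectability would not be a non-signal, and
every cost and perception term involving the signal must vanish for it.
All `r nrow(enumerate_strategies())` triples exist
(`enumerate_strategies()`, lexicographic with N < L < H so outputs are
deterministic); the default admissible set applies two constraints — signal
level non-decreasing with threat, and at most one level change along the
sequence — leaving the nine codes returned by `default_strategies()`. Both
constraints are arguments of `filter_allowed()`, and any subset of the 27
codes can be made admissible through `apo_config(allowed_strategies = )`.

## The interaction frame

Each generation is 50 frames; each frame has three time steps separated by
the two possible attack events. The procedure order inside a step is fixed
(predators act, prey react, prey pay costs, predators observe/learn/decide)
and all survival modifiers are multiplicative, so a prey's survival chance
is a product of per-step factors and attack damages. Two properties follow
and are exploited by the tests:

- a prey never encountered in a generation has the closed-form survival
  `[(1 − c_maint)(1 − penalty · i_rest)]^(3F)` after `F` frames
  (maintenance cost applying only to switchable strategies);
- detection happens once per frame, *before* any attack, at the
  approached-state intensity — so a post-attack switcher is searched for at
  the bare basal detectability while a pre-attack switcher is searched for
  at full display. This asymmetry is the model's core opportunity cost and
  is tested directly.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `world_size` | 14 | grid side; 196 squares |
| `prey_frequency` | 0.92 | occupied squares; 180 prey (carrying capacity) |
| `predator_frequency` | 0.23 | 45 predators |
| `generation_length` | 50 | frames per generation |
| `n_generations` | 500 | horizon of a run |
| `intensity_L`, `intensity_H` | 0.3, 1 | numeric signal intensities |
| `initial_attack_damage` | 0.1 | survival factor 0.9 at the first attack |
| `subsequent_attack_damage` | 0.4 | survival factor 0.6 at the second |
| `basal_cognitive_cue` | 0.1 | cue floor for learning/recall |
| `repulsive_taste` | 0.1 | unconditional stimulus during attacks |
| `switching_cost` | 5e-4 | per level change ("moderate" preset) |
| `switchability_maintenance_cost` | 2.03e-4 | per step, switchable prey |
| `basal_detectability` | 0.4 | detection floor |
| `predator_turnover` | 0.25 | naive replacement probability per generation |
| `learning_speed` | 1 | memory-buildup coefficient, unbounded |
| `signaling_penalty` | 0.13 | cost · intensity per step |

All fractions live in [0, 1]; learning speed has no upper bound (the sweep
uses up to 1000). The five sweep variables default to a moderate point of
their grids so that an unadorned `apo_config()` is a sensible reference
condition; the sweep machinery (`build_grid()`) supplies the full factorial
design — 3 switchable-penalty presets × 4 detectabilities × 4 turnover
rates × 12 learning speeds × 51 signal penalties = 29,376 conditions, three
repeats, 88,128 runs. The 51-value penalty ladder is geometric from 0.13
with ratio 0.85 (50 nonzero terms) plus 0. The "high" maintenance-cost
preset is 0.00340 as tabulated; 0.000255, a value that also circulates for
that preset, is accepted through the config like any other number.

## What the simulator emulates — and what it does not

The simulator is itself the data generator: all experiments are runs of the
model, and all package-level claims are claims about the model's behavior,
not about any particular natural system. The spatial grid is inert by
construction (predators are re-assigned to random occupied squares every
frame, prey are re-placed every generation), so placement carries no
information; it is retained for interface fidelity only. Passing tests
therefore demonstrate internal correctness — equations, orderings,
conservation laws, seeded reproducibility — and qualitative regime
structure (e.g. non-learning predators select the silent strategy), never
quantitative predictions for real predator–prey systems.

## Numerical and design choices

Several points are underdetermined by the model description alone; the
package resolves them as follows.

- **Frequency → count rounding** is half away from zero. The reference
  instance (180.32 → 180, 45.08 → 45) does not discriminate between floor
  and round; round behaves symmetrically on other grids.
- **Initial uniform mix**: each admissible strategy gets
  `floor(n/k)` individuals; the remainder goes to strategies drawn without
  replacement, seed-reproducibly. Fewer prey than strategies is a
  configuration error.
- **Predator → prey assignment** is sampling without replacement (at most
  one predator per prey per frame), matching the one-pair interaction
  narrative; surplus predators idle. A `allow_shared_targets` toggle
  enables with-replacement assignment for exploration.
- **Switching cost on switch-off**: charged. The per-use cost attaches to
  any level change, including reverting to rest after an abandonment,
  because the cost models the act of switching, not its direction. The
  end-of-frame reversion is free (no cost-paying procedure follows it).
  Toggle: `cost_on_switch_off`.
- **Maintenance cost** is charged in every one of the three time steps to
  every prey with a switchable strategy, encountered or not — it is the
  price of owning the machinery, not of using it.
- **Learning** uses the predator's current unconditional stimulus (0 until
  it has attacked, the repulsive taste afterwards) in the memory increment
  `λ · us · cs`. Predators that never attack learn nothing, however
  conspicuous the prey.
- **Step-3 abandonment**: a predator that attacked initially but declines
  the subsequent attack still observes the prey (now reverted to resting)
  and learns from that cue with the taste it retains. Toggle:
  `learn_on_step3_abandon`.
- **Predator turnover** is per-predator Bernoulli at the configured rate.
  A deterministic `round(rate · n)` reading would make the lowest grid
  level (0.01 on 45 predators → 0 replacements) indistinguishable from no
  turnover at all; the stochastic reading preserves four distinct levels.
  The deterministic variant remains available (`turnover_stochastic =
  FALSE`).
- **Extinction rescue** replaces one uniformly chosen individual per
  missing strategy (missing strategies processed in random order). The
  victim is drawn among individuals that are not themselves the last of an
  admissible strategy, so the rescue invariant — every strategy present
  afterwards — holds even in degenerate tiny populations; at the default
  180/9 this guard is essentially never active.
- **Total extinction**: if no prey survives selection, parents are drawn
  from the full pre-death generation — the smallest assumption consistent
  with the no-extinction design of the rescue rule.
- **Winner and ties**: the winner is the most abundant strategy in the
  population produced by the final reproduction stage; exact ties (possible
  in principle, never observed at default sizes) are broken uniformly with
  the run RNG and flagged in the result.
- **Determinism**: one seeded Mersenne-Twister stream per run, consumed in
  predator-index order; `(config, seed)` reproduces bit-identical results.
  Sweep runs derive their seeds as a fixed integer hash of (master seed,
  condition id, repeat), all below 2^31, so any subset of a sweep is
  reproducible in isolation and results are invariant to the worker count.
- **No epsilon clamping** beyond the single `min(1, ·)` in learned
  repulsiveness; probabilities are used exactly, and degenerate
  configurations (0 predators, 0 learning, 0 costs) are legal and exercised
  by tests.

## Verification strategy

Every equation path through a frame is checked against
`brute_force_frame()`, a straight-line re-derivation for a single
predator–prey pair that shares no code with the engine and consumes a
scripted outcome sequence instead of the RNG. The tests run randomized
parameter draws across all eight detection/attack outcome combinations and
compare every intermediate quantity to 1e-12. A hand-computable reference
chain (post-attack switcher, detection and both attacks forced) pins the
end-of-frame survival at 0.436915, the predator memory at 0.2 and the
mid-frame motivation at 0.81.

Population-level behavior is checked with closed forms (unencountered-prey
survival), conservation laws (capacity and strategy presence every
generation), and seeded Monte-Carlo expectations (selection, reproduction,
turnover rates, neutral drift around the uniform mix). Long stochastic
regressions use reduced problem sizes — 50-generation runs for drift, a
360-run reduced sweep grid — chosen to keep the default test run fast while
leaving the regime structure visible; full-scale runs (500 generations,
29,376 conditions) use exactly the same code path.

## Known limitations

The model omits deimatic startle effects, learning facilitation by the
switching act, memory decay, predator energy budgets and predator
evolution; prey are asexual, immobile between frames, and uniform in
defense. Spatial structure is deliberately neutral. Conclusions should be
read as statements about cost-driven selection among signaling strategies
under associative-learning predation pressure, not as quantitative
predictions for any particular species pair.
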