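# aposwitch

An individual-based simulator of the evolution of **switchable aposematism**:
warning signals that chemically defended prey can turn on behaviorally,
either when a predator approaches (*pre-attack* switching) or only after an
attack has begun (*post-attack* switching), in competition with permanent
signaling and with not signaling at all.

The package is for evolutionary ecologists who want to explore when
switchable warning signals out-compete permanent ones: it provides the full
agent-based model, a factorial parameter-sweep engine with deterministic
per-run seeding, tidy (tibble) results with `tidy()`/`glance()` methods, and
categorical phase-diagram graphics.

## The model

Prey carry a heritable **behavioral strategy**: a triple of discrete signal
levels — none (N, intensity 0), low (L, default 0.3), high (H, default 1) —
assigned to the three threat states *resting*, *approached*, *attacked*, and
written as a three-letter code. `NHH` is a pre-attack switcher, `NNH` a
post-attack switcher, `HHH` a permanent strong signal. Of the 27 possible
triples, 9 are admissible under the default constraints (signal level
non-decreasing with threat, at most one switch): NNN, NNL, NNH, NLL, NHH,
LLL, LLH, LHH, HHH.

Each prey generation consists of 50 **interaction frames**. In a frame every
predator lands on a random occupied grid square and the pair interacts over
three time steps (pre-attack, between attacks, post-attack). The prey's
survival chance *S* starts each generation at 1 and is only ever multiplied
down:

- `S ← S · (1 − c_switch)` each time the prey changes signal level
  (per-use switching cost),
- `S ← S · (1 − c_maint)` every time step for every prey whose strategy is
  switchable (maintenance cost of the switching machinery),
- `S ← S · (1 − penalty · intensity)` every time step (all other costs of an
  active signal),
- `S ← S · (1 − damage)` per attack (0.1 for the initial, 0.4 for the
  subsequent attack).

The predator side is classical conditioning. Detection is a single check per
frame at probability `bd + i·(1 − bd)` (basal detectability plus signal
headroom). The appearance cue (**conditional stimulus**)
`cs = bcc + i·(1 − bcc)` and the taste felt during attacks
(**unconditional stimulus**, 0 until the first attack) feed an unbounded,
non-decaying **aversive memory**, `m ← m + λ · us · cs` with learning speed
λ. Recall is `min(1, m · cs)`; attractiveness
`(1 − learned)(1 − instinctive)` multiplies the per-encounter **motivation**,
which is the attack probability at each act step.

Selection is clonal: prey survive Bernoulli trials at their final survival
chance, survivors are resampled with replacement to the carrying capacity
(180 on the default 14 × 14 world with 45 predators), an extinction-rescue
rule keeps every admissible strategy represented, and a configurable
fraction of predators is replaced by naive individuals each generation. The
**winner** of a run is the most abundant strategy after 500 generations.

## A worked example

Slowly learning predators, hard-to-find prey, and a noticeable signal
penalty — conditions that should reward hiding until an attack forces the
signal on:

```r
library(aposwitch)

cfg <- apo_config(learning_speed = 0.3, basal_detectability = 0.05,
                  signaling_penalty = 0.03)
run <- run_simulation(cfg, seed = 42)
run
#> <apo_run> winner NNH after 500 generations (seed 42)
#>   final counts: NNN=1 NNL=3 NNH=170 NLL=1 NHH=1 LLL=1 LLH=1 LHH=1 HHH=1
```

The post-attack switcher `NNH` fixes (the eight 1s are the extinction-rescue
floor). `tidy(run)` gives the per-generation records — strategy counts,
survivor numbers, mean predator memory — and `glance(run)` a one-row
summary:

```r
glance(run)
#> # A tibble: 1 × 13
#>   winner tie    seed n_generations count_NNN count_NNL count_NNH ...
#> 1 NNH    FALSE    42           500         1         3       170 ...
```

Sweeps cross the five experiment variables (switchable-signal penalty
preset, basal detectability, predator turnover, learning speed, a 51-step
signal-penalty ladder) into 29,376 conditions; `run_sweep()` executes any
subset reproducibly and `autoplot()` draws the winner phase diagrams:

```r
grid <- smoke_grid(master_seed = 7)        # 360-run reduced grid
res  <- run_sweep(grid, apo_config(), n_generations = 50)
autoplot(res, switch_penalty_level = "moderate")
```

A thin command-line front end covers the same workflow:

```sh
Rscript inst/cli/aposwitch.R sweep --grid smoke --master-seed 7 --generations 50 --out sweep.csv
Rscript inst/cli/aposwitch.R plot --in sweep.csv --out-dir figs/
```

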