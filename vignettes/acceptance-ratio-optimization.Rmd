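---
title: "Acceptance-ratio driven optimization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acceptance-ratio driven optimization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aropt)
```

## The problem this engine solves

Many modelling tasks in computational biology — rate constants of a kinetic
scheme, coefficients of an empirical model, a constrained arrangement of
discrete genomic elements — reduce to minimizing an objective over a parameter
state `K` whose landscape is non-smooth, rugged, or only available through a
black-box simulation. Metropolis Monte Carlo handles all of these, but its
classic weakness is the temperature scale: a schedule that works for one
objective (or one region of one objective) freezes or boils another, and a
chain caught in a deep local minimum simply stops moving.

`aropt` inverts the control problem. The user never chooses temperatures.
Instead the engine is steered by the **acceptance ratio (AR)** — the fraction
of proposed moves accepted within a *statistics window* of fixed length — a
quantity that is dimensionless, comparable across problems, and directly
observable. A feedback controller (*adaptive thermoregulation*) adjusts an
unconstrained pseudo-temperature after every window so the observed AR tracks a
prescribed target. Two drivers sit on top:

* **AR simulated annealing (AR-SA)** anneals the *target AR* linearly from an
  exploratory value (default 0.9) to a greedy one (default 0.01) within each
  cycle, over several cycles. The temperature goes wherever it must.
* **AR replica exchange (AR-RE)** runs several replicas, each holding a
  *fixed* target AR (its own temperature adapting), and periodically swaps the
  current configurations of a selected adjacent pair *unconditionally*.

Because we only want the best configuration ever visited — not equilibrium
ensemble statistics — both drivers are free to break detailed balance, and
AR-RE deliberately does.

## The problem interface

A problem is three functions plus an initial state `k0` and an optional opaque
`data` payload the engine never touches:

```{r interface}
pf <- generate_polyfit(seed = 1)
names(pf$problem)   # move, model, evaluate
validate_problem(pf$problem, pf$k0, pf$data, seed = 1)$initial
```

`evaluate` returns a pseudo-energy `E` (minimized; "pseudo" because it need
not be physical) and a quality `Q` (reported alongside, never used in
acceptance decisions). `E = +Inf` is the hard-constraint sentinel: a forbidden
proposal is always rejected from a feasible state, and a chain whose current
state is itself forbidden treats forbidden-to-forbidden moves as ties so it
can wander back to feasibility. `NaN` energies are errors caught at the first
evaluation. When the lowest energy and the best quality disagree, the reported
optimum is the lowest energy; `Q` of that same configuration is reported with
it. (The alternative — selecting by extreme `Q` — would make the reported
answer depend on a quantity the sampler never controlled.)

**Randomness.** R has a single global random generator, so rather than passing
a generator object into callbacks, the engine gives every chain, replica and
scheduler a private `rng_stream` — a snapshot of generator state swapped in
around each window. Callbacks just call `rnorm()`/`sample()`. Consequences:
seeded runs replay byte-identically, parallel SA runs equal their sequential
execution, and replica trajectories are independent of the interleaving order.

## The thermoregulation law

The controller is proportional in log-temperature. After a window with
observed AR `o` and target `a`:

```
s     = clamp(gain * (a - o), -max_log10_step, +max_log10_step)
s     = s + frozen_boost_log10   if o == 0 and a > 0
T_new = clamp(T * 10^s, t_min, t_max)
```

Multiplicative control is the only scale-free choice — the useful temperature
for an objective measured in (RSS units, adjacency counts, kcal/mol) can
differ by many orders of magnitude, and a controller additive in `T` could
never traverse them. The defaults are `gain = 5` (an AR error of 0.2 moves the
temperature a full decade), `max_log10_step = 1` (stability cap per update),
`t_min = 1e-12`, `t_max = 1e12` (bounds wide enough to be effectively
unconstrained while excluding over/underflow), and `window_size = 20` (AR
resolution 0.05 per window; smaller windows react faster but measure AR more
noisily).

The **frozen-state boost** is the trap-escape mechanism: a window with zero
acceptances carries no gradient information about *how* frozen the chain is,
so the controller adds an extra decade on top of the (saturated) proportional
term — deliberately outside the per-step cap. Successive all-reject windows
therefore raise the temperature geometrically until moves start being
accepted, which produces the abrupt temperature spikes characteristic of this
family of methods. The observed AR is computed per-window only, with no
smoothing across windows: smoothing would dilute exactly the all-reject signal
the boost keys on.

## The annealing driver

Within a cycle of `n` steps the target AR is the exact linear interpolation
from `ar_initial` (step 0) to `ar_final` (step `n-1`). AR is only measurable
per window, so the continuous regimen is sampled at each window's *last* step
index to set that window's target; the final window of every cycle thus
targets `ar_final` exactly. `window_size` must divide the cycle length —
ragged final windows would measure AR at a different resolution.

The pseudo-temperature is **not** reset at cycle boundaries. The restarting
high-AR target forces the controller to reheat within a few windows anyway
(this reheat is asserted in the test suite), and keeping the temperature
continuous preserves the scale information the controller has learned about
the landscape.

Multiple SA runs fan out pairwise-distinct seeds from one master seed
(`fan_out_seeds`) and are embarrassingly parallel; `parallel = TRUE` uses
forked workers and is bit-identical to sequential execution by the stream
design. The overall answer is the lowest energy across all cycles and runs.

## The replica-exchange driver

Replicas are ordered by strictly decreasing target AR (replica 0 most
exploratory; the default ladder `0.9 … 0.01` has eight rungs). Every
`exchange_period_windows` windows, one **adjacent** pair — uniformly chosen by
a dedicated stream — swaps current configurations, energies and qualities
*unconditionally*. Everything else (identity, target AR, temperature,
best-so-far record, stream) stays put. Design notes:

* *Adjacent* pairs: swapping a near-greedy replica into a 0.9-AR regime (or
  vice versa) is a configuration shock with little refinement value; adjacent
  targets hand work down a gentle gradient. The selection rule is isolated in
  `select_exchange_pair()` and documented as replaceable.
* *Unconditional*: a Metropolis swap test would re-impose the equilibrium
  criteria we have explicitly abandoned; for pure optimization the swap can
  only help the cold replica and costs the hot one nothing it cannot re-find.
* Energies travel with configurations and are not re-evaluated on arrival
  (`evaluate` is deterministic by contract), and exchanges happen only at
  window boundaries so no window's AR statistic mixes two configurations'
  histories.
* Best-so-far records deliberately stay home: every configuration was already
  counted by the replica that generated it, so the global best (the minimum
  over replicas) is unaffected, and per-replica bests remain interpretable as
  "best found by this regime".

A period longer than the run degenerates AR-RE into independent fixed-AR
optimizations, which is also how the package measures the benefit of
exchanging (paired seeds, identical streams, exchanges on vs off).

## The bundled example problems

Each generator builds a seeded synthetic instance with known ground truth, so
every engine mode is testable end to end with no external data:

* `generate_polyfit()` — quadratic with coefficients `(2, -1, 0.5)` on 50
  equally spaced points over `[-3, 3]`, Gaussian noise sd 0.05; energy is the
  residual sum of squares, moves perturb one coefficient (`sd = 0.1`, roughly
  the target precision scale).
* `generate_odefit()` — irreversible two-compartment kinetics
  `A -k1-> B -k2->` (`dA/dt = -k1 A`, `dB/dt = k1 A - k2 B`, `A(0) = a0 = 1`),
  rates `(1.0, 0.3)` per unit time, 12 samples over `[0, 10]`, noise sd
  `0.01·a0` on both species. This scheme was chosen because it has a closed
  form (for `k1 ≠ k2`), so the fixed-step fourth-order Runge–Kutta integrator
  is verifiable independently of the optimizer: at step 0.001 it matches the
  closed form to better than 1e-6 relative error (the suite observes ~1e-13).
  The in-loop default step of 0.1 keeps each energy evaluation cheap while
  remaining orders of magnitude below the noise floor. Moves are
  multiplicative log-normal (`sdlog = 0.15`) on one rate — rates are positive
  scale parameters — and non-positive rates are forbidden states, exercising
  the `+Inf` mechanism.
* `generate_shuffle()` — a length-8 random integer sequence with 2 locked
  positions; energy is the total adjacent dissimilarity `Σ|v_i − v_{i+1}|`,
  moves swap two unlocked positions. Discrete, constrained and non-smooth,
  with ≤ 6 free positions it admits an exhaustive 720-arrangement oracle
  (`brute_force_shuffle_optimum()`).

Two analytic one-dimensional landscapes support the engine's own diagnostics:
a quadratic bowl (AR tracking, since any target AR is attainable there) and a
tilted double well `(k²-1)² + 0.3k` started in the shallower well (barrier
crossing and the exchange benefit).

**What passing these tests does and does not show.** The generators emulate
the *structure* of real tasks — smooth and rugged continuous landscapes, hard
constraints, discrete moves — at sizes where ground truth is computable. They
do not emulate high dimensionality, strongly correlated parameters,
heteroscedastic or non-Gaussian noise, or expensive simulators; success here
demonstrates the engine's mechanics, not performance guarantees on any
particular research problem.

## Numerical choices and degenerate inputs

* Acceptance is classical Metropolis, `exp(-ΔE/T)`; ties (`ΔE = 0`) are always
  accepted, so the rule has an exact closed form the tests can pin down.
* The linear regimen uses the convex form `a_i(1-f) + a_f f` so both endpoints
  are exact in floating point.
* The initial `k0` is evaluated once, before step 0, and is not counted in any
  window's AR (windows measure *move* acceptance only).
* Best-so-far updates on strictly lower energy; among equal-energy optima the
  first one visited is reported. Across parallel runs/replicas, ties go to the
  lowest run index (`which.min`).
* One-step cycles return `ar_initial`; `window_size` must divide the cycle
  (SA) or total (RE) length, violations are configuration errors.
* Trace tables are TSV with `.` decimals and 17 significant digits, written
  atomically (temp file + rename), so a crashed run never leaves a truncated
  table and a written trace replays a run exactly.

## Problem sizes used by the package's own diagnostics

The test-suite and acceptance-script runs use: 1e5 draws for the Metropolis
frequency check; 200 windows × 50 steps × 5 seeds per tracking target;
the default 3 × 10 000-step cycles for polynomial recovery; 3 × 1000-step
cycles for the kinetic fit (each step integrates the ODE); 2 × 2500-step SA
and 4-replica × 1500-step RE runs for the shuffle; and 11 paired seeds of
4-replica × 2000-step runs for the exchange-benefit comparison. These sizes
were chosen as the smallest at which each stochastic property is comfortably
resolved.

## Known limitations

* The thermoregulation law is a proportional controller with a heuristic
  boost; it tracks well in practice but is not claimed optimal, and no
  integral/derivative terms or stochastic-approximation tuning are provided.
* Exchange-pair selection is uniform-adjacent; energy-informed selection might
  exchange more productively on some landscapes.
* No gradient refinement, no constraint language beyond the `+Inf` sentinel,
  no mid-cycle checkpointing, and no ensemble statistics — the engine answers
  "what is the best configuration you found", nothing more.
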