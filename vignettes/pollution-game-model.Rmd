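---
title: "The spatial pollution game: model, dynamics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The spatial pollution game: model, dynamics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollutiongame)
```

## The model

`pollutiongame` simulates a social dilemma of pollution on a doubly periodic
square lattice (a discrete torus) of side $L$. Each of $N$ agents occupies
one site, at most one agent per site, and plays one of two strategies:

* a **cooperator** (cleaner) pays a fee $f$ and removes $\phi$ units of
  pollution from its own site and the four axis-adjacent sites — a
  "cleaning well" of depth $\phi$ on the five sites within distance 1;
* a **defector** (polluter) collects a benefit $g$ and emits pollution with
  a long-range kernel: 1 unit on every site within distance 1 of itself and
  $d^{-2}$ units at toroidal distance $d$, out to a radius $R$.

Distances are folded Euclidean geodesics on the torus,
$\lVert p,q\rVert = \sqrt{\min(|\Delta x|, L-|\Delta x|)^2 +
\min(|\Delta y|, L-|\Delta y|)^2}$, so both kernels wrap around the lattice
edges. The instantaneous pollution field is the superposition of all
agents' kernels; it is recomputed from the current configuration at every
step and does not accumulate over time. Because the field is linear in
agents, its lattice total is conserved at
$N_D S_D - 5 \phi N_C$, where $S_D$ is the lattice mass of one defector
kernel — a cheap invariant the test suite checks on every recorded state.

Agents relocate greedily: an agent with mobility cost $\mu_a$ moves to the
site minimizing *(pollution at the candidate site, in the field as it stood
before anyone moved this step)* $+\ \mu_a \times$ *(distance from its
current site)*, over all unoccupied sites plus its own. The agent's own
kernel is part of the field it evaluates — a defector is repelled by its
own cloud, which is what drives the characteristic "hop to the edge of the
well on the far side of a cooperator". An agent's **expense** for the step
is the pollution felt at its (post-move) site, plus the strategy cost ($f$
for a cooperator, $-g$ for a defector), plus $\mu_a$ times the distance it
just moved. Imitation copies the strategy of the neighbour (distance
$\le 1$, i.e. the four axis-adjacent sites) with the lowest expense.

A time step has four phases, all agents acting in each: (I) imitation,
(II) movement, (III) pollution (field recomputation), (IV) expense
calculation. The **fast-movement limit** (movement much faster than
strategy revision) skips phase I, freezing strategies; the
**coevolutionary regime** runs all four phases every step.

With the default parameters $f = g = 3.5$, $\phi = 5$, $R = 5$ the
two-player game at adjacency is a social dilemma: defection is strictly
dominant ($f + g > 1 + \phi$) while mutual cooperation is socially optimal
($f + g < 2 + 2\phi$). `dilemma_regime()` rebuilds the payoff matrix from
the kernels and checks both conditions against these closed forms.

## Parameters and defaults

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| `L` | lattice side | 50 | sites |
| `N` | population | 20/50/80 | agents |
| `f` | cooperation fee | 3.5 | expense |
| `g` | defection benefit | 3.5 | expense |
| `phi` | cleaning per site | 5 | pollution |
| `R` | pollution radius | 5 | lattice units |
| `T_steps` | horizon | 50 | steps |
| `mu` | mobility cost | swept in $[0, 1]$ | expense per unit distance |

The defaults are the study conditions throughout: a $50 \times 50$ city,
environmental factors $R = \phi = 5$, strategy costs $f = g = 3.5$, and
$T = 50$ steps (the dynamics typically settle within 20–40 steps, so the
horizon is comfortable). Note $L^2 / (\pi R^2) \approx 32$: about 32
defector clouds tile the lattice, which is what makes $N = 20$ a sparse,
$N = 50$ a medium and $N = 80$ a dense population.

Mobility-cost schemes:

* **homogeneous** — everyone pays `mu`;
* **heterogeneous** — a minority fraction `alpha` (default 0.2) pays `mu_m`,
  the majority pays `mu_M`; fixing the population mean `mu_hat` gives
  `mu_M = (mu_hat - alpha mu_m)/(1 - alpha)`, i.e. `(5 mu_hat - mu_m)/4`
  at `alpha = 0.2`;
* **strategy-dependent** — cooperators pay `mu_C`, defectors `mu_D`
  (derivable from a mean constraint at a fixed cooperator fraction, e.g.
  `mu_C = 0.1, c = 0.8, mu_hat = 0.4` fixes `mu_D = 1.6`). Only accepted in
  the fast-movement limit: tying costs to strategies under coevolution
  would let an agent's cost jump with every imitation event, which the
  model treats as unrealistic.

## Small-population analytics as an oracle

The package carries closed-form results for $N \le 2$ that double as an
independent oracle for the engine:

* An isolated cooperator sits at the bottom of its own well: it stays put
  for every $\mu > 0$.
* An isolated defector minimizes the radial objective $1 + \mu r$ ($r<1$),
  $r^{-2} + \mu r$ ($1 \le r < R$), $\mu r$ ($r \ge R$). The textbook
  three-regime answer ($r_* = R$, then $(2/\mu)^{1/3}$, then 0) is reported
  alongside the true global minimizer, and the two disagree in part of the
  intermediate regime: the interior branch value $3(\mu/2)^{2/3}$ already
  exceeds the staying value 1 once $\mu > 2/\sqrt{27} \approx 0.385$, so
  cross-branch comparison favours staying well before $\mu = 2$.
  `single_agent_optimum()` exposes both rather than silently correcting
  either; tests pin only the regimes where they agree.
* `two_agent_optimum()` solves the two-agent relocation by exhaustive
  lattice search with per-pair kernel evaluation — a code path deliberately
  disjoint from the engine's precomputed kernel tables, so agreement
  between the two is a meaningful check (the suite verifies it on 200
  random small configurations).
* `two_cooperator_longterm()` is the long-run separation map of two
  cooperators: stay if $r \le 1$ or $r > 2$; step closer
  ($r \mapsto r - 1$) if $1 < r \le 2$ and $\mu < \phi/(r-1)$.

One boundary convention deserves note: the lattice kernel uses the closed
inequality $d \le R$ (the boundary offset $(3,4)$ at $R=5$ contributes
$1/25$), while the continuous radial objective uses the strict $r < R$.
The two disagree only at $d = R$ exactly. Both conventions appear in the
model's source formulations; the package implements each where it is
stated and surfaces the difference here instead of merging them.

## Numerical choices

* **Tie-breaks.** Movement objectives are compared with an absolute
  tolerance of $10^{-9}$ (lattice distances and kernel weights are exact or
  near-exact in floating point; the tolerance only guards sums). Ties are
  resolved by smallest movement distance, then lexicographic $(x, y)$ —
  so staying wins any tie it is part of, and $\mu = 0$ behaviour is
  deterministic. Imitation ties among equally cheap neighbours are broken
  uniformly at random from the run's seeded RNG stream.
* **Phase II scheduling.** Agents move in a fresh random permutation each
  step (a fixed id order would systematically privilege early agents). The
  field is frozen at its phase-start state — "prior to movement" — while
  occupancy is live, so a site vacated earlier in the phase can be taken
  and single occupancy is never violated.
* **Phase I synchrony.** All agents read the previous step's expenses and
  strategies, then all update at once; the copy is unconditional (an agent
  adopts the cheapest neighbour's strategy even when its own expense is
  lower). An `only_if_better` switch implements the self-inclusive variant
  but is off by default; see the limitations section.
* **Initialization.** Agents are placed uniformly without replacement;
  exactly `round(c0 * N)` cooperators and (heterogeneous runs) exactly
  `round(alpha * N)` minority members are drawn as uniform subsets, which
  removes needless ensemble variance in the controlled fractions. The run
  starts with one pollution + expense pass at zero movement cost so the
  first imitation phase has expenses to read.
* **Determinism.** A run is a pure function of `(config, seed)`. Sweep
  cells derive per-run seeds as
  `(base_seed + 1000003 * cell + 7919 * run) mod 2147483647`, so cells can
  execute in any order (or in parallel) and reproduce bit-for-bit.

## What the generator emulates, and what it does not

Random initial placement emulates an undifferentiated, initially clean
environment — no geography, no prior inhabitants, no background pollution.
Real cities violate all three, and the model further attributes all
pollution to individual agents. Passing tests therefore certify the
dynamics of this idealised commons dilemma, not quantitative predictions
for any real city. Within the model, the reported ensembles use desk-scale
sizes — 20 to 30 seeds per parameter cell rather than the hundreds a
full-resolution heatmap would use — which is ample for the
order-of-magnitude contrasts the tests assert (ensemble standard
deviations of the final cooperator fraction are typically 0.1–0.2).

## Known limitations

* The imitation rule is implemented literally: copy the cheapest
  neighbour, unconditionally. Under this reading, several defectors
  crowding a lone cooperator all copy the cooperator (well-edge sites are
  mutually non-adjacent at distance $\le 1$) while the cooperator copies
  one defector — so crowding events net-produce cooperators, and in sparse
  lattices low-but-nonzero mobility costs end up *maximising* cooperation
  in this implementation. The self-inclusive variant (`only_if_better =
  TRUE`) reverses that local outcome and produces the opposite sparse-
  lattice trend, but collapses cooperation in dense lattices, where
  unconditional copying is what lets clustered cooperators absorb incoming
  defectors. Neither variant reproduces every qualitative regime
  simultaneously; the package defaults to the literal rule and exposes the
  switch.
* Movement is globally informed (argmin over the whole lattice); there is
  no distance-limited candidate set.
* No birth/death, mutation, background pollution, static polluters, or
  place attachment; pollution does not persist between steps.
* Pairwise-comparison (Fermi) imitation is deliberately not implemented.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(L = 50, N = 80, T_steps = 50, regime = "coevolutionary",
                  c0 = 0.3, scheme = cost_scheme_homogeneous(0.8))
ens <- run_ensemble(cfg, n_runs = 20, base_seed = 1)
ens$summary
```

With 30% initial cooperators and a high homogeneous mobility cost, the
dense lattice still converges to a cooperator majority (ensemble-mean
final $c \approx 0.86$ for the seeds above): high costs keep defectors
from swarming nascent cooperator clusters faster than the clusters can
absorb them.
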