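# pollutiongame

An R package for simulating a **spatial social dilemma of pollution with
costly mobility**. It is aimed at researchers in evolutionary game theory
and social physics who want a tested, reproducible implementation of a
lattice pollution game: cooperators (cleaners) pay to improve their
neighbourhood, defectors (polluters) free-ride with a long-range
externality, and everyone can pay to move somewhere cleaner.

## The model

$N$ agents occupy distinct sites of a doubly periodic $L \times L$ lattice
with toroidal geodesic distance
$\lVert p,q\rVert = \sqrt{\min(|\Delta x|,L-|\Delta x|)^2+\min(|\Delta y|,L-|\Delta y|)^2}$.
Each agent plays $\sigma_a \in \{C, D\}$:

- a cooperator pays $f$ and removes $\phi$ pollution units from the five
  sites within distance 1 of itself;
- a defector gains $g$ and deposits 1 unit within distance 1 and $d^{-2}$
  units at distance $d \le R$.

The pollution field is the instantaneous superposition of all agents'
kernels. An agent with mobility cost $\mu_a$ relocates to

$$\mathbf{r}_a(t+1) = \arg\min_{\mathbf{r}}\left[P_t(\mathbf{r}) + \mu_a\,\lVert \mathbf{r}, \mathbf{r}_a(t)\rVert\right]$$

over unoccupied sites (plus staying), and its expense for the step is
$E_a = P[\mathbf{r}_a] + \varepsilon(\sigma_a) + \mu_a\,\lVert \mathbf{r}_a(t), \mathbf{r}_a(t-1)\rVert$
with $\varepsilon(C) = f$, $\varepsilon(D) = -g$. Imitation copies the
strategy of the axis-adjacent neighbour with the lowest expense. Steps run
four phases — imitation, movement, pollution, expense — with the
fast-movement limit skipping imitation. Homogeneous, two-group
heterogeneous ($\alpha$, $\mu_m$, $\mu_M$) and strategy-dependent
($\mu_C$, $\mu_D$) cost schemes are supported, plus closed-form
small-population analytics (`single_agent_optimum()`,
`two_agent_optimum()`, `dilemma_regime()`) that serve as independent
oracles for the engine.

## A worked example

```r
library(pollutiongame)

# dense city, 30% initial cooperators, high homogeneous mobility cost
cfg <- sim_config(L = 50, N = 80, T_steps = 50, regime = "coevolutionary",
                  c0 = 0.3, scheme = cost_scheme_homogeneous(0.8))
sim <- run_simulation(cfg, seed = 1)
sim
#> Pollution-game run: L = 50, N = 80, coevolutionary, T = 50 (seed 1)
#>   final c = 0.537, delta PCP = -8.862, kappa = 0.550
tail(sim$metrics, 3)
#>     t      c       pcp delta_pcp kappa c_m
#> 49 48 0.5375 -9.690281 -8.862045  0.55  NA
#> 50 49 0.5375 -9.689656 -8.861420  0.55  NA
#> 51 50 0.5375 -9.690281 -8.862045  0.55  NA
```

Starting from a defector majority, this run ends with 53.7% cooperators,
over half the agents clustered (`kappa` = 0.55), and per-capita felt
pollution down 8.9 units from the initial configuration. Averaging over an ensemble:

```r
ens <- run_ensemble(cfg, n_runs = 20, base_seed = 1)
ens$summary[ens$summary$quantity %in% c("c", "kappa"), ]
#>   quantity     mean        sd
#> 1        c 0.857500 0.1262047
#> 4    kappa 0.861875 0.1273125
```

Small-system analytics, e.g. the isolated defector's optimal hop:

```r
single_agent_optimum("D", mu = 0.01)
#> Single-agent optimum: r* = 5.0000 (objective 0.0500, low_cost regime; tabulated prediction 5.0000)
dilemma_regime(game_params())$social_dilemma
#> [1] TRUE
```

A thin command-line front end ships in `inst/cli/pollution-game`
(subcommands `run`, `sweep`, `analytics`, `snapshot`); output column
meanings are documented in `inst/extdata/metrics-schema.json`.

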