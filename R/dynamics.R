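#' Simulation schedule
#'
#' The time-step regime and horizon. Each discrete step has four phases, all
#' agents acting in each: (I) imitation, (II) movement, (III) pollution,
#' (IV) expense calculation. `"fast_movement"` encodes the limit of fast
#' movement and slow strategy revision (movement time-scale much shorter
#' than the strategy one), in which phase I is skipped and strategies stay
#' frozen; `"coevolutionary"` runs imitation and movement on the same unit
#' time-scale, so all four phases run every step.
#'
#' @param regime `"coevolutionary"` or `"fast_movement"`.
#' @param T_steps Number of steps, at least 1 (0 allowed for an
#'   initialization-only trajectory).
#' @return An object of class `schedule_params`.
#' @export
schedule_params <- function(regime = c("coevolutionary", "fast_movement"),
                            T_steps = 50) {
  regime <- match.arg(regime)
  if (T_steps < 0 || T_steps != round(T_steps))
    stop("T_steps must be a nonnegative integer")
  structure(list(regime = regime, T_steps = as.integer(T_steps)),
            class = "schedule_params")
}

#' Movement objective
#'
#' The quantity an agent minimizes when choosing where to relocate: the
#' pollution at the candidate site in the field as it stood before any agent
#' moved this step (including the moving agent's own kernel), plus the
#' mobility cost per unit distance times the toroidal distance from the
#' current site.
#'
#' @param candidate,current Sites as length-2 integer vectors.
#' @param field A `pollution_field` (the phase-start field).
#' @param mu_a The agent's mobility cost.
#' @param geom A [torus_geometry()] object.
#' @return The objective value (pollution units).
#' @export
movement_objective <- function(candidate, current, field, mu_a, geom) {
  candidate <- as_site(candidate, geom$L)
  field[candidate[1L] + 1L, candidate[2L] + 1L] +
    mu_a * toroidal_distance(candidate, current, geom)
}

# Tolerance for objective ties: lattice distances and kernel weights are
# exact or near-exact in floating point; the tolerance only guards sums.
OBJ_TOL <- 1e-9

# Core argmin over all candidate sites for the agent in row `a` of
# state$agents. Candidates are the currently unoccupied sites plus the
# agent's own site; ties (within OBJ_TOL of the minimum) are broken by
# smallest movement distance, then lexicographic (x, y). Returns list(x, y,
# distance, objective).
best_move_idx <- function(state, a, field, mu_a) {
  L <- state$geom$L
  ax <- state$agents$x[a]; ay <- state$agents$y[a]
  dmat <- dist_to_all(ax, ay, state$geom)
  obj <- unclass(field) + mu_a * dmat
  blocked <- state$occ
  blocked[ax + 1L, ay + 1L] <- 0L
  obj[blocked > 0L] <- Inf
  m <- min(obj)
  cand <- which(obj <= m + OBJ_TOL)
  cx <- (cand - 1L) %% L
  cy <- (cand - 1L) %/% L
  pick <- order(dmat[cand], cx, cy)[1L]
  list(x = cx[pick], y = cy[pick],
       distance = dmat[cand[pick]], objective = obj[cand[pick]])
}

#' Best relocation site for one agent
#'
#' Exhaustive minimization of the [movement_objective()] over all currently
#' unoccupied sites plus the agent's own site (staying is always feasible
#' and costs nothing). Ties within a small tolerance are broken by smallest
#' movement distance, then lexicographic `(x, y)` — so staying wins any tie
#' it is part of.
#'
#' @param state A `population_state` carrying live occupancy.
#' @param id Agent id.
#' @param field The phase-start `pollution_field` (computed before any agent
#'   moved; it includes the focal agent's own kernel).
#' @param scheme A `cost_scheme` used to look up the agent's mobility cost.
#' @param params A [game_params()] object (used only when the scheme is
#'   strategy-dependent, to validate strategies).
#' @return List with `site` (length-2 integer vector), `distance` moved and
#'   `objective` at the chosen site.
#' @export
best_move <- function(state, id, field, scheme, params = game_params()) {
  a <- match(id, state$agents$id)
  if (is.na(a)) stop("unknown agent id")
  mu_a <- mobility_costs(state$agents, scheme)[a]
  res <- best_move_idx(state, a, field, mu_a)
  list(site = c(res$x, res$y), distance = res$distance,
       objective = res$objective)
}

#' Expense of an agent
#'
#' The total expense for the step: pollution felt at the agent's (post-move)
#' site in the phase-III field, plus the strategy cost (`f` for a
#' cooperator, `-g` for a defector), plus the mobility cost times the
#' distance just moved. Imitation copies the neighbour with the lowest
#' expense, so expense is the (negated) payoff of the game.
#'
#' @param agent A list or one-row data frame with `x`, `y`, `strategy`,
#'   `group`.
#' @param field The `pollution_field` recomputed after movement (phase III
#'   of the same step).
#' @param moved_distance Nonnegative distance the agent moved this step.
#' @param params A [game_params()] object.
#' @param scheme A `cost_scheme`.
#' @return List with `E` and its three `components` (site pollution,
#'   strategy cost, movement cost).
#' @export
expense <- function(agent, field, moved_distance, params, scheme) {
  if (moved_distance < 0) stop("moved_distance must be nonnegative")
  p <- field[agent$x + 1L, agent$y + 1L]
  eps <- strategy_cost(agent$strategy, params)
  mv <- mobility_cost_of(agent, scheme) * moved_distance
  list(E = p + eps + mv,
       components = c(site_pollution = p, strategy_cost = eps,
                      movement_cost = mv))
}

# Ids of agents within toroidal distance <= 1 of agent row a: on the
# integer lattice these are exactly the 4 axis-adjacent sites.
neighbour_ids <- function(state, a) {
  L <- state$geom$L
  x <- state$agents$x[a]; y <- state$agents$y[a]
  nb <- c(state$occ[(x - 1L) %% L + 1L, y + 1L],
          state$occ[(x + 1L) %% L + 1L, y + 1L],
          state$occ[x + 1L, (y - 1L) %% L + 1L],
          state$occ[x + 1L, (y + 1L) %% L + 1L])
  nb[nb > 0L]
}

#' Imitation target of an agent
#'
#' The strategy the agent will hold after phase I: that of the neighbour
#' (toroidal distance at most 1, excluding itself) with the lowest expense
#' from the previous step's phase IV. The copy is unconditional — the agent
#' adopts the best neighbour's strategy even if its own expense is lower —
#' unless `only_if_better = TRUE`. With no neighbours the strategy is
#' unchanged; ties among minimal neighbours are broken uniformly at random
#' using the current RNG stream.
#'
#' @param state A `population_state` whose agents carry `last_expense`.
#' @param id Agent id.
#' @param only_if_better If `TRUE`, copy only when the best neighbour's
#'   expense is strictly lower than the agent's own. Off by default.
#' @return The strategy (`"C"` or `"D"`) the agent adopts.
#' @export
imitation_target <- function(state, id, only_if_better = FALSE) {
  a <- match(id, state$agents$id)
  if (is.na(a)) stop("unknown agent id")
  nb <- neighbour_ids(state, a)
  if (length(nb) == 0L) return(state$agents$strategy[a])
  En <- state$agents$last_expense[match(nb, state$agents$id)]
  if (anyNA(En)) stop("missing expense record for a neighbour")
  best <- nb[which(En <= min(En) + OBJ_TOL)]
  b <- if (length(best) > 1L) best[sample.int(length(best), 1L)] else best
  if (only_if_better) {
    Ea <- state$agents$last_expense[a]
    if (!is.na(Ea) && min(En) >= Ea) return(state$agents$strategy[a])
  }
  state$agents$strategy[match(b, state$agents$id)]
}

# Phase I: synchronous imitation. All agents read the previous step's
# expenses and strategies, then all update at once. Positions never change.
phase_imitation <- function(state, only_if_better = FALSE) {
  ag <- state$agents
  new_strategy <- ag$strategy
  for (a in seq_len(nrow(ag)))
    new_strategy[a] <- imitation_target(state, ag$id[a], only_if_better)
  state$agents$strategy <- new_strategy
  state
}

# Phase II: movement. Agents act in a fresh random permutation; each argmin
# uses the frozen phase-start field but live occupancy, so sites vacated
# earlier in the phase are available and sites claimed are blocked.
phase_movement <- function(state, field, scheme) {
  mu <- mobility_costs(state$agents, scheme)
  ord <- sample.int(nrow(state$agents))
  for (a in ord) {
    res <- best_move_idx(state, a, field, mu[a])
    ox <- state$agents$x[a]; oy <- state$agents$y[a]
    state$occ[ox + 1L, oy + 1L] <- 0L
    state$occ[res$x + 1L, res$y + 1L] <- state$agents$id[a]
    state$agents$x[a] <- res$x
    state$agents$y[a] <- res$y
    state$agents$last_move_distance[a] <- res$distance
  }
  state
}

# Phase IV: vectorized expenses for all agents against the phase-III field.
phase_expense <- function(state, field, params, scheme) {
  ag <- state$agents
  p <- unclass(field)[cbind(ag$x + 1L, ag$y + 1L)]
  state$agents$last_expense <- p + strategy_cost(ag$strategy, params) +
    mobility_costs(ag, scheme) * ag$last_move_distance
  state
}

#' Advance one time step
#'
#' Runs one discrete step of the pollution game on `state`. Under the
#' coevolutionary regime the four phases run in order — (I) synchronous
#' imitation from the previous step's expenses, (II) movement in a fresh
#' random permutation against the frozen phase-start field, (III) field
#' recomputation, (IV) expense calculation. The fast-movement limit skips
#' phase I, so strategies never change. Occupancy stays injective
#' throughout.
#'
#' @param state A `population_state` with `field` attribute from the
#'   previous phase III (as produced by [sim_init()] or a previous
#'   `sim_step()`) and expenses in `agents$last_expense`.
#' @param params A [game_params()] object.
#' @param scheme A `cost_scheme`; the strategy-dependent variant is only
#'   accepted under the fast-movement regime.
#' @param schedule A [schedule_params()] object.
#' @param only_if_better Passed to [imitation_target()].
#' @return The updated `population_state`, with `time` advanced, a fresh
#'   `field` attribute, and per-agent `last_move_distance`/`last_expense`.
#' @export
sim_step <- function(state, params, scheme, schedule, only_if_better = FALSE) {
  if (scheme$variant == "strategy_dependent" &&
      schedule$regime != "fast_movement")
    stop("strategy-dependent costs are only defined in the fast-movement limit")
  field <- attr(state, "field")
  if (is.null(field)) stop("state lacks a phase-III field; run sim_init() first")
  if (schedule$regime == "coevolutionary")
    state <- phase_imitation(state, only_if_better)
  state <- phase_movement(state, field, scheme)
  field <- total_field(state, params)
  state <- phase_expense(state, field, params, scheme)
  state$time <- state$time + 1L
  attr(state, "field") <- field
  state
}

#' Prepare a freshly initialized state for stepping
#'
#' Runs phases III and IV once on an initial configuration (with zero
#' movement cost) so that the state carries the baseline field and the
#' expenses that the first step's imitation phase reads.
#'
#' @param state A `population_state` straight from
#'   [initialize_population()] or [population_from_agents()].
#' @param params A [game_params()] object.
#' @param scheme A `cost_scheme`.
#' @return The state with a `field` attribute and `last_expense` filled in.
#' @export
sim_init <- function(state, params, scheme) {
  state$agents$last_move_distance <- 0
  field <- total_field(state, params)
  state <- phase_expense(state, field, params, scheme)
  attr(state, "field") <- field
  state
}

#' Simulation configuration
#'
#' Bundles everything but the seed: lattice size, population size, horizon,
#' regime, initial cooperator fraction, game parameters and cost scheme.
#'
#' @param L Lattice side length.
#' @param N Population size.
#' @param T_steps Number of time steps.
#' @param regime `"coevolutionary"` or `"fast_movement"`.
#' @param c0 Initial cooperator fraction.
#' @param params A [game_params()] object.
#' @param scheme A `cost_scheme`.
#' @param only_if_better Imitation switch, see [imitation_target()].
#' @param record_states If `TRUE`, keep a copy of the state at every step.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(L = 50, N = 50, T_steps = 50,
                       regime = c("coevolutionary", "fast_movement"),
                       c0 = 0.5, params = game_params(),
                       scheme = cost_scheme_homogeneous(0.5),
                       only_if_better = FALSE, record_states = FALSE) {
  regime <- match.arg(regime)
  if (params$R >= L / 2) stop("R must be < L/2")
  if (scheme$variant == "strategy_dependent" && regime != "fast_movement")
    stop("strategy-dependent costs are only defined in the fast-movement limit")
  structure(list(L = L, N = N, schedule = schedule_params(regime, T_steps),
                 c0 = c0, params = params, scheme = scheme,
                 only_if_better = only_if_better,
                 record_states = record_states),
            class = "sim_config")
}

#' Run a seeded simulation
#'
#' Initializes a population from `config`, seeds the expenses with one
#' pollution + expense pass (zero movement cost), then advances
#' `config$schedule$T_steps` steps, recording the lattice metrics after
#' phase IV of every step. The whole trajectory is a deterministic function
#' of `(config, seed)`.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed for all randomness (placement, strategy and
#'   group assignment, movement order, imitation tie-breaks).
#' @param state Optional pre-built `population_state` to use instead of
#'   random initialization (its geometry overrides `config$L`).
#' @return An object of class `pollution_sim`: list with `metrics` (data
#'   frame with columns `t`, `c`, `pcp`, `delta_pcp`, `kappa`, `c_m`; one
#'   row per step from `t = 0` to `T`), `final_state`, `config`, `seed`,
#'   and `states` (list of per-step states if `record_states`).
#' @examples
#' cfg <- sim_config(L = 20, N = 10, T_steps = 5, c0 = 0.5,
#'                   scheme = cost_scheme_homogeneous(0.3))
#' sim <- run_simulation(cfg, seed = 1)
#' tail(sim$metrics, 1)
#' @export
run_simulation <- function(config, seed, state = NULL) {
  set.seed(seed)
  if (is.null(state)) {
    geom <- torus_geometry(config$L)
    state <- initialize_population(geom, config$N, config$c0, config$scheme)
  }
  state <- sim_init(state, config$params, config$scheme)
  alpha <- if (config$scheme$variant == "heterogeneous")
    config$scheme$alpha else NA_real_
  pcp0 <- mean(unclass(attr(state, "field"))[
    cbind(state$agents$x + 1L, state$agents$y + 1L)])
  rec <- function(state, t) {
    fld <- unclass(attr(state, "field"))
    pcp <- mean(fld[cbind(state$agents$x + 1L, state$agents$y + 1L)])
    data.frame(t = t,
               c = cooperator_fraction(state),
               pcp = pcp,
               delta_pcp = pcp - pcp0,
               kappa = clustering_fraction(state),
               c_m = if (is.na(alpha)) NA_real_ else
                 sum(state$agents$strategy == "C" &
                     state$agents$group == "minority") / nrow(state$agents))
  }
  metrics <- vector("list", config$schedule$T_steps + 1L)
  metrics[[1L]] <- rec(state, 0L)
  states <- if (config$record_states) list(state) else NULL
  for (t in seq_len(config$schedule$T_steps)) {
    state <- sim_step(state, config$params, config$scheme, config$schedule,
                      config$only_if_better)
    metrics[[t + 1L]] <- rec(state, t)
    if (config$record_states) states[[t + 1L]] <- state
  }
  structure(list(metrics = do.call(rbind, metrics), final_state = state,
                 config = config, seed = seed, states = states),
            class = "pollution_sim")
}

#' @export
print.pollution_sim <- function(x, ...) {
  fin <- x$metrics[nrow(x$metrics), ]
  cat(sprintf(
    "Pollution-game run: L = %d, N = %d, %s, T = %d (seed %d)\n",
    x$config$L, x$config$N, x$config$schedule$regime,
    x$config$schedule$T_steps, x$seed))
  cat(sprintf(
    "  final c = %.3f, delta PCP = %.3f, kappa = %.3f\n",
    fin$c, fin$delta_pcp, fin$kappa))
  invisible(x)
}

#' Write per-step metrics to CSV
#'
#' Columns `t`, `c`, `pcp`, `delta_pcp`, `kappa`, `c_m` (the latter `NA`
#' outside heterogeneous runs); see the schema file shipped in
#' `inst/extdata/metrics-schema.json`.
#'
#' @param sim A `pollution_sim` from [run_simulation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(sim, path) {
  utils::write.csv(sim$metrics, path, row.names = FALSE)
  invisible(path)
}
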