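geom <- torus_geometry(50)
params <- game_params()
hom <- function(mu) cost_scheme_homogeneous(mu)

field_for <- function(pop) total_field(pop, params)

test_that("the movement objective adds distance cost to the frozen field", {
  pop <- population_from_agents(geom, c(0, 2), c(0, 0), c("C", "D"))
  fld <- field_for(pop)
  # staying costs nothing
  expect_equal(movement_objective(c(2, 0), c(2, 0), fld, 0.1, geom),
               fld[3, 1])
  # candidate (-1, 0): cleaned by the well, grazed by own cloud, 3 away
  expect_equal(movement_objective(c(-1, 0), c(2, 0), fld, 0.1, geom),
               -5 + 1 / 9 + 0.3)
  expect_equal(movement_objective(c(5, 5), c(2, 0), fld, 0, geom),
               fld[6, 6])
})

test_that("best_move reproduces the small-system optima", {
  # isolated cooperator sits at the bottom of its own well
  st <- sim_init(population_from_agents(geom, 0, 0, "C"), params, hom(0.1))
  bm <- best_move(st, 1, attr(st, "field"), hom(0.1))
  expect_equal(bm$site, c(0, 0))
  expect_equal(bm$distance, 0)
  # defector beside a cooperator crosses to the far edge of the well
  st <- sim_init(population_from_agents(geom, c(0, 2), c(0, 0), c("C", "D")),
                 params, hom(0.1))
  bm <- best_move(st, 2, attr(st, "field"), hom(0.1))
  expect_equal(bm$site, c(49, 0))
  expect_equal(bm$objective, -5 + 1 / 9 + 0.3)
  # two cooperators two apart close to the shared-well midpoint
  st <- sim_init(population_from_agents(geom, c(0, 2), c(0, 0), c("C", "C")),
                 params, hom(1))
  bm <- best_move(st, 2, attr(st, "field"), hom(1))
  expect_equal(bm$site, c(1, 0))
  expect_equal(bm$distance, 1)
})

test_that("expense sums felt pollution, strategy cost and movement cost", {
  stC <- sim_init(population_from_agents(geom, 0, 0, "C"), params, hom(0.1))
  expect_equal(stC$agents$last_expense, -5 + 3.5)
  stD <- sim_init(population_from_agents(geom, 0, 0, "D"), params, hom(0.1))
  expect_equal(stD$agents$last_expense, 1 - 3.5)
  e <- expense(list(x = 0, y = 0, strategy = "C", group = "none"),
               attr(stC, "field"), 2, params, hom(0.25))
  expect_equal(e$E, -5 + 3.5 + 0.5)
  expect_equal(unname(sum(e$components)), e$E)
  expect_error(expense(list(x = 0, y = 0, strategy = "C", group = "none"),
                       attr(stC, "field"), -1, params, hom(0.1)),
               "nonnegative")
  # zero cost, zero field, free cooperation
  z <- expense(list(x = 20, y = 20, strategy = "C", group = "none"),
               attr(stC, "field"), 0, game_params(f = 0), hom(0))
  expect_equal(z$E, 0)
})

test_that("imitation copies the cheapest axis neighbour, unconditionally", {
  # C at (0,0) with a cheaper D neighbour: adopts D even though both E < own
  st <- sim_init(population_from_agents(geom, c(0, 1), c(0, 0), c("C", "D")),
                 params, hom(0.1))
  expect_equal(imitation_target(st, 1), "D")
  expect_equal(imitation_target(st, 2), "C")
  # diagonal contact is distance sqrt(2): no neighbours, unchanged
  st2 <- sim_init(population_from_agents(geom, c(0, 1), c(0, 1), c("C", "D")),
                  params, hom(0.1))
  expect_equal(imitation_target(st2, 1), "C")
  # isolated agent keeps its strategy
  st3 <- sim_init(population_from_agents(geom, 0, 0, "C"), params, hom(0.1))
  expect_equal(imitation_target(st3, 1), "C")
  # only-if-better switch suppresses adopting a worse neighbour
  st4 <- sim_init(population_from_agents(geom, c(0, 1), c(0, 0), c("D", "C")),
                  params, hom(0.1))
  expect_equal(imitation_target(st4, 1), "C")      # literal rule copies
  expect_equal(imitation_target(st4, 1, only_if_better = TRUE), "D")
})

test_that("small fixed points persist under stepping", {
  sch <- schedule_params("fast_movement", 1)
  # a lone cooperator never moves and its expense is constant
  st <- sim_init(population_from_agents(geom, 7, 9, "C"), params, hom(0.5))
  for (i in 1:3) {
    st <- sim_step(st, params, hom(0.5), sch)
    expect_equal(c(st$agents$x, st$agents$y), c(7, 9))
    expect_equal(st$agents$last_expense, -1.5)
  }
  # two cooperators at distance 2 close to 1, then freeze
  st <- sim_init(population_from_agents(geom, c(0, 2), c(0, 0), c("C", "C")),
                 params, hom(1))
  st <- sim_step(st, params, hom(1), sch)
  d1 <- toroidal_distance(c(st$agents$x[1], st$agents$y[1]),
                          c(st$agents$x[2], st$agents$y[2]), geom)
  expect_equal(d1, 1)
  st <- sim_step(st, params, hom(1), sch)
  expect_equal(toroidal_distance(c(st$agents$x[1], st$agents$y[1]),
                                 c(st$agents$x[2], st$agents$y[2]), geom), 1)
})

test_that("an all-defector population is frozen when movement is expensive", {
  set.seed(21)
  idx <- sample(50^2, 12)
  pop <- population_from_agents(geom, (idx - 1) %% 50, (idx - 1) %/% 50,
                                rep("D", 12))
  st <- sim_init(pop, params, hom(10))
  # staying bound: any move of distance >= 1 costs at least mu = 10, more
  # than the largest possible pollution drop; verified by the engine
  x0 <- st$agents$x; y0 <- st$agents$y
  sch <- schedule_params("fast_movement", 1)
  for (i in 1:3) {
    st <- sim_step(st, params, hom(10), sch)
    expect_equal(st$agents$x, x0)
    expect_equal(st$agents$y, y0)
  }
})

test_that("executed moves are always at least as good as staying", {
  set.seed(31)
  for (rep in 1:20) {
    L <- sample(11:15, 1)
    g <- torus_geometry(L)
    N <- sample(2:6, 1)
    ag <- random_small_config(L, N)
    pop <- population_from_agents(g, ag$x, ag$y, ag$strategy)
    mu <- runif(1, 0, 1)
    st <- sim_init(pop, params, hom(mu))
    fld <- attr(st, "field")
    for (a in seq_len(N)) {
      bm <- best_move(st, a, fld, hom(mu))
      stay <- movement_objective(c(ag$x[a], ag$y[a]), c(ag$x[a], ag$y[a]),
                                 fld, mu, g)
      expect_lte(bm$objective, stay + 1e-9)
      if (bm$distance > 0) expect_lt(bm$objective, stay - 1e-9)
    }
  }
})

test_that("occupancy stays injective through full steps", {
  set.seed(77)
  sch <- schedule_params("coevolutionary", 1)
  for (rep in 1:100) {
    L <- sample(11:15, 1)
    g <- torus_geometry(L)
    N <- sample(2:min(10, L^2 %/% 3), 1)
    ag <- random_small_config(L, N)
    pop <- population_from_agents(g, ag$x, ag$y, ag$strategy)
    mu <- runif(1, 0, 0.5)
    st <- sim_init(pop, params, hom(mu))
    st <- sim_step(st, params, hom(mu), sch)
    expect_false(anyDuplicated(cbind(st$agents$x, st$agents$y)) > 0)
    expect_equal(sum(st$occ > 0), N)
    expect_equal(st$occ[cbind(st$agents$x + 1, st$agents$y + 1)],
                 st$agents$id)
  }
})

test_that("fast movement never changes strategies; imitation never moves agents", {
  cfg <- sim_config(L = 20, N = 15, T_steps = 5, regime = "fast_movement",
                    c0 = 0.4, scheme = hom(0.2), record_states = TRUE)
  sim <- run_simulation(cfg, 9)
  s0 <- sim$states[[1]]$agents$strategy
  for (s in sim$states) expect_identical(s$agents$strategy, s0)
  # phase I in isolation changes only the strategy column
  st <- sim_init(initialize_population(torus_geometry(20), 15, 0.4, hom(0.2),
                                       seed = 2), params, hom(0.2))
  st1 <- pollutiongame:::phase_imitation(st)
  expect_identical(st1$agents$x, st$agents$x)
  expect_identical(st1$agents$y, st$agents$y)
  expect_identical(st1$occ, st$occ)
})

test_that("best_move agrees with the independent exhaustive oracle", {
  set.seed(55)
  for (rep in 1:60) {
    L <- sample(11:15, 1)
    g <- torus_geometry(L)
    N <- sample(1:6, 1)
    ag <- random_small_config(L, N)
    a <- sample(N, 1)
    mu <- sample(c(0, 0.05, 0.2, 0.5, 1), 1)
    pop <- population_from_agents(g, ag$x, ag$y, ag$strategy)
    st <- sim_init(pop, params, hom(mu))
    bm <- best_move(st, a, attr(st, "field"), hom(mu))
    ob <- oracle_best_move(ag, a, mu, L)
    expect_equal(bm$site, c(ob$x, ob$y))
    expect_equal(bm$objective, ob$obj, tolerance = 1e-10)
  }
})

test_that("moved distance is non-increasing in mobility cost for small systems", {
  mus <- seq(0, 1.2, by = 0.1)
  # lone defector (engine path)
  d1 <- sapply(mus, function(mu) {
    st <- sim_init(population_from_agents(geom, 0, 0, "D"), params, hom(mu))
    best_move(st, 1, attr(st, "field"), hom(mu))$distance
  })
  expect_true(all(diff(d1) <= 1e-9))
  # mobile defector near a cooperator, and two cooperators (oracle path)
  for (strats in list(c("C", "D"), c("C", "C"), c("D", "D"))) {
    d2 <- sapply(mus, function(mu)
      two_agent_optimum(strats[1], strats[2], c(3, 0), mu, params,
                        geom)$distance)
    expect_true(all(diff(d2) <= 1e-9))
  }
})

test_that("a free defector relocates into a distant cooperator's well", {
  st <- sim_init(population_from_agents(geom, c(0, 20), c(0, 20),
                                        c("C", "D")), params, hom(0))
  bm <- best_move(st, 2, attr(st, "field"), hom(0))
  expect_lte(toroidal_distance(bm$site, c(0, 0), geom), 1)
})

test_that("trajectories are reproducible and sized T + 1", {
  cfg <- sim_config(L = 20, N = 10, T_steps = 7, c0 = 0.5, scheme = hom(0.3))
  a <- run_simulation(cfg, 123)
  b <- run_simulation(cfg, 123)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$final_state$agents, b$final_state$agents)
  expect_equal(nrow(a$metrics), 8)
  expect_equal(a$metrics$delta_pcp[1], 0)
  cfg0 <- sim_config(L = 20, N = 10, T_steps = 0, c0 = 0.5, scheme = hom(0.3))
  expect_equal(nrow(run_simulation(cfg0, 1)$metrics), 1)
})
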