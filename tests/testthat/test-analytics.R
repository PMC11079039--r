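params <- game_params()
geom <- torus_geometry(50)

test_that("the radial defector objective follows its three branches", {
  expect_equal(defector_radial_objective(0, 0.1, 5), 1)
  expect_equal(defector_radial_objective(3, 0.1, 5), 1 / 9 + 0.3)
  # strict convention: at exactly r = R the cloud term is gone
  expect_equal(defector_radial_objective(5, 0.01, 5), 0.05)
  expect_equal(defector_radial_objective(c(0.5, 2, 7), 0.2, 5),
               c(1.1, 0.25 + 0.4, 1.4))
})

test_that("single-agent optima land in the tabulated regimes", {
  expect_equal(single_agent_optimum("C", 0.1, params)$r_star, 0)
  expect_equal(single_agent_optimum("C", 0, params)$r_star, 0)
  low <- single_agent_optimum("D", 0.01, params)
  expect_equal(low$r_star, 5)
  expect_equal(low$regime_label, "low_cost")
  expect_equal(low$objective_value, 0.05)
  hi <- single_agent_optimum("D", 3, params)
  expect_equal(hi$r_star, 0)
  expect_equal(hi$regime_label, "immobile")
  # mu = 0: minimizer set is {r >= R}; smallest reported, flagged non-unique
  free <- single_agent_optimum("D", 0, params)
  expect_equal(free$r_star, 5)
  expect_true(free$nonunique)
  # where the printed intermediate prediction and global minimization agree
  mid <- single_agent_optimum("D", 0.1, params)
  expect_equal(mid$r_star, (2 / 0.1)^(1 / 3), tolerance = 1e-3)
  expect_equal(mid$r_star, mid$predicted_r_star, tolerance = 1e-3)
  # ... and where they differ: cross-branch comparison favours staying
  late <- single_agent_optimum("D", 1, params)
  expect_equal(late$r_star, 0)
  expect_equal(late$predicted_r_star, 2^(1 / 3))
})

test_that("continuous and lattice single-defector optima agree up to discretization", {
  for (mu in c(0.005, 0.1, 3)) {
    cont <- single_agent_optimum("D", mu, params)$r_star
    st <- sim_init(population_from_agents(geom, 0, 0, "D"), params,
                   cost_scheme_homogeneous(mu))
    latt <- best_move(st, 1, attr(st, "field"),
                      cost_scheme_homogeneous(mu))$distance
    expect_lte(abs(latt - cont), 1)
  }
})

test_that("two-agent optima reproduce the worked scenarios", {
  cc <- two_agent_optimum("C", "C", c(2, 0), 1, params, geom)
  expect_equal(cc$site, c(1, 0))
  cd <- two_agent_optimum("C", "D", c(2, 0), 0.1, params, geom)
  expect_equal(cd$signed, c(-1, 0))
  expect_equal(cd$objective, -5 + 1 / 9 + 0.3)
  # adjacent cooperators have no better site at any positive cost
  near <- two_agent_optimum("C", "C", c(1, 0), 0.5, params, geom)
  expect_equal(near$site, c(1, 0))
  expect_error(two_agent_optimum("C", "C", c(0, 0), 0.5, params, geom),
               "origin")
})

test_that("two-agent optimum matches the engine's best_move", {
  for (case in list(list(s = c("C", "D"), start = c(2, 0), mu = 0.1),
                    list(s = c("C", "C"), start = c(2, 0), mu = 1),
                    list(s = c("D", "D"), start = c(4, 0), mu = 0.05))) {
    st <- sim_init(population_from_agents(geom, c(0, case$start[1]),
                                          c(0, case$start[2]), case$s),
                   params, cost_scheme_homogeneous(case$mu))
    bm <- best_move(st, 2, attr(st, "field"),
                    cost_scheme_homogeneous(case$mu))
    or <- two_agent_optimum(case$s[1], case$s[2], case$start, case$mu,
                            params, geom)
    expect_equal(bm$site, or$site)
  }
})

test_that("the two-cooperator long-term map is piecewise and idempotent", {
  expect_equal(two_cooperator_longterm(2, 1, 5), 1)
  expect_equal(two_cooperator_longterm(3, 0.01, 5), 3)
  expect_equal(two_cooperator_longterm(1.5, 20, 5), 1.5)  # 20 >= 5/0.5
  expect_equal(two_cooperator_longterm(0.8, 0.1, 5), 0.8)
  expect_error(two_cooperator_longterm(0, 0.1, 5), "positive")
  set.seed(5)
  for (rep in 1:50) {
    r <- runif(1, 0.05, 4); mu <- runif(1, 0, 12); phi <- runif(1, 0.5, 8)
    once <- two_cooperator_longterm(r, mu, phi)
    expect_equal(two_cooperator_longterm(once, mu, phi), once)
  }
})

test_that("dilemma classification matches the closed-form conditions", {
  d <- dilemma_regime(params)
  expect_equal(d$payoff_matrix["C", "C"], 2 * 5 - 3.5)       # 6.5
  expect_equal(d$payoff_matrix["D", "C"], 5 + 3.5 - 1)       # 7.5
  expect_equal(d$payoff_matrix["C", "D"], 5 - 3.5 - 1)       # 0.5
  expect_equal(d$payoff_matrix["D", "D"], 3.5 - 2)           # 1.5
  expect_true(d$defection_dominant)       # f + g = 7 > 1 + phi = 6
  expect_true(d$mutual_cooperation_socially_optimal)  # 7 < 2 + 2 phi = 12
  expect_true(d$social_dilemma)
  expect_false(dilemma_regime(game_params(f = 0, g = 0))$defection_dominant)
  set.seed(17)
  for (rep in 1:100) {
    p <- game_params(f = runif(1, 0, 8), g = runif(1, 0, 8),
                     phi = runif(1, 0, 8), R = 5)
    dd <- dilemma_regime(p)
    expect_identical(dd$defection_dominant, dd$dominance_inequality)
    expect_identical(dd$mutual_cooperation_socially_optimal,
                     dd$social_optimality_inequality)
  }
})

test_that("the regime table spans all three cost regimes", {
  tab <- single_agent_regime_table(c(0.005, 0.1, 0.5, 2.5))
  expect_equal(tab$regime_label,
               c("low_cost", "intermediate", "intermediate", "immobile"))
  expect_equal(tab$r_star[1], 5)
  expect_equal(tab$r_star[4], 0)
})
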