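#' Radial movement objective of an isolated defector
#'
#' The movement objective of a single defector at the origin, written in
#' radial form thanks to circular symmetry: `1 + mu*r` inside its own unit
#' core (`r < 1`), `r^-2 + mu*r` inside the cloud (`1 <= r < R`), and the
#' bare movement cost `mu*r` beyond. Note the strict inequality at `r = R`:
#' the continuous analytic objective places the cloud boundary outside the
#' cloud, whereas the lattice kernel of the simulator uses the closed
#' inequality `d <= R` (the two conventions disagree only at `d = R`
#' exactly).
#'
#' @param r Nonnegative radial distance(s); vectorized.
#' @param mu Nonnegative mobility cost.
#' @param R Pollution radius, greater than 1.
#' @return Objective value(s).
#' @examples
#' defector_radial_objective(0, mu = 0.1, R = 5)   # 1
#' defector_radial_objective(3, mu = 0.1, R = 5)   # 1/9 + 0.3
#' @export
defector_radial_objective <- function(r, mu, R) {
  stopifnot(all(r >= 0), mu >= 0, R > 1)
  ifelse(r < 1, 1 + mu * r,
         ifelse(r < R, r^-2 + mu * r, mu * r))
}

#' Optimal relocation distance of an isolated agent
#'
#' For a single agent at the origin, the radial distance `r_star` that
#' globally minimizes its movement objective. A cooperator sits at the
#' bottom of its own cleaning well, so it stays put for every `mu > 0` (and
#' is indifferent over the well at `mu = 0`, resolved to staying). A
#' defector minimizes [defector_radial_objective()]; the minimizer is found
#' by piecewise analysis (branch endpoints plus the interior stationary
#' point `(2/mu)^(1/3)` of the cloud branch) and cross-checked against a
#' dense grid search with step `1e-4`.
#'
#' The result also reports the three-regime textbook prediction
#' (`R` for `mu < 2 R^-3`; `(2/mu)^(1/3)` for `2 R^-3 <= mu < 2`; 0 for
#' `mu >= 2`) separately as `predicted_r_star`. The two agree in the
#' low-cost and immobile regimes but not throughout the intermediate one:
#' global minimization across branches keeps `r_star = R` slightly above
#' `2 R^-3` and switches to staying (`r = 0`, value 1) well below `mu = 2`,
#' because the interior value `3 (mu/2)^(2/3)` exceeds 1 once
#' `mu > 2/sqrt(27)`. Both answers are exposed rather than silently
#' reconciled.
#'
#' @param sigma `"C"` or `"D"`.
#' @param mu Nonnegative mobility cost.
#' @param params A [game_params()] object (supplies `R`).
#' @return An object of class `single_agent_optimum`: list with `r_star`,
#'   `objective_value`, `regime_label` (`"low_cost"`, `"intermediate"` or
#'   `"immobile"`), and `predicted_r_star`. For a defector at `mu = 0` the
#'   minimizer set is `{r >= R}` (objective 0 everywhere there); the
#'   smallest, `r_star = R`, is reported with `nonunique = TRUE`.
#' @export
single_agent_optimum <- function(sigma, mu, params = game_params()) {
  stopifnot(sigma %in% c("C", "D"), mu >= 0)
  R <- params$R
  if (sigma == "C")
    return(structure(list(r_star = 0, objective_value = -params$phi,
                          regime_label = "immobile",
                          predicted_r_star = 0, nonunique = FALSE),
                     class = "single_agent_optimum"))
  predicted <- if (mu < 2 * R^-3) R else if (mu < 2) (2 / mu)^(1 / 3) else 0
  label <- if (mu < 2 * R^-3) "low_cost" else if (mu < 2) "intermediate"
           else "immobile"
  if (mu == 0)
    return(structure(list(r_star = R, objective_value = 0,
                          regime_label = label, predicted_r_star = predicted,
                          nonunique = TRUE),
                     class = "single_agent_optimum"))
  # candidate minimizers: branch endpoints and the cloud branch's interior
  # stationary point; the tail mu*r is increasing so r = R caps it.
  cand <- c(0, 1, R)
  ri <- (2 / mu)^(1 / 3)
  if (ri >= 1 && ri < R) cand <- c(cand, ri)
  vals <- defector_radial_objective(cand, mu, R)
  r_star <- cand[which.min(vals)]
  grid <- seq(0, 2 * R, by = 1e-4)
  gvals <- defector_radial_objective(grid, mu, R)
  g_star <- grid[which.min(gvals)]
  if (abs(g_star - r_star) > 1e-3 &&
      min(gvals) < min(vals) - 1e-9)
    r_star <- g_star  # grid found a lower basin the analysis missed
  structure(list(r_star = r_star, objective_value = min(vals, min(gvals)),
                 regime_label = label, predicted_r_star = predicted,
                 nonunique = FALSE),
            class = "single_agent_optimum")
}

#' @export
print.single_agent_optimum <- function(x, ...) {
  cat(sprintf(
    "Single-agent optimum: r* = %.4f (objective %.4f, %s regime; tabulated prediction %.4f)\n",
    x$r_star, x$objective_value, x$regime_label, x$predicted_r_star))
  invisible(x)
}

#' Optimal relocation of a mobile agent beside a stationary one
#'
#' Brute-force oracle for the two-agent system: a stationary agent `a0`
#' sits at the origin, a mobile agent `a1` at `start` chooses where to
#' relocate. The pre-movement field is the sum of both agents' lattice
#' kernels (including the mobile agent's own, centred at `start`); the
#' mobile agent exhaustively minimizes field value plus `mu` times the
#' toroidal distance from `start` over all unoccupied sites plus its own,
#' with the same tie-break as the simulation engine (smallest distance,
#' then lexicographic). The field here is evaluated per pair directly from
#' distances, independent of the engine's precomputed kernel tables, so
#' this operation can serve as an oracle for [best_move()].
#'
#' @param sigma0 Strategy of the stationary agent at the origin.
#' @param sigma1 Strategy of the mobile agent.
#' @param start Mobile agent's site, not the origin.
#' @param mu Mobility cost of the mobile agent.
#' @param params A [game_params()] object.
#' @param geom A [torus_geometry()] object.
#' @return List with `site`, `signed` (coordinates unwrapped to
#'   `(-L/2, L/2]`), `distance` moved and `objective`.
#' @examples
#' geom <- torus_geometry(50)
#' # a defector beside a cooperator crosses to the far edge of the well
#' two_agent_optimum("C", "D", start = c(2, 0), mu = 0.1,
#'                   params = game_params(), geom = geom)$signed # (-1, 0)
#' @export
two_agent_optimum <- function(sigma0, sigma1, start, mu, params, geom) {
  L <- geom$L
  start <- as_site(start, L)
  if (all(start == c(0L, 0L))) stop("start must differ from the origin")
  best <- NULL
  for (sy in 0:(L - 1L)) for (sx in 0:(L - 1L)) {
    s <- c(sx, sy)
    if (sx == 0L && sy == 0L) next  # origin occupied by a0
    val <- contribution(sigma0, c(0L, 0L), s, params, geom) +
      contribution(sigma1, start, s, params, geom)
    d <- toroidal_distance(s, start, geom)
    obj <- val + mu * d
    if (is.null(best) || obj < best$objective - OBJ_TOL ||
        (obj <= best$objective + OBJ_TOL &&
         (d < best$distance - OBJ_TOL ||
          (abs(d - best$distance) <= OBJ_TOL &&
           (sx < best$site[1L] ||
            (sx == best$site[1L] && sy < best$site[2L]))))))
      best <- list(site = s, distance = d, objective = obj)
  }
  best$signed <- signed_coordinate(best$site, L)
  best
}

#' Long-term separation of two cooperators
#'
#' Closed-form long-run map for the distance between two cooperators that
#' start `r` apart. Very near (`0 < r <= 1`) they already share both
#' cleaning wells and stay; far apart (`r > 2`) they act as independent
#' single-cooperator systems and stay; in between (`1 < r <= 2`) they move
#' one step closer, to share the site cleaned by both wells, provided the
#' cost is low enough (`mu < phi / (r - 1)`), otherwise movement is too
#' costly and they stay. The map is idempotent: applying it twice gives the
#' same answer as once.
#'
#' @param r Initial separation, positive.
#' @param mu Nonnegative mobility cost.
#' @param phi Cleaning amount, positive.
#' @return The long-run separation `r(Inf)`.
#' @export
two_cooperator_longterm <- function(r, mu, phi) {
  if (r <= 0) stop("r must be positive")
  stopifnot(mu >= 0, phi > 0)
  if (r > 1 && r <= 2 && mu < phi / (r - 1)) r - 1 else r
}

#' Classify the two-player dilemma regime
#'
#' Builds the payoff matrix of the two-player game at adjacency — two agents
#' on neighbouring sites, far from everyone else — directly from the lattice
#' kernels: each entry is the negative of the focal agent's expense at zero
#' movement, i.e. `pi_C(C) = 2 phi - f`, `pi_D(C) = phi + g - 1`,
#' `pi_C(D) = phi - f - 1`, `pi_D(D) = g - 2`. From the matrix it decides
#' whether defection is strictly dominant (equivalently `f + g > 1 + phi`)
#' and whether mutual cooperation is socially optimal, i.e.
#' `2 pi_C(C)` exceeds both the mixed-pair total and `2 pi_D(D)`
#' (equivalently `f + g < 2 + 2 phi`). When both hold the game is a social
#' dilemma. The closed-form inequalities are evaluated independently and
#' returned alongside the matrix-based booleans.
#'
#' @param params A [game_params()] object.
#' @return An object of class `dilemma_classification`: list with
#'   `payoff_matrix` (rows: focal strategy, columns: partner strategy),
#'   `defection_dominant`, `mutual_cooperation_socially_optimal`,
#'   `social_dilemma`, and the closed-form booleans
#'   `dominance_inequality`, `social_optimality_inequality`.
#' @examples
#' dilemma_regime(game_params(f = 3.5, g = 3.5, phi = 5))$social_dilemma
#' @export
dilemma_regime <- function(params) {
  geom <- torus_geometry(max(3L, 2L * ceiling(params$R) + 3L))
  p0 <- c(0L, 0L); p1 <- c(1L, 0L)
  payoff <- matrix(NA_real_, 2L, 2L,
                   dimnames = list(focal = c("C", "D"),
                                   partner = c("C", "D")))
  for (s1 in c("C", "D")) for (s2 in c("C", "D")) {
    pol <- contribution(s1, p0, p0, params, geom) +
      contribution(s2, p1, p0, params, geom)
    payoff[s1, s2] <- -(pol + strategy_cost(s1, params))
  }
  dominant <- payoff["D", "C"] > payoff["C", "C"] &&
    payoff["D", "D"] > payoff["C", "D"]
  social <- 2 * payoff["C", "C"] >
    max(payoff["C", "D"] + payoff["D", "C"], 2 * payoff["D", "D"])
  structure(list(
    payoff_matrix = payoff,
    defection_dominant = dominant,
    mutual_cooperation_socially_optimal = social,
    social_dilemma = dominant && social,
    dominance_inequality = params$f + params$g > 1 + params$phi,
    social_optimality_inequality = params$f + params$g < 2 + 2 * params$phi),
    class = "dilemma_classification")
}

#' @export
print.dilemma_classification <- function(x, ...) {
  cat("Two-player game at adjacency (payoff = -expense):\n")
  print(x$payoff_matrix)
  cat(sprintf("defection dominant: %s; mutual cooperation socially optimal: %s\n",
              x$defection_dominant, x$mutual_cooperation_socially_optimal))
  if (x$social_dilemma) cat("=> social dilemma\n")
  invisible(x)
}

#' Single-agent regime table over a cost grid
#'
#' Tabulates [single_agent_optimum()] for a defector over a grid of
#' mobility costs; the `analytics` CLI subcommand writes this as CSV.
#'
#' @param mu_grid Numeric vector of mobility costs.
#' @param params A [game_params()] object.
#' @return Data frame with columns `mu`, `r_star`, `objective_value`,
#'   `regime_label`, `predicted_r_star`.
#' @export
single_agent_regime_table <- function(mu_grid, params = game_params()) {
  rows <- lapply(mu_grid, function(m) {
    o <- single_agent_optimum("D", m, params)
    data.frame(mu = m, r_star = o$r_star,
               objective_value = o$objective_value,
               regime_label = o$regime_label,
               predicted_r_star = o$predicted_r_star)
  })
  do.call(rbind, rows)
}
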