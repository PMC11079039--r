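#' Pollution-game parameters
#'
#' The four parameters of the pollution game: the cooperation fee `f` paid by
#' a cleaner, the defection benefit `g` collected by a polluter, the amount
#' of pollution `phi` a cleaner removes from its own site and the four
#' axis-adjacent sites, and the radius `R` of a polluter's inverse-square
#' pollution cloud. Defaults are the study conditions `f = g = 3.5`,
#' `phi = 5`, `R = 5`, for which the two-player game at adjacency is a
#' social dilemma (see [dilemma_regime()]).
#'
#' @param f Cooperation fee (expense units), nonnegative.
#' @param g Defection benefit (expense units), nonnegative.
#' @param phi Cleaning amount per site (pollution units), nonnegative.
#' @param R Pollution radius (lattice units), at least 1; must also satisfy
#'   `R < L/2` for any lattice it is used on (checked at field construction).
#' @return An object of class `game_params`.
#' @export
game_params <- function(f = 3.5, g = 3.5, phi = 5, R = 5) {
  stopifnot(is.numeric(f), is.numeric(g), is.numeric(phi), is.numeric(R),
            length(f) == 1L, length(g) == 1L, length(phi) == 1L,
            length(R) == 1L)
  if (f < 0 || g < 0 || phi < 0) stop("f, g and phi must be nonnegative")
  if (R < 1) stop("R must be >= 1")
  structure(list(f = f, g = g, phi = phi, R = R), class = "game_params")
}

#' @export
print.game_params <- function(x, ...) {
  cat(sprintf("Pollution game: f = %g, g = %g, phi = %g, R = %g\n",
              x$f, x$g, x$phi, x$R))
  invisible(x)
}

#' Mobility-cost schemes
#'
#' Three ways of assigning the per-unit-distance mobility cost an agent pays
#' when relocating:
#'
#' * `cost_scheme_homogeneous(mu)`: every agent pays the same `mu`.
#' * `cost_scheme_heterogeneous()`: a minority fraction `alpha` of agents
#'   pays `mu_m` and the majority pays `mu_M`. Either give `mu_M` directly
#'   or give the population mean `mu_hat`, in which case
#'   `mu_M = (mu_hat - alpha * mu_m) / (1 - alpha)` — at `alpha = 0.2` this
#'   is `(5 * mu_hat - mu_m) / 4`.
#' * `cost_scheme_strategy()`: cooperators pay `mu_C` and defectors `mu_D`.
#'   `mu_D` may be derived from a mean constraint
#'   `mu_hat = c * mu_C + (1 - c) * mu_D` at a fixed cooperator fraction
#'   `c`. Only meaningful in the fast-movement regime, where strategies are
#'   frozen; the simulator refuses it under coevolution.
#'
#' @param mu,mu_m,mu_M,mu_C,mu_D Nonnegative mobility costs
#'   (expense units per lattice unit moved).
#' @param alpha Minority fraction, in (0, 0.5).
#' @param mu_hat Population-mean mobility cost used to derive the missing
#'   group cost.
#' @param c_frac Fixed cooperator fraction used to derive `mu_D` from
#'   `mu_hat` in the strategy-dependent scheme.
#' @return An object of class `cost_scheme` with a `variant` field in
#'   `homogeneous`, `heterogeneous` or `strategy_dependent`.
#' @examples
#' cost_scheme_heterogeneous(mu_m = 0.2, mu_hat = 0.4) # mu_M = 0.45
#' cost_scheme_strategy(mu_C = 0.1, mu_hat = 0.4, c_frac = 0.8) # mu_D = 1.6
#' @export
cost_scheme_homogeneous <- function(mu) {
  stopifnot(is.numeric(mu), length(mu) == 1L, mu >= 0)
  structure(list(variant = "homogeneous", mu = mu), class = "cost_scheme")
}

#' @rdname cost_scheme_homogeneous
#' @export
cost_scheme_heterogeneous <- function(mu_m, mu_M = NULL, mu_hat = NULL,
                                      alpha = 0.2) {
  stopifnot(is.numeric(mu_m), length(mu_m) == 1L, mu_m >= 0,
            is.numeric(alpha), length(alpha) == 1L)
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must lie in (0, 0.5)")
  if (is.null(mu_M)) {
    if (is.null(mu_hat))
      stop("supply either mu_M or the population mean mu_hat")
    mu_M <- (mu_hat - alpha * mu_m) / (1 - alpha)
  }
  if (mu_M < 0)
    stop("infeasible heterogeneous scheme: derived mu_M is negative")
  structure(list(variant = "heterogeneous", alpha = alpha, mu_m = mu_m,
                 mu_M = mu_M, mu_hat = alpha * mu_m + (1 - alpha) * mu_M),
            class = "cost_scheme")
}

#' @rdname cost_scheme_homogeneous
#' @export
cost_scheme_strategy <- function(mu_C, mu_D = NULL, mu_hat = NULL,
                                 c_frac = NULL) {
  stopifnot(is.numeric(mu_C), length(mu_C) == 1L, mu_C >= 0)
  if (is.null(mu_D)) {
    if (is.null(mu_hat) || is.null(c_frac))
      stop("supply either mu_D or both mu_hat and c_frac")
    if (c_frac <= 0 || c_frac >= 1) stop("c_frac must lie in (0, 1)")
    mu_D <- (mu_hat - c_frac * mu_C) / (1 - c_frac)
  }
  if (mu_D < 0)
    stop("infeasible strategy-dependent scheme: derived mu_D is negative")
  structure(list(variant = "strategy_dependent", mu_C = mu_C, mu_D = mu_D),
            class = "cost_scheme")
}

#' @export
print.cost_scheme <- function(x, ...) {
  switch(x$variant,
    homogeneous = cat(sprintf("Homogeneous mobility cost: mu = %g\n", x$mu)),
    heterogeneous = cat(sprintf(
      "Heterogeneous mobility costs: alpha = %g, mu_m = %g, mu_M = %g (mean %g)\n",
      x$alpha, x$mu_m, x$mu_M, x$mu_hat)),
    strategy_dependent = cat(sprintf(
      "Strategy-dependent mobility costs: mu_C = %g, mu_D = %g\n",
      x$mu_C, x$mu_D)))
  invisible(x)
}

#' Mobility cost of one agent under a scheme
#'
#' @param agent A list or one-row data frame with at least `strategy`
#'   (`"C"`/`"D"`) and `group` (`"minority"`, `"majority"` or `"none"`).
#' @param scheme A `cost_scheme` object.
#' @return A single nonnegative mobility cost.
#' @export
mobility_cost_of <- function(agent, scheme) {
  switch(scheme$variant,
    homogeneous = scheme$mu,
    heterogeneous = {
      if (!agent$group %in% c("minority", "majority"))
        stop("heterogeneous scheme requires minority/majority group labels")
      if (agent$group == "minority") scheme$mu_m else scheme$mu_M
    },
    strategy_dependent =
      if (agent$strategy == "C") scheme$mu_C else scheme$mu_D)
}

# Vectorized mobility costs for all agents of a population state.
mobility_costs <- function(agents, scheme) {
  switch(scheme$variant,
    homogeneous = rep(scheme$mu, nrow(agents)),
    heterogeneous = ifelse(agents$group == "minority",
                           scheme$mu_m, scheme$mu_M),
    strategy_dependent = ifelse(agents$strategy == "C",
                                scheme$mu_C, scheme$mu_D))
}
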