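#' Cooperator fraction
#'
#' Fraction of agents currently playing the cooperator (cleaner) strategy.
#'
#' @param pop A `population_state`.
#' @return A fraction in `[0, 1]`.
#' @export
cooperator_fraction <- function(pop) {
  n <- nrow(pop$agents)
  if (n == 0L) stop("cooperator fraction is undefined for an empty population")
  sum(pop$agents$strategy == "C") / n
}

#' Per-capita pollution and its change along a trajectory
#'
#' Per-capita pollution (PCP) is the mean pollution felt by agents at their
#' own sites, evaluating the phase-III field of step `t` at the step-`t`
#' positions. `pcp_change()` returns its change relative to the baseline
#' recorded after the initialization pollution pass, i.e. the `delta_pcp`
#' column of the metrics: negative values mean agents feel cleaner sites
#' than they started on.
#'
#' @param sim A `pollution_sim` from [run_simulation()].
#' @param t Step index (default: the final step).
#' @return A single real (pollution units); 0 at `t = 0` by definition.
#' @export
pcp_change <- function(sim, t = max(sim$metrics$t)) {
  row <- sim$metrics[sim$metrics$t == t, ]
  if (nrow(row) != 1L) stop("no metrics recorded at step ", t)
  row$delta_pcp
}

#' Clustering fraction
#'
#' Fraction of agents with at least one other agent within toroidal distance
#' 1 (i.e. on one of the four axis-adjacent sites; diagonal contact at
#' distance sqrt(2) does not count).
#'
#' @param pop A `population_state`.
#' @return A fraction in `[0, 1]`.
#' @export
clustering_fraction <- function(pop) {
  ag <- pop$agents
  n <- nrow(ag)
  if (n == 0L) stop("clustering is undefined for an empty population")
  L <- pop$geom$L
  occ <- pop$occ > 0L
  has_nb <- occ[cbind((ag$x - 1L) %% L + 1L, ag$y + 1L)] |
    occ[cbind((ag$x + 1L) %% L + 1L, ag$y + 1L)] |
    occ[cbind(ag$x + 1L, (ag$y - 1L) %% L + 1L)] |
    occ[cbind(ag$x + 1L, (ag$y + 1L) %% L + 1L)]
  sum(has_nb) / n
}

#' Strategy-by-group frequency table
#'
#' Measures the global cooperator fraction `c` and the minority-cooperator
#' fraction `c_m` (agents that are both cooperators and minority members,
#' over the whole population) and derives the remaining joint fractions from
#' the margins: `c_M = c - c_m`, `d_m = alpha - c_m`,
#' `d_M = 1 - alpha - c + c_m`. Also reports the relative minority
#' cooperation `c_m / alpha - c`, which is 0 exactly when strategy and group
#' membership are independent, positive when the minority disproportionately
#' cooperates, and bounded in `[alpha - 1, 1 - alpha]`.
#'
#' @param pop A `population_state` with minority/majority group labels.
#' @param alpha Minority fraction; defaults to the observed fraction.
#' @return List of class `frequency_table` with fields `c`, `c_m`, `c_M`,
#'   `d_m`, `d_M`, `alpha` and `relative_minority_cooperation`.
#' @export
frequency_table <- function(pop, alpha = NULL) {
  ag <- pop$agents
  n <- nrow(ag)
  if (is.null(alpha)) alpha <- sum(ag$group == "minority") / n
  c_all <- sum(ag$strategy == "C") / n
  c_m <- sum(ag$strategy == "C" & ag$group == "minority") / n
  structure(list(c = c_all, c_m = c_m, c_M = c_all - c_m,
                 d_m = alpha - c_m, d_M = 1 - alpha - c_all + c_m,
                 alpha = alpha,
                 relative_minority_cooperation = c_m / alpha - c_all),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  m <- matrix(c(x$c_m, x$c_M, x$c, x$d_m, x$d_M, 1 - x$c,
                x$alpha, 1 - x$alpha, 1),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("Cooperator", "Defector", "Total"),
                              c("Minority", "Majority", "Total")))
  print(round(m, 4))
  cat(sprintf("Relative minority cooperation c_m/alpha - c = %.4f\n",
              x$relative_minority_cooperation))
  invisible(x)
}

#' Ensemble mean and standard deviation
#'
#' Aggregates per-run scalar metrics over an ensemble of simulations: the
#' arithmetic mean and the sample (n-1) standard deviation of each column.
#'
#' @param runs A data frame with one row per run and one numeric column per
#'   quantity (non-numeric columns are ignored).
#' @return An object of class `ensemble_summary`: data frame with columns
#'   `quantity`, `mean`, `sd`, plus attribute `n_runs`.
#' @export
ensemble_summary <- function(runs) {
  num <- vapply(runs, is.numeric, logical(1L))
  qs <- names(runs)[num]
  out <- data.frame(
    quantity = qs,
    mean = vapply(qs, function(q) mean(runs[[q]]), numeric(1L)),
    sd = vapply(qs, function(q) stats::sd(runs[[q]]), numeric(1L)),
    row.names = NULL)
  structure(out, n_runs = nrow(runs), class = c("ensemble_summary",
                                                "data.frame"))
}
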