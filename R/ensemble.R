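#' Run a seeded ensemble of simulations
#'
#' Repeats [run_simulation()] with seeds `base_seed, base_seed + 1, ...,
#' base_seed + n_runs - 1` and summarises the final-step metrics over the
#' ensemble. Deterministic given `base_seed`; pooling two disjoint seed
#' blocks reproduces the mean of the combined block.
#'
#' @param config A [sim_config()] object.
#' @param n_runs Number of runs, at least 1.
#' @param base_seed First seed of the block.
#' @return List of class `pollution_ensemble` with `runs` (data frame of
#'   final-step metrics, one row per run, with `seed`), `summary` (an
#'   [ensemble_summary()]), `config` and `base_seed`.
#' @export
run_ensemble <- function(config, n_runs, base_seed) {
  if (n_runs < 1) stop("n_runs must be >= 1")
  rows <- lapply(seq_len(n_runs) - 1L, function(i) {
    sim <- run_simulation(config, base_seed + i)
    fin <- sim$metrics[nrow(sim$metrics), ]
    cbind(seed = base_seed + i, fin)
  })
  runs <- do.call(rbind, rows)
  keep <- setdiff(names(runs), c("seed", "t"))
  structure(list(runs = runs, summary = ensemble_summary(runs[keep]),
                 config = config, base_seed = base_seed),
            class = "pollution_ensemble")
}

#' @export
print.pollution_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d runs (seeds %d..%d):\n", nrow(x$runs),
              x$base_seed, x$base_seed + nrow(x$runs) - 1L))
  print(as.data.frame(x$summary))
  invisible(x)
}

# Stable per-run seed for sweep cells, so cells can run in any order (or in
# parallel) and still reproduce: documented as
# (base_seed + 1000003*cell + 7919*run) mod 2147483647.
sweep_run_seed <- function(base_seed, cell_index, run_index) {
  as.integer((as.numeric(base_seed) + 1000003 * cell_index +
                7919 * run_index) %% 2147483647)
}

#' Parameter-sweep specification
#'
#' Describes the cross-product experimental design behind the heatmap
#' figures: one named axis per swept parameter, a run count per cell and a
#' base seed. Recognised axis names: `mu` (homogeneous cost), `mu_m`
#' (heterogeneous minority cost, with fixed `mu_hat` and `alpha` in
#' `fixed`), `c0` and `N`. Everything else is fixed via the `fixed` list,
#' which accepts the [sim_config()] arguments plus `mu_hat` and `alpha`.
#'
#' @param axes Named list of numeric vectors.
#' @param runs_per_cell Runs per grid cell.
#' @param base_seed Base seed for the per-cell seed derivation.
#' @param fixed Named list of fixed configuration values.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(axes, runs_per_cell = 20, base_seed = 1,
                       fixed = list()) {
  known <- c("mu", "mu_m", "c0", "N")
  if (is.null(names(axes)) || !all(names(axes) %in% known))
    stop("axis names must be among: ", paste(known, collapse = ", "))
  if (!all(vapply(axes, function(v) all(is.finite(v)) && all(v >= 0),
                  logical(1L))))
    stop("axis values must be finite and nonnegative")
  if (runs_per_cell < 1) stop("runs_per_cell must be >= 1")
  structure(list(axes = axes, runs_per_cell = runs_per_cell,
                 base_seed = base_seed, fixed = fixed),
            class = "sweep_spec")
}

# Assemble the sim_config for one sweep cell from the fixed values plus the
# cell's axis values. Returns NULL for infeasible heterogeneous cells.
cell_config <- function(cell, fixed) {
  get <- function(name, default) {
    if (!is.null(cell[[name]])) cell[[name]]
    else if (!is.null(fixed[[name]])) fixed[[name]]
    else default
  }
  scheme <- if (!is.null(cell$mu_m) || !is.null(fixed$mu_m)) {
    mu_M <- tryCatch(
      cost_scheme_heterogeneous(get("mu_m", 0),
                                mu_hat = get("mu_hat", 0.4),
                                alpha = get("alpha", 0.2)),
      error = function(e) NULL)
    mu_M
  } else cost_scheme_homogeneous(get("mu", 0.5))
  if (is.null(scheme)) return(NULL)
  sim_config(L = get("L", 50), N = get("N", 50),
             T_steps = get("T_steps", 50),
             regime = get("regime", "coevolutionary"),
             c0 = get("c0", 0.5),
             params = if (is.null(fixed$params)) game_params()
                      else fixed$params,
             scheme = scheme)
}

#' Execute a parameter sweep
#'
#' Runs a seeded ensemble for every cell of the cross-product grid and
#' returns one row per cell with the ensemble mean and standard deviation
#' of the final-step metrics. Per-run seeds are derived reproducibly from
#' `(base_seed, cell index, run index)`, so the result table is
#' bit-reproducible and independent of execution order. Heterogeneous cells
#' whose derived majority cost would be negative are flagged `feasible =
#' FALSE` and skipped with a warning.
#'
#' @param spec A [sweep_spec()] object.
#' @return Data frame of class `sweep_result`: the axis columns, `feasible`,
#'   `n_runs`, and `<metric>_mean` / `<metric>_sd` columns for `c`,
#'   `delta_pcp`, `kappa`, `c_m` and (for heterogeneous cells)
#'   `relative_minority_cooperation`.
#' @export
run_sweep <- function(spec) {
  grid <- expand.grid(spec$axes, KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cell <- as.list(grid[i, , drop = FALSE])
    cfg <- cell_config(cell, spec$fixed)
    if (is.null(cfg)) {
      warning(sprintf("sweep cell %d infeasible (negative majority cost); skipped", i))
      out[[i]] <- cbind(grid[i, , drop = FALSE], feasible = FALSE,
                        n_runs = 0L)
      next
    }
    rows <- lapply(seq_len(spec$runs_per_cell), function(j) {
      sim <- run_simulation(cfg, sweep_run_seed(spec$base_seed, i, j))
      fin <- sim$metrics[nrow(sim$metrics), ]
      if (cfg$scheme$variant == "heterogeneous")
        fin$relative_minority_cooperation <-
          fin$c_m / cfg$scheme$alpha - fin$c
      fin
    })
    runs <- do.call(rbind, rows)
    stats_cols <- setdiff(names(runs), "t")
    cellrow <- cbind(grid[i, , drop = FALSE], feasible = TRUE,
                     n_runs = spec$runs_per_cell)
    for (q in stats_cols) {
      cellrow[[paste0(q, "_mean")]] <- mean(runs[[q]])
      cellrow[[paste0(q, "_sd")]] <- stats::sd(runs[[q]])
    }
    out[[i]] <- cellrow
  }
  res <- do.call(rbind, lapply(out, function(df) {
    missing <- setdiff(unique(unlist(lapply(out, names))), names(df))
    for (m in missing) df[[m]] <- NA
    df
  }))
  rownames(res) <- NULL
  class(res) <- c("sweep_result", "data.frame")
  res
}
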