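#' Initialize a population on the lattice
#'
#' Places `N` agents uniformly at random on distinct sites of the lattice,
#' assigns exactly `round(c0 * N)` of them (a uniformly random subset) the
#' cooperator strategy, and — under a heterogeneous cost scheme — assigns a
#' uniformly random subset of `round(alpha * N)` agents to the minority
#' group. Strategy counts are exact rather than Bernoulli draws, which
#' removes one source of ensemble variance when sweeping the initial
#' cooperator fraction. Group membership is independent of both strategy and
#' position.
#'
#' @param geom A [torus_geometry()] object.
#' @param N Number of agents, at most `L^2`.
#' @param c0 Initial cooperator fraction in `[0, 1]`.
#' @param scheme A `cost_scheme`; group labels are only drawn for the
#'   heterogeneous variant.
#' @param seed Optional integer seed; if given, `set.seed(seed)` is called
#'   first so the state is reproducible in isolation. Leave `NULL` when the
#'   caller manages the RNG stream (as [run_simulation()] does).
#' @return A `population_state`: list with `agents` (data frame `id`, `x`,
#'   `y`, `strategy`, `group`, `last_move_distance`, `last_expense`), `occ`
#'   (L x L integer occupancy matrix, 0 for empty), `time` and `geom`.
#' @examples
#' geom <- torus_geometry(50)
#' pop <- initialize_population(geom, N = 50, c0 = 0.2,
#'                              cost_scheme_homogeneous(0.3), seed = 1)
#' sum(pop$agents$strategy == "C") # exactly 10
#' @export
initialize_population <- function(geom, N, c0, scheme, seed = NULL) {
  L <- geom$L
  if (N < 1 || N != round(N)) stop("N must be a positive integer")
  if (N > L^2) stop("N exceeds lattice capacity L^2")
  if (c0 < 0 || c0 > 1) stop("c0 must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(L^2, N)
  strategy <- rep("D", N)
  nC <- round(c0 * N)
  if (nC > 0) strategy[sample.int(N, nC)] <- "C"
  group <- rep("none", N)
  if (scheme$variant == "heterogeneous") {
    group <- rep("majority", N)
    nm <- round(scheme$alpha * N)
    if (nm > 0) group[sample.int(N, nm)] <- "minority"
  }
  agents <- data.frame(
    id = seq_len(N),
    x = (idx - 1L) %% L,
    y = (idx - 1L) %/% L,
    strategy = strategy,
    group = group,
    last_move_distance = 0,
    last_expense = NA_real_,
    stringsAsFactors = FALSE)
  occ <- matrix(0L, L, L)
  occ[cbind(agents$x + 1L, agents$y + 1L)] <- agents$id
  structure(list(agents = agents, occ = occ, time = 0L, geom = geom),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  ag <- x$agents
  cat(sprintf(
    "Population state: N = %d on %d x %d lattice, t = %d (%d C / %d D)\n",
    nrow(ag), x$geom$L, x$geom$L, x$time,
    sum(ag$strategy == "C"), sum(ag$strategy == "D")))
  invisible(x)
}

#' Save and restore population snapshots as JSON
#'
#' The snapshot records `{time, L, agents: [{id, x, y, strategy, group}]}`
#' and can be read back to resume or replay a configuration. Movement
#' distances and expenses are transient per-step quantities and are not part
#' of the snapshot; a restored state behaves like a freshly initialized one.
#'
#' @param state A `population_state`.
#' @param path File path.
#' @return `write_state_json()` returns `path` invisibly;
#'   `read_state_json()` returns a `population_state`.
#' @export
write_state_json <- function(state, path) {
  ag <- state$agents
  jsonlite::write_json(
    list(time = state$time, L = state$geom$L,
         agents = ag[, c("id", "x", "y", "strategy", "group")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_state_json
#' @export
read_state_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- torus_geometry(obj$L)
  ag <- obj$agents
  ag$last_move_distance <- 0
  ag$last_expense <- NA_real_
  if (anyDuplicated(cbind(ag$x, ag$y)))
    stop("snapshot has colliding agent positions")
  occ <- matrix(0L, geom$L, geom$L)
  occ[cbind(ag$x + 1L, ag$y + 1L)] <- ag$id
  structure(list(agents = ag, occ = occ, time = as.integer(obj$time),
                 geom = geom),
            class = "population_state")
}

#' Build a population from explicit placements
#'
#' Deterministic constructor for scenario fixtures: give the coordinates and
#' strategies outright instead of sampling them. Positions are reduced
#' modulo `L` and must be distinct.
#'
#' @param geom A [torus_geometry()] object.
#' @param x,y Integer coordinate vectors, one entry per agent.
#' @param strategy Character vector of `"C"`/`"D"`.
#' @param group Optional group labels (`"minority"`, `"majority"`, `"none"`).
#' @return A `population_state`.
#' @examples
#' geom <- torus_geometry(50)
#' # a stationary cooperator at the origin and a defector two sites away
#' pop <- population_from_agents(geom, x = c(0, 2), y = c(0, 0),
#'                               strategy = c("C", "D"))
#' @export
population_from_agents <- function(geom, x, y, strategy,
                                   group = rep("none", length(x))) {
  L <- geom$L
  x <- as.integer(x) %% L; y <- as.integer(y) %% L
  if (anyDuplicated(cbind(x, y))) stop("agent positions must be distinct")
  if (!all(strategy %in% c("C", "D"))) stop("strategies must be 'C' or 'D'")
  agents <- data.frame(
    id = seq_along(x), x = x, y = y, strategy = strategy, group = group,
    last_move_distance = 0, last_expense = NA_real_,
    stringsAsFactors = FALSE)
  occ <- matrix(0L, L, L)
  occ[cbind(x + 1L, y + 1L)] <- agents$id
  structure(list(agents = agents, occ = occ, time = 0L, geom = geom),
            class = "population_state")
}
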