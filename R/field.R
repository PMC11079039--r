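#' Strategy cost
#'
#' The direct cost of an agent's strategy: a cooperator pays the fee `f`, a
#' defector collects the benefit `g` (a negative cost).
#'
#' @param sigma Strategy vector with values `"C"` or `"D"` (vectorized).
#' @param params A [game_params()] object.
#' @return `f` for cooperators, `-g` for defectors.
#' @export
strategy_cost <- function(sigma, params) {
  if (!all(sigma %in% c("C", "D"))) stop("strategies must be 'C' or 'D'")
  ifelse(sigma == "C", params$f, -params$g)
}

# Per-strategy kernel as an offset table: integer offsets (dx, dy) from the
# agent plus the weight each receives. The defector cloud uses the closed
# inequality d <= R, so the boundary offset (3, 4) at R = 5 contributes
# 1/25; the analytic radial objective in the small-N module uses the strict
# convention instead (the two disagree only at d = R exactly).
kernel_offsets <- function(sigma, params) {
  if (sigma == "C") {
    off <- expand.grid(dx = -1:1, dy = -1:1)
    keep <- off$dx^2 + off$dy^2 <= 1
    list(dx = off$dx[keep], dy = off$dy[keep],
         w = rep(-params$phi, sum(keep)))
  } else {
    R <- params$R
    k <- floor(R)
    off <- expand.grid(dx = -k:k, dy = -k:k)
    d2 <- off$dx^2 + off$dy^2
    keep <- d2 <= R^2 * (1 + 1e-12)
    d2 <- d2[keep]
    list(dx = off$dx[keep], dy = off$dy[keep],
         w = ifelse(d2 <= 1, 1, 1 / d2))
  }
}

# Total lattice mass of one agent's kernel (sum of its weights): the
# conserved quantity per defector (S_D) or cooperator (-5 phi).
kernel_mass <- function(sigma, params) sum(kernel_offsets(sigma, params)$w)

#' Pollution or cleaning contributed by one agent to one site
#'
#' The per-agent kernel evaluated directly from the toroidal distance `d`
#' between `source` (the agent's site) and `target`: a cooperator
#' contributes `-phi` wherever `d <= 1` and 0 elsewhere; a defector
#' contributes 1 where `d <= 1`, `d^-2` where `1 < d <= R` and 0 beyond.
#' The source site itself (`d = 0`) is included in both supports.
#'
#' @param sigma `"C"` or `"D"`.
#' @param source,target Sites as length-2 integer vectors.
#' @param params A [game_params()] object.
#' @param geom A [torus_geometry()] object; `R` must be `< L/2`.
#' @return The contribution in pollution units (negative for a cooperator).
#' @export
contribution <- function(sigma, source, target, params, geom) {
  if (params$R >= geom$L / 2) stop("R must be < L/2")
  d <- toroidal_distance(source, target, geom)
  if (sigma == "C") {
    if (d <= 1) -params$phi else 0
  } else if (sigma == "D") {
    if (d <= 1) 1
    else if (d <= params$R * (1 + 1e-12)) 1 / d^2
    else 0
  } else stop("strategies must be 'C' or 'D'")
}

#' Instantaneous pollution field of a population
#'
#' The superposed field of all agents at the current time step: the value at
#' every site is the sum of each agent's kernel ([contribution()]) evaluated
#' there. The field is instantaneous — pollution does not accumulate across
#' steps — and linear in agents, so the lattice total always equals
#' `N_D * S_D - N_C * 5 * phi` where `S_D` is the defector kernel mass.
#'
#' @param pop A `population_state` (see [initialize_population()]).
#' @param params A [game_params()] object.
#' @return An L x L numeric matrix of class `pollution_field`, indexed
#'   `[x + 1, y + 1]`, with attributes `L` and `time`.
#' @export
total_field <- function(pop, params) {
  geom <- pop$geom
  if (params$R >= geom$L / 2) stop("R must be < L/2")
  L <- geom$L
  fld <- matrix(0, L, L)
  kC <- kernel_offsets("C", params)
  kD <- kernel_offsets("D", params)
  ag <- pop$agents
  for (a in seq_len(nrow(ag))) {
    k <- if (ag$strategy[a] == "C") kC else kD
    ix <- cbind((ag$x[a] + k$dx) %% L + 1L, (ag$y[a] + k$dy) %% L + 1L)
    fld[ix] <- fld[ix] + k$w
  }
  structure(fld, L = L, time = pop$time, class = "pollution_field")
}

#' @export
print.pollution_field <- function(x, ...) {
  cat(sprintf("Pollution field on %d x %d lattice at t = %d\n",
              attr(x, "L"), attr(x, "L"), attr(x, "time")))
  cat(sprintf("  total %.4f, range [%.4f, %.4f]\n",
              sum(x), min(x), max(x)))
  invisible(x)
}

#' Export a pollution field snapshot
#'
#' `write_field_tsv()` writes the field as a dense tab-separated matrix, one
#' line per lattice row (fixed `y`, `x` varying across columns).
#' `write_field_json()` writes `{L, time, values}` with values in row-major
#' order by `y`. `read_field_json()` reads the latter back.
#'
#' @param field A `pollution_field` from [total_field()].
#' @param path Output file path.
#' @return `path`, invisibly (readers return the field).
#' @export
write_field_tsv <- function(field, path) {
  utils::write.table(t(unclass(field)), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_field_tsv
#' @export
write_field_json <- function(field, path) {
  jsonlite::write_json(
    list(L = attr(field, "L"), time = attr(field, "time"),
         values = apply(unclass(field), 2L, identity, simplify = FALSE)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_field_tsv
#' @export
read_field_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- matrix(unlist(obj$values), nrow = obj$L, ncol = obj$L)
  structure(vals, L = obj$L, time = obj$time, class = "pollution_field")
}
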