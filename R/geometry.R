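#' Periodic square-lattice geometry
#'
#' Constructs the doubly periodic L x L lattice (a discrete 2-torus) on which
#' all agents live. Sites are 0-based integer coordinate pairs `(x, y)` with
#' both components in `[0, L)`; every stored position is reduced modulo `L`.
#' The constructor precomputes the folded-offset distance table used by the
#' movement engine, so geometry objects should be built once and reused.
#'
#' @param L Integer lattice side length, at least 3. The lattice has `L^2`
#'   sites.
#' @return An object of class `torus_geometry`: a list with elements `L` and
#'   `dist0`, where `dist0[i, j]` is the toroidal distance between the origin
#'   and the site with offset `(i - 1, j - 1)`.
#' @examples
#' geom <- torus_geometry(50)
#' toroidal_distance(c(0, 0), c(49, 0), geom) # wraps around: 1
#' @export
torus_geometry <- function(L) {
  if (length(L) != 1L || !is.finite(L) || L != round(L) || L < 3)
    stop("L must be a single integer >= 3")
  L <- as.integer(L)
  fold <- pmin(0:(L - 1L), L - (0:(L - 1L)))
  structure(list(L = L, dist0 = sqrt(outer(fold^2, fold^2, "+"))),
            class = "torus_geometry")
}

#' @export
print.torus_geometry <- function(x, ...) {
  cat("Toroidal lattice geometry:", x$L, "x", x$L,
      sprintf("(%d sites)\n", x$L^2))
  invisible(x)
}

as_site <- function(p, L) {
  if (length(p) != 2L || anyNA(p) || !is.numeric(p))
    stop("a site must be a numeric vector of length 2")
  if (any(p != round(p)))
    stop("site coordinates must be integers")
  as.integer(round(p)) %% L
}

#' Geodesic distance on the torus
#'
#' Distance between two lattice sites with each coordinate difference folded
#' into `[0, L/2]` before taking the Euclidean norm, so paths may wrap around
#' either lattice edge.
#'
#' @param p,q Sites as length-2 integer vectors `(x, y)`; coordinates outside
#'   `[0, L)` are reduced modulo `L`.
#' @param geom A [torus_geometry()] object.
#' @return The nonnegative geodesic distance. Zero if and only if `p` and `q`
#'   are the same site; each folded component is at most `L/2`.
#' @examples
#' geom <- torus_geometry(50)
#' toroidal_distance(c(0, 0), c(3, 4), geom) # 5, no folding
#' @export
toroidal_distance <- function(p, q, geom) {
  L <- geom$L
  p <- as_site(p, L); q <- as_site(q, L)
  dx <- abs(p[1L] - q[1L]); dy <- abs(p[2L] - q[2L])
  sqrt(min(dx, L - dx)^2 + min(dy, L - dy)^2)
}

#' Sites within a toroidal radius
#'
#' All lattice sites whose toroidal distance from `center` is at most
#' `radius` (closed ball, including the center itself). The radius must stay
#' below `L/2` so that the ball cannot wrap onto itself and double-count
#' sites.
#'
#' @param center Site as a length-2 integer vector.
#' @param radius Nonnegative radius in lattice units, strictly less than
#'   `L/2`.
#' @param geom A [torus_geometry()] object.
#' @return Integer matrix with columns `x`, `y`, one row per site, reduced
#'   modulo `L`.
#' @export
sites_within <- function(center, radius, geom) {
  L <- geom$L
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0)
    stop("radius must be a single nonnegative number")
  if (radius >= L / 2)
    stop("radius must be < L/2 so the neighbourhood cannot wrap onto itself")
  center <- as_site(center, L)
  k <- floor(radius)
  off <- expand.grid(dx = -k:k, dy = -k:k)
  keep <- off$dx^2 + off$dy^2 <= radius^2 * (1 + 1e-12)
  cbind(x = (center[1L] + off$dx[keep]) %% L,
        y = (center[2L] + off$dy[keep]) %% L)
}

# Toroidal distance from (x, y) to every lattice site, as an L x L matrix
# indexed [sx + 1, sy + 1]. A permuted view of the precomputed dist0 table;
# this is the hot path of the movement phase.
dist_to_all <- function(x, y, geom) {
  L <- geom$L
  geom$dist0[((0:(L - 1L)) - x) %% L + 1L, ((0:(L - 1L)) - y) %% L + 1L]
}

# Fold a 0-based coordinate to its signed representative in (-L/2, L/2].
signed_coordinate <- function(x, L) {
  s <- x %% L
  ifelse(s > L / 2, s - L, s)
}
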