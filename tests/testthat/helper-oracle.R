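# Independent brute-force oracle for the movement rule. Deliberately shares
# no code with the package's kernel-table path: distances and piecewise
# kernel values are recomputed from first principles per site pair.

oracle_dist <- function(x1, y1, x2, y2, L) {
  dx <- abs(x1 - x2); dy <- abs(y1 - y2)
  sqrt(min(dx, L - dx)^2 + min(dy, L - dy)^2)
}

oracle_kernel <- function(sigma, d, phi, R) {
  if (sigma == "C") {
    if (d <= 1) -phi else 0
  } else {
    if (d <= 1) 1 else if (d <= R) 1 / d^2 else 0
  }
}

# Best move of agent `a` (row index) given data frame ag with x, y, strategy:
# exhaustive search over all sites, frozen field including a's own kernel,
# unoccupied-or-own candidate set, tie-break (distance, x, y).
oracle_best_move <- function(ag, a, mu, L, phi = 5, R = 5) {
  best <- NULL
  for (sy in 0:(L - 1)) for (sx in 0:(L - 1)) {
    occupied <- any(ag$x == sx & ag$y == sy & seq_len(nrow(ag)) != a)
    if (occupied) next
    val <- 0
    for (b in seq_len(nrow(ag)))
      val <- val + oracle_kernel(ag$strategy[b],
                                 oracle_dist(ag$x[b], ag$y[b], sx, sy, L),
                                 phi, R)
    d <- oracle_dist(ag$x[a], ag$y[a], sx, sy, L)
    obj <- val + mu * d
    if (is.null(best) || obj < best$obj - 1e-9 ||
        (obj <= best$obj + 1e-9 &&
         (d < best$d - 1e-9 ||
          (abs(d - best$d) <= 1e-9 &&
           (sx < best$x || (sx == best$x && sy < best$y))))))
      best <- list(x = sx, y = sy, d = d, obj = obj)
  }
  best
}

# Random small configuration on its own RNG draw: distinct sites, random
# strategies. Returns the agents data frame.
random_small_config <- function(L, N) {
  idx <- sample(L^2, N)
  data.frame(x = (idx - 1) %% L, y = (idx - 1) %/% L,
             strategy = sample(c("C", "D"), N, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Defector kernel lattice mass by direct offset enumeration (independent of
# kernel_offsets): 5 core sites plus inverse-square shell up to R.
oracle_defector_mass <- function(R = 5) {
  s <- 0
  for (dx in -R:R) for (dy in -R:R) {
    d <- sqrt(dx^2 + dy^2)
    if (d <= 1) s <- s + 1 else if (d <= R) s <- s + 1 / d^2
  }
  s
}
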