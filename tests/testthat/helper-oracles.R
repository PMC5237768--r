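# Independent oracles kept deliberately separate from the package's
# implementation paths.

# Element stiffness by brute-force numerical integration of B' D B over
# the reference square with a fine Simpson grid (no Gauss points shared
# with the implementation).
oracle_element_stiffness <- function(coords, E, mu, thickness = 10,
                                     n = 41) {
  stopifnot(n %% 2 == 1)
  xi <- seq(-1, 1, length.out = n)
  w <- rep(c(4, 2), length.out = n - 2)
  w <- c(1, w[-(n - 1)], 1) * (2 / (n - 1)) / 3  # Simpson weights
  D <- E / (1 - mu^2) * matrix(c(1, mu, 0, mu, 1, 0, 0, 0, (1 - mu) / 2), 3, 3)
  K <- matrix(0, 8, 8)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      x <- xi[a]; y <- xi[b]
      dN <- rbind(
        c(-(1 - y), (1 - y), (1 + y), -(1 + y)) / 4,
        c(-(1 - x), -(1 + x), (1 + x), (1 - x)) / 4
      )
      J <- dN %*% coords
      dNxy <- solve(J, dN)
      B <- matrix(0, 3, 8)
      B[1, seq(1, 8, 2)] <- dNxy[1, ]
      B[2, seq(2, 8, 2)] <- dNxy[2, ]
      B[3, seq(1, 8, 2)] <- dNxy[2, ]
      B[3, seq(2, 8, 2)] <- dNxy[1, ]
      K <- K + w[a] * w[b] * crossprod(B, D %*% B) * det(J) * thickness
    }
  }
  K
}

# Exhaustive grid search for the mass-constrained fixed-stress energy
# minimum on 2- or 3-element problems. Objective: sum U_j (rho_j/x_j)^3
# subject to sum x_j v_j = M, lo <= x_j <= hi.
oracle_density_optimum <- function(U, rho, v, M, lo, hi, step = 1e-3) {
  n <- length(U)
  obj <- function(x) sum(U * (rho / x)^3)
  best <- NULL; best_val <- Inf
  if (n == 2) {
    for (x1 in seq(lo, hi, by = step)) {
      x2 <- (M - x1 * v[1]) / v[2]
      if (x2 < lo - 1e-12 || x2 > hi + 1e-12) next
      val <- obj(c(x1, x2))
      if (val < best_val) { best_val <- val; best <- c(x1, x2) }
    }
  } else if (n == 3) {
    for (x1 in seq(lo, hi, by = step)) {
      for (x2 in seq(lo, hi, by = step)) {
        x3 <- (M - x1 * v[1] - x2 * v[2]) / v[3]
        if (x3 < lo - 1e-12 || x3 > hi + 1e-12) next
        val <- obj(c(x1, x2, x3))
        if (val < best_val) { best_val <- val; best <- c(x1, x2, x3) }
      }
    }
  } else {
    stop("oracle supports 2 or 3 elements")
  }
  best
}
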