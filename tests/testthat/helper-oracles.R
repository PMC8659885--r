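# Independent oracles used to validate the implementation.  These share no
# code path with the package internals: composite-Simpson quadrature, naive
# time stepping with bisection refinement, Horn's quaternion superposition,
# and brute-force double loops.

# composite Simpson average of f over [lo, hi]
oracle_shell_average <- function(f, lo, hi, n = 20000L) {
  if (n %% 2L == 1L) n <- n + 1L
  x <- seq(lo, hi, length.out = n + 1L)
  y <- vapply(x, f, 0)
  h <- (hi - lo) / n
  int <- h / 3 * (y[1] + y[n + 1L] + 4 * sum(y[seq(2L, n, 2L)]) +
                    2 * sum(y[seq(3L, n - 1L, 2L)]))
  int / (hi - lo)
}

# first time at which |r + v t| crosses any of the radii, by fine stepping
# plus bisection on the exact linear-motion distance
oracle_first_crossing <- function(r, v, radii, t_max = 50, dt = 1e-4) {
  dist_at <- function(t) sqrt(sum((r + v * t)^2))
  d0 <- dist_at(0)
  side0 <- vapply(radii, function(R) d0 > R, TRUE)
  t <- 0
  while (t < t_max) {
    t1 <- t + dt
    d1 <- dist_at(t1)
    side1 <- vapply(radii, function(R) d1 > R, TRUE)
    flip <- which(side1 != side0)
    if (length(flip)) {
      R <- radii[flip[1]]
      lo <- t; hi <- t1
      for (k in 1:200) {
        mid <- (lo + hi) / 2
        if ((dist_at(mid) > R) == side0[flip[1]]) lo <- mid else hi <- mid
      }
      return(list(time = (lo + hi) / 2, radius_index = flip[1]))
    }
    t <- t1
  }
  list(time = Inf, radius_index = NA_integer_)
}

# Horn's closed-form quaternion superposition RMSD (align == measure set)
oracle_rmsd_quaternion <- function(X, Y) {
  X0 <- sweep(X, 2, colMeans(X))
  Y0 <- sweep(Y, 2, colMeans(Y))
  S <- crossprod(X0, Y0)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[3, 1] + S[1, 3]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(X0^2) + sum(Y0^2) - 2 * lmax) / nrow(X)
  sqrt(max(msd, 0))
}

# two-pass mass-weighted radius of gyration (Angstrom)
oracle_rg <- function(x, m) {
  com <- colSums(x * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(x, 2, com)^2)) / sum(m))
}

oracle_min_cross_distance <- function(xa, xb, box_L = 0) {
  best <- Inf
  for (i in seq_len(nrow(xa))) for (j in seq_len(nrow(xb))) {
    d <- xa[i, ] - xb[j, ]
    if (box_L > 0) d <- d - box_L * round(d / box_L)
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# minimal trajectory object for analysis-layer tests
fake_traj <- function(topology, frames, times, box_L = 0) {
  sys <- list(topology = topology, box_L = box_L)
  class(sys) <- "pacsab_system"
  tr <- list(frames = frames, times = times, system = sys)
  class(tr) <- "pacsab_trajectory"
  tr
}

AB40_SEQ <- "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVV"

# minimal two-particle, two-chain topology for association observables
two_point_topology <- function() {
  atoms <- data.frame(index = 1:2, kind = "P", resno = 1L, resid = "XXX",
                      chain = c("A", "B"), mass = 1, radius = 1, type = "toy",
                      stringsAsFactors = FALSE)
  structure(list(atoms = atoms, constraints = data.frame(),
                 sequence = c(A = "X", B = "X")),
            class = "pacsab_topology")
}
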