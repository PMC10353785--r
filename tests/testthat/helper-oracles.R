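# Independent oracles used across the suite. Each reimplements the checked
# operation by a different route (brute force, closed form, dense algebra)
# and never calls the code path it validates.

# Bit-loop Morton oracle: bit b of i -> 3b, of j -> 3b+1, of k -> 3b+2.
mortonOracle <- function(i, j, k) {
  key <- 0
  for (b in 0:20) {
    key <- key + bitwAnd(bitwShiftR(i, b), 1L) * 2^(3 * b)
    key <- key + bitwAnd(bitwShiftR(j, b), 1L) * 2^(3 * b + 1)
    key <- key + bitwAnd(bitwShiftR(k, b), 1L) * 2^(3 * b + 2)
  }
  key
}

# All-pairs O(n^2) force oracle, fully vectorized (no neighbour lists).
allPairsForces <- function(pos, radius, params) {
  n <- nrow(pos)
  dx <- outer(pos[, 1], pos[, 1], function(a, b) b - a)
  dy <- outer(pos[, 2], pos[, 2], function(a, b) b - a)
  dz <- outer(pos[, 3], pos[, 3], function(a, b) b - a)
  d <- sqrt(dx^2 + dy^2 + dz^2)
  RR <- outer(radius, radius, "+")
  RA <- params$adhesion_distance_factor * RR
  m <- params$C_cca * (1 - d / RA)^2 * (d <= RA) -
    params$C_ccr * (1 - d / RR)^2 * (d <= RR)
  diag(m) <- 0
  diag(d) <- 1  # avoid 0/0; the diagonal magnitude is already zero
  w <- m / d
  cbind(rowSums(w * dx), rowSums(w * dy), rowSums(w * dz)) +
    matrix(params$F_mot, n, 3, byrow = TRUE)
}

# Dense solve of a tridiagonal system via base R linear algebra.
denseTridiagSolve <- function(sub, dg, super, rhs) {
  n <- length(dg)
  A <- diag(dg, n, n)
  if (n > 1) {
    A[cbind(2:n, 1:(n - 1))] <- sub
    A[cbind(1:(n - 1), 2:n)] <- super
  }
  solve(A, rhs)
}

# Equilibrium separation of two identical adhering cells: the root of
# sqrt(C_ccr) (1 - d/R_R) = sqrt(C_cca) (1 - d/R_A).
twoCellEquilibrium <- function(R, params) {
  RR <- 2 * R
  RA <- params$adhesion_distance_factor * RR
  g <- function(d) sqrt(params$C_ccr) * (1 - d / RR) -
    sqrt(params$C_cca) * (1 - d / RA)
  stats::uniroot(g, c(1e-6, RR - 1e-6), tol = 1e-12)$root
}

# Uniform sample in a ball (test geometry helper).
.sampleBallForTest <- function(n, r) {
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  rr <- r * runif(n)^(1 / 3)
  s <- sqrt(1 - z^2)
  cbind(rr * s * cos(phi), rr * s * sin(phi), rr * z)
}

# Small random population helper.
randomPopulation <- function(n, box_lo, box_hi, phase = QUIESCENT) {
  pos <- cbind(runif(n, box_lo[1], box_hi[1]),
               runif(n, box_lo[2], box_hi[2]),
               runif(n, box_lo[3], box_hi[3]))
  vp <- volumeParams()
  V_NS <- vp$V_NS_target[QUIESCENT]
  V_CS <- vp$V_CS_target[QUIESCENT]
  V_F <- vp$f_F / (1 - vp$f_F) * (V_NS + V_CS)
  newCellPopulation(pos, phase = phase, V_F = V_F, V_NS = V_NS, V_CS = V_CS)
}
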