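# Shared fixtures and independent oracles for the test suite. Oracles here
# deliberately avoid the package's computational paths (pseudo-inverse,
# closed-form scans) so that agreement is informative.

# canonical 12-site helix network at the default parameters
fix12 <- local({
  s <- generate_helix(12)
  topo <- build_contacts(s, 12.5)
  H <- build_hessian(s, topo, 1)
  list(s = s, topo = topo, H = H,
       C = covariance_from_hessian(H))
})

# orthonormal rigid-body basis built from scratch (translations + infinitesimal
# rotations about the centroid), for the solve()-based oracles below
oracle_rigid_basis <- function(coords) {
  n <- nrow(coords)
  rc <- sweep(coords, 2L, colMeans(coords))
  gens <- matrix(0, 3L * n, 6L)
  for (ax in 1:3) gens[seq(ax, 3L * n, 3L), ax] <- 1
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  for (ax in 1:3) {
    a <- replace(numeric(3L), ax, 1)
    gens[, 3L + ax] <- as.vector(t(t(apply(rc, 1L, cross, b = -a))))
  }
  qr.Q(qr(gens))
}

# covariance oracle: for K with null space spanned by R (orthonormal),
# K^+ = solve(K + R R^T) - R R^T; independent of eigen-decomposition
oracle_covariance <- function(K, coords, kBT = 1) {
  R <- oracle_rigid_basis(coords)
  RR <- tcrossprod(R)
  kBT * (solve(K + RR) - RR)
}

# energy function of the harmonic contact network, for finite-difference
# Hessian checks
network_energy <- function(r, r0, pairs, k = 1) {
  r <- matrix(r, ncol = 3L, byrow = TRUE)
  d <- sqrt(rowSums((r[pairs[, 1L], , drop = FALSE] -
                       r[pairs[, 2L], , drop = FALSE])^2))
  d0 <- sqrt(rowSums((r0[pairs[, 1L], , drop = FALSE] -
                        r0[pairs[, 2L], , drop = FALSE])^2))
  0.5 * k * sum((d - d0)^2)
}

# brute-force contact enumeration (double loop, strict independence from
# build_contacts)
oracle_contacts <- function(coords, cutoff) {
  n <- nrow(coords)
  out <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (sqrt(sum((coords[i, ] - coords[j, ])^2)) <= cutoff) {
        out <- rbind(out, c(i, j))
      }
    }
  }
  out
}

make_toy_block <- function(nrow_, ncol_, seed) {
  set.seed(seed)
  structure(list(i = 1L, j = 2L,
                 matrix = matrix(rnorm(nrow_ * ncol_), nrow_, ncol_)),
            class = "overlap_block")
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(abs(b))
}
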