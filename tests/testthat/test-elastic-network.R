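# Structure parsing, contact topology, Hessian assembly, covariance and
# linear response.

pdb_multi <- paste(c(
  "HEADER    SYNTHETIC TEST STRUCTURE",
  "MODEL        1",
  "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C",
  "ATOM      3  CA AALA A   2       4.000   5.000   6.000  0.40  0.00           C",
  "ATOM      4  CA BALA A   2       4.500   5.500   6.500  0.60  0.00           C",
  "ATOM      5  CA  GLY B   1       7.000   8.000   9.000  1.00  0.00           C",
  "ATOM      6  CA  GLY B   2      10.000  11.000  12.000  1.00  0.00           C",
  "HETATM    7 CA    CA A 101      20.000  20.000  20.000  1.00  0.00          CA",
  "ENDMDL",
  "MODEL        2",
  "ATOM      1  CA  GLY A   1      -1.000  -2.000  -3.000  1.00  0.00           C",
  "ATOM      2  CA  GLY A   2      -4.000  -5.000  -6.000  1.00  0.00           C",
  "ENDMDL",
  "END"), collapse = "\n")

test_that("parse_ca_structure handles chains, models, altlocs and hetero records", {
  s <- parse_ca_structure(pdb_multi)
  expect_equal(s$n_sites, 4L)  # chains concatenated in file order
  expect_equal(s$site_ids, c("A:1", "A:2", "B:1", "B:2"))
  # altloc B has the higher occupancy
  expect_equal(unname(s$coords[2L, ]), c(4.5, 5.5, 6.5))

  sb <- parse_ca_structure(pdb_multi, chain = "B")
  expect_equal(sb$n_sites, 2L)
  expect_equal(unname(sb$coords[1L, ]), c(7, 8, 9))

  s2 <- parse_ca_structure(pdb_multi, model = 2L)
  expect_equal(unname(s2$coords[1L, ]), c(-1, -2, -3))

  expect_error(parse_ca_structure(pdb_multi, chain = "Z"),
               class = "mrscan_chain_not_found")
  het_only <- "HETATM    1 CA    CA A 101      20.000  20.000  20.000  1.00  0.00          CA"
  expect_error(parse_ca_structure(het_only),
               class = "mrscan_empty_structure")
})

test_that("fixture PDB text round-trips through the parser", {
  s <- generate_helix(5)
  back <- parse_ca_structure(write_fixture_pdb(s))
  expect_equal(back$n_sites, 5L)
  expect_equal(unname(back$coords), unname(round(s$coords, 3L)))
})

test_that("build_contacts matches brute-force enumeration", {
  # unit square, cutoff 1.5: all 6 pairs qualify (diagonal sqrt(2))
  sq <- ca_structure(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)))
  topo <- build_contacts(sq, 1.5)
  expect_equal(nrow(topo$pairs), 6L)
  expect_equal(topo$cn, rep(3L, 4L))
  expect_equal(topo$pairs, oracle_contacts(sq$coords, 1.5),
               ignore_attr = TRUE)

  # collinear chain at 3.8 A spacing: interior sites see 3 partners each way
  chain <- ca_structure(cbind(3.8 * (1:10), 0, 0))
  tc <- build_contacts(chain, 12.5)
  expect_equal(tc$cn[4:7], rep(6L, 4L))
  expect_equal(tc$pairs, oracle_contacts(chain$coords, 12.5),
               ignore_attr = TRUE)

  # helix at the default cutoff agrees with the double loop too
  expect_equal(fix12$topo$pairs, oracle_contacts(fix12$s$coords, 12.5),
               ignore_attr = TRUE)
})

test_that("contact unit vectors are antisymmetric and normalized", {
  topo <- fix12$topo
  for (j in seq_len(topo$n_sites)) {
    ev <- topo$evecs[[j]]
    expect_equal(unname(colSums(ev^2)), rep(1, ncol(ev)))
    for (q in seq_along(topo$neighbors[[j]])) {
      l <- topo$neighbors[[j]][q]
      qq <- match(j, topo$neighbors[[l]])
      expect_equal(unname(ev[, q]), -unname(topo$evecs[[l]][, qq]))
    }
  }
})

test_that("disconnected or isolated networks are rejected", {
  two_far <- ca_structure(rbind(c(0, 0, 0), c(20, 0, 0)))
  expect_error(build_contacts(two_far, 12.5),
               class = "mrscan_disconnected_network")
  # two connected clusters far apart
  clusters <- ca_structure(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0),
                                 c(50, 0, 0), c(53, 0, 0), c(50, 3, 0)))
  expect_error(build_contacts(clusters, 5),
               class = "mrscan_disconnected_network")
})

test_that("contact topology is stable under site permutations", {
  set.seed(42)
  perm <- sample(12L)
  sp <- ca_structure(fix12$s$coords[perm, ])
  tp <- build_contacts(sp, 12.5)
  inv <- order(perm)
  # relabel permuted pairs back and compare as sets
  orig <- apply(fix12$topo$pairs, 1L, function(p)
    paste(sort(p), collapse = "-"))
  relab <- apply(tp$pairs, 1L, function(p)
    paste(sort(perm[p]), collapse = "-"))
  expect_setequal(unname(relab), unname(orig))
  expect_equal(tp$cn, fix12$topo$cn[perm])
})

test_that("Hessian is symmetric, annihilates translations, matches finite differences", {
  K <- fix12$H$matrix
  expect_identical(K, t(K))
  n <- fix12$s$n_sites
  for (ax in 1:3) {
    t_ax <- rep(replace(numeric(3L), ax, 1), n)
    expect_lt(max(abs(K %*% t_ax)), 1e-12)
  }

  # finite-difference oracle on a 2-site system
  s2 <- ca_structure(rbind(c(0, 0, 0), c(2, 1, 2)))
  t2 <- build_contacts(s2, 5)
  K2 <- build_hessian(s2, t2, k = 1)$matrix
  r0 <- as.vector(t(s2$coords))
  h <- 1e-4
  Kfd <- matrix(0, 6L, 6L)
  for (a in 1:6) {
    for (b in 1:6) {
      shift <- function(sa, sb) {
        r <- r0
        r[a] <- r[a] + sa * h
        r[b] <- r[b] + sb * h
        network_energy(r, s2$coords, t2$pairs)
      }
      Kfd[a, b] <- (shift(1, 1) - shift(1, -1) - shift(-1, 1) +
                      shift(-1, -1)) / (4 * h^2)
    }
  }
  expect_lt(max(abs(K2 - Kfd)) / max(abs(K2)), 1e-6)

  expect_error(build_hessian(s2, fix12$topo),
               class = "mrscan_inconsistent_inputs")
})

test_that("Hessian has exactly 6 rigid-body zero modes with a large spectral gap", {
  for (n in c(12L, 20L)) {
    s <- generate_helix(n, jitter = if (n == 20L) 0.2 else 0, seed = 5L)
    topo <- build_contacts(s, 12.5)
    lam <- eigen(build_hessian(s, topo)$matrix, symmetric = TRUE,
                 only.values = TRUE)$values
    lam <- sort(lam)
    tol <- 1e-8 * max(lam)
    expect_equal(sum(lam <= tol), 6L)
    expect_gt(lam[7L] / tol, 1e3)
  }
})

test_that("covariance satisfies the pseudo-inverse identities and the solve oracle", {
  for (n in c(12L, 50L)) {
    s <- if (n == 12L) fix12$s else generate_helix(50L)
    topo <- if (n == 12L) fix12$topo else build_contacts(s, 12.5)
    H <- if (n == 12L) fix12$H else build_hessian(s, topo)
    C <- if (n == 12L) fix12$C else covariance_from_hessian(H)
    K <- H$matrix; Cm <- C$matrix
    fro <- function(m) sqrt(sum(m^2))
    expect_lt(fro(K %*% Cm %*% K - C$kBT * K) / fro(K), 1e-8)
    expect_lt(fro(Cm %*% K %*% Cm - C$kBT * Cm) / fro(Cm), 1e-8)
    expect_identical(Cm, t(Cm))
    # rigid-body null space is annihilated
    R <- oracle_rigid_basis(s$coords)
    expect_lt(max(abs(Cm %*% R)), 1e-8)
    # independent dense-solve oracle
    expect_lt(rel_err(Cm, oracle_covariance(K, s$coords)), 1e-6)
  }
})

test_that("covariance scales as kBT / k and rejects rank-deficient networks", {
  s <- fix12$s; topo <- fix12$topo
  C1 <- covariance_from_hessian(build_hessian(s, topo, k = 1))
  C2 <- covariance_from_hessian(build_hessian(s, topo, k = 2))
  expect_lt(rel_err(C2$matrix, C1$matrix / 2), 1e-10)
  C3 <- covariance_from_hessian(build_hessian(s, topo, k = 1), kBT = 3)
  expect_lt(rel_err(C3$matrix, 3 * C1$matrix), 1e-10)

  chain <- ca_structure(cbind(3.8 * (1:10), 0, 0))
  tc <- build_contacts(chain, 12.5)
  err <- tryCatch(covariance_from_hessian(build_hessian(chain, tc)),
                  mrscan_rank_deficiency = function(e) e)
  expect_s3_class(err, "mrscan_rank_deficiency")
  expect_gt(err$n_zero, 6L)  # message names the count found
})

test_that("linear response is linear and matches constrained minimization", {
  C <- fix12$C
  n3 <- 3L * C$n_sites
  expect_equal(linear_response(C, numeric(n3))$vector, numeric(n3))

  set.seed(7)
  f <- assemble_force_vector(3L, rnorm(fix12$topo$cn[3L]), fix12$topo)
  d1 <- linear_response(C, f)$vector
  expect_equal(linear_response(C, 2.5 * f)$vector, 2.5 * d1)

  # minimizer of (1/2) d' K d - f' d on the non-rigid subspace, by solve()
  K <- fix12$H$matrix
  R <- oracle_rigid_basis(fix12$s$coords)
  RR <- tcrossprod(R)
  x <- solve(K + RR, f)
  d_star <- as.vector(x - RR %*% x)
  expect_lt(max(abs(d1 - d_star)) / max(abs(d_star)), 1e-6)

  expect_equal(site_displacement(linear_response(C, f), 2L),
               d1[4:6])
  expect_error(linear_response(C, numeric(10L)),
               class = "mrscan_inconsistent_inputs")
})
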