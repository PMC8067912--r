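# Double mutation-response scanning: the N x N compensation matrix D, by
# closed formula (aDMRS) and by Monte-Carlo simulation (sDMRS). Both routes
# run through the contact-space overlap blocks A_ij.

#' Contact-space overlap block A_ij
#'
#' The CN(i) x CN(j) bilinear form that expresses the dot product of two
#' mutation deformations in terms of their contact-force scalars:
#' A_{ik,jl} = e_ik^T (C_k - C_i)^T (C_l - C_j) e_jl, with C_x the 3N x 3
#' site column-block of the covariance matrix. For any pair of forces,
#' f(i)^T A_ij f(j) equals delta_r0(i)^T delta_r0(j).
#'
#' @param covariance a [covariance_from_hessian()] result.
#' @param topology matching [build_contacts()] topology.
#' @param i,j site indices (rows of A index contacts of i, columns contacts
#'   of j, in partner-index order).
#' @return An object of class `overlap_block` with fields `i`, `j`,
#'   `matrix`.
#' @export
overlap_block <- function(covariance, topology, i, j) {
  for (x in c(i, j)) {
    if (topology$cn[x] < 1L) {
      mrscan_error("isolated_site", sprintf("site %d has no contacts", x))
    }
  }
  Gi <- contact_response_matrix(covariance, topology, i)
  Gj <- contact_response_matrix(covariance, topology, j)
  structure(list(i = i, j = j, matrix = crossprod(Gi, Gj)),
            class = "overlap_block")
}

#' Maximal squared overlap given the first mutation
#'
#' Closed-form maximum of (f_i^T A_ij f_j)^2 over all second-mutation
#' scalars f_j on the constraint sphere ||f_j||^2 = sigma^2 CN(j):
#' sigma^2 * CN(j) * ||A_ij^T f_i||^2, attained at f_j proportional to
#' A_ij^T f_i (Cauchy-Schwarz equality case).
#'
#' @param f_i contact scalars of the first mutation (length CN(i)).
#' @param block an [overlap_block()] A_ij.
#' @param sigma force scale.
#' @param cn_j contact number of the second site (defaults to
#'   `ncol(block$matrix)`).
#' @return The maximal squared overlap (scalar).
#' @export
max_compensation_given_first <- function(f_i, block, sigma,
                                         cn_j = ncol(block$matrix)) {
  A <- block$matrix
  if (length(f_i) != nrow(A)) {
    mrscan_error("inconsistent_inputs",
                 sprintf("f_i has length %d, block has %d rows",
                         length(f_i), nrow(A)))
  }
  sigma^2 * cn_j * sum(as.vector(crossprod(A, f_i))^2)
}

#' Analytical compensation matrix (aDMRS)
#'
#' Expectation over first mutations (renormalized forces, uniform on the
#' radius sigma*sqrt(CN(i)) sphere) of the maximal squared overlap, under
#' the outer square root of the compensation definition:
#' D_ij = sigma^2 * sqrt( CN(j) * Tr(A_ij A_ij^T) ).
#' The pair loop computes A_ij once per unordered pair and fills the (j,i)
#' entry from the transpose identity A_ji = A_ij^T.
#'
#' @param covariance a [covariance_from_hessian()] result.
#' @param topology matching [build_contacts()] topology.
#' @param sigma force scale (default 0.3).
#' @return A `compensation_matrix` (N x N, class `scan_matrix`), rows =
#'   first-mutated site i, columns = compensating site j.
#' @export
admrs_compensation <- function(covariance, topology, sigma = 0.3) {
  if (covariance$n_sites != topology$n_sites) {
    mrscan_error("inconsistent_inputs",
                 "covariance and topology have different site counts")
  }
  n <- topology$n_sites
  G <- lapply(seq_len(n), function(x)
    contact_response_matrix(covariance, topology, x))
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      tr <- sum(crossprod(G[[i]], G[[j]])^2)  # Frobenius norm^2 of A_ij
      D[i, j] <- sigma^2 * sqrt(topology$cn[j] * tr)
      D[j, i] <- sigma^2 * sqrt(topology$cn[i] * tr)
    }
  }
  new_scan_matrix(D, "compensation_matrix", "admrs", sigma, covariance,
                  topology)
}

#' Simulated compensation matrix (sDMRS)
#'
#' For every site, M renormalized mutation forces are drawn once
#' (site-major, before the pair loop) and reused across all pairs. For a
#' pair (i, j), the overlap of every (mu, nu) force combination is the
#' bilinear form f(i,mu)^T A_ij f(j,nu); its square is maximized over nu
#' and averaged over mu, and D_ij is the square root of that mean.
#' Deterministic given the model seed.
#'
#' @param covariance a [covariance_from_hessian()] result.
#' @param topology matching [build_contacts()] topology.
#' @param model a [force_model()]; the renormalization constraint is always
#'   applied for double scanning, whatever the model flag.
#' @param M mutations per site (default 200).
#' @return A `compensation_matrix` with simulation metadata.
#' @export
sdmrs_compensation <- function(covariance, topology, model = force_model(),
                               M = 200L) {
  if (covariance$n_sites != topology$n_sites) {
    mrscan_error("inconsistent_inputs",
                 "covariance and topology have different site counts")
  }
  if (!is_scalar_number(M) || M < 1) {
    mrscan_error("invalid_parameter", "M must be >= 1")
  }
  M <- as.integer(M)
  n <- topology$n_sites
  rmodel <- force_model(sigma = model$sigma, renormalize = TRUE,
                        seed = model$seed)
  fs <- with_seed(rmodel$seed, {
    lapply(seq_len(n), function(x)
      draw_scalar_matrix(rmodel, x, topology, M))
  })
  G <- lapply(seq_len(n), function(x)
    contact_response_matrix(covariance, topology, x))
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      A <- crossprod(G[[i]], G[[j]])
      P2 <- (crossprod(fs[[i]], A %*% fs[[j]]))^2  # M x M squared overlaps
      # rows index mu at i (max over nu in columns); (j,i) uses t(P2)
      D[i, j] <- sqrt(mean(apply(P2, 1L, max)))
      D[j, i] <- sqrt(mean(apply(P2, 2L, max)))
    }
  }
  new_scan_matrix(D, "compensation_matrix", "sdmrs", rmodel$sigma,
                  covariance, topology, M = M, seed = rmodel$seed)
}

#' Marginal profiles of a compensation matrix
#'
#' Averaging D over rows gives the compensating-power profile D_j (how well
#' mutations at j compensate first mutations elsewhere); averaging over
#' columns gives the compensability profile D_i (how well a first mutation
#' at i can be compensated).
#'
#' @param D an N x N matrix (typically a `compensation_matrix`).
#' @return List of class `marginal_profiles` with vectors `power` (per
#'   column j) and `compensability` (per row i).
#' @export
compensation_profiles <- function(D) {
  p <- marginal_profiles(D)
  structure(list(power = p$influence, compensability = p$sensitivity),
            class = "marginal_profiles")
}
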