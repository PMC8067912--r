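# Mutation-response scanning: the N x N sensitivity matrix S, by closed
# formula (aMRS) and by Monte-Carlo simulation (sMRS).

# 3N x CN(j) matrix whose column for partner l is (C_l - C_j) e_jl:
# the response field per unit scalar force on contact jl.
contact_response_matrix <- function(covariance, topology, j) {
  partners <- topology$neighbors[[j]]
  Cj <- site_columns(covariance, j)
  ev <- topology$evecs[[j]]
  G <- matrix(0, 3L * topology$n_sites, length(partners))
  for (q in seq_along(partners)) {
    G[, q] <- (site_columns(covariance, partners[q]) - Cj) %*% ev[, q]
  }
  G
}

# 3N x CN(j) assembly operator P: f_assembled = P %*% contact_scalars
assembly_operator <- function(site, topology) {
  partners <- topology$neighbors[[site]]
  ev <- topology$evecs[[site]]
  P <- matrix(0, 3L * topology$n_sites, length(partners))
  for (q in seq_along(partners)) {
    P[site_dof(partners[q]), q] <- ev[, q]
  }
  P[site_dof(site), ] <- -ev
  P
}

# collapse a 3N x m matrix of displacements to N x m per-site squared norms
per_site_sq_norms <- function(delta) {
  n <- nrow(delta) / 3L
  sq <- delta^2
  out <- sq[seq(1L, 3L * n, 3L), , drop = FALSE] +
    sq[seq(2L, 3L * n, 3L), , drop = FALSE] +
    sq[seq(3L, 3L * n, 3L), , drop = FALSE]
  out
}

new_scan_matrix <- function(mat, subclass, method, sigma, covariance,
                            topology, M = NA_integer_, seed = NA_integer_) {
  dimnames(mat) <- list(topology$site_ids, topology$site_ids)
  structure(mat,
            meta = list(method = method, sigma = sigma, k = covariance$k,
                        kBT = covariance$kBT, R0 = topology$cutoff,
                        M = M, seed = seed),
            class = c(subclass, "scan_matrix", class(mat)))
}

#' Scan matrix metadata
#'
#' @param x a `scan_matrix` (sensitivity or compensation matrix).
#' @return Named list with `method`, `sigma`, `k`, `kBT`, `R0`, `M`, `seed`.
#' @export
scan_meta <- function(x) attr(x, "meta")

#' @export
print.scan_matrix <- function(x, ...) {
  m <- scan_meta(x)
  cat(sprintf("%s matrix: %d x %d (sigma = %g, k = %g, kBT = %g, R0 = %g%s)\n",
              m$method, nrow(x), ncol(x), m$sigma, m$k, m$kBT, m$R0,
              if (is.na(m$M)) "" else sprintf(", M = %d, seed = %d",
                                              m$M, m$seed)))
  cat(sprintf("  mean %.4g, range [%.4g, %.4g]\n", mean(x), min(x), max(x)))
  invisible(x)
}

#' Analytical sensitivity matrix (aMRS)
#'
#' Closed-form expectation of the mean squared structural response:
#' S_ij = sigma^2 * sum_{jl in C(j)} || (C_il - C_ij) e_jl ||^2,
#' the exact mean of the simulation estimator over i.i.d. N(0, sigma^2)
#' contact forces. Organised over the 3N x 3 site column-blocks of C so each
#' contact's response field is computed once and reused for all response
#' sites.
#'
#' @param covariance a [covariance_from_hessian()] result.
#' @param topology the [build_contacts()] topology of the same structure.
#' @param sigma force scale (default 0.3).
#' @return A `sensitivity_matrix` (N x N, class `scan_matrix`), rows =
#'   response site i, columns = mutated site j.
#' @export
amrs_sensitivity <- function(covariance, topology, sigma = 0.3) {
  if (covariance$n_sites != topology$n_sites) {
    mrscan_error("inconsistent_inputs",
                 "covariance and topology have different site counts")
  }
  n <- topology$n_sites
  S <- matrix(0, n, n)
  for (j in seq_len(n)) {
    G <- contact_response_matrix(covariance, topology, j)
    S[, j] <- sigma^2 * rowSums(per_site_sq_norms(G))
  }
  new_scan_matrix(S, "sensitivity_matrix", "amrs", sigma, covariance,
                  topology)
}

#' Simulated sensitivity matrix (sMRS)
#'
#' For each site j, draws M random mutation forces, assembles the 3N force
#' vectors, computes the responses by linear response with the full
#' covariance matrix, and averages the per-site squared displacements:
#' S_ij = (1/M) sum_mu ||delta_r0_i(j, mu)||^2. Deterministic given the
#' model seed; sites are processed in order so draws are site-major.
#'
#' @param covariance a [covariance_from_hessian()] result.
#' @param topology matching [build_contacts()] topology.
#' @param model a [force_model()] (unrenormalized Gaussian forces).
#' @param M mutations per site (default 200).
#' @return A `sensitivity_matrix` with simulation metadata.
#' @export
smrs_sensitivity <- function(covariance, topology, model = force_model(),
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
  S <- matrix(0, n, n)
  with_seed(model$seed, {
    for (j in seq_len(n)) {
      scalars <- draw_scalar_matrix(model, j, topology, M)
      forces <- assembly_operator(j, topology) %*% scalars
      delta <- linear_response(covariance, forces)
      S[, j] <- rowMeans(per_site_sq_norms(delta))
    }
  })
  new_scan_matrix(S, "sensitivity_matrix", "smrs", model$sigma, covariance,
                  topology, M = M, seed = model$seed)
}

#' Marginal profiles of a sensitivity matrix
#'
#' Averaging S over rows gives the influence profile S_j (mean effect of
#' mutating j on the rest of the structure); averaging over columns gives
#' the sensitivity profile S_i (mean response of i to mutations elsewhere).
#'
#' @param S an N x N matrix (typically a `sensitivity_matrix`).
#' @return List of class `marginal_profiles` with numeric vectors
#'   `influence` (per column j) and `sensitivity` (per row i).
#' @examples
#' marginal_profiles(rbind(c(1, 2), c(3, 4)))
#' @export
marginal_profiles <- function(S) {
  S <- unclass(S)
  if (!is.matrix(S) || nrow(S) != ncol(S)) {
    mrscan_error("inconsistent_inputs", "S must be a square matrix")
  }
  structure(list(influence = colMeans(S), sensitivity = rowMeans(S)),
            class = "marginal_profiles")
}
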