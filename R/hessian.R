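#' Assemble the ANM Hessian
#'
#' Second-derivative matrix of the harmonic network energy
#' V = (1/2) sum_{jl in contacts} k (||r_j - r_l|| - ||r0_j - r0_l||)^2
#' evaluated at the native structure. For each contact jl the 3x3
#' super-element is -k e_jl e_jl^T off-diagonal; diagonal blocks are minus
#' the sum of the site's off-diagonal blocks, so uniform translations are
#' annihilated exactly.
#'
#' @param structure a [ca_structure()].
#' @param topology a [build_contacts()] result for the same structure.
#' @param k spring force constant in energy/Angstrom^2 units (default 1).
#' @return An object of class `anm_hessian` with fields `k`, `matrix`
#'   (3N x 3N symmetric), `n_sites`.
#' @export
build_hessian <- function(structure, topology, k = 1) {
  if (topology$n_sites != structure$n_sites) {
    mrscan_error("inconsistent_inputs",
                 "topology and structure have different site counts")
  }
  if (!is_scalar_number(k) || k <= 0) {
    mrscan_error("invalid_parameter", "k must be a positive number")
  }
  n <- structure$n_sites
  K <- matrix(0, 3L * n, 3L * n)
  for (p in seq_len(nrow(topology$pairs))) {
    j <- topology$pairs[p, 1L]
    l <- topology$pairs[p, 2L]
    e <- structure$coords[l, ] - structure$coords[j, ]
    e <- e / sqrt(sum(e^2))
    blk <- k * tcrossprod(e)
    dj <- site_dof(j); dl <- site_dof(l)
    K[dj, dl] <- K[dj, dl] - blk
    K[dl, dj] <- K[dl, dj] - blk
    K[dj, dj] <- K[dj, dj] + blk
    K[dl, dl] <- K[dl, dl] + blk
  }
  structure(list(k = k, matrix = K, n_sites = n), class = "anm_hessian")
}

#' Covariance matrix from the Hessian pseudo-inverse
#'
#' C = kBT * K^+ where the pseudo-inverse inverts all eigenvalues except the
#' six rigid-body zero modes. Eigenvalues with lambda <= rel_tol * lambda_max
#' are treated as zero; exactly six such modes are required (connected,
#' non-collinear network), otherwise a rank-deficiency error is raised naming
#' the count found. Degenerate geometries (collinear or coincident sites) are
#' rejected by this rank check.
#'
#' @param hessian an [build_hessian()] result.
#' @param kBT thermal energy scale (default 1; see the package vignette on
#'   unit conventions).
#' @param rel_tol relative eigenvalue tolerance for the null space
#'   (default 1e-8).
#' @return An object of class `covariance_matrix` with fields `kBT`,
#'   `matrix` (3N x 3N symmetric), `n_sites`, `n_zero_modes`.
#' @export
covariance_from_hessian <- function(hessian, kBT = 1, rel_tol = 1e-8) {
  if (!is_scalar_number(kBT) || kBT <= 0) {
    mrscan_error("invalid_parameter", "kBT must be a positive number")
  }
  eig <- eigen(hessian$matrix, symmetric = TRUE)
  lam <- eig$values
  thresh <- rel_tol * max(lam)
  zero <- lam <= thresh
  if (sum(zero) != 6L) {
    mrscan_error("rank_deficiency",
                 sprintf("expected 6 rigid-body zero modes, found %d (tolerance %.3g)",
                         sum(zero), thresh),
                 n_zero = sum(zero))
  }
  inv <- ifelse(zero, 0, 1 / lam)
  C <- eig$vectors %*% (inv * t(eig$vectors)) * kBT
  C <- (C + t(C)) / 2
  structure(list(kBT = kBT, matrix = C, n_sites = hessian$n_sites,
                 k = hessian$k, n_zero_modes = 6L),
            class = "covariance_matrix")
}

#' 3x3 site-pair block of the covariance matrix
#'
#' @param covariance a [covariance_from_hessian()] result.
#' @param x,y site indices.
#' @return The 3x3 block C_xy.
#' @export
pair_block <- function(covariance, x, y) {
  covariance$matrix[site_dof(x), site_dof(y)]
}

#' 3N x 3 site column-block of the covariance matrix
#'
#' The three columns of C corresponding to site `x`; stacking the rows of
#' site i gives the pair block C_ix.
#'
#' @param covariance a [covariance_from_hessian()] result.
#' @param x site index.
#' @return The 3N x 3 block C_x.
#' @export
site_columns <- function(covariance, x) {
  covariance$matrix[, site_dof(x), drop = FALSE]
}

#' Linear response to an applied force
#'
#' Linear response approximation: delta_r0 = (C / kBT) f. Accepts a single
#' 3N force vector or a 3N x m matrix of forces in columns.
#'
#' @param covariance a [covariance_from_hessian()] result.
#' @param force numeric vector of length 3N, or a 3N x m matrix.
#' @return For a vector force, a `displacement_field` (fields `vector`,
#'   `n_sites`); for a matrix, a 3N x m matrix of responses.
#' @export
linear_response <- function(covariance, force) {
  n3 <- 3L * covariance$n_sites
  if (is.matrix(force)) {
    if (nrow(force) != n3) {
      mrscan_error("inconsistent_inputs",
                   sprintf("force has %d rows, expected %d", nrow(force), n3))
    }
    return(covariance$matrix %*% force / covariance$kBT)
  }
  if (length(force) != n3) {
    mrscan_error("inconsistent_inputs",
                 sprintf("force has length %d, expected %d",
                         length(force), n3))
  }
  structure(list(vector = as.vector(covariance$matrix %*% force) /
                   covariance$kBT,
                 n_sites = covariance$n_sites),
            class = "displacement_field")
}

#' Per-site displacement of a displacement field
#'
#' @param field a `displacement_field` from [linear_response()].
#' @param i site index.
#' @return Length-3 numeric vector delta_r0_i.
#' @export
site_displacement <- function(field, i) {
  field$vector[site_dof(i)]
}
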