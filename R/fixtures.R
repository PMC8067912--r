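# Deterministic synthetic C-alpha fixtures and brute-force oracles, so every
# algorithmic claim can be tested without downloading structures.

#' Generate a synthetic helical C-alpha trace
#'
#' Site t is placed at (r cos(t theta), r sin(t theta), t * rise). The
#' defaults (rise 1.5 A, radius 2.3 A, turn 100 degrees) give consecutive
#' C-alpha spacings of ~3.8 A, mimicking a protein backbone, so the default
#' 12.5 A cutoff yields a connected, non-collinear contact network with
#' realistic contact densities. Optional seeded Gaussian jitter perturbs the
#' ideal geometry.
#'
#' @param n_sites number of sites (>= 4).
#' @param rise rise per residue in Angstrom.
#' @param radius helix radius in Angstrom.
#' @param turn turn angle per residue in degrees.
#' @param jitter standard deviation of Gaussian coordinate noise in
#'   Angstrom (0 = ideal helix, independent of seed).
#' @param seed RNG seed for the jitter.
#' @return A [ca_structure()].
#' @examples
#' generate_helix(12)
#' @export
generate_helix <- function(n_sites, rise = 1.5, radius = 2.3, turn = 100,
                           jitter = 0, seed = 1L) {
  if (!is_scalar_number(n_sites) || n_sites < 4) {
    mrscan_error("invalid_parameter", "n_sites must be >= 4")
  }
  t <- seq_len(n_sites)
  th <- t * turn * pi / 180
  coords <- cbind(radius * cos(th), radius * sin(th), t * rise)
  if (jitter > 0) {
    coords <- coords + with_seed(seed, {
      matrix(stats::rnorm(3L * n_sites, 0, jitter), ncol = 3L)
    })
  }
  s <- ca_structure(coords)
  # fixtures must support the default analysis cutoff
  ok <- tryCatch({build_contacts(s, 12.5); TRUE},
                 mrscan_disconnected_network = function(e) FALSE)
  if (!ok) {
    mrscan_error("bad_fixture",
                 "generated helix is disconnected at the 12.5 A cutoff; increase radius or reduce rise/jitter")
  }
  s
}

#' Write a structure as minimal PDB text
#'
#' Emits conformant fixed-width ATOM records (atom name CA, residue GLY,
#' chain A, serial numbering), 80 columns per line, such that
#' [parse_ca_structure()] reproduces the coordinates at the 3-decimal
#' precision of the format.
#'
#' @param structure a [ca_structure()].
#' @return A single string of PDB text.
#' @export
write_fixture_pdb <- function(structure) {
  n <- structure$n_sites
  if (n > 9999L) {
    mrscan_error("overflow",
                 "fixed-width PDB residue field overflows beyond 9999 sites")
  }
  lines <- vapply(seq_len(n), function(i) {
    sprintf("ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, i, structure$coords[i, 1L], structure$coords[i, 2L],
            structure$coords[i, 3L], 1, 0, "C")
  }, character(1L))
  paste(c(lines, "END"), collapse = "\n")
}

#' Monte-Carlo expectation oracle for one sensitivity column
#'
#' Plain Monte-Carlo estimate of the expected per-site squared responses to
#' mutations at one site, computed only through [sample_mutation_force()]
#' and [linear_response()] (never through the closed formula): the
#' independent oracle for [amrs_sensitivity()].
#'
#' @param covariance a [covariance_from_hessian()] result.
#' @param topology matching topology.
#' @param sigma force scale.
#' @param site_j mutated site.
#' @param n_samples Monte-Carlo sample count (>= 1000 recommended).
#' @param seed RNG seed.
#' @return List with vectors `mean` (length N, the estimated column of S)
#'   and `se` (standard errors).
#' @export
mc_expectation_oracle <- function(covariance, topology, sigma, site_j,
                                  n_samples = 1e4, seed = 1L) {
  n <- topology$n_sites
  model <- force_model(sigma = max(sigma, .Machine$double.xmin),
                       renormalize = FALSE, seed = seed)
  if (sigma == 0) {
    return(list(mean = numeric(n), se = numeric(n)))
  }
  forces <- with_seed(seed, {
    vapply(seq_len(n_samples), function(mu)
      sample_mutation_force(model, site_j, topology)$assembled,
      numeric(3L * n))
  })
  delta <- linear_response(covariance, forces)
  sq <- per_site_sq_norms(delta)  # N x n_samples
  list(mean = rowMeans(sq),
       se = apply(sq, 1L, stats::sd) / sqrt(n_samples))
}

# quasi-uniform directions on the unit sphere in d dimensions (d <= 3):
# d = 1: both signs; d = 2: uniform angle grid; d = 3: Fibonacci sphere.
unit_directions <- function(d, n_directions) {
  if (d == 1L) return(matrix(c(1, -1), nrow = 1L))
  if (d == 2L) {
    ang <- 2 * pi * (seq_len(n_directions) - 1L) / n_directions
    return(rbind(cos(ang), sin(ang)))
  }
  i <- seq_len(n_directions) - 0.5
  phi <- acos(1 - 2 * i / n_directions)
  theta <- pi * (1 + sqrt(5)) * i
  rbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Dense direction-search oracle for the compensation maximum
#'
#' Brute-force maximum of the squared overlap (f_i^T A f_j)^2 over
#' `n_directions` quasi-uniform points f_j on the constraint sphere of
#' radius sigma*sqrt(CN(j)): the independent oracle for
#' [max_compensation_given_first()]. Feasible only for CN(j) <= 3.
#'
#' @param block an [overlap_block()].
#' @param f_i contact scalars of the first mutation.
#' @param sigma force scale.
#' @param n_directions number of search directions (default 1e4).
#' @return The approximate maximal squared overlap (a lower bound on the
#'   true supremum).
#' @export
max_overlap_oracle <- function(block, f_i, sigma, n_directions = 1e4) {
  A <- block$matrix
  d <- ncol(A)
  if (d > 3L) {
    mrscan_error("oracle_out_of_range",
                 sprintf("dense direction search supports CN(j) <= 3, got %d", d))
  }
  dirs <- unit_directions(d, n_directions) * (sigma * sqrt(d))
  max(as.vector(crossprod(f_i, A %*% dirs))^2)
}
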