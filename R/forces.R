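# Mutations modelled as random forces on the contacts of the mutated site.

#' Force model for mutation scanning
#'
#' A point mutation at site j is modelled by drawing one scalar force f(jl)
#' per contact jl of j, i.i.d. N(0, sigma^2), and applying f(jl) e_jl to the
#' partner l with the reaction -f(jl) e_jl on j. For double scanning the
#' scalars are renormalized onto the sphere sum f(jl)^2 = sigma^2 CN(j) so
#' that the compensation maximum is well defined.
#'
#' @param sigma force scale in 1/Angstrom units (default 0.3).
#' @param renormalize logical; renormalize draws onto the constraint sphere
#'   (default FALSE; double scanning sets TRUE).
#' @param seed integer seed owned by the scan that uses this model.
#' @return An object of class `force_model`.
#' @export
force_model <- function(sigma = 0.3, renormalize = FALSE, seed = 1L) {
  if (!is_scalar_number(sigma) || sigma <= 0) {
    mrscan_error("invalid_parameter", "sigma must be a positive number")
  }
  structure(list(sigma = sigma, renormalize = isTRUE(renormalize),
                 seed = as.integer(seed)),
            class = "force_model")
}

# evaluate expr with a temporarily seeded RNG, restoring the caller's state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw one random mutation force
#'
#' Draws CN(site) contact scalars i.i.d. N(0, sigma^2) from the current RNG
#' state (advance the state by wrapping calls in a seeded scan), renormalizes
#' if the model requires it, and assembles the 3N force vector.
#'
#' @param model a [force_model()].
#' @param site mutated site index.
#' @param topology a [build_contacts()] result.
#' @return An object of class `mutation_force` with fields `site`,
#'   `contact_scalars` (ordered by partner index) and `assembled` (3N
#'   vector).
#' @export
sample_mutation_force <- function(model, site, topology) {
  cn <- topology$cn[site]
  if (is.na(cn) || cn < 1L) {
    mrscan_error("isolated_site",
                 sprintf("site %d has no contacts", site))
  }
  scalars <- stats::rnorm(cn, mean = 0, sd = model$sigma)
  force <- structure(list(site = site, contact_scalars = scalars,
                          assembled = assemble_force_vector(site, scalars,
                                                            topology)),
                     class = "mutation_force")
  if (model$renormalize) force <- renormalize_force(force, model$sigma,
                                                    topology)
  force
}

#' Renormalize a mutation force onto the constraint sphere
#'
#' Rescales the contact scalars so that sum f(jl)^2 = sigma^2 CN(site)
#' exactly, leaving their ratios unchanged, and rebuilds the assembled
#' vector. The constraint applies to the CN(site)-vector of contact scalars,
#' not to the assembled 3N vector.
#'
#' @param force a `mutation_force`.
#' @param sigma force scale.
#' @param topology the topology the force was drawn on.
#' @return The renormalized `mutation_force`.
#' @export
renormalize_force <- function(force, sigma, topology) {
  nrm <- sqrt(sum(force$contact_scalars^2))
  if (nrm == 0) {
    mrscan_error("all_zero_force",
                 "all-zero force draw cannot be renormalized; redraw")
  }
  target <- sigma * sqrt(length(force$contact_scalars))
  scalars <- force$contact_scalars * (target / nrm)
  structure(list(site = force$site, contact_scalars = scalars,
                 assembled = assemble_force_vector(force$site, scalars,
                                                   topology)),
            class = "mutation_force")
}

#' Assemble the 3N force vector of a mutation
#'
#' For each contact jl of the mutated site, adds f(jl) e_jl at the partner l
#' and the reaction -f(jl) e_jl at the site itself; all other entries are
#' zero, so the net force vanishes by construction.
#'
#' @param site mutated site index.
#' @param contact_scalars numeric vector of length CN(site), ordered by
#'   partner index.
#' @param topology a [build_contacts()] result.
#' @return Numeric vector of length 3N.
#' @export
assemble_force_vector <- function(site, contact_scalars, topology) {
  partners <- topology$neighbors[[site]]
  if (length(contact_scalars) != length(partners)) {
    mrscan_error("inconsistent_inputs",
                 sprintf("expected %d contact scalars for site %d, got %d",
                         length(partners), site, length(contact_scalars)))
  }
  f <- numeric(3L * topology$n_sites)
  ev <- topology$evecs[[site]]  # 3 x CN, columns e_{site,partner}
  for (q in seq_along(partners)) {
    contrib <- contact_scalars[q] * ev[, q]
    dl <- site_dof(partners[q])
    f[dl] <- f[dl] + contrib
  }
  f[site_dof(site)] <- -ev %*% contact_scalars
  f
}

# CN(x) x M matrix of contact scalars for one site, drawn from the current
# RNG state; columns are mutations. Renormalized columns lie on the sphere
# of radius sigma*sqrt(CN).
draw_scalar_matrix <- function(model, site, topology, M) {
  cn <- topology$cn[site]
  s <- matrix(stats::rnorm(cn * M, 0, model$sigma), nrow = cn, ncol = M)
  if (model$renormalize) {
    nrm <- sqrt(colSums(s^2))
    bad <- nrm == 0
    while (any(bad)) {  # probability-zero guard: redraw degenerate columns
      s[, bad] <- stats::rnorm(cn * sum(bad), 0, model$sigma)
      nrm <- sqrt(colSums(s^2))
      bad <- nrm == 0
    }
    s <- sweep(s, 2L, model$sigma * sqrt(cn) / nrm, "*")
  }
  s
}
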