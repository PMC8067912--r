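#' Build the ANM contact topology
#'
#' All pairs of sites whose C-alpha distance is at most `cutoff` are contacts.
#' For every site the partner list (sorted by partner index), the unit vectors
#' e_jl pointing from the site toward each partner, and the contact number
#' CN are stored. The contact graph must be connected with no isolated site:
#' the Hessian pseudo-inverse downstream assumes exactly six rigid-body zero
#' modes, which requires connectivity.
#'
#' @param structure a [ca_structure()].
#' @param cutoff contact cutoff R0 in Angstrom (default 12.5).
#' @return An object of class `contact_topology` with fields:
#'   `cutoff`, `pairs` (m x 2 matrix, first column < second),
#'   `neighbors` (list of sorted partner indices per site),
#'   `evecs` (list of 3 x CN matrices of unit vectors, columns matching
#'   `neighbors`), `cn` (integer contact counts), `n_sites`.
#' @examples
#' topo <- build_contacts(generate_helix(12), cutoff = 12.5)
#' topo$cn
#' @export
build_contacts <- function(structure, cutoff = 12.5) {
  if (!is_scalar_number(cutoff) || cutoff <= 0) {
    mrscan_error("invalid_parameter", "cutoff must be a positive number")
  }
  n <- structure$n_sites
  d <- as.matrix(stats::dist(structure$coords))
  adj <- d <= cutoff & upper.tri(d)
  pairs <- which(adj, arr.ind = TRUE)
  pairs <- cbind(pairs[, 1L], pairs[, 2L])[order(pairs[, 1L], pairs[, 2L]), ,
                                           drop = FALSE]
  amat <- matrix(FALSE, n, n)
  amat[pairs] <- TRUE
  amat <- amat | t(amat)
  cn <- as.integer(rowSums(amat))
  if (any(cn == 0L)) {
    mrscan_error("disconnected_network",
                 sprintf("isolated site(s) at cutoff %.3g: %s", cutoff,
                         paste(which(cn == 0L), collapse = ", ")),
                 sites = which(cn == 0L))
  }
  # connectivity by breadth-first search over the adjacency matrix
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0L) {
    nb <- which(amat[queue[1L], ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue[-1L], nb)
  }
  if (!all(seen)) {
    mrscan_error("disconnected_network",
                 sprintf("contact graph disconnected at cutoff %.3g (%d of %d sites reachable)",
                         cutoff, sum(seen), n))
  }
  neighbors <- lapply(seq_len(n), function(j) which(amat[j, ]))
  evecs <- lapply(seq_len(n), function(j) {
    e <- t(structure$coords[neighbors[[j]], , drop = FALSE]) -
      structure$coords[j, ]
    sweep(e, 2L, sqrt(colSums(e^2)), "/")
  })
  structure(list(cutoff = cutoff, pairs = pairs, neighbors = neighbors,
                 evecs = evecs, cn = cn, n_sites = n,
                 site_ids = structure$site_ids),
            class = "contact_topology")
}

#' @export
print.contact_topology <- function(x, ...) {
  cat(sprintf("ANM contact topology: %d sites, %d contacts, cutoff %.3g A, CN in [%d, %d]\n",
              x$n_sites, nrow(x$pairs), x$cutoff, min(x$cn), max(x$cn)))
  invisible(x)
}
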