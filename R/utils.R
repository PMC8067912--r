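# Internal helpers: classed conditions and small numeric utilities.

mrscan_error <- function(class, message, ...) {
  stop(structure(
    class = c(paste0("mrscan_", class), "mrscan_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# 3N index range of site i (sites are 1-based, coordinates x,y,z contiguous)
site_dof <- function(i) {
  c(3L * i - 2L, 3L * i - 1L, 3L * i)
}

# Orthonormal basis of the rigid-body space (3 translations + 3 rotations
# about the centroid). For collinear structures the rotation about the axis
# degenerates; qr() handles the rank drop and callers check mode counts.
rigid_body_basis <- function(coords) {
  n <- nrow(coords)
  cen <- colMeans(coords)
  rc <- sweep(coords, 2L, cen)
  basis <- matrix(0, nrow = 3L * n, ncol = 6L)
  for (ax in 1:3) basis[seq(ax, 3L * n, by = 3L), ax] <- 1
  # infinitesimal rotations: delta_i = a x (r_i - centroid)
  for (ax in 1:3) {
    a <- c(0, 0, 0); a[ax] <- 1
    rot <- t(apply(rc, 1L, function(r) c(a[2] * r[3] - a[3] * r[2],
                                         a[3] * r[1] - a[1] * r[3],
                                         a[1] * r[2] - a[2] * r[1])))
    basis[, 3L + ax] <- as.vector(t(rot))
  }
  q <- qr(basis)
  qr.Q(q)[, seq_len(q$rank), drop = FALSE]
}
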