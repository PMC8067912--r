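# Comparison diagnostics between simulated and analytical scan matrices:
# mean-one normalization, log-scale Pearson correlation, convergence curves.

#' Normalize a matrix to grand mean one
#'
#' Divides every entry by the grand mean, so the output mean is exactly 1.
#' This is the normalization applied before all matrix and profile
#' comparisons, making them invariant to the sigma^2/k^2 scale factor.
#'
#' @param m numeric matrix (or vector) with positive mean.
#' @return The rescaled object, same shape.
#' @export
normalize_mean_one <- function(m) {
  g <- mean(m)
  if (!is.finite(g) || g <= 0) {
    mrscan_error("non_normalizable",
                 sprintf("grand mean %.3g is not positive", g))
  }
  m / g
}

#' Pearson correlation of log-transformed, mean-normalized values
#'
#' Both inputs are normalized to mean one, log-transformed (natural log) and
#' correlated elementwise. Nonpositive entries cannot be logged: such pairs
#' are excluded, their count recorded, and a warning issued when more than
#' 1% of pairs are dropped. By positive-scale invariance of the Pearson
#' correlation of logs, the result does not depend on the scale of either
#' input.
#'
#' @param a,b numeric matrices or vectors of identical shape.
#' @param exclude_diagonal logical; for square matrices, drop the diagonal
#'   before correlating (default FALSE).
#' @return The correlation, with attributes `n_excluded` (pairs dropped for
#'   nonpositivity) and `n_used`.
#' @export
log_pearson <- function(a, b, exclude_diagonal = FALSE) {
  a <- unclass(a); b <- unclass(b)
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b))) {
    mrscan_error("inconsistent_inputs", "inputs must have identical shape")
  }
  if (exclude_diagonal && is.matrix(a) && nrow(a) == ncol(a)) {
    off <- row(a) != col(a)
    a <- a[off]; b <- b[off]
  }
  a <- as.vector(normalize_mean_one(a))
  b <- as.vector(normalize_mean_one(b))
  ok <- a > 0 & b > 0
  n_excl <- sum(!ok)
  if (n_excl > 0.01 * length(ok)) {
    warning(sprintf("log_pearson: %d of %d pairs nonpositive and excluded",
                    n_excl, length(ok)))
  }
  r <- stats::cor(log(a[ok]), log(b[ok]))
  structure(r, n_excluded = n_excl, n_used = sum(ok))
}

#' Comparison report between a simulated and an analytical scan matrix
#'
#' Log-scale Pearson correlations of the mean-normalized matrices and of
#' their row/column marginal profiles.
#'
#' @param simulated,analytical N x N matrices.
#' @param exclude_diagonal drop the diagonal from the matrix correlation.
#' @return List of class `comparison_report`: `R_matrix`, `R_col_profile`
#'   (influence / D_j), `R_row_profile` (sensitivity / D_i), `n_excluded`.
#' @export
comparison_report <- function(simulated, analytical,
                              exclude_diagonal = FALSE) {
  rm_ <- log_pearson(simulated, analytical,
                     exclude_diagonal = exclude_diagonal)
  ps <- marginal_profiles(simulated)
  pa <- marginal_profiles(analytical)
  structure(list(R_matrix = as.numeric(rm_),
                 R_col_profile = as.numeric(log_pearson(ps$influence,
                                                        pa$influence)),
                 R_row_profile = as.numeric(log_pearson(ps$sensitivity,
                                                        pa$sensitivity)),
                 n_excluded = attr(rm_, "n_excluded")),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("R (matrix) = %.2f, R (column profile) = %.2f, R (row profile) = %.2f\n",
              x$R_matrix, x$R_col_profile, x$R_row_profile))
  if (x$n_excluded > 0) {
    cat(sprintf("  %d nonpositive pairs excluded from the matrix correlation\n",
                x$n_excluded))
  }
  invisible(x)
}

#' Convergence of a simulation method toward its analytical counterpart
#'
#' For each number of mutations per site M in `M_grid` and each seed, runs
#' `simulator(M, seed)` and records the log-scale Pearson correlations with
#' the analytical matrix and its marginal profiles.
#'
#' @param analytical N x N analytical scan matrix.
#' @param simulator function of `(M, seed)` returning an N x N matrix.
#' @param M_grid increasing integer vector of mutation counts.
#' @param seeds integer vector of seeds (one replicate per seed).
#' @param method label recorded in the output (default "scan").
#' @return A data.frame with columns `method`, `M`, `seed`, `R_matrix`,
#'   `R_row_profile`, `R_col_profile`, sorted by (method, M, seed).
#' @export
convergence_curve <- function(analytical, simulator, M_grid, seeds = 1L,
                              method = "scan") {
  if (length(M_grid) == 0L || is.unsorted(M_grid, strictly = TRUE)) {
    mrscan_error("invalid_parameter",
                 "M_grid must be non-empty and strictly increasing")
  }
  rows <- list()
  for (M in sort(M_grid)) {
    for (seed in sort(seeds)) {
      rep <- comparison_report(simulator(M, seed), analytical)
      rows[[length(rows) + 1L]] <-
        data.frame(method = method, M = M, seed = seed,
                   R_matrix = rep$R_matrix,
                   R_row_profile = rep$R_row_profile,
                   R_col_profile = rep$R_col_profile)
    }
  }
  do.call(rbind, rows)
}
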