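#' Nearest correlation matrix (alternating projections)
#'
#' Projects a symmetric matrix onto the set of correlation matrices
#' (symmetric positive semi-definite, unit diagonal) by Higham's
#' alternating-projection algorithm with Dykstra correction.
#'
#' @param m Symmetric matrix.
#' @param tol Convergence tolerance on the max-norm change per sweep
#'   (default 1e-8).
#' @param max_iter Maximum sweeps (default 200).
#' @return The nearest correlation matrix.
#' @export
nearest_correlation <- function(m, tol = 1e-8, max_iter = 200L) {
  if (!isSymmetric(unname(m), tol = 1e-10)) {
    stop_restconn("input must be symmetric")
  }
  n <- nrow(m)
  y <- m
  ds <- matrix(0, n, n)
  for (iter in seq_len(max_iter)) {
    r <- y - ds
    eig <- eigen(r, symmetric = TRUE)
    x <- eig$vectors %*% (pmax(eig$values, 0) * t(eig$vectors))
    x <- (x + t(x)) / 2
    ds <- x - r
    y_new <- x
    diag(y_new) <- 1
    delta <- max(abs(y_new - y))
    y <- y_new
    if (delta < tol) {
      # final clean-up: clip residual negative eigenvalues, restore the
      # unit diagonal exactly
      eig <- eigen(y, symmetric = TRUE)
      if (min(eig$values) < -sqrt(tol)) break
      y <- eig$vectors %*% (pmax(eig$values, 0) * t(eig$vectors))
      y <- stats::cov2cor((y + t(y)) / 2)
      return((y + t(y)) / 2)
    }
  }
  stop_restconn("nearest-correlation projection did not converge",
                class = "restconn_psd_error")
}

# Internal: random correlation matrix with orthogonal eigenvectors and
# gamma-normalised (Dirichlet) eigenvalues summing to n.  shape controls
# how close the matrix is to the identity (larger = weaker correlations).
random_correlation <- function(n_rois, shape = 5, seed = 1L) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(n_rois^2), n_rois)))
  lam <- rgamma(n_rois, shape = shape)
  lam <- lam / sum(lam) * n_rois
  s <- q %*% (lam * t(q))
  r <- stats::cov2cor((s + t(s)) / 2)
  (r + t(r)) / 2
}

#' Build group correlation matrices with injected edge effects
#'
#' Starts from one shared random correlation matrix, offsets the listed
#' edges in Fisher-z space symmetrically (+delta_z/2 for group A,
#' -delta_z/2 for group B), and projects each matrix back to the nearest
#' valid correlation matrix. The realised z-difference at each effect
#' edge is checked against `delta_tol`.
#'
#' @param config A [sim_config()].
#' @param delta_tol Allowed deviation of the realised z-difference from
#'   the requested `delta_z` after projection (default 0.05).
#' @return A list with elements `corr_a`, `corr_b` (correlation matrices)
#'   and `ground_truth` (list with the base matrix, effect edges with
#'   realised deltas, and the score edge).
#' @export
build_group_covariances <- function(config, delta_tol = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_rois
  base <- random_correlation(n, seed = child_seed(config$seed, "basecorr"))
  z <- atanh(base)
  diag(z) <- 0
  za <- z
  zb <- z
  ee <- config$effect_edges
  if (!is.null(ee) && nrow(ee) > 0) {
    for (k in seq_len(nrow(ee))) {
      i <- ee$roi_i[k]; j <- ee$roi_j[k]; d <- ee$delta_z[k]
      za[i, j] <- za[j, i] <- z[i, j] + d / 2
      zb[i, j] <- zb[j, i] <- z[i, j] - d / 2
    }
    ra <- tanh(za); diag(ra) <- 1
    rb <- tanh(zb); diag(rb) <- 1
    corr_a <- nearest_correlation(ra)
    corr_b <- nearest_correlation(rb)
    realised <- vapply(seq_len(nrow(ee)), function(k) {
      i <- ee$roi_i[k]; j <- ee$roi_j[k]
      atanh(corr_a[i, j]) - atanh(corr_b[i, j])
    }, numeric(1))
    if (any(abs(realised - ee$delta_z) > delta_tol)) {
      stop_restconn("PSD projection moved an effect edge outside tolerance",
                    class = "restconn_psd_error")
    }
    ee$realised_delta_z <- realised
  } else {
    corr_a <- base
    corr_b <- base
  }
  ground_truth <- list(
    base_correlation = base,
    effect_edges = ee,
    score_edge = config$score_edge
  )
  list(corr_a = corr_a, corr_b = corr_b, ground_truth = ground_truth)
}
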