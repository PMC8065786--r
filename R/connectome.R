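#' Representative ROI time series by first principal component
#'
#' Returns the first principal-component score series of the
#' column-centred (per-voxel demeaned) voxel matrix of one ROI, scaled
#' to unit variance. The PC sign is indeterminate, so it is fixed by
#' requiring a non-negative Pearson correlation with the ROI mean
#' series, making connectivity signs reproducible.
#'
#' @param voxel_signals `voxels x T` matrix for one ROI (>= 2 voxels,
#'   >= 3 volumes).
#' @return Length-`T` numeric vector with unit variance.
#' @export
extract_roi_representative <- function(voxel_signals) {
  x <- as.matrix(voxel_signals)
  if (nrow(x) < 2 || ncol(x) < 3) {
    stop_restconn("need >= 2 voxels and >= 3 volumes")
  }
  if (all(x == 0)) stop_restconn("all-zero ROI")
  xc <- x - rowMeans(x)
  sv <- svd(t(xc), nu = 1, nv = 0)
  pc1 <- sv$u[, 1] * sv$d[1]
  if (stats::sd(pc1) == 0) stop_restconn("degenerate ROI: constant PC1")
  roi_mean <- colMeans(x)
  if (stats::sd(roi_mean) > 0 && stats::cor(pc1, roi_mean) < 0) pc1 <- -pc1
  as.numeric(scale(pc1))
}

#' Pairwise Pearson connectivity over ROIs
#'
#' @param roi_series `n_rois x T` matrix of representative series (rows
#'   are ROIs).
#' @param parcellation Optional parcellation tibble used to label the
#'   matrix dimnames.
#' @param id Optional participant identifier carried in the result.
#' @return An object of class `connectivity_matrix`: list with `r`
#'   (symmetric correlation matrix, unit diagonal), `z` (Fisher
#'   transform, `NA` diagonal), `id`.
#' @export
pairwise_connectivity <- function(roi_series, parcellation = NULL, id = NULL) {
  x <- as.matrix(roi_series)
  v <- apply(x, 1, stats::var)
  if (any(v == 0 | !is.finite(v))) {
    bad <- which(v == 0 | !is.finite(v))
    stop_restconn(sprintf("zero-variance ROI series: %s",
                          paste(head(bad, 5), collapse = ", ")))
  }
  r <- stats::cor(t(x))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  if (!is.null(parcellation)) {
    dimnames(r) <- list(parcellation$abbrev, parcellation$abbrev)
  }
  off <- r[row(r) != col(r)]
  if (any(abs(off) >= 1 - 1e-12)) {
    warn("perfectly correlated ROI pair: Fisher z not computed")
    z <- NULL
  } else {
    z <- fisher_transform(r)
  }
  structure(list(r = r, z = z, id = id), class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d x %d%s\n", nrow(x$r), ncol(x$r),
              if (!is.null(x$id)) paste0(" (", x$id, ")") else ""))
  invisible(x)
}

#' Fisher r-to-z transform of a correlation matrix
#'
#' `z = atanh(r)` applied off-diagonal; the diagonal is stored as `NA`
#' (a correlation of a region with itself carries no information and
#' must not leak into edge features).
#'
#' @param r_matrix Symmetric correlation matrix.
#' @return Symmetric matrix of z values with `NA` diagonal.
#' @export
fisher_transform <- function(r_matrix) {
  r <- as.matrix(r_matrix)
  off <- abs(r[row(r) != col(r)])
  if (any(off >= 1)) {
    idx <- which(abs(r) >= 1 & row(r) != col(r), arr.ind = TRUE)[1, ]
    stop_restconn(sprintf(
      "|r| = 1 at ROI pair (%d, %d): Fisher z undefined", idx[1], idx[2]))
  }
  z <- atanh(r)
  diag(z) <- NA_real_
  z
}

#' Flatten the upper triangle of an edge matrix (row-major)
#'
#' Edge order is (1,2), (1,3), ..., (1,n), (2,3), ...; for 112 ROIs the
#' vector has length 6216. [edge_devectorize()] inverts the operation.
#'
#' @param m Symmetric matrix.
#' @return Numeric vector of length `n(n-1)/2`.
#' @export
edge_vectorize <- function(m) {
  m <- as.matrix(m)
  t(m)[lower.tri(m)]
}

#' @rdname edge_vectorize
#' @param v Edge vector of length `n(n-1)/2`.
#' @param diag_value Value placed on the diagonal (default `NA`).
#' @return `edge_devectorize()`: the symmetric `n x n` matrix.
#' @export
edge_devectorize <- function(v, diag_value = NA_real_) {
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (n != round(n)) stop_restconn("vector length is not n(n-1)/2")
  n <- as.integer(n)
  tm <- matrix(diag_value, n, n)
  tm[lower.tri(tm)] <- v      # column-major lower of t(m) = row-major upper
  m <- t(tm)
  m[lower.tri(m)] <- tm[lower.tri(tm)]
  m
}

#' Stack per-participant edge vectors into a feature matrix
#'
#' @param preproc A `restconn_preproc` (see [preprocess_cohort()]), or a
#'   named list of ROI x T matrices together with `participants`.
#' @param participants Participants tibble (`id`, `group`); taken from
#'   `preproc` when available.
#' @param parcellation Optional parcellation for labelling.
#' @return A list of class `edge_features`: `z` (subjects x E matrix of
#'   Fisher-z edge values, rownames = participant ids), `r` (same for
#'   raw correlations), `edges` (edge index tibble), `participants`.
#' @export
connectivity_features <- function(preproc, participants = NULL,
                                  parcellation = NULL) {
  if (inherits(preproc, "restconn_preproc")) {
    series <- preproc$clean
    participants <- participants %||% preproc$participants
  } else {
    series <- preproc
    if (is.null(participants)) stop_restconn("participants required")
  }
  n_rois <- nrow(series[[1]])
  edges <- edge_index_table(n_rois, parcellation)
  mats <- lapply(participants$id, function(id) {
    pairwise_connectivity(series[[id]], parcellation, id = id)
  })
  zmat <- do.call(rbind, lapply(mats, function(m) edge_vectorize(m$z)))
  rmat <- do.call(rbind, lapply(mats, function(m) edge_vectorize(m$r)))
  rownames(zmat) <- rownames(rmat) <- participants$id
  structure(list(z = zmat, r = rmat, edges = edges,
                 participants = participants,
                 matrices = mats),
            class = "edge_features")
}

#' @export
print.edge_features <- function(x, ...) {
  cat(sprintf("<edge_features> %d participants x %d edges\n",
              nrow(x$z), ncol(x$z)))
  invisible(x)
}

#' Heatmap of a connectivity matrix
#'
#' @param object A `connectivity_matrix`.
#' @param what `"r"` or `"z"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.connectivity_matrix <- function(object, what = c("r", "z"), ...) {
  what <- match.arg(what)
  m <- object[[what]]
  df <- tibble(
    roi_a = rep(seq_len(nrow(m)), times = ncol(m)),
    roi_b = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$roi_a, .data$roi_b,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  na.value = "grey85") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "ROI", y = "ROI", fill = what,
                  title = object$id %||% "connectivity")
}
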