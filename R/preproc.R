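#' Frame-wise displacement from rigid-body realignment parameters
#'
#' FD at volume t is the sum of absolute backward differences of the six
#' realignment parameters, with rotations (radians) converted to arc
#' length on a sphere of radius `rotation_radius_mm` (Power convention):
#' `FD[t] = sum |d trans| + radius * sum |d rot|`, and `FD[1] = 0`.
#'
#' @param motion `T x 6` matrix or data frame: translations x, y, z in
#'   mm then rotations in radians.
#' @param rotation_radius_mm Sphere radius for the rotation-to-mm
#'   conversion (default 50).
#' @param threshold_mm Threshold used to count supra-threshold volumes
#'   (default 0.5).
#' @param initial_drop Leading volumes ignored by the supra-threshold
#'   count (default 4); the FD series itself always covers all volumes.
#' @return A tibble with columns `volume`, `fd`, plus attributes
#'   `threshold_mm` and `supra_threshold_count` (count of `fd >
#'   threshold` among volumes after `initial_drop`).
#' @export
#' @examples
#' m <- matrix(0, 10, 6)
#' m[5, 1:3] <- 0.1; m[5, 4:6] <- 0.001
#' compute_framewise_displacement(m)$fd[5] # 0.45
compute_framewise_displacement <- function(motion, rotation_radius_mm = 50,
                                           threshold_mm = 0.5,
                                           initial_drop = 4L) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6 || nrow(motion) < 2) {
    stop_restconn("motion must be a T x 6 matrix with T >= 2")
  }
  bad <- which(!stats::complete.cases(motion) |
                 rowSums(!is.finite(motion)) > 0)
  if (length(bad)) {
    stop_restconn(sprintf("non-finite motion parameters at volume(s) %s",
                          paste(head(bad, 5), collapse = ", ")))
  }
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            rotation_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  keep <- seq_len(nrow(motion)) > initial_drop
  out <- tibble(volume = seq_len(nrow(motion)), fd = fd)
  attr(out, "threshold_mm") <- threshold_mm
  attr(out, "supra_threshold_count") <- sum(fd[keep] > threshold_mm)
  attr(out, "initial_drop") <- as.integer(initial_drop)
  class(out) <- c("restconn_fd", class(out))
  out
}

#' Plan cohort-uniform volume trimming
#'
#' All participants share the same raw volume count; after dropping the
#' first `initial_drop` volumes, the participant with the most
#' supra-threshold FD volumes sets the cohort-wide removal count. Each
#' participant loses all of their supra-threshold volumes; participants
#' with fewer flagged volumes additionally lose their highest-FD
#' remaining volumes (ties broken by later volume first) until every
#' participant retains the same number of volumes.
#'
#' @param fd_list List of FD tibbles from
#'   [compute_framewise_displacement()] (one per participant).
#' @param threshold_mm FD threshold in mm (default 0.5).
#' @param initial_drop Leading volumes removed for signal equilibration
#'   (default 4).
#' @return An object of class `trim_plan`: list with `removal_count`,
#'   `retained_volume_count`, `initial_drop`, and `kept` (list of
#'   strictly increasing volume indices per participant).
#' @export
plan_uniform_trimming <- function(fd_list, threshold_mm = 0.5,
                                  initial_drop = 4L) {
  stopifnot(length(fd_list) >= 1)
  tt <- unique(vapply(fd_list, nrow, integer(1)))
  if (length(tt) != 1) {
    stop_restconn("all participants must share the same raw volume count")
  }
  candidates <- (initial_drop + 1L):tt
  flagged <- lapply(fd_list, function(f) {
    candidates[f$fd[candidates] > threshold_mm]
  })
  removal_count <- max(vapply(flagged, length, integer(1)))
  retained <- tt - initial_drop - removal_count
  if (retained <= 0) {
    stop_restconn("trimming would remove every volume")
  }
  kept <- lapply(seq_along(fd_list), function(p) {
    drop_idx <- flagged[[p]]
    extra_needed <- removal_count - length(drop_idx)
    if (extra_needed > 0) {
      remaining <- setdiff(candidates, drop_idx)
      fdv <- fd_list[[p]]$fd[remaining]
      # highest FD first; ties broken by later volume index first
      ord <- order(-fdv, -remaining)
      drop_idx <- c(drop_idx, remaining[ord[seq_len(extra_needed)]])
    }
    sort(setdiff(candidates, drop_idx))
  })
  names(kept) <- names(fd_list)
  structure(list(removal_count = removal_count,
                 retained_volume_count = retained,
                 initial_drop = as.integer(initial_drop),
                 threshold_mm = threshold_mm,
                 kept = kept),
            class = "trim_plan")
}

#' @export
print.trim_plan <- function(x, ...) {
  cat(sprintf("<trim_plan> drop first %d + %d censored -> %d volumes retained (%d participants)\n",
              x$initial_drop, x$removal_count, x$retained_volume_count,
              length(x$kept)))
  invisible(x)
}

#' @rdname plan_uniform_trimming
#' @param x A `trim_plan`.
#' @param ... Unused.
#' @export
tidy.trim_plan <- function(x, ...) {
  tibble(participant = names(x$kept) %||% as.character(seq_along(x$kept)),
         n_kept = vapply(x$kept, length, integer(1)),
         n_removed = x$removal_count)
}

#' Apply a trimming plan to a signals-by-time matrix
#'
#' @param signals Matrix with volumes as columns.
#' @param plan A `trim_plan`.
#' @param participant Participant name or position within the plan.
#' @return The matrix restricted to kept volumes.
#' @export
apply_trimming <- function(signals, plan, participant = 1L) {
  kept <- plan$kept[[participant]]
  if (is.null(kept)) stop_restconn("participant not found in trim plan")
  signals[, kept, drop = FALSE]
}

#' Extract top principal-component series from tissue voxel signals
#'
#' Implements the anatomical CompCor step: after removing each voxel's
#' mean, the top `k` principal-component time series of the voxel bank
#' are returned with unit variance, ordered by explained variance.
#'
#' @param tissue_voxel_signals `voxels x T` matrix.
#' @param k Number of components (default 5). Must not exceed the rank
#'   of the centred matrix.
#' @return `T x k` matrix of unit-variance component series.
#' @export
extract_nuisance_components <- function(tissue_voxel_signals, k = 5L) {
  x <- as.matrix(tissue_voxel_signals)
  k <- check_count(k, "k", 1L)
  xc <- x - rowMeans(x)
  sv <- svd(t(xc), nu = min(dim(xc)), nv = 0)
  rank <- sum(sv$d > max(dim(xc)) * max(sv$d) * .Machine$double.eps)
  if (k > rank) {
    stop_restconn(sprintf("requested %d components but matrix rank is %d",
                          k, rank))
  }
  comp <- sv$u[, seq_len(k), drop = FALSE] *
    rep(sv$d[seq_len(k)], each = ncol(x))
  scale(comp)[, , drop = FALSE]
}

#' Build the nuisance regression design matrix
#'
#' Columns: intercept, linear trend, `k` WM components, `k` CSF
#' components, and the six linearly detrended motion parameters.
#'
#' @param wm_components,csf_components `T x k` component matrices (see
#'   [extract_nuisance_components()]).
#' @param motion `T x 6` realignment parameter matrix (already trimmed
#'   to the retained volumes).
#' @return A `T x (2 + 2k + 6)` design matrix with named columns.
#' @export
build_nuisance_design <- function(wm_components, csf_components, motion) {
  tt <- nrow(motion)
  if (nrow(wm_components) != tt || nrow(csf_components) != tt) {
    stop_restconn("component series and motion must cover the same volumes")
  }
  trend <- seq(-1, 1, length.out = tt)
  mot <- apply(as.matrix(motion), 2, function(col) {
    residuals(lm(col ~ trend))
  })
  design <- cbind(intercept = 1, trend = trend,
                  wm = wm_components, csf = csf_components, motion = mot)
  colnames(design) <- c("intercept", "trend",
                        paste0("wm_pc", seq_len(ncol(wm_components))),
                        paste0("csf_pc", seq_len(ncol(csf_components))),
                        paste0("motion", 1:6))
  design
}

#' Regress nuisance signals out of ROI or voxel time series
#'
#' Ordinary least-squares residualisation of each signal row on the
#' design matrix. Residuals are orthogonal to every design column.
#'
#' @param signals `rows x T` matrix.
#' @param design `T x p` design matrix (see [build_nuisance_design()]).
#' @return Residual matrix, same shape as `signals`.
#' @export
regress_nuisance <- function(signals, design) {
  signals <- as.matrix(signals)
  design <- as.matrix(design)
  if (ncol(signals) != nrow(design)) {
    stop_restconn("design rows must match the number of volumes")
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop_restconn(paste0("nuisance design is rank deficient; collinear: ",
                         paste(dropped, collapse = ", ")))
  }
  t(qr.resid(qrd, t(signals)))
}

#' Bandpass filter specification
#'
#' @param low_hz,high_hz Band edges in Hz (defaults 0.01 and 0.1).
#' @param tr_seconds Repetition time in seconds (default 2, i.e. a
#'   sampling rate of 0.5 Hz).
#' @param order Butterworth section order (default 2; applied
#'   forward-backward, so the effective order is 4).
#' @return A list of class `bandpass_spec`.
#' @export
bandpass_spec <- function(low_hz = 0.01, high_hz = 0.1, tr_seconds = 2,
                          order = 2L) {
  fs <- 1 / tr_seconds
  if (!(0 < low_hz && low_hz < high_hz && high_hz < fs / 2)) {
    stop_restconn("band edges must satisfy 0 < low < high < Nyquist")
  }
  structure(list(low_hz = low_hz, high_hz = high_hz, sampling_hz = fs,
                 order = as.integer(order), zero_phase = TRUE),
            class = "bandpass_spec")
}

# Internal: zero-phase Butterworth bandpass of one demeaned series using
# odd-extension padding to suppress edge transients.
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  pad <- min(n - 1L, 100L)
  mu <- mean(x)
  xc <- x - mu
  ext <- c(2 * xc[1] - xc[seq(pad + 1L, 2L)], xc,
           2 * xc[n] - xc[seq(n - 1L, n - pad)])
  y <- signal::filtfilt(bf, ext)
  y[(pad + 1L):(pad + n)]
}

#' Zero-phase bandpass filter a signals-by-time matrix
#'
#' Butterworth bandpass applied forward-backward per row (zero phase).
#' Each row is demeaned first; the pass band retains at least 90% of the
#' amplitude at band centre while DC and frequencies at twice the upper
#' edge are attenuated to below 10%.
#'
#' @param signals `rows x T` matrix.
#' @param spec A [bandpass_spec()].
#' @return Filtered matrix of the same shape.
#' @export
bandpass_filter <- function(signals, spec = bandpass_spec()) {
  stopifnot(inherits(spec, "bandpass_spec"))
  signals <- as.matrix(signals)
  ntaps <- 2L * spec$order + 1L
  if (ncol(signals) < 3 * ntaps) {
    stop_restconn("too few volumes for the requested filter order")
  }
  w <- c(spec$low_hz, spec$high_hz) / (spec$sampling_hz / 2)
  bf <- signal::butter(spec$order, w, type = "pass")
  t(apply(signals, 1, function(row) filtfilt_padded(bf, row)))
}

#' Run the full signal-level preprocessing on a cohort
#'
#' Pipeline order: frame-wise displacement, cohort-uniform trimming,
#' CompCor + motion nuisance regression, zero-phase bandpass.
#'
#' @param cohort A `restconn_cohort` (or a compatible list with
#'   `timeseries`, `motion`, `wm`, `csf` lists and a `participants`
#'   tibble).
#' @param fd_threshold_mm FD censoring threshold (default 0.5).
#' @param initial_drop Leading volumes removed (default 4).
#' @param compcor_k Principal components per tissue (default 5).
#' @param band A [bandpass_spec()]; defaults to 0.01-0.1 Hz at the
#'   cohort's TR.
#' @param rotation_radius_mm FD rotation radius (default 50).
#' @return A list of class `restconn_preproc`: `clean` (list of
#'   ROI x T_retained matrices), `plan` (the `trim_plan`), `fd`
#'   (list of FD tibbles), `participants`.
#' @export
preprocess_cohort <- function(cohort, fd_threshold_mm = 0.5,
                              initial_drop = 4L, compcor_k = 5L,
                              band = NULL, rotation_radius_mm = 50) {
  tr <- if (!is.null(cohort$config)) cohort$config$tr_seconds else 2
  band <- band %||% bandpass_spec(tr_seconds = tr)
  ids <- cohort$participants$id
  fd <- lapply(cohort$motion, compute_framewise_displacement,
               rotation_radius_mm = rotation_radius_mm,
               threshold_mm = fd_threshold_mm, initial_drop = initial_drop)
  plan <- plan_uniform_trimming(fd, threshold_mm = fd_threshold_mm,
                                initial_drop = initial_drop)
  clean <- lapply(ids, function(id) {
    kept <- plan$kept[[id]]
    sig <- cohort$timeseries[[id]][, kept, drop = FALSE]
    wm_pc <- extract_nuisance_components(cohort$wm[[id]][, kept, drop = FALSE],
                                         k = compcor_k)
    csf_pc <- extract_nuisance_components(cohort$csf[[id]][, kept, drop = FALSE],
                                          k = compcor_k)
    design <- build_nuisance_design(wm_pc, csf_pc,
                                    cohort$motion[[id]][kept, , drop = FALSE])
    resid <- regress_nuisance(sig, design)
    bandpass_filter(resid, band)
  })
  names(clean) <- ids
  structure(list(clean = clean, plan = plan, fd = fd,
                 participants = cohort$participants,
                 band = band),
            class = "restconn_preproc")
}
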