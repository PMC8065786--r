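#' Sample one participant's ROI time series
#'
#' Draws a zero-mean multivariate normal series with the given ROI
#' correlation structure, optionally adds a slow per-ROI linear drift and
#' white observation noise. Rows are ROIs, columns volumes.
#'
#' @param correlation Positive semi-definite correlation matrix.
#' @param n_volumes Number of volumes.
#' @param noise_sd White observation noise sd (latent signal has unit
#'   variance), default 0.
#' @param drift_amplitude Peak-to-peak amplitude of a per-ROI linear
#'   drift, default 0.
#' @param seed Integer seed.
#' @return An `n_rois x n_volumes` matrix.
#' @export
sample_participant_timeseries <- function(correlation, n_volumes,
                                          noise_sd = 0,
                                          drift_amplitude = 0,
                                          seed = 1L) {
  n_volumes <- check_count(n_volumes, "n_volumes", 2L)
  eig <- eigen(correlation, symmetric = TRUE)
  if (min(eig$values) < -1e-8) {
    stop_restconn("correlation matrix is not positive semi-definite")
  }
  n <- nrow(correlation)
  set.seed(seed)
  root <- eig$vectors %*% (sqrt(pmax(eig$values, 0)) * t(eig$vectors))
  x <- root %*% matrix(rnorm(n * n_volumes), n, n_volumes)
  if (drift_amplitude > 0) {
    slope <- runif(n, -drift_amplitude, drift_amplitude)
    tgrid <- seq(-0.5, 0.5, length.out = n_volumes)
    x <- x + outer(slope, tgrid)
  }
  if (noise_sd > 0) {
    x <- x + noise_sd * matrix(rnorm(n * n_volumes), n, n_volumes)
  }
  x
}

#' Generate a six-parameter rigid-body motion trace
#'
#' The baseline is a slow random walk (per-step sd 0.02 mm translations /
#' 0.0002 rad rotations, steps clamped so baseline frame-wise
#' displacement stays well below threshold). Motion spikes are permanent
#' single-volume translation jumps of `spike_magnitude_mm`, each of which
#' produces exactly one supra-threshold FD value.
#'
#' @param n_volumes Number of volumes.
#' @param spike_count Number of spikes to place (outside the first
#'   `initial_drop` volumes).
#' @param spike_magnitude_mm Jump size in mm; must exceed
#'   `threshold_mm` plus the maximum baseline contribution.
#' @param seed Integer seed.
#' @param threshold_mm FD threshold the spikes must exceed (default 0.5).
#' @param initial_drop Volumes at the start that must stay spike-free
#'   (default 4).
#' @param rotation_radius_mm Radius used by the downstream FD computation
#'   (default 50).
#' @return A `n_volumes x 6` matrix (3 translations mm, 3 rotations rad).
#' @export
generate_motion_trace <- function(n_volumes, spike_count, spike_magnitude_mm = 1,
                                  seed = 1L, threshold_mm = 0.5,
                                  initial_drop = 4L,
                                  rotation_radius_mm = 50) {
  n_volumes <- check_count(n_volumes, "n_volumes", 8L)
  spike_count <- check_count(spike_count, "spike_count", 0L)
  if (spike_count >= n_volumes - initial_drop) {
    stop_restconn("spike_count must be < n_volumes - initial_drop")
  }
  # baseline caps: 3 translation steps <= 0.05 mm and 3 rotation steps
  # <= 0.0005 rad give FD <= 0.225 mm at radius 50
  t_cap <- 0.05
  r_cap <- 0.0005
  baseline_max <- 3 * t_cap + rotation_radius_mm * 3 * r_cap
  if (spike_magnitude_mm - t_cap <= threshold_mm) {
    stop_restconn(sprintf(
      "spike magnitude %.3f mm too small to guarantee FD > %.2f mm",
      spike_magnitude_mm, threshold_mm))
  }
  stopifnot(baseline_max < threshold_mm)
  set.seed(seed)
  steps_t <- matrix(pmin(pmax(rnorm(n_volumes * 3, sd = 0.02), -t_cap), t_cap),
                    n_volumes, 3)
  steps_r <- matrix(pmin(pmax(rnorm(n_volumes * 3, sd = 2e-4), -r_cap), r_cap),
                    n_volumes, 3)
  steps_t[1, ] <- 0
  steps_r[1, ] <- 0
  if (spike_count > 0) {
    eligible <- (initial_drop + 1L):n_volumes
    at <- sort(sample(eligible, spike_count))
    # permanent level shift in x translation; alternate sign
    steps_t[at, 1] <- steps_t[at, 1] +
      spike_magnitude_mm * rep_len(c(1, -1), spike_count)
  }
  params <- cbind(apply(steps_t, 2, cumsum), apply(steps_r, 2, cumsum))
  colnames(params) <- c("trans_x", "trans_y", "trans_z",
                        "rot_pitch", "rot_roll", "rot_yaw")
  params
}

#' Attach behavioural scores coupled to an edge's connectivity
#'
#' Scores are a linear transform of the per-participant Fisher-z values
#' at a designated edge plus Gaussian noise, calibrated so the generative
#' (population) Pearson correlation between score and z equals
#' `coupling_r`.
#'
#' @param edge_z Numeric vector: per-participant Fisher-z values at the
#'   designated edge.
#' @param coupling_r Target correlation, |coupling_r| < 1.
#' @param score_mean,score_sd Marginal score distribution.
#' @param seed Integer seed.
#' @param noise_sd Optional override for the noise sd; the default
#'   `score_sd * sqrt(1 - coupling_r^2)` realises the target correlation.
#'   `noise_sd = 0` gives perfectly coupled scores.
#' @return Numeric vector of scores.
#' @export
attach_scores <- function(edge_z, coupling_r, score_mean, score_sd,
                          seed = 1L, noise_sd = NULL) {
  if (length(edge_z) < 3) stop_restconn("need at least 3 participants")
  if (abs(coupling_r) >= 1) stop_restconn("|coupling_r| must be < 1")
  sz <- stats::sd(edge_z)
  if (!is.finite(sz) || sz == 0) {
    stop_restconn("edge z values have zero variance; cannot couple scores")
  }
  slope <- coupling_r * score_sd / sz
  noise_sd <- noise_sd %||% (score_sd * sqrt(1 - coupling_r^2))
  set.seed(seed)
  score_mean + slope * (edge_z - mean(edge_z)) +
    rnorm(length(edge_z), sd = noise_sd)
}

#' Expand ROI series to noisy voxel series
#'
#' Each ROI contributes `voxels_per_roi` voxels sharing the ROI's latent
#' series plus independent white noise, mimicking the data a first
#' principal component extraction would see.
#'
#' @param roi_series `n_rois x T` matrix.
#' @param voxels_per_roi Voxels per ROI (>= 2).
#' @param voxel_noise_sd Independent voxel noise sd.
#' @param seed Integer seed.
#' @return List with `voxels` (`(n_rois*voxels_per_roi) x T` matrix) and
#'   `labels` (ROI index of each voxel row).
#' @export
expand_to_voxels <- function(roi_series, voxels_per_roi, voxel_noise_sd = 0.2,
                             seed = 1L) {
  voxels_per_roi <- check_count(voxels_per_roi, "voxels_per_roi", 2L)
  n <- nrow(roi_series)
  tt <- ncol(roi_series)
  set.seed(seed)
  labels <- rep(seq_len(n), each = voxels_per_roi)
  voxels <- roi_series[labels, , drop = FALSE]
  if (voxel_noise_sd > 0) {
    voxels <- voxels + voxel_noise_sd *
      matrix(rnorm(length(labels) * tt), length(labels), tt)
  }
  list(voxels = voxels, labels = labels)
}

# Internal: nuisance voxel bank whose top principal components are known
# sinusoids, used for WM and CSF compartments.
make_nuisance_bank <- function(n_volumes, tr_seconds, n_voxels = 40,
                               freqs_hz = c(0.08, 0.03), amps = c(3, 2),
                               noise_sd = 0.5, seed = 1L) {
  set.seed(seed)
  tsec <- (seq_len(n_volumes) - 1) * tr_seconds
  sources <- vapply(seq_along(freqs_hz), function(k) {
    amps[k] * sin(2 * pi * freqs_hz[k] * tsec + runif(1, 0, 2 * pi))
  }, numeric(n_volumes))                      # T x K
  loadings <- matrix(rnorm(n_voxels * length(freqs_hz)), n_voxels)
  voxels <- loadings %*% t(sources) +
    noise_sd * matrix(rnorm(n_voxels * n_volumes), n_voxels, n_volumes)
  list(voxels = voxels, sources = t(sources))
}

#' Simulate a full two-group cohort
#'
#' Generates everything downstream stages need: per-participant ROI (or
#' voxel) time series contaminated with nuisance sources and motion
#' artefacts, motion parameter traces with a known number of FD spikes,
#' WM/CSF nuisance voxel banks, group labels, behavioural scores coupled
#' to the designated edge, and a ground-truth record.
#'
#' Contamination model: observed ROI signal = latent MVN signal + per-ROI
#' loadings on the leading WM and CSF nuisance sources + a linear
#' combination of the (detrended) motion parameters + linear drift +
#' white noise. Every contaminant lies in the span of the preprocessing
#' regressors, so parameter-recovery tests exercise the full chain.
#'
#' @param config A [sim_config()].
#' @return An object of class `restconn_cohort`: a list with
#'   `participants` (tibble: id, group, score, spike_count),
#'   `timeseries`, `motion`, `wm`, `csf` (lists keyed by participant),
#'   `parcellation` (when `n_rois == 112`), `ground_truth`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cov <- build_group_covariances(config)
  n_a <- config$n_group_a
  n_b <- config$n_group_b
  n <- n_a + n_b
  ids <- sprintf("sub-%03d", seq_len(n))
  group <- rep(c("A", "B"), c(n_a, n_b))

  timeseries <- vector("list", n)
  latent <- vector("list", n)
  motion <- vector("list", n)
  wm <- vector("list", n)
  csf <- vector("list", n)
  names(timeseries) <- names(motion) <- names(wm) <- names(csf) <- ids

  for (p in seq_len(n)) {
    corr <- if (group[p] == "A") cov$corr_a else cov$corr_b
    lat <- sample_participant_timeseries(
      corr, config$n_volumes, noise_sd = 0,
      seed = child_seed(config$seed, paste0("ts", p)))
    if (!is.null(config$score_edge) &&
        (config$score_edge_het_sd %||% 0) > 0) {
      # subject-level connectivity heterogeneity at the score edge: a
      # shared rank-1 component added to both ROIs moves the edge's true
      # correlation by a participant-specific amount while the joint
      # covariance stays positive semi-definite by construction
      se <- config$score_edge
      set.seed(child_seed(config$seed, paste0("het", p)))
      d <- rnorm(1, 0, config$score_edge_het_sd)
      common <- rnorm(config$n_volumes)
      amp <- sqrt(abs(d))
      lat[se$roi_i, ] <- lat[se$roi_i, ] + amp * common
      lat[se$roi_j, ] <- lat[se$roi_j, ] + sign(d) * amp * common
    }
    mot <- generate_motion_trace(
      config$n_volumes, config$motion_spikes_per_participant[p],
      spike_magnitude_mm = config$fd_spike_magnitude,
      seed = child_seed(config$seed, paste0("mot", p)))
    wm_bank <- make_nuisance_bank(
      config$n_volumes, config$tr_seconds, freqs_hz = c(0.08, 0.03),
      seed = child_seed(config$seed, paste0("wm", p)))
    csf_bank <- make_nuisance_bank(
      config$n_volumes, config$tr_seconds, freqs_hz = c(0.12, 0.05),
      seed = child_seed(config$seed, paste0("csf", p)))
    # motion contaminant: standardised combination of the raw parameters,
    # which nuisance regression removes exactly
    mot_std <- scale(mot)
    mot_std[, !is.finite(colSums(mot_std))] <- 0
    mot_mix <- as.numeric(mot_std %*% c(0.5, 0.3, 0.2, 0.3, 0.2, 0.1))
    set.seed(child_seed(config$seed, paste0("mix", p)))
    mix <- lat +
      outer(runif(config$n_rois, 0.2, 0.6), wm_bank$sources[1, ]) +
      outer(runif(config$n_rois, 0.1, 0.5), csf_bank$sources[1, ]) +
      outer(runif(config$n_rois, 0.2, 0.5), mot_mix) +
      outer(runif(config$n_rois, -0.6, 0.6),
            seq(-0.5, 0.5, length.out = config$n_volumes))
    if (config$noise_sd > 0) {
      mix <- mix + config$noise_sd *
        matrix(rnorm(length(mix)), nrow(mix), ncol(mix))
    }
    latent[[p]] <- lat
    timeseries[[p]] <- mix
    motion[[p]] <- mot
    wm[[p]] <- wm_bank$voxels
    csf[[p]] <- csf_bank$voxels
  }

  # scores coupled to the realised z value at the designated edge
  # (computed from the uncontaminated latent series) in group A; group B
  # scores are drawn from its own marginal, uncoupled
  scores <- numeric(n)
  if (!is.null(config$score_edge)) {
    se <- config$score_edge
    edge_z <- vapply(seq_len(n), function(p) {
      x <- latent[[p]]
      atanh(stats::cor(x[se$roi_i, ], x[se$roi_j, ]))
    }, numeric(1))
    scores[group == "A"] <- attach_scores(
      edge_z[group == "A"], se$coupling_r, config$score_mean,
      config$score_sd, seed = child_seed(config$seed, "scoresA"))
    set.seed(child_seed(config$seed, "scoresB"))
    scores[group == "B"] <- rnorm(n_b, config$score_mean_b, config$score_sd_b)
  } else {
    set.seed(child_seed(config$seed, "scores"))
    scores[group == "A"] <- rnorm(n_a, config$score_mean, config$score_sd)
    scores[group == "B"] <- rnorm(n_b, config$score_mean_b, config$score_sd_b)
  }

  participants <- tibble(
    id = ids, group = group, score = round(scores, 2),
    spike_count = config$motion_spikes_per_participant
  )

  parcellation <- if (config$n_rois == 112) default_parcellation() else NULL

  out <- list(
    participants = participants,
    timeseries = timeseries,
    motion = motion,
    wm = wm,
    csf = csf,
    parcellation = parcellation,
    ground_truth = c(cov$ground_truth,
                     list(spike_counts = config$motion_spikes_per_participant)),
    config = config
  )
  if (config$voxel_mode) {
    out$voxels <- lapply(seq_len(n), function(p) {
      expand_to_voxels(timeseries[[p]], config$voxels_per_roi,
                       config$voxel_noise_sd,
                       seed = child_seed(config$seed, paste0("vox", p)))
    })
    names(out$voxels) <- ids
  }
  structure(out, class = "restconn_cohort")
}

#' @export
print.restconn_cohort <- function(x, ...) {
  cat("<restconn_cohort>\n")
  cat(sprintf("  %d participants (%d A / %d B), %d ROIs, %d volumes\n",
              nrow(x$participants), sum(x$participants$group == "A"),
              sum(x$participants$group == "B"),
              x$config$n_rois, x$config$n_volumes))
  invisible(x)
}
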