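#' Configuration for a synthetic two-group resting-state cohort
#'
#' The defaults emulate a two-group expertise study: 21 experts and 23
#' controls, 420 volumes acquired at TR = 2 s, 112 ROIs, a handful of
#' edges whose Fisher-z connectivity differs between groups, motion
#' spikes that trip the 0.5 mm frame-wise displacement threshold, and a
#' behavioural score linearly coupled to one designated edge.
#'
#' @param n_group_a,n_group_b Group sizes (defaults 21 and 23).
#' @param n_rois Number of ROIs (default 112, matching the bundled
#'   parcellation).
#' @param n_volumes Raw volumes per scan (default 420).
#' @param tr_seconds Repetition time in seconds (default 2).
#' @param effect_edges Data frame with columns `roi_i`, `roi_j`, `delta_z`
#'   giving between-group connectivity offsets in Fisher-z units
#'   (positive: group A stronger). Default: five edges at |delta_z| = 0.8,
#'   three stronger in group A and two stronger in group B.
#' @param score_edge List with `roi_i`, `roi_j`, `coupling_r`: the edge
#'   whose per-participant Fisher-z value drives the behavioural score,
#'   and the target Pearson correlation. Default couples the left/right
#'   caudate edge at r = -0.511 in group A.
#' @param score_mean,score_sd Score distribution per group A (group B gets
#'   `score_mean_b`); defaults 70.95 (7.13) and 40.71 (7.69).
#' @param score_mean_b,score_sd_b See above.
#' @param score_edge_het_sd Between-subject sd (Fisher-z units, both
#'   groups) of the score edge's true connectivity (default 0.3). Without
#'   subject-level heterogeneity the only variation across participants
#'   would be estimation noise, and an edge-score correlation would be
#'   unrecoverable from finite scans.
#' @param motion_spikes_per_participant Integer vector (length
#'   `n_group_a + n_group_b`) of motion-spike counts, or `NULL` to draw
#'   counts 0..8 with participant 1 set to 37 spikes (the cohort's
#'   worst mover, so uniform trimming removes 37 volumes and retains 379).
#' @param fd_spike_magnitude Translation jump (mm) used for each spike
#'   (default 1). Must exceed the FD threshold by a safety margin.
#' @param noise_sd White observation noise added on top of the latent ROI
#'   signals, in units of the unit-variance latent signal (default 0.2).
#' @param voxel_mode If `TRUE`, emit voxel-level data (`voxels_per_roi`
#'   voxels per ROI) instead of ROI series.
#' @param voxels_per_roi Voxels per ROI in voxel mode (default 30).
#' @param voxel_noise_sd Independent voxel noise sd (default 0.2).
#' @param seed Integer seed; the full cohort is reproducible given the
#'   config.
#' @return An object of class `sim_config` (a list).
#' @export
sim_config <- function(n_group_a = 21, n_group_b = 23, n_rois = 112,
                       n_volumes = 420, tr_seconds = 2,
                       effect_edges = default_effect_edges(),
                       score_edge = list(roi_i = 99L, roi_j = 100L,
                                         coupling_r = -0.511),
                       score_mean = 70.95, score_sd = 7.13,
                       score_mean_b = 40.71, score_sd_b = 7.69,
                       score_edge_het_sd = 0.3,
                       motion_spikes_per_participant = NULL,
                       fd_spike_magnitude = 1.0,
                       noise_sd = 0.2,
                       voxel_mode = FALSE, voxels_per_roi = 30,
                       voxel_noise_sd = 0.2,
                       seed = 1L) {
  n_group_a <- check_count(n_group_a, "n_group_a", 2L)
  n_group_b <- check_count(n_group_b, "n_group_b", 2L)
  n_rois <- check_count(n_rois, "n_rois", 2L)
  n_volumes <- check_count(n_volumes, "n_volumes", 8L)
  seed <- check_count(seed, "seed", 0L)
  if (!is.null(effect_edges) && nrow(effect_edges) > 0) {
    ee <- effect_edges
    stopifnot(all(c("roi_i", "roi_j", "delta_z") %in% names(ee)))
    if (any(ee$roi_i >= ee$roi_j)) {
      stop_restconn("effect edges must have roi_i < roi_j")
    }
    if (any(ee$roi_i < 1 | ee$roi_j > n_rois)) {
      stop_restconn("effect edge index out of range")
    }
    if (any(duplicated(paste(ee$roi_i, ee$roi_j)))) {
      stop_restconn("effect edges must be distinct")
    }
    if (any(!is.finite(ee$delta_z))) stop_restconn("delta_z must be finite")
  }
  if (!is.null(score_edge)) {
    if (abs(score_edge$coupling_r) >= 1) {
      stop_restconn("|coupling_r| must be < 1")
    }
    if (score_edge$roi_i < 1 || score_edge$roi_j > n_rois ||
        score_edge$roi_i >= score_edge$roi_j) {
      stop_restconn("score edge indices invalid")
    }
  }
  n <- n_group_a + n_group_b
  if (is.null(motion_spikes_per_participant)) {
    set.seed(child_seed(seed, "spikes"))
    motion_spikes_per_participant <- sample(0:8, n, replace = TRUE)
    motion_spikes_per_participant[1] <- 37L
  }
  if (length(motion_spikes_per_participant) != n) {
    stop_restconn("motion_spikes_per_participant must have one count per participant")
  }
  if (any(motion_spikes_per_participant >= n_volumes - 4L)) {
    stop_restconn("spike count must be < n_volumes - 4")
  }
  structure(list(
    n_group_a = n_group_a, n_group_b = n_group_b, n_rois = n_rois,
    n_volumes = n_volumes, tr_seconds = tr_seconds,
    effect_edges = effect_edges, score_edge = score_edge,
    score_mean = score_mean, score_sd = score_sd,
    score_mean_b = score_mean_b, score_sd_b = score_sd_b,
    score_edge_het_sd = score_edge_het_sd,
    motion_spikes_per_participant = as.integer(motion_spikes_per_participant),
    fd_spike_magnitude = fd_spike_magnitude, noise_sd = noise_sd,
    voxel_mode = isTRUE(voxel_mode), voxels_per_roi = voxels_per_roi,
    voxel_noise_sd = voxel_noise_sd, seed = seed
  ), class = "sim_config")
}

#' Default injected group-difference edges
#'
#' Five edges with |delta_z| = 0.8: three with stronger connectivity in
#' group A (frontal-subcortical style pairs) and two stronger in group B.
#' Indices refer to the bundled 112-region parcellation.
#'
#' @return A tibble with columns `roi_i`, `roi_j`, `delta_z`.
#' @export
default_effect_edges <- function() {
  # LOrG.L-TrIFG.L, VDc.R-FP.R, CN.L-OpIFG.R stronger in group A;
  # LOrG.L-Pcun.R, Th.R-LOrG.R stronger in group B.
  tibble(
    roi_i = c(11L, 2L, 10L, 17L, 18L),
    roi_j = c(17L, 108L, 99L, 56L, 106L),
    delta_z = c(0.8, 0.8, 0.8, -0.8, -0.8)
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  groups: %d + %d participants, %d ROIs, %d volumes @ TR %.1fs\n",
              x$n_group_a, x$n_group_b, x$n_rois, x$n_volumes, x$tr_seconds))
  ne <- if (is.null(x$effect_edges)) 0L else nrow(x$effect_edges)
  cat(sprintf("  effect edges: %d; score edge: %s; seed: %d\n", ne,
              if (is.null(x$score_edge)) "none" else
                sprintf("(%d,%d) r=%.3f", x$score_edge$roi_i,
                        x$score_edge$roi_j, x$score_edge$coupling_r),
              x$seed))
  invisible(x)
}
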