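test_that("group covariances honour injected z-space offsets and stay PSD", {
  cfg0 <- sim_config(n_rois = 20, effect_edges = NULL, score_edge = NULL,
                     motion_spikes_per_participant = rep(0, 44), seed = 3)
  out0 <- build_group_covariances(cfg0)
  expect_identical(out0$corr_a, out0$corr_b)

  cfg <- sim_config(
    n_rois = 20,
    effect_edges = tibble::tibble(roi_i = 2L, roi_j = 7L, delta_z = 0.5),
    score_edge = NULL, motion_spikes_per_participant = rep(0, 44), seed = 3)
  out <- build_group_covariances(cfg)
  dz <- atanh(out$corr_a) - atanh(out$corr_b)
  diag(dz) <- 0
  expect_lt(abs(dz[2, 7] - 0.5), 0.05)
  dz[2, 7] <- dz[7, 2] <- 0
  expect_lt(max(abs(dz)), 0.05)
  for (m in list(out$corr_a, out$corr_b)) {
    expect_gte(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
    expect_equal(unname(diag(m)), rep(1, 20))
  }
})

test_that("sampled time series reproduce the target correlation structure", {
  # identity correlation: all empirical off-diagonal |r| small at T = 5000
  x <- sample_participant_timeseries(diag(8), 5000, seed = 42)
  r <- cor(t(x))
  expect_lt(max(abs(r[upper.tri(r)])), 0.1)

  # a strong target edge is recovered
  rho <- diag(4)
  rho[1, 2] <- rho[2, 1] <- 0.8
  x2 <- sample_participant_timeseries(rho, 5000, seed = 7)
  expect_lt(abs(cor(x2[1, ], x2[2, ]) - 0.8), 0.05)

  # determinism
  expect_identical(sample_participant_timeseries(rho, 100, seed = 5),
                   sample_participant_timeseries(rho, 100, seed = 5))

  # non-PSD input rejected
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(sample_participant_timeseries(bad, 10),
               "positive semi-definite")
})

test_that("motion traces contain exactly the requested FD spikes", {
  m0 <- generate_motion_trace(200, 0, seed = 1)
  fd0 <- compute_framewise_displacement(m0)
  expect_lte(max(fd0$fd), 0.5)

  for (k in c(3, 37)) {
    m <- generate_motion_trace(420, k, seed = k)
    fd <- compute_framewise_displacement(m)
    expect_identical(attr(fd, "supra_threshold_count"), as.integer(k))
  }

  # cohort whose worst mover has 37 spikes retains 379 of 420 volumes
  fds <- lapply(c(37, 5, 0), function(k) {
    compute_framewise_displacement(generate_motion_trace(420, k, seed = k + 1))
  })
  plan <- plan_uniform_trimming(fds)
  expect_identical(plan$retained_volume_count, 379L)

  expect_error(generate_motion_trace(100, 2, spike_magnitude_mm = 0.3),
               "too small")
})

test_that("score attachment realises the requested coupling", {
  set.seed(99)
  z <- rnorm(1000, 0, 0.3)
  s0 <- attach_scores(z, 0, 50, 10, seed = 2)
  expect_lt(abs(cor(z, s0)), 0.1)

  s1 <- attach_scores(z, -0.511, 70.95, 7.13, seed = 2)
  expect_lt(abs(cor(z, s1) - (-0.511)), 0.06)

  s2 <- attach_scores(z[1:10], 0.4, 50, 10, seed = 2, noise_sd = 0)
  expect_equal(abs(cor(z[1:10], s2)), 1)

  expect_error(attach_scores(z, 1.2, 50, 10), "coupling_r")
  expect_error(attach_scores(z[1:2], 0.5, 50, 10), "3 participants")
})

test_that("voxel expansion preserves the latent ROI signal", {
  roi <- sample_participant_timeseries(diag(3), 200, seed = 8)
  v0 <- expand_to_voxels(roi, 4, voxel_noise_sd = 0, seed = 1)
  expect_equal(v0$voxels[1, ], roi[1, ])
  expect_equal(v0$voxels[5, ], roi[2, ])

  v <- expand_to_voxels(roi, 50, voxel_noise_sd = 0.3, seed = 1)
  for (k in 1:3) {
    pc1 <- extract_roi_representative(v$voxels[v$labels == k, ])
    expect_gt(abs(cor(pc1, roi[k, ])), 0.95)
  }
  expect_identical(expand_to_voxels(roi, 5, 0.2, seed = 3),
                   expand_to_voxels(roi, 5, 0.2, seed = 3))
})

test_that("identical configs give bitwise-identical cohorts", {
  c1 <- simulate_cohort(tiny_config(seed = 5))
  c2 <- simulate_cohort(tiny_config(seed = 5))
  expect_identical(c1$timeseries, c2$timeseries)
  expect_identical(c1$motion, c2$motion)
  expect_identical(c1$participants, c2$participants)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(effect_edges = tibble::tibble(
    roi_i = 5L, roi_j = 5L, delta_z = 1)), "roi_i < roi_j")
  expect_error(sim_config(effect_edges = tibble::tibble(
    roi_i = c(1L, 1L), roi_j = c(2L, 2L), delta_z = c(1, 2))), "distinct")
  expect_error(sim_config(score_edge = list(roi_i = 1L, roi_j = 2L,
                                            coupling_r = 1)), "coupling_r")
  expect_error(sim_config(n_rois = 1), "n_rois")
})
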