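test_that("frame-wise displacement matches the hand-computed definition", {
  m <- matrix(0, 10, 6)
  expect_equal(compute_framewise_displacement(m)$fd, rep(0, 10))

  # one step of +0.1 mm on each translation and +0.001 rad on each
  # rotation: FD = 0.3 + 50 * 0.003 = 0.45
  m2 <- m
  m2[5:10, 1:3] <- 0.1
  m2[5:10, 4:6] <- 0.001
  fd <- compute_framewise_displacement(m2, rotation_radius_mm = 50)
  expect_equal(fd$fd[5], 0.45)
  expect_equal(fd$fd[6], 0)

  # linearity: doubling increments doubles FD
  expect_equal(compute_framewise_displacement(2 * m2)$fd, 2 * fd$fd)

  # invariance to constant offsets
  expect_equal(compute_framewise_displacement(m2 + 3)$fd, fd$fd)

  m3 <- m2
  m3[7, 2] <- NA
  expect_error(compute_framewise_displacement(m3), "volume")
})

test_that("uniform trimming equalises retained volumes by the stated rule", {
  # 420 volumes, worst mover flagged 37 times -> 379 retained everywhere
  fds <- lapply(c(37, 12, 0), function(k) {
    compute_framewise_displacement(generate_motion_trace(420, k, seed = k + 2))
  })
  plan <- plan_uniform_trimming(fds)
  expect_identical(plan$removal_count, 37L)
  expect_identical(plan$retained_volume_count, 379L)
  expect_true(all(vapply(plan$kept, length, integer(1)) == 379L))
  # no kept index inside the initial drop, all strictly increasing
  for (kept in plan$kept) {
    expect_gt(min(kept), 4)
    expect_true(all(diff(kept) > 0))
  }

  # no supra-threshold volumes anywhere: only the initial drop applies
  quiet <- lapply(1:2, function(k) {
    compute_framewise_displacement(generate_motion_trace(50, 0, seed = k))
  })
  plan_q <- plan_uniform_trimming(quiet)
  expect_identical(plan_q$removal_count, 0L)
  expect_identical(plan_q$retained_volume_count, 46L)

  # brute-force check of the equalisation rule on constructed FD series
  mk_fd <- function(fd_values) {
    out <- tibble::tibble(volume = seq_along(fd_values), fd = fd_values)
    class(out) <- c("restconn_fd", class(out))
    out
  }
  fd1 <- rep(0.1, 20); fd1[c(5, 11)] <- 0.9           # 2 flagged
  fd1[c(7, 15, 16)] <- c(0.30, 0.40, 0.40)            # extra-removal order
  fd2 <- rep(0.1, 20); fd2[6:10] <- 0.8               # 5 flagged
  plan2 <- plan_uniform_trimming(list(mk_fd(fd1), mk_fd(fd2)),
                                 initial_drop = 2L)
  expect_identical(plan2$removal_count, 5L)
  expect_true(all(vapply(plan2$kept, length, integer(1)) == 13L))
  # participant 1 loses its 2 flagged volumes plus the 3 highest-FD
  # remaining; the 0.40 tie is broken by the later volume first
  expect_false(any(c(5, 11, 7, 15, 16) %in% plan2$kept[[1]]))
  expect_true(all(setdiff(3:20, c(5, 11, 7, 15, 16)) %in% plan2$kept[[1]]))

  expect_error(plan_uniform_trimming(list(mk_fd(rep(0.9, 8))),
                                     initial_drop = 2L),
               "every volume")
})

test_that("CompCor components recover embedded sources in variance order", {
  tt <- 150
  s1 <- sin(2 * pi * 0.08 * (1:tt))          # stronger source
  s2 <- cos(2 * pi * 0.031 * (1:tt))         # weaker, near-orthogonal
  set.seed(4)
  vox <- rbind(
    outer(rnorm(30, 0, 1.5), s1) + outer(rnorm(30, 0, 0.4), s2),
    outer(rnorm(10, 0, 0.2), s1) + outer(rnorm(10, 0, 0.3), s2)
  ) + matrix(rnorm(40 * tt, 0, 0.05), 40)
  pcs <- extract_nuisance_components(vox, k = 2)
  expect_equal(dim(pcs), c(tt, 2))
  expect_gt(abs(cor(pcs[, 1], s1)), 0.99)
  expect_gt(abs(cor(pcs[, 2], s2)), 0.99)
  expect_equal(unname(apply(pcs, 2, sd)), c(1, 1))

  # rank-1 bank: PC1 is the common series
  rank1 <- outer(c(1, -2, 0.5), s1)
  expect_gt(abs(cor(extract_nuisance_components(rank1, 1)[, 1], s1)),
            1 - 1e-10)

  # k beyond rank is an error
  rank3 <- outer(rnorm(10), s1) + outer(rnorm(10), s2) +
    outer(rnorm(10), (1:tt) / tt)
  expect_error(extract_nuisance_components(rank3, k = 5), "rank")
})

test_that("nuisance regression is an exact orthogonal projection", {
  tt <- 120
  mot <- generate_motion_trace(tt, 0, seed = 2)
  wm <- extract_nuisance_components(
    rbind(outer(rnorm(20), sin(2 * pi * 0.07 * (1:tt)))) +
      matrix(rnorm(20 * tt, 0, 0.1), 20), k = 2)
  csf <- extract_nuisance_components(
    rbind(outer(rnorm(20), cos(2 * pi * 0.05 * (1:tt)))) +
      matrix(rnorm(20 * tt, 0, 0.1), 20), k = 2)
  design <- build_nuisance_design(wm, csf, mot)

  # a signal equal to a design column is annihilated
  sig <- rbind(design[, "wm_pc1"])
  expect_lt(max(abs(regress_nuisance(sig, design))), 1e-8)

  # an orthogonal signal passes unchanged
  set.seed(1)
  raw <- rnorm(tt)
  ortho <- unname(qr.resid(qr(design), raw))
  expect_equal(unname(drop(regress_nuisance(rbind(ortho), design))), ortho,
               tolerance = 1e-8)

  # mix of design columns + orthogonal target -> target recovered
  mix <- rbind(2 * design[, "trend"] - 0.5 * design[, "csf_pc2"] + ortho)
  expect_equal(unname(drop(regress_nuisance(mix, design))), unname(ortho),
               tolerance = 1e-6)

  # residuals orthogonal to every column; idempotent
  set.seed(2)
  signals <- matrix(rnorm(5 * tt), 5)
  res <- regress_nuisance(signals, design)
  expect_lt(max(abs(res %*% design)) /
              max(abs(signals)) / max(abs(design)), 1e-8)
  expect_equal(regress_nuisance(res, design), res, tolerance = 1e-10)

  bad <- cbind(design, dup = design[, "trend"])
  expect_error(regress_nuisance(signals, bad), "rank deficient")
})

test_that("bandpass filter meets its gain contract", {
  spec <- bandpass_spec()        # 0.01-0.1 Hz at TR 2 s
  # constant input is removed entirely (demeaning + zero DC gain)
  const <- rbind(rep(7, 379))
  expect_lt(max(abs(bandpass_filter(const, spec))), 1e-6 * 7)

  expect_gt(measured_gain(0.05, spec), 0.9)    # band centre
  expect_lt(measured_gain(0.2, spec), 0.1)     # 2x upper edge
  expect_lt(measured_gain(0.003, spec), 0.1)   # below lower edge

  # refiltering changes passband content by < 2%
  tt <- seq_len(3000) / spec$sampling_hz
  s <- rbind(sin(2 * pi * 0.05 * tt))
  y1 <- bandpass_filter(s, spec)
  y2 <- bandpass_filter(y1, spec)
  mid <- 500:2500
  expect_lt(abs(sd(y2[mid]) / sd(y1[mid]) - 1), 0.02)

  expect_error(bandpass_spec(low_hz = 0.2, high_hz = 0.4, tr_seconds = 2),
               "Nyquist")
  expect_error(bandpass_filter(rbind(rnorm(10)), spec), "too few volumes")
})

test_that("cohort preprocessing returns balanced, clean series", {
  coh <- simulate_cohort(tiny_config(seed = 2))
  pre <- preprocess_cohort(coh)
  lens <- vapply(pre$clean, ncol, integer(1))
  expect_true(all(lens == pre$plan$retained_volume_count))
  expect_identical(names(pre$clean), coh$participants$id)
  # each cleaned series is centred (small mean relative to scale) and
  # non-degenerate
  id <- coh$participants$id[1]
  sds <- apply(pre$clean[[id]], 1, sd)
  expect_true(all(sds > 0))
  expect_true(all(is.finite(pre$clean[[id]])))
})
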