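# Independent oracles used across tests. These deliberately avoid the
# package's own vectorised code paths.

# Pooled-variance two-sample t statistic, textbook form.
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

# Exact permutation p-value by full enumeration of label assignments.
oracle_exhaustive_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  t_obs <- abs(oracle_pooled_t(x, y))
  combs <- combn(n, nx)
  tp <- apply(combs, 2, function(idx) {
    abs(oracle_pooled_t(pooled[idx], pooled[-idx]))
  })
  mean(tp >= t_obs - 1e-12)
}

# Closed-form Pearson correlation and its two-sided t-test p-value.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), n - 2))
}

# Pearson chi-square on a 2x2 table, by expected counts.
oracle_chisq_2x2 <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - e)^2 / e)
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

# A small cohort config that keeps test runtimes low.
tiny_config <- function(seed = 1L, ...) {
  sim_config(
    n_group_a = 5, n_group_b = 5, n_rois = 12, n_volumes = 80,
    effect_edges = tibble::tibble(roi_i = 1L, roi_j = 2L, delta_z = 0.9),
    score_edge = list(roi_i = 3L, roi_j = 4L, coupling_r = -0.5),
    motion_spikes_per_participant = c(6, rep(1, 9)),
    seed = seed, ...
  )
}

# Amplitude-ratio gain of the bandpass filter at one frequency,
# measured on a long sinusoid (transients negligible relative to T).
measured_gain <- function(freq_hz, spec = bandpass_spec(), t_len = 3000) {
  tt <- seq_len(t_len) / spec$sampling_hz
  s <- sin(2 * pi * freq_hz * tt)
  y <- drop(bandpass_filter(rbind(s), spec))
  mid <- seq(round(t_len * 0.15), round(t_len * 0.85))
  sd(y[mid]) / sd(s[mid])
}
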