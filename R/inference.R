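# Internal: pooled-variance two-sample t statistics for all columns of X
# given a logical group-A mask matrix G (perms x n). Returns perms x E.
pooled_t_many <- function(G, X, n_a, n_b) {
  S <- colSums(X)
  SS <- colSums(X^2)
  sumA <- G %*% X
  sumsqA <- G %*% (X^2)
  meanA <- sumA / n_a
  meanB <- sweep(-sumA, 2, S, "+") / n_b
  ssA <- sumsqA - sumA^2 / n_a
  ssB <- sweep(-sumsqA, 2, SS, "+") - (n_b * meanB^2)
  sp2 <- (ssA + ssB) / (n_a + n_b - 2)
  denom <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  tt <- (meanA - meanB) / denom
  tt[denom == 0] <- 0
  tt
}

#' Edge-wise permutation two-sample t-test
#'
#' For every edge, computes the observed pooled-variance two-sample t
#' statistic and a two-sided permutation p-value obtained by randomly
#' reassigning group labels. With `replicates = B` Monte-Carlo draws the
#' estimator is `p = (1 + #(|t_perm| >= |t_obs|)) / (B + 1)`, which can
#' never return zero. When the total number of distinct label
#' assignments is at most `exhaustive_limit` the test enumerates all of
#' them instead and reports the exact p-value.
#'
#' @param z_a `n_a x E` matrix of group-A edge values (e.g. Fisher-z).
#' @param z_b `n_b x E` matrix of group-B edge values.
#' @param replicates Monte-Carlo replicates B (default 10000).
#' @param seed Integer seed (Monte-Carlo mode).
#' @param edges Optional edge index tibble ([edge_index_table()]) used to
#'   label rows.
#' @param direction_labels Length-2 character: labels used when group A
#'   (resp. B) has the larger mean.
#' @param exhaustive_limit Enumerate exactly when `choose(n, n_a)` is at
#'   most this value (default 184756, i.e. 10+10).
#' @param chunk_size Permutations processed per block (memory control).
#' @return A tibble of class `edge_stat_tbl` with columns `edge`,
#'   `roi_i`, `roi_j` (when `edges` given), `t`, `p`, `direction`, and
#'   attributes `replicates`, `seed`, `method` ("exhaustive" or
#'   "monte_carlo").
#' @export
permutation_edge_test <- function(z_a, z_b, replicates = 10000L, seed = 1L,
                                  edges = NULL,
                                  direction_labels = c("A > B", "B > A"),
                                  exhaustive_limit = 184756,
                                  chunk_size = 1000L) {
  z_a <- rbind(z_a)
  z_b <- rbind(z_b)
  n_a <- nrow(z_a)
  n_b <- nrow(z_b)
  if (n_a < 2 || n_b < 2) stop_restconn("need >= 2 subjects per group")
  if (ncol(z_a) != ncol(z_b)) stop_restconn("edge counts differ")
  X <- rbind(z_a, z_b)
  E <- ncol(X)
  n <- n_a + n_b

  obs_mask <- matrix(0, 1, n)
  obs_mask[1, seq_len(n_a)] <- 1
  t_obs <- drop(pooled_t_many(obs_mask, X, n_a, n_b))
  Xa <- X[seq_len(n_a), , drop = FALSE]
  Xb <- X[-seq_len(n_a), , drop = FALSE]
  var_a <- colSums(Xa^2) / n_a - colMeans(Xa)^2
  var_b <- colSums(Xb^2) / n_b - colMeans(Xb)^2
  tol_a <- .Machine$double.eps * pmax(1, colSums(Xa^2) / n_a) * 100
  tol_b <- .Machine$double.eps * pmax(1, colSums(Xb^2) / n_b) * 100
  degenerate <- var_a <= tol_a & var_b <= tol_b
  if (any(degenerate)) {
    warn(sprintf("%d edge(s) have zero variance in both groups; p set to 1",
                 sum(degenerate)))
  }

  n_comb <- choose(n, n_a)
  exhaustive <- n_comb <= exhaustive_limit
  abs_obs <- abs(t_obs) - 1e-12
  count_ge <- numeric(E)
  total <- 0L
  if (exhaustive) {
    combs <- utils::combn(n, n_a)
    for (start in seq(1, ncol(combs), by = chunk_size)) {
      idx <- start:min(start + chunk_size - 1L, ncol(combs))
      G <- matrix(0, length(idx), n)
      G[cbind(rep(seq_along(idx), each = n_a), as.vector(combs[, idx]))] <- 1
      tp <- pooled_t_many(G, X, n_a, n_b)
      count_ge <- count_ge + colSums(abs(tp) >= rep(abs_obs, each = nrow(tp)))
      total <- total + length(idx)
    }
    p <- count_ge / n_comb
    method <- "exhaustive"
  } else {
    set.seed(seed)
    B <- check_count(replicates, "replicates", 1L)
    done <- 0L
    while (done < B) {
      nb <- min(chunk_size, B - done)
      G <- matrix(0, nb, n)
      for (b in seq_len(nb)) G[b, sample.int(n, n_a)] <- 1
      tp <- pooled_t_many(G, X, n_a, n_b)
      count_ge <- count_ge + colSums(abs(tp) >= rep(abs_obs, each = nb))
      done <- done + nb
    }
    p <- (1 + count_ge) / (B + 1)
    method <- "monte_carlo"
  }
  t_obs[degenerate] <- 0
  p[degenerate] <- 1

  mean_diff <- colMeans(z_a) - colMeans(z_b)
  direction <- ifelse(mean_diff >= 0, direction_labels[1], direction_labels[2])
  out <- tibble(edge = seq_len(E), t = t_obs, p = p, direction = direction)
  if (!is.null(edges)) {
    out <- dplyr::left_join(out, edges, by = "edge") |>
      dplyr::relocate(dplyr::any_of(c("edge", "roi_i", "roi_j",
                                      "abbrev_i", "abbrev_j")))
  }
  attr(out, "replicates") <- if (exhaustive) n_comb else replicates
  attr(out, "seed") <- seed
  attr(out, "method") <- method
  attr(out, "n_a") <- n_a
  attr(out, "n_b") <- n_b
  attr(out, "direction_labels") <- direction_labels
  class(out) <- c("edge_stat_tbl", class(out))
  out
}

#' Filter edge statistics at a significance threshold
#'
#' Retains edges with `p < alpha`, ordered in direction blocks (group-A
#' greater first) with ascending p inside each block.
#'
#' @param stats An `edge_stat_tbl` (or any tibble with `p` and
#'   `direction` columns).
#' @param alpha Significance threshold (default 0.01, uncorrected).
#' @return The filtered tibble, with attributes `alpha` and
#'   `direction_counts` (named integer vector).
#' @export
filter_significant <- function(stats, alpha = 0.01) {
  labels <- attr(stats, "direction_labels") %||% unique(stats$direction)
  out <- stats |>
    filter(.data$p < alpha) |>
    mutate(direction = factor(.data$direction, levels = labels)) |>
    arrange(.data$direction, .data$p) |>
    mutate(direction = as.character(.data$direction))
  counts <- table(factor(out$direction, levels = labels))
  attr(out, "alpha") <- alpha
  attr(out, "direction_counts") <- setNames(as.integer(counts), names(counts))
  for (a in c("replicates", "seed", "method", "n_a", "n_b",
              "direction_labels")) {
    attr(out, a) <- attr(stats, a)
  }
  class(out) <- unique(c("edge_stat_tbl", class(out)))
  out
}

#' @export
glance.edge_stat_tbl <- function(x, ...) {
  counts <- attr(x, "direction_counts")
  out <- tibble(n_edges = nrow(x),
                alpha = attr(x, "alpha") %||% NA_real_,
                replicates = attr(x, "replicates") %||% NA_integer_,
                method = attr(x, "method") %||% NA_character_)
  if (!is.null(counts)) {
    out$n_a_greater <- counts[[1]]
    out$n_b_greater <- counts[[2]]
  }
  out
}

#' Correlate one edge's connectivity with behavioural scores
#'
#' Pearson correlation with the usual two-sided t-test on n - 2 degrees
#' of freedom, computed within one group.
#'
#' @param edge_z Per-participant connectivity values (Fisher-z).
#' @param scores Per-participant scores.
#' @param group_mask Optional logical vector selecting the group.
#' @return One-row tibble: `r`, `p`, `n`.
#' @export
edge_score_correlation <- function(edge_z, scores, group_mask = NULL) {
  if (!is.null(group_mask)) {
    edge_z <- edge_z[group_mask]
    scores <- scores[group_mask]
  }
  if (length(edge_z) < 3) stop_restconn("need >= 3 participants")
  if (stats::sd(scores) == 0) stop_restconn("scores have zero variance")
  ct <- stats::cor.test(edge_z, scores, method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(edge_z))
}

#' Score correlations for every significant edge, per group
#'
#' Replicates the uncorrected per-edge score-correlation scan over a set
#' of significant edges: within each group, each edge's Fisher-z values
#' are correlated with the group's scores.
#'
#' @param features An `edge_features` object ([connectivity_features()]).
#' @param significant An `edge_stat_tbl` of significant edges (must have
#'   an `edge` column).
#' @param scores Per-participant scores aligned with
#'   `features$participants`.
#' @return Tibble: `edge`, `roi_i`, `roi_j`, `group`, `r`, `p`, `n`
#'   (p-values are uncorrected).
#' @export
score_correlation_scan <- function(features, significant, scores) {
  part <- features$participants
  purrr::map_dfr(unique(part$group), function(g) {
    mask <- part$group == g
    purrr::map_dfr(significant$edge, function(e) {
      res <- edge_score_correlation(features$z[mask, e], scores[mask])
      ed <- features$edges[features$edges$edge == e, c("roi_i", "roi_j")]
      dplyr::bind_cols(tibble(edge = e), ed, tibble(group = g), res)
    })
  })
}

#' Two-sample t-test from summary statistics
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries.
#' @param variant `"pooled"` (Student) or `"welch"`.
#' @return One-row tibble: `t`, `df`, `p` (two-sided).
#' @export
summary_two_sample_t <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                                 variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(sd_a > 0, sd_b > 0, n_a >= 2, n_b >= 2)
  if (variant == "pooled") {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  } else {
    va <- sd_a^2 / n_a
    vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  }
  t <- (mean_a - mean_b) / se
  tibble(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pearson chi-square test on a 2x2 table
#'
#' No continuity correction, 1 degree of freedom.
#'
#' @param a,b,c,d Counts, row-wise: `(a, b)` is the first group's
#'   (e.g. male/female) split, `(c, d)` the second's.
#' @return One-row tibble: `statistic`, `df`, `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop_restconn("counts must be non-negative")
  m <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop_restconn("zero margin in 2x2 table")
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = ct$p.value)
}

#' Demographic comparison table from group summaries
#'
#' Recomputes the usual cohort-comparison statistics from printed group
#' summaries: independent two-sample t-tests for numeric measures and a
#' Pearson chi-square (no continuity correction) for 2x2 categorical
#' measures.
#'
#' @param summaries Tibble with columns `measure`, `type` ("t" or
#'   "chisq"), `a1`, `a2`, `b1`, `b2`, `n_a`, `n_b` and optionally
#'   `printed_p`. For `type == "t"` the value columns are mean and sd
#'   per group; for `type == "chisq"` they are the 2x2 counts.
#' @param variant t-test variant, `"pooled"` or `"welch"`.
#' @return The input with `statistic` and `p` columns appended.
#' @export
cohort_table <- function(summaries, variant = "pooled") {
  res <- purrr::pmap_dfr(summaries, function(measure, type, a1, a2, b1, b2,
                                             n_a, n_b, ...) {
    if (type == "t") {
      r <- summary_two_sample_t(a1, a2, n_a, b1, b2, n_b, variant = variant)
      tibble(statistic = r$t, p = r$p)
    } else {
      r <- chi_square_2x2(a1, a2, b1, b2)
      tibble(statistic = r$statistic, p = r$p)
    }
  })
  dplyr::bind_cols(summaries, res)
}
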