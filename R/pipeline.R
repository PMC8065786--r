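#' Run the full analysis pipeline on a cohort
#'
#' Stages: preprocessing (FD, uniform trimming, nuisance regression,
#' bandpass), connectivity (ROI correlation and Fisher-z edge features),
#' group inference (edge-wise permutation t-tests, significance filter,
#' per-group score correlations on the significant edges), and
#' classification (t-ranked sequential feature addition with linear SVM
#' LOOCV). When no edge survives the threshold the classification stage
#' is skipped with a message.
#'
#' @param cohort A `restconn_cohort` (simulated or read from disk).
#' @param replicates Permutation replicates (default 10000).
#' @param alpha Edge significance threshold (default 0.01, uncorrected).
#' @param k_max Cap on classifier feature-set size (default 46; reduced
#'   to the number of significant edges when fewer).
#' @param fd_threshold_mm,initial_drop,compcor_k Preprocessing knobs.
#' @param seed Integer seed for the permutation stage.
#' @param config A [classifier_config()].
#' @param direction_labels Direction labels, group A first.
#' @return A list of class `restconn_result`: `preproc`, `features`,
#'   `edge_stats`, `significant`, `score_correlations`, `curve` (or
#'   `NULL`), `manifest` (parameters, seeds and stage fingerprints).
#' @export
run_pipeline <- function(cohort, replicates = 10000L, alpha = 0.01,
                         k_max = 46L, fd_threshold_mm = 0.5,
                         initial_drop = 4L, compcor_k = 5L, seed = 1L,
                         config = classifier_config(),
                         direction_labels = c("A > B", "B > A")) {
  stopifnot(inherits(cohort, "restconn_cohort"))
  pre <- preprocess_cohort(cohort, fd_threshold_mm = fd_threshold_mm,
                           initial_drop = initial_drop,
                           compcor_k = compcor_k)
  feats <- connectivity_features(pre, parcellation = cohort$parcellation)
  grp <- feats$participants$group
  is_a <- grp == sort(unique(grp))[1]
  stats <- permutation_edge_test(feats$z[is_a, , drop = FALSE],
                                 feats$z[!is_a, , drop = FALSE],
                                 replicates = replicates, seed = seed,
                                 edges = feats$edges,
                                 direction_labels = direction_labels)
  sig <- filter_significant(stats, alpha = alpha)
  scores <- feats$participants$score
  score_cor <- if (nrow(sig) > 0 && !is.null(scores)) {
    score_correlation_scan(feats, sig, scores)
  }
  curve <- NULL
  if (nrow(sig) > 0) {
    kk <- min(k_max, nrow(sig))
    Xsig <- feats$z[, sig$edge, drop = FALSE]
    curve <- accuracy_curve(Xsig, grp, k_max = kk, config = config)
  } else {
    message("no significant edges at alpha = ", alpha,
            "; classification skipped")
  }
  manifest <- list(
    parameters = list(replicates = replicates, alpha = alpha, k_max = k_max,
                      fd_threshold_mm = fd_threshold_mm,
                      initial_drop = initial_drop, compcor_k = compcor_k,
                      seed = seed,
                      svm_kernel = config$kernel, svm_cost = config$cost,
                      standardize = config$standardize),
    retained_volume_count = pre$plan$retained_volume_count,
    removal_count = pre$plan$removal_count,
    n_significant = nrow(sig),
    direction_counts = attr(sig, "direction_counts"),
    fingerprints = list(
      z_sum = signif(sum(feats$z), 12),
      t_sum = signif(sum(stats$t), 12),
      p_min = signif(min(stats$p), 12),
      accuracy_star = if (!is.null(curve)) attr(curve, "accuracy_star")
    )
  )
  structure(list(preproc = pre, features = feats, edge_stats = stats,
                 significant = sig, score_correlations = score_cor,
                 curve = curve, manifest = manifest),
            class = "restconn_result")
}

#' @export
print.restconn_result <- function(x, ...) {
  cat("<restconn_result>\n")
  cat(sprintf("  retained volumes: %d (removed %d)\n",
              x$manifest$retained_volume_count, x$manifest$removal_count))
  cat(sprintf("  significant edges: %d", x$manifest$n_significant))
  dc <- x$manifest$direction_counts
  if (!is.null(dc)) cat(sprintf(" (%s)", paste(names(dc), dc, sep = ": ",
                                               collapse = "; ")))
  cat("\n")
  if (!is.null(x$curve)) {
    cat(sprintf("  LOOCV accuracy: max %.2f%% at k = %d\n",
                100 * attr(x$curve, "accuracy_star"),
                attr(x$curve, "k_star")))
  }
  invisible(x)
}

#' @export
glance.restconn_result <- function(x, ...) {
  tibble(
    retained_volumes = x$manifest$retained_volume_count,
    n_significant = x$manifest$n_significant,
    accuracy_star = if (!is.null(x$curve)) attr(x$curve, "accuracy_star")
                    else NA_real_,
    k_star = if (!is.null(x$curve)) attr(x$curve, "k_star") else NA_integer_
  )
}
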