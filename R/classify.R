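#' Classifier configuration
#'
#' @param kernel SVM kernel (default `"linear"`).
#' @param cost Regularisation constant C > 0 (default 1).
#' @param standardize Standardise features using training-fold mean/sd
#'   before fitting (default `TRUE`); the held-out subject is scaled
#'   with the training statistics, so no information leaks.
#' @param seed Integer seed (the linear SVM on fixed folds is
#'   deterministic; the seed is carried for provenance).
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(kernel = "linear", cost = 1,
                              standardize = TRUE, seed = 1L) {
  if (cost <= 0) stop_restconn("cost must be > 0")
  structure(list(kernel = kernel, cost = cost,
                 standardize = isTRUE(standardize), seed = seed),
            class = "classifier_config")
}

#' Rank features by two-sample t-test p-value
#'
#' Features are ordered by ascending pooled-variance two-sample t-test
#' p-value between the two classes; ties are broken by ascending column
#' index. Features constant in both classes cannot be tested and are
#' ranked last with a warning.
#'
#' @param feature_matrix `subjects x E` matrix.
#' @param labels Factor or vector with exactly two levels.
#' @param scope `"full_sample"` ranks on all subjects (the conventional,
#'   non-nested protocol); ranking within training folds is handled by
#'   [selection_bias_audit()].
#' @return Tibble of class `feature_ranking`: `rank`, `feature`
#'   (column index), `t`, `p`.
#' @export
rank_features <- function(feature_matrix, labels,
                          scope = c("full_sample", "within_fold")) {
  scope <- match.arg(scope)
  X <- as.matrix(feature_matrix)
  f <- as.factor(labels)
  if (nlevels(f) != 2) stop_restconn("labels must have exactly two levels")
  if (min(table(f)) < 2) stop_restconn("need >= 2 subjects per class")
  mask <- matrix(as.numeric(f == levels(f)[1]), 1)
  n_a <- sum(f == levels(f)[1])
  n_b <- sum(f == levels(f)[2])
  t_col <- drop(pooled_t_many(mask, X, n_a, n_b))
  p <- 2 * pt(-abs(t_col), df = n_a + n_b - 2)
  const <- apply(X, 2, function(col) {
    stats::var(col[f == levels(f)[1]]) == 0 &&
      stats::var(col[f == levels(f)[2]]) == 0
  })
  if (any(const)) {
    warn(sprintf("%d constant feature(s) ranked last", sum(const)))
    p[const] <- Inf
    t_col[const] <- 0
  }
  ord <- order(p, seq_along(p))
  out <- tibble(rank = seq_along(ord), feature = ord,
                t = t_col[ord], p = p[ord])
  attr(out, "scope") <- scope
  class(out) <- c("feature_ranking", class(out))
  out
}

# Internal: predictions for every held-out subject using top features.
loocv_predictions <- function(X, f, config) {
  n <- nrow(X)
  vapply(seq_len(n), function(i) {
    tr_x <- X[-i, , drop = FALSE]
    tr_y <- f[-i]
    if (nlevels(droplevels(tr_y)) < 2) {
      stop_restconn("a training fold lost a class")
    }
    te_x <- X[i, , drop = FALSE]
    if (isTRUE(config$standardize)) {
      mu <- colMeans(tr_x)
      sdev <- apply(tr_x, 2, stats::sd)
      sdev[sdev == 0] <- 1
      tr_x <- sweep(sweep(tr_x, 2, mu), 2, sdev, "/")
      te_x <- sweep(sweep(te_x, 2, mu), 2, sdev, "/")
    }
    fit <- e1071::svm(tr_x, tr_y, kernel = config$kernel,
                      cost = config$cost, scale = FALSE)
    as.character(stats::predict(fit, te_x))
  }, character(1))
}

#' Leave-one-out cross-validated accuracy
#'
#' For each held-out subject the classifier is trained on all others
#' (features standardised on the training fold only) and the held-out
#' label predicted.
#'
#' @param feature_matrix `subjects x k` matrix.
#' @param labels Two-level factor or vector.
#' @param config A [classifier_config()].
#' @return Accuracy in `[0, 1]`.
#' @export
loocv_accuracy <- function(feature_matrix, labels,
                           config = classifier_config()) {
  X <- as.matrix(feature_matrix)
  f <- as.factor(labels)
  if (nrow(X) < 3) stop_restconn("need >= 3 subjects")
  if (nlevels(f) != 2) stop_restconn("labels must have exactly two levels")
  pred <- loocv_predictions(X, f, config)
  mean(pred == as.character(f))
}

#' LOOCV accuracy curve over nested feature sets
#'
#' Evaluates LOOCV accuracy using the top-k ranked features for every
#' k = 1..k_max and reports the operating point: the smallest k
#' attaining the maximum accuracy.
#'
#' @param feature_matrix `subjects x E` matrix.
#' @param labels Two-level labels.
#' @param ranking A `feature_ranking` ([rank_features()]); computed on
#'   the full sample when omitted.
#' @param k_max Largest feature-set size (defaults to all ranked
#'   features).
#' @param config A [classifier_config()].
#' @return Tibble of class `accuracy_curve` (`k`, `accuracy`) with
#'   attributes `k_star` and `accuracy_star`.
#' @export
accuracy_curve <- function(feature_matrix, labels, ranking = NULL,
                           k_max = NULL, config = classifier_config()) {
  X <- as.matrix(feature_matrix)
  f <- as.factor(labels)
  ranking <- ranking %||% rank_features(X, f)
  k_max <- k_max %||% nrow(ranking)
  k_max <- check_count(k_max, "k_max", 1L)
  if (k_max > nrow(ranking)) {
    stop_restconn("k_max exceeds the number of ranked features")
  }
  acc <- vapply(seq_len(k_max), function(k) {
    loocv_accuracy(X[, ranking$feature[seq_len(k)], drop = FALSE], f, config)
  }, numeric(1))
  out <- tibble(k = seq_len(k_max), accuracy = acc)
  k_star <- which.max(acc)  # first maximiser = smallest k
  attr(out, "k_star") <- k_star
  attr(out, "accuracy_star") <- acc[k_star]
  attr(out, "config") <- config
  class(out) <- c("accuracy_curve", class(out))
  out
}

#' @export
glance.accuracy_curve <- function(x, ...) {
  tibble(k_star = attr(x, "k_star"),
         accuracy_star = attr(x, "accuracy_star"),
         k_max = nrow(x))
}

#' @param object An `accuracy_curve`.
#' @param ... Unused.
#' @rdname accuracy_curve
#' @export
autoplot.accuracy_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$k, .data$accuracy)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::annotate("point", x = attr(object, "k_star"),
                      y = attr(object, "accuracy_star"),
                      shape = 8, size = 3, colour = "firebrick") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "number of features", y = "LOOCV accuracy",
                  title = sprintf("max %.1f%% at k = %d",
                                  100 * attr(object, "accuracy_star"),
                                  attr(object, "k_star")))
}

#' Quantify selection bias of full-sample feature ranking
#'
#' Compares the maximum of the LOOCV accuracy curve under (a) the
#' conventional non-nested protocol, where features are ranked once on
#' the full sample, against (b) a nested protocol where the ranking is
#' recomputed inside each training fold. On null data protocol (a) is
#' optimistically biased because the held-out subject influenced the
#' feature ranking.
#'
#' @param feature_matrix `subjects x E` candidate feature matrix.
#' @param labels Two-level labels.
#' @param k_max Largest feature-set size (default: all columns).
#' @param config A [classifier_config()].
#' @return Tibble with one row per protocol: `protocol`, `max_accuracy`,
#'   `k_star`, `mean_accuracy` (the curve mean over k). Note that even a
#'   nested curve's *maximum* is optimistic on null data, because picking
#'   the best of `k_max` correlated accuracy estimates is itself a
#'   selection step; the nested `mean_accuracy` is the unbiased
#'   chance-level reference.
#' @export
selection_bias_audit <- function(feature_matrix, labels, k_max = NULL,
                                 config = classifier_config()) {
  X <- as.matrix(feature_matrix)
  f <- as.factor(labels)
  k_max <- k_max %||% ncol(X)

  full <- accuracy_curve(X, f, k_max = k_max, config = config)

  # nested: per held-out subject, rank on the training fold, then record
  # that subject's prediction for every k
  n <- nrow(X)
  correct <- matrix(NA, n, k_max)
  for (i in seq_len(n)) {
    tr_x <- X[-i, , drop = FALSE]
    tr_y <- droplevels(f[-i])
    rk <- rank_features(tr_x, tr_y)
    mu <- colMeans(tr_x)
    sdev <- apply(tr_x, 2, stats::sd)
    sdev[sdev == 0] <- 1
    tr_s <- sweep(sweep(tr_x, 2, mu), 2, sdev, "/")
    te_s <- sweep(sweep(X[i, , drop = FALSE], 2, mu), 2, sdev, "/")
    for (k in seq_len(k_max)) {
      cols <- rk$feature[seq_len(k)]
      fit <- e1071::svm(tr_s[, cols, drop = FALSE], tr_y,
                        kernel = config$kernel, cost = config$cost,
                        scale = FALSE)
      pred <- as.character(stats::predict(fit, te_s[, cols, drop = FALSE]))
      correct[i, k] <- pred == as.character(f[i])
    }
  }
  nested_acc <- colMeans(correct)
  nested_k <- which.max(nested_acc)
  tibble(
    protocol = c("full_sample", "nested"),
    max_accuracy = c(attr(full, "accuracy_star"), nested_acc[nested_k]),
    k_star = c(attr(full, "k_star"), nested_k),
    mean_accuracy = c(mean(full$accuracy), mean(nested_acc))
  )
}
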