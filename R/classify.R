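# Pairwise classification protocol: LDA and Gaussian-RBF SVM under repeated
# random subsampling, with accuracy / sensitivity / specificity / ROC-AUC
# reporting per channel and task pair.

#' Gaussian RBF kernel specification
#'
#' The kernel `k(x, x') = exp(-||x - x'||^2 / (2 sigma^2))`.  With
#' `sigma = NULL` the width is set per fit to the median pairwise Euclidean
#' distance between training points (a scale-adaptive, parameter-free
#' default).
#'
#' @param sigma Kernel width (> 0), or `NULL` for the median heuristic.
#' @param C Soft-margin penalty (> 0).
#' @return Object of class `kernel_spec`.
#' @export
kernel_spec <- function(sigma = NULL, C = 1) {
  if (!is.null(sigma) && (!is.finite(sigma) || sigma <= 0)) {
    stop("sigma must be a positive finite number or NULL")
  }
  if (!is.finite(C) || C <= 0) stop("C must be positive")
  structure(list(kind = "gaussian_rbf", sigma = sigma, C = C),
            class = "kernel_spec")
}

#' Repeated random-subsampling protocol
#'
#' Defaults mirror the package's standard evaluation: per repetition, 50
#' epochs per class are drawn without replacement for training and 50 test
#' epochs (balanced across the two classes) are drawn from the disjoint
#' remainder; the whole procedure is repeated 100 times with fresh draws.
#'
#' @param n_train_per_class Training epochs drawn per class.
#' @param n_test_draw Total test epochs drawn per repetition.
#' @param n_repetitions Number of repetitions (>= 1).
#' @param rng_seed Integer seed making the full evaluation reproducible.
#' @return Object of class `protocol_spec`.
#' @export
protocol_spec <- function(n_train_per_class = 50, n_test_draw = 50,
                          n_repetitions = 100, rng_seed = 1L) {
  stopifnot(n_train_per_class >= 1, n_test_draw >= 1, n_repetitions >= 1)
  structure(list(n_train_per_class = n_train_per_class,
                 n_test_draw = n_test_draw,
                 n_repetitions = n_repetitions,
                 rng_seed = as.integer(rng_seed)),
            class = "protocol_spec")
}

#' Linear discriminant classification with ridge-stabilized pooled covariance
#'
#' Fits Fisher's linear discriminant with equal priors: the projection
#' direction is `S^-1 (mu2 - mu1)` where `S` is the pooled within-class
#' covariance plus a small ridge (`1e-6 * trace(S) / d`, or `1e-8` when the
#' trace is zero) guaranteeing invertibility even for degenerate training
#' sets.  The returned decision score is positive toward the second class
#' level; a score of exactly zero is classified as the first level.
#'
#' @param train_x Numeric training matrix (rows = samples).
#' @param train_y Factor of two class labels, aligned with `train_x` rows.
#' @param test_x Numeric matrix of test samples.
#' @return List with `labels` (factor of predictions) and `scores`
#'   (numeric; larger means more like the second level).
#' @export
fit_predict_lda <- function(train_x, train_y, test_x) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  train_y <- droplevels(as.factor(train_y))
  lev <- levels(train_y)
  if (length(lev) != 2) stop("fit_predict_lda needs exactly two classes")
  if (min(table(train_y)) < 2) stop("need >= 2 training samples per class")
  d <- ncol(train_x)
  x1 <- train_x[train_y == lev[1], , drop = FALSE]
  x2 <- train_x[train_y == lev[2], , drop = FALSE]
  mu1 <- colMeans(x1)
  mu2 <- colMeans(x2)
  S <- ((nrow(x1) - 1) * stats::cov(x1) + (nrow(x2) - 1) * stats::cov(x2)) /
    (nrow(x1) + nrow(x2) - 2)
  ridge <- 1e-6 * sum(diag(S)) / d
  if (ridge <= 0) ridge <- 1e-8
  S <- S + diag(ridge, d)
  w <- solve(S, mu2 - mu1)
  scores <- as.numeric(test_x %*% w - sum(w * (mu1 + mu2)) / 2)
  labels <- factor(ifelse(scores > 0, lev[2], lev[1]), levels = lev)
  list(labels = labels, scores = scores)
}

median_sigma <- function(x) {
  d <- stats::dist(x)
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}

#' Gaussian-RBF support vector classification
#'
#' Soft-margin SVM with the Gaussian RBF kernel, fitted with
#' [e1071::svm()]; the prediction is the sign of the kernel decision
#' function and the continuous decision values are returned for ROC
#' analysis, oriented so that larger scores favour the second class level.
#'
#' @inheritParams fit_predict_lda
#' @param kernel A [kernel_spec()].
#' @return List with `labels` and `scores` as in [fit_predict_lda()].
#' @export
fit_predict_svm <- function(train_x, train_y, test_x,
                            kernel = kernel_spec()) {
  stopifnot(inherits(kernel, "kernel_spec"))
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  train_y <- droplevels(as.factor(train_y))
  lev <- levels(train_y)
  if (length(lev) != 2) stop("fit_predict_svm needs exactly two classes")
  sigma <- if (is.null(kernel$sigma)) median_sigma(train_x) else kernel$sigma
  fit <- e1071::svm(train_x, train_y, type = "C-classification",
                    kernel = "radial", gamma = 1 / (2 * sigma^2),
                    cost = kernel$C, scale = FALSE)
  pred <- stats::predict(fit, test_x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  scores <- as.numeric(dv[, 1])
  # e1071 orients decision values positive toward the class named first in
  # the column label; flip if needed so positive always means level 2
  first_of_pair <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  if (first_of_pair == lev[1]) scores <- -scores
  labels <- factor(as.character(pred), levels = lev)
  list(labels = labels, scores = scores)
}

#' ROC curve and AUC of a binary score
#'
#' Computes the receiver operating characteristic over all score thresholds
#' (sensitivity against 1 - specificity) and the area under it.  The AUC is
#' computed by the rank (Mann-Whitney) formula with average ranks for ties,
#' which equals the trapezoidal area under the empirical ROC and the
#' probability of concordance.
#'
#' @param scores Continuous decision values, larger meaning more positive.
#' @param labels Logical or two-level factor; `TRUE` / second level =
#'   positive class.
#' @param positive Which label value counts as positive (default: `TRUE`
#'   for logical labels, the second factor level otherwise).
#' @return List of class `roc_curve` with `fpr`, `tpr`, `thresholds`
#'   and `auc`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  if (is.logical(labels)) {
    pos <- if (is.null(positive)) TRUE else positive
    is_pos <- labels == pos
  } else {
    labels <- as.factor(labels)
    pos <- if (is.null(positive)) levels(labels)[2] else positive
    is_pos <- labels == pos
  }
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC is undefined: both classes must be present in the labels")
  }
  r <- rank(scores)
  auc <- (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(is_pos[ord])
  fp <- cumsum(!is_pos[ord])
  keep <- c(diff(scores[ord]) != 0, TRUE)   # one point per distinct threshold
  structure(list(fpr = c(0, fp[keep] / n_neg),
                 tpr = c(0, tp[keep] / n_pos),
                 thresholds = c(Inf, scores[ord][keep]),
                 auc = auc),
            class = "roc_curve")
}

resolve_classifier <- function(classifier_id, kernel) {
  if (is.function(classifier_id)) return(classifier_id)
  switch(match.arg(classifier_id, c("lda", "svm_rbf")),
         lda = fit_predict_lda,
         svm_rbf = function(tx, ty, sx) fit_predict_svm(tx, ty, sx, kernel))
}

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sdev <- apply(x, 2, stats::sd)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  list(mu = mu, sd = sdev)
}

standardize_apply <- function(x, z) {
  sweep(sweep(x, 2, z$mu, "-"), 2, z$sd, "/")
}

#' Evaluate a binary classifier under the repeated-subsampling protocol
#'
#' For each repetition: draw `n_train_per_class` epochs per class without
#' replacement for training; from the disjoint remainder draw a balanced
#' test set of `n_test_draw` epochs; z-score features using the training
#' split only; fit and predict; record accuracy, the confusion counts and
#' the ROC AUC.  The positive class for sensitivity/specificity is the
#' first factor level of `y` (the first task of the pair).
#'
#' @param x Numeric feature matrix, one row per epoch.
#' @param y Two-level factor of task labels aligned with `x`.
#' @param classifier_id `"lda"`, `"svm_rbf"`, or a function
#'   `(train_x, train_y, test_x) -> list(labels, scores)` (scores oriented
#'   toward the second level).
#' @param protocol A [protocol_spec()].
#' @param kernel [kernel_spec()] used when `classifier_id = "svm_rbf"`.
#' @param channel_name Optional channel annotation for the result.
#' @return Object of class `evaluation_result`: per-repetition accuracies
#'   (%), their mean and sd, mean sensitivity/specificity (%), mean AUC,
#'   and the summed confusion counts.
#' @export
evaluate_pairwise <- function(x, y, classifier_id = "svm_rbf",
                              protocol = protocol_spec(),
                              kernel = kernel_spec(),
                              channel_name = NA_character_) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  lev <- levels(y)
  if (length(lev) != 2) stop("evaluate_pairwise needs exactly two classes")
  idx_by_class <- split(seq_along(y), y)
  n_test_per_class <- protocol$n_test_draw %/% 2
  need <- protocol$n_train_per_class + n_test_per_class
  for (cl in lev) {
    if (length(idx_by_class[[cl]]) < need) {
      stop("class ", cl, " has ", length(idx_by_class[[cl]]),
           " epochs but the protocol needs at least ", need,
           " (", protocol$n_train_per_class, " train + ",
           n_test_per_class, " test)")
    }
  }
  clf <- resolve_classifier(classifier_id, kernel)
  old_seed <- globalenv()$.Random.seed
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(protocol$rng_seed)
  nrep <- protocol$n_repetitions
  acc <- numeric(nrep)
  sens <- numeric(nrep)
  spec <- numeric(nrep)
  aucs <- numeric(nrep)
  conf <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  for (r in seq_len(nrep)) {
    train_idx <- test_idx <- integer(0)
    for (cl in lev) {
      pool <- idx_by_class[[cl]]
      tr <- sample(pool, protocol$n_train_per_class)
      te <- sample(setdiff(pool, tr), n_test_per_class)
      train_idx <- c(train_idx, tr)
      test_idx <- c(test_idx, te)
    }
    z <- standardize_fit(x[train_idx, , drop = FALSE])
    pred <- clf(standardize_apply(x[train_idx, , drop = FALSE], z),
                y[train_idx],
                standardize_apply(x[test_idx, , drop = FALSE], z))
    truth <- y[test_idx]
    # positive class = first task of the pair
    tp <- sum(pred$labels == lev[1] & truth == lev[1])
    tn <- sum(pred$labels == lev[2] & truth == lev[2])
    fp <- sum(pred$labels == lev[1] & truth == lev[2])
    fn <- sum(pred$labels == lev[2] & truth == lev[1])
    conf <- conf + c(TP = tp, TN = tn, FP = fp, FN = fn)
    acc[r] <- 100 * (tp + tn) / length(truth)
    sens[r] <- 100 * tp / (tp + fn)
    spec[r] <- 100 * tn / (tn + fp)
    aucs[r] <- roc_auc(-pred$scores, truth == lev[1])$auc
  }
  structure(
    list(task_pair = lev, channel_name = channel_name,
         classifier_id = if (is.function(classifier_id)) "custom" else classifier_id,
         accuracies = acc,
         mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
         sensitivity = mean(sens), specificity = mean(spec),
         auc = mean(aucs), confusion = conf,
         protocol = protocol),
    class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(
    "<evaluation_result %s vs %s [%s, %s]: accuracy %.2f%% +/- %.2f, sens %.2f%%, spec %.2f%%, AUC %.3f>\n",
    x$task_pair[1], x$task_pair[2], x$channel_name, x$classifier_id,
    x$mean_accuracy, x$sd_accuracy, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}
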