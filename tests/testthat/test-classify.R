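# fabricate a two-class Gaussian feature set
gauss_classes <- function(n, mu_a, mu_b, sd = 1, seed = 1) {
  set.seed(seed)
  d <- length(mu_a)
  x <- rbind(matrix(rnorm(n * d, sd = sd), n, d) + rep(mu_a, each = n),
             matrix(rnorm(n * d, sd = sd), n, d) + rep(mu_b, each = n))
  list(x = x, y = factor(rep(c("A", "B"), each = n), levels = c("A", "B")))
}

test_that("LDA assigns a test point to the nearest class mean", {
  train <- rbind(matrix(0, 5, 3), matrix(1, 5, 3)) +
    matrix(rnorm(30, sd = 1e-3), 10, 3)
  y <- factor(rep(c("A", "B"), each = 5))
  pred <- fit_predict_lda(train, y, matrix(c(0.9, 0.9, 0.9), 1))
  expect_equal(as.character(pred$labels), "B")
  expect_gt(pred$scores, 0)
})

test_that("an equidistant point scores zero and goes to the first class", {
  d <- gauss_classes(20, c(-1, 0), c(1, 0), seed = 4)
  # symmetrize so the midpoint is exactly equidistant under the pooled metric
  x <- rbind(d$x[d$y == "A", ], -d$x[d$y == "A", ])
  pred <- fit_predict_lda(x, d$y, matrix(0, 1, 2))
  expect_equal(abs(pred$scores), 0, tolerance = 1e-12)
  expect_equal(as.character(pred$labels), "A")
})

test_that("LDA survives singular within-class scatter via the ridge", {
  x <- rbind(matrix(c(0, 0), 3, 2, byrow = TRUE),
             matrix(c(1, 1), 3, 2, byrow = TRUE))  # zero variance everywhere
  y <- factor(rep(c("A", "B"), each = 3))
  pred <- fit_predict_lda(x, y, rbind(c(0.1, 0.1), c(0.9, 0.9)))
  expect_true(all(is.finite(pred$scores)))
  expect_equal(as.character(pred$labels), c("A", "B"))
})

test_that("identically distributed classes classify at chance", {
  accs <- replicate(20, {
    d <- gauss_classes(60, c(0, 0, 0), c(0, 0, 0),
                       seed = sample.int(1e6, 1))
    tr <- c(1:30, 61:90)
    te <- c(31:60, 91:120)
    pred <- fit_predict_lda(d$x[tr, ], d$y[tr], d$x[te, ])
    mean(pred$labels == d$y[te])
  })
  expect_gt(mean(accs), 0.42)
  expect_lt(mean(accs), 0.58)
})

test_that("the RBF SVM solves XOR while LDA stays at chance", {
  set.seed(99)
  n <- 50
  quad <- function(cx, cy) cbind(rnorm(n, cx, 0.2), rnorm(n, cy, 0.2))
  x <- rbind(quad(0, 0), quad(1, 1), quad(0, 1), quad(1, 0))
  y <- factor(rep(c("A", "B"), each = 2 * n))
  tr <- c(1:35, 51:85, 101:135, 151:185)
  te <- setdiff(1:200, tr)
  svm_pred <- fit_predict_svm(x[tr, ], y[tr], x[te, ], kernel_spec(sigma = 0.5))
  lda_pred <- fit_predict_lda(x[tr, ], y[tr], x[te, ])
  expect_gt(mean(svm_pred$labels == y[te]), 0.9)
  expect_lt(abs(mean(lda_pred$labels == y[te]) - 0.5), 0.2)
})

test_that("widely separated classes are perfectly classified by the SVM", {
  d <- gauss_classes(40, c(-10, -10, -10), c(10, 10, 10), sd = 0.5, seed = 2)
  pred <- fit_predict_svm(d$x[c(1:20, 41:60), ], d$y[c(1:20, 41:60)],
                          d$x[c(21:40, 61:80), ])
  expect_equal(mean(pred$labels == d$y[c(21:40, 61:80)]), 1)
  # scores must be oriented: positive toward the second level
  expect_true(all(pred$scores[21:40] > 0))
  expect_true(all(pred$scores[1:20] < 0))
})

test_that("conflicting duplicate training labels do not break the SVM", {
  x <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1), c(0.5, 0.5), c(0.5, 0.5))
  y <- factor(c("A", "B", "A", "B", "A", "B"))
  pred <- fit_predict_svm(x, y, matrix(c(0.2, 0.8), 1),
                          kernel_spec(sigma = 1, C = 0.01))
  expect_true(all(is.finite(pred$scores)))
})

test_that("kernel parameters are validated", {
  expect_error(kernel_spec(sigma = -1), "sigma")
  expect_error(kernel_spec(C = 0), "C")
})

test_that("ROC/AUC calibrates at 1 for separation and 0.5 for noise", {
  r1 <- roc_auc(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3))
  expect_equal(r1$auc, 1)
  set.seed(8)
  n <- 10000
  r2 <- roc_auc(rnorm(n), sample(c(TRUE, FALSE), n, replace = TRUE))
  expect_lt(abs(r2$auc - 0.5), 0.02)
})

test_that("AUC follows the worked four-score example and handles errors", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8),
               factor(c("neg", "neg", "pos", "pos")), positive = "pos")
  expect_equal(r$auc, 0.75)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "undefined")
})

test_that("AUC equals the concordant-pair-count statistic, ties included", {
  set.seed(202)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    scores <- round(rnorm(n), 1)          # coarse rounding forces ties
    is_pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(is_pos) || all(is_pos)) next
    r <- roc_auc(scores, is_pos)
    expect_equal(r$auc, oracle_auc_paircount(scores, is_pos))
    # the curve starts at (0,0), ends at (1,1) and is monotone
    expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
    expect_equal(c(max(r$fpr), max(r$tpr)), c(1, 1))
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  scores <- rnorm(200) + rep(c(0, 1), each = 100)
  labels <- rep(c(0, 1), each = 100)
  mine <- roc_auc(scores, labels == 1)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(mine, ref)
})

test_that("the subsampling protocol yields one accuracy per repetition, reproducibly", {
  d <- gauss_classes(70, c(0, 0, 0), c(2, 2, 2), seed = 10)
  proto <- protocol_spec(n_train_per_class = 30, n_test_draw = 40,
                         n_repetitions = 25, rng_seed = 77)
  r1 <- evaluate_pairwise(d$x, d$y, "lda", proto)
  r2 <- evaluate_pairwise(d$x, d$y, "lda", proto)
  expect_length(r1$accuracies, 25)
  expect_identical(r1$accuracies, r2$accuracies)
  expect_equal(r1$mean_accuracy, mean(r1$accuracies))
  expect_equal(r1$sd_accuracy, sd(r1$accuracies))
  # accuracy identity from the summed confusion counts
  cf <- r1$confusion
  expect_equal((cf[["TP"]] + cf[["TN"]]) / sum(cf) * 100, r1$mean_accuracy)
})

test_that("a degenerate always-first-class classifier gives acc 50, sens 100, spec 0", {
  d <- gauss_classes(60, c(0, 0), c(1, 1), seed = 3)
  always_a <- function(train_x, train_y, test_x) {
    list(labels = factor(rep(levels(train_y)[1], nrow(test_x)),
                         levels = levels(train_y)),
         scores = rep(-1, nrow(test_x)))
  }
  r <- evaluate_pairwise(d$x, d$y, always_a,
                         protocol_spec(20, 30, 10, rng_seed = 5))
  expect_equal(r$mean_accuracy, 50)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 0)
})

test_that("the protocol refuses classes with too few epochs", {
  d <- gauss_classes(30, c(0, 0), c(1, 1), seed = 6)
  expect_error(
    evaluate_pairwise(d$x, d$y, "lda", protocol_spec(28, 10, 5)),
    "needs at least")
})

test_that("high-SNR alpha contrast is recovered at >= 95%, identical profiles at chance", {
  prof <- function(amp, task) {
    task_profile(task, alpha_amp = amp, alpha_freq = 10, beta1_amp = 0.5,
                 beta1_freq = 18, beta2_amp = 0.4, beta2_freq = 24,
                 noise_scale = 0.3, channel_gains = 1)
  }
  make_features <- function(amp_a, amp_b, seed) {
    trials <- c(
      generate_trials(list(prof(amp_a, "RS")), 50, fs = 256, duration_s = 10,
                      seed = seed, channels = "F3"),
      generate_trials(list(prof(amp_b, "MA")), 50, fs = 256, duration_s = 10,
                      seed = seed + 1, channels = "F3"))
    feature_table(segment_trials(trials), "bandpeak",
                  welch_params(nperseg = 256))
  }
  proto <- protocol_spec(n_train_per_class = 30, n_test_draw = 40,
                         n_repetitions = 50, rng_seed = 8)
  ft <- make_features(3.0, 1.0, seed = 60)
  y <- factor(ft$task, levels = c("RS", "MA"))
  r_sep <- evaluate_pairwise(feature_matrix(ft), y, "svm_rbf", proto)
  expect_gte(r_sep$mean_accuracy, 95)
  expect_gt(r_sep$auc, 0.97)
  ft0 <- make_features(1.5, 1.5, seed = 61)
  y0 <- factor(ft0$task, levels = c("RS", "MA"))
  r_null <- evaluate_pairwise(feature_matrix(ft0), y0, "svm_rbf", proto)
  expect_gte(r_null$mean_accuracy, 45)
  expect_lte(r_null$mean_accuracy, 55)
})
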