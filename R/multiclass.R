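# Five-class decoding by two-level max-win voting: level 1 combines the 10
# pairwise classifiers within a channel; level 2 combines channels, each
# vote weighted by the channel's classification accuracy (CA).

#' All unordered task pairs
#'
#' @param tasks Task labels in enumeration order.
#' @return List of length-2 character vectors, C(n, 2) of them.
#' @export
task_pairs <- function(tasks = TASKS) {
  pairs <- utils::combn(tasks, 2, simplify = FALSE)
  pairs
}

#' Max-win vote over pairwise winners
#'
#' Given one predicted winner per unordered task pair, returns the task
#' with the most pairwise wins.  Ties are broken by the fixed task
#' enumeration order (RS < MA < RH < LH < LA).
#'
#' @param pairwise_winners Character vector of winning task labels, one per
#'   pair; must cover all `choose(length(tasks), 2)` pairs.
#' @param tasks Task enumeration (default `TASKS`).
#' @return Single winning task label.
#' @export
maxwin_vote <- function(pairwise_winners, tasks = TASKS) {
  n_pairs <- choose(length(tasks), 2)
  if (length(pairwise_winners) != n_pairs) {
    stop("expected one winner for each of the ", n_pairs,
         " task pairs, got ", length(pairwise_winners))
  }
  bad <- setdiff(unique(pairwise_winners), tasks)
  if (length(bad) > 0) stop("unknown task label(s): ", paste(bad, collapse = ", "))
  wins <- table(factor(pairwise_winners, levels = tasks))
  tasks[which.max(wins)]   # which.max takes the first maximum: ties break
                           # toward the earlier task in enumeration order
}

#' Accuracy-weighted vote across channels
#'
#' Each channel casts one vote for its predicted task, weighted by the
#' channel's classification accuracy; the task with the largest summed
#' weight wins.  With all weights equal this reduces to plurality voting.
#' Ties break by task enumeration order.
#'
#' @param per_channel_labels Named character vector (or list) mapping
#'   channel name to its predicted task.
#' @param channel_weights Named numeric vector of CA weights covering every
#'   voting channel, or `NULL` for unweighted voting.
#' @param tasks Task enumeration.
#' @return Single winning task label.
#' @export
channel_vote <- function(per_channel_labels, channel_weights = NULL,
                         tasks = TASKS) {
  labels <- unlist(per_channel_labels)
  if (length(labels) == 0) stop("channel_vote needs at least one channel")
  if (is.null(channel_weights)) {
    weights <- rep(1, length(labels))
  } else {
    missing_w <- setdiff(names(labels), names(channel_weights))
    if (!is.null(names(labels)) && length(missing_w) > 0) {
      stop("no CA weight for channel(s): ", paste(missing_w, collapse = ", "))
    }
    weights <- if (is.null(names(labels))) unlist(channel_weights)
               else unlist(channel_weights)[names(labels)]
  }
  tally <- tapply(weights, factor(labels, levels = tasks), sum, default = 0)
  tasks[which.max(tally)]
}

# Fit all pairwise classifiers for one channel on (already standardized)
# training data; returns a function mapping a feature matrix to per-row
# max-win task labels.
fit_channel_voter <- function(train_x, train_y, clf, tasks) {
  pairs <- task_pairs(tasks)
  fits <- lapply(pairs, function(pr) {
    sel <- train_y %in% pr
    list(pair = pr, x = train_x[sel, , drop = FALSE],
         y = factor(train_y[sel], levels = pr))
  })
  function(newx) {
    winners <- vapply(fits, function(f) {
      pred <- clf(f$x, f$y, newx)
      as.character(pred$labels)
    }, character(nrow(newx)))
    if (nrow(newx) == 1) winners <- matrix(winners, nrow = 1)
    apply(winners, 1, maxwin_vote, tasks = tasks)
  }
}

#' Multiclass evaluation with two-level max-win voting
#'
#' Per repetition and channel, all `choose(n_tasks, 2)` pairwise
#' classifiers are trained on `n_train_per_class` epochs per task; each
#' channel's label for a test epoch is the max-win winner of its pairwise
#' predictions, and the final label is the CA-weighted channel vote, where
#' each channel's CA is its max-win accuracy on its own training epochs
#' (training-phase estimation).  Test draws are balanced across tasks
#' (`n_test_draw %/% n_tasks` epochs per task) so chance level is exactly
#' `1 / n_tasks`.
#'
#' @param features Feature table ([feature_table()]) covering all tasks and
#'   the requested channels; epochs are matched across channels by
#'   (`trial_id`, `part`).
#' @param channels Channels whose classifiers vote (default F3, F4, C3,
#'   C4).
#' @param classifier_id `"lda"`, `"svm_rbf"` or a classifier function.
#' @param protocol A [protocol_spec()].
#' @param kernel [kernel_spec()] for the SVM.
#' @param weighted Use CA weights at level 2 (default TRUE); otherwise
#'   plurality voting.
#' @param tasks Task enumeration.
#' @return Object of class `multiclass_result`: per-task accuracy (%), sd
#'   over repetitions, overall accuracy and sd.
#' @export
evaluate_multiclass <- function(features, channels = c("F3", "F4", "C3", "C4"),
                                classifier_id = "svm_rbf",
                                protocol = protocol_spec(),
                                kernel = kernel_spec(),
                                weighted = TRUE, tasks = TASKS) {
  stopifnot(all(channels %in% features$channel))
  clf <- resolve_classifier(classifier_id, kernel)
  feats <- features[features$channel %in% channels, , drop = FALSE]
  feats$epoch_key <- paste(feats$trial_id, feats$part, sep = "#")
  # one feature matrix per channel, rows aligned on epoch_key
  keys <- sort(unique(feats$epoch_key))
  by_channel <- lapply(channels, function(ch) {
    sub <- feats[feats$channel == ch, , drop = FALSE]
    sub <- sub[match(keys, sub$epoch_key), , drop = FALSE]
    if (anyNA(sub$task)) stop("channel ", ch, " is missing epochs present elsewhere")
    feature_matrix(sub[, setdiff(names(sub), "epoch_key"), drop = FALSE])
  })
  names(by_channel) <- channels
  task_of_key <- feats$task[match(keys, feats$epoch_key)]
  missing_tasks <- setdiff(tasks, unique(task_of_key))
  if (length(missing_tasks) > 0) {
    stop("tasks absent from the feature table: ",
         paste(missing_tasks, collapse = ", "))
  }
  idx_by_task <- split(seq_along(keys), factor(task_of_key, levels = tasks))
  n_test_per_task <- max(1L, protocol$n_test_draw %/% length(tasks))
  need <- protocol$n_train_per_class + n_test_per_task
  for (tk in tasks) {
    if (length(idx_by_task[[tk]]) < need) {
      stop("task ", tk, " has ", length(idx_by_task[[tk]]),
           " epochs but the protocol needs at least ", need)
    }
  }
  old_seed <- globalenv()$.Random.seed
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(protocol$rng_seed)
  nrep <- protocol$n_repetitions
  per_task_acc <- matrix(NA_real_, nrep, length(tasks),
                         dimnames = list(NULL, tasks))
  overall_acc <- numeric(nrep)
  for (r in seq_len(nrep)) {
    train_idx <- test_idx <- integer(0)
    for (tk in tasks) {
      pool <- idx_by_task[[tk]]
      tr <- sample(pool, protocol$n_train_per_class)
      te <- sample(setdiff(pool, tr), n_test_per_task)
      train_idx <- c(train_idx, tr)
      test_idx <- c(test_idx, te)
    }
    train_y <- factor(task_of_key[train_idx], levels = tasks)
    test_y <- factor(task_of_key[test_idx], levels = tasks)
    ch_labels <- matrix(NA_character_, length(test_idx), length(channels),
                        dimnames = list(NULL, channels))
    ca <- numeric(length(channels))
    names(ca) <- channels
    for (ch in channels) {
      z <- standardize_fit(by_channel[[ch]][train_idx, , drop = FALSE])
      tr_x <- standardize_apply(by_channel[[ch]][train_idx, , drop = FALSE], z)
      te_x <- standardize_apply(by_channel[[ch]][test_idx, , drop = FALSE], z)
      voter <- fit_channel_voter(tr_x, as.character(train_y), clf, tasks)
      ca[ch] <- 100 * mean(voter(tr_x) == as.character(train_y))
      ch_labels[, ch] <- voter(te_x)
    }
    final <- vapply(seq_len(nrow(ch_labels)), function(i) {
      channel_vote(stats::setNames(ch_labels[i, ], channels),
                   channel_weights = if (weighted) ca else NULL,
                   tasks = tasks)
    }, character(1))
    correct <- final == as.character(test_y)
    overall_acc[r] <- 100 * mean(correct)
    for (tk in tasks) {
      sel <- test_y == tk
      per_task_acc[r, tk] <- 100 * mean(correct[sel])
    }
  }
  structure(
    list(channels = channels,
         classifier_id = if (is.function(classifier_id)) "custom" else classifier_id,
         weighted = weighted,
         per_task_accuracy = colMeans(per_task_acc),
         per_task_sd = apply(per_task_acc, 2, stats::sd),
         overall_accuracy = mean(overall_acc),
         overall_sd = stats::sd(overall_acc),
         per_repetition_overall = overall_acc,
         protocol = protocol),
    class = "multiclass_result")
}

#' @export
print.multiclass_result <- function(x, ...) {
  cat(sprintf("<multiclass_result [%s; %s]: overall %.2f%% +/- %.2f>\n",
              paste(x$channels, collapse = ","), x$classifier_id,
              x$overall_accuracy, x$overall_sd))
  for (tk in names(x$per_task_accuracy)) {
    cat(sprintf("  %s: %.2f%% +/- %.2f\n", tk, x$per_task_accuracy[tk],
                x$per_task_sd[tk]))
  }
  invisible(x)
}
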