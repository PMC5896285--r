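# End-to-end orchestration: generate (or load) trials, filter, segment,
# estimate spectra, extract features, then run the pairwise or multiclass
# evaluation from a single declarative config with a global seed.

#' Derive a stage seed from the global seed
#'
#' Each pipeline stage draws randomness from its own child seed, computed
#' by mixing a fixed hash of the stage name into the global seed.  This
#' isolates the stages (changing the number of draws in one stage does not
#' perturb another) without seed collisions.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 2147483647
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with the package's standard
#' defaults: 512 Hz trials of 10 s, 10th-order 50 Hz Butterworth low-pass,
#' 2 s preparation removal and two 4 s epochs per trial, 400-point Hamming
#' Welch estimation at 50% overlap, alpha/beta band-peak features, and a
#' 50-train/50-test 100-repetition subsampling protocol.
#'
#' @param profiles Generator profiles (default [default_profiles()]); or
#'   set `fixture_path` to load trials from disk instead.
#' @param fixture_path Optional path prefix of a fixture written by
#'   [write_fixture()]; overrides the generator.
#' @param n_trials_per_task Trials generated per task (default 100).
#' @param fs,duration_s Sampling rate and trial length.
#' @param cutoff,order Low-pass filter settings.
#' @param prep_duration,n_parts Segmentation settings.
#' @param welch [welch_params()].
#' @param alpha,beta Band definitions.
#' @param extractor_id `"bandpeak"`, `"minmaxmeanstd"` or `"bandpower"`.
#' @param classifier_id `"svm_rbf"` or `"lda"` (or both, for
#'   [run_pairwise()]).
#' @param protocol [protocol_spec()]; its `rng_seed` is overridden by the
#'   stage seed derived from `seed`.
#' @param kernel [kernel_spec()].
#' @param channels Channels analysed (all nine by default).
#' @param multiclass_channels Channels voting in [run_multiclass()].
#' @param outdir Output directory for result CSVs.
#' @param seed Global seed fanned out to the stages.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(profiles = default_profiles(),
                            fixture_path = NULL,
                            n_trials_per_task = 100,
                            fs = 512, duration_s = 10,
                            cutoff = 50, order = 10,
                            prep_duration = 2, n_parts = 2,
                            welch = welch_params(),
                            alpha = alpha_band(), beta = beta_band(),
                            extractor_id = "bandpeak",
                            classifier_id = c("lda", "svm_rbf"),
                            protocol = protocol_spec(),
                            kernel = kernel_spec(),
                            channels = CHANNELS,
                            multiclass_channels = c("F3", "F4", "C3", "C4"),
                            outdir = tempdir(),
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

pipeline_log <- function(...) {
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

# generate -> filter -> segment -> features, shared by both runners
pipeline_features <- function(config) {
  trials <- if (!is.null(config$fixture_path)) {
    pipeline_log("loading trials from fixture ", config$fixture_path)
    read_fixture(config$fixture_path)
  } else {
    pipeline_log("generating ", config$n_trials_per_task,
                 " trials/task at ", config$fs, " Hz")
    generate_trials(config$profiles, config$n_trials_per_task,
                    fs = config$fs, duration_s = config$duration_s,
                    seed = derive_seed(config$seed, "generate"),
                    channels = config$channels)
  }
  pipeline_log("filtering (Butterworth order ", config$order, ", ",
               config$cutoff, " Hz) and segmenting")
  trials <- lapply(trials, lowpass_filter, cutoff = config$cutoff,
                   order = config$order)
  epochs <- segment_trials(trials, prep_duration = config$prep_duration,
                           n_parts = config$n_parts)
  pipeline_log(length(epochs), " epochs; extracting ", config$extractor_id,
               " features")
  feature_table(epochs, config$extractor_id, params = config$welch,
                alpha = config$alpha, beta = config$beta)
}

#' Run the full pairwise experiment
#'
#' Evaluates every task pair at every channel with every configured
#' classifier, writing `pairwise_results.csv` (one row per pair x channel x
#' classifier with mean/sd accuracy, sensitivity, specificity and AUC) and
#' `pairwise_best_channels.csv` (the best channel per pair and classifier)
#' to `config$outdir`.
#'
#' @param config A [pipeline_config()].
#' @param features Optional precomputed [feature_table()] (skips the
#'   generation stages).
#' @return Invisibly, a list with the results data frame, the best-channel
#'   summary and the feature table.
#' @export
run_pairwise <- function(config = pipeline_config(), features = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(features)) features <- pipeline_features(config)
  eval_seed <- derive_seed(config$seed, "evaluate")
  pairs <- task_pairs(intersect(TASKS, unique(features$task)))
  rows <- list()
  for (clf in config$classifier_id) {
    for (pr in pairs) {
      for (ch in config$channels) {
        sub <- features[features$channel == ch & features$task %in% pr, ,
                        drop = FALSE]
        proto <- config$protocol
        proto$rng_seed <- derive_seed(eval_seed,
                                      paste(clf, pr[1], pr[2], ch, sep = ":"))
        res <- evaluate_pairwise(feature_matrix(sub),
                                 factor(sub$task, levels = pr),
                                 classifier_id = clf, protocol = proto,
                                 kernel = config$kernel, channel_name = ch)
        rows[[length(rows) + 1]] <- data.frame(
          task_a = pr[1], task_b = pr[2], channel = ch, classifier = clf,
          mean_accuracy = res$mean_accuracy, sd_accuracy = res$sd_accuracy,
          sensitivity = res$sensitivity, specificity = res$specificity,
          auc = res$auc)
      }
    }
    pipeline_log("finished classifier ", clf)
  }
  results <- do.call(rbind, rows)
  best <- do.call(rbind, lapply(
    split(results, list(results$task_a, results$task_b, results$classifier),
          drop = TRUE),
    function(g) g[which.max(g$mean_accuracy), ]))
  rownames(best) <- NULL
  best <- best[order(best$classifier, match(best$task_a, TASKS),
                     match(best$task_b, TASKS)), ]
  if (!dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)
  utils::write.csv(results, file.path(config$outdir, "pairwise_results.csv"),
                   row.names = FALSE)
  utils::write.csv(best, file.path(config$outdir, "pairwise_best_channels.csv"),
                   row.names = FALSE)
  pipeline_log("wrote ", nrow(results), " result rows to ", config$outdir)
  invisible(list(results = results, best_channels = best,
                 features = features))
}

#' Run the multiclass voting experiment
#'
#' Evaluates the five-class decoder on `config$multiclass_channels` and
#' writes `multiclass_results.csv` (per-task accuracy and sd plus an
#' overall row) to `config$outdir`.
#'
#' @inheritParams run_pairwise
#' @return Invisibly, a list with the `multiclass_result`, its data frame
#'   and the feature table.
#' @export
run_multiclass <- function(config = pipeline_config(), features = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(config$multiclass_channels) < 1) {
    stop("run_multiclass needs at least one voting channel")
  }
  if (is.null(features)) features <- pipeline_features(config)
  proto <- config$protocol
  proto$rng_seed <- derive_seed(config$seed, "multiclass")
  clf <- config$classifier_id[length(config$classifier_id)]
  res <- evaluate_multiclass(features, channels = config$multiclass_channels,
                             classifier_id = clf, protocol = proto,
                             kernel = config$kernel)
  df <- rbind(
    data.frame(task = names(res$per_task_accuracy),
               accuracy = unname(res$per_task_accuracy),
               sd = unname(res$per_task_sd)),
    data.frame(task = "overall", accuracy = res$overall_accuracy,
               sd = res$overall_sd))
  if (!dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)
  utils::write.csv(df, file.path(config$outdir, "multiclass_results.csv"),
                   row.names = FALSE)
  pipeline_log("multiclass overall accuracy ",
               sprintf("%.2f%%", res$overall_accuracy))
  invisible(list(result = res, table = df, features = features))
}

#' Read a pipeline configuration from a JSON file
#'
#' Recognized keys mirror the arguments of [pipeline_config()]; scalar
#' settings map directly, `welch`, `protocol` and `kernel` are nested
#' objects, and `profiles` is a list of objects with the [task_profile()]
#' fields.  Unspecified keys keep the package defaults.
#'
#' @param path JSON file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (key in c("fixture_path", "n_trials_per_task", "fs", "duration_s",
                "cutoff", "order", "prep_duration", "n_parts",
                "extractor_id", "classifier_id", "channels",
                "multiclass_channels", "outdir", "seed")) {
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  }
  if (!is.null(raw$welch)) args$welch <- do.call(welch_params, raw$welch)
  if (!is.null(raw$protocol)) args$protocol <- do.call(protocol_spec, raw$protocol)
  if (!is.null(raw$kernel)) args$kernel <- do.call(kernel_spec, raw$kernel)
  if (!is.null(raw$profiles)) {
    args$profiles <- lapply(raw$profiles, function(p) do.call(task_profile, p))
  }
  do.call(pipeline_config, args)
}
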