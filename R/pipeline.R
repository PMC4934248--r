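#' End-to-end pipeline configuration
#'
#' Bundles the per-stage settings of the synthetic experiment: sensing node
#' geometry, segmentation, per-sequence/cluster HMM size (8 states, 2
#' Gaussians), spectral clustering (`C_max = 10`, local-scaling `K = 7`),
#' the one-class SVM (`nu = 0.01`, median-heuristic kernel width) and the
#' experiment design (8 subjects x 5 activities x 10 repetitions; 240 normal
#' samples for training, remaining normals plus all falls for testing).
#'
#' @param sensing,segmentation,hmm,spectral,osvm,experiment Named lists
#'   overriding individual defaults within each stage.
#' @param seed Global seed; per-stage seeds are derived from it by fixed
#'   offsets so every stage is independently reproducible.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sensing = list(), segmentation = list(),
                            hmm = list(), spectral = list(), osvm = list(),
                            experiment = list(), seed = 1L) {
  merge <- function(defaults, user) {
    stopifnot(all(names(user) %in% names(defaults)))
    utils::modifyList(defaults, user)
  }
  cfg <- list(
    sensing = merge(list(config = partition_config(),
                         h = impulse_response(),
                         noise_sd = 0.02, clip = 2.0), sensing),
    segmentation = merge(list(threshold = NULL, min_duration_s = 0.6,
                              hangover_s = 0.5), segmentation),
    hmm = merge(list(n_states = 8, n_mix = 2, max_iter = 100, tol = 1e-4),
                hmm),
    spectral = merge(list(C_max = 10, K = 7), spectral),
    osvm = merge(list(nu = 0.01, gamma = NULL, standardize = TRUE), osvm),
    experiment = merge(list(n_subjects = 8,
                            activities = c("falling", "sitting_down",
                                           "standing_up", "walking",
                                           "jogging"),
                            reps_per_activity = 10,
                            train_size = 240,
                            abnormal_activity = "falling"), experiment),
    seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

# fixed per-stage seed offsets (all < 2^31 for any seed < 2^30)
.stage_seed <- function(seed, stage) {
  offs <- c(simulate = 11L, split = 23L, perseq = 101L, cluster_models = 307L,
            onehmm = 401L)
  (as.integer(seed) %% 1009001L) * 1000L + offs[[stage]]
}

#' Run the full synthetic abnormal-activity detection experiment
#'
#' The two-phase pipeline on a generated dataset: (1) simulate the activity
#' streams and segment them into samples by short-time energy; (2) set aside
#' all abnormal (fall) samples for testing, draw `train_size` normal samples
#' for unsupervised training, and keep the remaining normals plus all falls
#' as the mixed test set; (3) phase one — per-sequence HMMs, symmetrized-KL
#' distances, self-tuning spectral clustering of the training samples; (4)
#' phase two — cluster HMMs, cluster-likelihood features, one-class SVM; (5)
#' score the test set with the trained detector and with the single-HMM
#' baseline, and evaluate both by ROC/AUC. Training never sees activity
#' labels; they are used only to hold out falls and to evaluate.
#'
#' @param config A [pipeline_config()].
#' @param seed Optional override of `config$seed`.
#' @param verbose Print stage progress to stderr.
#' @return Object of class `experiment_result`: cluster solution, models,
#'   test scores and labels, `auc_osvm`, `auc_onehmm`, timings, config.
#' @export
run_experiment <- function(config = pipeline_config(), seed = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  sd0 <- config$seed
  say <- function(...) if (verbose) message(sprintf(...))
  tic <- function() proc.time()[["elapsed"]]
  timings <- c()
  t0 <- tic()

  ex <- config$experiment
  say("simulating %d x %d x %d streams",
      ex$n_subjects, length(ex$activities), ex$reps_per_activity)
  streams <- generate_dataset(
    n_subjects = ex$n_subjects, activities = ex$activities,
    reps_per_activity = ex$reps_per_activity,
    seed = .stage_seed(sd0, "simulate"),
    config = config$sensing$config, h = config$sensing$h,
    noise_sd = config$sensing$noise_sd, clip = config$sensing$clip)
  timings["simulate"] <- tic() - t0; t0 <- tic()

  seg <- config$segmentation
  samples <- list(); labels <- character(0)
  for (st in streams) {
    parts <- segment_stream(st, threshold = seg$threshold,
                            min_duration_s = seg$min_duration_s,
                            hangover_s = seg$hangover_s)
    for (p in parts) {
      samples[[length(samples) + 1L]] <- p
      labels <- c(labels, st$metadata$activity)
    }
  }
  say("segmented %d streams into %d samples", length(streams),
      length(samples))
  timings["segment"] <- tic() - t0; t0 <- tic()

  abnormal <- labels == ex$abnormal_activity
  normal_idx <- which(!abnormal)
  if (ex$train_size > length(normal_idx))
    stop(sprintf("train_size %d exceeds the %d available normal samples",
                 ex$train_size, length(normal_idx)))
  train_idx <- .with_seed(.stage_seed(sd0, "split"), function()
    sort(sample(normal_idx, ex$train_size)))
  test_idx <- sort(c(setdiff(normal_idx, train_idx), which(abnormal)))
  train <- samples[train_idx]
  test <- samples[test_idx]
  test_abnormal <- abnormal[test_idx]

  say("phase 1: %d per-sequence HMMs + distances", length(train))
  sd_ <- sequence_distances(train, n_states = config$hmm$n_states,
                            n_mix = config$hmm$n_mix,
                            seed = .stage_seed(sd0, "perseq"),
                            max_iter = config$hmm$max_iter,
                            tol = config$hmm$tol)
  timings["distances"] <- tic() - t0; t0 <- tic()

  sol <- cluster_distances(sd_$D,
                           spectral_config(C_max = config$spectral$C_max,
                                           K = config$spectral$K))
  say("phase 1: C_best = %d", sol$C_best)
  timings["cluster"] <- tic() - t0; t0 <- tic()

  say("phase 2: cluster models + OSVM")
  cmods <- fit_cluster_models(train, sol$labels,
                              n_states = config$hmm$n_states,
                              n_mix = config$hmm$n_mix,
                              seed = .stage_seed(sd0, "cluster_models"),
                              max_iter = config$hmm$max_iter,
                              tol = config$hmm$tol)
  feat_train <- extract_features(train, cmods)
  osvm <- train_osvm(feat_train, nu = config$osvm$nu,
                     gamma = config$osvm$gamma,
                     standardize = config$osvm$standardize,
                     cluster_labels = sol$labels)
  feat_test <- extract_features(test, cmods)
  scores_osvm <- decision_score(feat_test, osvm)
  timings["osvm"] <- tic() - t0; t0 <- tic()

  base <- onehmm_baseline(train, test, n_states = config$hmm$n_states,
                          n_mix = config$hmm$n_mix,
                          seed = .stage_seed(sd0, "onehmm"),
                          max_iter = config$hmm$max_iter,
                          tol = config$hmm$tol)
  timings["onehmm"] <- tic() - t0

  roc_osvm <- roc_auc(scores_osvm, test_abnormal)
  roc_onehmm <- roc_auc(base$scores, test_abnormal)
  say("AUC: SC+OSVM %.3f, OneHMM %.3f", roc_osvm$auc, roc_onehmm$auc)

  structure(list(
    n_samples = length(samples), n_train = length(train),
    n_test = length(test), n_test_abnormal = sum(test_abnormal),
    clusters = sol, cluster_models = cmods, osvm = osvm,
    scores_osvm = scores_osvm, scores_onehmm = base$scores,
    test_abnormal = test_abnormal, test_activity = labels[test_idx],
    roc_osvm = roc_osvm, roc_onehmm = roc_onehmm,
    auc_osvm = roc_osvm$auc, auc_onehmm = roc_onehmm$auc,
    timings = timings, seed = sd0, config = config),
    class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf(paste0(
    "experiment_result (seed %d): %d samples, %d train / %d test ",
    "(%d abnormal)\n  C_best = %d; AUC SC+OSVM = %.3f, OneHMM = %.3f\n"),
    x$seed, x$n_samples, x$n_train, x$n_test, x$n_test_abnormal,
    x$clusters$C_best, x$auc_osvm, x$auc_onehmm))
  invisible(x)
}

#' Write an experiment report as JSON
#'
#' Deterministic (byte-identical for identical config and seed) summary:
#' sample counts, selected cluster count, alignment-cost curve, per-sample
#' test scores and both AUCs.
#'
#' @param result An `experiment_result`.
#' @param path Output path.
#' @export
write_report <- function(result, path) {
  obj <- list(seed = result$seed, n_samples = result$n_samples,
              n_train = result$n_train, n_test = result$n_test,
              n_test_abnormal = result$n_test_abnormal,
              C_best = result$clusters$C_best,
              alignment_costs = as.list(result$clusters$costs),
              auc_osvm = result$auc_osvm, auc_onehmm = result$auc_onehmm,
              scores_osvm = result$scores_osvm,
              scores_onehmm = result$scores_onehmm,
              test_abnormal = result$test_abnormal,
              test_activity = result$test_activity)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
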