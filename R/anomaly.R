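#' Fit one HMM per activity cluster
#'
#' Multi-sequence Baum-Welch on each cluster of (unlabeled) normal training
#' sequences, producing the cluster profile models used for feature
#' extraction.
#'
#' @param sequences List of observation sequences.
#' @param labels Integer cluster labels (1..C), every cluster non-empty.
#' @param n_states,n_mix Model size (defaults 8 states, 2 components).
#' @param seed Base seed; cluster `j` is fitted with `seed + j`.
#' @param ... Passed to [fit_hmm()].
#' @return List of `hmm_params`, one per cluster.
#' @export
fit_cluster_models <- function(sequences, labels, n_states = 8, n_mix = 2,
                               seed = 1L, ...) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(sequences))
  C <- max(labels)
  if (!setequal(unique(labels), seq_len(C)))
    stop("labels must cover 1..C with every cluster non-empty")
  lapply(seq_len(C), function(j)
    fit_hmm(sequences[labels == j], n_states = n_states, n_mix = n_mix,
            seed = seed + j, ...))
}

#' Cluster-likelihood feature vectors
#'
#' Maps each variable-length sequence to a fixed `C`-dimensional feature
#' vector whose `j`-th component is the forward-algorithm log-likelihood of
#' the sequence under cluster model `j`. By default each component is
#' divided by the sequence length (the same per-sample normalization the
#' likelihood matrix uses), so features of sequences with different
#' durations are comparable; set `per_sample = FALSE` for raw
#' log-likelihoods.
#'
#' @param sequences One sequence or a list of sequences.
#' @param cluster_models List of `C` `hmm_params` from
#'   [fit_cluster_models()].
#' @param per_sample Normalize by sequence length (default `TRUE`).
#' @return `N x C` numeric matrix (one row per sequence).
#' @export
extract_features <- function(sequences, cluster_models, per_sample = TRUE) {
  if (!is.list(sequences) || inherits(sequences, "sensor_stream"))
    sequences <- list(sequences)
  obs <- lapply(sequences, .as_obs)
  X <- vapply(cluster_models, function(m)
    as.numeric(cpp_hmm_loglik_many(obs, m$pi, m$A, m$w, m$mu, m$sigma2)),
    numeric(length(obs)))
  X <- matrix(X, nrow = length(obs))
  if (per_sample) X <- X / vapply(obs, nrow, 1L)
  colnames(X) <- paste0("cluster", seq_along(cluster_models))
  X
}

#' Train a one-class SVM (support vector data description)
#'
#' Finds the minimum-enclosing sphere of the training features in the RBF
#' kernel space, allowing a `nu`-controlled fraction of outliers: the dual
#' `min_alpha alpha' K alpha - alpha' diag(K)` over the simplex with box
#' bound `alpha_i <= 1/(nu * n)` is solved as a quadratic program. The radius
#' `R` is the kernel-space distance from the center to the boundary support
#' vectors (those with interior coefficients), taken as their median for
#' robustness. Features are standardized per component (training mean/sd)
#' before the kernel by default, since cluster log-likelihoods live on very
#' different scales.
#'
#' @param features `n x C` matrix of training feature vectors.
#' @param nu Outlier-fraction parameter (default 0.01): at most a `nu`
#'   fraction of the training points lies strictly outside the sphere.
#' @param gamma RBF kernel width `k(x, y) = exp(-gamma ||x - y||^2)`;
#'   `NULL` for the median heuristic `1 / (2 * median ||x_i - x_j||^2)`.
#'   When `cluster_labels` are supplied the median runs over within-cluster
#'   pairs only: normal activity is multimodal in feature space, and the
#'   kernel width should match the spread *within* a mode (the same local
#'   notion of scale the affinity kernel uses), not the distance between
#'   modes.
#' @param standardize Standardize feature columns before the kernel.
#' @param cluster_labels Optional cluster labels of the training rows, used
#'   only by the `gamma` heuristic. These come from the unsupervised
#'   clustering stage, never from activity annotations.
#' @return Object of class `osvm_model`.
#' @export
train_osvm <- function(features, nu = 0.01, gamma = NULL,
                       standardize = TRUE, cluster_labels = NULL) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 training points")
  if (nu <= 0 || nu > 1) stop("nu must be in (0, 1]")
  center <- if (standardize) colMeans(X) else rep(0, ncol(X))
  scale_ <- if (standardize) {
    s <- apply(X, 2, stats::sd)
    ifelse(s > 0, s, 1)
  } else rep(1, ncol(X))
  Xs <- sweep(sweep(X, 2, center), 2, scale_, `/`)
  D2 <- as.matrix(stats::dist(Xs))^2
  if (is.null(gamma)) {
    med <- if (is.null(cluster_labels)) {
      stats::median(D2[upper.tri(D2)])
    } else {
      stopifnot(length(cluster_labels) == n)
      stats::median(unlist(lapply(unique(cluster_labels), function(j) {
        d <- D2[cluster_labels == j, cluster_labels == j, drop = FALSE]
        d[upper.tri(d)]
      })))
    }
    gamma <- if (is.finite(med) && med > 0) 1 / (2 * med) else 1
  }
  Km <- exp(-gamma * D2)
  ub <- 1 / (nu * n)
  # ipop: min c'a + a'Ha/2  s.t.  b <= Aa <= b + r,  l <= a <= u
  sol <- kernlab::ipop(c = -diag(Km), H = 2 * Km,
                       A = matrix(1, 1, n), b = 1, r = 0,
                       l = rep(0, n), u = rep(ub, n), sigf = 9)
  alpha <- kernlab::primal(sol)
  alpha <- pmin(pmax(alpha, 0), ub)
  alpha[alpha <= 1e-6 * ub] <- 0   # drop numerically inactive coefficients
  # project back onto the feasible set {0 <= a <= ub, sum a = 1}: spread the
  # mass deficit over coordinates with headroom (the deficit is ~1e-7)
  for (it in 1:50) {
    deficit <- 1 - sum(alpha)
    if (abs(deficit) < 1e-14) break
    free <- if (deficit > 0) alpha > 0 & alpha < ub else alpha > 0
    alpha[free] <- alpha[free] + deficit * alpha[free] / sum(alpha[free])
    alpha <- pmin(pmax(alpha, 0), ub)
  }
  aKa <- as.numeric(t(alpha) %*% Km %*% alpha)
  # kernel-space squared distance of training point i to the center
  d2 <- diag(Km) - 2 * as.numeric(Km %*% alpha) + aKa
  tol <- 1e-6 * ub
  boundary <- which(alpha > tol & alpha < ub - tol)
  R2 <- if (length(boundary) > 0) stats::median(d2[boundary])
        else if (any(alpha > tol)) max(d2[alpha > tol]) else 0
  keep <- which(alpha > tol)
  structure(list(alpha = alpha[keep], sv = Xs[keep, , drop = FALSE],
                 sv_index = keep, gamma = gamma, nu = nu, R2 = R2,
                 aKa = aKa, n_train = n,
                 feature_center = center, feature_scale = scale_,
                 train_scores = R2 - d2),
            class = "osvm_model")
}

#' @export
print.osvm_model <- function(x, ...) {
  cat(sprintf("osvm_model: %d support vectors / %d points, nu = %g, gamma = %.4g, R^2 = %.4g\n",
              length(x$alpha), x$n_train, x$nu, x$gamma, x$R2))
  invisible(x)
}

#' Decision score of the one-class SVM
#'
#' `score(x) = R^2 - ||phi(x) - a||^2` via the kernel expansion: positive
#' inside the sphere of normal activity, negative (abnormal) outside. The
#' continuous score is kept so ROC curves can sweep the operating point.
#'
#' @param x Feature vector or `n x C` matrix (raw, unstandardized scale).
#' @param model An `osvm_model`.
#' @return Numeric scores, one per row; larger means more normal.
#' @export
decision_score <- function(x, model) {
  X <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  Xs <- sweep(sweep(X, 2, model$feature_center), 2, model$feature_scale, `/`)
  cross <- sapply(seq_len(nrow(model$sv)), function(i)
    exp(-model$gamma * rowSums(sweep(Xs, 2, model$sv[i, ])^2)))
  cross <- matrix(cross, nrow = nrow(Xs))
  d2 <- 1 - 2 * as.numeric(cross %*% model$alpha) + model$aKa
  model$R2 - d2
}

#' @method predict osvm_model
#' @export
predict.osvm_model <- function(object, newdata, ...) {
  s <- decision_score(newdata, object)
  ifelse(s < 0, "abnormal", "normal")
}

#' Single-HMM baseline scores
#'
#' Profiles all normal training sequences with one HMM (no clustering) and
#' scores test sequences by their length-normalized log-likelihood; a
#' threshold on that score separates normal from abnormal, and sweeping it
#' yields the baseline ROC.
#'
#' @param train_sequences,test_sequences Lists of observation sequences.
#' @param n_states,n_mix Model size.
#' @param seed Fit seed.
#' @param ... Passed to [fit_hmm()].
#' @return List with `model` and `scores` (length-normalized log-likelihood
#'   per test sequence; larger means more normal).
#' @export
onehmm_baseline <- function(train_sequences, test_sequences, n_states = 8,
                            n_mix = 2, seed = 1L, ...) {
  if (length(train_sequences) == 0) stop("empty training set")
  m <- fit_hmm(train_sequences, n_states = n_states, n_mix = n_mix,
               seed = seed, ...)
  obs <- lapply(test_sequences, .as_obs)
  ll <- as.numeric(cpp_hmm_loglik_many(obs, m$pi, m$A, m$w, m$mu, m$sigma2))
  list(model = m, scores = ll / vapply(obs, nrow, 1L))
}

#' Serialize / restore a one-class SVM model as JSON
#'
#' @param model An `osvm_model`.
#' @param path File path.
#' @return `osvm_from_json` returns an `osvm_model`.
#' @export
osvm_to_json <- function(model, path) {
  obj <- unclass(model)
  obj$sv <- as.matrix(obj$sv)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname osvm_to_json
#' @export
osvm_from_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  o$sv <- matrix(unlist(o$sv), nrow = length(o$alpha))
  structure(o, class = "osvm_model")
}
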