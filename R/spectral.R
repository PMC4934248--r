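#' Self-tuning spectral clustering configuration
#'
#' @param C_max Largest candidate cluster count (default 10).
#' @param K Neighbor index for local scaling: the kernel width at point `i`
#'   is its distance to its `K`-th nearest neighbor (default 7).
#' @param step Initial gradient-descent step on the Givens angles.
#' @param max_iter Maximum gradient sweeps for the rotation recovery.
#' @param tol Relative alignment-cost convergence tolerance.
#' @param quality_band Candidates whose normalized alignment quality
#'   `1 - (J/N - 1)/c` lies within this band of the best quality count as
#'   "minimal cost"; the largest such candidate is selected. The
#'   normalization by `c` makes candidates of different sizes comparable
#'   (the raw cost's ceiling grows with `c`), following the selection rule
#'   of the rotation-based self-tuning algorithm this module implements.
#' @return Object of class `spectral_config`.
#' @export
spectral_config <- function(C_max = 10, K = 7, step = 0.1, max_iter = 200,
                            tol = 1e-6, quality_band = 0.001) {
  stopifnot(C_max >= 2, K >= 1, step > 0, max_iter >= 1, tol > 0,
            quality_band >= 0)
  structure(list(C_max = C_max, K = K, step = step, max_iter = max_iter,
                 tol = tol, quality_band = quality_band),
            class = "spectral_config")
}

#' Local scaling parameters
#'
#' `sigma_i` is the distance from point `i` to its `K`-th nearest neighbor
#' (self excluded), so the affinity kernel width adapts to the local density
#' of each point's neighborhood. Scales of duplicated points are floored.
#'
#' @param D Symmetric distance matrix.
#' @param K Neighbor index.
#' @param floor Lower bound for degenerate (duplicate-point) scales.
#' @return Numeric vector of length `N`.
#' @export
local_scales <- function(D, K = 7, floor = 1e-12) {
  D <- as.matrix(D)
  N <- nrow(D)
  if (K >= N) stop("K must be below the number of points")
  s <- vapply(seq_len(N), function(i) sort(D[i, -i], partial = K)[K], 0)
  pmax(s, floor)
}

#' Locally scaled affinity matrix
#'
#' `shat_ij = exp(-d_ij^2 / (sigma_i sigma_j))` off the diagonal, 0 on it.
#' With all scales equal this reduces to the single-width Gaussian kernel.
#'
#' @param D Symmetric distance matrix.
#' @param sigma Per-point scales from [local_scales()].
#' @return Symmetric matrix with entries in `[0, 1]` and zero diagonal.
#' @export
affinity <- function(D, sigma) {
  D <- as.matrix(D)
  stopifnot(length(sigma) == nrow(D), all(sigma > 0))
  A <- exp(-D^2 / outer(sigma, sigma))
  diag(A) <- 0
  (A + t(A)) / 2
}

#' Symmetric normalized graph Laplacian
#'
#' `La = D^{-1/2} S D^{-1/2}` with `d_ii` the vertex degrees. Its largest
#' eigenvalue is 1 (eigenvector `D^{1/2} 1`), with multiplicity equal to the
#' number of connected components.
#'
#' @param A Affinity matrix with positive degrees.
#' @return Symmetric matrix.
#' @export
normalized_laplacian <- function(A) {
  A <- as.matrix(A)
  d <- rowSums(A)
  if (any(d <= 0)) stop("isolated vertex: zero degree")
  La <- A / sqrt(outer(d, d))
  (La + t(La)) / 2
}

# Givens rotation in dimension c acting on coordinates (i, j)
.givens <- function(c, i, j, th) {
  G <- diag(c)
  G[i, i] <- cos(th); G[j, j] <- cos(th)
  G[i, j] <- -sin(th); G[j, i] <- sin(th)
  G
}

.rotation_from_angles <- function(theta, pairs, c) {
  R <- diag(c)
  for (k in seq_along(theta))
    R <- R %*% .givens(c, pairs[k, 1], pairs[k, 2], theta[k])
  R
}

# alignment cost of a rotated eigenvector matrix; rows that are numerically
# zero (possible when an eigensolver returns a degenerate-subspace basis
# supported on a subset of graph components) are unassignable and charged
# the per-row maximum cost.
.alignment_cost <- function(Z) {
  Z2 <- Z^2
  mi <- max.col(Z2, ties.method = "first")
  zm2 <- Z2[cbind(seq_len(nrow(Z)), mi)]
  dead <- zm2 <= 1e-12 * max(Z2)
  zm2 <- pmax(zm2, 1e-300)
  ratio <- rowSums(Z2) / zm2
  ratio[dead] <- ncol(Z)
  list(J = sum(ratio), mi = mi, zm2 = zm2)
}

# analytic gradient of the alignment cost wrt a single Givens angle,
# given the current rotated matrix Z and the sensitivity A = X dR_k
.angle_grad <- function(Z, A) {
  Z2 <- Z^2
  mi <- max.col(Z2, ties.method = "first")
  idx <- cbind(seq_len(nrow(Z)), mi)
  zm <- Z[idx]
  zm2 <- pmax(zm^2, 1e-300)
  zm3 <- ifelse(zm >= 0, 1, -1) * pmax(abs(zm)^3, 1e-300)
  sum(2 * Z * A / zm2) - sum(2 * rowSums(Z2) * A[idx] / zm3)
}

#' Recover the rotation aligning eigenvectors with cluster indicators
#'
#' Finds an orthogonal rotation `R` (a product of `c(c-1)/2` Givens
#' rotations) of the top-`c` eigenvector matrix `X` that minimizes the
#' alignment cost `J = sum_ij Z_ij^2 / M_i^2` (with `Z = X R` and `M_i` the
#' largest-magnitude entry of row `i`): in a perfectly aligned basis every
#' row has a single non-zero entry and `J = N`. The cost is minimized by
#' gradient descent on the Givens angles with backtracking step control.
#'
#' @param X `N x c` matrix of stacked eigenvectors (orthonormal columns).
#' @param theta_init Optional initial angles (e.g. the previous candidate's
#'   solution when scanning cluster counts); zeros otherwise.
#' @param config A [spectral_config()] (step, iteration cap, tolerance).
#' @return List with `Z`, `R`, `J`, `theta`, `pairs`, `Mi` (row maxima of
#'   `Z`), `converged`, and `C = ncol(X)`. `J(identity)` is never exceeded.
#' @export
align_rotation <- function(X, theta_init = NULL, config = spectral_config()) {
  X <- as.matrix(X)
  c <- ncol(X)
  if (c < 2) stop("need at least 2 eigenvectors")
  pairs <- t(utils::combn(c, 2))
  K <- nrow(pairs)
  theta <- if (is.null(theta_init)) numeric(K) else {
    stopifnot(length(theta_init) == K)
    as.numeric(theta_init)
  }
  cost_of <- function(th) {
    Z <- X %*% .rotation_from_angles(th, pairs, c)
    .alignment_cost(Z)$J
  }
  # a warm start must never do worse than the zero-angle start
  if (!is.null(theta_init) && cost_of(numeric(K)) < cost_of(theta))
    theta <- numeric(K)

  steps <- rep(config$step, K)   # per-angle adaptive step sizes
  J <- cost_of(theta)
  converged <- FALSE
  for (sweep in seq_len(config$max_iter)) {
    J_sweep <- J
    # prefix products G_1..G_{k-1} maintained as the sweep advances
    Gs <- lapply(seq_len(K), function(k)
      .givens(c, pairs[k, 1], pairs[k, 2], theta[k]))
    post <- vector("list", K + 1)      # post[[k]] = G_k ... G_K
    post[[K + 1]] <- diag(c)
    for (k in rev(seq_len(K))) post[[k]] <- Gs[[k]] %*% post[[k + 1]]
    XP <- X                            # X %*% (G_1 ... G_{k-1})
    for (k in seq_len(K)) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      th <- theta[k]
      G <- .givens(c, i, j, th)
      dG <- matrix(0, c, c)
      dG[i, i] <- -sin(th); dG[j, j] <- -sin(th)
      dG[i, j] <- -cos(th); dG[j, i] <- cos(th)
      Z <- XP %*% (G %*% post[[k + 1]])
      g <- .angle_grad(Z, XP %*% (dG %*% post[[k + 1]]))
      if (abs(g) > 1e-12) {
        while (steps[k] > 1e-10) {
          cand <- th - steps[k] * g
          Gc <- .givens(c, i, j, cand)
          Jc <- .alignment_cost(XP %*% (Gc %*% post[[k + 1]]))$J
          if (Jc < J) {
            theta[k] <- cand
            G <- Gc
            J <- Jc
            steps[k] <- min(steps[k] * 1.2, 1)
            break
          }
          steps[k] <- steps[k] / 2
        }
        steps[k] <- max(steps[k], 1e-6)  # allow growth again next sweep
      }
      XP <- XP %*% G
    }
    if ((J_sweep - J) <= config$tol * (abs(J_sweep) + 1e-300)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("rotation alignment did not converge; returning best-so-far")
  R <- .rotation_from_angles(theta, pairs, c)
  Z <- X %*% R
  mi <- max.col(Z^2, ties.method = "first")
  list(Z = Z, R = R, J = .alignment_cost(Z)$J, theta = theta, pairs = pairs,
       Mi = Z[cbind(seq_len(nrow(Z)), mi)], converged = converged, C = c)
}

#' Cluster with automatic selection of the cluster count
#'
#' Scans candidate cluster counts `c = 2..C_max`: for each, stacks the top
#' `c` eigenvectors of the normalized Laplacian, recovers the best aligning
#' rotation (warm-started from the previous candidate's angles, with a cold
#' restart as a safeguard) and records the alignment cost `J(c)`. The
#' selected count is the *largest* `c` whose normalized alignment quality
#' `1 - (J/N - 1)/c` falls within `quality_band` of the best candidate
#' (minimal-cost selection made comparable across candidate sizes); points
#' are assigned to the cluster of their largest squared rotated coordinate.
#'
#' @param La Normalized Laplacian from [normalized_laplacian()].
#' @param config A [spectral_config()].
#' @return Object of class `cluster_solution`: `labels`, `C_best`, `costs`
#'   (named vector `J(c)`), `quality` (normalized alignment quality per
#'   candidate), `eigenvalues`, and the selected `rotation`.
#' @export
select_and_cluster <- function(La, config = spectral_config()) {
  La <- as.matrix(La)
  N <- nrow(La)
  C_max <- min(config$C_max, N - 1)
  if (C_max < 2) stop("too few points to cluster")
  eig <- eigen(La, symmetric = TRUE)
  vecs <- eig$vectors[, seq_len(C_max), drop = FALSE]
  # canonical signs: largest-magnitude entry of each eigenvector positive
  for (j in seq_len(ncol(vecs))) {
    m <- which.max(abs(vecs[, j]))
    if (vecs[m, j] < 0) vecs[, j] <- -vecs[, j]
  }
  costs <- stats::setNames(rep(NA_real_, C_max - 1), 2:C_max)
  rotations <- vector("list", C_max - 1)
  prev_theta <- NULL
  prev_pairs <- NULL
  for (c in 2:C_max) {
    pairs <- t(utils::combn(c, 2))
    theta0 <- numeric(nrow(pairs))
    if (!is.null(prev_theta)) {
      key_new <- paste(pairs[, 1], pairs[, 2])
      key_old <- paste(prev_pairs[, 1], prev_pairs[, 2])
      hit <- match(key_old, key_new)
      theta0[hit[!is.na(hit)]] <- prev_theta[!is.na(hit)]
    }
    # optimize from the warm start and from rest; keep the better minimum
    # (the warm chain can inherit a poor basin from the previous candidate)
    Xc <- vecs[, seq_len(c), drop = FALSE]
    rot <- align_rotation(Xc, theta_init = theta0, config = config)
    rot_cold <- align_rotation(Xc, config = config)
    if (rot_cold$J < rot$J) rot <- rot_cold
    costs[as.character(c)] <- rot$J
    rotations[[c - 1]] <- rot
    prev_theta <- rot$theta
    prev_pairs <- rot$pairs
  }
  quality <- 1 - (costs / N - 1) / as.integer(names(costs))
  minimal <- which(quality >= max(quality) - config$quality_band)
  C_best <- as.integer(names(costs)[max(minimal)])
  rot <- rotations[[C_best - 1]]
  labels <- max.col(rot$Z^2, ties.method = "first")
  # guard: renumber if the argmax assignment left a candidate column empty
  used <- sort(unique(labels))
  labels <- match(labels, used)
  structure(list(labels = labels, C_best = length(used),
                 C_selected = C_best, costs = costs, quality = quality,
                 eigenvalues = eig$values, rotation = rot),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("cluster_solution: %d clusters over %d points (costs J(c): %s)\n",
              x$C_best, length(x$labels),
              paste(sprintf("%s=%.1f", names(x$costs), x$costs),
                    collapse = " ")))
  invisible(x)
}

#' Distance matrix to cluster solution
#'
#' The self-tuning chain: local scales, locally scaled affinity, normalized
#' Laplacian, rotation-based model selection and assignment.
#'
#' @param D Symmetric distance matrix.
#' @param config A [spectral_config()].
#' @return A `cluster_solution` (see [select_and_cluster()]).
#' @export
cluster_distances <- function(D, config = spectral_config()) {
  sigma <- local_scales(D, K = min(config$K, nrow(as.matrix(D)) - 1))
  A <- affinity(D, sigma)
  La <- normalized_laplacian(A)
  select_and_cluster(La, config)
}
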