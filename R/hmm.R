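#' Gaussian-mixture-emission hidden Markov model parameters
#'
#' Container for an HMM with `n_states` hidden states, each emitting from a
#' mixture of `n_mix` diagonal-covariance Gaussians over `M`-dimensional
#' observations: initial distribution `pi`, transition matrix `A`, mixture
#' weights `w` (`S x K`), means `mu` and variances `sigma2` (arrays
#' `S x K x M`).
#'
#' @param pi Initial state distribution (length `S`, sums to 1).
#' @param A Transition matrix (`S x S`, rows sum to 1).
#' @param w Mixture weights (`S x K`, rows sum to 1).
#' @param mu,sigma2 Arrays `S x K x M`; `sigma2` entries must be positive.
#' @return Object of class `hmm_params`.
#' @export
hmm_params <- function(pi, A, w, mu, sigma2) {
  pi <- as.numeric(pi)
  A <- as.matrix(A)
  w <- as.matrix(w)
  S <- length(pi)
  K <- ncol(w)
  mu <- array(mu, dim = c(S, K, length(mu) / (S * K)))
  sigma2 <- array(sigma2, dim = dim(mu))
  stopifnot(nrow(A) == S, ncol(A) == S, nrow(w) == S,
            abs(sum(pi) - 1) < 1e-8,
            all(abs(rowSums(A) - 1) < 1e-8),
            all(abs(rowSums(w) - 1) < 1e-8),
            all(sigma2 > 0))
  structure(list(n_states = S, n_mix = K, n_dim = dim(mu)[3],
                 pi = pi, A = A, w = w, mu = mu, sigma2 = sigma2),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(sprintf("hmm_params: %d states, %d mixture components, %d-dim emissions\n",
              x$n_states, x$n_mix, x$n_dim))
  invisible(x)
}

# coerce a sequence (sensor_stream, M x T matrix per the node convention)
# to the internal T x M orientation
.as_obs <- function(Y) {
  if (inherits(Y, "sensor_stream")) Y <- Y$values
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  t(Y)
}

#' Forward-algorithm log-likelihood
#'
#' Total natural-log likelihood of an observation sequence under the model,
#' computed by the forward recursion. Two implementations are provided and
#' must agree: a scaled forward pass (compiled, the default) and a pure
#' log-space recursion using log-sum-exp.
#'
#' @param Y Observation sequence: `M x T` matrix (channels x time) or a
#'   `sensor_stream`.
#' @param model An `hmm_params`.
#' @param method `"scaled"` (compiled) or `"log"` (reference log-space).
#' @return Scalar log-likelihood (finite for any finite input).
#' @export
log_likelihood <- function(Y, model, method = c("scaled", "log")) {
  method <- match.arg(method)
  obs <- .as_obs(Y)
  if (ncol(obs) != model$n_dim)
    stop(sprintf("dimension mismatch: sequence has %d channels, model expects %d",
                 ncol(obs), model$n_dim))
  if (method == "scaled") {
    cpp_hmm_loglik(obs, model$pi, model$A, model$w, model$mu, model$sigma2)
  } else {
    .loglik_logspace(obs, model)
  }
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# per-time, per-state log mixture emission densities (T x S), in R
.log_emissions_r <- function(obs, model) {
  T_ <- nrow(obs); S <- model$n_states; K <- model$n_mix; M <- ncol(obs)
  logB <- matrix(-Inf, T_, S)
  for (s in seq_len(S)) {
    comp <- matrix(-Inf, T_, K)
    for (k in seq_len(K)) {
      mu <- model$mu[s, k, ]; v <- model$sigma2[s, k, ]
      z <- sweep(obs, 2, mu)
      q <- rowSums(sweep(z^2, 2, v, `/`))
      comp[, k] <- -0.5 * (q + sum(log(v)) + M * log(2 * pi)) +
        log(max(model$w[s, k], 1e-300))
    }
    logB[, s] <- apply(comp, 1, .logsumexp)
  }
  logB
}

.loglik_logspace <- function(obs, model) {
  logB <- .log_emissions_r(obs, model)
  logA <- log(pmax(model$A, 1e-300))
  la <- log(pmax(model$pi, 1e-300)) + logB[1, ]
  T_ <- nrow(obs)
  if (T_ > 1) {
    for (t in 2:T_) {
      la <- apply(la + logA, 2, .logsumexp) + logB[t, ]
    }
  }
  .logsumexp(la)
}

#' Sample a sequence from an HMM
#'
#' @param model An `hmm_params`.
#' @param len Sequence length.
#' @param seed Integer seed.
#' @return List with `Y` (`M x len` observation matrix) and `states`.
#' @export
sample_hmm <- function(model, len, seed = 1L) {
  stopifnot(len >= 1)
  .with_seed(seed, function() {
    S <- model$n_states; K <- model$n_mix; M <- model$n_dim
    states <- integer(len)
    Y <- matrix(0, M, len)
    st <- sample.int(S, 1, prob = model$pi)
    for (t in seq_len(len)) {
      if (t > 1) st <- sample.int(S, 1, prob = model$A[st, ])
      states[t] <- st
      k <- sample.int(K, 1, prob = model$w[st, ])
      Y[, t] <- stats::rnorm(M, model$mu[st, k, ], sqrt(model$sigma2[st, k, ]))
    }
    list(Y = Y, states = states)
  })
}

# k-means based initialization of means/variances; uniform-plus-jitter pi, A
.init_hmm <- function(obs_list, n_states, n_mix, var_floor) {
  pooled <- do.call(rbind, obs_list)
  M <- ncol(pooled)
  n <- nrow(pooled)
  pick_centers <- function(X, k) {
    ux <- unique(X)
    if (nrow(ux) <= k) {
      ctr <- ux[rep_len(seq_len(nrow(ux)), k), , drop = FALSE]
      ctr + matrix(stats::rnorm(k * ncol(X), sd = 1e-3), k)
    } else {
      km <- suppressWarnings(stats::kmeans(X, centers = k, nstart = 3,
                                           iter.max = 30))
      km$centers
    }
  }
  state_ctr <- pick_centers(pooled, n_states)
  # assign pooled points to nearest state center, split each within-state
  d2 <- sapply(seq_len(n_states), function(s)
    rowSums(sweep(pooled, 2, state_ctr[s, ])^2))
  assign <- max.col(-matrix(d2, nrow = n), ties.method = "first")
  pooled_var <- pmax(apply(pooled, 2, stats::var), var_floor)
  mu <- array(0, c(n_states, n_mix, M))
  sigma2 <- array(rep(pooled_var, each = n_states * n_mix),
                  c(n_states, n_mix, M))
  for (s in seq_len(n_states)) {
    Xs <- pooled[assign == s, , drop = FALSE]
    if (nrow(Xs) == 0) Xs <- state_ctr[s, , drop = FALSE]
    ctr <- pick_centers(Xs, n_mix)
    mu[s, , ] <- ctr
  }
  pi0 <- rep(1 / n_states, n_states) + stats::runif(n_states, 0, 0.01)
  A0 <- matrix(1 / n_states, n_states, n_states) +
    matrix(stats::runif(n_states^2, 0, 0.01), n_states)
  list(pi = pi0 / sum(pi0), A = A0 / rowSums(A0),
       w = matrix(1 / n_mix, n_states, n_mix), mu = mu, sigma2 = sigma2)
}

#' Fit a Gaussian-mixture HMM by Baum-Welch
#'
#' Expectation-maximization on one sequence or a list of sequences (the
#' multi-sequence extension sums the sufficient statistics). Means are
#' initialized by k-means on the pooled observations, the initial and
#' transition distributions uniformly with seeded jitter. Diagonal variances
#' are floored, which keeps the constrained M-step (and hence the EM
#' likelihood ascent) well defined on degenerate data.
#'
#' @param Y One sequence (`M x T` matrix or `sensor_stream`) or a list of
#'   them.
#' @param n_states,n_mix Model size; defaults 8 states, 2 components.
#' @param seed Integer seed (initialization); fits are deterministic given
#'   `(Y, seed)`.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param var_floor Lower bound on diagonal variances.
#' @return An `hmm_params` with attributes `loglik_trace` (per-iteration
#'   total training log-likelihood) and `converged`.
#' @export
fit_hmm <- function(Y, n_states = 8, n_mix = 2, seed = 1L, max_iter = 100,
                    tol = 1e-4, var_floor = 1e-3) {
  obs_list <- if (is.list(Y) && !inherits(Y, "sensor_stream"))
    lapply(Y, .as_obs) else list(.as_obs(Y))
  lens <- vapply(obs_list, nrow, 1L)
  if (any(lens < n_states))
    stop(sprintf("sequence of length %d is too short for %d states",
                 min(lens), n_states))
  M <- ncol(obs_list[[1]])
  if (any(vapply(obs_list, ncol, 1L) != M)) stop("channel counts differ")
  if (any(!vapply(obs_list, function(o) all(is.finite(o)), TRUE)))
    stop("non-finite observations")
  pooled_sd <- stats::sd(unlist(obs_list))
  if (!is.finite(pooled_sd) || pooled_sd == 0)
    warning("constant observations: variances floored")

  par <- .with_seed(seed, function()
    .init_hmm(obs_list, n_states, n_mix, var_floor))
  S <- n_states; K <- n_mix
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    g1 <- numeric(S); xi <- matrix(0, S, S)
    nk <- matrix(0, S, K)
    sy <- array(0, c(S, K, M)); sy2 <- array(0, c(S, K, M))
    ll <- 0
    for (o in obs_list) {
      st <- cpp_hmm_estep(o, par$pi, par$A, par$w, par$mu, par$sigma2)
      ll <- ll + st$loglik
      g1 <- g1 + st$gamma1
      xi <- xi + st$xi
      nk <- nk + st$nk
      sy <- sy + st$sum_y
      sy2 <- sy2 + st$sum_y2
    }
    trace <- c(trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) <= tol * (abs(ll_prev) + 1)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    # M-step (states/components with vanishing occupancy keep their params)
    par$pi <- g1 / sum(g1)
    rs <- rowSums(xi)
    for (s in seq_len(S)) if (rs[s] > 1e-10) par$A[s, ] <- xi[s, ] / rs[s]
    ns <- rowSums(nk)
    for (s in seq_len(S)) {
      if (ns[s] <= 1e-10) next
      par$w[s, ] <- nk[s, ] / ns[s]
      for (k in seq_len(K)) {
        if (nk[s, k] <= 1e-10) next
        m <- sy[s, k, ] / nk[s, k]
        v <- sy2[s, k, ] / nk[s, k] - m^2
        par$mu[s, k, ] <- m
        par$sigma2[s, k, ] <- pmax(v, var_floor)
      }
    }
  }
  out <- hmm_params(par$pi, par$A, par$w, par$mu, par$sigma2)
  attr(out, "loglik_trace") <- trace
  attr(out, "converged") <- converged
  out
}

#' Serialize / restore HMM parameters as JSON
#'
#' @param model An `hmm_params`.
#' @param path File path.
#' @return `hmm_from_json` returns an `hmm_params`.
#' @export
hmm_to_json <- function(model, path) {
  obj <- list(n_states = model$n_states, n_mix = model$n_mix,
              n_dim = model$n_dim, pi = model$pi, A = model$A, w = model$w,
              mu = as.vector(model$mu), sigma2 = as.vector(model$sigma2))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname hmm_to_json
#' @export
hmm_from_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- c(o$n_states, o$n_mix, o$n_dim)
  hmm_params(o$pi, o$A, matrix(o$w, o$n_states, o$n_mix),
             array(o$mu, d), array(o$sigma2, d))
}
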