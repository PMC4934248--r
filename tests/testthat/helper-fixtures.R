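# shared fixtures built in code

default_node <- function() build_partition(partition_config())

# a small random Gaussian-mixture HMM for oracle tests
random_hmm <- function(n_states, n_mix = 1, n_dim = 1, seed = 1) {
  set.seed(seed)
  pi <- runif(n_states) + 0.1
  A <- matrix(runif(n_states^2) + 0.1, n_states)
  w <- matrix(runif(n_states * n_mix) + 0.1, n_states)
  hmm_params(pi / sum(pi), A / rowSums(A), w / rowSums(w),
             mu = array(rnorm(n_states * n_mix * n_dim),
                        c(n_states, n_mix, n_dim)),
             sigma2 = array(runif(n_states * n_mix * n_dim, 0.5, 2),
                            c(n_states, n_mix, n_dim)))
}

# brute-force log-likelihood by enumerating all state paths (1-mix models)
enumerate_loglik <- function(Y, m) {
  obs <- t(as.matrix(Y))
  T_ <- nrow(obs)
  S <- m$n_states
  dens <- sapply(seq_len(S), function(s) sapply(seq_len(T_), function(t)
    prod(stats::dnorm(obs[t, ], m$mu[s, 1, ], sqrt(m$sigma2[s, 1, ])))))
  dens <- matrix(dens, T_, S)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), T_)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    p <- m$pi[paths[r, 1]] * dens[1, paths[r, 1]]
    if (T_ > 1) for (t in 2:T_)
      p <- p * m$A[paths[r, t - 1], paths[r, t]] * dens[t, paths[r, t]]
    tot <- tot + p
  }
  log(tot)
}

# the four well-separated generating HMMs used in clustering recovery tests:
# 2-state chains with 2-d emissions at the four corners (+-2, +-2), the
# second state pulled halfway to the centre on one axis, unit variance
separated_generators <- function() {
  mk <- function(m1, m2) hmm_params(
    pi = c(0.6, 0.4), A = matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE),
    w = matrix(1, 2, 1), mu = array(c(m1, m2), c(2, 1, 2)),
    sigma2 = array(1, c(2, 1, 2)))
  list(mk(c(-2, -2), c(-1, -2)), mk(c(2, 2), c(1, 2)),
       mk(c(-2, 2), c(-2, 1)), mk(c(2, -2), c(2, -1)))
}

# sequences from the separated generators: k clusters x n_each, length len
generator_sequences <- function(seed, n_each = 10, len = 80) {
  gens <- separated_generators()
  seqs <- list()
  lab <- integer(0)
  for (g in seq_along(gens)) {
    for (r in seq_len(n_each)) {
      seqs[[length(seqs) + 1]] <-
        sample_hmm(gens[[g]], len, seed = seed * 1000 + g * 100 + r)$Y
      lab <- c(lab, g)
    }
  }
  list(sequences = seqs, labels = lab)
}

random_orthogonal <- function(c, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(c * c), c)))
}
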