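test_that("forward log-likelihood equals brute-force path enumeration", {
  set.seed(100)
  for (i in 1:20) {
    S <- sample(2:3, 1)
    M <- sample(1:2, 1)
    T_ <- sample(2:5, 1)
    m <- random_hmm(S, 1, M, seed = 100 + i)
    Y <- matrix(rnorm(M * T_), M)
    expected <- enumerate_loglik(Y, m)
    expect_equal(log_likelihood(Y, m), expected,
                 tolerance = 1e-8)
  }
})

test_that("scaled and log-space forward implementations agree", {
  for (i in 1:10) {
    m <- random_hmm(sample(2:4, 1), sample(1:2, 1), 3, seed = 200 + i)
    set.seed(300 + i)
    Y <- matrix(rnorm(3 * 30), 3)
    a <- log_likelihood(Y, m, method = "scaled")
    b <- log_likelihood(Y, m, method = "log")
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("single-state single-component model reduces to the iid Gaussian", {
  m <- hmm_params(1, matrix(1, 1, 1), matrix(1, 1, 1),
                  array(c(0.5, -1), c(1, 1, 2)),
                  array(c(2, 0.7), c(1, 1, 2)))
  set.seed(5)
  Y <- matrix(rnorm(2 * 12), 2)
  expected <- sum(dnorm(Y[1, ], 0.5, sqrt(2), log = TRUE)) +
    sum(dnorm(Y[2, ], -1, sqrt(0.7), log = TRUE))
  expect_equal(log_likelihood(Y, m), expected, tolerance = 1e-10)
})

test_that("log-likelihood is invariant under state relabeling", {
  m <- random_hmm(3, 2, 2, seed = 77)
  perm <- c(3, 1, 2)
  mp <- hmm_params(m$pi[perm], m$A[perm, perm], m$w[perm, ],
                   m$mu[perm, , , drop = FALSE],
                   m$sigma2[perm, , , drop = FALSE])
  set.seed(6)
  Y <- matrix(rnorm(2 * 25), 2)
  expect_equal(log_likelihood(Y, m), log_likelihood(Y, mp),
               tolerance = 1e-10)
})

test_that("far-from-model sequences still get finite log-likelihoods", {
  m <- random_hmm(3, 1, 2, seed = 8)
  Y <- matrix(1e3, 2, 40)
  ll <- log_likelihood(Y, m)
  expect_true(is.finite(ll))
  expect_lt(ll, -1e5)
})

test_that("Baum-Welch recovers a well-separated two-state model", {
  truth <- hmm_params(c(0.5, 0.5),
                      matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
                      matrix(1, 2, 1), array(c(-5, 5), c(2, 1, 1)),
                      array(1, c(2, 1, 1)))
  Y <- sample_hmm(truth, 2000, seed = 3)$Y
  fit <- fit_hmm(Y, n_states = 2, n_mix = 1, seed = 5)
  expect_equal(sort(as.vector(fit$mu)), c(-5, 5), tolerance = 0.2)
  ord <- order(as.vector(fit$mu))
  expect_equal(fit$A[ord, ord], truth$A, tolerance = 0.1,
               ignore_attr = TRUE)
})

test_that("every fit keeps its distributions normalized and is deterministic", {
  pv <- default_node()
  st <- simulate_stream(activity_script("walking", seed = 31),
                        pv$partition, pv$V)
  seg <- segment_stream(st)[[1]]
  f1 <- fit_hmm(seg, n_states = 4, n_mix = 2, seed = 9)
  f2 <- fit_hmm(seg, n_states = 4, n_mix = 2, seed = 9)
  expect_identical(f1$A, f2$A)
  expect_identical(f1$mu, f2$mu)
  expect_equal(sum(f1$pi), 1, tolerance = 1e-10)
  expect_equal(rowSums(f1$A), rep(1, 4), tolerance = 1e-10)
  expect_equal(rowSums(f1$w), rep(1, 4), tolerance = 1e-10)
  expect_true(all(f1$sigma2 >= 1e-3 - 1e-12))
})

test_that("training log-likelihood never decreases across EM iterations", {
  # a variety of data shapes, single and multi-sequence
  cases <- list(
    list(Y = sample_hmm(random_hmm(3, 1, 2, seed = 1), 150, seed = 2)$Y,
         S = 3, K = 2),
    list(Y = matrix(rnorm(7 * 60), 7), S = 4, K = 2),
    list(Y = lapply(1:4, function(i) matrix(rnorm(3 * 50), 3)), S = 3,
         K = 1))
  for (cs in cases) {
    fit <- fit_hmm(cs$Y, n_states = cs$S, n_mix = cs$K, seed = 11)
    trace <- attr(fit, "loglik_trace")
    expect_gte(length(trace), 2)
    expect_true(all(diff(trace) >= -1e-6))
  }
})

test_that("degenerate and invalid inputs are handled", {
  expect_warning(fit_hmm(matrix(1, 2, 40), n_states = 2, n_mix = 1,
                         seed = 1), "constant")
  expect_error(fit_hmm(matrix(rnorm(2 * 3), 2), n_states = 8),
               "too short")
  m <- random_hmm(2, 1, 3, seed = 1)
  expect_error(log_likelihood(matrix(0, 2, 5), m), "dimension mismatch")
})

test_that("sampled sequences follow the model and round-trip through JSON", {
  m <- random_hmm(3, 2, 2, seed = 55)
  s1 <- sample_hmm(m, 100, seed = 4)
  s2 <- sample_hmm(m, 100, seed = 4)
  expect_identical(s1$Y, s2$Y)
  expect_equal(dim(s1$Y), c(2, 100))
  expect_true(all(s1$states %in% 1:3))
  path <- tempfile(fileext = ".json")
  hmm_to_json(m, path)
  m2 <- hmm_from_json(path)
  expect_equal(m$A, m2$A, ignore_attr = TRUE)
  expect_equal(m$mu, m2$mu, ignore_attr = TRUE)
  expect_equal(log_likelihood(s1$Y, m), log_likelihood(s1$Y, m2))
})
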