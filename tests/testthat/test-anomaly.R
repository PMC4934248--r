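test_that("one model per cluster, scoring own members higher", {
  gs <- generator_sequences(seed = 51, n_each = 6, len = 60)
  mods <- fit_cluster_models(gs$sequences, gs$labels, n_states = 2,
                             n_mix = 1, seed = 7)
  expect_length(mods, 4)
  feat <- extract_features(gs$sequences, mods)
  expect_equal(dim(feat), c(24, 4))
  # on average, a cluster's model explains its own members best
  own <- feat[cbind(seq_len(24), gs$labels)]
  other <- (rowSums(feat) - own) / 3
  expect_gt(mean(own), mean(other))
  # feature argmax identifies the generating cluster on held-out data
  held <- generator_sequences(seed = 52, n_each = 5, len = 60)
  fh <- extract_features(held$sequences, mods)
  expect_gte(mean(max.col(fh) == held$labels), 0.9)
  # determinism
  mods2 <- fit_cluster_models(gs$sequences, gs$labels, n_states = 2,
                              n_mix = 1, seed = 7)
  expect_identical(mods[[1]]$mu, mods2[[1]]$mu)
  expect_identical(extract_features(gs$sequences[[1]], mods),
                   extract_features(gs$sequences[[1]], mods))
  expect_error(fit_cluster_models(gs$sequences, c(rep(1, 23), 3)), "cover")
})

test_that("the SVDD dual solution is feasible and nu bounds the outliers", {
  for (s in 1:20) {
    set.seed(1000 + s)
    n <- sample(c(60, 100, 150), 1)
    nu <- sample(c(0.05, 0.1, 0.2), 1)
    X <- matrix(rnorm(n * 3), n)
    m <- train_osvm(X, nu = nu)
    alpha_full <- numeric(n)
    alpha_full[m$sv_index] <- m$alpha
    expect_equal(sum(alpha_full), 1, tolerance = 1e-8)
    expect_true(all(alpha_full >= -1e-8 &
                      alpha_full <= 1 / (nu * n) + 1e-8))
    # "strictly outside" is judged above the QP solver's precision:
    # boundary vectors sit on the sphere only to ~1e-7
    outliers <- mean(m$train_scores < -1e-6)
    expect_lte(outliers, nu + 2 / n)
  }
})

test_that("identical training points give a zero-radius sphere", {
  X <- matrix(1, 10, 3)
  m <- train_osvm(X, nu = 0.5, standardize = FALSE)
  expect_equal(m$R2, 0, tolerance = 1e-10)
  expect_gte(min(decision_score(X, m)), -1e-10)
  expect_lt(decision_score(c(4, 4, 4), m), 0)
})

test_that("boundary support vectors sit on the sphere", {
  set.seed(31)
  X <- matrix(rnorm(120 * 2), 120)
  m <- train_osvm(X, nu = 0.1, standardize = FALSE)
  alpha_full <- numeric(120)
  alpha_full[m$sv_index] <- m$alpha
  ub <- 1 / (0.1 * 120)
  boundary <- which(alpha_full > 1e-6 * ub & alpha_full < ub * (1 - 1e-6))
  expect_gt(length(boundary), 0)
  sc <- decision_score(X[boundary, , drop = FALSE], m)
  expect_lt(median(abs(sc)), 1e-2 * max(m$R2, 1))
})

test_that("points far from all training data are declared abnormal", {
  set.seed(32)
  X <- matrix(rnorm(80 * 2), 80)
  m <- train_osvm(X, nu = 0.05)
  far <- matrix(c(50, 50, -60, 40), 2, byrow = TRUE)
  expect_true(all(decision_score(far, m) < 0))
  expect_equal(unname(predict(m, far)), c("abnormal", "abnormal"))
  # deterministic scoring
  expect_identical(decision_score(far, m), decision_score(far, m))
})

test_that("decision ranking matches an established one-class SVM", {
  # for an RBF kernel the SVDD dual coincides with the nu-one-class-SVM
  # dual, so the decision orderings must agree
  set.seed(33)
  X <- matrix(rnorm(150 * 3), 150)
  m <- train_osvm(X, nu = 0.1, standardize = FALSE)
  ref <- e1071::svm(X, type = "one-classification", nu = 0.1,
                    gamma = m$gamma, scale = FALSE, kernel = "radial")
  dv <- as.numeric(attr(predict(ref, X, decision.values = TRUE),
                        "decision.values"))
  expect_gt(cor(decision_score(X, m), dv), 0.99)
})

test_that("the within-cluster kernel-width heuristic uses only same-label pairs", {
  set.seed(34)
  X <- rbind(matrix(rnorm(40 * 2, 0, 0.1), 40),
             matrix(rnorm(40 * 2, 20, 0.1), 40))
  lab <- rep(1:2, each = 40)
  m_global <- train_osvm(X, nu = 0.1, standardize = FALSE)
  m_local <- train_osvm(X, nu = 0.1, standardize = FALSE, cluster_labels = lab)
  expect_gt(m_local$gamma / m_global$gamma, 100)
})

test_that("the single-HMM baseline scores familiar data above noise", {
  gs <- generator_sequences(seed = 61, n_each = 5, len = 60)
  test_seqs <- c(gs$sequences[1],
                 list(matrix(rnorm(2 * 60, sd = 30), 2)))
  base <- onehmm_baseline(gs$sequences, test_seqs, n_states = 3,
                          n_mix = 1, seed = 3)
  expect_length(base$scores, 2)
  expect_gt(base$scores[1], base$scores[2])
  base2 <- onehmm_baseline(gs$sequences, test_seqs, n_states = 3,
                           n_mix = 1, seed = 3)
  expect_identical(base$scores, base2$scores)
  expect_error(onehmm_baseline(list(), test_seqs), "empty")
})

test_that("OSVM models round-trip through JSON", {
  set.seed(35)
  X <- matrix(rnorm(60 * 2), 60)
  m <- train_osvm(X, nu = 0.1)
  path <- tempfile(fileext = ".json")
  osvm_to_json(m, path)
  m2 <- osvm_from_json(path)
  probe <- matrix(rnorm(10 * 2), 10)
  expect_equal(decision_score(probe, m), decision_score(probe, m2),
               tolerance = 1e-12)
})
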