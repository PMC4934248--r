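test_that("local scales are K-th neighbor distances", {
  D <- as.matrix(dist(c(0, 1, 3)))
  expect_equal(local_scales(D, K = 1), c(1, 1, 2))
  expect_equal(local_scales(D, K = 2), c(3, 2, 3))  # K = N-1: farthest
  # duplicates floor at a tiny positive value
  Dz <- matrix(0, 4, 4)
  expect_equal(local_scales(Dz, K = 2), rep(1e-12, 4))
  expect_error(local_scales(D, K = 3), "below")
})

test_that("locally scaled affinity is symmetric, bounded and reduces to the single-scale kernel", {
  set.seed(13)
  P <- matrix(rnorm(16), 8)
  D <- as.matrix(dist(P))
  sig <- local_scales(D, K = 3)
  A <- affinity(D, sig)
  expect_equal(A, t(A))
  expect_equal(unname(diag(A)), rep(0, 8))
  expect_true(all(A >= 0 & A <= 1))
  expect_true(all(A[upper.tri(A)] > 0))
  # equal scales: same as exp(-d^2 / sigma^2), i.e. the global Gaussian kernel
  A2 <- affinity(D, rep(0.7, 8))
  expected <- exp(-D^2 / 0.49)
  diag(expected) <- 0
  expect_equal(A2, expected)
})

test_that("the normalized Laplacian has unit spectral radius", {
  set.seed(14)
  for (i in 1:5) {
    A <- matrix(runif(49), 7)
    A <- (A + t(A)) / 2
    diag(A) <- 0
    La <- normalized_laplacian(A)
    expect_equal(La, t(La))
    ev <- eigen(La, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(max(ev), 1, tolerance = 1e-10)
  }
  # c disconnected blocks: eigenvalue 1 with multiplicity c
  B <- matrix(0, 9, 9)
  for (b in 0:2) B[b * 3 + 1:3, b * 3 + 1:3] <- 0.8
  diag(B) <- 0
  ev <- eigen(normalized_laplacian(B), symmetric = TRUE,
              only.values = TRUE)$values
  expect_equal(sum(ev > 1 - 1e-10), 3)
  expect_error(normalized_laplacian(matrix(0, 3, 3)), "isolated")
})

test_that("a canonical indicator matrix is already aligned (J = N, R = I)", {
  set.seed(15)
  lab <- sample(rep(1:3, each = 7))
  X <- matrix(0, 21, 3)
  X[cbind(1:21, lab)] <- 1
  X <- sweep(X, 2, sqrt(colSums(X^2)), `/`)
  r <- align_rotation(X)
  expect_equal(r$J, 21, tolerance = 1e-9)
  expect_equal(r$R, diag(3), tolerance = 1e-6)
  expect_equal(crossprod(r$R), diag(3), tolerance = 1e-8)
})

test_that("rotation recovery undoes a random orthogonal mixing", {
  N <- 60
  for (c in 2:6) {
    set.seed(400 + c)
    lab <- sample(rep_len(1:c, N))
    X0 <- matrix(0, N, c)
    X0[cbind(1:N, lab)] <- 1
    X0 <- sweep(X0, 2, sqrt(colSums(X0^2)), `/`)
    X <- X0 %*% random_orthogonal(c, seed = 500 + c)
    r <- align_rotation(X)
    expect_lte(r$J, N * (1 + 1e-3))
    expect_equal(crossprod(r$R), diag(c), tolerance = 1e-8)
    recovered <- max.col(r$Z^2)
    expect_equal(length(unique(paste(lab, recovered))), c)
  }
})

test_that("alignment cost respects its per-row bounds", {
  set.seed(16)
  for (i in 1:10) {
    N <- sample(10:40, 1)
    c <- sample(2:5, 1)
    X <- qr.Q(qr(matrix(rnorm(N * c), N)))
    r <- align_rotation(X)
    expect_gte(r$J, N - 1e-9)
    expect_lte(r$J, N * c + 1e-9)
  }
})

test_that("block-structured affinities select the block count and labels", {
  # weak background coupling keeps model selection well posed: on exactly
  # disconnected blocks any split of a component aligns for free and the
  # largest-minimal-cost rule cannot distinguish candidate counts
  B <- matrix(0.05, 30, 30)
  for (b in 0:2) B[b * 10 + 1:10, b * 10 + 1:10] <- 0.9
  diag(B) <- 0
  sol <- select_and_cluster(normalized_laplacian(B),
                            spectral_config(C_max = 6))
  expect_equal(sol$C_best, 3)
  truth <- rep(1:3, each = 10)
  expect_equal(length(unique(paste(truth, sol$labels))), 3)
  # on exactly disconnected blocks the correct count still attains the
  # indicator optimum J = N with block-exact labels
  B0 <- B
  B0[B0 == 0.05] <- 0
  La0 <- normalized_laplacian(B0)
  vecs <- eigen(La0, symmetric = TRUE)$vectors[, 1:3]
  r <- align_rotation(vecs)
  expect_equal(r$J, 30, tolerance = 1e-8)
  expect_equal(length(unique(paste(truth, max.col(r$Z^2)))), 3)
})

test_that("two distant point clouds cluster into two groups", {
  set.seed(18)
  P <- rbind(matrix(rnorm(40, 0), ncol = 2),
             matrix(rnorm(40, 12), ncol = 2))
  sol <- cluster_distances(as.matrix(dist(P)), spectral_config(C_max = 6))
  expect_equal(sol$C_best, 2)
  truth <- rep(1:2, each = 20)
  expect_equal(length(unique(paste(truth, sol$labels))), 2)
})

test_that("clustering is equivariant under permutation of the points", {
  gs <- generator_sequences(seed = 77, n_each = 6, len = 60)
  res <- sequence_distances(gs$sequences, n_states = 2, n_mix = 1,
                            seed = 19)
  sol <- cluster_distances(res$D, spectral_config(C_max = 6))
  set.seed(20)
  perm <- sample(length(gs$labels))
  solp <- cluster_distances(res$D[perm, perm], spectral_config(C_max = 6))
  expect_equal(solp$C_best, sol$C_best)
  # same partition up to label names
  expect_equal(mclust::adjustedRandIndex(solp$labels, sol$labels[perm]), 1)
})

test_that("the selected count is the largest with near-minimal cost", {
  B <- matrix(0, 24, 24)
  for (b in 0:3) B[b * 6 + 1:6, b * 6 + 1:6] <- 0.7
  B <- B + 0.05          # weak coupling between the blocks
  diag(B) <- 0
  cfg <- spectral_config(C_max = 7)
  sol <- select_and_cluster(normalized_laplacian(B), cfg)
  minimal <- which(sol$quality >= max(sol$quality) - cfg$quality_band)
  expect_equal(sol$C_selected,
               as.integer(names(sol$costs)[max(minimal)]))
})
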