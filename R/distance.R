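#' Per-sequence likelihood matrix
#'
#' Entry `(i, j)` is the length-normalized log-likelihood of sequence `j`
#' under the HMM trained on sequence `i`:
#' `l_ij = log P(Y_j; lambda_i) / length(Y_j)`. Column `j` thus records how
#' every model in the collection explains sequence `j`, embedding each
#' sequence in the space spanned by all trained models.
#'
#' @param sequences List of `N` observation sequences (`M x T_j` matrices or
#'   `sensor_stream`s).
#' @param models List of `N` `hmm_params`, model `i` trained on sequence `i`.
#' @return `N x N` numeric matrix (rows = models, columns = sequences).
#' @export
likelihood_matrix <- function(sequences, models) {
  N <- length(sequences)
  if (length(models) != N) stop("need as many models as sequences")
  obs <- lapply(sequences, .as_obs)
  lens <- vapply(obs, nrow, 1L)
  L <- matrix(0, N, N)
  for (i in seq_len(N)) {
    m <- models[[i]]
    L[i, ] <- cpp_hmm_loglik_many(obs, m$pi, m$A, m$w, m$mu, m$sigma2) / lens
  }
  if (!all(is.finite(L))) {
    bad <- which(!is.finite(L), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite log-likelihood at model %d, sequence %d",
                 bad[1], bad[2]))
  }
  L
}

#' Column-normalize a likelihood matrix into per-sequence pdfs
#'
#' Turns each column of length-normalized log-likelihoods into a probability
#' distribution over the trained models via a column-wise softmax, computed
#' with log-sum-exp for stability. Column `j` is then the pdf over the
#' discrete model space conditioned on sequence `j`; every column sums to 1.
#'
#' @param L Likelihood matrix from [likelihood_matrix()].
#' @return Column-stochastic matrix of the same shape, all entries positive.
#' @export
normalize_columns <- function(L) {
  L <- as.matrix(L)
  if (!all(is.finite(L))) stop("non-finite entries")
  mx <- apply(L, 2, max)
  E <- exp(sweep(L, 2, mx))
  sweep(E, 2, colSums(E), `/`)
}

#' Kullback-Leibler divergence of discrete pdfs
#'
#' `D_KL(fP || fQ) = sum_i fP(i) log(fP(i) / fQ(i))`, with the conventions
#' `0 * log(0/q) = 0` and `fQ` floored at `floor` before division (guarding
#' against underflowed softmax entries).
#'
#' @param fP,fQ Non-negative vectors of equal length summing to 1.
#' @param floor Lower bound applied to `fQ`.
#' @return Non-negative scalar (nats).
#' @export
kl_divergence <- function(fP, fQ, floor = 1e-12) {
  if (length(fP) != length(fQ)) stop("pdfs have different lengths")
  pos <- fP > 0
  sum(fP[pos] * (log(fP[pos]) - log(pmax(fQ[pos], floor))))
}

#' Symmetrized-KL distance matrix between sequences
#'
#' `d_ij` is the symmetrized KL divergence between the model-space pdfs of
#' sequences `i` and `j` (columns of the normalized likelihood matrix):
#' `d_ij = (D_KL(f_i||f_j) + D_KL(f_j||f_i)) / 2`.
#'
#' @param LN Column-stochastic matrix from [normalize_columns()].
#' @param floor KL floor, as in [kl_divergence()].
#' @return Symmetric, non-negative `N x N` matrix with zero diagonal.
#' @export
distance_matrix <- function(LN, floor = 1e-12) {
  F_ <- as.matrix(LN)
  G <- log(pmax(F_, floor))
  self <- colSums(ifelse(F_ > 0, F_ * G, 0))
  cross <- t(F_) %*% G                   # (i, j) = sum_k F[k,i] log F[k,j]
  KL <- self - cross                     # KL(f_i || f_j)
  D <- (KL + t(KL)) / 2
  D <- pmax(D, 0)
  diag(D) <- 0
  D
}

#' Sequence collection to distance matrix
#'
#' The full likelihood-space chain: fit one HMM per sequence, build the
#' likelihood matrix, normalize columns, and return the symmetrized-KL
#' distances.
#'
#' @param sequences List of observation sequences.
#' @param n_states,n_mix Per-sequence HMM size.
#' @param seed Base seed; sequence `i` is fitted with `seed + i`.
#' @param ... Passed to [fit_hmm()].
#' @return List with `models`, `L`, `LN` and `D`.
#' @export
sequence_distances <- function(sequences, n_states = 8, n_mix = 2,
                               seed = 1L, ...) {
  models <- lapply(seq_along(sequences), function(i)
    fit_hmm(sequences[[i]], n_states = n_states, n_mix = n_mix,
            seed = seed + i, ...))
  L <- likelihood_matrix(sequences, models)
  LN <- normalize_columns(L)
  list(models = models, L = L, LN = LN, D = distance_matrix(LN))
}
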