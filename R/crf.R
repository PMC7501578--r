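# Linear-chain CRF over encoder hidden vectors. The sequence score is the sum
# of per-position emission scores p[i, y_i] and label-transition scores
# A[y_{i-1}, y_i] over n+1 transitions including explicit START and STOP
# states; the conditional probability normalizes over all k^n label paths via
# the forward algorithm in log space. Emission scores are unnormalized logits
# from a linear projection of the hidden vectors; the CRF normalizes globally.

MASK_NEG <- -1e4  # finite stand-in for -Inf: keeps log-sum-exp NaN-free

#' Initialize CRF parameters
#'
#' Builds the (k+2) x (k+2) transition matrix (rows = from, cols = to) with
#' explicit START/STOP states, and the linear emission projection from
#' encoder hidden vectors to the k label scores.
#'
#' @param labels character vector of the k BIO labels, in decoding order.
#' @param hidden_dim dimension of the encoder hidden vectors fed to the
#'   emission projection.
#' @return list with `labels`, `k`, `start`, `stop`, `trans`, `W_e`
#'   (`hidden_dim` x k), `b_e` (k). Transitions into START and out of STOP
#'   are masked to a large negative constant and never updated.
#' @export
crf_init <- function(labels, hidden_dim) {
  k <- length(labels)
  stopifnot(k >= 1L, hidden_dim >= 1L)
  trans <- matrix(0, k + 2L, k + 2L)
  trans[, k + 1L] <- MASK_NEG          # nothing enters START
  trans[k + 2L, ] <- MASK_NEG          # nothing leaves STOP
  trans[k + 1L, k + 2L] <- MASK_NEG    # START cannot jump straight to STOP
  list(labels = labels, k = k, start = k + 1L, stop = k + 2L,
       trans = trans, W_e = init_matrix(hidden_dim, k), b_e = init_vector(k))
}

#' Emission scores from hidden vectors
#'
#' @param hidden n x hidden_dim matrix of encoder outputs.
#' @param crf CRF parameters from [crf_init()].
#' @return n x k emission score matrix.
#' @export
crf_emissions <- function(hidden, crf) {
  sweep(hidden %*% crf$W_e, 2L, crf$b_e, "+")
}

check_labels <- function(y, k) {
  if (any(y < 1L | y > k)) stop("label index out of range 1..", k)
}

#' Score of one label sequence
#'
#' Sum of n emission scores and n+1 transition scores
#' (START -> y_1 -> ... -> y_n -> STOP).
#'
#' @param emissions n x k emission matrix.
#' @param crf CRF parameters.
#' @param y integer label sequence (1-based indices into `crf$labels`).
#' @return scalar score.
#' @export
crf_sequence_score <- function(emissions, crf, y) {
  n <- nrow(emissions)
  stopifnot(length(y) == n)
  check_labels(y, crf$k)
  path <- c(crf$start, y, crf$stop)
  sum(emissions[cbind(seq_len(n), y)]) +
    sum(crf$trans[cbind(path[-length(path)], path[-1L])])
}

#' Log-partition function
#'
#' `log sum_y exp(S(X, y))` over all k^n label sequences, by the forward
#' recursion in log space (log-sum-exp at every step).
#'
#' @inheritParams crf_sequence_score
#' @return scalar log-partition.
#' @export
crf_log_partition <- function(emissions, crf) {
  crf_forward(emissions, crf)$logZ
}

# forward recursion; returns alpha (n x k, log forward scores) and logZ
crf_forward <- function(emissions, crf) {
  n <- nrow(emissions); k <- crf$k
  A <- crf$trans[seq_len(k), seq_len(k), drop = FALSE]
  alpha <- matrix(0, n, k)
  alpha[1L, ] <- crf$trans[crf$start, seq_len(k)] + emissions[1L, ]
  if (n > 1L) for (t in 2L:n) {
    m <- alpha[t - 1L, ] + A  # k x k: prev score + transition, per column j
    alpha[t, ] <- apply(m, 2L, logsumexp) + emissions[t, ]
  }
  logZ <- logsumexp(alpha[n, ] + crf$trans[seq_len(k), crf$stop])
  list(alpha = alpha, logZ = logZ)
}

# backward recursion; beta[t, i] = log sum over completions from label i at t
crf_backward <- function(emissions, crf) {
  n <- nrow(emissions); k <- crf$k
  A <- crf$trans[seq_len(k), seq_len(k), drop = FALSE]
  beta <- matrix(0, n, k)
  beta[n, ] <- crf$trans[seq_len(k), crf$stop]
  if (n > 1L) for (t in (n - 1L):1L) {
    m <- sweep(A, 2L, emissions[t + 1L, ] + beta[t + 1L, ], "+")
    beta[t, ] <- apply(m, 1L, logsumexp)
  }
  beta
}

#' Negative log-likelihood of a label sequence
#'
#' `-log P(y | X) = logZ - S(X, y) >= 0`.
#'
#' @inheritParams crf_sequence_score
#' @return scalar loss.
#' @export
crf_nll <- function(emissions, crf, y) {
  crf_log_partition(emissions, crf) - crf_sequence_score(emissions, crf, y)
}

# NLL plus analytic gradients via forward-backward marginals.
# d logZ / d emission[t,j]  = P(y_t = j | X)
# d logZ / d trans[i,j]     = expected count of transition i -> j
# Subtracting the gold-path indicator counts gives the NLL gradient.
crf_nll_grad <- function(emissions, crf, y) {
  n <- nrow(emissions); k <- crf$k
  fw <- crf_forward(emissions, crf)
  beta <- crf_backward(emissions, crf)
  logZ <- fw$logZ; alpha <- fw$alpha
  A <- crf$trans[seq_len(k), seq_len(k), drop = FALSE]

  marg <- exp(alpha + beta - logZ)            # n x k unary marginals
  d_em <- marg
  d_em[cbind(seq_len(n), y)] <- d_em[cbind(seq_len(n), y)] - 1

  d_tr <- matrix(0, k + 2L, k + 2L)
  if (n > 1L) for (t in seq_len(n - 1L)) {
    pair <- exp(outer(alpha[t, ], emissions[t + 1L, ] + beta[t + 1L, ], "+") +
                  A - logZ)
    d_tr[seq_len(k), seq_len(k)] <- d_tr[seq_len(k), seq_len(k)] + pair
  }
  # START row and STOP column marginals
  d_tr[crf$start, seq_len(k)] <- d_tr[crf$start, seq_len(k)] +
    exp(crf$trans[crf$start, seq_len(k)] + emissions[1L, ] + beta[1L, ] - logZ)
  d_tr[seq_len(k), crf$stop] <- d_tr[seq_len(k), crf$stop] +
    exp(alpha[n, ] + crf$trans[seq_len(k), crf$stop] - logZ)
  # gold counts
  path <- c(crf$start, y, crf$stop)
  for (t in seq_len(n + 1L))
    d_tr[path[t], path[t + 1L]] <- d_tr[path[t], path[t + 1L]] - 1
  # masked entries stay fixed
  d_tr[, crf$start] <- 0
  d_tr[crf$stop, ] <- 0
  d_tr[crf$start, crf$stop] <- 0

  loss <- logZ - crf_sequence_score(emissions, crf, y)
  list(loss = loss, d_emissions = d_em, d_trans = d_tr)
}

#' Mask of BIO-invalid transitions
#'
#' Additive matrix (same shape as `crf$trans`) that forbids `O -> I-X`,
#' `B-X -> I-Y`, `I-X -> I-Y` (X != Y) and `START -> I-X` at decode time.
#' The gold path of schema-consistent data is never made infeasible.
#'
#' @param crf CRF parameters.
#' @return (k+2) x (k+2) matrix of 0 / large-negative entries.
#' @export
crf_bio_mask <- function(crf) {
  k <- crf$k; lab <- crf$labels
  m <- matrix(0, k + 2L, k + 2L)
  cat_of <- function(l) ifelse(l == "O", NA_character_, substr(l, 3L, nchar(l)))
  for (j in seq_len(k)) {
    if (!startsWith(lab[j], "I-")) next
    for (i in seq_len(k)) {
      ok <- !startsWith(lab[i], "O") && identical(cat_of(lab[i]), cat_of(lab[j]))
      if (!ok) m[i, j] <- MASK_NEG
    }
    m[crf$start, j] <- MASK_NEG
  }
  m
}

#' Viterbi decoding
#'
#' Exact argmax over label sequences. Ties break toward the lowest label
#' index, so decoding is deterministic.
#'
#' @param emissions n x k emission matrix.
#' @param crf CRF parameters.
#' @param bio_mask apply [crf_bio_mask()] so decoded sequences are always
#'   BIO-consistent (default TRUE).
#' @return list with `path` (integer labels) and `score`.
#' @export
crf_viterbi <- function(emissions, crf, bio_mask = TRUE) {
  n <- nrow(emissions); k <- crf$k
  trans <- crf$trans
  if (bio_mask) trans <- trans + crf_bio_mask(crf)
  A <- trans[seq_len(k), seq_len(k), drop = FALSE]
  delta <- matrix(0, n, k)
  back <- matrix(0L, n, k)
  delta[1L, ] <- trans[crf$start, seq_len(k)] + emissions[1L, ]
  if (n > 1L) for (t in 2L:n) {
    m <- delta[t - 1L, ] + A
    back[t, ] <- apply(m, 2L, which.max)
    delta[t, ] <- m[cbind(back[t, ], seq_len(k))] + emissions[t, ]
  }
  fin <- delta[n, ] + trans[seq_len(k), crf$stop]
  path <- integer(n)
  path[n] <- which.max(fin)
  if (n > 1L) for (t in n:2L) path[t - 1L] <- back[t, path[t]]
  list(path = path, score = max(fin))
}
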