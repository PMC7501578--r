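# Lattice LSTM encoder.
#
# A character-level LSTM whose cell path is augmented by lexicon words: every
# dictionary match (b, e) spawns an output-gate-free "word cell" from the
# recurrent state at its first character and injects it into the character
# cell at its last character. At an injection (merge) position the cell is a
# convex combination -- weights alpha from an elementwise softmax over the
# combine-gate logits of each incoming word cell and the character input-gate
# logit -- of the word cells and the tanh candidate; the forget path from
# c_{t-1} is not used there. Hidden states are o * tanh(c) everywhere.
#
# Gate weights are stored stacked: W_c is (4H) x (d+H) with row blocks
# [input; forget; output; candidate] acting on [x_t, h_{t-1}]; W_w is
# (3H) x (dw+H) with blocks [input; forget; candidate] acting on
# [x_w, h_spawn]; the combine gate W_l is H x (d+H) acting on [x_t, c_w].
# All biases sit inside the nonlinearity.

#' Initialize lattice encoder parameters (one direction)
#'
#' @param input_dim per-character input size `d` (e.g. 100 static, or 200 with
#'   contextual embeddings concatenated).
#' @param hidden_dim recurrent size `H` (default 200).
#' @param word_dim lexicon-word embedding size (default 100).
#' @return parameter list (`W_c`, `b_c`, `W_w`, `b_w`, `W_l`, `b_l`) plus the
#'   dimensions.
#' @export
lattice_init <- function(input_dim, hidden_dim = 200L, word_dim = 100L) {
  H <- hidden_dim
  b_c <- init_vector(4L * H)
  b_c[(H + 1L):(2L * H)] <- 1          # forget-gate bias 1: healthy memory at init
  b_w <- init_vector(3L * H)
  b_w[(H + 1L):(2L * H)] <- 1
  list(W_c = init_matrix(4L * H, input_dim + H), b_c = b_c,
       W_w = init_matrix(3L * H, word_dim + H), b_w = b_w,
       W_l = init_matrix(H, input_dim + H), b_l = init_vector(H),
       input_dim = input_dim, hidden_dim = H, word_dim = word_dim)
}

lattice_weight_names <- c("W_c", "b_c", "W_w", "b_w", "W_l", "b_l")

#' Word memory cell for a lexicon match
#'
#' Computes the output-gate-free cell for a matched term: input and forget
#' gates and a tanh candidate over `[x_w, h_b]`, then
#' `c_w = f_w * c_b + i_w * candidate`. No hidden output is produced.
#'
#' @param x_w word embedding vector.
#' @param h_b,c_b hidden and cell state at the match's first character.
#' @param params lattice parameters.
#' @return the word cell vector (length `hidden_dim`).
#' @export
word_cell <- function(x_w, h_b, c_b, params) {
  H <- params$hidden_dim
  a <- drop(params$W_w %*% c(x_w, h_b)) + params$b_w
  i_w <- sigmoid(a[1:H]); f_w <- sigmoid(a[(H + 1L):(2L * H)])
  g_w <- tanh(a[(2L * H + 1L):(3L * H)])
  f_w * c_b + i_w * g_w
}

# elementwise softmax over the rows of a matrix (per column)
softmax_cols <- function(m) {
  mx <- apply(m, 2L, max)
  e <- exp(sweep(m, 2L, mx, "-"))
  sweep(e, 2L, colSums(e), "/")
}

#' One character step of the lattice recurrence
#'
#' With no incoming word cells this is the standard LSTM update. With
#' incoming cells, the new cell value is the alpha-weighted sum of the word
#' cells and the tanh candidate, where alpha is an elementwise softmax over
#' each cell's combine-gate logit and the character input-gate logit, so the
#' weights at every position sum to 1.
#'
#' @param x_c character input vector.
#' @param h_prev,c_prev previous hidden and cell state.
#' @param incoming list of word-cell vectors ending exactly at this position
#'   (possibly empty).
#' @param params lattice parameters.
#' @return list with `h`, `c`, and `alphas` (an `(M+1) x H` matrix at merge
#'   positions -- one row per word cell plus the final character row -- or
#'   NULL).
#' @export
char_step <- function(x_c, h_prev, c_prev, incoming, params) {
  H <- params$hidden_dim
  a <- drop(params$W_c %*% c(x_c, h_prev)) + params$b_c
  a_i <- a[1:H]; a_f <- a[(H + 1L):(2L * H)]
  a_o <- a[(2L * H + 1L):(3L * H)]; a_g <- a[(3L * H + 1L):(4L * H)]
  o <- sigmoid(a_o); g <- tanh(a_g)
  M <- length(incoming)
  if (M == 0L) {
    c_t <- sigmoid(a_f) * c_prev + sigmoid(a_i) * g
    alphas <- NULL
  } else {
    logits <- matrix(0, M + 1L, H)
    for (m in seq_len(M))
      logits[m, ] <- drop(params$W_l %*% c(x_c, incoming[[m]])) + params$b_l
    logits[M + 1L, ] <- a_i
    alphas <- softmax_cols(logits)
    cw <- do.call(rbind, incoming)
    c_t <- colSums(alphas[seq_len(M), , drop = FALSE] * cw) + alphas[M + 1L, ] * g
  }
  list(h = o * tanh(c_t), c = c_t, alphas = alphas)
}

# ---- full forward pass with cache ------------------------------------------

# matches: data.frame(begin, end, term_id) 0-based half-open; XW: one word
# embedding row per match. Word cell for match (b, e) spawns from the state
# after character b+1 (1-based) and merges into the cell at character e.
lattice_forward <- function(X, matches, XW, params) {
  n <- nrow(X); H <- params$hidden_dim; d <- params$input_dim
  nm <- if (is.null(matches)) 0L else nrow(matches)
  W_ch <- params$W_c[, (d + 1L):(d + H), drop = FALSE]
  GX <- tcrossprod(X, params$W_c[, 1:d, drop = FALSE])  # n x 4H input parts

  spawn_at <- if (nm) matches$begin + 1L else integer(0)
  merge_at <- if (nm) matches$end else integer(0)

  Hs <- matrix(0, n, H); Cs <- matrix(0, n, H)
  A <- matrix(0, n, 4L * H)         # gate preactivations
  cw <- vector("list", nm)          # word cell values
  wcache <- vector("list", nm)      # word-cell internals
  mcache <- vector("list", n)       # merge internals per position

  h <- numeric(H); c <- numeric(H)
  idx_i <- 1:H; idx_f <- (H + 1L):(2L * H)
  idx_o <- (2L * H + 1L):(3L * H); idx_g <- (3L * H + 1L):(4L * H)

  for (t in seq_len(n)) {
    a <- GX[t, ] + drop(W_ch %*% h) + params$b_c
    A[t, ] <- a
    o <- sigmoid(a[idx_o]); g <- tanh(a[idx_g])
    inc <- which(merge_at == t)
    if (length(inc) == 0L) {
      i <- sigmoid(a[idx_i]); f <- sigmoid(a[idx_f])
      c_new <- f * c + i * g
      mcache[[t]] <- list(merge = FALSE, c_prev = c)
    } else {
      M <- length(inc)
      logits <- matrix(0, M + 1L, H)
      for (j in seq_len(M))
        logits[j, ] <- drop(params$W_l %*% c(X[t, ], cw[[inc[j]]])) + params$b_l
      logits[M + 1L, ] <- a[idx_i]
      alphas <- softmax_cols(logits)
      CWm <- do.call(rbind, cw[inc])
      c_new <- colSums(alphas[seq_len(M), , drop = FALSE] * CWm) +
        alphas[M + 1L, ] * g
      mcache[[t]] <- list(merge = TRUE, inc = inc, alphas = alphas)
    }
    c <- c_new
    h <- o * tanh(c)
    Hs[t, ] <- h; Cs[t, ] <- c
    for (j in which(spawn_at == t)) {
      z_w <- c(XW[j, ], h)
      a_w <- drop(params$W_w %*% z_w) + params$b_w
      i_w <- sigmoid(a_w[1:H]); f_w <- sigmoid(a_w[(H + 1L):(2L * H)])
      g_w <- tanh(a_w[(2L * H + 1L):(3L * H)])
      cw[[j]] <- f_w * c + i_w * g_w
      wcache[[j]] <- list(i_w = i_w, f_w = f_w, g_w = g_w, spawn = t)
    }
  }
  list(H = Hs, C = Cs, A = A, cw = cw, wcache = wcache, mcache = mcache,
       X = X, XW = XW, spawn_at = spawn_at, merge_at = merge_at, n = n)
}

# Backward pass. dH: n x H gradient on hidden outputs. Returns gradients on
# inputs, word embeddings and parameters.
lattice_backward <- function(cache, dH, params) {
  n <- cache$n; H <- params$hidden_dim; d <- params$input_dim
  dw <- params$word_dim
  idx_i <- 1:H; idx_f <- (H + 1L):(2L * H)
  idx_o <- (2L * H + 1L):(3L * H); idx_g <- (3L * H + 1L):(4L * H)
  W_cx <- params$W_c[, 1:d, drop = FALSE]
  W_ch <- params$W_c[, (d + 1L):(d + H), drop = FALSE]

  dA <- matrix(0, n, 4L * H)           # gate preactivation grads
  dX <- matrix(0, n, d)
  nm <- length(cache$cw)
  dXW <- if (nm) matrix(0, nm, dw) else matrix(0, 0L, dw)
  dcw <- vector("list", nm)            # accumulated word-cell grads
  for (j in seq_len(nm)) dcw[[j]] <- numeric(H)
  dAw_rows <- matrix(0, max(nm, 1L), 3L * H)  # word gate preact grads
  dLog_list <- list()                  # combine logits: rows + their (t, cw)

  dW_l <- params$W_l * 0; db_l <- numeric(H)
  dc_next <- numeric(H)                # dc flowing into step t from t+1
  dh_next <- numeric(H)

  for (t in rev(seq_len(n))) {
    dh <- dH[t, ] + dh_next
    dc <- dc_next
    # word cells spawned here consumed (h_t, c_t)
    for (j in which(cache$spawn_at == t)) {
      wc <- cache$wcache[[j]]
      g_cw <- dcw[[j]]
      c_spawn <- cache$C[t, ]
      da_wi <- g_cw * wc$g_w * wc$i_w * (1 - wc$i_w)
      da_wf <- g_cw * c_spawn * wc$f_w * (1 - wc$f_w)
      da_wg <- g_cw * wc$i_w * (1 - wc$g_w^2)
      da_w <- c(da_wi, da_wf, da_wg)
      dAw_rows[j, ] <- da_w
      dz_w <- drop(crossprod(params$W_w, da_w))
      dXW[j, ] <- dXW[j, ] + dz_w[1:dw]
      dh <- dh + dz_w[(dw + 1L):(dw + H)]
      dc <- dc + g_cw * wc$f_w
    }
    a <- cache$A[t, ]
    o <- sigmoid(a[idx_o]); g <- tanh(a[idx_g])
    tc <- tanh(cache$C[t, ])
    do_ <- dh * tc
    dc <- dc + dh * o * (1 - tc^2)
    da <- numeric(4L * H)
    da[idx_o] <- do_ * o * (1 - o)
    mc <- cache$mcache[[t]]
    if (isTRUE(mc$merge)) {
      inc <- mc$inc; M <- length(inc)
      alphas <- mc$alphas
      CWm <- do.call(rbind, cache$cw[inc])
      dalpha <- matrix(0, M + 1L, H)
      for (m in seq_len(M)) {
        dalpha[m, ] <- dc * CWm[m, ]
        dcw[[inc[m]]] <- dcw[[inc[m]]] + dc * alphas[m, ]
      }
      dalpha[M + 1L, ] <- dc * g
      dg <- dc * alphas[M + 1L, ]
      # softmax backward, per column
      dot <- colSums(alphas * dalpha)
      dlog <- alphas * sweep(dalpha, 2L, dot, "-")
      for (m in seq_len(M)) {
        dW_l <- dW_l + outer(dlog[m, ], c(cache$X[t, ], CWm[m, ]))
        db_l <- db_l + dlog[m, ]
        dv <- drop(crossprod(params$W_l, dlog[m, ]))
        dX[t, ] <- dX[t, ] + dv[1:d]
        dcw[[inc[m]]] <- dcw[[inc[m]]] + dv[(d + 1L):(d + H)]
      }
      da[idx_i] <- dlog[M + 1L, ]
      da[idx_g] <- dg * (1 - g^2)
      dc_next <- numeric(H)            # forget path unused at merges
    } else {
      i <- sigmoid(a[idx_i]); f <- sigmoid(a[idx_f])
      di <- dc * g; df <- dc * mc$c_prev; dg <- dc * i
      da[idx_i] <- di * i * (1 - i)
      da[idx_f] <- df * f * (1 - f)
      da[idx_g] <- dg * (1 - g^2)
      dc_next <- dc * f
    }
    dA[t, ] <- da
    dh_next <- drop(crossprod(W_ch, da))
  }
  # deferred bulk accumulations
  Z_h <- rbind(numeric(H), cache$H[-n, , drop = FALSE])  # h_{t-1} rows
  dW_c <- crossprod(dA, cbind(cache$X, Z_h))
  db_c <- colSums(dA)
  dX <- dX + dA %*% W_cx
  if (nm) {
    Z_w <- matrix(0, nm, dw + H)
    for (j in seq_len(nm))
      Z_w[j, ] <- c(cache$XW[j, ], cache$H[cache$wcache[[j]]$spawn, ])
    dW_w <- crossprod(dAw_rows[seq_len(nm), , drop = FALSE], Z_w)
    db_w <- colSums(dAw_rows[seq_len(nm), , drop = FALSE])
  } else {
    dW_w <- params$W_w * 0; db_w <- numeric(3L * H)
  }
  list(dX = dX, dXW = dXW,
       grads = list(W_c = dW_c, b_c = db_c, W_w = dW_w, b_w = db_w,
                    W_l = dW_l, b_l = db_l))
}

#' Encode a sentence with the lattice LSTM (one direction)
#'
#' @param inputs n x input_dim matrix of per-character input vectors.
#' @param matches data.frame from [lexicon_match()] (may have zero rows).
#' @param word_vectors one embedding row per match (n_matches x word_dim), or
#'   NULL when there are no matches.
#' @param params lattice parameters from [lattice_init()].
#' @param direction `"forward"` or `"backward"`; the backward direction
#'   reverses the characters and mirrors the match coordinates first, and
#'   returns hidden states in original sentence order.
#' @return n x hidden_dim matrix of hidden states.
#' @export
lattice_encode <- function(inputs, matches, word_vectors, params,
                           direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  n <- nrow(inputs)
  nm <- if (is.null(matches)) 0L else nrow(matches)
  if (nm == 0L) {
    matches <- data.frame(begin = integer(0), end = integer(0),
                          term_id = integer(0))
    word_vectors <- matrix(0, 0L, params$word_dim)
  }
  if (any(matches$end - matches$begin < 2L)) stop("match shorter than 2")
  if (any(matches$end > n | matches$begin < 0L)) stop("match out of range")
  if (direction == "backward") {
    rev_m <- data.frame(begin = n - matches$end, end = n - matches$begin,
                        term_id = matches$term_id)
    ord <- order(rev_m$end, rev_m$begin)
    out <- lattice_forward(inputs[n:1, , drop = FALSE],
                           rev_m[ord, , drop = FALSE],
                           word_vectors[ord, , drop = FALSE], params)
    out$H[n:1, , drop = FALSE]
  } else {
    lattice_forward(inputs, matches, word_vectors, params)$H
  }
}

#' Bidirectional lattice encoding
#'
#' Runs [lattice_encode()] forward and backward with separate parameter sets
#' and concatenates the per-position hidden states.
#'
#' @inheritParams lattice_encode
#' @param params_fwd,params_bwd forward and backward parameter sets.
#' @return n x (2 * hidden_dim) matrix.
#' @export
lattice_encode_bidirectional <- function(inputs, matches, word_vectors,
                                         params_fwd, params_bwd) {
  cbind(lattice_encode(inputs, matches, word_vectors, params_fwd, "forward"),
        lattice_encode(inputs, matches, word_vectors, params_bwd, "backward"))
}

#' Assemble per-character input vectors
#'
#' Concatenates the static character embedding with the contextualized
#' (scalar-mixed language model) embedding when available; applies inverted
#' dropout to the concatenated vector at training time.
#'
#' @param chars character vector.
#' @param static_table character `embedding_table`.
#' @param elmo optional n x elmo_dim matrix of contextual embeddings.
#' @param dropout_rate dropout probability (applied only when
#'   `training = TRUE`).
#' @param training logical.
#' @return list with `X` (n x d input matrix) and `mask` (the dropout mask,
#'   or NULL), needed to route gradients at training time.
#' @export
build_input_representation <- function(chars, static_table, elmo = NULL,
                                       dropout_rate = 0, training = FALSE) {
  X <- emb_rows(static_table, chars)
  if (!is.null(elmo)) {
    if (nrow(elmo) != length(chars))
      stop("contextual embedding rows (", nrow(elmo),
           ") do not match sentence length (", length(chars), ")")
    X <- cbind(X, elmo)
  }
  mask <- NULL
  if (training && dropout_rate > 0) {
    keep <- 1 - dropout_rate
    mask <- matrix(stats::rbinom(length(X), 1L, keep) / keep, nrow = nrow(X))
    X <- X * mask
  }
  list(X = X, mask = mask)
}
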