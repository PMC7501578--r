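# Variant contextualized character language model.
#
# A two-layer bidirectional LSTM language model over single characters: the
# convolutional character encoder of the original architecture is removed and
# a plain character embedding (dim 100) feeds the recurrent layers directly.
# Each direction's layer output is projected to 50 dimensions, so each
# combined layer representation [forward; backward] is 100-dimensional, as is
# the token layer. The forward direction predicts each character from its
# left context and the backward direction from its right context; the
# training objective is the summed log-likelihood of both directions. The
# vocabulary softmax is shared between directions. Sentinel BOS/EOS tokens
# are added internally and stripped from representations.

BOS <- "<bos>"; EOS <- "<eos>"; UNK_TOK <- "<unk>"

#' Initialize bidirectional language model parameters
#'
#' @param vocab character vector of known characters (sentinels are added).
#' @param emb_dim token embedding size (default 100).
#' @param hidden_dim per-direction LSTM size before projection (default 100).
#' @param proj_dim per-direction projected size (default 50, so each combined
#'   layer is `2 * proj_dim` = 100-dim).
#' @param n_layers number of recurrent layers per direction (default 2).
#' @param seed integer seed for initialization.
#' @return parameter list of class `bilm_params`.
#' @export
bilm_init <- function(vocab, emb_dim = 100L, hidden_dim = 100L,
                      proj_dim = 50L, n_layers = 2L, seed = 1L) {
  vocab <- unique(c(BOS, EOS, UNK_TOK, vocab))
  V <- length(vocab)
  idx <- seq_len(V); names(idx) <- vocab
  with_seed(seed, {
    mk_dir <- function() {
      layers <- vector("list", n_layers)
      d_in <- emb_dim
      for (l in seq_len(n_layers)) {
        b <- init_vector(4L * hidden_dim)
        b[(hidden_dim + 1L):(2L * hidden_dim)] <- 1   # forget bias 1
        layers[[l]] <- list(W = init_matrix(4L * hidden_dim, d_in + hidden_dim),
                            b = b,
                            P = init_matrix(proj_dim, hidden_dim),
                            pb = init_vector(proj_dim))
        d_in <- proj_dim
      }
      layers
    }
    params <- list(emb = init_matrix(V, emb_dim),
                   fwd = mk_dir(), bwd = mk_dir(),
                   W_s = init_matrix(V, proj_dim), b_s = init_vector(V))
  })
  structure(c(params,
              list(vocab = idx, emb_dim = emb_dim, hidden_dim = hidden_dim,
                   proj_dim = proj_dim, n_layers = n_layers)),
            class = "bilm_params")
}

bilm_weight_names <- c("emb", "fwd", "bwd", "W_s", "b_s")

bilm_ids <- function(chars, params) {
  i <- params$vocab[chars]
  i[is.na(i)] <- params$vocab[[UNK_TOK]]
  unname(i)
}

# ---- batched plain LSTM layer ----------------------------------------------
# X: array (B, T, d_in). Returns hidden states (B, T, H) and a cache.

lstm_layer_forward <- function(X, layer, H) {
  B <- dim(X)[1]; T_ <- dim(X)[2]; d <- dim(X)[3]
  Xf <- matrix(X, B * T_, d)
  AX <- Xf %*% t(layer$W[, 1:d, drop = FALSE])
  W_h <- layer$W[, (d + 1L):(d + H), drop = FALSE]
  A <- array(0, c(B, T_, 4L * H)); Cs <- array(0, c(B, T_, H))
  Hs <- array(0, c(B, T_, H))
  h <- matrix(0, B, H); c <- matrix(0, B, H)
  ii <- 1:H; ff <- (H + 1L):(2L * H); oo <- (2L * H + 1L):(3L * H)
  gg <- (3L * H + 1L):(4L * H)
  for (t in seq_len(T_)) {
    a <- AX[(t - 1L) * B + seq_len(B), , drop = FALSE] + h %*% t(W_h)
    a <- sweep(a, 2L, layer$b, "+")
    i <- sigmoid(a[, ii, drop = FALSE]); f <- sigmoid(a[, ff, drop = FALSE])
    o <- sigmoid(a[, oo, drop = FALSE]); g <- tanh(a[, gg, drop = FALSE])
    c <- f * c + i * g
    h <- o * tanh(c)
    A[, t, ] <- a; Cs[, t, ] <- c; Hs[, t, ] <- h
  }
  list(H = Hs, cache = list(A = A, C = Cs, X = X, d = d))
}

lstm_layer_backward <- function(cache, dH, layer, H) {
  B <- dim(dH)[1]; T_ <- dim(dH)[2]; d <- cache$d
  W_h <- layer$W[, (d + 1L):(d + H), drop = FALSE]
  ii <- 1:H; ff <- (H + 1L):(2L * H); oo <- (2L * H + 1L):(3L * H)
  gg <- (3L * H + 1L):(4L * H)
  dA <- array(0, c(B, T_, 4L * H))
  dc <- matrix(0, B, H); dh_carry <- matrix(0, B, H)
  for (t in rev(seq_len(T_))) {
    a <- cache$A[, t, , drop = FALSE]; dim(a) <- c(B, 4L * H)
    ct <- cache$C[, t, , drop = FALSE]; dim(ct) <- c(B, H)
    c_prev <- if (t > 1L) {
      x <- cache$C[, t - 1L, , drop = FALSE]; dim(x) <- c(B, H); x
    } else matrix(0, B, H)
    i <- sigmoid(a[, ii, drop = FALSE]); f <- sigmoid(a[, ff, drop = FALSE])
    o <- sigmoid(a[, oo, drop = FALSE]); g <- tanh(a[, gg, drop = FALSE])
    tc <- tanh(ct)
    dh <- dH[, t, , drop = FALSE]; dim(dh) <- c(B, H)
    dh <- dh + dh_carry
    do_ <- dh * tc
    dc <- dc + dh * o * (1 - tc^2)
    dat <- matrix(0, B, 4L * H)
    dat[, ii] <- dc * g * i * (1 - i)
    dat[, ff] <- dc * c_prev * f * (1 - f)
    dat[, oo] <- do_ * o * (1 - o)
    dat[, gg] <- dc * i * (1 - g^2)
    dA[, t, ] <- dat
    dh_carry <- dat %*% W_h
    dc <- dc * f
  }
  dAf <- matrix(dA, B * T_, 4L * H)
  Hprev <- array(0, c(B, T_, H))
  if (T_ > 1L) Hprev[, 2:T_, ] <- tanh(cache$C[, 1:(T_ - 1L), , drop = FALSE]) *
      sigmoid(cache$A[, 1:(T_ - 1L), oo, drop = FALSE])
  Z <- cbind(matrix(cache$X, B * T_, d), matrix(Hprev, B * T_, H))
  dW <- t(dAf) %*% Z
  db <- colSums(dAf)
  dXf <- dAf %*% layer$W[, 1:d, drop = FALSE]
  list(dX = array(dXf, c(B, T_, d)), grads = list(W = dW, b = db))
}

# one direction of the LM over padded id matrix `ids` (B x T). Produces the
# projected states of every layer plus caches for backprop.
bilm_direction_forward <- function(ids, dir_layers, params) {
  B <- nrow(ids); T_ <- ncol(ids)
  H <- params$hidden_dim; P <- params$proj_dim
  X <- array(params$emb[as.vector(ids), ], c(B, T_, params$emb_dim))
  layer_in <- X
  outs <- list(); caches <- list()
  for (l in seq_len(params$n_layers)) {
    lay <- dir_layers[[l]]
    fw <- lstm_layer_forward(layer_in, lay, H)
    Hf <- matrix(fw$H, B * T_, H)
    Pf <- sweep(Hf %*% t(lay$P), 2L, lay$pb, "+")
    outs[[l]] <- array(Pf, c(B, T_, P))
    caches[[l]] <- list(lstm = fw$cache, Hflat = Hf, in_dim = dim(layer_in)[3])
    layer_in <- outs[[l]]
  }
  list(proj = outs, caches = caches, X = X)
}

# backprop one direction given gradients on each layer's projected output
bilm_direction_backward <- function(fwd, dProj, dir_layers, params, ids) {
  B <- nrow(ids); T_ <- ncol(ids)
  H <- params$hidden_dim; P <- params$proj_dim
  gl <- vector("list", params$n_layers)
  d_next_in <- NULL  # gradient flowing into layer l's input
  for (l in rev(seq_len(params$n_layers))) {
    lay <- dir_layers[[l]]
    dP_l <- dProj[[l]]
    if (!is.null(d_next_in)) dP_l <- dP_l + d_next_in
    dPf <- matrix(dP_l, B * T_, P)
    dHf <- dPf %*% lay$P
    dPw <- t(dPf) %*% fwd$caches[[l]]$Hflat
    dpb <- colSums(dPf)
    bk <- lstm_layer_backward(fwd$caches[[l]]$lstm, array(dHf, c(B, T_, H)),
                              lay, H)
    gl[[l]] <- list(W = bk$grads$W, b = bk$grads$b, P = dPw, pb = dpb)
    d_next_in <- bk$dX
  }
  demb <- matrix(0, nrow(params$emb), params$emb_dim)
  dXf <- matrix(d_next_in, B * T_, params$emb_dim)
  agg <- rowsum(dXf, group = as.vector(ids))
  demb[as.integer(rownames(agg)), ] <- agg
  list(layers = gl, demb = demb)
}

# pad sentences of ids to a B x T matrix (pad with BOS id; padded targets
# masked out of the loss)
pad_ids <- function(id_list, pad) {
  T_ <- max(lengths(id_list))
  out <- matrix(pad, length(id_list), T_)
  for (i in seq_along(id_list)) out[i, seq_along(id_list[[i]])] <- id_list[[i]]
  out
}

# forward + loss (+ optional grads) for a batch of sentences, both directions.
# Per-token loss = (forward NLL + backward NLL) / number of predicted targets
# (each direction predicts every character plus one sentinel).
bilm_batch <- function(sentences, params, want_grads = FALSE) {
  ids <- lapply(sentences, bilm_ids, params = params)
  bos <- params$vocab[[BOS]]; eos <- params$vocab[[EOS]]
  n_tok <- sum(lengths(ids) + 1L)
  # forward stream: input [BOS, t_1..t_n], target [t_1..t_n, EOS]
  in_f <- lapply(ids, function(x) c(bos, x))
  tg_f <- lapply(ids, function(x) c(x, eos))
  # backward stream: input [EOS, t_n..t_1], target [t_n..t_1, BOS]
  in_b <- lapply(ids, function(x) c(eos, rev(x)))
  tg_b <- lapply(ids, function(x) c(rev(x), bos))
  run_dir <- function(inp, tg, dir_layers) {
    M_in <- pad_ids(inp, bos)
    M_tg <- pad_ids(tg, bos)
    mask <- matrix(0, nrow(M_in), ncol(M_in))
    for (i in seq_along(inp)) mask[i, seq_along(inp[[i]])] <- 1
    fw <- bilm_direction_forward(M_in, dir_layers, params)
    B <- nrow(M_in); T_ <- ncol(M_in)
    top <- matrix(fw$proj[[params$n_layers]], B * T_, params$proj_dim)
    logits <- sweep(top %*% t(params$W_s), 2L, params$b_s, "+")
    mx <- apply(logits, 1L, max)
    lse <- mx + log(rowSums(exp(logits - mx)))
    tgt <- as.vector(M_tg); msk <- as.vector(mask)
    logp <- logits[cbind(seq_along(tgt), tgt)] - lse
    loss <- -sum(logp * msk)
    list(loss = loss, fw = fw, logits = logits, lse = lse, tgt = tgt,
         msk = msk, M_in = M_in, B = B, T_ = T_)
  }
  rf <- run_dir(in_f, tg_f, params$fwd)
  rb <- run_dir(in_b, tg_b, params$bwd)
  loss <- (rf$loss + rb$loss) / n_tok
  if (!want_grads) return(list(loss = loss, n_tok = n_tok))

  grad_dir <- function(r, dir_layers) {
    prob <- exp(r$logits - r$lse)
    dlogits <- prob
    dlogits[cbind(seq_along(r$tgt), r$tgt)] <-
      dlogits[cbind(seq_along(r$tgt), r$tgt)] - 1
    dlogits <- dlogits * r$msk / n_tok
    top <- matrix(r$fw$proj[[params$n_layers]], r$B * r$T_, params$proj_dim)
    dW_s <- t(dlogits) %*% top
    db_s <- colSums(dlogits)
    dTop <- dlogits %*% params$W_s
    dProj <- vector("list", params$n_layers)
    for (l in seq_len(params$n_layers))
      dProj[[l]] <- array(0, c(r$B, r$T_, params$proj_dim))
    dProj[[params$n_layers]] <- array(dTop, c(r$B, r$T_, params$proj_dim))
    bk <- bilm_direction_backward(r$fw, dProj, dir_layers, params, r$M_in)
    list(layers = bk$layers, demb = bk$demb, dW_s = dW_s, db_s = db_s)
  }
  gf <- grad_dir(rf, params$fwd)
  gb <- grad_dir(rb, params$bwd)
  grads <- list(emb = gf$demb + gb$demb, fwd = gf$layers, bwd = gb$layers,
                W_s = gf$dW_s + gb$dW_s, b_s = gf$db_s + gb$db_s)
  list(loss = loss, n_tok = n_tok, grads = grads)
}

#' Per-token negative log-likelihood of the language model
#'
#' The negated joint objective, averaged per predicted target: at every
#' position the forward direction predicts the character from its left
#' context and the backward direction from its right context, and both
#' contributions are summed.
#'
#' @param sentences list of character vectors.
#' @param params `bilm_params`.
#' @return scalar loss (>= 0).
#' @export
bilm_nll <- function(sentences, params) {
  if (length(sentences) == 0L) stop("empty batch")
  bilm_batch(sentences, params, want_grads = FALSE)$loss
}

#' Layer representations of a sentence
#'
#' Runs both directions and returns the `L + 1` layer stack: layer 0 is the
#' token embedding; layer j >= 1 concatenates the forward and backward
#' projected states (`2 * proj_dim` each). Sentinels are stripped: the
#' forward state at position k has consumed characters 1..k only, and the
#' backward state characters k..n only.
#'
#' @param chars character vector (length >= 1).
#' @param params `bilm_params`.
#' @return list of `n_layers + 1` matrices, each `n x (2 * proj_dim)`, class
#'   `layer_stack`.
#' @export
bilm_representations <- function(chars, params) {
  n <- length(chars)
  if (n == 0L) stop("empty sentence")
  ids <- bilm_ids(chars, params)
  bos <- params$vocab[[BOS]]; eos <- params$vocab[[EOS]]
  f <- bilm_direction_forward(matrix(c(bos, ids), 1L), params$fwd, params)
  b <- bilm_direction_forward(matrix(c(eos, rev(ids)), 1L), params$bwd, params)
  P <- params$proj_dim
  stack <- vector("list", params$n_layers + 1L)
  stack[[1]] <- params$emb[ids, , drop = FALSE]
  for (l in seq_len(params$n_layers)) {
    pf <- matrix(f$proj[[l]], n + 1L, P)[-1L, , drop = FALSE]      # after t_k
    pb <- matrix(b$proj[[l]], n + 1L, P)[-1L, , drop = FALSE]
    pb <- pb[n:1, , drop = FALSE]                                  # back to order
    stack[[l + 1L]] <- cbind(pf, pb)
  }
  structure(stack, class = "layer_stack")
}

#' Initialize scalar-mixer parameters
#'
#' @param n_layers number of recurrent layers L (the mixer has L + 1
#'   weights).
#' @return list with `s_logits` (zeros: uniform softmax) and `gamma` (1).
#' @export
scalar_mix_init <- function(n_layers = 2L) {
  list(s_logits = numeric(n_layers + 1L), gamma = 1)
}

#' Scalar mix of a layer stack
#'
#' `gamma * sum_j softmax(s)_j * layer_j`, the task-specific combination of
#' language-model layers.
#'
#' @param stack a `layer_stack` from [bilm_representations()].
#' @param mix parameters from [scalar_mix_init()].
#' @return n x dim matrix of contextual embeddings.
#' @export
scalar_mix <- function(stack, mix) {
  if (length(mix$s_logits) != length(stack))
    stop("mixer has ", length(mix$s_logits), " weights for ", length(stack),
         " layers")
  s <- exp(mix$s_logits - max(mix$s_logits))
  s <- s / sum(s)
  out <- stack[[1]] * 0
  for (j in seq_along(stack)) out <- out + s[j] * stack[[j]]
  mix$gamma * out
}

# gradient of scalar_mix wrt the mixer parameters (the language model itself
# stays frozen during tagger training)
scalar_mix_grad <- function(stack, mix, d_out) {
  s <- exp(mix$s_logits - max(mix$s_logits)); s <- s / sum(s)
  wsum <- stack[[1]] * 0
  for (j in seq_along(stack)) wsum <- wsum + s[j] * stack[[j]]
  dgamma <- sum(d_out * wsum)
  dots <- vapply(seq_along(stack),
                 function(j) sum(d_out * stack[[j]]) * mix$gamma, numeric(1))
  ds <- s * (dots - sum(s * dots))
  list(s_logits = ds, gamma = dgamma)
}

#' Pretrain the language model
#'
#' Minibatch Adam on the joint two-direction likelihood. All randomness
#' (initialization, shuffling) derives from `seed`.
#'
#' @param sentences list of character vectors (an unlabeled corpus).
#' @param epochs training epochs (0 returns the initialized model unchanged).
#' @param lr Adam learning rate.
#' @param batch_size sentences per update.
#' @param seed integer seed.
#' @param emb_dim,hidden_dim,proj_dim,n_layers architecture; see
#'   [bilm_init()].
#' @param verbose print per-epoch loss.
#' @return list with `params` (`bilm_params`) and `history` (per-epoch mean
#'   per-token NLL).
#' @export
train_bilm <- function(sentences, epochs = 100L, lr = 5e-3, batch_size = 32L,
                       seed = 1L, emb_dim = 100L, hidden_dim = 100L,
                       proj_dim = 50L, n_layers = 2L, verbose = FALSE) {
  if (length(sentences) == 0L) stop("empty corpus")
  vocab <- sort(unique(unlist(sentences)), method = "radix")
  params <- bilm_init(vocab, emb_dim, hidden_dim, proj_dim, n_layers,
                      seed = seed)
  meta <- params[c("vocab", "emb_dim", "hidden_dim", "proj_dim", "n_layers")]
  weights <- params[bilm_weight_names]
  opt <- adam_init(weights)
  history <- numeric(0)
  ns <- length(sentences)
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(ns)
      ep_loss <- 0; ep_tok <- 0
      for (s0 in seq(1L, ns, by = batch_size)) {
        idx <- ord[s0:min(s0 + batch_size - 1L, ns)]
        cur <- structure(c(weights, meta), class = "bilm_params")
        r <- bilm_batch(sentences[idx], cur, want_grads = TRUE)
        st <- adam_step(weights, r$grads, opt, lr = lr)
        weights <- st$params; opt <- st$state
        ep_loss <- ep_loss + r$loss * r$n_tok; ep_tok <- ep_tok + r$n_tok
      }
      history[ep] <- ep_loss / ep_tok
      if (verbose) message(sprintf("bilm epoch %d nll %.4f", ep, history[ep]))
    }
  })
  list(params = structure(c(weights, meta), class = "bilm_params"),
       history = history)
}
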