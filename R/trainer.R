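# End-to-end tagger: static character embeddings (optionally concatenated
# with frozen contextual language-model embeddings through a trainable scalar
# mixer) -> bidirectional lattice LSTM -> linear emission projection ->
# linear-chain CRF. Trained per sentence (batch size 1) by SGD with learning
# rate decay and global-norm gradient clipping; all gradients are analytic.

#' Training configuration
#'
#' Defaults are the study's hyperparameters: 100-dim character, word and
#' contextual embeddings, dropout 0.5, recurrent hidden size 200, one lattice
#' layer, SGD at 0.015 with decay 0.05, 10 epochs, batch size 1.
#'
#' @param char_emb_size,elmo_emb_size,word_emb_size embedding sizes.
#' @param dropout input-embedding dropout rate at training time.
#' @param hidden recurrent hidden size per direction.
#' @param lstm_layers number of lattice layers (1 supported).
#' @param lr,lr_decay SGD learning rate and decay; the rate at epoch e
#'   (0-based) is `lr / (1 + lr_decay * e)`.
#' @param epochs training epochs.
#' @param batch_size sentences per update (1; the lattice is unbatched).
#' @param seed integer seed controlling initialization, shuffling, dropout.
#' @param elmo_enabled concatenate contextual embeddings (needs a trained
#'   language model).
#' @param bidirectional encode in both directions (default TRUE).
#' @param use_lexicon disable to reduce the model to the plain
#'   character-BiLSTM-CRF baseline.
#' @param clip_norm global gradient-norm bound.
#' @param select_best_dev keep the epoch with the best dev F1 rather than the
#'   final one.
#' @return list of class `ner_config`.
#' @export
ner_config <- function(char_emb_size = 100L, elmo_emb_size = 100L,
                       word_emb_size = 100L, dropout = 0.5, hidden = 200L,
                       lstm_layers = 1L, lr = 0.015, lr_decay = 0.05,
                       epochs = 10L, batch_size = 1L, seed = 1L,
                       elmo_enabled = TRUE, bidirectional = TRUE,
                       use_lexicon = TRUE, clip_norm = 50,
                       select_best_dev = FALSE) {
  stopifnot(char_emb_size > 0, hidden > 0, lr > 0, lr_decay >= 0, epochs >= 0,
            batch_size == 1L, lstm_layers == 1L, dropout >= 0, dropout < 1)
  structure(as.list(environment()), class = "ner_config")
}

#' Learning rate schedule
#'
#' `lr0 / (1 + decay * epoch)` with a 0-based epoch, the schedule of the
#' lattice-LSTM lineage (the named rate and decay do not themselves fix a
#' formula).
#'
#' @param lr0 initial rate.
#' @param decay decay rate.
#' @param epoch 0-based epoch index.
#' @return the rate for that epoch.
#' @export
lr_at_epoch <- function(lr0, decay, epoch) {
  stopifnot(epoch >= 0)
  lr0 / (1 + decay * epoch)
}

label_set <- function(corpora) {
  cats <- unlist(lapply(corpora, function(s) tag_category(s$tags)))
  cats <- sort(unique(cats[!is.na(cats)]))
  if (length(cats) == 0L) return("O")
  c("O", as.vector(rbind(paste0("B-", cats), paste0("I-", cats))))
}

#' Initialize a tagger model
#'
#' @param labels BIO label set (e.g. from training tags).
#' @param char_table character `embedding_table`.
#' @param word_table word (lexicon term) `embedding_table`.
#' @param bilm optional frozen `bilm_params` for contextual embeddings.
#' @param config `ner_config`.
#' @return list of class `ner_model` holding the trainable weight tree, the
#'   frozen language model, the tables' vocabularies and the config.
#' @export
ner_init <- function(labels, char_table, word_table, bilm = NULL, config) {
  if (config$elmo_enabled && is.null(bilm))
    stop("elmo_enabled = TRUE but no language model supplied")
  d_in <- config$char_emb_size +
    if (config$elmo_enabled) config$elmo_emb_size else 0L
  H <- config$hidden
  with_seed(config$seed, {
    weights <- list(
      char_emb = char_table$vectors,
      word_emb = word_table$vectors,
      lat_fwd = lattice_init(d_in, H, config$word_emb_size)[lattice_weight_names],
      lat_bwd = if (config$bidirectional)
        lattice_init(d_in, H, config$word_emb_size)[lattice_weight_names]
        else NULL,
      crf = NULL,
      mix = if (config$elmo_enabled) scalar_mix_init(bilm$n_layers) else NULL)
    enc_dim <- if (config$bidirectional) 2L * H else H
    cr <- crf_init(labels, enc_dim)
    weights$crf <- cr[c("trans", "W_e", "b_e")]
  })
  weights <- Filter(Negate(is.null), weights)
  structure(list(weights = weights, labels = labels, k = length(labels),
                 char_vocab = char_table$vocab, char_unk = char_table$unk,
                 word_vocab = word_table$vocab, word_unk = word_table$unk,
                 bilm = bilm, config = config,
                 input_dim = d_in, hidden = H), class = "ner_model")
}

model_lattice_params <- function(model, which) {
  p <- model$weights[[which]]
  c(p, list(input_dim = model$input_dim, hidden_dim = model$hidden,
            word_dim = model$config$word_emb_size))
}

model_crf <- function(model) {
  c(model$weights$crf,
    list(labels = model$labels, k = model$k,
         start = model$k + 1L, stop = model$k + 2L))
}

char_row_idx <- function(model, chars) unname(model$char_vocab[chars])

static_rows <- function(model, chars) {
  idx <- char_row_idx(model, chars)
  X <- matrix(0, length(chars), model$config$char_emb_size)
  known <- !is.na(idx)
  if (any(known)) X[known, ] <- model$weights$char_emb[idx[known], , drop = FALSE]
  if (any(!known)) X[!known, ] <- matrix(model$char_unk, sum(!known),
                                         model$config$char_emb_size, byrow = TRUE)
  X
}

word_rows <- function(model, terms) {
  idx <- unname(model$word_vocab[terms])
  W <- matrix(0, length(terms), model$config$word_emb_size)
  known <- !is.na(idx)
  if (any(known)) W[known, ] <- model$weights$word_emb[idx[known], , drop = FALSE]
  if (any(!known)) W[!known, ] <- matrix(model$word_unk, sum(!known),
                                         model$config$word_emb_size, byrow = TRUE)
  list(W = W, idx = idx)
}

# Encode one sentence, optionally keeping caches for backprop.
# prep: list(chars, matches, terms, stack) precomputed per sentence.
ner_forward <- function(model, prep, training = FALSE) {
  cfg <- model$config
  n <- length(prep$chars)
  Xs <- static_rows(model, prep$chars)
  elmo <- NULL; stack <- NULL
  if (cfg$elmo_enabled) {
    stack <- prep$stack
    if (is.null(stack)) stack <- bilm_representations(prep$chars, model$bilm)
    elmo <- scalar_mix(stack, model$weights$mix)
  }
  X <- if (is.null(elmo)) Xs else cbind(Xs, elmo)
  mask <- NULL
  if (training && cfg$dropout > 0) {
    keep <- 1 - cfg$dropout
    mask <- matrix(stats::rbinom(length(X), 1L, keep) / keep, nrow = n)
    X <- X * mask
  }
  matches <- prep$matches
  if (!cfg$use_lexicon || is.null(matches) || nrow(matches) == 0L) {
    matches <- data.frame(begin = integer(0), end = integer(0),
                          term_id = integer(0))
    wr <- list(W = matrix(0, 0L, cfg$word_emb_size), idx = integer(0))
  } else {
    wr <- word_rows(model, prep$terms)
  }
  pf <- model_lattice_params(model, "lat_fwd")
  cache_f <- lattice_forward(X, matches, wr$W, pf)
  Henc <- cache_f$H
  cache_b <- NULL; ord_b <- NULL; matches_b <- NULL
  if (cfg$bidirectional) {
    pb <- model_lattice_params(model, "lat_bwd")
    mb <- data.frame(begin = n - matches$end, end = n - matches$begin,
                     term_id = matches$term_id)
    ord_b <- order(mb$end, mb$begin)
    matches_b <- mb[ord_b, , drop = FALSE]
    cache_b <- lattice_forward(X[n:1, , drop = FALSE], matches_b,
                               wr$W[ord_b, , drop = FALSE], pb)
    Henc <- cbind(Henc, cache_b$H[n:1, , drop = FALSE])
  }
  crf <- model_crf(model)
  emissions <- crf_emissions(Henc, crf)
  list(X = X, Xs = Xs, elmo = elmo, stack = stack, mask = mask,
       matches = matches, wr = wr, ord_b = ord_b,
       cache_f = cache_f, cache_b = cache_b, Henc = Henc,
       emissions = emissions, crf = crf, n = n)
}

# loss + full gradient tree for one sentence
ner_loss_grads <- function(model, prep, y) {
  cfg <- model$config
  fw <- ner_forward(model, prep, training = TRUE)
  n <- fw$n; H <- model$hidden
  cg <- crf_nll_grad(fw$emissions, fw$crf, y)
  dHenc <- cg$d_emissions %*% t(model$weights$crf$W_e)
  dW_e <- t(fw$Henc) %*% cg$d_emissions
  db_e <- colSums(cg$d_emissions)

  pf <- model_lattice_params(model, "lat_fwd")
  bk_f <- lattice_backward(fw$cache_f, dHenc[, 1:H, drop = FALSE], pf)
  dX <- bk_f$dX
  dXW <- bk_f$dXW
  g_bwd <- NULL
  if (cfg$bidirectional) {
    pb <- model_lattice_params(model, "lat_bwd")
    dHb <- dHenc[n:1, (H + 1L):(2L * H), drop = FALSE]
    bk_b <- lattice_backward(fw$cache_b, dHb, pb)
    dX <- dX + bk_b$dX[n:1, , drop = FALSE]
    if (length(fw$ord_b))
      dXW[fw$ord_b, ] <- dXW[fw$ord_b, , drop = FALSE] + bk_b$dXW
    g_bwd <- bk_b$grads
  }
  if (!is.null(fw$mask)) dX <- dX * fw$mask

  d_ce <- model$weights$char_emb * 0
  idx <- char_row_idx(model, prep$chars)
  ds <- dX[, seq_len(cfg$char_emb_size), drop = FALSE]
  known <- which(!is.na(idx))
  if (length(known)) {
    agg <- rowsum(ds[known, , drop = FALSE], group = idx[known])
    d_ce[as.integer(rownames(agg)), ] <- agg
  }
  d_we <- model$weights$word_emb * 0
  wk <- which(!is.na(fw$wr$idx))
  if (length(wk)) {
    agg <- rowsum(dXW[wk, , drop = FALSE], group = fw$wr$idx[wk])
    d_we[as.integer(rownames(agg)), ] <- agg
  }
  grads <- list(char_emb = d_ce, word_emb = d_we, lat_fwd = bk_f$grads)
  if (cfg$bidirectional) grads$lat_bwd <- g_bwd
  grads$crf <- list(trans = cg$d_trans, W_e = dW_e, b_e = db_e)
  if (cfg$elmo_enabled) {
    delmo <- dX[, cfg$char_emb_size + seq_len(cfg$elmo_emb_size), drop = FALSE]
    grads$mix <- scalar_mix_grad(fw$stack, model$weights$mix, delmo)
  }
  grads <- grads[names(model$weights)]
  list(loss = cg$loss, grads = grads)
}

# Precompute per-sentence inputs that are constant during training: lexicon
# matches with their term strings, and the frozen language-model layer stack.
ner_prepare <- function(model, sentences, lexicon) {
  cfg <- model$config
  lapply(sentences, function(s) {
    chars <- if (inherits(s, "annotated_sentence")) s$chars else s
    matches <- NULL; terms <- character(0)
    if (cfg$use_lexicon && !is.null(lexicon)) {
      matches <- lexicon_match(chars, lexicon)
      terms <- lexicon$terms[matches$term_id]
    }
    stack <- if (cfg$elmo_enabled) bilm_representations(chars, model$bilm)
      else NULL
    list(chars = chars, matches = matches, terms = terms, stack = stack)
  })
}

tags_to_y <- function(tags, labels) {
  y <- match(tags, labels)
  if (anyNA(y)) stop("tag not in label set: ",
                     paste(unique(tags[is.na(y)]), collapse = ", "))
  y
}

#' Train the tagger
#'
#' Per-sentence SGD (batch size 1) with the decaying learning rate schedule,
#' input dropout and gradient clipping; dev F1 is logged every epoch. The
#' language model, if supplied, stays frozen; the scalar-mix weights train
#' jointly with the tagger. Fully reproducible from `config$seed`.
#'
#' @param train_corpus,dev_corpus lists of [annotated_sentence()] (dev may be
#'   NULL).
#' @param lexicon `ner_lexicon` or NULL.
#' @param char_table,word_table `embedding_table`s.
#' @param bilm optional `bilm_params`.
#' @param config `ner_config`.
#' @param verbose print per-epoch loss / F1.
#' @return list with `model` (trained `ner_model`) and `history` (data.frame:
#'   epoch, lr, loss, dev_f1).
#' @export
train_ner <- function(train_corpus, dev_corpus = NULL, lexicon = NULL,
                      char_table, word_table, bilm = NULL, config = ner_config(),
                      verbose = FALSE) {
  stopifnot(length(train_corpus) > 0L)
  labels <- label_set(train_corpus)
  if (!is.null(dev_corpus)) {
    dev_cats <- setdiff(label_set(dev_corpus), labels)
    if (length(dev_cats))
      warning("dev labels absent from training: ",
              paste(dev_cats, collapse = ", "))
  }
  model <- ner_init(labels, char_table, word_table, bilm, config)
  prep_tr <- ner_prepare(model, train_corpus, lexicon)
  prep_dev <- if (!is.null(dev_corpus)) ner_prepare(model, dev_corpus, lexicon)
  ys <- lapply(train_corpus, function(s) tags_to_y(s$tags, labels))
  ns <- length(train_corpus)
  history <- data.frame(epoch = integer(0), lr = numeric(0), loss = numeric(0),
                        dev_f1 = numeric(0))
  best <- list(f1 = -Inf, weights = model$weights)
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      lr <- lr_at_epoch(config$lr, config$lr_decay, ep - 1L)
      ord <- sample.int(ns)
      ep_loss <- 0
      for (i in ord) {
        r <- ner_loss_grads(model, prep_tr[[i]], ys[[i]])
        model$weights <- sgd_step(model$weights, r$grads, lr,
                                  max_norm = config$clip_norm)
        ep_loss <- ep_loss + r$loss
      }
      dev_f1 <- NA_real_
      if (!is.null(dev_corpus)) {
        pred <- predict_prepared(model, prep_dev)
        dev_f1 <- strict_prf(lapply(dev_corpus, `[[`, "tags"),
                             pred)$micro[["f1"]]
        if (dev_f1 > best$f1) best <- list(f1 = dev_f1, weights = model$weights)
      }
      history <- rbind(history, data.frame(epoch = ep, lr = lr,
                                           loss = ep_loss / ns,
                                           dev_f1 = dev_f1))
      if (verbose)
        message(sprintf("epoch %d lr %.5f loss %.4f dev_f1 %s", ep, lr,
                        ep_loss / ns,
                        if (is.na(dev_f1)) "-" else sprintf("%.2f", dev_f1)))
    }
  })
  if (config$select_best_dev && is.finite(best$f1)) model$weights <- best$weights
  list(model = model, history = history)
}

predict_prepared <- function(model, preps) {
  lapply(preps, function(p) {
    fw <- ner_forward(model, p, training = FALSE)
    model$labels[crf_viterbi(fw$emissions, fw$crf)$path]
  })
}

#' Predict BIO tags
#'
#' Viterbi-decodes each sentence with dropout disabled and BIO transition
#' masking on, so output is deterministic and schema-consistent.
#'
#' @param model trained `ner_model`.
#' @param sentences list of character vectors or `annotated_sentence`s.
#' @param lexicon `ner_lexicon` (the one used in training) or NULL.
#' @return list of tag vectors.
#' @export
predict_ner <- function(model, sentences, lexicon = NULL) {
  if (length(sentences) == 0L) return(list())
  predict_prepared(model, ner_prepare(model, sentences, lexicon))
}

#' Replicated training runs
#'
#' Trains one model per seed, evaluates each on the test corpus with strict
#' matching, and reports the per-run metrics and their arithmetic mean --
#' the five-run averaging protocol.
#'
#' @param train_corpus,test_corpus corpora.
#' @param lexicon,char_table,word_table,bilm,config as in [train_ner()];
#'   `config$seed` is replaced by each element of `seeds`.
#' @param seeds integer vector, one per run.
#' @return list with `reports` (per-run `prf_report`s), `mean` (named vector
#'   precision/recall/f1), and `histories`.
#' @export
run_replicates <- function(train_corpus, test_corpus, lexicon = NULL,
                           char_table, word_table, bilm = NULL,
                           config = ner_config(), seeds = 1:5) {
  reports <- list(); histories <- list()
  gold <- lapply(test_corpus, `[[`, "tags")
  for (r in seq_along(seeds)) {
    cfg <- config; cfg$seed <- as.integer(seeds[r])
    fit <- train_ner(train_corpus, dev_corpus = NULL, lexicon = lexicon,
                     char_table = char_table, word_table = word_table,
                     bilm = bilm, config = cfg)
    pred <- predict_ner(fit$model, test_corpus, lexicon)
    reports[[r]] <- strict_prf(gold, pred)
    histories[[r]] <- fit$history
  }
  list(reports = reports, mean = average_prf(reports), histories = histories)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive of the weight tree, label set,
#' vocabularies, frozen language model and config.
#'
#' @param model a `ner_model`.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  structure(readRDS(path), class = "ner_model")
}
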