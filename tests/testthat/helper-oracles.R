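# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: brute-force enumeration, direct formula
# evaluation, and naive scans.

# every substring of length >= 2 that is a lexicon term, by direct scan
brute_force_matches <- function(chars, terms) {
  n <- length(chars)
  out <- data.frame(begin = integer(0), end = integer(0), term = character(0))
  if (n < 2L) return(out)
  for (b in 1:(n - 1L)) for (e in (b + 1L):n) {
    s <- paste(chars[b:e], collapse = "")
    if (s %in% terms)
      out <- rbind(out, data.frame(begin = b - 1L, end = e, term = s))
  }
  out
}

# regex-style span scan: B(I)* runs, independent of spans_from_tags
scan_spans <- function(tags) {
  out <- data.frame(begin = integer(0), end = integer(0),
                    category = character(0))
  i <- 1L
  while (i <= length(tags)) {
    if (grepl("^B-", tags[i])) {
      k <- sub("^B-", "", tags[i])
      j <- i
      while (j < length(tags) && tags[j + 1L] == paste0("I-", k)) j <- j + 1L
      out <- rbind(out, data.frame(begin = i - 1L, end = j, category = k))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# all BIO-consistent tag sequences of a given length over given categories
all_consistent_tag_seqs <- function(len, cats) {
  labels <- c("O", paste0("B-", cats), paste0("I-", cats))
  grids <- expand.grid(rep(list(labels), len), stringsAsFactors = FALSE)
  keep <- apply(grids, 1L, function(r) is_bio_consistent(unname(r)))
  lapply(which(keep), function(i) unname(unlist(grids[i, ])))
}

# plain unidirectional LSTM, written independently of the lattice encoder
reference_lstm <- function(X, W, b, H) {
  n <- nrow(X); h <- numeric(H); c <- numeric(H)
  out <- matrix(0, n, H)
  for (t in seq_len(n)) {
    a <- drop(W %*% c(X[t, ], h)) + b
    i <- stats::plogis(a[1:H]); f <- stats::plogis(a[(H + 1):(2 * H)])
    o <- stats::plogis(a[(2 * H + 1):(3 * H)]); g <- tanh(a[(3 * H + 1):(4 * H)])
    c <- f * c + i * g
    h <- o * tanh(c)
    out[t, ] <- h
  }
  out
}

# enumeration over all k^n paths: scores, log-partition, argmax
enumerate_crf <- function(emissions, crf) {
  n <- nrow(emissions); k <- crf$k
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  scores <- apply(paths, 1L, function(y) crf_sequence_score(emissions, crf, y))
  m <- max(scores)
  list(logZ = m + log(sum(exp(scores - m))),
       best = unname(paths[which.max(scores), ]), best_score = max(scores))
}

# strict micro P/R/F1 via explicit span-set intersection, independent of
# strict_prf's bookkeeping
oracle_micro_prf <- function(gold, pred) {
  keyset <- function(tagss) {
    out <- character(0)
    for (i in seq_along(tagss)) {
      sp <- scan_spans(repair_bio(tagss[[i]]))
      if (nrow(sp))
        out <- c(out, unique(paste(i, sp$begin, sp$end, sp$category)))
    }
    out
  }
  g <- keyset(gold); p <- keyset(pred)
  m <- length(intersect(g, p))
  prec <- if (length(p)) 100 * m / length(p) else 0
  rec <- if (length(g)) 100 * m / length(g) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(precision = prec, recall = rec, f1 = f1)
}

# random BIO-consistent tag vector via random non-overlapping spans
random_tags <- function(len, cats) {
  tags <- rep("O", len)
  pos <- 1L
  while (pos <= len) {
    if (stats::runif(1) < 0.4) {
      w <- sample(1:min(3L, len - pos + 1L), 1L)
      k <- sample(cats, 1L)
      tags[pos] <- paste0("B-", k)
      if (w > 1L) tags[(pos + 1L):(pos + w - 1L)] <- paste0("I-", k)
      pos <- pos + w
    } else pos <- pos + 1L
  }
  tags
}

# tiny deterministic study setup shared by trainer tests
tiny_study <- function(n_sentences = 12L, seed = 7L) {
  cfg <- fixture_config(alphabet_size = 12L, n_sentences = n_sentences,
                        len_range = c(5L, 10L), categories = c("ANA", "DRU"),
                        entity_density = 1, lexicon_size = 8L,
                        ambiguity_rate = 0.2, seed = seed)
  generate_study(cfg, n_test = 6L, emb_dim = 8L)
}

tiny_ner_config <- function(...) {
  defaults <- list(char_emb_size = 8L, elmo_emb_size = 8L, word_emb_size = 8L,
                   hidden = 6L, epochs = 2L, elmo_enabled = FALSE,
                   dropout = 0.5, seed = 3L)
  override <- list(...)
  do.call(ner_config, utils::modifyList(defaults, override))
}
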