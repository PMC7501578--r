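#' Embedding table
#'
#' A dense token -> vector map with a seeded UNK row for out-of-vocabulary
#' tokens. The UNK row is drawn uniformly from `[-0.5/dim, 0.5/dim]` (the
#' usual word2vec initialization scale) from `unk_seed`, so unknown-token
#' lookups are reproducible across runs and processes.
#'
#' @param tokens character vector of unique tokens.
#' @param vectors numeric matrix, `length(tokens)` x `dim`.
#' @param unk_seed integer seed for the UNK row.
#' @return object of class `embedding_table`: list with `dim`, `vocab`
#'   (named integer row index), `vectors`, `unk`.
#' @export
embedding_table <- function(tokens, vectors, unk_seed = 1L) {
  vectors <- as.matrix(vectors)
  if (anyDuplicated(tokens)) stop("duplicate tokens in embedding table")
  if (length(tokens) != nrow(vectors))
    stop("tokens/vectors row mismatch")
  if (ncol(vectors) < 1L) stop("embedding dim must be positive")
  dim <- ncol(vectors)
  vocab <- seq_along(tokens)
  names(vocab) <- tokens
  unk <- with_seed(unk_seed, stats::runif(dim, -0.5 / dim, 0.5 / dim))
  structure(list(dim = dim, vocab = vocab, vectors = unname(vectors), unk = unk),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat("<embedding_table>", length(x$vocab), "tokens, dim", x$dim, "\n")
  invisible(x)
}

#' Random embedding table
#'
#' Seeded Gaussian vectors for a token set; used by the synthetic fixture
#' generator and for randomly initialized tables.
#'
#' @param tokens character vector of unique tokens.
#' @param dim embedding dimensionality.
#' @param seed integer seed.
#' @param sd standard deviation of entries.
#' @return an `embedding_table`.
#' @export
random_embedding_table <- function(tokens, dim, seed = 1L, sd = 0.1) {
  vecs <- with_seed(seed, matrix(stats::rnorm(length(tokens) * dim, sd = sd),
                                 nrow = length(tokens)))
  embedding_table(tokens, vecs, unk_seed = seed + 1L)
}

#' Load a word2vec text-format embedding table
#'
#' Format: optional header line `"vocab_size dim"`, then one line per token:
#' `token v1 ... vd`. Duplicate tokens keep the first occurrence with a
#' warning.
#'
#' @param path file path.
#' @param unk_seed seed for the UNK row (see [embedding_table()]).
#' @return an `embedding_table`.
#' @export
read_word2vec <- function(path, unk_seed = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty embedding file: ", path)
  first <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  has_header <- length(first) == 2L &&
    !is.na(suppressWarnings(as.numeric(first[1]))) &&
    !is.na(suppressWarnings(as.numeric(first[2])))
  body <- if (has_header) lines[-1] else lines
  dim <- NA_integer_
  tokens <- character(0)
  rows <- list()
  for (i in seq_along(body)) {
    f <- strsplit(trimws(body[i]), "[ \t]+")[[1]]
    if (is.na(dim)) {
      dim <- length(f) - 1L
      if (has_header && dim != as.integer(first[2]))
        stop("header dim ", first[2], " disagrees with row arity ", dim)
      if (dim < 1L) stop("cannot infer embedding dim from line ",
                         i + has_header, " in ", path)
    }
    if (length(f) != dim + 1L)
      stop("line ", i + has_header, " in ", path, ": expected ", dim + 1L,
           " fields, got ", length(f))
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v)) stop("non-numeric value on line ", i + has_header, " in ", path)
    if (f[1] %in% tokens) {
      warning("duplicate token '", f[1], "' in ", path, "; keeping first")
      next
    }
    tokens <- c(tokens, f[1])
    rows[[length(rows) + 1L]] <- v
  }
  embedding_table(tokens, do.call(rbind, rows), unk_seed = unk_seed)
}

#' Write an embedding table in word2vec text format
#'
#' @param table an `embedding_table`.
#' @param path output path.
#' @param digits printed precision (round-trip is lossless to this precision).
#' @export
write_word2vec <- function(table, path, digits = 6L) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(length(table$vocab), table$dim), con)
  toks <- names(table$vocab)
  for (i in seq_along(toks)) {
    writeLines(paste(toks[i],
                     paste(formatC(table$vectors[i, ], format = "f",
                                   digits = digits), collapse = " ")), con)
  }
  invisible(path)
}

#' Look up a token's embedding
#'
#' Known tokens return their stored row; unknown tokens return the table's
#' seeded UNK row (identical on every lookup).
#'
#' @param table an `embedding_table`.
#' @param token a single token.
#' @return numeric vector of length `table$dim`.
#' @export
emb_lookup <- function(table, token) {
  i <- table$vocab[token]
  if (is.na(i)) table$unk else table$vectors[i, ]
}

#' Look up a batch of tokens as a matrix
#'
#' @param table an `embedding_table`.
#' @param tokens character vector.
#' @return `length(tokens)` x `dim` matrix; unknown tokens get the UNK row.
#' @export
emb_rows <- function(table, tokens) {
  idx <- table$vocab[tokens]
  out <- matrix(0, nrow = length(tokens), ncol = table$dim)
  known <- !is.na(idx)
  if (any(known)) out[known, ] <- table$vectors[idx[known], , drop = FALSE]
  if (any(!known)) out[!known, ] <- matrix(table$unk, nrow = sum(!known),
                                           ncol = table$dim, byrow = TRUE)
  out
}

# Row indices for gradient accumulation: NA for OOV tokens (their UNK row is
# fixed, not trained).
emb_indices <- function(table, tokens) unname(table$vocab[tokens])
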