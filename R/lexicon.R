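#' Build a lexicon with a trie index
#'
#' The lexicon holds the dictionary of multi-character clinical terms whose
#' matches in a sentence define the word paths of the lattice. Duplicates are
#' removed; single-character terms are rejected (a one-character "word" adds
#' nothing beyond the character path). Term ids are assigned densely by sorted
#' order, so they are stable rows into a word embedding table.
#'
#' @param terms character vector (or coercible) of terms, each of length >= 2
#'   characters. Terms shorter than 2 characters are dropped with a warning.
#' @return an object of class `ner_lexicon`: list with `terms` (sorted unique
#'   character vector; `term_ids` are their positions), `trie` (prefix tree),
#'   and `max_len` (length of the longest term, in characters).
#' @export
build_lexicon <- function(terms) {
  terms <- unique(as.character(terms))
  terms <- terms[nzchar(terms)]
  short <- nchar(terms) < 2L
  if (any(short)) {
    warning(sum(short), " single-character term(s) dropped")
    terms <- terms[!short]
  }
  terms <- sort(terms, method = "radix")
  trie <- trie_build(terms)
  structure(list(terms = terms, trie = trie,
                 max_len = if (length(terms)) max(nchar(terms)) else 0L),
            class = "ner_lexicon")
}

#' @export
print.ner_lexicon <- function(x, ...) {
  cat("<ner_lexicon>", length(x$terms), "terms, max length", x$max_len, "\n")
  invisible(x)
}

#' Read a lexicon file
#'
#' One term per line, UTF-8.
#'
#' @param path file path.
#' @return a `ner_lexicon` (see [build_lexicon()]).
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  build_lexicon(trimws(readLines(path, encoding = "UTF-8", warn = FALSE)))
}

#' Write a lexicon file
#' @param lexicon a `ner_lexicon`.
#' @param path output path.
#' @export
write_lexicon <- function(lexicon, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lexicon$terms, con)
  invisible(path)
}

# Trie as nested environments: each node has child environments keyed by
# character, and an optional ".id" terminal marker. Environments give O(1)
# child lookup without copying on insert.
trie_build <- function(terms) {
  root <- new.env(parent = emptyenv(), hash = TRUE)
  for (id in seq_along(terms)) {
    node <- root
    for (ch in strsplit(terms[id], "")[[1]]) {
      nxt <- get0(ch, envir = node, inherits = FALSE)
      if (is.null(nxt)) {
        nxt <- new.env(parent = emptyenv(), hash = TRUE)
        assign(ch, nxt, envir = node)
      }
      node <- nxt
    }
    assign(".id", id, envir = node)
  }
  root
}

#' Enumerate lexicon matches in a character sequence
#'
#' Walks the trie once from every start position and reports every
#' multi-character subsequence `chars[b:e]` that is a lexicon term, i.e. the
#' word lattice of the sentence. Overlapping and nested matches are all
#' retained.
#'
#' @param chars character vector of single characters.
#' @param lexicon a `ner_lexicon` from [build_lexicon()].
#' @param max_word_len optional cap on match length (default: none).
#' @return data.frame with columns `begin` (0-based inclusive), `end` (0-based
#'   exclusive), `term_id`, sorted by `(end, begin)`.
#' @export
lexicon_match <- function(chars, lexicon, max_word_len = Inf) {
  stopifnot(inherits(lexicon, "ner_lexicon"))
  n <- length(chars)
  begin <- integer(0); end <- integer(0); term_id <- integer(0)
  if (n >= 2L && length(lexicon$terms) > 0L) {
    cap <- min(lexicon$max_len, max_word_len)
    for (b in seq_len(n - 1L)) {
      node <- lexicon$trie
      e <- b
      while (e <= n && (e - b + 1L) <= cap) {
        node <- get0(chars[e], envir = node, inherits = FALSE)
        if (is.null(node)) break
        if (e > b) {
          id <- get0(".id", envir = node, inherits = FALSE)
          if (!is.null(id)) {
            begin <- c(begin, b - 1L); end <- c(end, e); term_id <- c(term_id, id)
          }
        }
        e <- e + 1L
      }
    }
  }
  out <- data.frame(begin = begin, end = end, term_id = term_id)
  out[order(out$end, out$begin), , drop = FALSE]
}
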