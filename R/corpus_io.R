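#' Annotated sentence
#'
#' Constructs the basic unit of training and evaluation: a sequence of single
#' characters with aligned BIO tags. Tags are `"O"` or `"B-<CAT>"`/`"I-<CAT>"`.
#'
#' @param chars character vector of single characters (one Unicode code point
#'   each; no grapheme clustering is performed).
#' @param tags character vector of BIO tags, same length as `chars`.
#' @param validate check BIO consistency (an `I-X` may only follow `B-X` or
#'   `I-X`); set `FALSE` when the caller repairs afterwards.
#' @return a list with elements `chars` and `tags`, class `annotated_sentence`.
#' @export
annotated_sentence <- function(chars, tags, validate = TRUE) {
  chars <- as.character(chars)
  tags <- as.character(tags)
  if (length(chars) < 1L)
    stop("annotated sentence must contain at least one character")
  if (length(chars) != length(tags))
    stop("chars and tags must have equal length (", length(chars), " vs ",
         length(tags), ")")
  bad <- !grepl("^(O|[BI]-.+)$", tags)
  if (any(bad))
    stop("malformed tag(s): ", paste(unique(tags[bad]), collapse = ", "))
  if (validate && !is_bio_consistent(tags))
    stop("tag sequence is not BIO-consistent; repair first")
  structure(list(chars = chars, tags = tags), class = "annotated_sentence")
}

#' @export
print.annotated_sentence <- function(x, ...) {
  cat(paste(x$chars, collapse = ""), "\n")
  cat(paste(x$tags, collapse = " "), "\n")
  invisible(x)
}

tag_category <- function(tags) {
  ifelse(tags == "O", NA_character_, substr(tags, 3L, nchar(tags)))
}

#' Check BIO consistency of a tag sequence
#'
#' A sequence is consistent when every `I-X` tag is preceded by `B-X` or `I-X`
#' of the same category.
#'
#' @param tags character vector of BIO tags.
#' @return `TRUE` or `FALSE`.
#' @export
is_bio_consistent <- function(tags) {
  if (length(tags) == 0L) return(TRUE)
  prev <- c("O", tags[-length(tags)])
  inside <- startsWith(tags, "I-")
  ok_prev <- !startsWith(prev, "O") & tag_category(prev) == tag_category(tags)
  ok_prev[is.na(ok_prev)] <- FALSE
  !any(inside & !ok_prev)
}

#' Repair a BIO tag sequence
#'
#' A bare `I-X` (following `O`, start of sentence, or a different category) is
#' relabeled `B-X`. Relabeling rather than dropping preserves entity mass.
#'
#' @param tags character vector of BIO tags.
#' @return a BIO-consistent tag vector of the same length.
#' @export
repair_bio <- function(tags) {
  n <- length(tags)
  if (n == 0L) return(tags)
  for (i in seq_len(n)) {
    if (!startsWith(tags[i], "I-")) next
    prev <- if (i == 1L) "O" else tags[i - 1L]
    if (prev == "O" || tag_category(prev) != tag_category(tags[i]))
      tags[i] <- sub("^I-", "B-", tags[i])
  }
  tags
}

#' Read a BIO-tagged corpus
#'
#' Reads a UTF-8 file in character-per-line format: `char<TAB>tag`, blank line
#' between sentences. Sentences longer than `max_len` are split at `max_len`
#' boundaries, moving the cut left to the nearest `O` so no entity is cut.
#'
#' @param path file path.
#' @param max_len maximum sentence length in characters (default 200).
#' @param schema_repair `"relabel"` (default; bare `I-X` becomes `B-X`) or
#'   `"error"` (inconsistent sequences abort).
#' @return list of [annotated_sentence()] objects, in file order.
#' @export
read_bio_corpus <- function(path, max_len = 200L, schema_repair = c("relabel", "error")) {
  schema_repair <- match.arg(schema_repair)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  out <- list()
  chars <- character(0)
  tags <- character(0)
  flush <- function() {
    if (length(chars) == 0L) return()
    if (!all(grepl("^(O|[BI]-.+)$", tags))) {
      bad <- tags[!grepl("^(O|[BI]-.+)$", tags)]
      stop("unknown tag prefix: ", bad[1])
    }
    if (!is_bio_consistent(tags)) {
      if (schema_repair == "error") stop("BIO-inconsistent sentence in ", path)
      tags <<- repair_bio(tags)
    }
    for (piece in split_annotated(chars, tags, max_len))
      out[[length(out) + 1L]] <<- piece
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) {
      flush()
      chars <- character(0); tags <- character(0)
      next
    }
    fields <- strsplit(ln, "[ \t]+")[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) != 2L)
      stop("malformed line ", i, " in ", path, ": expected 'char<TAB>tag', got: ", ln)
    chars <- c(chars, fields[1]); tags <- c(tags, fields[2])
  }
  flush()
  out
}

# Split an overlong tagged sequence at max_len boundaries, moving each cut
# left to the nearest position whose left neighbour ends an entity or is "O",
# so no entity straddles two pieces.
split_annotated <- function(chars, tags, max_len) {
  n <- length(chars)
  if (n <= max_len) return(list(annotated_sentence(chars, tags, validate = FALSE)))
  pieces <- list()
  start <- 1L
  while (start <= n) {
    end <- min(start + max_len - 1L, n)
    if (end < n) {
      # a cut after position `end` is safe if tags[end+1] is not I-*
      cut <- end
      while (cut > start && startsWith(tags[cut + 1L], "I-")) cut <- cut - 1L
      if (cut > start || !startsWith(tags[cut + 1L], "I-")) end <- cut
      # else: a single entity longer than max_len; hard split at max_len
    }
    idx <- start:end
    pieces[[length(pieces) + 1L]] <-
      annotated_sentence(chars[idx], repair_bio(tags[idx]), validate = FALSE)
    start <- end + 1L
  }
  pieces
}

#' Write a BIO-tagged corpus
#'
#' @param sentences list of [annotated_sentence()] objects.
#' @param path output file path (UTF-8, `char<TAB>tag`, blank line between
#'   sentences).
#' @export
write_bio_corpus <- function(sentences, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (s in sentences) {
    writeLines(paste(s$chars, s$tags, sep = "\t"), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write predictions in three-column format
#'
#' `char<TAB>gold<TAB>pred` per line, blank line between sentences; the format
#' accepted by external sequence-labeling evaluators.
#'
#' @param sentences list of [annotated_sentence()] (gold).
#' @param pred_tags list of predicted tag vectors, aligned with `sentences`.
#' @param path output path.
#' @export
write_predictions <- function(sentences, pred_tags, path) {
  stopifnot(length(sentences) == length(pred_tags))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_along(sentences)) {
    s <- sentences[[i]]
    stopifnot(length(s$chars) == length(pred_tags[[i]]))
    writeLines(paste(s$chars, s$tags, pred_tags[[i]], sep = "\t"), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read predictions in three-column format
#'
#' @param path file written by [write_predictions()].
#' @return list with `gold` and `pred`, each a list of tag vectors, plus
#'   `chars`, a list of character vectors.
#' @export
read_predictions <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  chars <- list(); gold <- list(); pred <- list()
  cc <- gg <- pp <- character(0)
  flush <- function() {
    if (length(cc) == 0L) return()
    chars[[length(chars) + 1L]] <<- cc
    gold[[length(gold) + 1L]] <<- gg
    pred[[length(pred) + 1L]] <<- pp
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) { flush(); cc <- gg <- pp <- character(0); next }
    f <- strsplit(ln, "[ \t]+")[[1]]
    f <- f[nzchar(f)]
    if (length(f) != 3L) stop("malformed line ", i, " in ", path)
    cc <- c(cc, f[1]); gg <- c(gg, f[2]); pp <- c(pp, f[3])
  }
  flush()
  list(chars = chars, gold = gold, pred = pred)
}

#' Split raw text into bounded sentences
#'
#' Splits on sentence-final punctuation (delimiter kept with the preceding
#' piece) and additionally hard-splits any remaining run at `max_len`.
#' Concatenating the output reproduces the input exactly.
#'
#' @param text a single string.
#' @param max_len maximum piece length (default 200).
#' @param delims character vector of sentence-final delimiters.
#' @return character vector of sentence strings (empty for empty input).
#' @export
split_sentences <- function(text, max_len = 200L,
                            delims = c("。", "；", "！", "？")) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) return(character(0))
  cp <- strsplit(text, "")[[1]]
  out <- character(0)
  buf <- character(0)
  for (ch in cp) {
    buf <- c(buf, ch)
    if (ch %in% delims || length(buf) >= max_len) {
      out <- c(out, paste(buf, collapse = ""))
      buf <- character(0)
    }
  }
  if (length(buf) > 0L) out <- c(out, paste(buf, collapse = ""))
  out
}

#' Extract entity spans from a BIO tag sequence
#'
#' Every maximal `B-X (I-X)*` run yields one span. Indices are 0-based,
#' half-open `[begin, end)`.
#'
#' @param tags BIO-consistent tag vector.
#' @return data.frame with columns `begin`, `end`, `category`, ordered by
#'   `begin`.
#' @export
spans_from_tags <- function(tags) {
  if (!is_bio_consistent(tags))
    stop("tags are not BIO-consistent; call repair_bio() first")
  n <- length(tags)
  begin <- integer(0); end <- integer(0); category <- character(0)
  i <- 1L
  while (i <= n) {
    if (startsWith(tags[i], "B-")) {
      cat_i <- tag_category(tags[i])
      j <- i + 1L
      while (j <= n && tags[j] == paste0("I-", cat_i)) j <- j + 1L
      begin <- c(begin, i - 1L); end <- c(end, j - 1L); category <- c(category, cat_i)
      i <- j
    } else i <- i + 1L
  }
  data.frame(begin = begin, end = end, category = category,
             stringsAsFactors = FALSE)
}

#' Build a BIO tag sequence from entity spans
#'
#' Inverse of [spans_from_tags()].
#'
#' @param spans data.frame with `begin`, `end`, `category` (0-based half-open,
#'   non-overlapping).
#' @param length sentence length.
#' @return character vector of BIO tags.
#' @export
tags_from_spans <- function(spans, length) {
  tags <- rep("O", length)
  if (nrow(spans) == 0L) return(tags)
  spans <- spans[order(spans$begin), , drop = FALSE]
  if (any(spans$begin < 0L) || any(spans$end > length) ||
      any(spans$begin >= spans$end))
    stop("span out of range")
  if (nrow(spans) > 1L && any(spans$begin[-1L] < spans$end[-nrow(spans)]))
    stop("overlapping spans")
  for (r in seq_len(nrow(spans))) {
    b <- spans$begin[r]; e <- spans$end[r]; k <- spans$category[r]
    tags[b + 1L] <- paste0("B-", k)
    if (e - b > 1L) tags[(b + 2L):e] <- paste0("I-", k)
  }
  tags
}
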