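# Seeded synthetic corpora.
#
# The restricted clinical datasets cannot be redistributed, so benchmarking
# runs on generated corpora that emulate their structural properties: a fixed
# set of entity categories, entities that are exactly lexicon terms (so a
# lattice word path exists for every gold entity), bounded sentence lengths,
# and an adjustable amount of character-level ambiguity between entity terms
# and filler text -- the property the lattice encoder is designed to exploit.
# Synthetic "characters" come from the Unicode private-use block, so no
# accidental linguistic semantics leak into tests.

#' Configuration for the synthetic generator
#'
#' @param alphabet_size number of distinct characters (private-use block).
#' @param n_sentences corpus size.
#' @param len_range inclusive range of filler-determined sentence lengths
#'   (entities are inserted within this budget); capped at `max_len`.
#' @param categories entity category labels (default six, mirroring the
#'   disease / image / laboratory / operation / drug / anatomy roles of
#'   clinical corpora).
#' @param entity_density expected entities per sentence (Poisson).
#' @param lexicon_size number of terms.
#' @param ambiguity_rate fraction in `[0, 1]`: of lexicon terms built to share
#'   character bigrams with other terms, and of filler characters drawn from
#'   the characters used inside entity terms.
#' @param seed integer seed; every generated artifact is a pure function of
#'   the config.
#' @param max_len hard sentence length cap (default 200).
#' @return list of class `fixture_config`.
#' @export
fixture_config <- function(alphabet_size = 20L, n_sentences = 100L,
                           len_range = c(8L, 20L),
                           categories = c("DIS", "IMG", "LAB", "OPE", "DRU", "ANA"),
                           entity_density = 1.5, lexicon_size = 50L,
                           ambiguity_rate = 0.3, seed = 1L, max_len = 200L) {
  stopifnot(alphabet_size >= 4L, entity_density >= 0, lexicon_size >= 0L,
            ambiguity_rate >= 0, ambiguity_rate <= 1,
            len_range[1] >= 1L, len_range[2] <= max_len,
            length(categories) >= 1L)
  structure(list(alphabet_size = as.integer(alphabet_size),
                 n_sentences = as.integer(n_sentences),
                 len_range = as.integer(len_range), categories = categories,
                 entity_density = entity_density,
                 lexicon_size = as.integer(lexicon_size),
                 ambiguity_rate = ambiguity_rate, seed = as.integer(seed),
                 max_len = as.integer(max_len)),
            class = "fixture_config")
}

#' Synthetic alphabet
#'
#' @param n number of characters.
#' @return character vector from the Unicode private-use area (U+E000 ...).
#' @export
fixture_alphabet <- function(n) {
  vapply(seq_len(n) - 1L, function(i) intToUtf8(0xE000 + i), character(1))
}

term_bigrams <- function(term) {
  ch <- strsplit(term, "")[[1]]
  if (length(ch) < 2L) return(character(0))
  paste0(ch[-length(ch)], ch[-1L])
}

#' Generate a synthetic lexicon
#'
#' Terms of length 2-5 over the synthetic alphabet, each assigned an entity
#' category. With `ambiguity_rate = 0`, no two terms share a character
#' bigram; a positive rate makes that fraction of terms share a prefix or
#' suffix with a previously generated term.
#'
#' @param config a `fixture_config`.
#' @return list with `lexicon` (a `ner_lexicon`), `term_categories` (named
#'   character vector term -> category), and `alphabet`.
#' @export
generate_lexicon <- function(config) {
  ab <- fixture_alphabet(config$alphabet_size)
  n_amb <- round(config$ambiguity_rate * config$lexicon_size)
  terms <- character(0)
  used_bigrams <- character(0)
  with_seed(config$seed, {
    tries <- 0L
    while (length(terms) < config$lexicon_size) {
      tries <- tries + 1L
      if (tries > 200L * max(config$lexicon_size, 1L))
        stop("cannot build ", config$lexicon_size, " terms over an alphabet of ",
             config$alphabet_size, " characters at ambiguity ",
             config$ambiguity_rate)
      want_amb <- length(terms) >= (config$lexicon_size - n_amb) &&
        length(terms) > 0L
      len <- sample(2:5, 1L)
      if (want_amb) {
        base <- strsplit(sample(terms, 1L), "")[[1]]
        keep <- min(length(base) - 1L, len - 1L)
        keep <- max(keep, 1L)
        stub <- if (stats::runif(1) < 0.5) base[seq_len(keep)] else
          base[(length(base) - keep + 1L):length(base)]
        fresh <- sample(ab, len - keep, replace = TRUE)
        cand <- if (stats::runif(1) < 0.5) paste(c(stub, fresh), collapse = "")
          else paste(c(fresh, stub), collapse = "")
      } else {
        cand <- paste(sample(ab, len, replace = TRUE), collapse = "")
      }
      if (cand %in% terms) next
      bg <- term_bigrams(cand)
      if (!want_amb && config$ambiguity_rate == 0 &&
          any(bg %in% used_bigrams)) next
      terms <- c(terms, cand)
      used_bigrams <- c(used_bigrams, bg)
    }
    cats <- sample(config$categories, length(terms), replace = TRUE)
  })
  names(cats) <- terms
  list(lexicon = build_lexicon(terms), term_categories = cats, alphabet = ab)
}

#' Generate a synthetic BIO-tagged corpus
#'
#' Sentences are filler characters with lexicon terms inserted at a Poisson
#' rate and tagged `B-`/`I-` with the term's category. Entities never
#' overlap; every entity is exactly a lexicon term, so the lattice word path
#' for every gold entity exists. Filler characters are drawn from the
#' characters appearing inside entity terms with probability
#' `ambiguity_rate`, otherwise from the full alphabet.
#'
#' @param lexicon a `ner_lexicon`.
#' @param term_categories named vector term -> category.
#' @param config a `fixture_config`.
#' @param seed optional seed override (defaults to `config$seed + 1`), so
#'   train/test splits can be drawn from one config.
#' @return list of [annotated_sentence()] objects.
#' @export
generate_corpus <- function(lexicon, term_categories, config,
                            seed = config$seed + 1L) {
  ab <- fixture_alphabet(config$alphabet_size)
  terms <- lexicon$terms
  entity_chars <- unique(unlist(strsplit(terms, "")))
  if (length(entity_chars) == 0L) entity_chars <- ab
  out <- vector("list", config$n_sentences)
  with_seed(seed, {
    for (s in seq_len(config$n_sentences)) {
      target_len <- sample(config$len_range[1]:config$len_range[2], 1L)
      n_ent <- if (length(terms)) stats::rpois(1L, config$entity_density) else 0L
      chars <- character(0); tags <- character(0)
      # alternate filler / entity segments until the budget is spent
      ents_left <- n_ent
      while (length(chars) < target_len || ents_left > 0L) {
        fill_len <- sample(1:4, 1L)
        amb <- stats::runif(fill_len) < config$ambiguity_rate
        fill <- ifelse(amb, sample(entity_chars, fill_len, replace = TRUE),
                       sample(ab, fill_len, replace = TRUE))
        chars <- c(chars, fill); tags <- c(tags, rep("O", fill_len))
        if (ents_left > 0L) {
          term <- sample(terms, 1L)
          tch <- strsplit(term, "")[[1]]
          if (length(chars) + length(tch) <= config$max_len) {
            k <- term_categories[[term]]
            chars <- c(chars, tch)
            tags <- c(tags, paste0("B-", k),
                      rep(paste0("I-", k), length(tch) - 1L))
          }
          ents_left <- ents_left - 1L
        }
        if (length(chars) >= config$max_len) break
      }
      if (length(chars) > config$max_len) {
        chars <- chars[seq_len(config$max_len)]
        tags <- repair_bio(tags[seq_len(config$max_len)])
      }
      out[[s]] <- annotated_sentence(chars, tags, validate = FALSE)
    }
  })
  out
}

#' Generate a memorization corpus for language-model benchmarking
#'
#' Sentences drawn from a small set of fixed character patterns. Such a
#' corpus has low intrinsic entropy: within a pattern every character is
#' determined by its context, so a language model that memorizes the
#' patterns approaches the entropy floor of roughly
#' `2 * log(n_patterns) / (pattern_len + 1)` nats per token (both directions
#' must still guess which pattern a sentence is before seeing any of it).
#'
#' @param n_sentences number of sentences.
#' @param n_patterns number of distinct sentence patterns.
#' @param pattern_len characters per pattern.
#' @param alphabet_size synthetic alphabet size.
#' @param seed integer seed.
#' @return list of character vectors.
#' @export
generate_lm_corpus <- function(n_sentences = 50L, n_patterns = 3L,
                               pattern_len = 30L, alphabet_size = 12L,
                               seed = 1L) {
  ab <- fixture_alphabet(alphabet_size)
  with_seed(seed, {
    patterns <- lapply(seq_len(n_patterns), function(i)
      sample(ab, pattern_len, replace = TRUE))
    # distinct first characters so patterns are identifiable immediately
    heads <- sample(ab, n_patterns)
    for (i in seq_len(n_patterns)) patterns[[i]][1] <- heads[i]
    idx <- sample.int(n_patterns, n_sentences, replace = TRUE)
  })
  lapply(idx, function(i) patterns[[i]])
}

#' Generate seeded character and word embedding tables
#'
#' Gaussian vectors for every alphabet character and every lexicon term, in
#' word2vec-writable tables; the word table covers every term id, so fixture
#' runs never hit the UNK row.
#'
#' @param lexicon a `ner_lexicon`.
#' @param alphabet character vector (e.g. from [generate_lexicon()]).
#' @param dim embedding dimensionality (default 100).
#' @param seed integer seed.
#' @param sd entry standard deviation (default 0.5, the scale of typical
#'   word2vec vectors).
#' @return list with `char_table` and `word_table` (`embedding_table`s).
#' @export
generate_embedding_tables <- function(lexicon, alphabet, dim = 100L,
                                      seed = 1L, sd = 0.5) {
  list(char_table = random_embedding_table(alphabet, dim, seed = seed, sd = sd),
       word_table = random_embedding_table(lexicon$terms, dim,
                                           seed = seed + 1L, sd = sd))
}

#' Generate a full synthetic study setup
#'
#' Convenience wrapper producing lexicon, train/test corpora and embedding
#' tables from one config; the test corpus is drawn from the same
#' distribution with a shifted seed.
#'
#' @param config a `fixture_config`.
#' @param n_test number of test sentences (default: a third of training).
#' @param emb_dim embedding size (default 100).
#' @return list with `lexicon`, `term_categories`, `alphabet`, `train`,
#'   `test`, `char_table`, `word_table`.
#' @export
generate_study <- function(config, n_test = ceiling(config$n_sentences / 3),
                           emb_dim = 100L) {
  lx <- generate_lexicon(config)
  train <- generate_corpus(lx$lexicon, lx$term_categories, config,
                           seed = config$seed + 1L)
  test_cfg <- config
  test_cfg$n_sentences <- as.integer(n_test)
  test <- generate_corpus(lx$lexicon, lx$term_categories, test_cfg,
                          seed = config$seed + 2L)
  tabs <- generate_embedding_tables(lx$lexicon, lx$alphabet, dim = emb_dim,
                                    seed = config$seed + 3L)
  c(lx, list(train = train, test = test), tabs)
}
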