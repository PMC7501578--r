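# Strict entity-level evaluation: a predicted entity counts as correct only
# when sentence, boundaries and category all match a gold entity exactly.

span_keys <- function(tags, sent_id) {
  sp <- spans_from_tags(tags)
  if (nrow(sp) == 0L) return(character(0))
  unique(paste(sent_id, sp$begin, sp$end, sp$category, sep = "\r"))
}

#' Strict precision / recall / F1
#'
#' Computes entity-level metrics under strict matching: an entity is a
#' triple (boundary begin, boundary end, category) within a sentence, and a
#' prediction scores only on exact agreement of all three. Predicted tag
#' sequences are first repaired to BIO consistency (a decoder with masking
#' off may emit bare `I-X`); duplicate identical gold spans are collapsed.
#' Metrics are percentages; 0/0 is reported as 0.
#'
#' @param gold list of gold BIO tag vectors.
#' @param pred list of predicted BIO tag vectors, aligned with `gold`.
#' @return object of class `prf_report`: list with `per_category`
#'   (data.frame: category, gold, pred, match, precision, recall, f1) and
#'   `micro` (named vector precision/recall/f1 plus counts).
#' @export
strict_prf <- function(gold, pred) {
  if (length(gold) != length(pred))
    stop("gold and pred differ in sentence count")
  g_keys <- character(0); p_keys <- character(0)
  for (i in seq_along(gold)) {
    if (length(gold[[i]]) != length(pred[[i]]))
      stop("sentence ", i, ": gold and pred lengths differ")
    g_keys <- c(g_keys, span_keys(repair_bio(gold[[i]]), i))
    p_keys <- c(p_keys, span_keys(repair_bio(pred[[i]]), i))
  }
  matched <- intersect(g_keys, p_keys)
  cat_of <- function(keys) vapply(strsplit(keys, "\r", fixed = TRUE),
                                  `[[`, character(1), 4L)
  cats <- sort(unique(c(cat_of(g_keys), cat_of(p_keys))))
  prf <- function(m, p, g) {
    prec <- if (p > 0) 100 * m / p else 0
    rec <- if (g > 0) 100 * m / g else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(precision = prec, recall = rec, f1 = f1)
  }
  rows <- lapply(cats, function(k) {
    g <- sum(cat_of(g_keys) == k); p <- sum(cat_of(p_keys) == k)
    m <- sum(cat_of(matched) == k)
    data.frame(category = k, gold = g, pred = p, match = m,
               t(prf(m, p, g)))
  })
  per_cat <- if (length(rows)) do.call(rbind, rows) else
    data.frame(category = character(0), gold = integer(0), pred = integer(0),
               match = integer(0), precision = numeric(0), recall = numeric(0),
               f1 = numeric(0))
  micro <- c(prf(length(matched), length(p_keys), length(g_keys)),
             gold = length(g_keys), pred = length(p_keys),
             match = length(matched))
  structure(list(per_category = per_cat, micro = micro), class = "prf_report")
}

#' @export
print.prf_report <- function(x, ...) {
  cat(report_table(x))
  invisible(x)
}

#' Format a PRF report as a TSV table
#'
#' One row per category plus an `All` row; percentages to two decimals.
#' The text round-trips through [utils::read.delim()].
#'
#' @param report a `prf_report` from [strict_prf()].
#' @return a single string (TSV with header).
#' @export
report_table <- function(report) {
  pc <- report$per_category
  fmt <- function(x) formatC(x, format = "f", digits = 2)
  lines <- c("category\tgold\tpred\tmatch\tprecision\trecall\tf1")
  for (r in seq_len(nrow(pc)))
    lines <- c(lines, paste(pc$category[r], pc$gold[r], pc$pred[r], pc$match[r],
                            fmt(pc$precision[r]), fmt(pc$recall[r]),
                            fmt(pc$f1[r]), sep = "\t"))
  m <- report$micro
  lines <- c(lines, paste("All", m[["gold"]], m[["pred"]], m[["match"]],
                          fmt(m[["precision"]]), fmt(m[["recall"]]),
                          fmt(m[["f1"]]), sep = "\t"))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Average several PRF reports
#'
#' Arithmetic mean of micro precision, recall and F1 across replicate runs
#' (the five-run averaging protocol).
#'
#' @param reports list of `prf_report` objects.
#' @return named numeric vector (precision, recall, f1).
#' @export
average_prf <- function(reports) {
  m <- vapply(reports, function(r) r$micro[c("precision", "recall", "f1")],
              numeric(3))
  rowMeans(m)
}
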