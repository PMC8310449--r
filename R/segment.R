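# Lexicon-driven segmentation: unigram maximum-probability path over a
# position lattice, solved by dynamic programming.

LEX_CATEGORIES <- c("DIS", "SYM", "ZCY", "general")

#' Build a segmentation lexicon
#'
#' The lexicon holds domain words (symptoms, diseases, CPM products, plus
#' general filler) with corpus frequencies. Duplicate words have their
#' frequencies summed; the category of the first occurrence is kept.
#'
#' @param words Character vector of words (for whitespace-tokenized text a
#'   "word" may contain internal spaces and so span several tokens).
#' @param freqs Positive integer frequencies, same length as `words`.
#' @param categories Categories, one of `DIS`, `SYM`, `ZCY`, `general`;
#'   recycled if length 1.
#' @return An object of class `cpm_lexicon` with `entries` (data.frame
#'   `word`, `freq`, `category`) and `total` (sum of frequencies).
#' @export
#' @examples
#' lex <- build_lexicon(c("chest pain", "cough"), c(10, 25), "SYM")
build_lexicon <- function(words, freqs, categories = "general") {
  if (!length(words)) stop("lexicon entries must be non-empty")
  freqs <- as.numeric(freqs)
  if (any(!is.finite(freqs)) || any(freqs <= 0))
    stop("lexicon frequencies must be positive")
  categories <- rep_len(as.character(categories), length(words))
  if (!all(categories %in% LEX_CATEGORIES))
    stop(sprintf("lexicon categories must be in {%s}",
                 paste(LEX_CATEGORIES, collapse = ", ")))
  first <- !duplicated(words)
  freq <- vapply(split(freqs, factor(words, levels = words[first])),
                 sum, numeric(1))
  entries <- data.frame(word = words[first], freq = as.numeric(freq),
                        category = categories[first],
                        stringsAsFactors = FALSE)
  rownames(entries) <- NULL
  structure(list(entries = entries, total = sum(entries$freq)),
            class = "cpm_lexicon")
}

#' @export
print.cpm_lexicon <- function(x, ...) {
  cat(sprintf("CPM lexicon: %d words, total frequency %g\n",
              nrow(x$entries), x$total))
  print(table(factor(x$entries$category, levels = LEX_CATEGORIES)))
  invisible(x)
}

#' Read / write a lexicon as TSV
#'
#' Columns: word, frequency, category.
#'
#' @param path File path.
#' @return `read_lexicon` returns a `cpm_lexicon`; `write_lexicon` returns
#'   `path` invisibly.
#' @export
read_lexicon <- function(path) {
  d <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  build_lexicon(d$word, d$frequency, d$category)
}

#' @rdname read_lexicon
#' @param lexicon A `cpm_lexicon`.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "cpm_lexicon"))
  d <- lexicon$entries
  names(d) <- c("word", "frequency", "category")
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Lexicon category of a word
#'
#' @param lexicon A `cpm_lexicon`.
#' @param words Character vector.
#' @return Category per word; `"OOV"` for words not in the lexicon.
#' @export
lexicon_category <- function(lexicon, words) {
  i <- match(words, lexicon$entries$word)
  ifelse(is.na(i), "OOV", lexicon$entries$category[i])
}

#' Tokenize text into atomic units
#'
#' Characters for ideographic (CJK) text, whitespace-separated tokens
#' otherwise. The segmenter, tagger, and BIO codecs all operate on these
#' units, which makes the pipeline script-independent.
#'
#' @param text A single string.
#' @return A list with `tokens` (character vector) and `sep` (the string
#'   that re-joins them: `" "` or `""`).
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text)))
    return(list(tokens = character(), sep = " "))
  if (grepl("[\u4e00-\u9fff]", text)) {
    list(tokens = strsplit(gsub("\\s+", "", text), "")[[1]], sep = "")
  } else {
    list(tokens = strsplit(trimws(text), "\\s+")[[1]], sep = " ")
  }
}

# score of a candidate word: log(freq/total), with a smoothed pseudo-
# frequency of 0.5 for a single out-of-vocabulary token (guarantees a path
# exists for any input while preferring genuine lexicon words)
OOV_PSEUDO_FREQ <- 0.5

segment_word_score <- function(word, n_tokens, lex_map, total) {
  f <- lex_map[[word]]
  if (!is.null(f)) return(log(f / total))
  if (n_tokens == 1L) return(log(OOV_PSEUDO_FREQ / total))
  -Inf
}

# candidate comparison under the fixed tie-break: higher score, then fewer
# words, then lexicographically smaller word vector
seg_better <- function(score_a, words_a, score_b, words_b, tol = 1e-9) {
  if (score_a > score_b + tol) return(TRUE)
  if (score_a < score_b - tol) return(FALSE)
  if (length(words_a) != length(words_b))
    return(length(words_a) < length(words_b))
  for (k in seq_along(words_a)) {
    if (words_a[k] != words_b[k]) return(words_a[k] < words_b[k])
  }
  FALSE
}

#' Maximum-probability word segmentation
#'
#' Segments a token sequence into lexicon words by maximizing the unigram
#' log-probability sum `sum(log(freq(w)/total))` over all segmentations,
#' via dynamic programming over the position lattice. A single token absent
#' from the lexicon is usable with smoothed pseudo-frequency 0.5, so every
#' input admits a segmentation. Ties are broken by preferring fewer words,
#' then the lexicographically smaller word list; the result is
#' deterministic.
#'
#' @param text A single string (or an already-tokenized character vector).
#' @param lexicon A `cpm_lexicon`.
#' @param sep Joining separator when `text` is pre-tokenized; ignored
#'   otherwise.
#' @return Character vector of words whose concatenation (with `sep`)
#'   equals the input.
#' @export
#' @examples
#' lex <- build_lexicon(c("chest pain", "chest", "pain"), c(20, 5, 5), "SYM")
#' segment_text("chest pain", lex)
segment_text <- function(text, lexicon, sep = " ") {
  stopifnot(inherits(lexicon, "cpm_lexicon"))
  if (nrow(lexicon$entries) == 0L) stop("empty lexicon")
  if (is.character(text) && length(text) == 1L) {
    tk <- tokenize(text)
    tokens <- tk$tokens
    sep <- tk$sep
  } else {
    tokens <- as.character(text)
  }
  n <- length(tokens)
  if (n == 0L) return(character())
  lex_map <- as.list(lexicon$entries$freq)
  names(lex_map) <- lexicon$entries$word
  total <- lexicon$total
  max_len <- max(vapply(strsplit(lexicon$entries$word,
                                 if (identical(sep, "")) "" else sep,
                                 fixed = !identical(sep, "")),
                        length, integer(1)), 1L)
  # best[[j+1]]: best segmentation of tokens[1..j]; list(score, words)
  best <- vector("list", n + 1L)
  best[[1L]] <- list(score = 0, words = character())
  for (j in seq_len(n)) {
    for (i in max(1L, j - max_len + 1L):j) {
      prev <- best[[i]]
      if (is.null(prev)) next
      w <- paste(tokens[i:j], collapse = sep)
      ws <- segment_word_score(w, j - i + 1L, lex_map, total)
      if (!is.finite(ws)) next
      cand_score <- prev$score + ws
      cand_words <- c(prev$words, w)
      cur <- best[[j + 1L]]
      if (is.null(cur) ||
          seg_better(cand_score, cand_words, cur$score, cur$words))
        best[[j + 1L]] <- list(score = cand_score, words = cand_words)
    }
  }
  best[[n + 1L]]$words
}

#' Exhaustively enumerate and score all segmentations
#'
#' Reference implementation of the segmentation objective by brute force
#' over all `2^(n-1)` break-point subsets, with the same scoring and
#' tie-break as [segment_text()]. Intended for validation at small `n`.
#'
#' @param tokens Character vector of tokens (`length <= 16`).
#' @param lexicon A `cpm_lexicon`.
#' @param sep Joining separator.
#' @return Character vector of words, or `NULL` if no finite-score
#'   segmentation exists (cannot happen: single OOV tokens are smoothed).
#' @export
segment_bruteforce <- function(tokens, lexicon, sep = " ") {
  n <- length(tokens)
  if (n == 0L) return(character())
  stopifnot(n <= 16L)
  lex_map <- as.list(lexicon$entries$freq)
  names(lex_map) <- lexicon$entries$word
  total <- lexicon$total
  best <- NULL
  for (mask in 0:(2^(n - 1L) - 1L)) {
    cuts <- which(bitwAnd(mask, bitwShiftL(1L, 0:(max(n - 2L, 0L)))) > 0L)
    bounds <- c(0L, cuts, n)
    words <- character(length(bounds) - 1L)
    score <- 0
    ok <- TRUE
    for (k in seq_len(length(bounds) - 1L)) {
      span <- (bounds[k] + 1L):bounds[k + 1L]
      w <- paste(tokens[span], collapse = sep)
      s <- segment_word_score(w, length(span), lex_map, total)
      if (!is.finite(s)) { ok <- FALSE; break }
      words[k] <- w
      score <- score + s
    }
    if (!ok) next
    if (is.null(best) || seg_better(score, words, best$score, best$words))
      best <- list(score = score, words = words)
  }
  best$words
}
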