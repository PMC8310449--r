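# BIO tagging scheme over three entity categories:
#   DIS (disease), SYM (symptom), ZCY (Chinese patent medicine).
# Entity spans start with B-X, continue with I-X; everything else is O.

NER_LABELS <- c("DIS", "SYM", "ZCY")
BIO_TAGS <- c("O", as.vector(outer(c("B-", "I-"), NER_LABELS, paste0)))

#' Construct a mention table
#'
#' Mentions are labeled text spans in token coordinates: zero-based,
#' half-open `[start, end)`. Within one record they must be non-overlapping;
#' they are kept sorted by start.
#'
#' @param start,end Integer vectors, `0 <= start < end`.
#' @param label Labels in `DIS`, `SYM`, `ZCY`.
#' @param surface Covered text (optional, defaults to `NA`).
#' @param entity_id Linked graph node id or `NA`.
#' @param link_method One of `exact`, `alias`, `fuzzy`, `unlinked`.
#' @return A data.frame of class `cpm_mentions`.
#' @export
mentions <- function(start = integer(), end = integer(), label = character(),
                     surface = NA_character_, entity_id = NA_character_,
                     link_method = "unlinked") {
  n <- length(start)
  out <- data.frame(start = as.integer(start), end = as.integer(end),
                    label = as.character(label),
                    surface = rep_len(as.character(surface), n),
                    entity_id = rep_len(as.character(entity_id), n),
                    link_method = rep_len(as.character(link_method), n),
                    stringsAsFactors = FALSE)
  validate_mentions(out)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cpm_mentions", "data.frame")
  out
}

validate_mentions <- function(m, n_tokens = NULL) {
  if (!nrow(m)) return(invisible(m))
  if (any(m$start < 0L) || any(m$end <= m$start))
    stop("mention spans must satisfy 0 <= start < end")
  if (!all(m$label %in% NER_LABELS))
    stop(sprintf("mention labels must be in {%s}",
                 paste(NER_LABELS, collapse = ", ")))
  if (!is.null(n_tokens) && any(m$end > n_tokens))
    stop("mention span exceeds sequence length")
  o <- order(m$start)
  if (any(m$end[o][-length(o)] > m$start[o][-1L]))
    stop("mentions overlap")
  invisible(m)
}

#' Encode mentions as BIO tags
#'
#' @param n_tokens Sequence length.
#' @param m A mention table (see [mentions()]); must be non-overlapping and
#'   within bounds.
#' @return Character vector of `n_tokens` BIO tags.
#' @export
#' @examples
#' bio_encode(4, mentions(1, 3, "SYM"))
bio_encode <- function(n_tokens, m) {
  validate_mentions(m, n_tokens)
  tags <- rep("O", n_tokens)
  for (i in seq_len(nrow(m))) {
    span <- (m$start[i] + 1L):m$end[i]
    tags[span] <- paste0("I-", m$label[i])
    tags[span[1L]] <- paste0("B-", m$label[i])
  }
  tags
}

#' Decode BIO tags into mentions
#'
#' Maximal `B-X (I-X)*` runs become mentions. Ill-formed sequences are
#' repaired: an `I-X` not preceded by `B-X`/`I-X` of the same category is
#' treated as `B-X`.
#'
#' @param tokens Token vector.
#' @param tags BIO tag vector of the same length.
#' @param sep Separator used to rebuild surface strings.
#' @return A mention table.
#' @export
bio_decode <- function(tokens, tags, sep = " ") {
  if (length(tokens) != length(tags))
    stop("tokens and tags must have equal length")
  if (!all(tags %in% BIO_TAGS))
    stop(sprintf("unknown BIO tag(s): %s",
                 paste(unique(setdiff(tags, BIO_TAGS)), collapse = ", ")))
  starts <- integer(); ends <- integer(); labs <- character()
  cur_lab <- NA_character_; cur_start <- NA_integer_
  flush <- function(upto) {
    if (!is.na(cur_lab)) {
      starts <<- c(starts, cur_start)
      ends <<- c(ends, upto)
      labs <<- c(labs, cur_lab)
    }
  }
  for (i in seq_along(tags)) {
    t <- tags[i]
    if (t == "O") {
      flush(i - 1L); cur_lab <- NA_character_
    } else {
      pre <- substr(t, 1L, 1L)
      lab <- substr(t, 3L, nchar(t))
      if (pre == "B" || is.na(cur_lab) || cur_lab != lab) {
        flush(i - 1L)               # repair: orphan I-X opens a new span
        cur_lab <- lab
        cur_start <- i - 1L
      }
    }
  }
  flush(length(tags))
  surf <- vapply(seq_along(starts), function(k)
    paste(tokens[(starts[k] + 1L):ends[k]], collapse = sep), character(1))
  mentions(starts, ends, labs, surface = if (length(surf)) surf else NA)
}

#' Read / write a BIO corpus in CoNLL-style two-column format
#'
#' One `token TAB tag` pair per line, blank line between sequences, UTF-8.
#'
#' @param path File path.
#' @return `read_bio_corpus` returns a list of sequences, each a list with
#'   `tokens` and `tags`.
#' @export
read_bio_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  seqs <- list()
  tokens <- character(); tags <- character()
  push <- function() {
    if (length(tokens))
      seqs[[length(seqs) + 1L]] <<- list(tokens = tokens, tags = tags)
    tokens <<- character(); tags <<- character()
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) { push(); next }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop(sprintf("malformed corpus line (need token TAB tag): '%s'", ln))
    tokens <- c(tokens, parts[1]); tags <- c(tags, parts[2])
  }
  push()
  seqs
}

#' @rdname read_bio_corpus
#' @param corpus List of sequences (`tokens`, `tags`).
#' @export
write_bio_corpus <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (s in corpus) {
    stopifnot(length(s$tokens) == length(s$tags))
    writeLines(paste(s$tokens, s$tags, sep = "\t"), con)
    writeLines("", con)
  }
  invisible(path)
}
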