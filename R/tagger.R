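# Sequence tagger for clinical entity mentions. The default backend is a
# first-order conditional sequence model: an averaged structured perceptron
# over sparse per-token features, decoded by Viterbi best-path search.
# Heavier pretrained backends can be plugged in through the same contract.

# Per-token feature extraction. Features are identity-like strings; the
# model is linear in their indicators. The lexicon contributes word-level
# knowledge through the segmenter: each token inherits the category of the
# segmented word covering it plus its position (B/I) within that word, so
# a multi-token lexicon entry such as "symword3 sign" projects its SYM
# category onto both tokens even when the tokens were never seen in
# training.
# `vocab` is the set of tokens the model may memorize; tokens outside it
# are replaced by "<unk>" in the identity-like features. During training
# singletons are excluded from the vocabulary, so the model is forced to
# learn how to tag an unfamiliar token from its lexicon category rather
# than memorizing every surface form.
token_features <- function(tokens, lexicon = NULL, vocab = NULL) {
  n <- length(tokens)
  lc <- rep("NA", n)
  pw <- rep("B", n)
  if (!is.null(lexicon) && n > 0L) {
    words <- segment_text(tokens, lexicon, sep = " ")
    cats <- lexicon_category(lexicon, words)
    pos <- 1L
    for (k in seq_along(words)) {
      len <- length(strsplit(words[k], " ", fixed = TRUE)[[1]])
      lc[pos:(pos + len - 1L)] <- cats[k]
      if (len > 1L) pw[(pos + 1L):(pos + len - 1L)] <- "I"
      pos <- pos + len
    }
  }
  w <- tokens
  if (!is.null(vocab)) w[!w %in% vocab] <- "<unk>"
  lapply(seq_len(n), function(i) c(
    paste0("w=", w[i]),
    paste0("lc=", lc[i]),
    paste0("w&lc=", w[i], "&", lc[i]),
    paste0("pw=", pw[i]),
    paste0("pv=", if (i > 1L) w[i - 1L] else "<s>"),
    paste0("nx=", if (i < n) w[i + 1L] else "</s>"),
    "bias"))
}

# Weight lookup that works for both a live training environment and the
# frozen named-vector parameters of a saved model.
weight_get <- function(store, keys) {
  if (is.environment(store)) {
    vapply(keys, function(k) get0(k, envir = store, ifnotfound = 0),
           numeric(1), USE.NAMES = FALSE)
  } else {
    v <- unname(store[keys])
    v[is.na(v)] <- 0
    v
  }
}

# Viterbi decode: emission scores from feature weights, plus first-order
# transition weights keyed "prev>next".
viterbi_decode <- function(feats, labels, w, trans) {
  n <- length(feats)
  if (n == 0L) return(character())
  L <- length(labels)
  emit <- matrix(0, n, L)
  for (i in seq_len(n)) {
    for (l in seq_len(L)) {
      keys <- paste0(feats[[i]], "~", labels[l])
      emit[i, l] <- sum(weight_get(w, keys))
    }
  }
  keys <- outer(labels, labels, function(a, b) paste0(a, ">", b))
  tmat <- matrix(weight_get(trans, keys), L, L)
  delta <- matrix(-Inf, n, L)
  back <- matrix(0L, n, L)
  delta[1L, ] <- emit[1L, ]
  if (n > 1L) for (i in 2:n) {
    for (l in seq_len(L)) {
      sc <- delta[i - 1L, ] + tmat[, l]
      # deterministic tie-break: earliest label index wins
      b <- which.max(sc)
      delta[i, l] <- sc[b] + emit[i, l]
      back[i, l] <- b
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1L) for (i in (n - 1L):1L) path[i] <- back[i + 1L, path[i + 1L]]
  labels[path]
}

#' Train a sequence tagger on a BIO corpus
#'
#' The default backend (`"default_statistical"`) is an averaged structured
#' perceptron: per-token features (token identity, neighbouring tokens,
#' lexicon category, position-in-word from the segmenter) scored against
#' each BIO tag, with first-order tag-transition weights, decoded by
#' Viterbi search. Tokens occurring only once in the corpus are replaced
#' by an `<unk>` symbol in the identity features (and out-of-vocabulary
#' tokens at prediction time likewise), so tagging an unfamiliar surface
#' form falls back on its lexicon category instead of memorized
#' identities. Training is deterministic given the corpus and seed
#' (the seed fixes the per-epoch shuffling of sequences).
#'
#' A `"plugin"` backend delegates to user-supplied `train`/`predict`
#' closures in `backend_config`, so a pretrained contextual model can be
#' substituted without touching the rest of the pipeline.
#'
#' @param corpus List of sequences, each `list(tokens, tags)`.
#' @param lexicon Optional `cpm_lexicon` used for category and
#'   position-in-word features.
#' @param backend `"default_statistical"` or `"plugin"`.
#' @param backend_config For `"plugin"`: `list(train = function(corpus,
#'   seed), predict = function(state, tokens))`.
#' @param epochs Perceptron epochs (default 6).
#' @param seed Integer training seed.
#' @return An object of class `cpm_tagger`.
#' @export
train_tagger <- function(corpus, lexicon = NULL,
                         backend = c("default_statistical", "plugin"),
                         backend_config = NULL, epochs = 6L, seed = 1L) {
  backend <- match.arg(backend)
  if (!length(corpus)) stop("training corpus is empty")
  for (s in corpus) {
    if (length(s$tokens) != length(s$tags))
      stop("corpus sequence with unequal token/tag lengths")
    if (!all(s$tags %in% BIO_TAGS))
      stop("corpus contains unknown BIO tags")
  }
  if (backend == "plugin") {
    if (!is.function(backend_config$train) || !is.function(backend_config$predict))
      stop("plugin backend requires train and predict functions")
    state <- backend_config$train(corpus, seed)
    return(structure(list(backend = backend, labels = BIO_TAGS,
                          state = state, predict = backend_config$predict,
                          seed = seed),
                     class = "cpm_tagger"))
  }
  labels <- BIO_TAGS
  w <- new.env(parent = emptyenv())      # feature~label -> weight
  trans <- new.env(parent = emptyenv())  # prev>next -> weight
  wa <- new.env(parent = emptyenv())     # accumulators for averaging
  ta <- new.env(parent = emptyenv())
  step <- 0L
  bump <- function(env, acc, key, delta) {
    cur <- get0(key, envir = env, ifnotfound = 0)
    assign(key, cur + delta, envir = env)
    aval <- get0(key, envir = acc, ifnotfound = 0)
    assign(key, aval + step * delta, envir = acc)
  }
  tok_counts <- table(unlist(lapply(corpus, `[[`, "tokens")))
  vocab <- names(tok_counts)[tok_counts >= 2L]
  # word-dropout augmentation: each sequence is also trained with every
  # identity feature masked to <unk>, so the lexicon-category features are
  # forced to carry the tagging of unfamiliar tokens on their own
  feats_all <- c(lapply(corpus, function(s)
    token_features(s$tokens, lexicon, vocab)),
    lapply(corpus, function(s)
      token_features(s$tokens, lexicon, character())))
  tags_all <- c(lapply(corpus, `[[`, "tags"), lapply(corpus, `[[`, "tags"))
  env2vec <- function(e) {
    ks <- ls(e, sorted = TRUE)
    if (!length(ks)) return(stats::setNames(numeric(), character()))
    stats::setNames(vapply(ks, function(k) get(k, envir = e), numeric(1)), ks)
  }
  set.seed(seed)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(feats_all))
    for (si in ord) {
      feats <- feats_all[[si]]
      step <- step + 1L
      pred <- viterbi_decode(feats, labels, w, trans)
      gold <- tags_all[[si]]
      if (identical(pred, gold)) next
      for (i in seq_along(gold)) {
        if (pred[i] != gold[i]) {
          for (f in feats[[i]]) {
            bump(w, wa, paste0(f, "~", gold[i]), 1)
            bump(w, wa, paste0(f, "~", pred[i]), -1)
          }
        }
        gp <- if (i > 1L) gold[i - 1L] else NULL
        pp <- if (i > 1L) pred[i - 1L] else NULL
        if (i > 1L && (pred[i] != gold[i] || pred[i - 1L] != gold[i - 1L])) {
          bump(trans, ta, paste0(gp, ">", gold[i]), 1)
          bump(trans, ta, paste0(pp, ">", pred[i]), -1)
        }
      }
    }
  }
  # averaged weights: w_avg = w - acc/steps (timestamped accumulation)
  avg <- function(env, acc) {
    v <- env2vec(env)
    if (!length(v)) return(v)
    a <- env2vec(acc)
    a <- a[names(v)]
    a[is.na(a)] <- 0
    v - a / max(step, 1L)
  }
  structure(list(backend = backend, labels = labels,
                 weights = avg(w, wa), transitions = avg(trans, ta),
                 vocab = vocab,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 uses_lexicon = !is.null(lexicon)),
            class = "cpm_tagger")
}

#' Predict BIO tags for a token sequence
#'
#' @param object A `cpm_tagger`.
#' @param tokens Character vector of tokens.
#' @param lexicon Optional lexicon (must match training-time usage for best
#'   results).
#' @param ... Unused.
#' @return Character vector of BIO tags.
#' @export
predict.cpm_tagger <- function(object, tokens, lexicon = NULL, ...) {
  if (!length(tokens)) return(character())
  if (object$backend == "plugin")
    return(object$predict(object$state, tokens))
  feats <- token_features(tokens, lexicon, object$vocab)
  viterbi_decode(feats, object$labels, object$weights, object$transitions)
}

#' Extract entity mentions from free text
#'
#' Tokenizes, predicts BIO tags with the trained model, and decodes the
#' tags into mention spans.
#'
#' @param model A `cpm_tagger`.
#' @param text A single string.
#' @param lexicon Optional `cpm_lexicon`.
#' @return A mention table (see [mentions()]).
#' @export
tag_text <- function(model, text, lexicon = NULL) {
  stopifnot(inherits(model, "cpm_tagger"))
  tk <- tokenize(text)
  if (!length(tk$tokens)) return(mentions())
  tags <- predict(model, tk$tokens, lexicon)
  bio_decode(tk$tokens, tags, sep = tk$sep)
}

#' @export
print.cpm_tagger <- function(x, ...) {
  cat(sprintf("CPM sequence tagger (backend: %s)\n", x$backend))
  if (x$backend == "default_statistical")
    cat(sprintf("  %d feature weights, %d transition weights, %d epochs, seed %d\n",
                length(x$weights), length(x$transitions), x$epochs, x$seed))
  invisible(x)
}

#' Save / load a tagger model
#'
#' The artifact is a single self-describing JSON file carrying the backend
#' id, seed, label vocabulary, and learned parameters; byte-stable across
#' runs for identical training inputs. Plugin backends are not
#' serializable.
#'
#' @param model A `cpm_tagger` (default backend).
#' @param path File path.
#' @return `load_tagger` returns a `cpm_tagger`.
#' @export
save_tagger <- function(model, path) {
  stopifnot(inherits(model, "cpm_tagger"))
  if (model$backend != "default_statistical")
    stop("only the default_statistical backend is serializable")
  obj <- list(format = "cpm_tagger/1", backend = model$backend,
              labels = model$labels, epochs = model$epochs, seed = model$seed,
              uses_lexicon = isTRUE(model$uses_lexicon),
              vocab = model$vocab,
              weights = as.list(model$weights),
              transitions = as.list(model$transitions))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname save_tagger
#' @export
load_tagger <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "cpm_tagger/1"))
    stop("not a tagger model file")
  unwrap <- function(x) {
    v <- unlist(x)
    if (is.null(v)) stats::setNames(numeric(), character()) else v
  }
  structure(list(backend = obj$backend, labels = obj$labels,
                 weights = unwrap(obj$weights),
                 transitions = unwrap(obj$transitions),
                 vocab = as.character(obj$vocab),
                 epochs = as.integer(obj$epochs), seed = as.integer(obj$seed),
                 uses_lexicon = isTRUE(obj$uses_lexicon)),
            class = "cpm_tagger")
}
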