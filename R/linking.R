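# Entity linking: mention surface -> knowledge-graph node, by exact
# canonical name, then alias, then normalized-edit-distance fuzzy match
# restricted to nodes of the etype implied by the mention label.

LABEL_ETYPE <- c(DIS = "disease", SYM = "symptom", ZCY = "cpm_drug")

#' Normalized string similarity
#'
#' `1 - levenshtein(a, b) / max(nchar(a), nchar(b))`, in `[0, 1]`.
#'
#' @param a A single string.
#' @param b Character vector of candidates.
#' @return Numeric vector of similarities.
#' @export
string_similarity <- function(a, b) {
  if (!length(b)) return(numeric())
  d <- as.vector(utils::adist(a, b))
  m <- pmax(nchar(a), nchar(b))
  ifelse(m == 0, 1, 1 - d / m)
}

#' Link mentions to knowledge-graph nodes
#'
#' Per mention, in order: exact canonical-name match, alias match, fuzzy
#' match with normalized similarity at least `threshold`, all restricted to
#' nodes whose etype corresponds to the mention label (DIS -> disease,
#' SYM -> symptom, ZCY -> cpm_drug). Fuzzy ties are broken by similarity
#' then id. Unresolved mentions keep `link_method = "unlinked"` — an
#' expected outcome, not an error.
#'
#' @param m A mention table (see [mentions()]).
#' @param kg A `cpm_kg`.
#' @param threshold Fuzzy-link similarity threshold in `[0, 1]`
#'   (default 0.85).
#' @return The mention table with `entity_id` and `link_method` filled in.
#' @export
link_mentions <- function(m, kg, threshold = 0.85) {
  stopifnot(inherits(kg, "cpm_kg"), threshold >= 0, threshold <= 1)
  if (!nrow(m)) return(m)
  for (i in seq_len(nrow(m))) {
    et <- LABEL_ETYPE[[m$label[i]]]
    surf <- m$surface[i]
    cand_ids <- kg$nodes$id[kg$nodes$etype == et]
    m$entity_id[i] <- NA_character_
    m$link_method[i] <- "unlinked"
    if (is.na(surf) || !length(cand_ids)) next
    cand_names <- kg$nodes$name[match(cand_ids, kg$nodes$id)]
    hit <- cand_ids[cand_names == surf]
    if (length(hit)) {
      m$entity_id[i] <- hit[1L]
      m$link_method[i] <- "exact"
      next
    }
    alias_hit <- cand_ids[vapply(cand_ids, function(id)
      surf %in% kg$aliases[[id]], logical(1))]
    if (length(alias_hit)) {
      m$entity_id[i] <- sort(alias_hit)[1L]
      m$link_method[i] <- "alias"
      next
    }
    # fuzzy: best over canonical names and aliases of type-matching nodes
    best_id <- NA_character_; best_sim <- -1
    for (k in seq_along(cand_ids)) {
      strs <- c(cand_names[k], kg$aliases[[cand_ids[k]]])
      s <- max(string_similarity(surf, strs))
      if (s > best_sim + 1e-12 ||
          (abs(s - best_sim) <= 1e-12 && !is.na(best_id) &&
           cand_ids[k] < best_id)) {
        best_sim <- s
        best_id <- cand_ids[k]
      }
    }
    if (best_sim >= threshold) {
      m$entity_id[i] <- best_id
      m$link_method[i] <- "fuzzy"
    }
  }
  m
}
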