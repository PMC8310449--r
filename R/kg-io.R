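# Graph interchange: JSON Lines, one record per line, kinds
# "entity" / "triple" / "dosage_rule". UTF-8, ids are strings.

#' Save a knowledge graph to a JSON Lines interchange file
#'
#' One record per line; record kinds `entity`, `triple`, `dosage_rule`.
#' `kg_load(kg_save(...))` is the identity up to ordering.
#'
#' @param kg A `cpm_kg`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
kg_save <- function(kg, path) {
  stopifnot(inherits(kg, "cpm_kg"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  emit <- function(x) writeLines(jsonlite::toJSON(x, auto_unbox = TRUE), con)
  for (i in seq_len(nrow(kg$nodes))) {
    id <- kg$nodes$id[i]
    emit(list(kind = "entity", id = id, name = kg$nodes$name[i],
              etype = kg$nodes$etype[i],
              aliases = as.list(kg$aliases[[id]])))
  }
  for (i in seq_len(nrow(kg$triples)))
    emit(list(kind = "triple", head = kg$triples$head[i],
              relation = kg$triples$relation[i], tail = kg$triples$tail[i]))
  for (i in seq_len(nrow(kg$dosage)))
    emit(list(kind = "dosage_rule", drug = kg$dosage$drug[i],
              population = kg$dosage$population[i],
              min_daily = kg$dosage$min_daily[i],
              max_daily = kg$dosage$max_daily[i],
              unit = kg$dosage$unit[i]))
  invisible(path)
}

#' Load a knowledge graph from a JSON Lines interchange file
#'
#' Every record is validated (type signatures, dangling endpoints, duplicate
#' dosage rules); all failures are collected and reported with their line
#' numbers in a single error.
#'
#' @param path Input file path.
#' @return A `cpm_kg`.
#' @export
kg_load <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  errs <- character()
  bad <- function(ln, msg)
    errs[[length(errs) + 1L]] <<- sprintf("line %d: %s", ln, msg)
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    recs[[i]] <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                          error = function(e) {
                            bad(i, paste("malformed JSON:", conditionMessage(e)))
                            NULL
                          })
  }
  kg <- kg_new()
  try_step <- function(i, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) bad(i, conditionMessage(res)) else kg <<- res
  }
  # entities first so record order in the file does not matter
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    if (is.null(r) || !identical(r$kind, "entity")) next
    try_step(i, {
      if (is.null(r$id) || is.null(r$name) || is.null(r$etype))
        stop("entity record missing id/name/etype")
      kg_add_entity(kg, r$id, r$name, r$etype,
                    aliases = as.character(unlist(r$aliases)))
    })
  }
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    if (is.null(r) || identical(r$kind, "entity")) next
    if (identical(r$kind, "triple")) {
      try_step(i, {
        if (is.null(r$head) || is.null(r$relation) || is.null(r$tail))
          stop("triple record missing head/relation/tail")
        kg_add_triple(kg, r$head, r$relation, r$tail)
      })
    } else if (identical(r$kind, "dosage_rule")) {
      try_step(i, {
        if (is.null(r$drug) || is.null(r$min_daily) || is.null(r$max_daily))
          stop("dosage_rule record missing drug/min_daily/max_daily")
        kg_add_dosage_rule(
          kg, r$drug, r$min_daily, r$max_daily,
          unit = if (is.null(r$unit)) "g" else r$unit,
          population = if (is.null(r$population)) "default_adult" else r$population)
      })
    } else {
      bad(i, sprintf("unknown record kind '%s'", as.character(r$kind)[1]))
    }
  }
  if (length(errs))
    stop(sprintf("invalid graph file '%s':\n  %s", path,
                 paste(errs, collapse = "\n  ")), call. = FALSE)
  kg
}

#' Export the triples of a graph as TSV
#'
#' Three columns (head, relation, tail), for human inspection.
#'
#' @param kg A `cpm_kg`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
kg_export_tsv <- function(kg, path) {
  stopifnot(inherits(kg, "cpm_kg"))
  utils::write.table(kg$triples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Compare two graphs for set equality
#'
#' Equality of the node set (ids, names, etypes, alias sets), triple set,
#' and dosage-rule set, ignoring insertion order.
#'
#' @param a,b `cpm_kg` objects.
#' @return Logical scalar.
#' @export
kg_equal <- function(a, b) {
  norm_nodes <- function(kg) {
    n <- kg$nodes[order(kg$nodes$id), , drop = FALSE]
    n$aliases <- vapply(n$id, function(id)
      paste(sort(kg$aliases[[id]]), collapse = "|"), character(1))
    rownames(n) <- NULL
    n
  }
  norm_df <- function(d) {
    d <- d[do.call(order, d), , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  identical(norm_nodes(a), norm_nodes(b)) &&
    identical(norm_df(a$triples), norm_df(b$triples)) &&
    identical(norm_df(a$dosage), norm_df(b$dosage))
}
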