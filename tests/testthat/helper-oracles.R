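# Brute-force reference implementations, written against the raw triple
# table only, independent of the package's query code paths.

oracle_ingredients <- function(kg, d) {
  tr <- kg$triples
  sort(unique(tr$tail[tr$head == d & tr$relation == "contains_ingredient"]))
}

oracle_conflicts <- function(kg, a, b) {
  ia <- oracle_ingredients(kg, a)
  ib <- oracle_ingredients(kg, b)
  tr <- kg$triples
  out <- data.frame(ingredientA = character(), ingredientB = character(),
                    relation = character(), stringsAsFactors = FALSE)
  for (x in ia) for (y in ib) {
    hit <- tr$relation %in% c("incompatible_with", "fears") &
      ((tr$head == x & tr$tail == y) | (tr$head == y & tr$tail == x))
    for (rel in tr$relation[hit])
      out <- rbind(out, data.frame(ingredientA = x, ingredientB = y,
                                   relation = rel, stringsAsFactors = FALSE))
  }
  out <- unique(out)
  out <- out[order(out$ingredientA, out$ingredientB, out$relation), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_shared <- function(kg, a, b)
  sort(intersect(oracle_ingredients(kg, a), oracle_ingredients(kg, b)))

oracle_diseases_for_symptoms <- function(kg, sym_ids, min_overlap) {
  tr <- kg$triples
  diseases <- unique(tr$head[tr$relation == "has_symptom"])
  rows <- list()
  for (dz in diseases) {
    ov <- length(intersect(tr$tail[tr$head == dz & tr$relation == "has_symptom"],
                           sym_ids))
    if (ov >= min_overlap)
      rows[[length(rows) + 1L]] <- data.frame(disease = dz, score = ov,
                                              stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(disease = character(), score = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$score <- as.integer(out$score)
  out <- out[order(-out$score, out$disease), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Flagged (warning/critical) alerts of the five checks as
# (category, drugs-key, severity) rows, recomputed by direct scans.
oracle_flagged <- function(kg, record, k_shared = 1, min_overlap = 2) {
  ids <- vapply(record$items, function(it) it$drug_ref, character(1))
  ids <- ids[ids %in% kg$nodes$id[kg$nodes$etype == "cpm_drug"]]
  out <- data.frame(category = character(), drugs = character(),
                    severity = character(), stringsAsFactors = FALSE)
  push <- function(cat_, ds, sev)
    out[nrow(out) + 1L, ] <<- list(cat_, paste(sort(ds), collapse = "|"), sev)
  uids <- sort(unique(ids))
  if (length(uids) >= 2L) {
    for (i in seq_along(uids)) for (j in seq_along(uids)) {
      if (i >= j) next
      if (nrow(oracle_conflicts(kg, uids[i], uids[j])))
        push("combined_use", c(uids[i], uids[j]), "critical")
      if (length(oracle_shared(kg, uids[i], uids[j])) >= k_shared)
        push("repeated_efficacy", c(uids[i], uids[j]), "warning")
    }
  }
  for (d in unique(ids[duplicated(ids)]))
    push("repeated_efficacy", d, "critical")
  # symptomatic
  tr <- kg$triples
  diag_ids <- record$diagnoses[record$diagnoses %in% kg$nodes$id]
  candidates <- if (length(diag_ids)) diag_ids
  else oracle_diseases_for_symptoms(
    kg, record$symptoms[record$symptoms %in% kg$nodes$id], min_overlap)$disease
  if (length(candidates)) {
    for (d in uids) {
      ind <- tr$tail[tr$head == d & tr$relation == "indicated_for_disease"]
      if (length(ind) && !length(intersect(ind, candidates)))
        push("symptomatic", d, "warning")
    }
  }
  # dosage, replicating the fixed population priority
  groups <- population_groups(record$patient)
  prio <- c("pregnant", "lactating", "child", "elderly",
            "hepatic_impairment", "renal_impairment", "default_adult")
  for (it in record$items) {
    d <- it$drug_ref
    if (!d %in% uids) next
    rules <- kg$dosage[kg$dosage$drug == d, , drop = FALSE]
    rule <- NULL
    for (p in prio) {
      if (p != "default_adult" && !p %in% groups) next
      hit <- rules[rules$population == p, , drop = FALSE]
      if (nrow(hit)) { rule <- hit[1L, ]; break }
    }
    if (is.null(rule) || is.na(it$single_dose) || is.na(it$times_per_day))
      next
    if (!identical(it$unit, rule$unit)) {
      push("dosage", d, "warning")
      next
    }
    dd <- it$single_dose * it$times_per_day
    if (dd < rule$min_daily || dd > rule$max_daily)
      push("dosage", d, "critical")
  }
  # syndrome
  if (!is.null(record$syndrome) && record$syndrome %in% kg$nodes$id) {
    for (d in uids) {
      ind <- tr$tail[tr$head == d & tr$relation == "indicated_for_syndrome"]
      if (length(ind) && !record$syndrome %in% ind)
        push("syndrome", d, "warning")
    }
  }
  out[do.call(order, out), , drop = FALSE]
}

report_flagged_key <- function(report) {
  out <- data.frame(category = character(), drugs = character(),
                    severity = character(), stringsAsFactors = FALSE)
  for (a in report$alerts) {
    if (a$severity == "info") next
    out[nrow(out) + 1L, ] <- list(a$category,
                                  paste(sort(a$drugs), collapse = "|"),
                                  a$severity)
  }
  out[do.call(order, out), , drop = FALSE]
}

expect_same_rows <- function(a, b) {
  rownames(a) <- NULL
  rownames(b) <- NULL
  expect_equal(a, b)
}
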