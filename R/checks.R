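# The five prescription checks, run against the knowledge-graph rule base:
#   combined_use       - ingredient-level incompatibility ("eighteen
#                        contraindications", "nineteen fears") across all
#                        drug pairs of the prescription
#   repeated_efficacy  - duplicate products or distinct products sharing
#                        active ingredients
#   symptomatic        - drug not indicated for any recorded/inferred disease
#   dosage             - daily dose outside the population-applicable rule
#   syndrome           - drug's indicated syndromes do not cover the
#                        recorded TCM syndrome pattern
#
# Severity ladder (package convention): critical for incompatibility,
# duplicate products and dose out of range; warning for shared-ingredient,
# indication and syndrome mismatches; info for missing/unlinkable data.

ALERT_CATEGORIES <- c("combined_use", "repeated_efficacy", "symptomatic",
                      "dosage", "syndrome")
SEVERITY_LEVELS <- c("info", "warning", "critical")

new_alert <- function(category, severity, drugs, message, evidence = list()) {
  stopifnot(category %in% ALERT_CATEGORIES, severity %in% SEVERITY_LEVELS)
  if (severity != "info" && !length(evidence))
    stop("non-info alerts require evidence")
  structure(list(category = category, severity = severity,
                 drugs = sort(unique(as.character(drugs))),
                 evidence = evidence, message = message),
            class = "cpm_alert")
}

#' @export
print.cpm_alert <- function(x, ...) {
  cat(sprintf("[%s/%s] %s (drugs: %s)\n", x$category, x$severity, x$message,
              paste(x$drugs, collapse = ", ")))
  invisible(x)
}

# Resolve prescription items to drug ids. Returns list(ids = resolved id
# per item (NA when unlinkable), alerts = info alerts for unlinkable refs).
resolve_items <- function(items, kg) {
  ids <- character(length(items))
  alerts <- list()
  for (i in seq_along(items)) {
    id <- kg_resolve(kg, items[[i]]$drug_ref)
    if (!is.na(id) && kg_etype(kg, id) != "cpm_drug") id <- NA_character_
    ids[i] <- id
    if (is.na(id))
      alerts[[length(alerts) + 1L]] <- new_alert(
        "combined_use", "info", character(),
        sprintf("drug '%s' could not be linked to the rule base; not checked",
                items[[i]]$drug_ref))
  }
  list(ids = ids, alerts = alerts)
}

#' Combined-use incompatibility check
#'
#' For every unordered pair of distinct prescribed drugs, emits one
#' critical alert per non-empty ingredient-conflict set, citing the
#' conflicting ingredient triples as evidence. A set of n drugs is
#' screened over all n(n-1)/2 pairs; unlinkable items surface as info
#' alerts and are skipped.
#'
#' @param items List of [prescription_item()]s.
#' @param kg A `cpm_kg`.
#' @return List of alerts.
#' @export
check_combined_use <- function(items, kg) {
  res <- resolve_items(items, kg)
  alerts <- res$alerts
  ids <- unique(res$ids[!is.na(res$ids)])
  if (length(ids) >= 2L) {
    pairs <- utils::combn(sort(ids), 2L)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1L, k]; b <- pairs[2L, k]
      conf <- ingredient_conflicts(kg, a, b)
      if (nrow(conf)) {
        ev <- lapply(seq_len(nrow(conf)), function(j)
          list(head = conf$ingredientA[j], relation = conf$relation[j],
               tail = conf$ingredientB[j]))
        alerts[[length(alerts) + 1L]] <- new_alert(
          "combined_use", "critical", c(a, b),
          sprintf("incompatible ingredient combination between %s and %s (%s)",
                  a, b,
                  paste(sprintf("%s %s %s", conf$ingredientA, conf$relation,
                                conf$ingredientB), collapse = "; ")),
          evidence = ev)
      }
    }
  }
  alerts
}

#' Repeated-efficacy medication check
#'
#' The same product prescribed twice is a critical alert; two distinct
#' products sharing at least `k_shared` active ingredients is a warning
#' with the shared set as evidence.
#'
#' @param items List of [prescription_item()]s.
#' @param kg A `cpm_kg`.
#' @param k_shared Minimum shared-ingredient count (default 1).
#' @return List of alerts.
#' @export
check_repeated_efficacy <- function(items, kg, k_shared = 1L) {
  stopifnot(k_shared >= 1L)
  res <- resolve_items(items, kg)
  ids <- res$ids[!is.na(res$ids)]
  alerts <- list()
  dup <- unique(ids[duplicated(ids)])
  for (d in dup)
    alerts[[length(alerts) + 1L]] <- new_alert(
      "repeated_efficacy", "critical", d,
      sprintf("drug %s is prescribed more than once", d),
      evidence = list(list(rule = "duplicate_item", drug = d,
                           observed = sum(ids == d))))
  uids <- sort(unique(ids))
  if (length(uids) >= 2L) {
    pairs <- utils::combn(uids, 2L)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1L, k]; b <- pairs[2L, k]
      sh <- shared_ingredients(kg, a, b)
      if (length(sh) >= k_shared)
        alerts[[length(alerts) + 1L]] <- new_alert(
          "repeated_efficacy", "warning", c(a, b),
          sprintf("drugs %s and %s share active ingredient(s): %s", a, b,
                  paste(sh, collapse = ", ")),
          evidence = lapply(sh, function(s)
            list(rule = "shared_ingredient", ingredient = s)))
    }
  }
  alerts
}

#' Symptomatic-administration check
#'
#' The candidate disease set is the recorded diagnoses when present,
#' otherwise diseases inferred from the recorded symptoms by
#' [diseases_for_symptoms()] (requiring at least `min_overlap` matching
#' symptoms; with a single recorded symptom the check degrades to an info
#' alert, since one shared symptom is weak evidence when a disease maps to
#' dozens of symptoms). A drug with indication data but no indicated
#' disease among the candidates is a warning; a drug without indication
#' edges is an info alert.
#'
#' @param items List of [prescription_item()]s.
#' @param record A `cpm_record` (diagnoses/symptoms are read from it;
#'   names are resolved against the graph).
#' @param kg A `cpm_kg`.
#' @param min_overlap Minimum symptom overlap for disease inference
#'   (default 2).
#' @return List of alerts.
#' @export
check_symptomatic <- function(items, record, kg, min_overlap = 2L) {
  res <- resolve_items(items, kg)
  ids <- unique(res$ids[!is.na(res$ids)])
  alerts <- list()
  diag_ids <- stats::na.omit(vapply(record$diagnoses, function(d)
    kg_resolve(kg, d), character(1)))
  if (length(diag_ids)) {
    candidates <- unique(as.character(diag_ids))
  } else {
    sym_ids <- stats::na.omit(vapply(record$symptoms, function(s)
      kg_resolve(kg, s), character(1)))
    candidates <- if (length(sym_ids))
      suppressWarnings(diseases_for_symptoms(kg, sym_ids, min_overlap))$disease
    else character()
  }
  if (!length(candidates)) {
    alerts[[length(alerts) + 1L]] <- new_alert(
      "symptomatic", "info", character(),
      "no diagnosis recorded and none inferable from symptoms; indication check skipped")
    return(alerts)
  }
  for (d in ids) {
    ind <- indications(kg, d)$diseases
    if (!length(ind)) {
      alerts[[length(alerts) + 1L]] <- new_alert(
        "symptomatic", "info", d,
        sprintf("no indication data for drug %s", d))
    } else if (!length(intersect(ind, candidates))) {
      alerts[[length(alerts) + 1L]] <- new_alert(
        "symptomatic", "warning", d,
        sprintf("drug %s is not indicated for any recorded/inferred disease (%s)",
                d, paste(candidates, collapse = ", ")),
        evidence = lapply(ind, function(x)
          list(head = d, relation = "indicated_for_disease", tail = x)))
    }
  }
  alerts
}

#' Dosage check
#'
#' Per item, the applicable rule is found by [dosage_rule_lookup()] using
#' the patient's population groups. A daily dose outside the inclusive
#' `[min_daily, max_daily]` interval is a critical alert citing the rule
#' and the observed daily dose; a unit mismatch between item and rule is a
#' warning ("not evaluated"); missing dose data or missing rules give info
#' alerts.
#'
#' @param items List of [prescription_item()]s.
#' @param patient A `cpm_patient`.
#' @param kg A `cpm_kg`.
#' @param child_max_age,elderly_min_age Age cutoffs for the derived
#'   population groups.
#' @return List of alerts.
#' @export
check_dosage <- function(items, patient, kg, child_max_age = 14,
                         elderly_min_age = 65) {
  res <- resolve_items(items, kg)
  groups <- population_groups(patient, child_max_age, elderly_min_age)
  alerts <- list()
  for (i in seq_along(items)) {
    id <- res$ids[i]
    if (is.na(id)) next
    it <- items[[i]]
    rule <- dosage_rule_lookup(kg, id, groups)
    if (is.null(rule)) {
      alerts[[length(alerts) + 1L]] <- new_alert(
        "dosage", "info", id,
        sprintf("no dosage rule for drug %s; not evaluated", id))
      next
    }
    if (is.na(it$single_dose) || is.na(it$times_per_day)) {
      alerts[[length(alerts) + 1L]] <- new_alert(
        "dosage", "info", id,
        sprintf("dose for drug %s not recorded; not evaluated", id))
      next
    }
    if (!identical(it$unit, rule$unit)) {
      alerts[[length(alerts) + 1L]] <- new_alert(
        "dosage", "warning", id,
        sprintf("unit mismatch for drug %s (item '%s' vs rule '%s'), not evaluated",
                id, it$unit, rule$unit),
        evidence = list(list(rule = as.list(rule), observed_unit = it$unit)))
      next
    }
    dd <- daily_dose(it)
    if (dd < rule$min_daily || dd > rule$max_daily)
      alerts[[length(alerts) + 1L]] <- new_alert(
        "dosage", "critical", id,
        sprintf("daily dose %g %s of drug %s outside rule [%g, %g] %s (population %s)",
                dd, it$unit, id, rule$min_daily, rule$max_daily, rule$unit,
                rule$population),
        evidence = list(list(rule = as.list(rule), observed = dd)))
  }
  alerts
}

#' Syndrome-differentiation check
#'
#' The TCM principle that a drug should match the patient's diagnosed
#' syndrome pattern, not only the disease name. Without a recorded
#' syndrome the category degrades to a single info alert; otherwise each
#' drug carrying `indicated_for_syndrome` edges that do not include the
#' recorded syndrome is a warning, and drugs without syndrome data are
#' info alerts.
#'
#' @param items List of [prescription_item()]s.
#' @param record A `cpm_record`.
#' @param kg A `cpm_kg`.
#' @return List of alerts.
#' @export
check_syndrome <- function(items, record, kg) {
  res <- resolve_items(items, kg)
  ids <- unique(res$ids[!is.na(res$ids)])
  alerts <- list()
  syn <- if (is.null(record$syndrome)) NA_character_
         else kg_resolve(kg, record$syndrome)
  if (is.null(record$syndrome) || is.na(syn)) {
    alerts[[length(alerts) + 1L]] <- new_alert(
      "syndrome", "info", character(),
      "no (resolvable) syndrome recorded; syndrome differentiation not evaluated")
    return(alerts)
  }
  for (d in ids) {
    ind <- indications(kg, d)$syndromes
    if (!length(ind)) {
      alerts[[length(alerts) + 1L]] <- new_alert(
        "syndrome", "info", d,
        sprintf("no syndrome data for drug %s", d))
    } else if (!syn %in% ind) {
      alerts[[length(alerts) + 1L]] <- new_alert(
        "syndrome", "warning", d,
        sprintf("drug %s is not indicated for recorded syndrome %s", d, syn),
        evidence = lapply(ind, function(x)
          list(head = d, relation = "indicated_for_syndrome", tail = x)))
    }
  }
  alerts
}

#' Review one medical record against the rule base
#'
#' Runs all five checks and assembles a review report. When the record has
#' no structured items/diagnoses/symptoms but carries text sections, the
#' tagger and entity linker populate the missing fields from the text
#' (ZCY mentions become items with unknown dose, DIS mentions diagnoses,
#' SYM mentions symptoms). Deterministic given inputs and model.
#'
#' @param record A `cpm_record`.
#' @param kg A `cpm_kg`.
#' @param model Optional `cpm_tagger` (required only when structured
#'   fields are missing and must be recovered from text).
#' @param lexicon Optional `cpm_lexicon` for the tagger.
#' @param config Named list of thresholds: `k_shared`, `min_overlap`,
#'   `fuzzy_link`, `child_max_age`, `elderly_min_age` (missing entries take
#'   the package defaults).
#' @return A `cpm_report`.
#' @export
review_record <- function(record, kg, model = NULL, lexicon = NULL,
                          config = list()) {
  stopifnot(inherits(record, "cpm_record"), inherits(kg, "cpm_kg"))
  cfg <- utils::modifyList(list(k_shared = 1L, min_overlap = 2L,
                                fuzzy_link = 0.85, child_max_age = 14,
                                elderly_min_age = 65), config)
  needs_text <- !length(record$items) || (!length(record$diagnoses) &&
                                          !length(record$symptoms))
  if (needs_text &&
      (nzchar(record$course_record_text) || nzchar(record$discharge_summary_text))) {
    if (is.null(model))
      stop("record lacks structured fields; a tagger model is required")
    m <- rbind(tag_text(model, record$course_record_text, lexicon),
               tag_text(model, record$discharge_summary_text, lexicon))
    m <- link_mentions(m, kg, threshold = cfg$fuzzy_link)
    linked <- m[!is.na(m$entity_id), , drop = FALSE]
    if (!length(record$items))
      record$items <- lapply(unique(linked$entity_id[linked$label == "ZCY"]),
                             function(id) prescription_item(id, NA, NA))
    if (!length(record$diagnoses))
      record$diagnoses <- unique(linked$entity_id[linked$label == "DIS"])
    if (!length(record$symptoms))
      record$symptoms <- unique(linked$entity_id[linked$label == "SYM"])
  }
  if (!length(record$items) && !length(record$diagnoses) &&
      !length(record$symptoms))
    stop(sprintf("record %s has neither structured fields nor usable text",
                 record$record_id))
  alerts <- c(check_combined_use(record$items, kg),
              check_repeated_efficacy(record$items, kg, cfg$k_shared),
              check_symptomatic(record$items, record, kg, cfg$min_overlap),
              check_dosage(record$items, record$patient, kg,
                           cfg$child_max_age, cfg$elderly_min_age),
              check_syndrome(record$items, record, kg))
  new_report(record$record_id, alerts)
}

new_report <- function(record_id, alerts) {
  sev <- vapply(alerts, `[[`, character(1), "severity")
  cat_ <- vapply(alerts, `[[`, character(1), "category")
  verdicts <- vapply(ALERT_CATEGORIES, function(cc)
    if (any(cat_ == cc & sev %in% c("warning", "critical"))) "flagged" else "pass",
    character(1))
  counts <- vapply(SEVERITY_LEVELS, function(s) sum(sev == s), integer(1))
  structure(list(record_id = record_id, alerts = alerts,
                 verdicts = verdicts, counts = counts),
            class = "cpm_report")
}

#' @export
print.cpm_report <- function(x, ...) {
  cat(sprintf("Review report for record %s: %d alert(s) [%s]\n", x$record_id,
              length(x$alerts),
              paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", ")))
  for (cc in ALERT_CATEGORIES)
    cat(sprintf("  %-18s %s\n", cc, x$verdicts[[cc]]))
  for (a in x$alerts) {
    cat("  "); print(a)
  }
  invisible(x)
}

#' Does a report contain any critical alert?
#'
#' @param report A `cpm_report`.
#' @return Logical scalar.
#' @export
has_critical <- function(report) {
  any(vapply(report$alerts, `[[`, character(1), "severity") == "critical")
}

report_to_list <- function(rep) {
  list(record_id = rep$record_id,
       verdicts = as.list(rep$verdicts),
       counts = as.list(rep$counts),
       alerts = lapply(rep$alerts, function(a)
         list(category = a$category, severity = a$severity,
              drugs = as.list(a$drugs), message = a$message,
              evidence = a$evidence)),
       summary = paste(
         sprintf("record %s:", rep$record_id),
         paste(sprintf("%s=%s", names(rep$verdicts), rep$verdicts),
               collapse = " "),
         sprintf("(%d alerts)", length(rep$alerts))))
}

#' Write review reports as JSON
#'
#' A JSON array with one object per report: machine-readable alert array
#' plus a plain-text summary block.
#'
#' @param reports List of `cpm_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path) {
  obj <- lapply(reports, report_to_list)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}
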