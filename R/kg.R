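# Closed vocabularies for the typed graph ------------------------------------

#' Entity and relation vocabularies
#'
#' The graph is typed: every node carries one of six entity types, and every
#' relation constrains the types of its endpoints.
#'
#' @format Character vectors.
#' @name kg-vocab
NULL

KG_ETYPES <- c("cpm_drug", "ingredient", "disease", "symptom", "syndrome",
               "population_group")

# relation -> c(head etype, tail etype); NA tail means symptom-or-disease
KG_RELATIONS <- list(
  contains_ingredient           = c("cpm_drug",  "ingredient"),
  incompatible_with             = c("ingredient", "ingredient"),
  fears                         = c("ingredient", "ingredient"),
  indicated_for_disease         = c("cpm_drug",  "disease"),
  indicated_for_syndrome        = c("cpm_drug",  "syndrome"),
  contraindicated_for_population = c("cpm_drug", "population_group"),
  has_symptom                   = c("disease",   "symptom"),
  contributing_factor           = c("disease",   NA)  # symptom or disease
)

# Fixed priority when several population-specific dosage rules could apply.
POPULATION_PRIORITY <- c("pregnant", "lactating", "child", "elderly",
                         "hepatic_impairment", "renal_impairment",
                         "default_adult")

#' Create an empty knowledge graph
#'
#' The graph is the rule base of the screening engine: typed entity nodes
#' (drugs, ingredients, diseases, symptoms, syndromes, population groups),
#' relation triples with per-relation endpoint-type constraints, and dosage
#' rules. Names and aliases are indexed for entity linking.
#'
#' @return An object of class `cpm_kg`.
#' @export
#' @examples
#' kg <- kg_new()
#' kg <- kg_add_entity(kg, "d1", "liuwei pill", "cpm_drug")
kg_new <- function() {
  structure(list(
    nodes = data.frame(id = character(), name = character(),
                       etype = character(), stringsAsFactors = FALSE),
    aliases = list(),                       # id -> character vector
    triples = data.frame(head = character(), relation = character(),
                         tail = character(), stringsAsFactors = FALSE),
    dosage = data.frame(drug = character(), population = character(),
                        min_daily = numeric(), max_daily = numeric(),
                        unit = character(), stringsAsFactors = FALSE),
    index = character()                     # name/alias -> id
  ), class = "cpm_kg")
}

#' Add an entity node
#'
#' @param kg A `cpm_kg`.
#' @param id Unique opaque id string.
#' @param name Canonical display name (non-empty).
#' @param etype One of the closed entity-type vocabulary
#'   (`cpm_drug`, `ingredient`, `disease`, `symptom`, `syndrome`,
#'   `population_group`).
#' @param aliases Character vector of alternative names; duplicates and the
#'   canonical name itself are rejected.
#' @return The updated graph.
#' @export
kg_add_entity <- function(kg, id, name, etype, aliases = character()) {
  stopifnot(inherits(kg, "cpm_kg"))
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("entity id must be a non-empty string")
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("entity name must be non-empty")
  if (!etype %in% KG_ETYPES)
    stop(sprintf("unknown etype '%s' (must be one of %s)", etype,
                 paste(KG_ETYPES, collapse = ", ")))
  if (id %in% kg$nodes$id)
    stop(sprintf("duplicate entity id '%s'", id))
  aliases <- as.character(aliases)
  if (anyDuplicated(aliases))
    stop(sprintf("duplicate aliases for entity '%s'", id))
  if (name %in% aliases)
    stop(sprintf("alias of entity '%s' equals its canonical name", id))
  for (nm in c(name, aliases)) {
    if (nm %in% names(kg$index) && kg$index[[nm]] != id)
      stop(sprintf("name/alias '%s' already maps to entity '%s', cannot remap to '%s'",
                   nm, kg$index[[nm]], id))
  }
  kg$nodes <- rbind(kg$nodes, data.frame(id = id, name = name, etype = etype,
                                         stringsAsFactors = FALSE))
  kg$aliases[[id]] <- aliases
  add <- rep(id, 1L + length(aliases))
  names(add) <- c(name, aliases)
  kg$index <- c(kg$index, add[!names(add) %in% names(kg$index)])
  kg
}

kg_etype <- function(kg, id) {
  i <- match(id, kg$nodes$id)
  if (is.na(i)) NA_character_ else kg$nodes$etype[i]
}

#' Resolve a name, alias, or id to an entity id
#'
#' @param kg A `cpm_kg`.
#' @param x A single string: entity id, canonical name, or alias.
#' @return The entity id, or `NA_character_` if unresolvable.
#' @export
kg_resolve <- function(kg, x) {
  if (is.null(x) || is.na(x)) return(NA_character_)
  if (x %in% kg$nodes$id) return(x)
  if (x %in% names(kg$index)) return(unname(kg$index[[x]]))
  NA_character_
}

#' Add a relation triple
#'
#' Endpoint types must obey the relation signature (e.g.
#' `contains_ingredient` connects a `cpm_drug` to an `ingredient`).
#' `incompatible_with` is stored once per unordered pair and queried
#' symmetrically; `fears` is stored directed (traditional "A fears B") but
#' conflict queries treat it symmetrically. Duplicate triples are ignored
#' idempotently.
#'
#' @param kg A `cpm_kg`.
#' @param head,tail Entity ids already present in the graph.
#' @param relation One of the relation vocabulary.
#' @return The updated graph.
#' @export
kg_add_triple <- function(kg, head, relation, tail) {
  stopifnot(inherits(kg, "cpm_kg"))
  sig <- KG_RELATIONS[[relation]]
  if (is.null(sig))
    stop(sprintf("unknown relation '%s'", relation))
  ht <- kg_etype(kg, head); tt <- kg_etype(kg, tail)
  if (is.na(ht)) stop(sprintf("unknown head entity '%s'", head))
  if (is.na(tt)) stop(sprintf("unknown tail entity '%s'", tail))
  if (ht != sig[1L])
    stop(sprintf("relation '%s' requires head etype '%s' but '%s' is '%s'",
                 relation, sig[1L], head, ht))
  ok_tail <- if (is.na(sig[2L])) tt %in% c("symptom", "disease") else tt == sig[2L]
  if (!ok_tail)
    stop(sprintf("relation '%s' requires tail etype '%s' but '%s' is '%s'",
                 relation, if (is.na(sig[2L])) "symptom|disease" else sig[2L],
                 tail, tt))
  if (relation %in% c("incompatible_with", "fears") && head == tail)
    stop(sprintf("self-loop forbidden for relation '%s' ('%s')", relation, head))
  tr <- kg$triples
  dup <- tr$relation == relation &
    ((tr$head == head & tr$tail == tail) |
       (relation == "incompatible_with" & tr$head == tail & tr$tail == head))
  if (any(dup)) return(kg)   # idempotent
  kg$triples <- rbind(tr, data.frame(head = head, relation = relation,
                                     tail = tail, stringsAsFactors = FALSE))
  kg
}

#' Add a dosage rule
#'
#' At most one rule per (drug, population) pair; `population` is a
#' population-group id or the sentinel `"default_adult"`.
#'
#' @param kg A `cpm_kg`.
#' @param drug A `cpm_drug` id.
#' @param min_daily,max_daily Positive daily-amount bounds,
#'   `0 < min_daily <= max_daily`.
#' @param unit Unit string the bounds are expressed in.
#' @param population Population-group id or `"default_adult"`.
#' @return The updated graph.
#' @export
kg_add_dosage_rule <- function(kg, drug, min_daily, max_daily, unit = "g",
                               population = "default_adult") {
  stopifnot(inherits(kg, "cpm_kg"))
  if (kg_etype(kg, drug) != "cpm_drug" || is.na(kg_etype(kg, drug)))
    stop(sprintf("dosage rule drug '%s' is not a known cpm_drug", drug))
  if (population != "default_adult" &&
      (is.na(kg_etype(kg, population)) ||
       kg_etype(kg, population) != "population_group"))
    stop(sprintf("dosage rule population '%s' is not a known population_group",
                 population))
  if (!is.numeric(min_daily) || !is.numeric(max_daily) ||
      min_daily <= 0 || min_daily > max_daily)
    stop("dosage rule requires 0 < min_daily <= max_daily")
  if (any(kg$dosage$drug == drug & kg$dosage$population == population))
    stop(sprintf("duplicate dosage rule for drug '%s', population '%s'",
                 drug, population))
  kg$dosage <- rbind(kg$dosage,
                     data.frame(drug = drug, population = population,
                                min_daily = min_daily, max_daily = max_daily,
                                unit = unit, stringsAsFactors = FALSE))
  kg
}

#' Ingredients of a drug
#'
#' @param kg A `cpm_kg`.
#' @param drug A `cpm_drug` id.
#' @return Character vector of ingredient ids.
#' @export
kg_ingredients <- function(kg, drug) {
  check_drug_id(kg, drug)
  tr <- kg$triples
  sort(unique(tr$tail[tr$head == drug & tr$relation == "contains_ingredient"]))
}

check_drug_id <- function(kg, drug) {
  et <- kg_etype(kg, drug)
  if (is.na(et) || et != "cpm_drug")
    stop(sprintf("unknown cpm_drug id '%s'", drug))
  invisible(drug)
}

#' Pairwise ingredient-level conflicts between two drugs
#'
#' Implements the core combined-use taboo: the traditional "eighteen
#' contraindications" (mutually antagonistic pairs, relation
#' `incompatible_with`) and "nineteen fears" (directed `fears` pairs, treated
#' symmetrically for safety). A conflict exists between two finished products
#' whenever any cross-product pair of their ingredients appears in either
#' relation.
#'
#' @param kg A `cpm_kg`.
#' @param drugA,drugB `cpm_drug` ids.
#' @return A data.frame with columns `ingredientA` (from `drugA`),
#'   `ingredientB` (from `drugB`), and `relation`. Symmetric up to swapping
#'   the pair order.
#' @export
ingredient_conflicts <- function(kg, drugA, drugB) {
  ia <- kg_ingredients(kg, drugA)
  ib <- kg_ingredients(kg, drugB)
  out <- data.frame(ingredientA = character(), ingredientB = character(),
                    relation = character(), stringsAsFactors = FALSE)
  if (!length(ia) || !length(ib)) return(out)
  tr <- kg$triples[kg$triples$relation %in% c("incompatible_with", "fears"), ,
                   drop = FALSE]
  if (!nrow(tr)) return(out)
  # both orientations: an endpoint may belong to both ingredient sets
  fwd <- tr$head %in% ia & tr$tail %in% ib
  rev <- tr$tail %in% ia & tr$head %in% ib
  if (!any(fwd) && !any(rev)) return(out)
  out <- rbind(
    data.frame(ingredientA = tr$head[fwd], ingredientB = tr$tail[fwd],
               relation = tr$relation[fwd], stringsAsFactors = FALSE),
    data.frame(ingredientA = tr$tail[rev], ingredientB = tr$head[rev],
               relation = tr$relation[rev], stringsAsFactors = FALSE))
  out <- unique(out)
  out[order(out$ingredientA, out$ingredientB, out$relation), , drop = FALSE]
}

#' Shared active ingredients of two drugs
#'
#' Hidden duplication ("repeated efficacy medication") arises when distinct
#' products contain the same active ingredients.
#'
#' @param kg A `cpm_kg`.
#' @param drugA,drugB `cpm_drug` ids.
#' @return Sorted character vector of shared ingredient ids.
#' @export
shared_ingredients <- function(kg, drugA, drugB) {
  sort(intersect(kg_ingredients(kg, drugA), kg_ingredients(kg, drugB)))
}

#' Indications of a drug
#'
#' @param kg A `cpm_kg`.
#' @param drug A `cpm_drug` id.
#' @return A list with `diseases` and `syndromes`: the
#'   `indicated_for_disease` / `indicated_for_syndrome` out-neighbours.
#' @export
indications <- function(kg, drug) {
  check_drug_id(kg, drug)
  tr <- kg$triples[kg$triples$head == drug, , drop = FALSE]
  list(diseases = sort(unique(tr$tail[tr$relation == "indicated_for_disease"])),
       syndromes = sort(unique(tr$tail[tr$relation == "indicated_for_syndrome"])))
}

#' Candidate diseases explaining a symptom set
#'
#' One disease corresponds to dozens of symptoms, so disease inference from
#' symptoms is scored by overlap: a disease is a candidate when at least
#' `min_overlap` of its `has_symptom` neighbours appear in the query.
#' Unknown symptom ids are skipped with a warning rather than raising, since
#' tagger output may contain unlinkable mentions.
#'
#' @param kg A `cpm_kg`.
#' @param symptom_ids Character vector of symptom ids.
#' @param min_overlap Minimum overlap count (>= 1).
#' @return A data.frame with columns `disease` and `score` (the overlap
#'   count), sorted by score descending then disease id ascending.
#' @export
diseases_for_symptoms <- function(kg, symptom_ids, min_overlap = 2L) {
  stopifnot(min_overlap >= 1L)
  symptom_ids <- unique(as.character(symptom_ids))
  known <- vapply(symptom_ids, function(s) {
    et <- kg_etype(kg, s); !is.na(et) && et == "symptom"
  }, logical(1))
  if (any(!known)) {
    warning(sprintf("ignoring unknown symptom ids: %s",
                    paste(symptom_ids[!known], collapse = ", ")))
    symptom_ids <- symptom_ids[known]
  }
  empty <- data.frame(disease = character(), score = integer(),
                      stringsAsFactors = FALSE)
  if (!length(symptom_ids)) return(empty)
  tr <- kg$triples[kg$triples$relation == "has_symptom" &
                     kg$triples$tail %in% symptom_ids, , drop = FALSE]
  if (!nrow(tr)) return(empty)
  cnt <- table(tr$head)
  out <- data.frame(disease = names(cnt), score = as.integer(cnt),
                    stringsAsFactors = FALSE)
  out <- out[out$score >= min_overlap, , drop = FALSE]
  out <- out[order(-out$score, out$disease), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Look up the dosage rule applicable to a patient
#'
#' Population-specific rules take precedence over the `default_adult`
#' fallback. When several population groups apply, ties are broken by the
#' fixed priority order pregnant > lactating > child > elderly >
#' hepatic_impairment > renal_impairment > default_adult.
#'
#' @param kg A `cpm_kg`.
#' @param drug A `cpm_drug` id.
#' @param population_groups Character vector (possibly empty) of
#'   population-group ids applicable to the patient.
#' @return A one-row data.frame (the rule) or `NULL` when the drug has no
#'   applicable rule.
#' @export
dosage_rule_lookup <- function(kg, drug, population_groups = character()) {
  check_drug_id(kg, drug)
  rules <- kg$dosage[kg$dosage$drug == drug, , drop = FALSE]
  if (!nrow(rules)) return(NULL)
  for (pop in POPULATION_PRIORITY) {
    hit <- if (pop == "default_adult") rules$population == "default_adult"
           else rules$population == pop & pop %in% population_groups
    if (any(hit)) return(rules[which(hit)[1L], , drop = FALSE])
  }
  NULL
}

#' Entity/relation counts of a graph
#'
#' @param kg A `cpm_kg`.
#' @return A list with `n_nodes`, `n_triples`, `n_dosage_rules`, per-etype
#'   and per-relation counts.
#' @export
kg_stats <- function(kg) {
  stopifnot(inherits(kg, "cpm_kg"))
  list(n_nodes = nrow(kg$nodes),
       n_triples = nrow(kg$triples),
       n_dosage_rules = nrow(kg$dosage),
       by_etype = table(factor(kg$nodes$etype, levels = KG_ETYPES)),
       by_relation = table(factor(kg$triples$relation,
                                  levels = names(KG_RELATIONS))))
}

#' @export
print.cpm_kg <- function(x, ...) {
  s <- kg_stats(x)
  cat(sprintf("CPM knowledge graph: %d nodes, %d triples, %d dosage rules\n",
              s$n_nodes, s$n_triples, s$n_dosage_rules))
  et <- s$by_etype[s$by_etype > 0]
  if (length(et))
    cat("  nodes:   ", paste(sprintf("%s=%d", names(et), et), collapse = ", "), "\n")
  rl <- s$by_relation[s$by_relation > 0]
  if (length(rl))
    cat("  triples: ", paste(sprintf("%s=%d", names(rl), rl), collapse = ", "), "\n")
  invisible(x)
}
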