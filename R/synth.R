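# Deterministic synthetic fixtures: knowledge graphs, BIO corpora, and
# medical-record batches with planted, bookkept violations. The generators
# use a whitespace pseudo-language (tokens like "zcyword12"), so every
# downstream test is script-independent; real ideographic text flows
# through the same tokenizer at character granularity.

#' Generate a synthetic knowledge graph
#'
#' Emulates the schema of a CPM rational-use rule base: each drug contains
#' 2-8 ingredients; incompatibility (`incompatible_with`) and directed
#' `fears` edges are planted over ingredient pairs at `conflict_rate`;
#' each disease maps to 3-12 symptoms; each drug gets 1-3 indicated
#' diseases, 0-2 indicated syndromes, a default dosage rule and (for some
#' drugs) a child-specific rule. The manifest records every planted fact,
#' including the induced drug-level conflict and shared-ingredient pairs.
#'
#' @param n_drugs,n_ingredients,n_diseases,n_symptoms,n_syndromes Entity
#'   counts (positive).
#' @param conflict_rate Probability that an unordered ingredient pair is
#'   planted as a taboo combination.
#' @param share_rate Probability that a drug draws an ingredient already
#'   used by another drug (controls ingredient sharing).
#' @param seed Integer seed; identical parameters and seed reproduce the
#'   graph exactly.
#' @return A list with `kg` (a `cpm_kg`) and `manifest`.
#' @export
gen_kg <- function(n_drugs = 20L, n_ingredients = 60L, n_diseases = 15L,
                   n_symptoms = 40L, n_syndromes = 6L,
                   conflict_rate = 0.02, share_rate = 0.15, seed = 1L) {
  stopifnot(n_drugs >= 1L, n_ingredients >= 2L, n_diseases >= 1L,
            n_symptoms >= 1L, n_syndromes >= 1L,
            conflict_rate >= 0, conflict_rate <= 1,
            share_rate >= 0, share_rate <= 1)
  set.seed(seed)
  kg <- kg_new()
  pad <- function(prefix, i) sprintf("%s%02d", prefix, i)
  drug_ids <- vapply(seq_len(n_drugs), function(i) pad("d", i), character(1))
  ing_ids <- vapply(seq_len(n_ingredients), function(i) pad("i", i), character(1))
  dis_ids <- vapply(seq_len(n_diseases), function(i) pad("dz", i), character(1))
  sym_ids <- vapply(seq_len(n_symptoms), function(i) pad("sy", i), character(1))
  syn_ids <- vapply(seq_len(n_syndromes), function(i) pad("sd", i), character(1))
  mk_name <- function(base, i, suffix, p_suffix = 0.3) {
    nm <- sprintf("%s%d", base, i)
    if (stats::runif(1) < p_suffix) paste(nm, suffix) else nm
  }
  for (i in seq_len(n_drugs)) {
    al <- if (stats::runif(1) < 0.3) sprintf("zcyalt%d", i) else character()
    kg <- kg_add_entity(kg, drug_ids[i], mk_name("zcyword", i, "mixture"),
                        "cpm_drug", aliases = al)
  }
  for (i in seq_len(n_ingredients))
    kg <- kg_add_entity(kg, ing_ids[i], sprintf("ingword%d", i), "ingredient")
  for (i in seq_len(n_diseases)) {
    al <- if (stats::runif(1) < 0.3) sprintf("disalt%d", i) else character()
    kg <- kg_add_entity(kg, dis_ids[i], mk_name("disword", i, "disorder"),
                        "disease", aliases = al)
  }
  for (i in seq_len(n_symptoms))
    kg <- kg_add_entity(kg, sym_ids[i], mk_name("symword", i, "sign"), "symptom")
  for (i in seq_len(n_syndromes))
    kg <- kg_add_entity(kg, syn_ids[i], sprintf("synword%d", i), "syndrome")
  for (p in POPULATION_PRIORITY[POPULATION_PRIORITY != "default_adult"])
    kg <- kg_add_entity(kg, p, paste("population", p), "population_group")

  # drug -> ingredients, with controlled reuse across drugs
  used <- character()
  drug_ings <- list()
  for (d in drug_ids) {
    k <- sample(2:min(8L, n_ingredients), 1L)
    mine <- character()
    for (j in seq_len(k)) {
      pool_used <- setdiff(used, mine)
      pool_new <- setdiff(ing_ids, c(used, mine))
      pick <- if (length(pool_used) && (stats::runif(1) < share_rate ||
                                        !length(pool_new)))
        sample(pool_used, 1L)
      else if (length(pool_new)) sample(pool_new, 1L)
      else sample(setdiff(ing_ids, mine), 1L)
      mine <- c(mine, pick)
    }
    used <- union(used, mine)
    drug_ings[[d]] <- mine
    for (ing in mine) kg <- kg_add_triple(kg, d, "contains_ingredient", ing)
  }

  # taboo ingredient pairs
  conflict_pairs <- data.frame(a = character(), b = character(),
                               relation = character(), stringsAsFactors = FALSE)
  if (conflict_rate > 0 && n_ingredients >= 2L) {
    prs <- utils::combn(ing_ids, 2L)
    plant <- stats::runif(ncol(prs)) < conflict_rate
    for (k in which(plant)) {
      rel <- if (stats::runif(1) < 0.5) "incompatible_with" else "fears"
      a <- prs[1L, k]; b <- prs[2L, k]
      if (rel == "fears" && stats::runif(1) < 0.5) { tmp <- a; a <- b; b <- tmp }
      kg <- kg_add_triple(kg, a, rel, b)
      conflict_pairs <- rbind(conflict_pairs,
                              data.frame(a = a, b = b, relation = rel,
                                         stringsAsFactors = FALSE))
    }
  }

  # disease -> symptoms (+ occasional contributing factors)
  for (dz in dis_ids) {
    k <- sample(3:min(12L, n_symptoms), 1L)
    for (s in sample(sym_ids, k))
      kg <- kg_add_triple(kg, dz, "has_symptom", s)
    if (stats::runif(1) < 0.3) {
      tgt <- if (stats::runif(1) < 0.5 && n_diseases > 1L)
        sample(setdiff(dis_ids, dz), 1L) else sample(sym_ids, 1L)
      kg <- kg_add_triple(kg, dz, "contributing_factor", tgt)
    }
  }

  # drug indications, population contraindications, dosage rules
  for (d in drug_ids) {
    for (dz in sample(dis_ids, sample(1:min(3L, n_diseases), 1L)))
      kg <- kg_add_triple(kg, d, "indicated_for_disease", dz)
    n_syn <- sample(0:min(2L, n_syndromes), 1L)
    if (n_syn > 0L)
      for (s in sample(syn_ids, n_syn))
        kg <- kg_add_triple(kg, d, "indicated_for_syndrome", s)
    if (stats::runif(1) < 0.2)
      kg <- kg_add_triple(kg, d, "contraindicated_for_population",
                          sample(c("pregnant", "lactating", "child"), 1L))
    mn <- sample(2:6, 1L)
    mx <- mn + sample(2:8, 1L)
    kg <- kg_add_dosage_rule(kg, d, mn, mx, unit = "g")
    if (stats::runif(1) < 0.4)
      kg <- kg_add_dosage_rule(kg, d, mn / 2, mx / 2, unit = "g",
                               population = "child")
  }

  # induced drug-level facts, recorded for bookkeeping
  drug_conflicts <- data.frame(drugA = character(), drugB = character(),
                               stringsAsFactors = FALSE)
  drug_shared <- data.frame(drugA = character(), drugB = character(),
                            shared = character(), stringsAsFactors = FALSE)
  if (n_drugs >= 2L) {
    prs <- utils::combn(sort(drug_ids), 2L)
    for (k in seq_len(ncol(prs))) {
      a <- prs[1L, k]; b <- prs[2L, k]
      if (nrow(ingredient_conflicts(kg, a, b)))
        drug_conflicts <- rbind(drug_conflicts,
                                data.frame(drugA = a, drugB = b,
                                           stringsAsFactors = FALSE))
      sh <- shared_ingredients(kg, a, b)
      if (length(sh))
        drug_shared <- rbind(drug_shared,
                             data.frame(drugA = a, drugB = b,
                                        shared = paste(sh, collapse = "|"),
                                        stringsAsFactors = FALSE))
    }
  }
  manifest <- list(
    seed = seed,
    params = list(n_drugs = n_drugs, n_ingredients = n_ingredients,
                  n_diseases = n_diseases, n_symptoms = n_symptoms,
                  n_syndromes = n_syndromes, conflict_rate = conflict_rate,
                  share_rate = share_rate),
    counts = list(n_nodes = nrow(kg$nodes), n_triples = nrow(kg$triples),
                  n_dosage_rules = nrow(kg$dosage)),
    drug_ids = drug_ids, ingredient_ids = ing_ids, disease_ids = dis_ids,
    symptom_ids = sym_ids, syndrome_ids = syn_ids,
    drug_ingredients = drug_ings,
    conflict_ingredient_pairs = conflict_pairs,
    drug_conflict_pairs = drug_conflicts,
    drug_shared_pairs = drug_shared)
  list(kg = kg, manifest = manifest)
}

#' Build a segmentation lexicon from a knowledge graph
#'
#' Drug, disease, and symptom names (and aliases) become lexicon entries
#' of the matching category; filler words are added as `general` entries.
#'
#' @param kg A `cpm_kg`.
#' @param fillers Character vector of general-vocabulary words.
#' @return A `cpm_lexicon`.
#' @export
lexicon_from_kg <- function(kg, fillers = sprintf("filler%d", 1:30)) {
  et2cat <- c(cpm_drug = "ZCY", disease = "DIS", symptom = "SYM")
  keep <- kg$nodes$etype %in% names(et2cat)
  words <- kg$nodes$name[keep]
  cats <- unname(et2cat[kg$nodes$etype[keep]])
  for (i in which(keep)) {
    al <- kg$aliases[[kg$nodes$id[i]]]
    if (length(al)) {
      words <- c(words, al)
      cats <- c(cats, rep(et2cat[[kg$nodes$etype[i]]], length(al)))
    }
  }
  build_lexicon(c(words, fillers),
                c(rep(10, length(words)), rep(50, length(fillers))),
                c(cats, rep("general", length(fillers))))
}

#' Generate a BIO-annotated corpus from a knowledge graph
#'
#' Template sentences in the whitespace pseudo-language embed drug,
#' disease, and symptom names from the graph between filler tokens; gold
#' BIO tags are emitted alongside. At `ambiguity_rate`, an embedded
#' entity's first token is replaced by an ambiguous token drawn from a
#' small shared pool that also occurs as filler, so the tagging problem is
#' no longer separable by token identity alone.
#'
#' @param kg A `cpm_kg`.
#' @param n_sequences Number of sentences.
#' @param ambiguity_rate Probability of the ambiguous-token substitution.
#' @param seed Integer seed.
#' @return A list with `corpus` (list of `tokens`/`tags` sequences),
#'   `mentions` (gold mention tables), and `fillers`.
#' @export
gen_bio_corpus <- function(kg, n_sequences, ambiguity_rate = 0, seed = 1L) {
  stopifnot(inherits(kg, "cpm_kg"), n_sequences >= 0L,
            ambiguity_rate >= 0, ambiguity_rate <= 1)
  set.seed(seed)
  fillers <- sprintf("filler%d", 1:30)
  amb <- sprintf("ambig%d", 1:5)
  filler_pool <- if (ambiguity_rate > 0) c(fillers, amb) else fillers
  pools <- list(
    ZCY = kg$nodes$name[kg$nodes$etype == "cpm_drug"],
    DIS = kg$nodes$name[kg$nodes$etype == "disease"],
    SYM = kg$nodes$name[kg$nodes$etype == "symptom"])
  pools <- pools[vapply(pools, length, integer(1)) > 0L]
  if (!length(pools)) stop("graph has no drug/disease/symptom entities")
  corpus <- vector("list", n_sequences)
  gold <- vector("list", n_sequences)
  for (q in seq_len(n_sequences)) {
    tokens <- character(); tags <- character()
    starts <- integer(); ends <- integer(); labs <- character()
    n_ent <- sample(1:3, 1L)
    for (e in seq_len(n_ent)) {
      nfill <- sample(1:3, 1L)
      fl <- sample(filler_pool, nfill, replace = TRUE)
      tokens <- c(tokens, fl); tags <- c(tags, rep("O", nfill))
      lab <- sample(names(pools), 1L)
      surface <- sample(pools[[lab]], 1L)
      etoks <- strsplit(surface, " ", fixed = TRUE)[[1]]
      if (stats::runif(1) < ambiguity_rate)
        etoks[1L] <- sample(amb, 1L)
      starts <- c(starts, length(tokens))
      ends <- c(ends, length(tokens) + length(etoks))
      labs <- c(labs, lab)
      tokens <- c(tokens, etoks)
      tags <- c(tags, c(paste0("B-", lab),
                        rep(paste0("I-", lab), length(etoks) - 1L)))
    }
    nfill <- sample(1:2, 1L)
    fl <- sample(filler_pool, nfill, replace = TRUE)
    tokens <- c(tokens, fl); tags <- c(tags, rep("O", nfill))
    corpus[[q]] <- list(tokens = tokens, tags = tags)
    gold[[q]] <- mentions(starts, ends, labs,
                          surface = vapply(seq_along(starts), function(k)
                            paste(tokens[(starts[k] + 1L):ends[k]],
                                  collapse = " "), character(1)))
  }
  list(corpus = corpus, mentions = gold, fillers = fillers)
}

# -- record generation with planted violations -------------------------------

VIOLATION_CATEGORIES <- ALERT_CATEGORIES

#' Generate synthetic medical records with planted violations
#'
#' Each record samples up to five drugs whose non-planted part is clean by
#' construction: pairwise non-conflicting and non-sharing drugs, one
#' recorded diagnosis per drug drawn from its indications, doses inside
#' the population-applicable rule, and a syndrome common to the drugs'
#' syndrome indications (or absent). Per category, with the stated
#' probability, exactly one violation is planted — a conflicting drug
#' pair, a duplicate or ingredient-sharing drug, an off-indication drug,
#' a dose pushed outside its rule, or a mismatched syndrome — and logged
#' as a gold alert. Both the structured fields and free-text renderings of
#' each record are emitted.
#'
#' @param kg A `cpm_kg` (typically from [gen_kg()]).
#' @param n_records Number of records.
#' @param violation_rates Named list/vector, category -> probability in
#'   `[0, 1]`; missing categories default to 0.
#' @param seed Integer seed.
#' @return A list with `records` (list of `cpm_record`) and `gold`
#'   (data.frame: record_id, category, drugs — sorted ids joined by
#'   "|" — and severity).
#' @export
gen_records <- function(kg, n_records, violation_rates = list(), seed = 1L) {
  stopifnot(inherits(kg, "cpm_kg"), n_records >= 0L)
  rates <- stats::setNames(rep(0, length(VIOLATION_CATEGORIES)),
                           VIOLATION_CATEGORIES)
  for (nm in names(violation_rates)) {
    if (!nm %in% VIOLATION_CATEGORIES)
      stop(sprintf("unknown violation category '%s'", nm))
    r <- violation_rates[[nm]]
    stopifnot(r >= 0, r <= 1)
    rates[nm] <- r
  }
  set.seed(seed)
  drugs <- kg$nodes$id[kg$nodes$etype == "cpm_drug"]
  nd <- length(drugs)
  if (!nd) stop("graph has no drugs")
  # pair predicates, precomputed once
  conf <- matrix(FALSE, nd, nd, dimnames = list(drugs, drugs))
  shar <- matrix(FALSE, nd, nd, dimnames = list(drugs, drugs))
  if (nd >= 2L) {
    prs <- utils::combn(drugs, 2L)
    for (k in seq_len(ncol(prs))) {
      a <- prs[1L, k]; b <- prs[2L, k]
      if (nrow(ingredient_conflicts(kg, a, b)))
        conf[a, b] <- conf[b, a] <- TRUE
      if (length(shared_ingredients(kg, a, b)))
        shar[a, b] <- shar[b, a] <- TRUE
    }
  }
  clean_pair <- function(a, b) !conf[a, b] && !shar[a, b]
  compatible_with <- function(d, set) all(vapply(set, function(x)
    clean_pair(d, x), logical(1)))
  ind_dis <- lapply(stats::setNames(drugs, drugs),
                    function(d) indications(kg, d)$diseases)
  ind_syn <- lapply(stats::setNames(drugs, drugs),
                    function(d) indications(kg, d)$syndromes)
  syndromes <- kg$nodes$id[kg$nodes$etype == "syndrome"]

  conflict_cand <- which(conf & !shar, arr.ind = TRUE)
  conflict_cand <- conflict_cand[conflict_cand[, 1] < conflict_cand[, 2], ,
                                 drop = FALSE]
  share_cand <- which(shar & !conf, arr.ind = TRUE)
  share_cand <- share_cand[share_cand[, 1] < share_cand[, 2], , drop = FALSE]
  if (rates["combined_use"] > 0 && !nrow(conflict_cand))
    stop("requested combined_use violations but the graph has no clean conflicting drug pair: combined_use")
  if (rates["repeated_efficacy"] > 0 && !nrow(share_cand) && nd < 1L)
    stop("requested repeated_efficacy violations but none plantable: repeated_efficacy")
  if (rates["syndrome"] > 0 && !length(syndromes))
    stop("requested syndrome violations but the graph has no syndromes: syndrome")

  records <- vector("list", n_records)
  gold <- data.frame(record_id = character(), category = character(),
                     drugs = character(), severity = character(),
                     stringsAsFactors = FALSE)
  add_gold <- function(rid, category, ds, severity)
    gold[nrow(gold) + 1L, ] <<- list(rid, category,
                                     paste(sort(ds), collapse = "|"), severity)

  for (r in seq_len(n_records)) {
    rid <- sprintf("rec%05d", r)
    planted <- stats::runif(length(rates)) < rates
    names(planted) <- names(rates)
    built <- NULL
    for (attempt in 1:200) {
      set_ids <- character()
      ok <- TRUE
      if (planted["combined_use"]) {
        k <- sample.int(nrow(conflict_cand), 1L)
        pairAB <- c(drugs[conflict_cand[k, 1]], drugs[conflict_cand[k, 2]])
        set_ids <- pairAB
      } else pairAB <- NULL
      dup_drug <- NULL; share_pair <- NULL
      if (planted["repeated_efficacy"]) {
        mode <- if (nrow(share_cand)) sample(c("dup", "share"), 1L) else "dup"
        if (mode == "share") {
          found <- FALSE
          for (kk in sample.int(nrow(share_cand))) {
            cd <- c(drugs[share_cand[kk, 1]], drugs[share_cand[kk, 2]])
            if (!any(cd %in% set_ids) &&
                compatible_with(cd[1], set_ids) &&
                compatible_with(cd[2], set_ids)) {
              share_pair <- cd
              set_ids <- c(set_ids, cd)
              found <- TRUE
              break
            }
          }
          if (!found) mode <- "dup"   # fall back to duplication
        }
        if (mode == "dup") dup_drug <- NA  # resolved once the set is final
      }
      off_drug <- NULL
      # fill with clean drugs up to at most 5 distinct
      room <- 5L - length(set_ids) - as.integer(planted["symptomatic"])
      n_extra <- if (length(set_ids)) sample(0:max(room, 0L), 1L)
                 else sample(1:max(room, 1L), 1L)
      pool <- sample(setdiff(drugs, set_ids))
      for (d in pool) {
        if (n_extra <= 0L) break
        if (compatible_with(d, set_ids)) {
          set_ids <- c(set_ids, d)
          n_extra <- n_extra - 1L
        }
      }
      if (!length(set_ids) && !planted["symptomatic"]) { ok <- FALSE }
      # off-indication drug for the symptomatic violation
      if (ok && planted["symptomatic"]) {
        found <- FALSE
        for (x in sample(setdiff(drugs, set_ids))) {
          if (!length(ind_dis[[x]])) next
          if (!compatible_with(x, set_ids)) next
          # every other drug must have an indication outside x's set
          others_ok <- all(vapply(set_ids, function(d)
            length(setdiff(ind_dis[[d]], ind_dis[[x]])) > 0L ||
              !length(ind_dis[[d]]), logical(1)))
          # and at least one other drug must contribute a diagnosis
          any_diag <- any(vapply(set_ids, function(d)
            length(setdiff(ind_dis[[d]], ind_dis[[x]])) > 0L, logical(1)))
          if (others_ok && any_diag) {
            off_drug <- x
            set_ids <- c(set_ids, x)
            found <- TRUE
            break
          }
        }
        if (!found) ok <- FALSE
      }
      # syndrome assignment
      syn_rec <- NULL
      if (ok) {
        with_syn <- set_ids[vapply(set_ids, function(d)
          length(ind_syn[[d]]) > 0L, logical(1))]
        if (planted["syndrome"]) {
          cand_syn <- setdiff(syndromes,
                              unique(unlist(ind_syn[set_ids])))
          if (!length(with_syn) || !length(cand_syn)) ok <- FALSE
          else syn_rec <- sample(cand_syn, 1L)
        } else if (length(with_syn)) {
          common <- Reduce(intersect, ind_syn[with_syn])
          if (length(common)) syn_rec <- sample(common, 1L)
        }
      }
      if (ok) {
        built <- list(set_ids = set_ids, pairAB = pairAB,
                      dup_mode = !is.null(dup_drug), share_pair = share_pair,
                      off_drug = off_drug, syn_rec = syn_rec)
        break
      }
    }
    if (is.null(built)) {
      failed <- names(planted)[planted]
      stop(sprintf("could not plant requested violation(s) on this graph: %s",
                   paste(failed, collapse = ", ")))
    }
    set_ids <- built$set_ids
    if (built$dup_mode) dup_drug <- sample(set_ids, 1L) else dup_drug <- NULL

    # patient
    age <- sample(c(sample(20:60, 1L), 6L, 70L), 1L, prob = c(0.7, 0.15, 0.15))
    patient <- patient_profile(age)
    groups <- population_groups(patient)

    # diagnoses: one indicated disease per drug (avoiding the off drug's set)
    avoid <- if (!is.null(built$off_drug)) ind_dis[[built$off_drug]] else character()
    diagnoses <- character()
    for (d in setdiff(set_ids, built$off_drug)) {
      choices <- setdiff(ind_dis[[d]], avoid)
      if (length(choices)) diagnoses <- union(diagnoses, sample(choices, 1L))
    }
    # symptoms of a diagnosed disease, for text realism
    symptoms <- character()
    if (length(diagnoses)) {
      dz <- diagnoses[1L]
      ss <- kg$triples$tail[kg$triples$head == dz &
                              kg$triples$relation == "has_symptom"]
      if (length(ss)) symptoms <- sample(ss, min(length(ss), sample(1:3, 1L)))
    }

    # items with in-range doses
    item_drugs <- c(set_ids, dup_drug)
    items <- lapply(item_drugs, function(d) {
      rule <- dosage_rule_lookup(kg, d, groups)
      tpd <- sample(1:3, 1L)
      if (is.null(rule)) return(prescription_item(d, 1, tpd))
      target <- stats::runif(1, rule$min_daily, rule$max_daily)
      prescription_item(d, target / tpd, tpd, unit = rule$unit)
    })
    if (planted["dosage"]) {
      j <- sample.int(length(items), 1L)
      d <- item_drugs[j]
      rule <- dosage_rule_lookup(kg, d, groups)
      if (is.null(rule))
        stop("requested dosage violations but a drug lacks a rule: dosage")
      over <- stats::runif(1) < 0.5
      tpd <- items[[j]]$times_per_day
      target <- if (over) rule$max_daily * 2 else rule$min_daily / 2
      items[[j]] <- prescription_item(d, target / tpd, tpd, unit = rule$unit)
      add_gold(rid, "dosage", d, "critical")
    }
    if (planted["combined_use"])
      add_gold(rid, "combined_use", built$pairAB, "critical")
    if (!is.null(built$share_pair))
      add_gold(rid, "repeated_efficacy", built$share_pair, "warning")
    if (!is.null(dup_drug))
      add_gold(rid, "repeated_efficacy", dup_drug, "critical")
    if (!is.null(built$off_drug))
      add_gold(rid, "symptomatic", built$off_drug, "warning")
    if (planted["syndrome"]) {
      for (d in set_ids[vapply(set_ids, function(x)
        length(ind_syn[[x]]) > 0L, logical(1))])
        add_gold(rid, "syndrome", d, "warning")
    }

    name_of <- function(id) kg$nodes$name[match(id, kg$nodes$id)]
    course <- paste(c("filler1 patient reports",
                      vapply(symptoms, name_of, character(1)),
                      "filler2 diagnosed with",
                      vapply(diagnoses, name_of, character(1))),
                    collapse = " ")
    discharge <- paste(c("filler3 prescribed",
                         vapply(item_drugs, name_of, character(1)),
                         "filler4 on discharge"), collapse = " ")
    records[[r]] <- medical_record(
      rid, items = items, diagnoses = diagnoses, syndrome = built$syn_rec,
      symptoms = symptoms, patient = patient,
      course_record_text = course, discharge_summary_text = discharge)
  }
  list(records = records, gold = gold, seed = seed, rates = as.list(rates))
}

#' Extract the engine's flagged alerts in gold-comparable form
#'
#' Reduces a list of review reports to (record_id, category, drugs,
#' severity) rows for every alert of severity warning or critical — the
#' same shape as the `gold` table of [gen_records()].
#'
#' @param reports List of `cpm_report`.
#' @return A data.frame.
#' @export
flagged_alerts <- function(reports) {
  out <- data.frame(record_id = character(), category = character(),
                    drugs = character(), severity = character(),
                    stringsAsFactors = FALSE)
  for (rep in reports) {
    for (a in rep$alerts) {
      if (a$severity == "info") next
      out[nrow(out) + 1L, ] <- list(rep$record_id, a$category,
                                    paste(sort(a$drugs), collapse = "|"),
                                    a$severity)
    }
  }
  out
}
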