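test_that("entity insertion enforces id/name/alias uniqueness and lookup", {
  kg <- kg_new()
  kg <- kg_add_entity(kg, "d1", "liuwei pill", "cpm_drug", aliases = "six flavour")
  expect_equal(nrow(kg$nodes), 1L)
  expect_equal(kg_resolve(kg, "d1"), "d1")
  expect_equal(kg_resolve(kg, "liuwei pill"), "d1")
  expect_equal(kg_resolve(kg, "six flavour"), "d1")
  expect_true(is.na(kg_resolve(kg, "nonesuch")))
  expect_error(kg_add_entity(kg, "d1", "other", "cpm_drug"), "duplicate entity id")
  expect_error(kg_add_entity(kg, "d2", "liuwei pill", "cpm_drug"),
               "already maps to entity 'd1'.*'d2'")
  expect_error(kg_add_entity(kg, "d3", "x", "not_a_type"), "unknown etype")
  expect_error(kg_add_entity(kg, "d4", "y", "cpm_drug", aliases = c("a", "a")),
               "duplicate aliases")
  expect_error(kg_add_entity(kg, "d5", "z", "cpm_drug", aliases = "z"),
               "canonical name")
})

test_that("bulk alias lookup finds every inserted node", {
  set.seed(42)
  kg <- kg_new()
  n <- 100L
  for (i in seq_len(n))
    kg <- kg_add_entity(kg, sprintf("id%03d", i), sprintf("name%03d", i),
                        sample(c("cpm_drug", "ingredient", "disease"), 1L),
                        aliases = sprintf("alias%03d", i))
  for (i in sample(n)) {
    expect_equal(kg_resolve(kg, sprintf("alias%03d", i)), sprintf("id%03d", i))
    expect_equal(kg_resolve(kg, sprintf("name%03d", i)), sprintf("id%03d", i))
  }
})

test_that("triple insertion validates endpoints, signatures, self-loops", {
  kg <- toy_kg()
  expect_error(kg_add_triple(kg, "da", "contains_ingredient", "missing"),
               "unknown tail entity")
  expect_error(kg_add_triple(kg, "dz1", "has_symptom", "da"),
               "requires tail etype 'symptom'.*'cpm_drug'")
  expect_error(kg_add_triple(kg, "da", "has_symptom", "s1"),
               "requires head etype 'disease'")
  expect_error(kg_add_triple(kg, "ix", "incompatible_with", "ix"), "self-loop")
  expect_error(kg_add_triple(kg, "ix", "fears", "ix"), "self-loop")
  expect_error(kg_add_triple(kg, "da", "no_such_relation", "ix"),
               "unknown relation")
  # contributing_factor accepts symptom or disease tails, nothing else
  kg2 <- kg_add_triple(kg, "dz1", "contributing_factor", "s4")
  kg2 <- kg_add_triple(kg2, "dz1", "contributing_factor", "dz2")
  expect_error(kg_add_triple(kg2, "dz1", "contributing_factor", "da"),
               "symptom\\|disease")
  # duplicates are idempotent, including the reversed unordered pair
  n0 <- nrow(kg$triples)
  kg3 <- kg_add_triple(kg, "ix", "incompatible_with", "iy")
  kg3 <- kg_add_triple(kg3, "iy", "incompatible_with", "ix")
  expect_equal(nrow(kg3$triples), n0)
})

test_that("dosage rules validate bounds and (drug, population) uniqueness", {
  kg <- toy_kg()
  expect_error(kg_add_dosage_rule(kg, "da", 5, 2), "min_daily <= max_daily")
  expect_error(kg_add_dosage_rule(kg, "da", 0, 2), "min_daily")
  expect_error(kg_add_dosage_rule(kg, "da", 1, 2), "duplicate dosage rule")
  expect_error(kg_add_dosage_rule(kg, "nope", 1, 2), "not a known cpm_drug")
  expect_error(kg_add_dosage_rule(kg, "da", 1, 2, population = "s1"),
               "not a known population_group")
})

test_that("ingredient_conflicts finds planted taboos and is symmetric", {
  kg <- toy_kg()
  # disjoint, conflict-free pair
  expect_equal(nrow(ingredient_conflicts(kg, "db", "dc")), 0L)
  # planted incompatibility
  c_ab <- ingredient_conflicts(kg, "da", "db")
  expect_equal(c_ab$ingredientA, "ix")
  expect_equal(c_ab$ingredientB, "iy")
  expect_equal(c_ab$relation, "incompatible_with")
  # fears is directed in storage but symmetric in queries
  c_ad <- ingredient_conflicts(kg, "da", "dd")
  expect_equal(c_ad$relation, "fears")
  expect_equal(c_ad$ingredientA, "iw")
  c_da <- ingredient_conflicts(kg, "dd", "da")
  expect_equal(c_da$ingredientA, "iz")
  expect_equal(c_da$ingredientB, "iw")
  expect_error(ingredient_conflicts(kg, "da", "nope"), "unknown cpm_drug")
})

test_that("shared_ingredients is exact intersection, symmetric, idempotent", {
  kg <- toy_kg()
  expect_equal(shared_ingredients(kg, "da", "dc"), "iw")
  expect_equal(shared_ingredients(kg, "dc", "da"), "iw")
  expect_equal(shared_ingredients(kg, "db", "dc"), character())
  expect_equal(shared_ingredients(kg, "da", "da"), sort(c("ix", "iw")))
})

test_that("indications returns exactly the out-neighbours", {
  kg <- toy_kg()
  expect_equal(indications(kg, "da"),
               list(diseases = "dz1", syndromes = "sn1"))
  expect_equal(indications(kg, "dc"),
               list(diseases = character(), syndromes = character()))
})

test_that("diseases_for_symptoms scores, filters, sorts, skips unknowns", {
  kg <- toy_kg()
  expect_equal(nrow(diseases_for_symptoms(kg, character(), 1)), 0L)
  r <- diseases_for_symptoms(kg, c("s1", "s2"), 2)
  expect_equal(r$disease, "dz1")
  expect_equal(r$score, 2L)
  # s3 belongs to both; tie on score 1 broken by disease id
  r2 <- diseases_for_symptoms(kg, "s3", 1)
  expect_equal(r2$disease, c("dz1", "dz2"))
  expect_warning(r3 <- diseases_for_symptoms(kg, c("s1", "s2", "ghost"), 2),
                 "ghost")
  expect_equal(r3$disease, "dz1")
})

test_that("dosage_rule_lookup honours population priority and fallback", {
  kg <- toy_kg()
  # child-specific rule wins for a child
  r <- dosage_rule_lookup(kg, "da", "child")
  expect_equal(r$population, "child")
  expect_equal(r$min_daily, 1.5)
  # fallback to default when no population-specific rule exists
  r2 <- dosage_rule_lookup(kg, "db", "child")
  expect_equal(r2$population, "default_adult")
  # adult gets the default rule even when a child rule exists
  expect_equal(dosage_rule_lookup(kg, "da", character())$population,
               "default_adult")
  expect_null(dosage_rule_lookup(kg, "dc", character()))
})

test_that("graph queries match brute-force oracles on random graphs", {
  for (seed in 1:4) {
    g <- gen_kg(n_drugs = 10L, n_ingredients = 30L, n_diseases = 8L,
                n_symptoms = 20L, conflict_rate = 0.05, share_rate = 0.3,
                seed = seed)
    kg <- g$kg
    drugs <- g$manifest$drug_ids
    prs <- utils::combn(drugs, 2L)
    for (k in seq_len(ncol(prs))) {
      a <- prs[1L, k]; b <- prs[2L, k]
      expect_same_rows(ingredient_conflicts(kg, a, b),
                       oracle_conflicts(kg, a, b))
      expect_equal(shared_ingredients(kg, a, b), oracle_shared(kg, a, b))
      # symmetry as unordered pair sets
      fwd <- ingredient_conflicts(kg, a, b)
      rev <- ingredient_conflicts(kg, b, a)
      key <- function(d, x, y) sort(paste(pmin(d[[x]], d[[y]]),
                                          pmax(d[[x]], d[[y]]), d$relation))
      expect_equal(key(fwd, "ingredientA", "ingredientB"),
                   key(rev, "ingredientA", "ingredientB"))
    }
    for (d in drugs)
      expect_equal(indications(kg, d)$diseases,
                   sort(unique(kg$triples$tail[kg$triples$head == d &
                     kg$triples$relation == "indicated_for_disease"])))
    set.seed(seed)
    for (rep in 1:5) {
      q <- sample(g$manifest$symptom_ids, 5L)
      expect_same_rows(diseases_for_symptoms(kg, q, 2),
                       oracle_diseases_for_symptoms(kg, q, 2))
    }
  }
})
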