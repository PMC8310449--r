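test_that("graph generation is deterministic and respects rate extremes", {
  g1 <- gen_kg(n_drugs = 8L, n_ingredients = 20L, seed = 5)
  g2 <- gen_kg(n_drugs = 8L, n_ingredients = 20L, seed = 5)
  expect_true(kg_equal(g1$kg, g2$kg))
  expect_identical(g1$manifest, g2$manifest)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  kg_save(g1$kg, p1); kg_save(g2$kg, p2)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical files
  # conflict_rate 0: no taboo edges, no drug-level conflicts
  g0 <- gen_kg(n_drugs = 8L, n_ingredients = 20L, conflict_rate = 0, seed = 6)
  expect_equal(nrow(g0$manifest$drug_conflict_pairs), 0L)
  prs <- utils::combn(g0$manifest$drug_ids, 2L)
  for (k in seq_len(ncol(prs)))
    expect_equal(nrow(ingredient_conflicts(g0$kg, prs[1, k], prs[2, k])), 0L)
  # conflict_rate 1 on 2 ingredients: every drug pair spanning both conflicts
  gf <- gen_kg(n_drugs = 4L, n_ingredients = 2L, conflict_rate = 1, seed = 7)
  for (k in seq_len(ncol(utils::combn(gf$manifest$drug_ids, 2L)))) {
    pr <- utils::combn(gf$manifest$drug_ids, 2L)[, k]
    ia <- kg_ingredients(gf$kg, pr[1]); ib <- kg_ingredients(gf$kg, pr[2])
    if (length(union(ia, ib)) == 2L)
      expect_gt(nrow(ingredient_conflicts(gf$kg, pr[1], pr[2])), 0L)
  }
  # structural contract: every drug has 2-8 ingredients and >= 1 indication
  g <- gen_kg(seed = 8)
  for (d in g$manifest$drug_ids) {
    expect_gte(length(kg_ingredients(g$kg, d)), 2L)
    expect_lte(length(kg_ingredients(g$kg, d)), 8L)
    expect_gte(length(indications(g$kg, d)$diseases), 1L)
  }
  expect_error(gen_kg(n_ingredients = 1L), "n_ingredients")
})

test_that("generated corpora have aligned tags and honour ambiguity settings", {
  g <- gen_kg(n_drugs = 10L, n_ingredients = 25L, seed = 9)
  expect_length(gen_bio_corpus(g$kg, 0, seed = 1)$corpus, 0L)
  cb <- gen_bio_corpus(g$kg, 40, ambiguity_rate = 0, seed = 2)
  expect_length(cb$corpus, 40L)
  for (i in seq_along(cb$corpus)) {
    s <- cb$corpus[[i]]
    expect_equal(length(s$tokens), length(s$tags))
    # gold mentions re-encode to exactly the stored tags
    expect_equal(bio_encode(length(s$tokens), cb$mentions[[i]]), s$tags)
  }
  # ambiguity 0: entity tokens and O tokens are disjoint vocabularies
  ent_toks <- unlist(lapply(cb$corpus, function(s) s$tokens[s$tags != "O"]))
  o_toks <- unlist(lapply(cb$corpus, function(s) s$tokens[s$tags == "O"]))
  expect_length(intersect(ent_toks, o_toks), 0L)
  # written files: token/tag line counts agree per independent scan
  p <- withr::local_tempfile()
  write_bio_corpus(cb$corpus, p)
  lines <- readLines(p)
  expect_equal(sum(nzchar(lines)),
               sum(vapply(cb$corpus, function(s) length(s$tokens), integer(1))))
  # ambiguity > 0 plants tokens that occur both inside and outside entities
  ca <- gen_bio_corpus(g$kg, 60, ambiguity_rate = 0.5, seed = 3)
  ent2 <- unlist(lapply(ca$corpus, function(s) s$tokens[s$tags != "O"]))
  o2 <- unlist(lapply(ca$corpus, function(s) s$tokens[s$tags == "O"]))
  expect_gt(length(intersect(ent2, o2)), 0L)
  # determinism
  cb2 <- gen_bio_corpus(g$kg, 40, ambiguity_rate = 0, seed = 2)
  expect_identical(cb, cb2)
})

test_that("record generation is deterministic and rate extremes hold", {
  g <- gen_kg(n_drugs = 15L, n_ingredients = 35L, conflict_rate = 0.05,
              share_rate = 0.3, seed = 10)
  r1 <- gen_records(g$kg, 20, violation_rates = list(dosage = 0.5), seed = 4)
  r2 <- gen_records(g$kg, 20, violation_rates = list(dosage = 0.5), seed = 4)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_records(r1$records, p1); write_records(r2$records, p2)
  expect_identical(readLines(p1), readLines(p2))
  # all rates 0: no gold alerts, and the engine flags nothing beyond info
  r0 <- gen_records(g$kg, 30, seed = 5)
  expect_equal(nrow(r0$gold), 0L)
  for (rec in r0$records) {
    rep <- review_record(rec, g$kg)
    expect_equal(nrow(report_flagged_key(rep)), 0L)
  }
  # rate 1 for dosage: every record carries a gold dosage alert
  rd <- gen_records(g$kg, 25, violation_rates = list(dosage = 1), seed = 6)
  expect_equal(sort(unique(rd$gold$category)), "dosage")
  expect_setequal(unique(rd$gold$record_id),
                  vapply(rd$records, function(r) r$record_id, character(1)))
})

test_that("empirical planting rates match the request binomially", {
  g <- gen_kg(n_drugs = 15L, n_ingredients = 35L, conflict_rate = 0.05,
              share_rate = 0.3, seed = 10)
  rates <- list(combined_use = 0.3, repeated_efficacy = 0.2, dosage = 0.4)
  n <- 1000L
  rr <- gen_records(g$kg, n, violation_rates = rates, seed = 11)
  for (cat_ in names(rates)) {
    hit <- length(unique(rr$gold$record_id[rr$gold$category == cat_]))
    p <- rates[[cat_]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(hit / n - p), 3 * se)
  }
})

test_that("an impossible requested violation fails naming the category", {
  g0 <- gen_kg(n_drugs = 6L, n_ingredients = 15L, conflict_rate = 0, seed = 12)
  expect_error(gen_records(g0$kg, 5, violation_rates = list(combined_use = 1),
                           seed = 1),
               "combined_use")
  expect_error(gen_records(g0$kg, 5, violation_rates = list(nonsense = 1)),
               "unknown violation category")
})

test_that("every gold alert is recovered by the rule engine (master check)", {
  rates <- list(combined_use = 0.25, repeated_efficacy = 0.25,
                symptomatic = 0.25, dosage = 0.25, syndrome = 0.25)
  for (seed in 1:3) {
    g <- gen_kg(n_drugs = 15L, n_ingredients = 35L, conflict_rate = 0.05,
                share_rate = 0.3, seed = seed)
    rr <- gen_records(g$kg, 60, violation_rates = rates, seed = seed + 50)
    reports <- lapply(rr$records, review_record, kg = g$kg)
    pr <- alert_precision_recall(rr$gold, flagged_alerts(reports))
    expect_equal(unname(pr["precision"]), 100)
    expect_equal(unname(pr["recall"]), 100)
  }
})
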