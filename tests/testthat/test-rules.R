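test_that("combined-use check flags planted taboo pairs only", {
  kg <- toy_kg()
  expect_length(check_combined_use(list(item("da")), kg), 0L)
  a <- check_combined_use(list(item("da"), item("db")), kg)
  expect_length(a, 1L)
  expect_equal(a[[1]]$severity, "critical")
  expect_equal(a[[1]]$drugs, c("da", "db"))
  expect_equal(a[[1]]$evidence[[1]],
               list(head = "ix", relation = "incompatible_with", tail = "iy"))
  # n drugs screen all pairs: da-db, da-dd, dc-dd all conflict
  a4 <- check_combined_use(list(item("da"), item("db"), item("dc"),
                                item("dd")), kg)
  keys <- sort(vapply(a4, function(x) paste(x$drugs, collapse = "|"),
                      character(1)))
  expect_equal(keys, c("da|db", "da|dd", "dc|dd"))
  # unlinkable item degrades to an info alert, never an error
  u <- check_combined_use(list(item("mystery tonic")), kg)
  expect_equal(u[[1]]$severity, "info")
})

test_that("repeated-efficacy check distinguishes duplicates from sharing", {
  kg <- toy_kg()
  dup <- check_repeated_efficacy(list(item("da"), item("da")), kg)
  expect_length(dup, 1L)
  expect_equal(dup[[1]]$severity, "critical")
  sh <- check_repeated_efficacy(list(item("da"), item("dc")), kg)
  expect_length(sh, 1L)
  expect_equal(sh[[1]]$severity, "warning")
  expect_equal(sh[[1]]$evidence[[1]]$ingredient, "iw")
  # k_shared above the shared count suppresses the warning
  expect_length(check_repeated_efficacy(list(item("da"), item("dc")), kg,
                                        k_shared = 2L), 0L)
  expect_length(check_repeated_efficacy(list(item("db"), item("dd")), kg), 0L)
})

test_that("symptomatic check uses diagnoses, then symptom inference", {
  kg <- toy_kg()
  rec <- medical_record("r1", items = list(item("da")), diagnoses = "dz1")
  expect_length(check_symptomatic(rec$items, rec, kg), 0L)
  # drug indicated only for an unrelated disease
  rec2 <- medical_record("r2", items = list(item("da")), diagnoses = "dz2")
  a <- check_symptomatic(rec2$items, rec2, kg)
  expect_length(a, 1L)
  expect_equal(a[[1]]$severity, "warning")
  # drug without indication data -> info
  rec3 <- medical_record("r3", items = list(item("dc")), diagnoses = "dz2")
  expect_equal(check_symptomatic(rec3$items, rec3, kg)[[1]]$severity, "info")
  # symptom-driven inference: {s1,s2} -> dz1; da passes, db warns
  rec4 <- medical_record("r4", items = list(item("da"), item("db")),
                         symptoms = c("s1", "s2"))
  a4 <- check_symptomatic(rec4$items, rec4, kg)
  expect_length(a4, 1L)
  expect_equal(a4[[1]]$drugs, "db")
  # a single symptom cannot reach min_overlap 2 -> info for the category
  rec5 <- medical_record("r5", items = list(item("da")), symptoms = "s1")
  a5 <- check_symptomatic(rec5$items, rec5, kg)
  expect_length(a5, 1L)
  expect_equal(a5[[1]]$severity, "info")
})

test_that("dosage check honours inclusive bounds, populations, units", {
  kg <- toy_kg()
  adult <- patient_profile(40)
  child <- patient_profile(6)
  # daily dose equal to max is inside the inclusive interval
  expect_length(check_dosage(list(item("da", 4.5, 2)), adult, kg), 0L)
  expect_length(check_dosage(list(item("da", 3, 3)), adult, kg), 0L)
  over <- check_dosage(list(item("da", 5, 2)), adult, kg)
  expect_equal(over[[1]]$severity, "critical")
  expect_equal(over[[1]]$evidence[[1]]$observed, 10)
  # the same 9 g/day that passes for an adult breaches the child rule [1.5,4.5]
  ch <- check_dosage(list(item("da", 4.5, 2)), child, kg)
  expect_equal(ch[[1]]$severity, "critical")
  expect_equal(ch[[1]]$evidence[[1]]$rule$population, "child")
  # 2x the child maximum cited against the child rule
  ch2 <- check_dosage(list(item("da", 3, 3)), child, kg)
  expect_equal(ch2[[1]]$evidence[[1]]$rule$max_daily, 4.5)
  # unit mismatch -> warning, not evaluated
  um <- check_dosage(list(item("db", 3, 1, unit = "ml")), adult, kg)
  expect_equal(um[[1]]$severity, "warning")
  expect_match(um[[1]]$message, "unit mismatch")
  # no rule -> info
  expect_equal(check_dosage(list(item("dc")), adult, kg)[[1]]$severity, "info")
})

test_that("syndrome check compares the recorded pattern to indications", {
  kg <- toy_kg()
  rec <- medical_record("r1", items = list(item("da")), syndrome = "sn1")
  expect_length(check_syndrome(rec$items, rec, kg), 0L)
  rec2 <- medical_record("r2", items = list(item("da")), syndrome = "sn2")
  a <- check_syndrome(rec2$items, rec2, kg)
  expect_equal(a[[1]]$severity, "warning")
  # no syndrome recorded -> single info alert
  rec3 <- medical_record("r3", items = list(item("da")))
  a3 <- check_syndrome(rec3$items, rec3, kg)
  expect_length(a3, 1L)
  expect_equal(a3[[1]]$severity, "info")
  # drug without syndrome data -> info
  rec4 <- medical_record("r4", items = list(item("db")), syndrome = "sn1")
  expect_equal(check_syndrome(rec4$items, rec4, kg)[[1]]$severity, "info")
})

test_that("review_record reports all five categories exactly once", {
  kg <- toy_kg()
  clean <- medical_record("ok", items = list(item("db", 1.5, 2)),
                          diagnoses = "dz2")
  rep <- review_record(clean, kg)
  expect_s3_class(rep, "cpm_report")
  expect_equal(sort(names(rep$verdicts)),
               sort(c("combined_use", "repeated_efficacy", "symptomatic",
                      "dosage", "syndrome")))
  expect_true(all(rep$verdicts == "pass"))
  expect_false(has_critical(rep))
  # one planted violation per category flags all five
  bad <- medical_record(
    "bad",
    items = list(item("da", 5, 4), item("db"), item("da", 2, 1),
                 item("dc"), item("dd", 1, 1)),
    diagnoses = "dz2", syndrome = "sn2")
  repb <- review_record(bad, kg)
  expect_true(all(repb$verdicts == "flagged"))
  expect_true(has_critical(repb))
  expect_error(review_record(
    medical_record("empty", course_record_text = "some text"), kg),
    "tagger model is required")
})

test_that("alert multiset is invariant to item order and grows monotonically", {
  g <- gen_kg(n_drugs = 12L, n_ingredients = 30L, conflict_rate = 0.06,
              share_rate = 0.3, seed = 21)
  kg <- g$kg
  drugs <- g$manifest$drug_ids
  set.seed(22)
  for (trial in 1:10) {
    ids <- sample(drugs, sample(2:5, 1L))
    items <- lapply(ids, item)
    rec <- medical_record("p", items = items, diagnoses = "dz01")
    base <- review_record(rec, kg)
    perm <- medical_record("p", items = items[sample(length(items))],
                           diagnoses = "dz01")
    expect_same_rows(report_flagged_key(base),
                     report_flagged_key(review_record(perm, kg)))
    # adding a drug never removes combined_use / repeated_efficacy alerts
    extra <- sample(setdiff(drugs, ids), 1L)
    grown <- medical_record("p", items = c(items, list(item(extra))),
                            diagnoses = "dz01")
    gk <- report_flagged_key(review_record(grown, kg))
    bk <- report_flagged_key(base)
    for (cat_ in c("combined_use", "repeated_efficacy")) {
      was <- bk[bk$category == cat_, ]
      now <- gk[gk$category == cat_, ]
      expect_true(all(do.call(paste, was) %in% do.call(paste, now)))
    }
  }
})

test_that("all five checks match the brute-force oracle on random records", {
  for (seed in 1:3) {
    g <- gen_kg(n_drugs = 12L, n_ingredients = 30L, conflict_rate = 0.05,
                share_rate = 0.3, seed = seed)
    kg <- g$kg
    drugs <- g$manifest$drug_ids
    set.seed(100 + seed)
    for (trial in 1:15) {
      n <- sample(1:5, 1L)
      ids <- sample(drugs, n, replace = TRUE)
      items <- lapply(ids, function(d) {
        r <- kg$dosage[kg$dosage$drug == d &
                         kg$dosage$population == "default_adult", ]
        prescription_item(d, stats::runif(1, 0.1, r$max_daily * 0.8),
                          sample(1:3, 1L), unit = "g")
      })
      rec <- medical_record(
        "t", items = items,
        diagnoses = sample(g$manifest$disease_ids, sample(0:2, 1L)),
        symptoms = sample(g$manifest$symptom_ids, sample(0:4, 1L)),
        syndrome = if (stats::runif(1) < 0.5)
          sample(g$manifest$syndrome_ids, 1L) else NULL,
        patient = patient_profile(sample(c(6, 40, 70), 1L)))
      got <- report_flagged_key(review_record(rec, kg))
      want <- oracle_flagged(kg, rec)
      expect_same_rows(got, want)
    }
  }
})
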