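test_that("the fixture KB reproduces every reference verdict", {
  kb <- fixture_kb()
  # the 11 questionnaire key pairs
  items <- knowledge_items()
  for (i in seq_len(nrow(items)))
    expect_identical(
      resolve_pair(kb, items$drug_a[i], items$drug_b[i])$classification,
      items$key[i], label = paste(items$drug_a[i], items$drug_b[i]))
  # spot checks by name
  expect_identical(resolve_pair(kb, "heparin",
                                "potassium chloride")$classification,
                   "COMPATIBLE")
  expect_identical(resolve_pair(kb, "furosemide",
                                "pantoprazole")$classification,
                   "INCOMPATIBLE")
  expect_identical(resolve_pair(kb, "cefuroxime",
                                "urapidil")$classification,
                   "NOT_EVALUABLE")
})

test_that("exactly the five conflicting combinations are not evaluable", {
  kb <- fixture_kb()
  drugs <- kb$lexicon$canonical_name
  ne <- character()
  for (i in seq_len(length(drugs) - 1)) for (j in (i + 1):length(drugs)) {
    v <- resolve_pair(kb, drugs[i], drugs[j])
    if (v$classification == "NOT_EVALUABLE" && v$reason == "CONFLICT")
      ne <- c(ne, paste(sort(c(drugs[i], drugs[j])), collapse = " + "))
  }
  want <- c("metamizole + vancomycin", "clindamycin + metamizole",
            "metamizole + metoclopramide", "cefuroxime + urapidil",
            "furosemide + glucose solution")
  want <- vapply(strsplit(want, " \\+ "), function(p)
    paste(sort(p), collapse = " + "), "")
  expect_setequal(ne, want)
  expect_identical(length(ne), 5L)
})

test_that("all eleven named incompatible pairs resolve as incompatible", {
  kb <- fixture_kb()
  inc <- lumencheck:::fixture_incompatible_pairs()
  expect_identical(nrow(inc), 11L)
  for (i in seq_len(nrow(inc)))
    expect_identical(
      resolve_pair(kb, inc$drug_a[i], inc$drug_b[i])$classification,
      "INCOMPATIBLE", label = paste(inc$drug_a[i], inc$drug_b[i]))
})

test_that("the lexicon covers the formulary with its class tags", {
  lex <- fixture_lexicon()
  anti <- c("piperacillin/tazobactam", "cefuroxime",
            "ampicillin/sulbactam", "erythromycin", "metronidazole",
            "meropenem", "ciprofloxacin", "linezolid", "caspofungin",
            "vancomycin", "clindamycin")
  for (d in anti)
    expect_true("anti-infective" %in%
                  lex$class_tags[[match(d, lex$canonical_name)]],
                label = d)
  # synonymy: both published spellings resolve to one concept
  expect_identical(normalize_drug_name("Dipyrone", lex), "metamizole")
  expect_identical(normalize_drug_name("Heparine", lex), "heparin")
  expect_identical(normalize_drug_name("Cernevit", lex),
                   "multi-vitamin supplement")
})

test_that("cohorts are reproducible and respect their parameters", {
  p <- cohort_params(n_patients = 5, seed = 7)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(a, b)
  expect_error(cohort_params(n_patients = 3, seed = 1, planted_rate = 99),
               "planted_rate")
  expect_error(cohort_params(n_patients = 3, seed = 1, p_included = 1.2),
               "probabilities")
  expect_error(cohort_params(n_patients = 0, seed = 1), "n_patients")
})

test_that("nothing planted means nothing found", {
  co <- generate_cohort(cohort_params(n_patients = 4, planted_rate = 0,
                                      seed = 2))
  res <- analyze_cohort(co$charts, fixture_kb())
  expect_identical(res$summary$n_incompatible_combinations, 0L)
  expect_identical(nrow(co$truth$planted), 0L)
})

test_that("analysis recovers the planted multiset and inclusion labels", {
  kb <- fixture_kb()
  for (seed in c(3, 14, 27)) {
    co <- generate_cohort(cohort_params(n_patients = 8, seed = seed))
    res <- analyze_cohort(co$charts, kb)
    inc <- res$findings[res$findings$classification == "INCOMPATIBLE",
                        c("patient_id", "lumen", "drug_a", "drug_b")]
    rownames(inc) <- NULL
    expect_identical(inc, co$truth$planted,
                     label = paste("seed", seed))
    for (pid in names(co$charts))
      expect_identical(meets_inclusion(co$charts[[pid]])$included,
                       unname(co$truth$included[pid]),
                       label = paste("seed", seed, pid))
    # planted max-concurrency labels match the sweep line
    for (pid in names(co$charts)) {
      ch <- co$charts[[pid]]
      for (lum in seq_len(ch$catheter$n_lumens)) {
        win <- simultaneous_sets(ch, lum)
        got <- if (nrow(win)) max(win$n_drugs) else 0L
        expect_identical(got,
                         co$truth$max_simultaneous[[pid]][[as.character(lum)]],
                         label = paste(pid, "lumen", lum))
      }
    }
  }
})
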