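test_that("percent1 rounds half-up to one decimal", {
  expect_equal(percent1(64, 104), 61.5)
  expect_equal(percent1(81, 130), 62.3)
  expect_equal(percent1(18, 130), 13.8)
  expect_equal(percent1(1, 3), 33.3)
  expect_equal(percent1(1, 8), 12.5)
  expect_equal(percent1(5, 8), 62.5)   # .5 rounds up, not to even
  expect_error(percent1(1, 0), "denominator")
})

test_that("a three-drug lumen with one incompatible pair yields one finding", {
  kb <- fixture_kb()
  ch <- chart_of(rbind(
    ev_row("piperacillin/tazobactam", 3, 0, 60),
    ev_row("pantoprazole", 3, 10, 50),
    ev_row("sodium chloride", 3, 0, 120)))
  res <- analyze_cohort(list(ptX = ch), kb)
  expect_identical(res$summary$n_included, 1L)
  inc <- res$findings[res$findings$classification == "INCOMPATIBLE", ]
  expect_identical(nrow(inc), 1L)
  expect_identical(inc$drug_a, "pantoprazole")
  expect_identical(inc$drug_b, "piperacillin/tazobactam")
})

test_that("charts below the inclusion threshold contribute nothing", {
  kb <- fixture_kb()
  ch <- chart_of(rbind(ev_row("piperacillin/tazobactam", 3, 0, 60),
                       ev_row("pantoprazole", 3, 10, 50)))
  res <- analyze_cohort(list(ptX = ch), kb)
  expect_identical(res$summary$n_included, 0L)
  expect_identical(nrow(res$findings), 0L)
  expect_identical(res$summary$n_incompatible_combinations, 0L)
})

test_that("frequency table counts both members and conserves totals", {
  f <- data.frame(patient_id = c("p1", "p1"), lumen = 3L,
                  drug_a = c("a", "a"), drug_b = c("b", "c"),
                  classification = "INCOMPATIBLE", reason = "SINGLE_SOURCE",
                  stringsAsFactors = FALSE)
  tab <- drug_frequency_table(f)
  expect_identical(tab$drug, c("a", "b", "c"))
  expect_identical(tab$n, c(2L, 1L, 1L))
  expect_equal(tab$percent, c(100, 50, 50))
  expect_identical(sum(tab$n), 2L * nrow(f))
  # the published style: 18 of 130 incompatible combinations prints 13.8
  expect_equal(percent1(18, 130), 13.8)
})

test_that("cross table is symmetric with zero diagonal and conserved triangle", {
  set.seed(8)
  for (rep in 1:5) {
    drugs <- letters[1:6]
    n <- 15
    a <- sample(drugs, n, TRUE); b <- sample(drugs, n, TRUE)
    keep <- a != b
    f <- data.frame(patient_id = "p", lumen = 1L,
                    drug_a = pmin(a, b)[keep], drug_b = pmax(a, b)[keep],
                    classification = sample(c("INCOMPATIBLE", "COMPATIBLE"),
                                            sum(keep), TRUE),
                    reason = "SINGLE_SOURCE", stringsAsFactors = FALSE)
    m <- cross_table(f)
    expect_identical(m, t(m))
    expect_true(all(diag(m) == 0))
    expect_identical(sum(m[upper.tri(m)]),
                     sum(f$classification == "INCOMPATIBLE"))
    tab <- drug_frequency_table(f)
    expect_identical(sum(tab$n),
                     2L * sum(f$classification == "INCOMPATIBLE"))
  }
})

test_that("patient-level statistics include zero-count included patients", {
  f <- data.frame(patient_id = c("p2", "p3", "p3"), lumen = 1L,
                  drug_a = "a", drug_b = "b",
                  classification = "INCOMPATIBLE", reason = "SINGLE_SOURCE",
                  stringsAsFactors = FALSE)
  st <- patient_level_stats(f, c("p1", "p2", "p3"))
  expect_identical(st$n_with_incompatibility, 2L)
  expect_identical(unname(st$counts), c(0L, 1L, 2L))
  expect_equal(st$median, 1)
  empty <- patient_level_stats(f[0, ], c("p1", "p2"))
  expect_identical(empty$n_with_incompatibility, 0L)
  expect_identical(unname(empty$counts), c(0L, 0L))
})

test_that("removing a patient never increases any aggregate count", {
  kb <- fixture_kb()
  co <- generate_cohort(cohort_params(n_patients = 8, seed = 13))
  full <- analyze_cohort(co$charts, kb)
  drop <- analyze_cohort(co$charts[-1], kb)
  expect_lte(drop$summary$n_incompatible_combinations,
             full$summary$n_incompatible_combinations)
  expect_lte(drop$summary$n_included, full$summary$n_included)
  expect_lte(drop$summary$n_not_evaluable, full$summary$n_not_evaluable)
  t_full <- drug_frequency_table(full$findings)
  t_drop <- drug_frequency_table(drop$findings)
  shared <- intersect(t_full$drug, t_drop$drug)
  expect_true(all(t_drop$n[match(shared, t_drop$drug)] <=
                    t_full$n[match(shared, t_full$drug)]))
})

test_that("distinct-pair counting collapses repeats within a patient", {
  kb <- fixture_kb()
  ch <- chart_of(rbind(
    ev_row("piperacillin/tazobactam", 3, 0, 60),
    ev_row("pantoprazole", 3, 10, 50),
    ev_row("sodium chloride", 3, 0, 120),
    ev_row("piperacillin/tazobactam", 4, 0, 60),
    ev_row("pantoprazole", 4, 10, 50)), n_lumens = 5)
  occ <- analyze_cohort(list(ptX = ch), kb)
  dis <- analyze_cohort(list(ptX = ch), kb, distinct_pairs = TRUE)
  expect_identical(occ$summary$n_incompatible_combinations, 2L)
  expect_identical(dis$summary$n_incompatible_combinations, 1L)
})
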