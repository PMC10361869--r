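test_that("knowledge scoring matches hand-countable distributions", {
  items <- data.frame(item_id = "i1",
                      drug_a = "piperacillin/tazobactam",
                      drug_b = "pantoprazole", key = "INCOMPATIBLE",
                      stringsAsFactors = FALSE)
  resp <- responses_from_counts(items, 2, 12, 0, 14)
  sc <- score_knowledge(resp, items)
  expect_identical(sc$per_item$n_correct, 2L)
  expect_identical(sc$per_item$n_incorrect, 12L)
  expect_equal(sc$per_item$pct_correct, 14)
  expect_equal(sc$per_item$pct_incorrect, 86)
  expect_equal(sc$per_item$pct_blank, 0)

  blank <- data.frame(participant_id = sprintf("p%02d", 1:14),
                      item_id = "i1", answer = "BLANK",
                      stringsAsFactors = FALSE)
  sb <- score_knowledge(blank, items)
  expect_equal(unlist(sb$per_item[c("pct_correct", "pct_incorrect",
                                    "pct_blank")]),
               c(pct_correct = 0, pct_incorrect = 0, pct_blank = 100))

  dup <- rbind(resp, resp[1, ])
  expect_error(score_knowledge(dup, items), "duplicate")
  resp$answer[1] <- "MAYBE"
  expect_error(score_knowledge(resp, items), "answer token")
})

test_that("per-item invariants: counts sum to participants, totals to the grid", {
  items <- knowledge_items()
  set.seed(4)
  resp <- generate_survey(items, 14, prob_correct = items$pct_correct / 100,
                          prob_blank = items$pct_blank / 100, seed = 4)
  sc <- score_knowledge(resp, items)
  expect_true(all(sc$per_item$n_correct + sc$per_item$n_incorrect +
                    sc$per_item$n_blank == 14))
  expect_identical(sc$totals$n_responses, 14L * nrow(items))
})

test_that("Likert summaries exclude no-answers and match a sort-based oracle", {
  const <- data.frame(participant_id = 1:3, question_id = 1,
                      value = c(4, 4, 4))
  s <- summarize_likert(const)
  expect_equal(unlist(s[c("median", "q25", "q75", "min", "max")]),
               c(median = 4, q25 = 4, q75 = 4, min = 4, max = 4))

  minmax <- data.frame(participant_id = 1:2, question_id = 1,
                       value = c(0, 5))
  s2 <- summarize_likert(minmax)
  expect_equal(s2$min, 0); expect_equal(s2$max, 5)

  none <- data.frame(participant_id = 1:3, question_id = 7,
                     value = NA_real_)
  s3 <- summarize_likert(none)
  expect_identical(s3$n_answered, 0L)
  expect_true(is.na(s3$median))

  # weighted-average quantiles at (n+1)p against a direct computation
  set.seed(9)
  for (rep in 1:10) {
    x <- sample(0:5, 14, replace = TRUE)
    df <- data.frame(participant_id = 1:14, question_id = 1, value = x)
    s <- summarize_likert(df)
    direct <- function(p) {
      h <- (14 + 1) * p
      xs <- sort(x)
      lo <- max(1, floor(h)); hi <- min(14, ceiling(h))
      xs[lo] + (h - floor(h)) * (xs[hi] - xs[lo])
    }
    expect_equal(s$q25, direct(0.25))
    expect_equal(s$median, direct(0.5))
    expect_equal(s$q75, direct(0.75))
  }
  expect_error(summarize_likert(data.frame(participant_id = 1,
                                           question_id = 1, value = 7)),
               "0..5")
})

test_that("counts reconstruct from printed whole percents", {
  expect_identical(reconstruct_counts(86, 14), 12L)
  expect_identical(reconstruct_counts(100, 14), 14L)
  expect_identical(reconstruct_counts(0, 14), 0L)
  expect_identical(reconstruct_counts(79, 14), 11L)
  expect_identical(reconstruct_counts(57, 14), 8L)
  expect_error(reconstruct_counts(120, 14), "range")
})

test_that("sampled surveys hit their configured correctness probabilities", {
  items <- knowledge_items()
  resp <- generate_survey(items, 10000,
                          prob_correct = items$pct_correct / 100,
                          prob_blank = items$pct_blank / 100, seed = 99)
  sc <- score_knowledge(resp, items)
  # empirical correct fraction within 2 points of the configured
  # probability (among non-blank answers correctness was sampled
  # independently of blanking)
  frac_correct <- sc$per_item$n_correct / 10000
  target <- (items$pct_correct / 100) * (1 - items$pct_blank / 100)
  expect_true(all(abs(frac_correct - target) < 0.02))
  # degenerate probabilities are exact
  all1 <- generate_survey(items, 50, prob_correct = 1, seed = 1)
  expect_true(all(score_knowledge(all1, items)$per_item$pct_correct == 100))
  all0 <- generate_survey(items, 50, prob_correct = 0, seed = 1)
  expect_true(all(score_knowledge(all0, items)$per_item$n_incorrect == 50))
  # determinism
  expect_identical(generate_survey(items, 20, 0.5, seed = 3),
                   generate_survey(items, 20, 0.5, seed = 3))
})
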