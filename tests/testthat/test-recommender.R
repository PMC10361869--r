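# a small world of three mutually incompatible infusions plus a bystander
triangle_kb <- function() {
  lex <- drug_lexicon(c("alpha", "beta", "gamma", "delta"))
  pairs <- rbind(c("alpha", "beta"), c("alpha", "gamma"),
                 c("beta", "gamma"))
  knowledge_base(lex, data.frame(
    drug_a = pairs[, 1], drug_b = pairs[, 2], source = "STABILIS",
    verdict = "INCOMPATIBLE", stringsAsFactors = FALSE))
}

triangle_chart <- function(n_lumens, mode = "CONTINUOUS") {
  patient_chart("ptX", catheter_config(n_lumens), rbind(
    ev_row("alpha", 1, 0, 600, mode), ev_row("beta", 1, 0, 600, mode),
    ev_row("gamma", 1, 0, 600, mode), ev_row("delta", 1, 0, 600, mode)))
}

test_that("the incompatibility graph mirrors the findings", {
  kb <- triangle_kb()
  ch <- triangle_chart(3)
  f <- analyze_cohort(list(ptX = ch), kb)$findings
  g <- build_graph(ch, f, kb)
  expect_identical(sort(igraph::V(g)$name),
                   c("alpha", "beta", "delta", "gamma"))
  expect_identical(igraph::ecount(g), 3)
  expect_identical(igraph::degree(g)[["delta"]], 0)
  # no incompatible findings -> edgeless graph
  g0 <- build_graph(ch, f[0, ], kb)
  expect_identical(igraph::ecount(g0), 0)
})

test_that("sequential administration shifts the later short infusion minimally", {
  kb <- fixture_kb()
  ch <- chart_of(rbind(ev_row("piperacillin/tazobactam", 3, 0, 60),
                       ev_row("pantoprazole", 3, 30, 60)))
  s <- try_sequential(ch, c("piperacillin/tazobactam", "pantoprazole"), kb)
  expect_true(s$feasible)
  expect_identical(s$shifts$drug, "pantoprazole")
  expect_equal(s$shifts$delta_min, 35)  # ends at 60, plus 5-min flush
  after <- apply_plan(ch, list(type = "shift", drug = "pantoprazole",
                               lumen = 3L, delta_min = 35))
  expect_identical(count_incompatible_overlaps(after, kb), 0L)

  cont <- chart_of(rbind(ev_row("furosemide", 3, 0, 600, "CONTINUOUS"),
                         ev_row("pantoprazole", 3, 30, 60)))
  expect_false(try_sequential(cont, c("furosemide", "pantoprazole"),
                              kb)$feasible)
})

test_that("sequential administration fails when every shift hits the horizon", {
  kb <- triangle_kb()
  # beta can only move right, but any placement clear of alpha overruns
  # the configured horizon
  ch <- patient_chart("ptX", catheter_config(1), rbind(
    ev_row("alpha", 1, 0, 500), ev_row("beta", 1, 100, 480)),
    max_horizon = 600)
  cfg <- recommender_config(max_horizon = 600)
  expect_false(try_sequential(ch, c("alpha", "beta"), kb,
                              config = cfg)$feasible)
})

test_that("relocation feasibility equals the chromatic bound on a triangle", {
  kb <- triangle_kb()
  ch3 <- triangle_chart(3)
  f3 <- analyze_cohort(list(ptX = ch3), kb)$findings
  g3 <- build_graph(ch3, f3, kb)
  rel3 <- try_relocate(g3, ch3$catheter, kb$lexicon)
  expect_true(rel3$feasible)
  expect_identical(length(unique(rel3$assignment[c("alpha", "beta",
                                                   "gamma")])), 3L)

  ch2 <- triangle_chart(2)
  f2 <- analyze_cohort(list(ptX = ch2), kb)$findings
  g2 <- build_graph(ch2, f2, kb)
  expect_false(try_relocate(g2, ch2$catheter, kb$lexicon)$feasible)
})

test_that("greedy+backtracking assignment agrees with exhaustive enumeration", {
  set.seed(23)
  for (rep in 1:30) {
    n <- sample(3:8, 1)
    drugs <- paste0("d", seq_len(n))
    n_lumens <- sample(2:4, 1)
    edges <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- runif(nrow(edges)) < 0.35
    conflicts <- data.frame(drug_a = drugs[edges[keep, 1]],
                            drug_b = drugs[edges[keep, 2]],
                            stringsAsFactors = FALSE)
    allowed <- lapply(seq_len(n), function(i) {
      k <- sample(seq_len(n_lumens), sample(n_lumens, 1))
      sort(k)
    })
    names(allowed) <- drugs
    got <- lumen_assignment(drugs, conflicts, allowed)
    want <- exhaustive_assignment_feasible(drugs, conflicts, allowed,
                                           n_lumens)
    expect_identical(!is.null(got), want,
                     label = sprintf("rep %d (n=%d, l=%d)", rep, n,
                                     n_lumens))
    if (!is.null(got)) {
      expect_true(all(mapply(function(d, l) l %in% allowed[[d]],
                             names(got), got)))
      for (i in seq_len(nrow(conflicts)))
        expect_true(got[[conflicts$drug_a[i]]] !=
                      got[[conflicts$drug_b[i]]])
    }
  }
})

test_that("pausing applies only to a pausable continuous vs short conflict", {
  kb <- fixture_kb()
  lex <- kb$lexicon
  mix <- chart_of(rbind(ev_row("furosemide", 3, 0, 600, "CONTINUOUS"),
                        ev_row("pantoprazole", 3, 100, 130)))
  p <- try_pause(mix, c("furosemide", "pantoprazole"), lex)
  expect_true(p$feasible)
  expect_identical(p$plan[[1]]$drug, "furosemide")
  expect_equal(p$plan[[1]]$windows$start_min, 95)
  expect_equal(p$plan[[1]]$windows$end_min, 135)
  after <- apply_plan(mix, list(type = "pause", plans = p$plan))
  expect_identical(count_incompatible_overlaps(after, kb), 0L)
  # the infusion resumes: two carved segments remain
  fu <- after$events[after$events$drug == "furosemide", ]
  expect_equal(sort(fu$start_min), c(0, 135))

  cate <- chart_of(rbind(ev_row("adrenaline", 3, 0, 600, "CONTINUOUS"),
                         ev_row("pantoprazole", 3, 100, 130)))
  expect_false(try_pause(cate, c("adrenaline", "pantoprazole"),
                         lex)$feasible)
  both <- chart_of(rbind(ev_row("furosemide", 3, 0, 600, "CONTINUOUS"),
                         ev_row("pantoprazole", 3, 100, 130,
                                "CONTINUOUS")))
  expect_false(try_pause(both, c("furosemide", "pantoprazole"),
                         lex)$feasible)
})

test_that("fluid restriction disables the flush-adding steps", {
  kb <- fixture_kb()
  ch <- chart_of(rbind(ev_row("piperacillin/tazobactam", 3, 0, 60),
                       ev_row("pantoprazole", 3, 30, 60)),
                 fluid_restricted = TRUE)
  expect_false(try_sequential(ch, c("piperacillin/tazobactam",
                                    "pantoprazole"), kb)$feasible)
  expect_false(try_pause(ch, c("piperacillin/tazobactam", "pantoprazole"),
                         kb$lexicon)$feasible)
})

test_that("two short incompatible infusions get exactly one Step-1 recommendation", {
  kb <- fixture_kb()
  ch <- chart_of(rbind(ev_row("piperacillin/tazobactam", 3, 0, 60),
                       ev_row("pantoprazole", 3, 30, 60),
                       ev_row("sodium chloride", 3, 0, 120)))
  f <- analyze_cohort(list(ptX = ch), kb)$findings
  recs <- recommend(ch, f, kb)
  expect_identical(length(recs), 1L)
  expect_identical(recs[[1]]$step, 1L)
  expect_identical(recs[[1]]$step_name, "Administer sequentially")
  expect_identical(
    count_incompatible_overlaps(attr(recs, "transformed_chart"), kb), 0L)
  none <- recommend(ch, f[0, ], kb)
  expect_identical(length(none), 0L)
})

test_that("an over-constrained conflict clique escalates to Step 4 at the chromatic number", {
  kb <- triangle_kb()
  ch <- triangle_chart(2)
  f <- analyze_cohort(list(ptX = ch), kb)$findings
  recs <- recommend(ch, f, kb)
  expect_identical(length(recs), 1L)
  expect_identical(recs[[1]]$step, 4L)
  expect_identical(recs[[1]]$step_name, "Use catheters with more lumens")
  # brute-force chromatic number of a triangle is 3
  drugs <- c("alpha", "beta", "gamma", "delta")
  conf <- igraph::graph_attr(build_graph(ch, f, kb), "conflicts")
  feas <- vapply(2:4, function(k)
    exhaustive_assignment_feasible(
      drugs, conf, stats::setNames(rep(list(1:k), 4), drugs), k),
    TRUE)
  expect_identical(min((2:4)[feas]), recs[[1]]$plan$n_lumens)
  expect_identical(
    count_incompatible_overlaps(attr(recs, "transformed_chart"), kb), 0L)
  # minimality: the lower steps really are infeasible for these pairs
  expect_false(try_sequential(ch, c("alpha", "beta"), kb)$feasible)
  expect_false(try_relocate(build_graph(ch, f, kb), ch$catheter,
                            kb$lexicon)$feasible)
  expect_false(try_pause(ch, c("alpha", "beta"), kb$lexicon)$feasible)
})

test_that("recommendations are deterministic and replayable", {
  kb <- fixture_kb()
  co <- generate_cohort(cohort_params(n_patients = 6, seed = 31))
  res <- analyze_cohort(co$charts, kb)
  pids <- unique(incompat <- res$findings$patient_id[
    res$findings$classification == "INCOMPATIBLE"])
  for (pid in pids) {
    r1 <- recommend(co$charts[[pid]], res$findings, kb)
    r2 <- recommend(co$charts[[pid]], res$findings, kb)
    expect_identical(lapply(r1, unclass), lapply(r2, unclass))
    replayed <- apply_recommendations(co$charts[[pid]], r1)
    expect_identical(replayed$events,
                     attr(r1, "transformed_chart")$events)
  }
})
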