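#' Bundled drug lexicon of the critical-care formulary
#'
#' Canonical concepts, synonyms, and class tags for every drug and
#' infusate the package's fixtures and generators use. Combination
#' products are single concepts; carrier solutions, parenteral nutrition,
#' and vitamin supplements are concepts with their own class tags because
#' they take part in incompatibility reactions.
#'
#' @return a [drug_lexicon()].
#' @export
fixture_lexicon <- function() {
  entries <- list(
    list("furosemide", c(), c("diuretic")),
    list("pantoprazole", c(), c("proton-pump-inhibitor")),
    list("piperacillin/tazobactam", c("pip/tazo"), c("anti-infective"),
         TRUE),
    list("heparin", c("heparine"), c("anticoagulant")),
    list("erythromycin", c(), c("anti-infective")),
    list("cefuroxime", c(), c("anti-infective")),
    list("ringer's acetate", c("ringer acetate"), c("fluid")),
    list("ampicillin/sulbactam", c(), c("anti-infective"), TRUE),
    list("metoclopramide", c(), c("antiemetic")),
    list("caspofungin", c(), c("anti-infective")),
    list("metamizole", c("dipyrone"), c("non-opioid-analgesic")),
    list("levetiracetam", c(), c("anticonvulsant")),
    list("prednisolone", c(), c("corticosteroid")),
    list("magnesium sulfate", c(), c("electrolyte")),
    list("metronidazole", c(), c("anti-infective")),
    list("meropenem", c(), c("anti-infective")),
    list("ciprofloxacin", c(), c("anti-infective")),
    list("amiodarone", c(), c("antiarrhythmic")),
    list("linezolid", c(), c("anti-infective")),
    list("calcium chloride", c(), c("electrolyte")),
    list("vancomycin", c(), c("anti-infective")),
    list("clindamycin", c(), c("anti-infective")),
    list("urapidil", c(), c("antihypertensive")),
    list("glucose solution", c("glucose 5%"), c("fluid", "nutrition")),
    list("multi-vitamin supplement", c("cernevit"), c("nutrition")),
    list("esketamine", c(), c("sedative")),
    list("dexmedetomidine", c(), c("sedative")),
    list("sufentanil", c(), c("analgesic")),
    list("adrenaline", c("epinephrine"), c("catecholamine")),
    list("noradrenaline", c("norepinephrine"), c("catecholamine")),
    list("propofol", c(), c("sedative")),
    list("sodium chloride", c("nacl 0.9%", "sodium chloride 0.9%"),
         c("electrolyte", "fluid")),
    list("potassium chloride", c(), c("electrolyte")),
    list("sodium bicarbonate", c(), c("electrolyte")),
    list("parenteral nutrition", c("smofkabiven", "nutrition (smofkabiven)"),
         c("nutrition")),
    list("insulin", c(), c("hormone")))
  drug_lexicon(
    canonical_name = vapply(entries, `[[`, "", 1),
    synonyms = lapply(entries, function(x) as.character(x[[2]])),
    class_tags = lapply(entries, function(x) as.character(x[[3]])),
    is_combination = vapply(entries, function(x)
      length(x) > 3 && isTRUE(x[[4]]), TRUE))
}

# drugs whose pairwise co-administration the fixture asserts compatible;
# the generators draw filler sessions from this clique
compat_clique <- function() {
  c("dexmedetomidine", "esketamine", "glucose solution", "levetiracetam",
    "magnesium sulfate", "metoclopramide", "potassium chloride",
    "propofol", "sodium chloride")
}

# the incompatible drug pairs the fixture knowledge base encodes
fixture_incompatible_pairs <- function() {
  m <- rbind(
    c("erythromycin", "metoclopramide"),
    c("piperacillin/tazobactam", "pantoprazole"),
    c("prednisolone", "ampicillin/sulbactam"),
    c("cefuroxime", "ringer's acetate"),
    c("heparin", "calcium chloride"),
    c("erythromycin", "multi-vitamin supplement"),
    c("metamizole", "levetiracetam"),
    c("piperacillin/tazobactam", "ciprofloxacin"),
    c("heparin", "pantoprazole"),
    c("piperacillin/tazobactam", "erythromycin"),
    c("furosemide", "pantoprazole"))
  p <- pair_sort(m[, 1], m[, 2])
  data.frame(drug_a = p$a, drug_b = p$b, stringsAsFactors = FALSE)
}

# the pairs for which the evidence sources conflict, so the resolver must
# return NOT_EVALUABLE
fixture_not_evaluable_pairs <- function() {
  m <- rbind(
    c("metamizole", "vancomycin"),
    c("metamizole", "clindamycin"),
    c("metamizole", "metoclopramide"),
    c("cefuroxime", "urapidil"),
    c("furosemide", "glucose solution"))
  p <- pair_sort(m[, 1], m[, 2])
  data.frame(drug_a = p$a, drug_b = p$b, stringsAsFactors = FALSE)
}

#' Bundled fixture knowledge base
#'
#' A complete, self-contained knowledge base over the bundled lexicon,
#' constructed so that the default resolution policy reproduces the
#' reference verdicts the package's tests and examples use: eleven keyed
#' questionnaire pairs, eleven frequently observed incompatible pairs
#' (encoded as single-source assertions from the Stabilis-style source,
#' since such calls typically rest on a single primary study), five pairs
#' on which the sources genuinely conflict (hence `NOT_EVALUABLE`), and a
#' clique of routinely co-infused drugs asserted compatible.
#'
#' @return a [knowledge_base()].
#' @export
fixture_kb <- function() {
  lex <- fixture_lexicon()
  rows <- list()
  add <- function(a, b, source, verdict, note = "", cite = "")
    rows[[length(rows) + 1]] <<- data.frame(
      drug_a = a, drug_b = b, source = source, verdict = verdict,
      evidence_note = note, citation = cite, stringsAsFactors = FALSE)

  # questionnaire answer key: two agreeing sources each
  key <- knowledge_items()
  for (i in seq_len(nrow(key))) {
    v <- key$key[i]
    if (key$drug_a[i] == "pantoprazole" ||
        key$drug_b[i] == "pantoprazole") next  # single-source below
    add(key$drug_a[i], key$drug_b[i], "KIK", v, "questionnaire key pair")
    add(key$drug_a[i], key$drug_b[i], "TRISSEL", v,
        "questionnaire key pair")
  }

  # frequently observed incompatible pairs: one Stabilis-style assertion
  inc <- fixture_incompatible_pairs()
  for (i in seq_len(nrow(inc)))
    add(inc$drug_a[i], inc$drug_b[i], "STABILIS", "INCOMPATIBLE",
        "single primary study, evidence level not graded")

  # conflicting evidence: two data-bearing sources disagree
  ne <- fixture_not_evaluable_pairs()
  for (i in seq_len(nrow(ne))) {
    add(ne$drug_a[i], ne$drug_b[i], "KIK", "COMPATIBLE",
        "reported compatible here")
    add(ne$drug_a[i], ne$drug_b[i], "STABILIS", "INCOMPATIBLE",
        "reported incompatible here")
  }

  # routinely co-infused clique: pairwise compatible
  cl <- compat_clique()
  idx <- utils::combn(length(cl), 2)
  for (j in seq_len(ncol(idx)))
    add(cl[idx[1, j]], cl[idx[2, j]], "KIK", "COMPATIBLE",
        "routine co-infusion")

  knowledge_base(lex, do.call(rbind, rows))
}

#' Questionnaire knowledge items with answer key and published percents
#'
#' The eleven drug pairs of the staff knowledge questionnaire: the keyed
#' verdict plus the per-item whole-percent response distribution among the
#' 14 respondents (correct / incorrect / no answer), which the generators
#' use as default correctness probabilities.
#'
#' @return data frame `item_id, drug_a, drug_b, key, pct_correct,
#'   pct_incorrect, pct_blank`.
#' @export
knowledge_items <- function() {
  data.frame(
    item_id = sprintf("k%02d", 1:11),
    drug_a = c("amiodarone", "esketamine", "sufentanil", "amiodarone",
               "propofol", "piperacillin/tazobactam", "heparin",
               "cefuroxime", "parenteral nutrition",
               "parenteral nutrition", "furosemide"),
    drug_b = c("calcium chloride", "dexmedetomidine", "adrenaline",
               "sodium chloride", "esketamine", "pantoprazole",
               "potassium chloride", "sodium bicarbonate",
               "metronidazole", "cefuroxime", "pantoprazole"),
    key = c("INCOMPATIBLE", "COMPATIBLE", "COMPATIBLE", "INCOMPATIBLE",
            "COMPATIBLE", "INCOMPATIBLE", "COMPATIBLE", "INCOMPATIBLE",
            "COMPATIBLE", "COMPATIBLE", "INCOMPATIBLE"),
    pct_correct = c(100, 79, 57, 100, 93, 14, 21, 79, 79, 71, 43),
    pct_incorrect = c(0, 21, 43, 0, 7, 86, 79, 7, 21, 29, 57),
    pct_blank = c(0, 0, 0, 0, 0, 0, 0, 14, 0, 0, 0),
    stringsAsFactors = FALSE)
}

#' Cohort generator parameters
#'
#' Defaults describe the emulated critical-care cohort: a median of 19
#' drugs per patient (quartiles 15.75 / 23, discretized log-normal), about
#' 47% of admitted patients meeting the inclusion criterion, 3-lumen
#' catheters with a 5-lumen share for post-surgery patients, dedicated
#' catecholamine and analgesia lumens, a 1440-minute (one-day) horizon,
#' and on average 1.25 planted incompatible pair occurrences per included
#' patient.
#'
#' @param n_patients number of admitted patients.
#' @param p_included probability a patient receives a qualifying
#'   three-drug simultaneous administration.
#' @param p_five_lumen probability of a 5-lumen (post-surgery) catheter.
#' @param planted_rate mean planted incompatible (lumen, pair)
#'   occurrences per included patient (Poisson, truncated at the number
#'   of distinct incompatible fixture pairs).
#' @param drugs_median,drugs_sdlog log-normal parameters of the
#'   drugs-per-patient distribution (median and sdlog; the default sdlog
#'   reproduces quartiles 15.75 / 23).
#' @param horizon chart length in minutes.
#' @param seed integer seed; mandatory.
#' @return a `cohort_params` list.
#' @export
cohort_params <- function(n_patients = 20, p_included = 104 / 220,
                          p_five_lumen = 0.25, planted_rate = 1.25,
                          drugs_median = 19, drugs_sdlog = 0.2834,
                          horizon = 1440, seed) {
  if (missing(seed)) abort("cohort_params: seed is mandatory")
  probs <- c(p_included = p_included, p_five_lumen = p_five_lumen)
  if (any(probs < 0 | probs > 1))
    abort("probabilities must lie in [0, 1]")
  if (n_patients < 1) abort("n_patients must be >= 1")
  if (planted_rate < 0 ||
      planted_rate > nrow(fixture_incompatible_pairs()))
    abort("planted_rate must lie in [0, %d]",
          nrow(fixture_incompatible_pairs()))
  structure(list(n_patients = as.integer(n_patients),
                 p_included = p_included, p_five_lumen = p_five_lumen,
                 planted_rate = planted_rate, drugs_median = drugs_median,
                 drugs_sdlog = drugs_sdlog, horizon = horizon,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

#' Generate a synthetic patient cohort with planted ground truth
#'
#' Emulates one day of per-lumen medication schedules for an
#' interdisciplinary critical-care cohort. Each patient gets a dedicated
#' catecholamine lumen (continuous noradrenaline) and analgesia lumen
#' (continuous sufentanil); the remaining lumens carry successive
#' non-overlapping administration sessions. Filler sessions draw 1-3
#' pairwise-compatible drugs from the bundled compatible clique; included
#' patients get one three-drug session (guaranteeing the inclusion
#' criterion) and a Poisson number of planted sessions, each carrying one
#' incompatible pair from the fixture knowledge base with a randomized
#' mode profile (both short / continuous-vs-short / both continuous).
#' Because sessions on one lumen never overlap and fillers are pairwise
#' compatible, the incompatible (lumen, pair) occurrences recovered by
#' [analyze_cohort()] equal the planted multiset exactly. Peripheral
#' events pad the distinct-drug count toward the configured
#' drugs-per-patient distribution; they are parsed but ignored by the
#' analysis. Deterministic given the seed.
#'
#' @param params a [cohort_params()].
#' @return list with `charts` (named list of [patient_chart()]) and
#'   `truth`: `planted` (data frame `patient_id, lumen, drug_a, drug_b`),
#'   `included` (named logical), and `max_simultaneous` (named list of
#'   per-lumen maxima).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  lex <- fixture_lexicon()
  inc_pairs <- fixture_incompatible_pairs()
  clique <- compat_clique()
  withr_seed(params$seed, {
    charts <- list()
    planted <- list()
    included_flag <- logical(0)
    max_sim <- list()
    for (p in seq_len(params$n_patients)) {
      pid <- sprintf("pt%03d", p)
      n_lumens <- if (stats::runif(1) < params$p_five_lumen) 5L else 3L
      cath <- catheter_config(n_lumens,
                              c("1" = "catecholamine", "2" = "analgesic"))
      included <- stats::runif(1) < params$p_included
      horizon <- params$horizon
      ev <- list()
      add_event <- function(drug, lumen, s, e, mode,
                            route = "CENTRAL_VENOUS")
        ev[[length(ev) + 1]] <<- data.frame(
          drug = drug, route = route, lumen = lumen, start_min = s,
          end_min = e, mode = mode, stringsAsFactors = FALSE)
      add_event("noradrenaline", 1L, 0, horizon, "CONTINUOUS")
      add_event("sufentanil", 2L, 0, horizon, "CONTINUOUS")

      free <- setdiff(seq_len(n_lumens), c(1L, 2L))
      lumen_t <- stats::setNames(rep(0, length(free)), free)
      lumen_max <- stats::setNames(rep(1L, n_lumens),
                                   seq_len(n_lumens))
      place_session <- function(lumen, drugs, lens, modes) {
        key <- as.character(lumen)
        t0 <- lumen_t[[key]]
        for (k in seq_along(drugs))
          add_event(drugs[k], lumen, t0, t0 + lens[k], modes[k])
        lumen_t[[key]] <<- t0 + max(lens) +
          sample(5:30, 1)  # inter-session gap
        lumen_max[[key]] <<- max(lumen_max[[key]], length(drugs))
      }

      # planted incompatible sessions (included patients only)
      k_planted <- if (included)
        min(stats::rpois(1, params$planted_rate), nrow(inc_pairs)) else 0L
      my_pairs <- if (k_planted > 0)
        inc_pairs[sample(nrow(inc_pairs), k_planted), , drop = FALSE]
      else inc_pairs[0, ]
      for (i in seq_len(k_planted)) {
        profile <- sample(c("short", "mixed", "long"), 1,
                          prob = c(0.5, 0.3, 0.2))
        modes <- switch(profile,
                        short = c("INTERMITTENT", "INTERMITTENT"),
                        mixed = c("CONTINUOUS", "INTERMITTENT"),
                        long = c("CONTINUOUS", "CONTINUOUS"))
        lens <- ifelse(modes == "CONTINUOUS", sample(240:360, 2, TRUE),
                       sample(30:60, 2, TRUE))
        lum <- free[sample.int(length(free), 1)]
        place_session(lum, c(my_pairs$drug_a[i], my_pairs$drug_b[i]),
                      lens, modes)
        planted[[length(planted) + 1]] <- data.frame(
          patient_id = pid, lumen = lum, drug_a = my_pairs$drug_a[i],
          drug_b = my_pairs$drug_b[i], stringsAsFactors = FALSE)
      }

      # one qualifying triple session for included patients
      if (included)
        place_session(free[1], sample(clique, 3), sample(45:90, 3, TRUE),
                      rep("INTERMITTENT", 3))

      # filler sessions until the free lumens are loosely booked
      for (lum in free) {
        while (lumen_t[[as.character(lum)]] < horizon * 0.6) {
          size <- if (included) sample(1:3, 1, prob = c(0.4, 0.4, 0.2))
                  else sample(1:2, 1, prob = c(0.6, 0.4))
          place_session(lum, sample(clique, size),
                        sample(30:120, size, TRUE),
                        rep("INTERMITTENT", size))
        }
      }

      events <- do.call(rbind, ev)
      # pad the distinct-drug count with peripheral administrations
      target <- round(stats::rlnorm(1, log(params$drugs_median),
                                    params$drugs_sdlog))
      pool <- setdiff(lex$canonical_name, unique(events$drug))
      extra <- min(max(0, target - length(unique(events$drug))),
                   length(pool))
      if (extra > 0) {
        per <- sample(pool, extra)
        starts <- sample(0:(horizon - 30), extra, TRUE)
        for (k in seq_len(extra))
          add_event(per[k], 1L, starts[k], starts[k] + 20,
                    "INTERMITTENT", route = "PERIPHERAL")
        events <- do.call(rbind, ev)
      }

      charts[[pid]] <- patient_chart(pid, cath, events,
                                     max_horizon = horizon + 200)
      included_flag[pid] <- included
      max_sim[[pid]] <- lumen_max
    }
    planted <- if (length(planted)) do.call(rbind, planted) else
      data.frame(patient_id = character(), lumen = integer(),
                 drug_a = character(), drug_b = character(),
                 stringsAsFactors = FALSE)
    planted <- planted[order(planted$patient_id, planted$lumen,
                             planted$drug_a, planted$drug_b), ,
                       drop = FALSE]
    rownames(planted) <- NULL
    list(charts = charts,
         truth = list(planted = planted, included = included_flag,
                      max_simultaneous = max_sim))
  })
}
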