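#' Score knowledge-item responses against the answer key
#'
#' Each participant judged a set of drug pairs as compatible or
#' incompatible; a response is correct when it matches the keyed verdict.
#' Per-item percentages are rounded half-up to whole percents; the totals
#' row sums counts over items.
#'
#' @param responses data frame `participant_id, item_id, answer` with
#'   `answer` one of `COMPATIBLE`, `INCOMPATIBLE`, `BLANK`. At most one
#'   response per (participant, item).
#' @param items data frame `item_id, drug_a, drug_b, key` with `key` one
#'   of `COMPATIBLE`, `INCOMPATIBLE`.
#' @return list with `per_item` (data frame `item_id, n_correct,
#'   n_incorrect, n_blank, pct_correct, pct_incorrect, pct_blank`) and
#'   `totals` (`n_responses, n_correct, n_incorrect, n_blank`).
#' @export
score_knowledge <- function(responses, items) {
  bad_item <- setdiff(unique(responses$item_id), items$item_id)
  if (length(bad_item))
    abort("responses reference unknown item(s): %s",
          paste(bad_item, collapse = ", "))
  bad_ans <- setdiff(unique(responses$answer),
                     c("COMPATIBLE", "INCOMPATIBLE", "BLANK"))
  if (length(bad_ans))
    abort("unknown answer token(s): %s", paste(bad_ans, collapse = ", "))
  key <- paste(responses$participant_id, responses$item_id)
  if (anyDuplicated(key))
    abort("duplicate response for (participant, item): %s",
          key[duplicated(key)][1])
  n_participants <- length(unique(responses$participant_id))
  per_item <- do.call(rbind, lapply(items$item_id, function(it) {
    r <- responses[responses$item_id == it, , drop = FALSE]
    k <- items$key[items$item_id == it]
    n_blank <- sum(r$answer == "BLANK")
    n_correct <- sum(r$answer == k)
    n_incorrect <- nrow(r) - n_blank - n_correct
    n <- max(nrow(r), 1L)
    data.frame(item_id = it, n_correct = n_correct,
               n_incorrect = n_incorrect, n_blank = n_blank,
               pct_correct = round_half_up(100 * n_correct / n),
               pct_incorrect = round_half_up(100 * n_incorrect / n),
               pct_blank = round_half_up(100 * n_blank / n),
               stringsAsFactors = FALSE)
  }))
  totals <- list(
    n_responses = sum(per_item$n_correct + per_item$n_incorrect +
                        per_item$n_blank),
    n_correct = sum(per_item$n_correct),
    n_incorrect = sum(per_item$n_incorrect),
    n_blank = sum(per_item$n_blank),
    n_participants = n_participants)
  list(per_item = per_item, totals = totals)
}

#' Summarize Likert assumption items
#'
#' Items use a 0 (never) to 5 (always) scale with an additional "no answer
#' possible" option; no-answers are excluded from the statistics, and a
#' question with no scored responses reports missing statistics rather
#' than zeros.
#'
#' @param responses data frame `participant_id, question_id, value` with
#'   `value` an integer 0-5 or `NA` for "no answer possible".
#' @param quantile_type quantile convention as in [stats::quantile()];
#'   default 6, the weighted-average-at-`(n+1)p` definition used by common
#'   commercial statistics software.
#' @return data frame `question_id, median, q25, q75, min, max,
#'   n_answered`.
#' @export
summarize_likert <- function(responses, quantile_type = 6) {
  v <- responses$value
  if (any(!is.na(v) & (v < 0 | v > 5 | v != floor(v))))
    abort("Likert values must be integers in 0..5 or NA")
  do.call(rbind, lapply(sort(unique(responses$question_id)), function(q) {
    x <- v[responses$question_id == q]
    x <- x[!is.na(x)]
    if (length(x) == 0)
      return(data.frame(question_id = q, median = NA_real_,
                        q25 = NA_real_, q75 = NA_real_, min = NA_real_,
                        max = NA_real_, n_answered = 0L))
    qs <- stats::quantile(x, c(0.25, 0.5, 0.75), type = quantile_type,
                          names = FALSE)
    data.frame(question_id = q, median = qs[2], q25 = qs[1], q75 = qs[3],
               min = min(x), max = max(x), n_answered = length(x))
  }))
}

#' Reconstruct a response count from a printed whole percent
#'
#' Published questionnaire tables often print whole percents rather than
#' raw counts; with the participant count known, the count is recovered by
#' half-up rounding of `pct * n / 100`.
#'
#' @param pct whole percent in 0..100.
#' @param n number of participants.
#' @return integer count.
#' @examples
#' reconstruct_counts(86, 14)  # 12
#' @export
reconstruct_counts <- function(pct, n) {
  if (any(pct < 0 | pct > 100)) abort("percent out of range 0..100")
  if (any(n <= 0)) abort("participant count must be positive")
  as.integer(round_half_up(pct * n / 100))
}

#' Deterministic response grid from per-item counts
#'
#' Builds a complete response table in which, for each item, the first
#' `n_correct` participants answer correctly, the next `n_incorrect`
#' answer incorrectly, and the rest leave the item blank. Used to turn
#' published per-item percentages back into a scoreable response set.
#'
#' @param items data frame `item_id, key` (see [score_knowledge()]).
#' @param n_correct,n_incorrect,n_blank integer vectors, one entry per
#'   item; must sum to `n` per item.
#' @param n number of participants.
#' @return a responses data frame as accepted by [score_knowledge()].
#' @export
responses_from_counts <- function(items, n_correct, n_incorrect, n_blank,
                                  n) {
  if (any(n_correct + n_incorrect + n_blank != n))
    abort("per-item counts must sum to the participant count")
  flip <- function(k) if (k == "COMPATIBLE") "INCOMPATIBLE" else "COMPATIBLE"
  rows <- lapply(seq_len(nrow(items)), function(i) {
    data.frame(
      participant_id = sprintf("p%02d", seq_len(n)),
      item_id = items$item_id[i],
      answer = c(rep(items$key[i], n_correct[i]),
                 rep(flip(items$key[i]), n_incorrect[i]),
                 rep("BLANK", n_blank[i])),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Sample a synthetic survey response grid
#'
#' Every participant answers every item; the probability of a correct
#' answer (and of leaving the item blank) is configurable per item.
#' Deterministic given the seed.
#'
#' @param items data frame `item_id, key`.
#' @param n_participants number of respondents.
#' @param prob_correct numeric vector (recycled) of per-item probabilities
#'   that a *given* (non-blank) answer is correct.
#' @param prob_blank per-item probability of no answer (default 0).
#' @param seed integer seed (mandatory: generated fixtures must be
#'   reproducible).
#' @return a responses data frame as accepted by [score_knowledge()].
#' @export
generate_survey <- function(items, n_participants, prob_correct,
                            prob_blank = 0, seed) {
  if (missing(seed)) abort("generate_survey: seed is mandatory")
  if (any(prob_correct < 0 | prob_correct > 1) ||
      any(prob_blank < 0 | prob_blank > 1))
    abort("probabilities must lie in [0, 1]")
  prob_correct <- rep_len(prob_correct, nrow(items))
  prob_blank <- rep_len(prob_blank, nrow(items))
  flip <- function(k) if (k == "COMPATIBLE") "INCOMPATIBLE" else "COMPATIBLE"
  withr_seed(seed, {
    rows <- lapply(seq_len(nrow(items)), function(i) {
      blank <- stats::runif(n_participants) < prob_blank[i]
      correct <- stats::runif(n_participants) < prob_correct[i]
      ans <- ifelse(blank, "BLANK",
                    ifelse(correct, items$key[i], flip(items$key[i])))
      data.frame(participant_id = sprintf("p%04d",
                                          seq_len(n_participants)),
                 item_id = items$item_id[i], answer = ans,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

# run code under a local RNG state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
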