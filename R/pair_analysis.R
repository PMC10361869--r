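#' Percentage with one decimal, half-up
#'
#' The reporting style used throughout the cohort summaries: percentages
#' printed to one decimal with commercial rounding.
#'
#' @param numerator,denominator counts; `denominator` must be positive.
#' @return numeric scalar, `100 * numerator / denominator` rounded half-up
#'   to one decimal.
#' @examples
#' percent1(64, 104)  # 61.5
#' percent1(18, 130)  # 13.8
#' @export
percent1 <- function(numerator, denominator) {
  if (any(denominator <= 0)) abort("percent1: denominator must be > 0")
  round_half_up(100 * numerator / denominator, 1)
}

#' Classify every co-administered pair of a cohort
#'
#' Runs the per-lumen co-administration analysis over all charts, resolves
#' every same-lumen simultaneous pair through the knowledge base, and
#' collects the findings. Only charts meeting the inclusion criterion
#' (>= 3 drugs simultaneously via one lumen, see [meets_inclusion()])
#' contribute findings. A pair occurring in several patients (or on several
#' lumens of one patient) is counted once per (patient, lumen, pair)
#' occurrence; `distinct_pairs = TRUE` switches to counting each pair at
#' most once per patient.
#'
#' @param charts named list of [patient_chart()] objects.
#' @param kb a [knowledge_base()].
#' @param policy a [resolution_policy()].
#' @param distinct_pairs collapse multiple lumens of one patient to one
#'   finding per pair.
#' @param slack co-administration padding in minutes, see
#'   [simultaneous_sets()]; default 0.
#' @return list with
#'   * `findings`: data frame `patient_id, lumen, drug_a, drug_b,
#'     classification, reason` over all co-administered pairs (all three
#'     classifications; `NOT_EVALUABLE` findings are kept, never silently
#'     dropped);
#'   * `summary`: a `cohort_summary` list with `n_admitted`, `n_included`,
#'     `n_patients_with_incompatibility`, `n_incompatible_combinations`,
#'     `n_not_evaluable`, and `per_patient_counts` (incompatible findings
#'     per included patient, zeros included).
#' @export
analyze_cohort <- function(charts, kb, policy = resolution_policy(),
                           distinct_pairs = FALSE, slack = 0) {
  rows <- list()
  included <- character()
  for (ch in charts) {
    if (!meets_inclusion(ch)$included) next
    included <- c(included, ch$patient_id)
    for (lum in seq_len(ch$catheter$n_lumens)) {
      pr <- coadministered_pairs(ch, lum, slack = slack)
      for (i in seq_len(nrow(pr))) {
        v <- resolve_pair(kb, pr$drug_a[i], pr$drug_b[i], policy)
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = ch$patient_id, lumen = lum,
          drug_a = v$drug_a, drug_b = v$drug_b,
          classification = v$classification, reason = v$reason,
          stringsAsFactors = FALSE)
      }
    }
  }
  findings <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), lumen = integer(),
               drug_a = character(), drug_b = character(),
               classification = character(), reason = character(),
               stringsAsFactors = FALSE)
  if (distinct_pairs && nrow(findings)) {
    key <- paste(findings$patient_id,
                 pair_key(findings$drug_a, findings$drug_b))
    findings <- findings[!duplicated(key), , drop = FALSE]
  }
  findings <- findings[order(findings$patient_id, findings$lumen,
                             findings$drug_a, findings$drug_b), ,
                       drop = FALSE]
  rownames(findings) <- NULL

  inc <- findings[findings$classification == "INCOMPATIBLE", , drop = FALSE]
  per_patient <- table(factor(inc$patient_id, levels = sort(included)))
  summary <- structure(list(
    n_admitted = length(charts),
    n_included = length(included),
    n_patients_with_incompatibility = sum(per_patient > 0),
    n_incompatible_combinations = nrow(inc),
    n_not_evaluable = sum(findings$classification == "NOT_EVALUABLE"),
    per_patient_counts = stats::setNames(as.integer(per_patient),
                                         names(per_patient))),
    class = "cohort_summary")
  list(findings = findings, summary = summary)
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<cohort_summary> %d admitted, %d included; %d incompatible ",
           "combinations in %d patients (%s%%); %d not evaluable\n"),
    x$n_admitted, x$n_included, x$n_incompatible_combinations,
    x$n_patients_with_incompatibility,
    if (x$n_included > 0)
      format(percent1(x$n_patients_with_incompatibility, x$n_included))
    else "-",
    x$n_not_evaluable))
  invisible(x)
}

incompatible_findings <- function(findings)
  findings[findings$classification == "INCOMPATIBLE", , drop = FALSE]

#' Frequency table of drugs involved in incompatible combinations
#'
#' Every incompatible finding increments both member drugs, so the counts
#' sum to twice the number of incompatible findings; the percentage
#' denominator is the number of incompatible findings. Rows are sorted by
#' count descending, ties alphabetical.
#'
#' @param findings the findings data frame from [analyze_cohort()].
#' @return data frame `drug, n, percent` (percent half-up to one decimal).
#' @export
drug_frequency_table <- function(findings) {
  inc <- incompatible_findings(findings)
  if (nrow(inc) == 0)
    return(data.frame(drug = character(), n = integer(),
                      percent = numeric()))
  counts <- table(c(inc$drug_a, inc$drug_b))
  df <- data.frame(drug = names(counts), n = as.integer(counts),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$n, df$drug), , drop = FALSE]
  df$percent <- percent1(df$n, nrow(inc))
  rownames(df) <- NULL
  df
}

#' Cross-table of definitely incompatible drug pairs
#'
#' Symmetric drug-by-drug matrix of incompatible-pair occurrence counts.
#' Only findings with a definite `INCOMPATIBLE` verdict enter;
#' `NOT_EVALUABLE` pairs are excluded (they are reported separately).
#'
#' @param findings the findings data frame from [analyze_cohort()].
#' @return symmetric integer matrix with zero diagonal; its upper-triangle
#'   sum equals the number of incompatible findings.
#' @export
cross_table <- function(findings) {
  inc <- incompatible_findings(findings)
  drugs <- sort(unique(c(inc$drug_a, inc$drug_b)))
  m <- matrix(0L, length(drugs), length(drugs),
              dimnames = list(drugs, drugs))
  for (i in seq_len(nrow(inc))) {
    a <- inc$drug_a[i]; b <- inc$drug_b[i]
    m[a, b] <- m[a, b] + 1L
    m[b, a] <- m[b, a] + 1L
  }
  m
}

#' Patient-level incompatibility statistics
#'
#' @param findings the findings data frame from [analyze_cohort()].
#' @param included_ids character vector of included patient ids; patients
#'   with zero incompatible findings enter the statistics with count 0.
#' @param quantile_type quantile convention as in [stats::quantile()];
#'   default 6, the weighted-average-at-`(n+1)p` definition used by common
#'   commercial statistics software.
#' @return list `n_with_incompatibility, median, q25, q75, counts`.
#' @export
patient_level_stats <- function(findings, included_ids, quantile_type = 6) {
  inc <- incompatible_findings(findings)
  counts <- table(factor(inc$patient_id, levels = sort(included_ids)))
  counts <- stats::setNames(as.integer(counts), names(counts))
  if (length(counts) == 0)
    return(list(n_with_incompatibility = 0L, median = NA_real_,
                q25 = NA_real_, q75 = NA_real_, counts = counts))
  q <- stats::quantile(counts, c(0.25, 0.5, 0.75), type = quantile_type,
                       names = FALSE)
  list(n_with_incompatibility = sum(counts > 0),
       median = q[2], q25 = q[1], q75 = q[3], counts = counts)
}
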