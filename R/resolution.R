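#' Construct a resolution policy
#'
#' The policy codifies how verdicts from several evidence sources are
#' combined into one final classification per drug pair.
#'
#' Two modes are provided. `STRICT_CONSENSUS` (the default) consults every
#' source: if all data-bearing sources agree, that classification wins; any
#' disagreement between data-bearing sources yields `NOT_EVALUABLE` with
#' reason `CONFLICT`. A source that contradicts itself
#' (`CONFLICTING_WITHIN_SOURCE`) also taints the pair as conflicting —
#' unless `incompatible_dominates` is on and every data-bearing source says
#' `INCOMPATIBLE`, in which case the pair is classified `INCOMPATIBLE`: a
#' safety tool should fail toward "incompatible". `PRECEDENCE_FIRST` lets
#' the first data-bearing source in `source_order` decide alone.
#'
#' @param source_order character; sources in precedence order, no
#'   duplicates. Defaults to [builtin_sources()].
#' @param mode `"STRICT_CONSENSUS"` or `"PRECEDENCE_FIRST"`.
#' @param incompatible_dominates logical; see Details. Default `TRUE`.
#' @return a `resolution_policy` object.
#' @export
resolution_policy <- function(source_order = builtin_sources(),
                              mode = c("STRICT_CONSENSUS",
                                       "PRECEDENCE_FIRST"),
                              incompatible_dominates = TRUE) {
  mode <- match.arg(mode)
  source_order <- as.character(source_order)
  if (anyDuplicated(source_order))
    abort("policy: duplicate source in source_order")
  if (length(source_order) == 0)
    abort("policy: source_order must name at least one source")
  structure(list(source_order = source_order, mode = mode,
                 incompatible_dominates = isTRUE(incompatible_dominates)),
            class = "resolution_policy")
}

#' Read a resolution policy from a YAML or JSON file
#'
#' The file holds `source_order`, `mode`, and `incompatible_dominates`;
#' missing fields fall back to the defaults of [resolution_policy()].
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return a [resolution_policy()].
#' @export
load_policy <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  resolution_policy(
    source_order = obj$source_order %||% builtin_sources(),
    mode = obj$mode %||% "STRICT_CONSENSUS",
    incompatible_dominates = obj$incompatible_dominates %||% TRUE)
}

# core combiner: named verdict vector (one entry per source, in policy
# order) -> classification/reason + which entries decided
resolve_verdicts <- function(verdicts, policy) {
  verdicts <- verdicts[policy$source_order]
  data_bearing <- verdicts %in% c("COMPATIBLE", "INCOMPATIBLE")
  conflicted <- verdicts == "CONFLICTING_WITHIN_SOURCE"
  V <- verdicts[data_bearing]

  if (policy$mode == "PRECEDENCE_FIRST") {
    if (any(data_bearing)) {
      i <- which(data_bearing)[1]
      used <- seq_along(verdicts) == i
      return(list(classification = unname(verdicts[i]),
                  reason = "SINGLE_SOURCE", used = used))
    }
    # fall through to the no-data / conflict-only outcomes below
  }

  used <- data_bearing | conflicted
  if (length(V) == 0) {
    if (any(conflicted))
      return(list(classification = "NOT_EVALUABLE", reason = "CONFLICT",
                  used = used))
    return(list(classification = "NOT_EVALUABLE", reason = "NO_DATA",
                used = rep(TRUE, length(verdicts))))
  }
  if (all(c("COMPATIBLE", "INCOMPATIBLE") %in% V))
    return(list(classification = "NOT_EVALUABLE", reason = "CONFLICT",
                used = used))
  cls <- V[1]
  agree_reason <- if (length(V) == 1) "SINGLE_SOURCE" else "AGREEMENT"
  if (any(conflicted)) {
    if (cls == "INCOMPATIBLE" && policy$incompatible_dominates)
      return(list(classification = "INCOMPATIBLE", reason = agree_reason,
                  used = used))
    return(list(classification = "NOT_EVALUABLE", reason = "CONFLICT",
                used = used))
  }
  list(classification = unname(cls), reason = agree_reason, used = used)
}

#' Resolve the final verdict for one drug pair
#'
#' Consults every source of the policy's `source_order` via [kb_lookup()]
#' and combines the per-source verdicts into a final classification with an
#' auditable evidence trail. The result is a pure function of
#' `(kb, pair, policy)` and symmetric in the two drugs.
#'
#' @param kb a [knowledge_base()].
#' @param a,b drug names (normalized through the lexicon); distinct.
#' @param policy a [resolution_policy()].
#' @return a `pair_verdict`: list with `classification` (`COMPATIBLE`,
#'   `INCOMPATIBLE`, or `NOT_EVALUABLE`), `reason` (`AGREEMENT`,
#'   `SINGLE_SOURCE`, `CONFLICT`, or `NO_DATA`), and `trail`, a data frame
#'   of every consulted source with its verdict and whether it contributed
#'   to the decision (all sources are recorded even in `PRECEDENCE_FIRST`
#'   mode, for auditability).
#' @examples
#' kb <- fixture_kb()
#' resolve_pair(kb, "piperacillin/tazobactam", "pantoprazole")
#' @export
resolve_pair <- function(kb, a, b, policy = resolution_policy()) {
  a <- normalize_drug_name(a, kb$lexicon)
  b <- normalize_drug_name(b, kb$lexicon)
  if (a == b)
    abort("pair of a drug with itself is undefined ('%s')", a)
  missing <- setdiff(policy$source_order, kb$sources)
  if (length(missing))
    abort("policy consults unregistered source(s): %s",
          paste(missing, collapse = ", "))
  verdicts <- kb_pair_verdicts(kb, a, b, policy$source_order)
  res <- resolve_verdicts(verdicts, policy)
  p <- pair_sort(a, b)
  structure(list(
    drug_a = p$a, drug_b = p$b,
    classification = res$classification,
    reason = res$reason,
    trail = data.frame(source = policy$source_order,
                       verdict = unname(verdicts),
                       used = res$used,
                       stringsAsFactors = FALSE)),
    class = "pair_verdict")
}

#' @export
print.pair_verdict <- function(x, ...) {
  cat(sprintf("<%s + %s> %s (%s)\n", x$drug_a, x$drug_b,
              x$classification, x$reason))
  for (i in seq_len(nrow(x$trail)))
    cat(sprintf("  %-9s %-26s%s\n", x$trail$source[i], x$trail$verdict[i],
                if (x$trail$used[i]) "" else "  [consulted, unused]"))
  invisible(x)
}

#' Exhaustive policy truth table
#'
#' Enumerates every combination of per-source verdicts over the policy's
#' sources (4^k tuples for k sources) and records the resolved
#' classification and reason for each. Intended as an audit and debugging
#' aid: the full decision surface of a policy on one page.
#'
#' @param policy a [resolution_policy()].
#' @return data frame with one column per source plus `classification` and
#'   `reason`.
#' @export
classify_policy_table <- function(policy = resolution_policy()) {
  k <- length(policy$source_order)
  grid <- expand.grid(rep(list(source_verdicts()), k),
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- policy$source_order
  out <- t(vapply(seq_len(nrow(grid)), function(i) {
    v <- stats::setNames(as.character(grid[i, ]), policy$source_order)
    r <- resolve_verdicts(v, policy)
    c(r$classification, r$reason)
  }, character(2)))
  grid$classification <- out[, 1]
  grid$reason <- out[, 2]
  grid
}
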