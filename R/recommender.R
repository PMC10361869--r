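#' Recommender configuration
#'
#' Tunable operating parameters of the four-step avoidance engine.
#'
#' @param flush_gap minutes of carrier-solution flush inserted between two
#'   sequentially administered incompatible drugs, and padding around a
#'   pause window (default 5).
#' @param non_pausable_tags class tags whose continuous infusions must
#'   never be interrupted (default `"catecholamine"`: an interruption, or
#'   the bolus on resume, has immediate hemodynamic consequences).
#' @param max_horizon latest allowed event end after rescheduling, minutes.
#' @param bolus_cap passed through to chart revalidation.
#' @param backtrack_limit largest node count for which the exact
#'   backtracking lumen-assignment search is attempted after the greedy
#'   pass fails (default 12).
#' @return a `recommender_config` list.
#' @export
recommender_config <- function(flush_gap = 5,
                               non_pausable_tags = "catecholamine",
                               max_horizon = 1600, bolus_cap = 15,
                               backtrack_limit = 12) {
  structure(list(flush_gap = flush_gap,
                 non_pausable_tags = as.character(non_pausable_tags),
                 max_horizon = max_horizon, bolus_cap = bolus_cap,
                 backtrack_limit = as.integer(backtrack_limit)),
            class = "recommender_config")
}

intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# does any central event of drug x overlap one of drug y (same lumen only
# when same_lumen, else on any lumen)?
drugs_overlap <- function(chart, x, y, same_lumen = TRUE) {
  ex <- central_events(chart); ey <- ex[ex$drug == y, , drop = FALSE]
  ex <- ex[ex$drug == x, , drop = FALSE]
  for (i in seq_len(nrow(ex))) for (j in seq_len(nrow(ey))) {
    if (same_lumen && ex$lumen[i] != ey$lumen[j]) next
    if (intervals_overlap(ex$start_min[i], ex$end_min[i],
                          ey$start_min[j], ey$end_min[j])) return(TRUE)
  }
  FALSE
}

drug_is_continuous <- function(chart, drug) {
  ev <- central_events(chart)
  any(ev$mode[ev$drug == drug] == "CONTINUOUS")
}

drug_pausable <- function(drug, lexicon, config) {
  !any(drug_tags(lexicon, drug) %in% config$non_pausable_tags)
}

# reserved lumen a drug is pinned to (its class tags include the lumen's
# purpose), or NA
pinned_lumen <- function(drug, catheter, lexicon) {
  if (!length(catheter$reserved)) return(NA_integer_)
  tags <- drug_tags(lexicon, drug)
  hit <- which(catheter$reserved %in% tags)
  if (length(hit)) as.integer(names(catheter$reserved)[hit[1]])
  else NA_integer_
}

#' Build the incompatibility graph of one patient
#'
#' Nodes are the patient's central-venous drugs; edges are the observed
#' problems — pairs with an `INCOMPATIBLE` verdict co-scheduled on the same
#' lumen (taken from the findings). The graph additionally carries, as the
#' `conflicts` graph attribute, every *potential* conflict: incompatible
#' pairs whose events overlap in time regardless of lumen. Relocation must
#' respect the potential conflicts, since moving two incompatible drugs
#' onto a shared lumen would create a new problem.
#'
#' @param chart a [patient_chart()].
#' @param findings findings data frame (from [analyze_cohort()]); rows of
#'   other patients are ignored.
#' @param kb,policy knowledge base and policy used to resolve pairs not
#'   present in the findings (pairs currently on different lumens).
#' @return an [igraph::graph] with vertex attributes `mode`, `pausable`,
#'   `pinned` and graph attribute `conflicts` (data frame `drug_a,
#'   drug_b`).
#' @export
build_graph <- function(chart, findings, kb, policy = resolution_policy()) {
  drugs <- sort(unique(central_events(chart)$drug))
  f <- findings[findings$patient_id == chart$patient_id &
                  findings$classification == "INCOMPATIBLE", , drop = FALSE]
  edges <- unique(f[, c("drug_a", "drug_b")])
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(drugs), name = drugs)
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(edges$drug_a, edges$drug_b))
  cfg <- recommender_config()
  igraph::V(g)$mode <- ifelse(
    vapply(drugs, drug_is_continuous, TRUE, chart = chart),
    "CONTINUOUS", "INTERMITTENT")
  igraph::V(g)$pausable <-
    vapply(drugs, drug_pausable, TRUE, lexicon = kb$lexicon, config = cfg)
  igraph::V(g)$pinned <-
    vapply(drugs, pinned_lumen, 1L, catheter = chart$catheter,
           lexicon = kb$lexicon)
  conf <- list()
  if (length(drugs) > 1) {
    idx <- utils::combn(length(drugs), 2)
    for (j in seq_len(ncol(idx))) {
      a <- drugs[idx[1, j]]; b <- drugs[idx[2, j]]
      if (!drugs_overlap(chart, a, b, same_lumen = FALSE)) next
      v <- resolve_pair(kb, a, b, policy)
      if (v$classification == "INCOMPATIBLE")
        conf[[length(conf) + 1]] <- c(a, b)
    }
  }
  conflicts <- if (length(conf)) {
    m <- do.call(rbind, conf)
    data.frame(drug_a = m[, 1], drug_b = m[, 2], stringsAsFactors = FALSE)
  } else data.frame(drug_a = character(), drug_b = character())
  g <- igraph::set_graph_attr(g, "conflicts", conflicts)
  g
}

## ---- constrained lumen assignment ------------------------------------

#' Assign drugs to lumens so no conflicting pair shares one
#'
#' Constrained graph coloring: lumens are the colors, conflicting pairs
#' (incompatible and time-overlapping) must get different lumens, and each
#' drug may only use its allowed lumens (pinned drugs have exactly one).
#' Solved greedily largest-conflict-degree-first with an exact backtracking
#' fallback for small instances; the backtracking search is complete, so
#' for instances within `backtrack_limit` nodes a `NULL` return proves
#' infeasibility.
#'
#' @param drugs character vector of drug names.
#' @param conflicts data frame `drug_a, drug_b` of pairs that must be
#'   separated.
#' @param allowed named list mapping each drug to its allowed lumen ids.
#' @param backtrack_limit see [recommender_config()].
#' @return named integer vector drug -> lumen, or `NULL` when no
#'   assignment exists.
#' @export
lumen_assignment <- function(drugs, conflicts, allowed,
                             backtrack_limit = 12) {
  drugs <- sort(drugs)
  if (!all(drugs %in% names(allowed)))
    abort("lumen_assignment: every drug needs an allowed-lumen set")
  if (any(lengths(allowed[drugs]) == 0)) return(NULL)
  nbrs <- stats::setNames(rep(list(character()), length(drugs)), drugs)
  for (i in seq_len(nrow(conflicts))) {
    a <- conflicts$drug_a[i]; b <- conflicts$drug_b[i]
    if (a == b || !a %in% drugs || !b %in% drugs) next
    nbrs[[a]] <- union(nbrs[[a]], b)
    nbrs[[b]] <- union(nbrs[[b]], a)
  }
  deg <- lengths(nbrs)
  order_ix <- order(-deg, drugs)  # largest degree first, ties by name
  ordered <- drugs[order_ix]

  greedy <- stats::setNames(rep(NA_integer_, length(drugs)), drugs)
  ok <- TRUE
  for (d in ordered) {
    taken <- greedy[nbrs[[d]]]
    free <- setdiff(sort(allowed[[d]]), taken[!is.na(taken)])
    if (!length(free)) { ok <- FALSE; break }
    greedy[d] <- free[1]
  }
  if (ok) return(greedy)
  if (length(drugs) > backtrack_limit) return(NULL)

  assign <- stats::setNames(rep(NA_integer_, length(drugs)), drugs)
  solve <- function(k) {
    if (k > length(ordered)) return(TRUE)
    d <- ordered[k]
    taken <- assign[nbrs[[d]]]
    for (lum in sort(allowed[[d]])) {
      if (lum %in% taken[!is.na(taken)]) next
      assign[d] <<- lum
      if (solve(k + 1)) return(TRUE)
      assign[d] <<- NA_integer_
    }
    FALSE
  }
  if (solve(1)) assign else NULL
}

allowed_lumens <- function(drugs, catheter, lexicon) {
  res_ids <- as.integer(names(catheter$reserved))
  free <- setdiff(seq_len(catheter$n_lumens), res_ids)
  out <- list()
  for (d in drugs) {
    pin <- pinned_lumen(d, catheter, lexicon)
    out[[d]] <- if (!is.na(pin)) pin
    else sort(c(free,
                res_ids[catheter$reserved %in% drug_tags(lexicon, d)]))
  }
  out
}

## ---- step feasibility predicates -------------------------------------

#' Step 1 — administer sequentially
#'
#' Feasible only when neither member of the pair runs as a continuous
#' infusion (a continuous infusion cannot simply be scheduled "after" the
#' other drug) and the patient is not fluid-restricted (sequential
#' administration needs a flush between the two drugs). The proposed shift
#' is minimal: on each lumen where the pair overlaps, the later-starting
#' member is moved after the earlier member's end plus the flush gap, the
#' smallest shift that removes the overlap without creating a new
#' incompatible overlap on that lumen and without running past the
#' horizon.
#'
#' @param chart a [patient_chart()].
#' @param pair character vector of the two drug names.
#' @param kb,policy for checking that a shift creates no new incompatible
#'   overlap.
#' @param config a [recommender_config()].
#' @return list with `feasible` and, when feasible, `shifts` (data frame
#'   `drug, lumen, delta_min`).
#' @export
try_sequential <- function(chart, pair, kb,
                           policy = resolution_policy(),
                           config = recommender_config()) {
  infeasible <- list(feasible = FALSE, shifts = NULL)
  if (chart$fluid_restricted) return(infeasible)
  a <- pair[1]; b <- pair[2]
  if (drug_is_continuous(chart, a) || drug_is_continuous(chart, b))
    return(infeasible)
  lumens <- pair_conflict_lumens(chart, a, b)
  if (!length(lumens)) return(list(feasible = TRUE, shifts = NULL))
  shifts <- list()
  work <- chart
  for (lum in lumens) {
    s <- best_shift_on_lumen(work, lum, a, b, kb, policy, config)
    if (is.null(s)) return(infeasible)
    shifts[[length(shifts) + 1]] <- s
    work <- apply_plan(work, list(type = "shift", drug = s$drug,
                                  lumen = s$lumen, delta_min = s$delta_min),
                       config)
  }
  list(feasible = TRUE, shifts = do.call(rbind, shifts))
}

pair_conflict_lumens <- function(chart, a, b) {
  ev <- central_events(chart)
  lums <- sort(unique(ev$lumen[ev$drug %in% c(a, b)]))
  keep <- logical(length(lums))
  for (k in seq_along(lums)) {
    sub <- ev[ev$lumen == lums[k], , drop = FALSE]
    ea <- sub[sub$drug == a, , drop = FALSE]
    eb <- sub[sub$drug == b, , drop = FALSE]
    keep[k] <- any(outer(seq_len(nrow(ea)), seq_len(nrow(eb)),
                         Vectorize(function(i, j)
                           intervals_overlap(ea$start_min[i], ea$end_min[i],
                                             eb$start_min[j],
                                             eb$end_min[j]))))
  }
  lums[keep]
}

# minimal right-shift of one pair member on one lumen; NULL if none works
best_shift_on_lumen <- function(chart, lum, a, b, kb, policy, config) {
  ev <- central_events(chart, lum)
  # move the later-starting member; on a tie, the lexicographically later
  first_start <- vapply(c(a, b), function(d)
    min(ev$start_min[ev$drug == d]), 0)
  movers <- c(a, b)[order(-first_start, c(a, b) != sort(c(a, b))[2])]
  for (m in movers) {
    em <- ev[ev$drug == m, , drop = FALSE]
    eo <- ev[ev$drug != m, , drop = FALSE]  # all other drugs' events:
    # every overlap-free placement starts right after some event's end
    cand <- sort(unique(as.vector(
      outer(eo$end_min + config$flush_gap, em$start_min, `-`))))
    cand <- cand[cand > 0]
    for (delta in cand) {
      if (max(em$end_min) + delta > config$max_horizon) break
      if (shift_is_clean(ev, m, delta, kb, policy)) {
        return(data.frame(drug = m, lumen = lum, delta_min = delta,
                          stringsAsFactors = FALSE))
      }
    }
  }
  NULL
}

# after shifting drug m by delta on this lumen, does m overlap any drug it
# is incompatible with?
shift_is_clean <- function(ev, m, delta, kb, policy) {
  em <- ev[ev$drug == m, , drop = FALSE]
  em$start_min <- em$start_min + delta
  em$end_min <- em$end_min + delta
  others <- setdiff(unique(ev$drug), m)
  for (z in others) {
    ez <- ev[ev$drug == z, , drop = FALSE]
    hit <- FALSE
    for (i in seq_len(nrow(em))) for (j in seq_len(nrow(ez)))
      if (intervals_overlap(em$start_min[i], em$end_min[i],
                            ez$start_min[j], ez$end_min[j])) hit <- TRUE
    if (hit &&
        resolve_pair(kb, m, z, policy)$classification == "INCOMPATIBLE")
      return(FALSE)
  }
  TRUE
}

#' Step 2 — use another lumen
#'
#' Seeks a reassignment of the patient's central-venous drugs to the
#' catheter's existing lumens such that no incompatible pair shares a
#' lumen while overlapping in time, pinned drugs keep their reserved
#' lumens, and reserved lumens accept only drugs of their purpose. See
#' [lumen_assignment()] for the solver.
#'
#' @param graph an incompatibility graph from [build_graph()].
#' @param catheter a [catheter_config()].
#' @param lexicon the drug lexicon (for purpose tags).
#' @param config a [recommender_config()].
#' @return list with `feasible` and `assignment` (named drug -> lumen).
#' @export
try_relocate <- function(graph, catheter, lexicon,
                         config = recommender_config()) {
  drugs <- igraph::V(graph)$name
  conflicts <- igraph::graph_attr(graph, "conflicts")
  allowed <- allowed_lumens(drugs, catheter, lexicon)
  asg <- lumen_assignment(drugs, conflicts, allowed,
                          config$backtrack_limit)
  list(feasible = !is.null(asg), assignment = asg)
}

#' Step 3 — take a break
#'
#' Feasible only for the asymmetric conflict the step was designed for: a
#' pausable continuous infusion meeting a non-continuous drug. The plan
#' interrupts the continuous infusion, flushes, runs the short infusion,
#' flushes again, and resumes — i.e., the short drug's administration
#' windows, padded by the flush gap on both sides, are carved out of the
#' continuous infusion. Fluid-restricted patients get no flush-adding
#' plan.
#'
#' @param chart a [patient_chart()].
#' @param pair character vector of the two drug names.
#' @param lexicon the drug lexicon (pausability is tag-based:
#'   catecholamines are never paused by default).
#' @param config a [recommender_config()].
#' @return list with `feasible` and, when feasible, `plan` (list with the
#'   paused `drug`, `lumen`, and carve `windows`).
#' @export
try_pause <- function(chart, pair, lexicon,
                      config = recommender_config()) {
  infeasible <- list(feasible = FALSE, plan = NULL)
  if (chart$fluid_restricted) return(infeasible)
  cont <- vapply(pair, drug_is_continuous, TRUE, chart = chart)
  if (sum(cont) != 1) return(infeasible)
  long <- pair[cont]; short <- pair[!cont]
  if (!drug_pausable(long, lexicon, config)) return(infeasible)
  plans <- list()
  for (lum in pair_conflict_lumens(chart, long, short)) {
    ev <- central_events(chart, lum)
    es <- ev[ev$drug == short, , drop = FALSE]
    windows <- data.frame(
      start_min = pmax(0, es$start_min - config$flush_gap),
      end_min = es$end_min + config$flush_gap)
    plans[[length(plans) + 1]] <-
      list(drug = long, lumen = lum, windows = windows)
  }
  if (!length(plans)) return(list(feasible = TRUE, plan = NULL))
  list(feasible = TRUE, plan = plans)
}

## ---- plan application ------------------------------------------------

#' Apply one plan delta to a chart
#'
#' Plan deltas are the declarative schedule or lumen changes attached to a
#' recommendation: `shift` (move one drug's events on one lumen right by
#' `delta_min`), `reassign` (move each drug's central-venous events to its
#' assigned lumen), `pause` (carve windows out of a continuous infusion),
#' `expand` (replace the catheter by one with more lumens, then
#' reassign).
#'
#' @param chart a [patient_chart()].
#' @param plan a plan-delta list with a `type` field.
#' @param config a [recommender_config()] (validation limits).
#' @return the transformed [patient_chart()].
#' @export
apply_plan <- function(chart, plan, config = recommender_config()) {
  ev <- chart$events
  catheter <- chart$catheter
  if (plan$type == "shift") {
    sel <- ev$route == "CENTRAL_VENOUS" & ev$drug == plan$drug &
      ev$lumen == plan$lumen
    ev$start_min[sel] <- ev$start_min[sel] + plan$delta_min
    ev$end_min[sel] <- ev$end_min[sel] + plan$delta_min
  } else if (plan$type == "reassign") {
    for (d in names(plan$assignment)) {
      sel <- ev$route == "CENTRAL_VENOUS" & ev$drug == d
      ev$lumen[sel] <- plan$assignment[[d]]
    }
  } else if (plan$type == "pause") {
    for (p in plan$plans) {
      sel <- which(ev$route == "CENTRAL_VENOUS" & ev$drug == p$drug &
                     ev$lumen == p$lumen)
      pieces <- carve_intervals(ev[sel, , drop = FALSE], p$windows)
      ev <- rbind(ev[-sel, , drop = FALSE], pieces)
    }
  } else if (plan$type == "expand") {
    catheter <- catheter_config(plan$n_lumens, catheter$reserved)
    for (d in names(plan$assignment)) {
      sel <- ev$route == "CENTRAL_VENOUS" & ev$drug == d
      ev$lumen[sel] <- plan$assignment[[d]]
    }
  } else abort("unknown plan type '%s'", plan$type)
  patient_chart(chart$patient_id, catheter, ev,
                fluid_restricted = chart$fluid_restricted,
                bolus_cap = config$bolus_cap,
                max_horizon = config$max_horizon)
}

# subtract a union of windows from a set of events, splitting as needed
carve_intervals <- function(events, windows) {
  out <- list()
  for (i in seq_len(nrow(events))) {
    segs <- data.frame(start = events$start_min[i], end = events$end_min[i])
    for (j in seq_len(nrow(windows))) {
      ws <- windows$start_min[j]; we <- windows$end_min[j]
      nxt <- list()
      for (k in seq_len(nrow(segs))) {
        s <- segs$start[k]; e <- segs$end[k]
        if (!intervals_overlap(s, e, ws, we)) {
          nxt[[length(nxt) + 1]] <- c(s, e)
        } else {
          if (s < ws) nxt[[length(nxt) + 1]] <- c(s, ws)
          if (e > we) nxt[[length(nxt) + 1]] <- c(we, e)
        }
      }
      segs <- if (length(nxt)) {
        m <- do.call(rbind, nxt)
        data.frame(start = m[, 1], end = m[, 2])
      } else data.frame(start = numeric(), end = numeric())
    }
    for (k in seq_len(nrow(segs))) {
      piece <- events[i, , drop = FALSE]
      piece$start_min <- segs$start[k]
      piece$end_min <- segs$end[k]
      out[[length(out) + 1]] <- piece
    }
  }
  if (length(out)) do.call(rbind, out) else events[0, , drop = FALSE]
}

## ---- the four-step engine --------------------------------------------

step_names <- function() c("Administer sequentially", "Use another lumen",
                           "Take a break", "Use catheters with more lumens")

#' Recommend avoidance strategies for a patient's incompatible pairs
#'
#' Deterministic escalation per incompatible pair, always choosing the
#' lowest feasible step: Step 1 "Administer sequentially" when both drugs
#' are movable short administrations; else Step 2 "Use another lumen" when
#' a reassignment of drugs to the existing lumens separates every
#' remaining conflict (one shared relocation covers all pairs it resolves
#' in a single recommendation); else Step 3 "Take a break" when a pausable
#' continuous infusion meets a short one; else Step 4 "Use catheters with
#' more lumens", annotated with the minimal lumen count that admits a
#' conflict-free assignment. Plans are applied cumulatively while
#' escalating, so applying every returned plan delta in order leaves the
#' chart free of incompatible same-lumen simultaneous pairs.
#'
#' @param chart a [patient_chart()].
#' @param findings findings data frame from [analyze_cohort()] (other
#'   patients' rows are ignored).
#' @param kb a [knowledge_base()].
#' @param policy a [resolution_policy()].
#' @param config a [recommender_config()].
#' @return list of `recommendation` objects (fields `patient_id`, `pairs`,
#'   `step`, `step_name`, `rationale`, `plan`); the transformed chart is
#'   attached as attribute `transformed_chart`.
#' @export
recommend <- function(chart, findings, kb, policy = resolution_policy(),
                      config = recommender_config()) {
  f <- findings[findings$patient_id == chart$patient_id &
                  findings$classification == "INCOMPATIBLE", , drop = FALSE]
  pairs <- unique(f[order(f$drug_a, f$drug_b), c("drug_a", "drug_b"),
                    drop = FALSE])
  recs <- list()
  cur <- chart
  new_rec <- function(pairs, step, rationale, plan)
    structure(list(patient_id = chart$patient_id, pairs = pairs,
                   step = step, step_name = step_names()[step],
                   rationale = rationale, plan = plan),
              class = "recommendation")

  pending <- list()
  for (i in seq_len(nrow(pairs))) {
    pr <- c(pairs$drug_a[i], pairs$drug_b[i])
    if (!length(pair_conflict_lumens(cur, pr[1], pr[2]))) next
    s1 <- try_sequential(cur, pr, kb, policy, config)
    if (s1$feasible) {
      plans <- lapply(seq_len(nrow(s1$shifts)), function(k)
        list(type = "shift", drug = s1$shifts$drug[k],
             lumen = s1$shifts$lumen[k],
             delta_min = s1$shifts$delta_min[k]))
      recs[[length(recs) + 1]] <- new_rec(
        list(pr), 1L,
        sprintf(paste0("both %s and %s are short administrations; give ",
                       "%s after %s with a %d-min flush"),
                pr[1], pr[2], s1$shifts$drug[1],
                setdiff(pr, s1$shifts$drug[1]), config$flush_gap),
        if (length(plans) == 1) plans[[1]]
        else list(type = "multi", plans = plans))
      for (p in plans) cur <- apply_plan(cur, p, config)
    } else {
      pending[[length(pending) + 1]] <- pr
    }
  }

  if (length(pending)) {
    g <- build_graph(cur, findings_from_chart(cur, kb, policy), kb, policy)
    rel <- try_relocate(g, cur$catheter, kb$lexicon, config)
    if (rel$feasible) {
      plan <- list(type = "reassign", assignment = as.list(rel$assignment))
      recs[[length(recs) + 1]] <- new_rec(
        pending, 2L,
        sprintf(paste0("a reassignment of drugs to the existing %d lumens ",
                       "separates every remaining incompatible pair"),
                cur$catheter$n_lumens),
        plan)
      cur <- apply_plan(cur, plan, config)
      pending <- list()
    }
  }

  still <- list()
  for (pr in pending) {
    if (!length(pair_conflict_lumens(cur, pr[1], pr[2]))) next
    s3 <- try_pause(cur, pr, kb$lexicon, config)
    if (s3$feasible) {
      plan <- list(type = "pause", plans = s3$plan)
      long <- pr[vapply(pr, drug_is_continuous, TRUE, chart = cur)]
      recs[[length(recs) + 1]] <- new_rec(
        list(pr), 3L,
        sprintf(paste0("interrupt the continuous %s infusion, flush, run ",
                       "%s, flush, resume"),
                long, setdiff(pr, long)),
        plan)
      cur <- apply_plan(cur, plan, config)
    } else still[[length(still) + 1]] <- pr
  }

  still <- Filter(function(pr)
    length(pair_conflict_lumens(cur, pr[1], pr[2])) > 0, still)
  if (length(still)) {
    g <- build_graph(cur, findings_from_chart(cur, kb, policy), kb, policy)
    sol <- minimal_lumen_solution(g, cur$catheter, kb$lexicon, config)
    plan <- list(type = "expand", n_lumens = sol$n_lumens,
                 assignment = as.list(sol$assignment))
    recs[[length(recs) + 1]] <- new_rec(
      still, 4L,
      sprintf(paste0("no feasible schedule or reassignment with %d lumens; ",
                     "a %d-lumen catheter admits a conflict-free ",
                     "assignment%s"),
              cur$catheter$n_lumens, sol$n_lumens,
              if (sol$relaxed_pinning)
                " (reserved-lumen pinning had to be relaxed)" else ""),
      plan)
    cur <- apply_plan(cur, plan, config)
  }
  attr(recs, "transformed_chart") <- cur
  recs
}

#' @export
print.recommendation <- function(x, ...) {
  cat(sprintf("<recommendation patient %s> Step %d: %s\n", x$patient_id,
              x$step, x$step_name))
  for (p in x$pairs) cat(sprintf("  %s + %s\n", p[1], p[2]))
  cat(sprintf("  %s\n", x$rationale))
  invisible(x)
}

# recompute this chart's incompatible same-lumen findings directly
findings_from_chart <- function(chart, kb, policy) {
  rows <- list()
  for (lum in seq_len(chart$catheter$n_lumens)) {
    pr <- coadministered_pairs(chart, lum)
    for (i in seq_len(nrow(pr))) {
      v <- resolve_pair(kb, pr$drug_a[i], pr$drug_b[i], policy)
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = chart$patient_id, lumen = lum,
        drug_a = v$drug_a, drug_b = v$drug_b,
        classification = v$classification, reason = v$reason,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), lumen = integer(),
               drug_a = character(), drug_b = character(),
               classification = character(), reason = character())
}

#' Count incompatible same-lumen simultaneous pairs of one chart
#'
#' The quantity every applied recommendation set must drive to zero.
#'
#' @param chart a [patient_chart()].
#' @param kb,policy knowledge base and resolution policy.
#' @return integer count of (lumen, pair) occurrences with an
#'   `INCOMPATIBLE` verdict.
#' @export
count_incompatible_overlaps <- function(chart, kb,
                                        policy = resolution_policy()) {
  f <- findings_from_chart(chart, kb, policy)
  sum(f$classification == "INCOMPATIBLE")
}

# smallest lumen count admitting a conflict-free assignment; pinning is
# relaxed as a last resort (two conflicting drugs pinned to one reserved
# lumen can never be separated otherwise)
minimal_lumen_solution <- function(graph, catheter, lexicon, config) {
  drugs <- igraph::V(graph)$name
  conflicts <- igraph::graph_attr(graph, "conflicts")
  upper <- length(drugs) + length(catheter$reserved) + 1L
  for (relax in c(FALSE, TRUE)) {
    for (n in seq(catheter$n_lumens + 1L, max(catheter$n_lumens + 1L,
                                              upper))) {
      cath <- catheter_config(n, catheter$reserved)
      allowed <- if (relax)
        stats::setNames(rep(list(seq_len(n)), length(drugs)), drugs)
      else allowed_lumens(drugs, cath, lexicon)
      asg <- lumen_assignment(drugs, conflicts, allowed,
                              config$backtrack_limit)
      if (!is.null(asg))
        return(list(n_lumens = n, assignment = asg,
                    relaxed_pinning = relax))
    }
  }
  abort("no conflict-free lumen assignment exists even without pinning")
}

#' Apply a list of recommendations to a chart
#'
#' Replays every recommendation's plan delta in order; equals the
#' transformed chart that [recommend()] attaches to its result.
#'
#' @param chart the original [patient_chart()].
#' @param recs list of recommendations from [recommend()].
#' @param config a [recommender_config()].
#' @return the transformed [patient_chart()].
#' @export
apply_recommendations <- function(chart, recs,
                                  config = recommender_config()) {
  cur <- chart
  for (r in recs) {
    plans <- if (identical(r$plan$type, "multi")) r$plan$plans
             else list(r$plan)
    for (p in plans) cur <- apply_plan(cur, p, config)
  }
  cur
}
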