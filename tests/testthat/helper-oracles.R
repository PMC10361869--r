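# Independent reference implementations used as oracles. These are written
# as plainly as possible (minute grids, exhaustive enumeration) and share no
# code with the package's algorithms.

# -- resolution oracle: spell the policy semantics out case by case --------
oracle_resolve <- function(verdicts, mode = "STRICT_CONSENSUS",
                           incompatible_dominates = TRUE) {
  data_bearing <- verdicts[verdicts == "COMPATIBLE" |
                             verdicts == "INCOMPATIBLE"]
  has_cw <- any(verdicts == "CONFLICTING_WITHIN_SOURCE")
  if (mode == "PRECEDENCE_FIRST" && length(data_bearing) > 0)
    return(c(data_bearing[1], "SINGLE_SOURCE"))
  if (length(data_bearing) == 0) {
    if (has_cw) return(c("NOT_EVALUABLE", "CONFLICT"))
    return(c("NOT_EVALUABLE", "NO_DATA"))
  }
  n_comp <- sum(data_bearing == "COMPATIBLE")
  n_inc <- sum(data_bearing == "INCOMPATIBLE")
  if (n_comp > 0 && n_inc > 0) return(c("NOT_EVALUABLE", "CONFLICT"))
  reason <- if (length(data_bearing) == 1) "SINGLE_SOURCE" else "AGREEMENT"
  if (has_cw) {
    if (n_inc > 0 && incompatible_dominates)
      return(c("INCOMPATIBLE", reason))
    return(c("NOT_EVALUABLE", "CONFLICT"))
  }
  c(data_bearing[1], reason)
}

# -- minute-grid oracle for lumen activity --------------------------------
# active drug set at each whole minute, from a brute-force per-minute scan
grid_active_sets <- function(events, horizon) {
  lapply(seq_len(horizon) - 1, function(t) {
    sort(unique(events$drug[events$start_min <= t & events$end_min > t]))
  })
}

# expand sweep-line windows back onto the minute grid
windows_to_grid <- function(windows, horizon) {
  out <- rep(list(character()), horizon)
  for (i in seq_len(nrow(windows))) {
    mins <- seq(windows$start_min[i], windows$end_min[i] - 1)
    for (t in mins + 1) out[[t]] <- windows$drugs[[i]]
  }
  out
}

# -- all-pairs interval-intersection oracle -------------------------------
brute_pairs <- function(events) {
  out <- character()
  n <- nrow(events)
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (events$drug[i] == events$drug[j]) next
    if (events$start_min[i] < events$end_min[j] &&
        events$start_min[j] < events$end_min[i]) {
      p <- sort(c(events$drug[i], events$drug[j]))
      out <- c(out, paste(p[1], p[2], sep = "|"))
    }
  }
  sort(unique(out))
}

# -- exhaustive lumen-assignment oracle -----------------------------------
# enumerate every assignment of drugs to lumens; feasible iff one respects
# both the allowed-lumen sets and the conflict separations
exhaustive_assignment_feasible <- function(drugs, conflicts, allowed,
                                           n_lumens) {
  grid <- expand.grid(rep(list(seq_len(n_lumens)), length(drugs)),
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- drugs
  ok <- rep(TRUE, nrow(grid))
  for (d in drugs) ok <- ok & grid[[d]] %in% allowed[[d]]
  for (i in seq_len(nrow(conflicts))) {
    a <- conflicts$drug_a[i]; b <- conflicts$drug_b[i]
    if (a %in% drugs && b %in% drugs) ok <- ok & grid[[a]] != grid[[b]]
  }
  any(ok)
}

# -- shared fixtures -------------------------------------------------------
mini_lexicon <- function() {
  drug_lexicon(c("metamizole", "furosemide", "piperacillin/tazobactam",
                 "pantoprazole", "sodium chloride"),
               synonyms = list("dipyrone", character(), "pip/tazo",
                               character(), "nacl 0.9%"),
               class_tags = list(character(), "diuretic", "anti-infective",
                                 character(), "electrolyte"),
               is_combination = c(FALSE, FALSE, TRUE, FALSE, FALSE))
}

random_events <- function(n, drugs, horizon = 200) {
  start <- sample(0:(horizon - 10), n, replace = TRUE)
  len <- sample(5:60, n, replace = TRUE)
  data.frame(drug = sample(drugs, n, replace = TRUE),
             route = "CENTRAL_VENOUS", lumen = 1L,
             start_min = start, end_min = pmin(start + len, horizon),
             mode = "INTERMITTENT", stringsAsFactors = FALSE)
}

chart_of <- function(events, n_lumens = 3,
                     reserved = c("1" = "catecholamine",
                                  "2" = "analgesic"), ...) {
  patient_chart("ptX", catheter_config(n_lumens, reserved), events, ...)
}

# quick event-row builder
ev_row <- function(drug, lumen, start, end, mode = "INTERMITTENT",
                   route = "CENTRAL_VENOUS") {
  data.frame(drug = drug, route = route, lumen = lumen,
             start_min = start, end_min = end, mode = mode,
             stringsAsFactors = FALSE)
}
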