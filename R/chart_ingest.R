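#' Construct a catheter configuration
#'
#' @param n_lumens integer >= 1; number of lumens (3 for the regular
#'   central-venous catheter, 5 for post-surgery patients).
#' @param reserved named character vector mapping lumen ids (as names) to a
#'   purpose tag (e.g., `c("1" = "catecholamine", "2" = "analgesic")`).
#'   Reserved lumens accept only drugs carrying the matching class tag;
#'   drugs with a reserved purpose tag are pinned to their lumen by the
#'   recommender.
#' @return a `catheter_config` object.
#' @export
catheter_config <- function(n_lumens = 3, reserved = character()) {
  n_lumens <- as.integer(n_lumens)
  if (is.na(n_lumens) || n_lumens < 1)
    abort("catheter: n_lumens must be a positive integer")
  reserved <- stats::setNames(as.character(reserved), names(reserved))
  if (length(reserved)) {
    ids <- as.integer(names(reserved))
    if (anyNA(ids) || any(ids < 1) || any(ids > n_lumens))
      abort("catheter: reserved lumen ids must lie in 1..n_lumens")
    if (anyDuplicated(reserved))
      abort("catheter: reserved purposes must be unique")
  }
  structure(list(n_lumens = n_lumens, reserved = reserved),
            class = "catheter_config")
}

chart_modes <- function() c("CONTINUOUS", "INTERMITTENT", "BOLUS")
chart_routes <- function() c("CENTRAL_VENOUS", "PERIPHERAL", "OTHER")

#' Construct a patient chart
#'
#' One chart covers one day of treatment: drug administration events with
#' half-open time intervals `[start, end)` in whole minutes from chart
#' start, each tied to a catheter lumen. Multi-day records must be
#' pre-split; a configurable horizon check enforces this.
#'
#' @param patient_id scalar identifier.
#' @param catheter a [catheter_config()].
#' @param events data frame with columns `drug`, `route`, `lumen`,
#'   `start_min`, `end_min`, `mode`.
#' @param fluid_restricted logical; patients under salt/fluid restriction
#'   get no flush-adding avoidance plans.
#' @param bolus_cap maximum duration (minutes) of a `BOLUS` event.
#' @param max_horizon maximum allowed `end_min`; guards against multi-day
#'   charts slipping in.
#' @return a `patient_chart` object.
#' @export
patient_chart <- function(patient_id, catheter, events,
                          fluid_restricted = FALSE,
                          bolus_cap = 15, max_horizon = 1600) {
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  needed <- c("drug", "route", "lumen", "start_min", "end_min", "mode")
  miss <- setdiff(needed, names(events))
  if (length(miss))
    abort("chart %s: missing event columns: %s", patient_id,
          paste(miss, collapse = ", "))
  events$lumen <- as.integer(events$lumen)
  events$start_min <- as.numeric(events$start_min)
  events$end_min <- as.numeric(events$end_min)
  errs <- validate_events(events, catheter, bolus_cap, max_horizon)
  if (length(errs))
    abort("chart %s: %s", patient_id, paste(errs, collapse = "; "))
  events <- events[order(events$lumen, events$start_min, events$drug), ]
  rownames(events) <- NULL
  structure(list(patient_id = as.character(patient_id),
                 catheter = catheter, events = events,
                 fluid_restricted = isTRUE(fluid_restricted)),
            class = "patient_chart")
}

validate_events <- function(events, catheter, bolus_cap, max_horizon) {
  errs <- character()
  msg <- function(i, what)
    sprintf("row %s: %s", rownames(events)[i] %||% i, what)
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    if (!e$mode %in% chart_modes())
      errs <- c(errs, msg(i, paste0("unknown mode '", e$mode, "'")))
    if (!e$route %in% chart_routes())
      errs <- c(errs, msg(i, paste0("unknown route '", e$route, "'")))
    if (is.na(e$end_min) || is.na(e$start_min) || e$end_min <= e$start_min)
      errs <- c(errs, msg(i, sprintf("empty or inverted interval [%s, %s)",
                                     e$start_min, e$end_min)))
    else if (e$end_min > max_horizon)
      errs <- c(errs, msg(i, sprintf(
        "end %s exceeds the %s-minute horizon (split multi-day charts)",
        e$end_min, max_horizon)))
    if (identical(e$mode, "BOLUS") && !is.na(e$end_min) &&
        !is.na(e$start_min) && e$end_min - e$start_min > bolus_cap)
      errs <- c(errs, msg(i, sprintf("BOLUS longer than %d min", bolus_cap)))
    if (identical(e$route, "CENTRAL_VENOUS") &&
        (is.na(e$lumen) || e$lumen < 1 || e$lumen > catheter$n_lumens))
      errs <- c(errs, msg(i, sprintf("lumen %s outside 1..%d",
                                     e$lumen, catheter$n_lumens)))
  }
  errs
}

#' @export
print.patient_chart <- function(x, ...) {
  cat(sprintf("<patient_chart %s> %d-lumen catheter, %d events (%d central-venous)\n",
              x$patient_id, x$catheter$n_lumens, nrow(x$events),
              sum(x$events$route == "CENTRAL_VENOUS")))
  invisible(x)
}

central_events <- function(chart, lumen_id = NULL) {
  ev <- chart$events[chart$events$route == "CENTRAL_VENOUS", , drop = FALSE]
  if (!is.null(lumen_id)) ev <- ev[ev$lumen == lumen_id, , drop = FALSE]
  ev
}

#' Read patient charts and their catheter sidecar
#'
#' Charts come as long-format CSV with header
#' `patient_id,drug,route,lumen,start_min,end_min,mode`; the catheter
#' sidecar is YAML mapping each patient id to `n_lumens` and an optional
#' `reserved` lumen-to-purpose map (and an optional `fluid_restricted`
#' flag). Drug names are normalized through the lexicon; peripheral events
#' are parsed and kept but ignored by the per-lumen analysis. Row-level
#' validation failures are a hard error by default, reported with the
#' offending row numbers; `skip_bad_rows = TRUE` downgrades them to
#' warnings and drops the rows.
#'
#' @param path charts CSV path.
#' @param catheters path to the sidecar YAML, or a named list of
#'   [catheter_config()] per patient id.
#' @param lexicon a [drug_lexicon()] for name normalization.
#' @param skip_bad_rows drop invalid rows with a warning instead of
#'   failing.
#' @param bolus_cap,max_horizon validation limits, see [patient_chart()].
#' @return named list of [patient_chart()] objects, ordered by patient id.
#' @export
read_charts <- function(path, catheters, lexicon, skip_bad_rows = FALSE,
                        bolus_cap = 15, max_horizon = 1600) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$patient_id <- as.character(df$patient_id)
  df$.row <- seq_len(nrow(df)) + 1L  # header is line 1
  sidecar <- read_catheters(catheters)

  errs <- character()
  ok <- rep(TRUE, nrow(df))
  norm <- rep(NA_character_, nrow(df))
  for (i in seq_len(nrow(df))) {
    nm <- tryCatch(normalize_drug_name(df$drug[i], lexicon),
                   error = function(e) conditionMessage(e))
    if (nm %in% lexicon$canonical_name) norm[i] <- nm
    else { ok[i] <- FALSE
           errs <- c(errs, sprintf("line %d: %s", df$.row[i], nm)) }
  }
  df$drug[ok] <- norm[ok]

  charts <- list()
  for (pid in sort(unique(df$patient_id))) {
    cfg <- sidecar$configs[[pid]]
    if (is.null(cfg)) {
      errs <- c(errs, sprintf("patient %s: no catheter sidecar entry", pid))
      next
    }
    sub <- df[df$patient_id == pid & ok, , drop = FALSE]
    rownames(sub) <- sub$.row
    row_errs <- validate_events(sub, cfg, bolus_cap, max_horizon)
    if (length(row_errs) && !skip_bad_rows) {
      errs <- c(errs, sprintf("patient %s: %s", pid, row_errs))
      next
    }
    if (length(row_errs)) {
      warning(sprintf("patient %s: dropping bad rows: %s", pid,
                      paste(row_errs, collapse = "; ")), call. = FALSE)
      bad <- unique(sub("^row ([0-9]+):.*$", "\\1", row_errs))
      sub <- sub[!rownames(sub) %in% bad, , drop = FALSE]
    }
    charts[[pid]] <- patient_chart(
      pid, cfg, sub[, c("drug", "route", "lumen", "start_min",
                        "end_min", "mode")],
      fluid_restricted = isTRUE(sidecar$fluid_restricted[[pid]]),
      bolus_cap = bolus_cap, max_horizon = max_horizon)
  }
  if (length(errs) && !skip_bad_rows)
    abort("chart validation failed:\n  %s", paste(errs, collapse = "\n  "))
  if (length(errs))
    warning(paste(errs, collapse = "; "), call. = FALSE)
  charts
}

read_catheters <- function(catheters) {
  if (is.character(catheters)) {
    raw <- yaml::read_yaml(catheters)
    configs <- lapply(raw, function(x) {
      res <- x$reserved %||% list()
      catheter_config(x$n_lumens %||% 3,
                      stats::setNames(as.character(unlist(res)),
                                      names(res)))
    })
    fluid <- lapply(raw, function(x) isTRUE(x$fluid_restricted))
    list(configs = configs, fluid_restricted = fluid)
  } else {
    list(configs = catheters,
         fluid_restricted = stats::setNames(
           rep(list(FALSE), length(catheters)), names(catheters)))
  }
}

#' Write charts and catheter sidecar to disk
#'
#' Inverse of [read_charts()]; `read_charts(write_charts(...))` is the
#' identity on the event set.
#'
#' @param charts named list of [patient_chart()].
#' @param path charts CSV path.
#' @param catheter_path sidecar YAML path (omit to skip).
#' @return `path`, invisibly.
#' @export
write_charts <- function(charts, path, catheter_path = NULL) {
  rows <- lapply(charts, function(ch) {
    ev <- ch$events
    ev$patient_id <- ch$patient_id
    ev[, c("patient_id", "drug", "route", "lumen", "start_min",
           "end_min", "mode")]
  })
  utils::write.csv(do.call(rbind, c(rows, make.row.names = FALSE)),
                   path, row.names = FALSE, quote = FALSE)
  if (!is.null(catheter_path)) {
    obj <- lapply(charts, function(ch) {
      out <- list(n_lumens = ch$catheter$n_lumens)
      if (length(ch$catheter$reserved))
        out$reserved <- as.list(ch$catheter$reserved)
      if (ch$fluid_restricted) out$fluid_restricted <- TRUE
      out
    })
    yaml::write_yaml(obj, catheter_path)
  }
  invisible(path)
}

#' Maximal constant-activity windows of one lumen
#'
#' Sweep-line over the event endpoints of one lumen's central-venous
#' events: returns the maximal half-open windows within which the set of
#' concurrently running drugs is constant. Windows are disjoint, sorted,
#' and cover exactly the union of the event intervals; overlap is half-open
#' (`[0,60)` and `[60,120)` do not overlap).
#'
#' @param chart a [patient_chart()].
#' @param lumen_id lumen to analyze.
#' @param slack minutes of symmetric padding added to every interval
#'   before testing overlap (default 0: the strictest reading, where
#'   "simultaneous" means a nonempty intersection of positive duration).
#'   A positive slack treats administrations separated by less than
#'   `slack` minutes of line residence as still meeting in the lumen.
#' @return data frame with `start_min`, `end_min`, `n_drugs`, and a `drugs`
#'   list-column of sorted drug names active in each window.
#' @export
simultaneous_sets <- function(chart, lumen_id, slack = 0) {
  if (lumen_id < 1 || lumen_id > chart$catheter$n_lumens)
    abort("lumen %s outside 1..%d", lumen_id, chart$catheter$n_lumens)
  ev <- central_events(chart, lumen_id)
  if (slack > 0) {
    ev$start_min <- pmax(0, ev$start_min - slack)
    ev$end_min <- ev$end_min + slack
  }
  empty <- data.frame(start_min = numeric(), end_min = numeric(),
                      n_drugs = integer())
  empty$drugs <- list()
  if (nrow(ev) == 0) return(empty)
  pts <- sort(unique(c(ev$start_min, ev$end_min)))
  out <- list()
  for (i in seq_len(length(pts) - 1)) {
    s <- pts[i]; e <- pts[i + 1]
    active <- sort(unique(ev$drug[ev$start_min <= s & ev$end_min >= e]))
    if (length(active) == 0) next
    prev <- if (length(out)) out[[length(out)]] else NULL
    if (!is.null(prev) && prev$end == s && identical(prev$drugs, active)) {
      out[[length(out)]]$end <- e  # extend a maximal window
    } else {
      out[[length(out) + 1]] <- list(start = s, end = e, drugs = active)
    }
  }
  if (!length(out)) return(empty)
  res <- data.frame(start_min = vapply(out, `[[`, 0, "start"),
                    end_min = vapply(out, `[[`, 0, "end"),
                    n_drugs = vapply(out, function(w)
                      length(w$drugs), 0L))
  res$drugs <- lapply(out, `[[`, "drugs")
  res
}

#' Unordered drug pairs co-administered through one lumen
#'
#' Exactly the distinct drug pairs that run concurrently in some window of
#' [simultaneous_sets()]; pairs never span lumens.
#'
#' @inheritParams simultaneous_sets
#' @return data frame with `drug_a`, `drug_b` (sorted within and across
#'   rows), one row per distinct pair.
#' @export
coadministered_pairs <- function(chart, lumen_id, slack = 0) {
  win <- simultaneous_sets(chart, lumen_id, slack = slack)
  pairs <- list()
  for (drugs in win$drugs) {
    if (length(drugs) < 2) next
    idx <- utils::combn(length(drugs), 2)
    for (j in seq_len(ncol(idx)))
      pairs[[length(pairs) + 1]] <- c(drugs[idx[1, j]], drugs[idx[2, j]])
  }
  if (!length(pairs))
    return(data.frame(drug_a = character(), drug_b = character()))
  m <- unique(do.call(rbind, pairs))
  res <- data.frame(drug_a = m[, 1], drug_b = m[, 2],
                    stringsAsFactors = FALSE)
  res[order(res$drug_a, res$drug_b), , drop = FALSE]
}

#' Does a chart meet the cohort inclusion criterion?
#'
#' A patient enters the compatibility analysis only if at least three
#' distinct drugs run simultaneously through one lumen at some moment of
#' the day.
#'
#' @param chart a [patient_chart()].
#' @param min_drugs threshold of concurrently running drugs (default 3).
#' @return list with `included` (logical) and, when included, the witness
#'   `lumen` and `window` (`c(start, end)`) of the first qualifying moment.
#' @export
meets_inclusion <- function(chart, min_drugs = 3) {
  for (lum in seq_len(chart$catheter$n_lumens)) {
    win <- simultaneous_sets(chart, lum)
    hit <- which(win$n_drugs >= min_drugs)
    if (length(hit))
      return(list(included = TRUE, lumen = lum,
                  window = c(win$start_min[hit[1]], win$end_min[hit[1]])))
  }
  list(included = FALSE, lumen = NA_integer_, window = NULL)
}
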