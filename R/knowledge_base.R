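#' Built-in evidence sources
#'
#' The four compatibility evidence sources consulted by the default
#' resolution policy, in their default precedence order: the KIK catheter
#' compatibility database, the Stabilis database, the summary of product
#' characteristics (the drug label), and the Trissel handbook of injectable
#' drugs.
#'
#' @return character vector of source identifiers.
#' @export
builtin_sources <- function() c("KIK", "STABILIS", "SMPC", "TRISSEL")

#' Per-source verdict vocabulary
#'
#' What a single source can say about one drug pair. `NO_DATA` is the
#' implicit verdict of any absent assertion; `CONFLICTING_WITHIN_SOURCE`
#' records a source that contradicts itself (e.g., different monographs of
#' the same database disagree).
#'
#' @return character vector of verdict tokens.
#' @export
source_verdicts <- function() {
  c("COMPATIBLE", "INCOMPATIBLE", "CONFLICTING_WITHIN_SOURCE", "NO_DATA")
}

#' Construct a drug lexicon
#'
#' A lexicon maps raw drug names to canonical concepts. Combination products
#' (e.g., piperacillin/tazobactam) are single concepts, never decomposed to
#' their components. Non-drug infusates (carrier solutions, parenteral
#' nutrition, vitamin supplements) are ordinary concepts with a class tag,
#' because they take part in incompatibility reactions like any drug.
#'
#' @param canonical_name character; lowercase canonical names, nonempty,
#'   unique.
#' @param synonyms list of character vectors, one per concept. Synonym sets
#'   of distinct concepts must be disjoint and must not contain another
#'   concept's canonical name.
#' @param class_tags list of character vectors (e.g., `"anti-infective"`,
#'   `"electrolyte"`).
#' @param is_combination logical; `TRUE` for fixed-dose combination
#'   products.
#' @return a `drug_lexicon` data frame.
#' @export
drug_lexicon <- function(canonical_name,
                         synonyms = vector("list", length(canonical_name)),
                         class_tags = vector("list", length(canonical_name)),
                         is_combination = logical(length(canonical_name))) {
  canonical_name <- squish(canonical_name)
  if (any(!nzchar(canonical_name)))
    abort("lexicon: canonical names must be nonempty")
  if (anyDuplicated(canonical_name))
    abort("lexicon: duplicate canonical name '%s'",
          canonical_name[duplicated(canonical_name)][1])
  synonyms <- lapply(synonyms, function(s) unique(squish(as.character(s))))
  all_syn <- unlist(synonyms, use.names = FALSE)
  if (anyDuplicated(all_syn))
    abort("lexicon: synonym '%s' is listed under more than one concept",
          all_syn[duplicated(all_syn)][1])
  clash <- intersect(all_syn, canonical_name)
  # a concept's own canonical name may repeat as its synonym; cross-concept
  # reuse is an error
  for (nm in clash) {
    owner <- which(vapply(synonyms, function(s) nm %in% s, logical(1)))
    if (canonical_name[owner] != nm)
      abort("lexicon: '%s' is both a canonical name and a synonym of '%s'",
            nm, canonical_name[owner])
  }
  lex <- data.frame(canonical_name = canonical_name,
                    is_combination = as.logical(is_combination),
                    stringsAsFactors = FALSE)
  lex$synonyms <- synonyms
  lex$class_tags <- lapply(class_tags, as.character)
  class(lex) <- c("drug_lexicon", "data.frame")
  lex
}

# case-fold, trim, collapse internal whitespace
squish <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

#' Normalize a raw drug name to its canonical concept
#'
#' Matching is exact after case-folding, trimming, and internal-whitespace
#' collapse; there is deliberately no fuzzy matching, because a silently
#' wrong match in a medication-safety context is worse than a hard error.
#'
#' @param raw character vector of raw names.
#' @param lexicon a [drug_lexicon()].
#' @return character vector of canonical names.
#' @examples
#' lex <- drug_lexicon(c("metamizole", "furosemide"),
#'                     synonyms = list("dipyrone", character()))
#' normalize_drug_name("Dipyrone", lex)  # "metamizole"
#' @export
normalize_drug_name <- function(raw, lexicon) {
  if (nrow(lexicon) == 0) abort("lexicon is empty")
  key <- squish(raw)
  map <- lexicon_map(lexicon)
  hit <- map[key]
  if (anyNA(hit)) {
    bad <- unique(raw[is.na(hit)])
    abort("unknown drug name%s: %s", if (length(bad) > 1) "s" else "",
          paste(sQuote(bad), collapse = ", "))
  }
  unname(hit)
}

lexicon_map <- function(lexicon) {
  keys <- c(lexicon$canonical_name,
            unlist(lexicon$synonyms, use.names = FALSE))
  vals <- c(lexicon$canonical_name,
            rep(lexicon$canonical_name,
                lengths(lexicon$synonyms)))
  if (anyDuplicated(keys)) {
    dup <- keys[duplicated(keys)][1]
    tgt <- unique(vals[keys == dup])
    if (length(tgt) > 1)
      abort("ambiguous drug name '%s' (matches %s)", dup,
            paste(sQuote(tgt), collapse = " and "))
    keep <- !duplicated(keys)
    keys <- keys[keep]; vals <- vals[keep]
  }
  stats::setNames(vals, keys)
}

#' Construct a compatibility knowledge base
#'
#' Holds at most one assertion per (unordered pair, source). Pairs written
#' in either order collapse to one key; two rows for the same pair and
#' source with different verdicts are a hard error, never silently merged.
#'
#' @param lexicon a [drug_lexicon()].
#' @param assertions data frame with columns `drug_a`, `drug_b`, `source`,
#'   `verdict`, and optionally `evidence_note`, `citation`.
#' @param extra_sources character; additional source identifiers beyond
#'   [builtin_sources()], appended in precedence order.
#' @return a `knowledge_base` object.
#' @export
knowledge_base <- function(lexicon, assertions = NULL,
                           extra_sources = character()) {
  sources <- c(builtin_sources(), extra_sources)
  if (is.null(assertions) || nrow(assertions) == 0) {
    assertions <- data.frame(drug_a = character(), drug_b = character(),
                             source = character(), verdict = character(),
                             evidence_note = character(),
                             citation = character(),
                             stringsAsFactors = FALSE)
  } else {
    assertions <- as.data.frame(assertions, stringsAsFactors = FALSE)
    for (col in c("evidence_note", "citation"))
      if (is.null(assertions[[col]])) assertions[[col]] <- ""
    assertions$drug_a <- normalize_drug_name(assertions$drug_a, lexicon)
    assertions$drug_b <- normalize_drug_name(assertions$drug_b, lexicon)
    if (any(assertions$drug_a == assertions$drug_b))
      abort("assertion pairs a drug with itself: %s",
            assertions$drug_a[assertions$drug_a == assertions$drug_b][1])
    bad_src <- setdiff(unique(assertions$source), sources)
    if (length(bad_src))
      abort("unknown source(s): %s (register via extra_sources)",
            paste(bad_src, collapse = ", "))
    bad_v <- setdiff(unique(assertions$verdict), source_verdicts())
    if (length(bad_v))
      abort("unknown verdict token(s): %s", paste(bad_v, collapse = ", "))
    p <- pair_sort(assertions$drug_a, assertions$drug_b)
    assertions$drug_a <- p$a
    assertions$drug_b <- p$b
    key <- paste(pair_key(p$a, p$b), assertions$source, sep = "\r")
    if (anyDuplicated(key)) {
      for (k in unique(key[duplicated(key)])) {
        rows <- assertions[key == k, ]
        if (length(unique(rows$verdict)) > 1)
          abort(paste0("contradictory duplicate assertions for (%s, %s) ",
                       "from %s: %s"),
                rows$drug_a[1], rows$drug_b[1], rows$source[1],
                paste(rows$verdict, collapse = " vs "))
      }
      assertions <- assertions[!duplicated(key), ]
    }
    assertions <- assertions[order(assertions$drug_a, assertions$drug_b,
                                   match(assertions$source, sources)), ]
    rownames(assertions) <- NULL
  }
  structure(list(lexicon = lexicon, assertions = assertions,
                 sources = sources),
            class = "knowledge_base")
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat(sprintf("<knowledge_base> %d concepts, %d assertions, sources: %s\n",
              nrow(x$lexicon), nrow(x$assertions),
              paste(x$sources, collapse = ", ")))
  invisible(x)
}

#' Look up one source's verdict for a drug pair
#'
#' @param kb a [knowledge_base()].
#' @param a,b drug names (raw names are normalized through the lexicon);
#'   must be distinct concepts.
#' @param source a source identifier.
#' @return a verdict token; `NO_DATA` when the source holds no assertion for
#'   the pair. Symmetric in `a` and `b`.
#' @export
kb_lookup <- function(kb, a, b, source) {
  a <- normalize_drug_name(a, kb$lexicon)
  b <- normalize_drug_name(b, kb$lexicon)
  if (a == b)
    abort("pair of a drug with itself is undefined ('%s')", a)
  if (!source %in% kb$sources)
    abort("unknown source '%s'", source)
  p <- pair_sort(a, b)
  hit <- kb$assertions$drug_a == p$a & kb$assertions$drug_b == p$b &
    kb$assertions$source == source
  if (any(hit)) kb$assertions$verdict[which(hit)[1]] else "NO_DATA"
}

# all stored verdicts for one pair as a named vector over the given sources
kb_pair_verdicts <- function(kb, a, b, sources = kb$sources) {
  p <- pair_sort(a, b)
  hit <- kb$assertions[kb$assertions$drug_a == p$a &
                         kb$assertions$drug_b == p$b, , drop = FALSE]
  v <- stats::setNames(rep("NO_DATA", length(sources)), sources)
  v[hit$source[hit$source %in% sources]] <-
    hit$verdict[hit$source %in% sources]
  v
}

## ---- file formats ----------------------------------------------------

#' Read and write drug lexicon files
#'
#' CSV dialect: UTF-8, comma-separated, header
#' `canonical_name,synonyms,class_tags,is_combination`, with `;`-separated
#' multi-valued fields.
#'
#' @param path file path.
#' @return `read_lexicon` returns a [drug_lexicon()].
#' @export
read_lexicon <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  split_multi <- function(x)
    lapply(strsplit(x, ";", fixed = TRUE),
           function(s) s[nzchar(trimws(s))])
  drug_lexicon(df$canonical_name,
               synonyms = split_multi(df$synonyms %||% rep("", nrow(df))),
               class_tags = split_multi(df$class_tags %||% rep("", nrow(df))),
               is_combination =
                 tolower(df$is_combination %||% "false") %in%
                 c("true", "1", "yes"))
}

#' @rdname read_lexicon
#' @param lexicon a [drug_lexicon()] to write.
#' @export
write_lexicon <- function(lexicon, path) {
  df <- data.frame(
    canonical_name = lexicon$canonical_name,
    synonyms = vapply(lexicon$synonyms, paste, "", collapse = ";"),
    class_tags = vapply(lexicon$class_tags, paste, "", collapse = ";"),
    is_combination = tolower(as.character(lexicon$is_combination)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a knowledge base from disk
#'
#' Two on-disk formats are supported. CSV: an assertion table with header
#' `drug_a,drug_b,source,verdict,evidence_note,citation` plus a separate
#' lexicon file (see [read_lexicon()]). JSON: a single object with `lexicon`
#' and `assertions` arrays. Loading and saving round-trip the assertion set
#' exactly; rows stating the pair in either order collapse to one key, and
#' contradictory duplicates are a hard error.
#'
#' @param path path to the KB file.
#' @param format `"csv"` or `"json"`; `"auto"` guesses from the extension.
#' @param lexicon for CSV input: a [drug_lexicon()] or a path to a lexicon
#'   CSV. Ignored for JSON, which embeds its lexicon.
#' @param extra_sources passed to [knowledge_base()].
#' @return a [knowledge_base()].
#' @export
load_kb <- function(path, format = c("auto", "csv", "json"), lexicon = NULL,
                    extra_sources = character()) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  if (format == "csv") {
    if (is.character(lexicon)) lexicon <- read_lexicon(lexicon)
    if (is.null(lexicon))
      abort("CSV knowledge bases need a lexicon (object or file path)")
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    knowledge_base(lexicon, df, extra_sources = extra_sources)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    lex <- drug_lexicon(obj$lexicon$canonical_name,
                        synonyms = as_chr_list(obj$lexicon$synonyms),
                        class_tags = as_chr_list(obj$lexicon$class_tags),
                        is_combination = obj$lexicon$is_combination)
    knowledge_base(lex, obj$assertions, extra_sources = extra_sources)
  }
}

as_chr_list <- function(x) {
  if (is.null(x)) return(list())
  lapply(x, function(s) as.character(unlist(s)))
}

#' @rdname load_kb
#' @param kb a [knowledge_base()] to write.
#' @param lexicon_path for CSV output: where to write the companion lexicon
#'   file (omit to skip).
#' @export
save_kb <- function(kb, path, format = c("auto", "csv", "json"),
                    lexicon_path = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  if (format == "csv") {
    utils::write.csv(kb$assertions[, c("drug_a", "drug_b", "source",
                                       "verdict", "evidence_note",
                                       "citation")],
                     path, row.names = FALSE, quote = TRUE)
    if (!is.null(lexicon_path)) write_lexicon(kb$lexicon, lexicon_path)
  } else {
    obj <- list(
      lexicon = list(canonical_name = kb$lexicon$canonical_name,
                     synonyms = kb$lexicon$synonyms,
                     class_tags = kb$lexicon$class_tags,
                     is_combination = kb$lexicon$is_combination),
      assertions = kb$assertions)
    jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE)
  }
  invisible(path)
}

# class tags of one canonical drug
drug_tags <- function(lexicon, drug) {
  i <- match(drug, lexicon$canonical_name)
  if (is.na(i)) character() else lexicon$class_tags[[i]]
}
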