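# Name normalization and phonetic candidate suggestion for metabolites that
# lack structural information.
#
# Chemical synonyms differ in stereo prefixes (cis-, L-, alpha-), locant
# groups ("7,8-"), token order, -ic acid / -ate suffix convention, and plain
# spelling. Normalization strips the variation that never changes chemical
# identity; the phonetic encoder catches spelling variants of the remainder.
# Suggestions are ranked clues for a curator - they are never auto-applied.

.STEREO_TOKENS <- c("cis", "trans", "l", "d", "alpha", "beta", "gamma",
                    "r", "s", "e", "z", "meso", "sec", "tert", "n", "o", "p")

.DEFAULT_STOPWORDS <- c("use", "used", "for", "experiment", "acid", "an", "a",
                        "of", "the")

.GREEK <- c("α" = "alpha", "β" = "beta", "γ" = "gamma",
            "δ" = "delta", "ω" = "omega")

# Substituent prefixes split off compound tokens so that "5-aminoimidazole"
# and "5-amino-...-imidazole" normalize to the same token multiset.
.SUBSTITUENT_PREFIXES <- c("amino", "hydroxy", "phospho", "methyl", "ethyl",
                           "acetyl", "oxo", "keto", "deoxy", "chloro",
                           "succino", "carboxy", "thio", "glycero")

#' Normalize a metabolite name
#'
#' Case-folds, spells out Greek letters, rewrites every `"<stem>ic acid"` to
#' `"<stem>ate"` (before stopword removal, so "acid" never survives as a
#' token), splits on punctuation, and suppresses stereo descriptors
#' (`cis`, `trans`, `L-`, `D-`, `alpha`, ...), bare numerals and locant
#' groups, single-letter tokens and configured non-chemistry stopwords.
#' Compound tokens led by a known substituent prefix are split
#' (`"aminoimidazole"` to `"amino" + "imidazole"`) so that locant-order
#' variants of one name yield identical token multisets.
#'
#' @param name the raw metabolite name.
#' @param stopwords configurable non-chemistry stopword list.
#' @return an object of class `mrx_normalized_name`: list with `tokens`
#'   (ordered surviving tokens) and `suppressed` (removed tokens, for audit).
#' @export
#' @examples
#' normalize_name("cis-4-coumarate")$tokens
#' normalize_name("acetic acid")$tokens
normalize_name <- function(name, stopwords = .DEFAULT_STOPWORDS) {
  .check(is.character(name) && length(name) == 1 && nzchar(name),
         "name must be a non-empty string")
  s <- tolower(name)
  for (g in names(.GREEK)) s <- gsub(g, .GREEK[[g]], s, fixed = TRUE)
  # "-ic acid" == "-ate", applied before any token removal
  s <- gsub("([a-z]+)ic[ -]+acid", "\\1ate", s)
  raw_tokens <- strsplit(s, "[^a-z0-9]+")[[1]]
  raw_tokens <- raw_tokens[nzchar(raw_tokens)]

  split_prefixes <- function(tok) {
    for (pre in .SUBSTITUENT_PREFIXES) {
      if (startsWith(tok, pre) && nchar(tok) >= nchar(pre) + 4)
        return(c(pre, split_prefixes(substring(tok, nchar(pre) + 1L))))
    }
    tok
  }
  toks <- unlist(lapply(raw_tokens, split_prefixes))

  drop <- grepl("^[0-9]+$", toks) |          # bare numerals / locants
    nchar(toks) == 1 |                       # single letters incl. L, D, N
    toks %in% .STEREO_TOKENS |
    toks %in% stopwords
  structure(list(tokens = toks[!drop], suppressed = toks[drop]),
            class = "mrx_normalized_name")
}

#' @export
print.mrx_normalized_name <- function(x, ...) {
  cat("<normalized name> ", paste(x$tokens, collapse = " "), "\n", sep = "")
  if (length(x$suppressed))
    cat("  suppressed: ", paste(x$suppressed, collapse = " "), "\n", sep = "")
  invisible(x)
}

# canonical comparable rendering: sorted token multiset
.name_signature <- function(name, stopwords = .DEFAULT_STOPWORDS) {
  paste(sort(normalize_name(name, stopwords)$tokens), collapse = "|")
}

#' Phonetic code of a normalized token
#'
#' A metaphone-style encoder: consonant classes that sound alike in Latinate
#' chemical vocabulary collapse to one symbol (C/K/Q, PH/F, D/T, S/Z, V/F),
#' vowels after the leading position are dropped, doubled letters collapse.
#' Deterministic; equal tokens always give equal codes. The encoder is
#' configurable at the call sites that consume it.
#'
#' @param token a lowercase token (as produced by [normalize_name()]).
#' @return a single uppercase code string.
#' @export
#' @examples
#' phonetic_key("coumarate") == phonetic_key("cumarate")
phonetic_key <- function(token) {
  .check(is.character(token) && length(token) == 1, "token must be a string")
  s <- tolower(gsub("[^a-zA-Z]", "", token))
  if (!nzchar(s)) return("")
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  out <- character(0)
  i <- 1L
  is_vowel <- function(c) c %in% c("a", "e", "i", "o", "u", "y")
  peek <- function(k) if (i + k <= n) ch[i + k] else ""
  while (i <= n) {
    c0 <- ch[i]
    nxt <- peek(1)
    code <- NULL
    adv <- 1L
    if (is_vowel(c0)) {
      if (i == 1L) code <- "A"                  # leading vowels collapse
    } else if (c0 == "c") {
      if (nxt == "h") { code <- "K"; adv <- 2L }
      else if (nxt %in% c("e", "i", "y")) code <- "S"
      else code <- "K"
    } else if (c0 == "p" && nxt == "h") { code <- "F"; adv <- 2L }
    else if (c0 == "s" && nxt == "h") { code <- "X"; adv <- 2L }
    else if (c0 == "t" && nxt == "h") { code <- "T"; adv <- 2L }
    else if (c0 == "g") code <- if (nxt %in% c("e", "i", "y")) "J" else "K"
    else if (c0 == "q") code <- "K"
    else if (c0 == "k") code <- "K"
    else if (c0 == "x") code <- "KS"
    else if (c0 == "z") code <- "S"
    else if (c0 == "d") code <- "T"
    else if (c0 == "v") code <- "F"
    else if (c0 == "w" || c0 == "h") code <- NULL
    else code <- toupper(c0)
    if (!is.null(code) && (length(out) == 0 || out[length(out)] != code))
      out <- c(out, code)
    i <- i + adv
  }
  paste(out, collapse = "")
}

#' Suggest identity matches for an unresolved metabolite
#'
#' Scores every structurally resolved candidate against the query name(s):
#' score 1 for exact equality of normalized token multisets, otherwise the
#' fraction of tokens whose phonetic codes match (symmetric: multiset
#' intersection of codes over the larger token count). Suggestions are
#' ordered by score (descending), evidence priority (exact-normalized before
#' phonetic before reaction-context), then candidate id (ascending), and are
#' never applied automatically.
#'
#' @param query a [metabolite_entry()] with resolution `"partial"` or
#'   `"none"`.
#' @param resolved list of candidate [metabolite_entry()]s with resolution
#'   `"full"`.
#' @param k maximum number of suggestions (default 5).
#' @param floor minimum score to report (default 0.5).
#' @return data frame with columns `candidate`, `score`, `evidence`, `rank`
#'   (empty when `resolved` is empty).
#' @export
suggest_matches <- function(query, resolved, k = 5, floor = 0.5) {
  .check(query$resolution %in% c("partial", "none"),
         "query %s is already fully resolved", query$id)
  empty <- data.frame(candidate = character(), score = numeric(),
                      evidence = character(), rank = integer(),
                      stringsAsFactors = FALSE)
  if (length(resolved) == 0) return(empty)

  q_sigs <- unique(vapply(query$names, .name_signature, character(1)))
  q_tokens <- sort(unique(unlist(
    lapply(query$names, function(nm) normalize_name(nm)$tokens))))
  q_codes <- vapply(q_tokens, phonetic_key, character(1))

  rows <- lapply(resolved, function(cand) {
    .check(identical(cand$resolution, "full"),
           "candidate %s is not fully resolved", cand$id)
    c_sigs <- unique(vapply(cand$names, .name_signature, character(1)))
    if (length(intersect(q_sigs, c_sigs[nzchar(c_sigs)])) > 0 &&
        any(nzchar(q_sigs)))
      return(data.frame(candidate = cand$id, score = 1,
                        evidence = "exact-normalized", stringsAsFactors = FALSE))
    c_tokens <- sort(unique(unlist(
      lapply(cand$names, function(nm) normalize_name(nm)$tokens))))
    if (length(q_tokens) == 0 || length(c_tokens) == 0) return(NULL)
    c_codes <- vapply(c_tokens, phonetic_key, character(1))
    # multiset intersection of phonetic codes, symmetric in the two sides
    shared <- sum(pmin(table(q_codes)[union(q_codes, c_codes)],
                       table(c_codes)[union(q_codes, c_codes)]), na.rm = TRUE)
    score <- shared / max(length(q_codes), length(c_codes))
    if (score < floor) return(NULL)
    data.frame(candidate = cand$id, score = score, evidence = "phonetic",
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  df <- do.call(rbind, rows)
  prio <- match(df$evidence, c("exact-normalized", "phonetic", "reaction-context"))
  df <- df[order(-df$score, prio, df$candidate), , drop = FALSE]
  df <- utils::head(df, k)
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}
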