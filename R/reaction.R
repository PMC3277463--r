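# Reaction-string parsing across the dialects found in published models.
#
# The same biochemical reaction appears in the wild under many surface forms:
# compartment prefixes "[c]:" / "[c]" / none, arrows "< = = >", "-- >",
# "< - >", "- >", "=", "< = >", unicode arrows, and varying coefficient
# grammars. The tokenizer is whitespace-tolerant inside arrows (published
# strings embed spaces, e.g. "< = = >") and splits participants on "+" at top
# level only.

# Arrow grammar, in priority order (longer/reversible forms first so that
# "- >" never fires inside "< - >" or "-- >").
.ARROWS <- list(
  list(re = "< *= *= *>", dir = "reversible", bare_eq = FALSE),
  list(re = "< *= *>",    dir = "reversible", bare_eq = FALSE),
  list(re = "< *- *>",    dir = "reversible", bare_eq = FALSE),
  list(re = "⇔",     dir = "reversible", bare_eq = FALSE),
  list(re = "- *- *>",    dir = "forward",    bare_eq = FALSE),
  list(re = "- *>",       dir = "forward",    bare_eq = FALSE),
  list(re = "→",     dir = "forward",    bare_eq = FALSE),
  list(re = "=",          dir = "forward",    bare_eq = TRUE))

#' Construct a reaction entry
#'
#' @param id source-scoped reaction identifier.
#' @param participants data frame with columns `met` (metabolite ref), `num`,
#'   `den` (signed exact rational coefficient, reactants negative, products
#'   positive) and `compartment` (tag or `NA`).
#' @param direction one of `"reversible"`, `"forward"`, `"backward"`.
#' @param ec,genes,source optional annotation strings.
#' @return an object of class `mrx_reaction`.
#' @export
reaction_entry <- function(id, participants, direction = "forward",
                           ec = NA_character_, genes = NA_character_,
                           source = NA_character_) {
  .check(is.character(id) && length(id) == 1 && nzchar(id),
         "reaction id must be a non-empty string")
  .check(direction %in% c("reversible", "forward", "backward"),
         "bad direction '%s' for reaction %s", direction, id)
  .check(is.data.frame(participants) && nrow(participants) > 0,
         "reaction %s has no participants", id)
  for (col in c("met", "num", "den")) {
    .check(col %in% names(participants),
           "participants of %s lack column '%s'", id, col)
  }
  if (!"compartment" %in% names(participants))
    participants$compartment <- NA_character_
  .check(all(participants$num != 0), "reaction %s has a zero coefficient", id)
  .check(all(participants$den > 0), "denominators must be positive in %s", id)
  g <- mapply(.gcd2, abs(participants$num), participants$den)
  participants$num <- participants$num / g
  participants$den <- participants$den / g
  participants$coef <- participants$num / participants$den
  side <- ifelse(participants$num < 0, "reactant", "product")
  dup <- duplicated(paste(side, participants$met))
  .check(!any(dup), "metabolite %s appears twice on one side of %s",
         paste(unique(participants$met[dup]), collapse = ","), id)
  participants <- participants[, c("met", "num", "den", "coef", "compartment")]
  rownames(participants) <- NULL
  structure(list(id = id, participants = participants, direction = direction,
                 ec = ec, genes = genes, source = source),
            class = "mrx_reaction")
}

reactants <- function(r) r$participants[r$participants$num < 0, , drop = FALSE]
products  <- function(r) r$participants[r$participants$num > 0, , drop = FALSE]

#' Parse one reaction string
#'
#' Recognizes the arrow conventions `< = = >`, `<=>`, `< - >`, `-- >`, `- >`,
#' unicode arrows and bare `=`, with or without a leading compartment prefix
#' (`"[c]:"` or `"[c]"`); per-metabolite compartment suffixes (`"ac[e]"`) are
#' accepted as an extension. Bidirectional arrows give direction
#' `"reversible"`; single-headed arrows give `"forward"`. A bare `=`
#' (KEGG-style equation) is stored as forward with a warning under
#' auto-detection, since such equations are conventionally undirected.
#' Coefficients default to 1 and may be integers, decimals or fractions; they
#' are stored as exact rationals.
#'
#' @param text the reaction string.
#' @param dialect `"auto"` (default) detects the convention.
#' @param id optional reaction id (defaults to the trimmed string itself).
#' @param source optional provenance tag.
#' @return an [reaction_entry()] with signed participants (reactants
#'   negative).
#' @export
#' @examples
#' r <- parse_reaction_string("[c]: g6p + nadp < = = > 6pgl + h + nadph")
#' r$direction
parse_reaction_string <- function(text, dialect = "auto", id = NULL,
                                  source = NA_character_) {
  .check(is.character(text) && length(text) == 1 && nzchar(trimws(text)),
         "reaction string must be non-empty")
  .check(identical(dialect, "auto") || dialect %in% c("prefix", "bare"),
         "unknown dialect '%s'", as.character(dialect))
  raw <- text
  s <- trimws(text)
  if (is.null(id)) id <- s

  compartment <- NA_character_
  m <- regmatches(s, regexec("^\\[([A-Za-z0-9]+)\\] *:? *", s))[[1]]
  if (length(m)) {
    compartment <- m[2]
    s <- substring(s, nchar(m[1]) + 1L)
  }

  hit <- NULL
  for (a in .ARROWS) {
    pos <- regexpr(a$re, s)
    if (pos > 0) { hit <- list(a = a, pos = pos); break }
  }
  if (is.null(hit))
    stop("no recognizable reaction arrow in: '", raw, "'", call. = FALSE)
  if (hit$a$bare_eq && identical(dialect, "auto"))
    warning("bare '=' equation treated as forward (direction unknown): '",
            raw, "'", call. = FALSE)
  lhs <- substr(s, 1L, hit$pos - 1L)
  rhs <- substring(s, hit$pos + attr(hit$pos, "match.length"))

  parse_side <- function(side_text, sign) {
    if (grepl("^\\s*\\+", side_text) || grepl("\\+\\s*$", side_text) ||
        grepl("\\+\\s*\\+", side_text) || !nzchar(trimws(side_text)))
      stop("dangling '+' in reaction: '", raw, "'", call. = FALSE)
    terms <- trimws(strsplit(side_text, " \\+ ")[[1]])
    if (length(terms) == 0 || any(!nzchar(terms)))
      stop("dangling '+' in reaction: '", raw, "'", call. = FALSE)
    out <- lapply(terms, function(term) {
      cm <- regmatches(term, regexec(
        "^([0-9]+/[0-9]+|[0-9]*\\.[0-9]+|[0-9]+) +(\\S.*)$", term))[[1]]
      coef <- c(num = 1, den = 1)
      if (length(cm)) {
        coef <- parse_coef(cm[2])
        term <- cm[3]
      }
      comp <- compartment
      sm <- regmatches(term, regexec("^(.*\\S) *\\[([A-Za-z0-9]+)\\]$", term))[[1]]
      if (length(sm)) {
        term <- sm[2]
        comp <- sm[3]
      }
      if (!nzchar(term))
        stop("missing metabolite name in reaction: '", raw, "'", call. = FALSE)
      data.frame(met = term, num = sign * coef[["num"]], den = coef[["den"]],
                 compartment = comp, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }

  lhs_df <- parse_side(lhs, -1)
  rhs_df <- parse_side(rhs, +1)
  reaction_entry(id = id, participants = rbind(lhs_df, rhs_df),
                 direction = hit$a$dir, source = source)
}

#' Render a reaction entry in the canonical dialect
#'
#' The canonical dialect uses a `"[c]: "` prefix when all participants share
#' one compartment, per-metabolite suffixes otherwise, `" + "` separators,
#' explicit coefficients other than 1, and arrows `"<=>"` / `"->"`. Parsing
#' the rendered string yields the same participants and direction
#' (backward-direction reactions are rendered with sides flipped, which
#' preserves the chemistry).
#'
#' @param r an [reaction_entry()].
#' @return a single string.
#' @export
render_reaction <- function(r) {
  p <- r$participants
  if (r$direction == "backward") {
    p$num <- -p$num
    dir <- "forward"
  } else dir <- r$direction
  comps <- unique(p$compartment)
  prefix <- ""
  suffix_each <- FALSE
  if (length(comps) == 1 && !is.na(comps)) {
    prefix <- paste0("[", comps, "]: ")
  } else if (any(!is.na(comps))) {
    suffix_each <- TRUE
  }
  term <- function(rows) {
    paste(vapply(seq_len(nrow(rows)), function(i) {
      cf <- fmt_coef(abs(rows$num[i]), rows$den[i])
      nm <- rows$met[i]
      if (suffix_each && !is.na(rows$compartment[i]))
        nm <- paste0(nm, "[", rows$compartment[i], "]")
      if (cf == "1") nm else paste(cf, nm)
    }, character(1)), collapse = " + ")
  }
  arrow <- if (dir == "reversible") "<=>" else "->"
  paste0(prefix, term(p[p$num < 0, , drop = FALSE]), " ", arrow, " ",
         term(p[p$num > 0, , drop = FALSE]))
}

#' @export
print.mrx_reaction <- function(x, ...) {
  cat(sprintf("<reaction %s> %s\n", x$id, render_reaction(x)))
  invisible(x)
}
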