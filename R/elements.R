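# Element vectors: the currency of all balancing arithmetic.

# Periodic-table symbols (1..118), used to validate formulas.
PERIODIC_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og")

#' Construct an element vector
#'
#' An element vector is a map from element symbols to non-negative counts plus
#' an integer net charge. It is the unit of all elemental/charge balancing
#' arithmetic in the package.
#'
#' @param counts named numeric vector of element counts (names are element
#'   symbols, values non-negative).
#' @param charge integer net charge (default 0).
#' @return an object of class `mrx_elements`.
#' @export
#' @examples
#' element_vector(c(H = 2, O = 1))
element_vector <- function(counts = numeric(), charge = 0) {
  if (length(counts)) {
    .check(!is.null(names(counts)) && all(nzchar(names(counts))),
           "element counts must be named")
    bad <- setdiff(names(counts), PERIODIC_SYMBOLS)
    .check(length(bad) == 0, "unknown element symbol(s): %s",
           paste(bad, collapse = ", "))
    .check(all(counts >= 0), "element counts must be non-negative")
    counts <- counts[counts != 0]
    counts <- counts[order(names(counts))]
  }
  .check(length(charge) == 1 && is.finite(charge) && charge == round(charge),
         "charge must be a single integer")
  structure(list(counts = counts, charge = as.numeric(charge)),
            class = "mrx_elements")
}

#' @export
print.mrx_elements <- function(x, ...) {
  body <- if (length(x$counts))
    paste0(names(x$counts), ifelse(x$counts == 1, "", x$counts), collapse = "")
  else "(empty)"
  ch <- if (x$charge == 0) "" else sprintf(" charge %+d", x$charge)
  cat("<element vector> ", body, ch, "\n", sep = "")
  invisible(x)
}

# a + k*b, exact for integer/rational inputs representable in doubles
ev_add <- function(a, b, k = 1) {
  sym <- union(names(a$counts), names(b$counts))
  ca <- a$counts[sym]; ca[is.na(ca)] <- 0
  cb <- b$counts[sym]; cb[is.na(cb)] <- 0
  out <- ca + k * cb
  names(out) <- sym
  out <- out[out != 0]
  structure(list(counts = out[order(names(out))], charge = a$charge + k * b$charge),
            class = "mrx_elements")
}

ev_zero <- function() element_vector()

ev_is_zero <- function(x) length(x$counts) == 0 && x$charge == 0

ev_equal <- function(a, b) {
  d <- ev_add(a, b, k = -1)
  # ev_add drops exact zeros; anything left is a true difference
  length(d$counts) == 0 && d$charge == 0
}

ev_count <- function(x, symbol) {
  v <- x$counts[symbol]
  if (is.na(v)) 0 else unname(v)
}

#' Parse a chemical formula into an element vector
#'
#' Accepts Hill-style formulas with optional integer counts and up to two
#' levels of parentheses, e.g. `"C10H12N5O13P3"`, `"Ca(OH)2"`. A trailing
#' charge term is recognized in the common renderings `"+"`, `"--"`, `"2-"`,
#' `"-2"`; an explicit `charge` argument overrides any trailing term.
#'
#' @param text formula string.
#' @param charge optional integer charge; overrides a trailing charge term.
#' @return an [element_vector()].
#' @export
#' @examples
#' parse_formula("H2O")
#' parse_formula("C9H21N2O2", charge = 1)
#' parse_formula("HPO4", charge = -2)
parse_formula <- function(text, charge = NULL) {
  .check(is.character(text) && length(text) == 1 && !is.na(text),
         "formula must be a single string")
  s <- gsub("[[:space:]]", "", text)
  .check(nzchar(s), "empty formula")

  # Trailing charge: repeated signs ("--", "+") or sign+digits ("-2").
  # The "2-" rendering is deliberately not accepted: "C2H3O2-" would be
  # ambiguous between a final element count and a charge magnitude.
  trailing <- 0
  m <- regmatches(s, regexec("^(.*?)(([+-]+)|([+-][0-9]+))$", s))[[1]]
  if (length(m) && nzchar(m[3])) {
    if (nzchar(m[4])) {            # "--", "+"
      signs <- strsplit(m[4], "")[[1]]
      .check(length(unique(signs)) == 1, "mixed charge signs in formula: %s", text)
      trailing <- if (signs[1] == "-") -length(signs) else length(signs)
    } else {                        # "-2", "+1"
      trailing <- as.numeric(m[5])
    }
    s <- m[2]
    .check(nzchar(s), "formula reduces to a bare charge: %s", text)
  }

  chars <- strsplit(s, "")[[1]]
  i <- 1L
  n <- length(chars)

  read_count <- function() {
    start <- i
    while (i <= n && grepl("[0-9]", chars[i])) i <<- i + 1L
    if (i == start) 1 else as.numeric(paste(chars[start:(i - 1L)], collapse = ""))
  }

  parse_seq <- function(depth) {
    .check(depth <= 2, "parentheses nested beyond depth 2 in formula: %s", text)
    acc <- ev_zero()
    while (i <= n && chars[i] != ")") {
      if (chars[i] == "(") {
        i <<- i + 1L
        inner <- parse_seq(depth + 1L)
        .check(i <= n && chars[i] == ")", "unbalanced '(' in formula: %s", text)
        i <<- i + 1L
        acc <- ev_add(acc, inner, k = read_count())
      } else if (grepl("[A-Z]", chars[i])) {
        sym <- chars[i]
        i <<- i + 1L
        if (i <= n && grepl("[a-z]", chars[i])) {
          sym <- paste0(sym, chars[i])
          i <<- i + 1L
        }
        .check(sym %in% PERIODIC_SYMBOLS,
               "unknown element symbol '%s' in formula: %s", sym, text)
        cnt <- read_count()
        acc <- ev_add(acc, element_vector(stats::setNames(cnt, sym)))
      } else {
        stop(sprintf("unexpected character '%s' in formula: %s", chars[i], text),
             call. = FALSE)
      }
    }
    acc
  }

  out <- parse_seq(1L)
  .check(i > n, "unbalanced ')' in formula: %s", text)
  .check(length(out$counts) > 0, "formula contains no elements: %s", text)
  out$charge <- if (!is.null(charge)) {
    .check(length(charge) == 1 && is.finite(charge) && charge == round(charge),
           "charge must be an integer (fractional charges are rejected, not rounded)")
    as.numeric(charge)
  } else trailing
  out
}

# Does a formula string carry wildcard/repeat-unit markers (R/X side chains,
# "(...)n" repeats)?  Used for resolution classification, never for balancing.
formula_has_wildcard <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(text)) return(FALSE)
  grepl("\\)n", text) ||
    grepl("(^|[^A-Za-z])(R|X)([0-9']*)($|[^a-z])", text) ||
    grepl("\\*", text)
}
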