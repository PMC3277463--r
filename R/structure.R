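# Canonical structure keys at two levels of stereo detail.
#
# Cross-source metabolite identity is decided on canonical SMILES: the stereo
# level preserves chirality and double-bond geometry (isomeric SMILES), the
# connectivity level encodes atom-atom connectivity only, which is the right
# join key when many models omit stereo-specificity. Canonicalization is
# delegated to the OpenBabel backend (ChemmineOB); keys carry a
# backend+version tag so corpora canonicalized by different toolkits refuse
# silent mixing (canonical SMILES are toolkit-specific).

.structure_cache <- new.env(parent = emptyenv())

structure_backend <- function() {
  paste0("ChemmineOB-", as.character(utils::packageVersion("ChemmineOB")))
}

# One backend call per distinct SMILES; memoized (canonicalization dominates
# corpus-scale runtimes otherwise).
.smiles_props <- function(smiles) {
  .check(is.character(smiles) && length(smiles) == 1 && !is.na(smiles) &&
           nzchar(trimws(smiles)), "SMILES descriptor must be a non-empty string")
  smiles <- trimws(smiles)
  hit <- .structure_cache[[smiles]]
  if (!is.null(hit)) return(hit)
  p <- tryCatch(
    suppressWarnings(ChemmineOB::prop_OB(
      ChemmineOB::forEachMol("SMILES", smiles, identity))),
    error = function(e) NULL)
  if (is.null(p) || !nzchar(p$cansmi[1]))
    stop("unparseable structure descriptor: '", smiles, "'", call. = FALSE)
  out <- list(stereo = p$cansmi[1], connectivity = p$cansmiNS[1],
              formula = p$formula[1], wildcard = grepl("*", smiles, fixed = TRUE))
  assign(smiles, out, envir = .structure_cache)
  out
}

#' Canonical structure key for a SMILES descriptor
#'
#' Produces the canonical identity string used as the join key for all
#' cross-source matching. At `level = "stereo"` chiral/stereo marks are
#' preserved (isomeric SMILES); at `level = "connectivity"` they are stripped,
#' so the L- and D- forms of a molecule share one connectivity key but keep
#' distinct stereo keys. Keys are fixed points of canonicalization and
#' deterministic across runs.
#'
#' @param descriptor a SMILES string.
#' @param level `"connectivity"` (default) or `"stereo"`.
#' @return an object of class `mrx_structure_key` with fields `level`, `key`,
#'   `wildcard` (TRUE when the descriptor contains a generic `*` atom) and
#'   `backend`.
#' @export
#' @examples
#' structure_key("OCC(O)CO")$key == structure_key("C(CO)(O)CO")$key
structure_key <- function(descriptor, level = c("connectivity", "stereo")) {
  level <- match.arg(level)
  p <- .smiles_props(descriptor)
  structure(list(level = level,
                 key = if (level == "stereo") p$stereo else p$connectivity,
                 wildcard = p$wildcard,
                 backend = structure_backend()),
            class = "mrx_structure_key")
}

#' @export
print.mrx_structure_key <- function(x, ...) {
  cat(sprintf("<structure key/%s%s> %s  [%s]\n", x$level,
              if (x$wildcard) ", wildcard" else "", x$key, x$backend))
  invisible(x)
}

# Equality that refuses to compare keys canonicalized by different backends.
key_equal <- function(a, b) {
  .check(a$backend == b$backend,
         "refusing to compare structure keys from different backends (%s vs %s)",
         a$backend, b$backend)
  .check(a$level == b$level, "refusing to compare %s and %s level keys",
         a$level, b$level)
  a$key == b$key
}

# Element vector implied by a structure (wildcard atoms contribute nothing).
smiles_elements <- function(descriptor) {
  p <- .smiles_props(descriptor)
  parse_formula(p$formula)
}

#' Classify the structural resolution of a metabolite entry
#'
#' `full`: a wildcard-free structure is present and, when a formula is also
#' given, the two agree on element counts. `partial`: the structure or formula
#' carries generic markers - a `*` (R-group) atom, an `R`/`X` side chain or an
#' unspecified repeat count such as `"(X)n"`. `none`: no usable structural
#' information (including name-only generic entries like "electron acceptor").
#'
#' @param m a [metabolite_entry()].
#' @return one of `"full"`, `"partial"`, `"none"`.
#' @export
resolution_class <- function(m) {
  has_smiles <- !is.null(m$smiles) && !is.na(m$smiles) && nzchar(m$smiles)
  has_formula <- !is.null(m$formula) && !is.na(m$formula) && nzchar(m$formula)
  if (has_smiles) {
    p <- tryCatch(.smiles_props(m$smiles), error = function(e) NULL)
    if (is.null(p)) return("none")
    if (p$wildcard) return("partial")
    if (has_formula) {
      if (formula_has_wildcard(m$formula)) return("partial")
      given <- tryCatch(parse_formula(m$formula), error = function(e) NULL)
      if (!is.null(given)) {
        derived <- parse_formula(p$formula)
        # charge lives on the entry, not the Hill string; compare elements only
        if (!identical(given$counts, derived$counts)) return("partial")
      }
    }
    return("full")
  }
  if (has_formula && formula_has_wildcard(m$formula)) return("partial")
  "none"
}

# Flag entries whose supplied formula disagrees with the formula implied by
# their structure (adjudication is deferred to the curator, not guessed).
formula_consistent <- function(m) {
  has_smiles <- !is.null(m$smiles) && !is.na(m$smiles) && nzchar(m$smiles)
  has_formula <- !is.null(m$formula) && !is.na(m$formula) && nzchar(m$formula)
  if (!has_smiles || !has_formula) return(NA)
  p <- tryCatch(.smiles_props(m$smiles), error = function(e) NULL)
  if (is.null(p) || p$wildcard || formula_has_wildcard(m$formula)) return(NA)
  given <- tryCatch(parse_formula(m$formula), error = function(e) NULL)
  if (is.null(given)) return(NA)
  identical(given$counts, parse_formula(p$formula)$counts)
}
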