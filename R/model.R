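# The in-memory model: source-scoped metabolite and reaction entries.

#' Construct a metabolite entry
#'
#' A source-scoped metabolite record: ordered synonym list, optional formula,
#' integer charge and SMILES descriptor, compartment tag, and a structural
#' resolution class (computed with [resolution_class()] unless supplied).
#' At least one of `names`/`smiles` must be present. Fractional charges are
#' rejected, not rounded: protonation states are expected to be the integer
#' charge of the major microspecies at the source's reference pH.
#'
#' @param id source-scoped identifier.
#' @param names character vector of synonyms (defaults to `id`).
#' @param formula optional element formula string.
#' @param charge optional integer charge.
#' @param smiles optional SMILES descriptor (stereo and/or connectivity
#'   detail).
#' @param compartment optional compartment tag.
#' @param resolution `"full"`, `"partial"` or `"none"`; computed when `NULL`.
#' @return an object of class `mrx_metabolite`.
#' @export
metabolite_entry <- function(id, names = NULL, formula = NA_character_,
                             charge = NA_real_, smiles = NA_character_,
                             compartment = NA_character_, resolution = NULL) {
  .check(is.character(id) && length(id) == 1 && nzchar(id),
         "metabolite id must be a non-empty string")
  if (is.null(names) || length(names) == 0) names <- id
  names <- as.character(names)
  has_smiles <- !is.na(smiles) && nzchar(smiles)
  .check(any(nzchar(names)) || has_smiles,
         "metabolite %s must have a name or a structure", id)
  if (!is.na(charge)) {
    .check(is.numeric(charge) && charge == round(charge),
           "charge of %s must be an integer (got %s)", id, format(charge))
    charge <- as.numeric(charge)
  }
  m <- structure(list(id = id, names = names, formula = formula,
                      charge = charge, smiles = smiles,
                      compartment = compartment, resolution = NA_character_),
                 class = "mrx_metabolite")
  m$resolution <- if (is.null(resolution)) resolution_class(m) else {
    .check(resolution %in% c("full", "partial", "none"),
           "bad resolution class '%s'", resolution)
    resolution
  }
  m
}

#' @export
print.mrx_metabolite <- function(x, ...) {
  cat(sprintf("<metabolite %s> %s  [%s]\n", x$id, x$names[1], x$resolution))
  if (!is.na(x$formula)) cat("  formula: ", x$formula,
                             if (!is.na(x$charge)) sprintf(" charge %+d", x$charge),
                             "\n", sep = "")
  if (!is.na(x$smiles)) cat("  smiles:  ", x$smiles, "\n", sep = "")
  invisible(x)
}

#' Construct a model
#'
#' @param name model name.
#' @param metabolites list of [metabolite_entry()] objects.
#' @param reactions list of [reaction_entry()] objects.
#' @param objective optional reaction id to maximize in FBA.
#' @param bounds named list of `c(lower, upper)` flux bounds per reaction id;
#'   reactions without explicit bounds get direction-based defaults at solve
#'   time.
#' @return an object of class `mrx_model`.
#' @export
new_model <- function(name, metabolites, reactions, objective = NULL,
                      bounds = list()) {
  mets <- stats::setNames(metabolites,
                          vapply(metabolites, `[[`, character(1), "id"))
  rxns <- stats::setNames(reactions,
                          vapply(reactions, `[[`, character(1), "id"))
  .check(!anyDuplicated(names(mets)), "duplicate metabolite ids in model %s", name)
  .check(!anyDuplicated(names(rxns)), "duplicate reaction ids in model %s", name)
  for (r in rxns) {
    missing <- setdiff(r$participants$met, names(mets))
    .check(length(missing) == 0,
           "reaction %s references unknown metabolite(s): %s",
           r$id, paste(missing, collapse = ", "))
  }
  if (!is.null(objective))
    .check(objective %in% names(rxns),
           "objective '%s' names no reaction in model %s", objective, name)
  structure(list(name = name, metabolites = mets, reactions = rxns,
                 objective = objective, bounds = bounds),
            class = "mrx_model")
}

#' @export
print.mrx_model <- function(x, ...) {
  res <- table(factor(vapply(x$metabolites, `[[`, character(1), "resolution"),
                      levels = c("full", "partial", "none")))
  cat(sprintf("<model %s> %d metabolites (%d full, %d partial, %d none), %d reactions\n",
              x$name, length(x$metabolites), res["full"], res["partial"],
              res["none"], length(x$reactions)))
  if (!is.null(x$objective)) cat("  objective:", x$objective, "\n")
  invisible(x)
}

#' Load a model from tabular files
#'
#' The reaction table is UTF-8 tab-separated with columns `id`, `equation`
#' and optional `ec`, `genes`; each equation is parsed with
#' [parse_reaction_string()]. The optional metabolite table has columns `id`,
#' `names` (synonyms separated by `|` or `;`), `formula`, `charge`, `smiles`.
#' Every reaction participant without a metabolite-table row gets an
#' auto-created entry with resolution `"none"`.
#'
#' @param reaction_table path to the reaction TSV (or an equivalent data
#'   frame).
#' @param metabolite_table optional path to the metabolite TSV (or data
#'   frame).
#' @param name model name (defaults to the reaction file name).
#' @param dialect passed to [parse_reaction_string()].
#' @return an [new_model()] object.
#' @export
load_model <- function(reaction_table, metabolite_table = NULL,
                       name = NULL, dialect = "auto") {
  rt <- if (is.data.frame(reaction_table)) reaction_table else
    utils::read.delim(reaction_table, stringsAsFactors = FALSE,
                      comment.char = "#", quote = "")
  .check(all(c("id", "equation") %in% names(rt)),
         "reaction table needs columns 'id' and 'equation'")
  .check(!anyDuplicated(rt$id), "duplicate reaction ids: %s",
         paste(unique(rt$id[duplicated(rt$id)]), collapse = ", "))
  if (is.null(name))
    name <- if (is.character(reaction_table))
      sub("\\.[^.]*$", "", basename(reaction_table)) else "model"

  rxns <- lapply(seq_len(nrow(rt)), function(i) {
    r <- parse_reaction_string(rt$equation[i], dialect = dialect,
                               id = as.character(rt$id[i]), source = name)
    if ("ec" %in% names(rt)) r$ec <- as.character(rt$ec[i])
    if ("genes" %in% names(rt)) r$genes <- as.character(rt$genes[i])
    r
  })

  mets <- list()
  if (!is.null(metabolite_table)) {
    mt <- if (is.data.frame(metabolite_table)) metabolite_table else
      utils::read.delim(metabolite_table, stringsAsFactors = FALSE,
                        comment.char = "#", quote = "")
    .check(all(c("id", "names") %in% names(mt)),
           "metabolite table needs columns 'id' and 'names'")
    for (i in seq_len(nrow(mt))) {
      ch <- NA_real_
      if ("charge" %in% names(mt) && !is.na(mt$charge[i]) &&
          nzchar(as.character(mt$charge[i]))) {
        chs <- as.character(mt$charge[i])
        .check(grepl("^[+-]?[0-9]+$", chs),
               "malformed charge '%s' for metabolite %s", chs, mt$id[i])
        ch <- as.numeric(chs)
      }
      getcol <- function(col) {
        if (col %in% names(mt) && !is.na(mt[[col]][i]) && nzchar(mt[[col]][i]))
          as.character(mt[[col]][i]) else NA_character_
      }
      mets[[as.character(mt$id[i])]] <- metabolite_entry(
        id = as.character(mt$id[i]),
        names = strsplit(as.character(mt$names[i]), "[|;]")[[1]],
        formula = getcol("formula"), charge = ch, smiles = getcol("smiles"))
    }
  }
  for (r in rxns) {
    for (j in seq_len(nrow(r$participants))) {
      met <- r$participants$met[j]
      if (is.null(mets[[met]]))
        mets[[met]] <- metabolite_entry(
          id = met, compartment = r$participants$compartment[j],
          resolution = "none")
    }
  }
  new_model(name, mets, rxns)
}
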