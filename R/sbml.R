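# SBML Level 3 Version 1 export/import with the fbc extension.
#
# Species are (metabolite, compartment) pairs; the objective and flux bounds
# travel through fbc. Exact rational stoichiometries and source-scoped
# metadata (original ids, synonyms, SMILES, direction of backward-written
# reactions) do not fit core SBML attributes, so they ride along as
# foreign-namespace attributes and are restored on import - the round trip
# preserves participants, direction, compartments, objective and bounds
# exactly.

.SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
.MRX_NS <- "https://metreconcile.r-pkg/ns/1"

# deterministic SId sanitization; collisions are an error, never silent
.sanitize_sid <- function(x) {
  s <- gsub("[^A-Za-z0-9_]", "_", x)
  ifelse(grepl("^[0-9]", s), paste0("_", s), s)
}

.sid_map <- function(ids, prefix) {
  sids <- paste0(prefix, .sanitize_sid(ids))
  dup <- duplicated(sids)
  .check(!any(dup),
         "SBML id sanitization collision: %s all map to '%s'",
         paste(ids[sids %in% sids[dup]], collapse = ", "), sids[dup][1])
  stats::setNames(sids, ids)
}

#' Export a model to SBML
#'
#' Writes SBML L3V1 with the fbc version 2 extension: compartments, species
#' (with fbc charge/formula where known), reactions with flux bounds, and
#' the active maximization objective when set. Metabolite ids not valid as
#' SBML SIds are sanitized deterministically; a collision raises an error.
#'
#' @param model an [new_model()] object.
#' @param file optional path; when given the document is also written there.
#' @return an `xml2::xml_document`, invisibly when `file` is given.
#' @export
export_sbml <- function(model, file = NULL) {
  comp_of <- function(x) ifelse(is.na(x) | !nzchar(x), "default", x)

  # species = (met, compartment) pairs actually used
  sp <- unique(do.call(rbind, lapply(model$reactions, function(r)
    data.frame(met = r$participants$met,
               comp = comp_of(r$participants$compartment),
               stringsAsFactors = FALSE))))
  # metabolites never referenced still belong to the model
  orphan <- setdiff(names(model$metabolites), sp$met)
  if (length(orphan))
    sp <- rbind(sp, data.frame(
      met = orphan,
      comp = comp_of(vapply(model$metabolites[orphan], `[[`, character(1),
                            "compartment")),
      stringsAsFactors = FALSE))
  met_sid <- .sid_map(unique(sp$met), "M_")
  rxn_sid <- .sid_map(names(model$reactions), "R_")
  sp$sid <- paste0(met_sid[sp$met], "_", .sanitize_sid(sp$comp))
  .check(!anyDuplicated(sp$sid), "SBML species id collision")

  doc <- xml2::xml_new_root(
    "sbml", "xmlns" = .SBML_NS, "xmlns:fbc" = .FBC_NS, "xmlns:mrx" = .MRX_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model",
                             id = .sanitize_sid(model$name),
                             name = model$name, "fbc:strict" = "false")

  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cid in sort(unique(sp$comp)))
    xml2::xml_add_child(lc, "compartment", id = .sanitize_sid(cid),
                        name = cid, constant = "true")

  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(sp))) {
    met <- model$metabolites[[sp$met[i]]]
    node <- xml2::xml_add_child(
      ls, "species", id = sp$sid[i], name = met$names[1],
      compartment = .sanitize_sid(sp$comp[i]), constant = "false",
      boundaryCondition = "false", hasOnlySubstanceUnits = "false",
      "mrx:id" = met$id, "mrx:compartment" = sp$comp[i],
      "mrx:names" = paste(met$names, collapse = "|"),
      "mrx:resolution" = met$resolution)
    if (!is.na(met$charge))
      xml2::xml_set_attr(node, "fbc:charge", format(met$charge))
    if (!is.na(met$formula))
      xml2::xml_set_attr(node, "fbc:chemicalFormula", met$formula)
    if (!is.na(met$smiles)) xml2::xml_set_attr(node, "mrx:smiles", met$smiles)
  }

  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (rid in names(model$reactions)) {
    explicit <- !is.null(model$bounds[[rid]])
    bd <- model$bounds[[rid]] %||% .default_bounds(model$reactions[[rid]])
    for (side in 1:2)
      xml2::xml_add_child(lp, "parameter",
                          id = paste0(c("P_lb_", "P_ub_")[side], rxn_sid[rid]),
                          value = format(bd[side], scientific = FALSE),
                          constant = "true",
                          "mrx:explicit" = tolower(as.character(explicit)))
  }

  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    node <- xml2::xml_add_child(
      lr, "reaction", id = rxn_sid[r$id],
      reversible = tolower(as.character(r$direction == "reversible")),
      fast = "false",
      "fbc:lowerFluxBound" = paste0("P_lb_", rxn_sid[r$id]),
      "fbc:upperFluxBound" = paste0("P_ub_", rxn_sid[r$id]),
      "mrx:id" = r$id, "mrx:direction" = r$direction)
    if (!is.na(r$ec)) xml2::xml_set_attr(node, "mrx:ec", r$ec)
    if (!is.na(r$genes)) xml2::xml_set_attr(node, "mrx:genes", r$genes)
    if (!is.na(r$source)) xml2::xml_set_attr(node, "mrx:source", r$source)
    p <- r$participants
    comp <- ifelse(is.na(p$compartment) | !nzchar(p$compartment), "default",
                   p$compartment)
    for (side in list(c("listOfReactants", -1), c("listOfProducts", 1))) {
      sel <- sign(p$num) == as.numeric(side[2])
      if (!any(sel)) next
      lst <- xml2::xml_add_child(node, side[1])
      for (j in which(sel))
        xml2::xml_add_child(
          lst, "speciesReference",
          species = paste0(met_sid[p$met[j]], "_", .sanitize_sid(comp[j])),
          stoichiometry = format(abs(p$coef[j]), digits = 17),
          constant = "true",
          "mrx:num" = format(abs(p$num[j]), scientific = FALSE),
          "mrx:den" = format(p$den[j], scientific = FALSE))
    }
  }

  if (!is.null(model$objective)) {
    lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lf, "fbc:fluxObjective",
                        "fbc:reaction" = rxn_sid[model$objective],
                        "fbc:coefficient" = "1")
  }

  if (!is.null(file)) {
    xml2::write_xml(doc, file)
    return(invisible(doc))
  }
  doc
}

#' Import a model from SBML
#'
#' Reads documents written by [export_sbml()] (and plain L3+fbc documents:
#' without the package's foreign attributes, ids fall back to SBML SIds,
#' stoichiometries to their decimal values, and direction to the
#' `reversible` flag).
#'
#' @param x path to an SBML file or an `xml2::xml_document`.
#' @return an [new_model()] object.
#' @export
import_sbml <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  ns <- xml2::xml_ns(doc)
  el <- function(node, name)                 # namespace-agnostic element find
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
  xattr <- function(node, name) {            # prefixed-attribute lookup
    at <- xml2::xml_attrs(node, ns)
    if (name %in% names(at)) unname(at[[name]]) else NA_character_
  }
  mdl <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  .check(!inherits(mdl, "xml_missing"), "no <model> element in SBML document")
  name <- xml2::xml_attr(mdl, "name")
  if (is.na(name)) name <- xml2::xml_attr(mdl, "id")

  attr_or <- function(node, name, default = NA_character_) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) default else v
  }

  mets <- list()
  sid_info <- list()
  for (node in el(mdl, "species")) {
    sid <- xml2::xml_attr(node, "id")
    mrx_id <- xattr(node, "mrx:id")
    mid <- if (!is.na(mrx_id)) mrx_id else sub("^M_", "", sid)
    comp <- xattr(node, "mrx:compartment")
    if (is.na(comp)) comp <- attr_or(node, "compartment", "default")
    sid_info[[sid]] <- list(met = mid,
                            comp = if (identical(comp, "default"))
                              NA_character_ else comp)
    if (is.null(mets[[mid]])) {
      charge <- xattr(node, "fbc:charge")
      nmattr <- xattr(node, "mrx:names")
      resol <- xattr(node, "mrx:resolution")
      mets[[mid]] <- metabolite_entry(
        id = mid,
        names = if (!is.na(nmattr)) strsplit(nmattr, "|", fixed = TRUE)[[1]]
                else attr_or(node, "name", mid),
        formula = xattr(node, "fbc:chemicalFormula"),
        charge = if (is.na(charge)) NA_real_ else as.numeric(charge),
        smiles = xattr(node, "mrx:smiles"),
        compartment = if (identical(comp, "default")) NA_character_ else comp,
        resolution = if (resol %in% c("full", "partial", "none")) resol
                     else NULL)
    }
  }

  params <- list()
  for (node in el(mdl, "parameter"))
    params[[xml2::xml_attr(node, "id")]] <-
      list(value = as.numeric(xml2::xml_attr(node, "value")),
           explicit = identical(xattr(node, "mrx:explicit"), "true"))

  rxns <- list(); bounds <- list()
  for (node in el(mdl, "reaction")) {
    sid <- xml2::xml_attr(node, "id")
    rid <- xattr(node, "mrx:id")
    if (is.na(rid)) rid <- sub("^R_", "", sid)
    direction <- xattr(node, "mrx:direction")
    if (is.na(direction))
      direction <- if (identical(xml2::xml_attr(node, "reversible"), "true"))
        "reversible" else "forward"

    part <- list()
    for (side in list(c("listOfReactants", -1), c("listOfProducts", 1))) {
      side_nodes <- xml2::xml_find_all(node, sprintf(
        "./*[local-name()='%s']/*[local-name()='speciesReference']", side[1]))
      for (ref in side_nodes) {
        info <- sid_info[[xml2::xml_attr(ref, "species")]]
        .check(!is.null(info), "reaction %s references unknown species %s",
               rid, xml2::xml_attr(ref, "species"))
        num <- xattr(ref, "mrx:num")
        den <- xattr(ref, "mrx:den")
        if (!is.na(num) && !is.na(den)) {
          num <- as.numeric(num); den <- as.numeric(den)
        } else {
          num <- as.numeric(xml2::xml_attr(ref, "stoichiometry")); den <- 1
          if (num != round(num)) {          # recover simple rationals
            den <- 10^min(nchar(sub("^[^.]*\\.", "", format(num))), 9)
            num <- round(num * den)
          }
        }
        part[[length(part) + 1L]] <- data.frame(
          met = info$met, num = as.numeric(side[2]) * num, den = den,
          compartment = info$comp, stringsAsFactors = FALSE)
      }
    }
    r <- reaction_entry(rid, do.call(rbind, part), direction = direction,
                        ec = xattr(node, "mrx:ec"),
                        genes = xattr(node, "mrx:genes"),
                        source = xattr(node, "mrx:source"))
    rxns[[rid]] <- r

    lbid <- xattr(node, "fbc:lowerFluxBound")
    ubid <- xattr(node, "fbc:upperFluxBound")
    lbp <- if (!is.na(lbid)) params[[lbid]] else NULL
    ubp <- if (!is.na(ubid)) params[[ubid]] else NULL
    if (!is.null(lbp) && !is.null(ubp) && (lbp$explicit || ubp$explicit))
      bounds[[rid]] <- c(lbp$value, ubp$value)
  }

  objective <- NULL
  fo <- el(mdl, "fluxObjective")
  if (length(fo)) {
    osid <- xattr(fo[[1]], "fbc:reaction")
    for (n in el(mdl, "reaction")) {
      if (identical(xml2::xml_attr(n, "id"), osid)) {
        oid <- xattr(n, "mrx:id")
        objective <- if (!is.na(oid)) oid else sub("^R_", "", osid)
        break
      }
    }
  }

  # species present in the file but unused by any reaction
  for (info in sid_info) {
    if (is.null(mets[[info$met]]))
      mets[[info$met]] <- metabolite_entry(info$met, compartment = info$comp,
                                           resolution = "none")
  }
  new_model(name, mets, rxns, objective = objective, bounds = bounds)
}
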