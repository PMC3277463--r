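# JSON serialization of models, the interchange format of the command-line
# tools.

#' Write a model to JSON
#'
#' @param model an [new_model()] object.
#' @param path output file; when `NULL` the JSON string is returned.
#' @return the path (invisibly) or a JSON string.
#' @export
write_model_json <- function(model, path = NULL) {
  obj <- list(
    name = model$name,
    metabolites = lapply(unname(model$metabolites), function(m)
      list(id = m$id, names = as.list(m$names), formula = m$formula,
           charge = m$charge, smiles = m$smiles, compartment = m$compartment,
           resolution = m$resolution)),
    reactions = lapply(unname(model$reactions), function(r)
      list(id = r$id, direction = r$direction, ec = r$ec, genes = r$genes,
           source = r$source,
           participants = lapply(seq_len(nrow(r$participants)), function(j)
             list(met = r$participants$met[j], num = r$participants$num[j],
                  den = r$participants$den[j],
                  compartment = r$participants$compartment[j])))),
    objective = model$objective,
    bounds = model$bounds)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", na = "null",
                         digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Read a model from JSON
#'
#' @param path path to a file written by [write_model_json()] (or a JSON
#'   string).
#' @return an [new_model()] object.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  chr1 <- function(x) if (is.null(x)) NA_character_ else as.character(x)
  mets <- lapply(obj$metabolites, function(m)
    metabolite_entry(m$id, names = unlist(m$names), formula = chr1(m$formula),
                     charge = if (is.null(m$charge)) NA_real_
                              else as.numeric(m$charge),
                     smiles = chr1(m$smiles),
                     compartment = chr1(m$compartment),
                     resolution = m$resolution))
  rxns <- lapply(obj$reactions, function(r) {
    p <- do.call(rbind, lapply(r$participants, function(pp)
      data.frame(met = pp$met, num = as.numeric(pp$num),
                 den = as.numeric(pp$den),
                 compartment = chr1(pp$compartment),
                 stringsAsFactors = FALSE)))
    reaction_entry(r$id, p, direction = r$direction, ec = chr1(r$ec),
                   genes = chr1(r$genes), source = chr1(r$source))
  })
  bounds <- lapply(obj$bounds, function(b) as.numeric(unlist(b)))
  new_model(obj$name, mets, rxns, objective = obj$objective, bounds = bounds)
}
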