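# Independent path-enumeration oracle: igraph simple paths on the bipartite
# graph, filtered by reaction length and one-orientation-per-reaction.

igraph_oracle <- function(g, source, target, slack) {
  edges <- unlist(lapply(names(g$out), function(from)
    as.vector(rbind(from, g$out[[from]]))))
  if (is.null(edges)) return(list(paths = list(), min_length = NA))
  ig <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE))
  if (!source %in% igraph::V(ig)$name || !target %in% igraph::V(ig)$name)
    return(list(paths = list(), min_length = NA))
  sp <- igraph::all_simple_paths(ig, from = source, to = target)
  keep <- list()
  for (p in sp) {
    nodes <- igraph::V(ig)$name[p]
    rxns <- nodes[seq(2, length(nodes), by = 2)]
    bases <- sub("#[fr]$", "", rxns)
    if (anyDuplicated(bases)) next
    keep[[length(keep) + 1L]] <- nodes
  }
  if (!length(keep)) return(list(paths = list(), min_length = NA))
  lens <- vapply(keep, function(p) (length(p) - 1L) %/% 2L, integer(1))
  lmin <- min(lens)
  keep <- keep[lens <= lmin + slack]
  list(paths = keep, min_length = lmin)
}
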