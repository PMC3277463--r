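# Bipartite metabolite-reaction graph construction and exhaustive minimal
# source-to-target pathway enumeration.
#
# Paths are graph-connective only: no stoichiometric feasibility is imposed,
# which is the standard trade-off that lets the enumeration stay exhaustive
# at database scale. Currency metabolites (protons, water, the adenylate and
# nicotinamide pools, CO2) carry no arcs at all, so they can never act as
# biologically meaningless shortcuts.

#' Default currency metabolite ids
#'
#' The ubiquitous cofactors excluded from path searches. The choice of
#' exclusion list changes path counts, so it is explicit and overridable.
#' @export
DEFAULT_CURRENCY <- c("h", "h2o", "atp", "adp", "pi", "nad", "nadh",
                      "nadp", "nadph", "co2")

#' Build the bipartite metabolite-reaction graph
#'
#' Each irreversible reaction contributes arcs substrate -> reaction and
#' reaction -> product; a reversible reaction contributes a mirrored pair of
#' orientation nodes (`id#f`, `id#r`). Metabolites in the currency set carry
#' no arcs. Reactions with a participant that does not map to a key are
#' skipped with a warning.
#'
#' @param reactions list of [reaction_entry()] objects.
#' @param currency character vector of currency metabolite keys (after `ids`
#'   mapping); default [DEFAULT_CURRENCY].
#' @param ids optional named character vector mapping metabolite ids to keys;
#'   by default metabolite ids are used as node keys directly.
#' @return an object of class `mrx_graph`: adjacency list `out`, node type
#'   map, and the excluded currency set.
#' @export
build_graph <- function(reactions, currency = DEFAULT_CURRENCY, ids = NULL) {
  out <- list()
  met_nodes <- character()
  rxn_nodes <- character()
  add_arc <- function(from, to) out[[from]] <<- c(out[[from]], to)

  for (r in reactions) {
    mets <- r$participants$met
    if (!is.null(ids)) {
      keys <- unname(ids[mets])
      if (anyNA(keys)) {
        warning("skipping reaction ", r$id, ": unresolved participant(s)",
                call. = FALSE)
        next
      }
    } else keys <- mets
    subs <- unique(keys[r$participants$num < 0])
    prods <- unique(keys[r$participants$num > 0])
    subs <- setdiff(subs, currency)
    prods <- setdiff(prods, currency)
    met_nodes <- union(met_nodes, c(subs, prods))
    orient <- if (r$direction == "reversible") {
      list(list(node = paste0(r$id, "#f"), s = subs, p = prods),
           list(node = paste0(r$id, "#r"), s = prods, p = subs))
    } else if (r$direction == "backward") {
      list(list(node = paste0(r$id, "#r"), s = prods, p = subs))
    } else {
      list(list(node = paste0(r$id, "#f"), s = subs, p = prods))
    }
    for (o in orient) {
      rxn_nodes <- c(rxn_nodes, o$node)
      for (s in o$s) add_arc(s, o$node)
      for (p in o$p) add_arc(o$node, p)
    }
  }
  # deterministic adjacency order
  out <- lapply(out, function(v) sort(unique(v)))
  structure(list(out = out, metabolites = sort(met_nodes),
                 reactions = sort(rxn_nodes), excluded = sort(currency)),
            class = "mrx_graph")
}

#' @export
print.mrx_graph <- function(x, ...) {
  cat(sprintf("<reaction graph> %d metabolite nodes, %d reaction orientation nodes, %d arcs\n",
              length(x$metabolites), length(x$reactions),
              sum(lengths(x$out))))
  invisible(x)
}

# reaction id behind an orientation node ("r1#f" -> "r1")
.orientation_base <- function(node) sub("#[fr]$", "", node)

#' Enumerate all minimal (and near-minimal) pathways
#'
#' Returns every path from `source` to `target` whose reaction count is at
#' most `L* + slack`, where `L*` is the minimum reaction count. A path is an
#' alternating metabolite/reaction sequence; a reaction may appear at most
#' once (in either orientation) and metabolites are never revisited. Output
#' order is deterministic: length ascending, then lexicographic on the
#' reaction-id sequence. Enumeration stops at `cap` paths with an explicit
#' truncation flag.
#'
#' @param g an [build_graph()] result.
#' @param source,target metabolite keys.
#' @param slack extra reaction-length beyond the minimum (default 0).
#' @param cap maximum number of paths to return (default 1000).
#' @return list of paths (each a character vector alternating metabolite,
#'   reaction-orientation, metabolite, ...), with attributes `reachable`,
#'   `truncated` and `min_length`.
#' @export
enumerate_min_paths <- function(g, source, target, slack = 0L, cap = 1000L) {
  .check(source %in% g$metabolites, "source '%s' not in graph", source)
  .check(target %in% g$metabolites, "target '%s' not in graph", target)

  # BFS over metabolite layers for the minimum reaction count
  dist <- stats::setNames(rep(Inf, length(g$metabolites)), g$metabolites)
  dist[source] <- 0
  frontier <- source
  while (length(frontier) && !is.finite(dist[target])) {
    nxt <- character()
    for (metn in frontier) {
      for (rn in g$out[[metn]] %||% character()) {
        for (pn in g$out[[rn]] %||% character()) {
          if (!is.finite(dist[pn])) {
            dist[pn] <- dist[metn] + 1
            nxt <- c(nxt, pn)
          }
        }
      }
    }
    frontier <- unique(nxt)
  }
  if (!is.finite(dist[target])) {
    out <- list()
    attr(out, "reachable") <- FALSE
    attr(out, "truncated") <- FALSE
    attr(out, "min_length") <- NA_integer_
    return(out)
  }
  lmax <- dist[[target]] + slack

  paths <- list()
  truncated <- FALSE
  # depth-first over sorted adjacency: lexicographic emission order within a
  # length class is produced by the final sort; the cap is applied after
  # ordering candidates of each length via full enumeration up to cap
  walk <- function(metn, seq_nodes, used_rxn, used_met, len) {
    if (truncated) return()
    if (metn == target && len >= 1) {
      paths[[length(paths) + 1L]] <<- seq_nodes
      if (length(paths) >= cap) truncated <<- TRUE
      return()
    }
    if (len >= lmax) return()
    for (rn in g$out[[metn]] %||% character()) {
      base <- .orientation_base(rn)
      if (base %in% used_rxn) next
      for (pn in g$out[[rn]] %||% character()) {
        if (pn %in% used_met) next
        walk(pn, c(seq_nodes, rn, pn), c(used_rxn, base),
             c(used_met, pn), len + 1L)
      }
    }
  }
  walk(source, source, character(), source, 0L)

  lens <- vapply(paths, function(p) (length(p) - 1L) %/% 2L, integer(1))
  rxn_seq <- vapply(paths, function(p)
    paste(p[seq(2, length(p), by = 2)], collapse = "\r"), character(1))
  ord <- order(lens, rxn_seq)
  paths <- paths[ord]
  attr(paths, "reachable") <- TRUE
  attr(paths, "truncated") <- truncated
  attr(paths, "min_length") <- as.integer(dist[[target]])
  paths
}
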