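# Cross-source reconciliation: canonical reaction keys, duplicate
# consolidation, iterative context-based resolution, and model comparison.
#
# All cross-source identity runs on connectivity-level structure keys.
# Reaction keys suppress direction, simplify compartments to
# internal/transport and exclude free protons: reactions that differ only in
# protonation convention are the same chemistry, whereas water differences
# change the chemistry (a wrong water coefficient is a balancing error, not a
# naming variant) and stay visible.

.proton_key <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- structure_key("[H+]", "connectivity")$key
    val
  }
})

# signal (not a plain error) for callers that route unresolvables to a tally
.unresolvable <- function(msg) {
  stop(structure(class = c("mrx_unresolvable", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Connectivity-key map for a model
#'
#' @param m an [new_model()] object.
#' @param level key level passed to [structure_key()].
#' @return named character vector: metabolite id to canonical key, for every
#'   entry with a parseable structure.
#' @export
model_keys <- function(m, level = "connectivity") {
  out <- character()
  for (met in m$metabolites) {
    if (is.na(met$smiles) || !nzchar(met$smiles)) next
    k <- tryCatch(structure_key(met$smiles, level)$key, error = function(e) NULL)
    if (!is.null(k)) out[[met$id]] <- k
  }
  out
}

#' Build cofactor family classes from structures
#'
#' Family-mode reaction keys collapse configured cofactor pairs (classically
#' NAD(+)/NADH, NADP(+)/NADPH, F420/F420H2) to one class token, mirroring the
#' temporary suppression of cofactor usage when grouping reactions into
#' families across organisms.
#'
#' @param classes named list: class token -> character vector of SMILES for
#'   the members of that class.
#' @return named character vector mapping connectivity keys to class tokens.
#' @export
make_cofactor_classes <- function(classes) {
  out <- character()
  for (token in names(classes)) {
    for (smi in classes[[token]])
      out[[structure_key(smi, "connectivity")$key]] <- token
  }
  out
}

# rational gcd of |num/den| coefficients: gcd(nums)/lcm(dens)
.coef_scale <- function(num, den) {
  g <- .gcd_v(abs(num))
  l <- .lcm_v(den)
  c(g, l)
}

# render one side of a reaction as a sorted multiset string of
# "token#coef" entries, scale-normalized by (g, l)
.side_string <- function(tokens, num, den, g, l) {
  if (length(tokens) == 0) return("")
  # |num/den| / (g/l) = |num| * l / (den * g), exact integers after reduction
  sc_num <- abs(num) * l
  sc_den <- den * g
  red <- mapply(function(a, b) { d <- .gcd2(a, b); c(a / d, b / d) },
                sc_num, sc_den)
  paste(sort(paste0(tokens, "#", red[1, ], "/", red[2, ])), collapse = ",")
}

#' Canonical reaction key
#'
#' Builds the canonical string identity of a reaction from the sorted
#' multiset of (participant connectivity key, scale-normalized |coefficient|,
#' side class), with direction suppressed, compartments simplified to
#' internal vs transport, and free protons excluded. The key is invariant
#' under direction flip and participant reordering. In `"family"` mode the
#' configured cofactor classes additionally collapse to class tokens.
#'
#' @param r an [reaction_entry()].
#' @param ids named character vector mapping metabolite ids to connectivity
#'   keys (see [model_keys()]).
#' @param mode `"strict"` (default) or `"family"`.
#' @param cofactor_classes named character vector (key -> class token) as
#'   built by [make_cofactor_classes()]; required for `"family"` mode.
#' @return an object of class `mrx_reaction_key` with fields `key`, `mode`,
#'   `compartment_class`.
#' @export
reaction_key <- function(r, ids, mode = c("strict", "family"),
                         cofactor_classes = NULL) {
  mode <- match.arg(mode)
  p <- r$participants
  keys <- unname(ids[p$met])
  missing <- unique(p$met[is.na(keys)])
  if (length(missing))
    .unresolvable(sprintf("reaction %s has unresolved participant(s): %s",
                          r$id, paste(missing, collapse = ", ")))
  keep <- keys != .proton_key()
  p <- p[keep, , drop = FALSE]
  keys <- keys[keep]
  .check(nrow(p) > 0, "reaction %s has only proton participants", r$id)
  if (mode == "family" && length(cofactor_classes)) {
    hit <- !is.na(cofactor_classes[keys])
    keys[hit] <- paste0("class:", cofactor_classes[keys[hit]])
  }
  sc <- .coef_scale(p$num, p$den)
  lhs <- p$num < 0
  sideA <- .side_string(keys[lhs], p$num[lhs], p$den[lhs], sc[1], sc[2])
  sideB <- .side_string(keys[!lhs], p$num[!lhs], p$den[!lhs], sc[1], sc[2])
  sides <- sort(c(sideA, sideB))
  comps <- unique(p$compartment[!is.na(p$compartment)])
  cclass <- if (length(comps) > 1) "transport" else "internal"
  structure(list(key = paste0(sides[1], " <> ", sides[2], " | ", cclass),
                 mode = mode, compartment_class = cclass),
            class = "mrx_reaction_key")
}

#' @export
print.mrx_reaction_key <- function(x, ...) {
  cat(sprintf("<reaction key/%s> %s\n", x$mode, x$key))
  invisible(x)
}

#' Consolidate duplicate metabolites across sources
#'
#' Groups every metabolite entry of the given models by connectivity key;
#' entries whose stereo keys conflict within a connectivity group are
#' sub-flagged (distinct stereo subgroups), not merged at stereo level.
#' Structure-less entries merge only on exact normalized-name signature;
#' entries with neither structure nor usable name never merge. Merging never
#' unites two entries with different connectivity keys.
#'
#' @param sources list of [new_model()] objects.
#' @return an object of class `mrx_consolidation`: data frame with one row
#'   per entry (`source`, `id`, `key`, `stereo_key`, `group`, `subgroup`,
#'   `evidence`, `representative`).
#' @export
consolidate_metabolites <- function(sources) {
  rows <- list()
  for (m in sources) {
    for (met in m$metabolites) {
      key <- stereo <- NA_character_
      if (!is.na(met$smiles) && nzchar(met$smiles)) {
        key <- tryCatch(structure_key(met$smiles, "connectivity")$key,
                        error = function(e) NA_character_)
        stereo <- tryCatch(structure_key(met$smiles, "stereo")$key,
                           error = function(e) NA_character_)
      }
      sig <- NA_character_
      if (length(met$names) && any(nzchar(met$names))) {
        s <- .name_signature(met$names[which(nzchar(met$names))[1]])
        if (nzchar(s)) sig <- s
      }
      rows[[length(rows) + 1L]] <- data.frame(
        source = m$name, id = met$id, key = key, stereo_key = stereo,
        name_sig = sig, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)

  group_id <- ifelse(!is.na(df$key), paste0("k:", df$key),
                     ifelse(!is.na(df$name_sig), paste0("n:", df$name_sig),
                            paste0("x:", df$source, ":", df$id)))
  df$evidence <- ifelse(!is.na(df$key), "structure",
                        ifelse(!is.na(df$name_sig), "name", "singleton"))
  df$group <- match(group_id, unique(group_id))
  # stereo subgroups within a connectivity group
  sub_id <- paste0(df$group, "/", ifelse(is.na(df$stereo_key), "-", df$stereo_key))
  df$subgroup <- stats::ave(seq_along(sub_id), df$group, FUN = function(ix) {
    match(sub_id[ix], unique(sub_id[ix]))
  })
  rep_label <- paste(df$source, df$id, sep = ":")
  df$representative <- stats::ave(rep_label, df$group, FUN = function(x) min(x))
  df$name_sig <- NULL
  structure(df, class = c("mrx_consolidation", "data.frame"))
}

#' @export
print.mrx_consolidation <- function(x, ...) {
  ng <- length(unique(x$group))
  multi <- table(x$group)
  cat(sprintf("<consolidation> %d entries in %d groups (%d groups of size > 1)\n",
              nrow(x), ng, sum(multi > 1)))
  invisible(x)
}

# ---- iterative context-based resolution ------------------------------------

# Leave-one-out context signature of participant j; returns NULL when any
# other participant lacks a key. Free protons are excluded from the context
# multiset, mirroring the strict reaction key: sources disagree on explicit
# protonation, and a context match must see through that.
.context_signature <- function(r, j, ids) {
  p <- r$participants
  slot_key <- unname(ids[p$met[j]])
  if (!is.na(slot_key) && slot_key == .proton_key()) return(NULL)
  other <- p[-j, , drop = FALSE]
  if (nrow(other) == 0) return(NULL)
  keys <- unname(ids[other$met])
  if (anyNA(keys)) return(NULL)
  keep <- keys != .proton_key()
  other <- other[keep, , drop = FALSE]
  keys <- keys[keep]
  if (nrow(other) == 0) return(NULL)
  # scale from the non-proton content of the full reaction (slot included)
  sc <- .coef_scale(c(other$num, p$num[j]), c(other$den, p$den[j]))
  lhs <- other$num < 0
  sideA <- .side_string(keys[lhs], other$num[lhs], other$den[lhs], sc[1], sc[2])
  sideB <- .side_string(keys[!lhs], other$num[!lhs], other$den[!lhs], sc[1], sc[2])
  slot_side <- if (p$num[j] < 0) "A" else "B"
  if (sideA > sideB || (sideA == sideB && slot_side == "B")) {
    tmp <- sideA; sideA <- sideB; sideB <- tmp
    slot_side <- if (slot_side == "A") "B" else "A"
  }
  g <- .gcd2(abs(p$num[j]) * sc[2], p$den[j] * sc[1])
  slot_coef <- paste0(abs(p$num[j]) * sc[2] / g, "/", p$den[j] * sc[1] / g)
  paste0(sideA, " <> ", sideB, " @", slot_side, "#", slot_coef)
}

#' Iteratively resolve unknown metabolites from reaction context
#'
#' Repeats until fixed point: every reaction with exactly one unresolved
#' participant is compared against the fully resolved reactions of the whole
#' corpus; if the remaining participant multiset (direction suppressed,
#' coefficients matched up to a global scale) matches a resolved reaction in
#' exactly one way, the missing participant inherits that slot's structure.
#' Ambiguous slots and reactions with several unknowns only produce
#' suggestions. Entries with partial structural detail (R-groups) are never
#' auto-resolved. An accepted-mapping table (curator decisions) is applied
#' before the first pass.
#'
#' @param corpus list of [new_model()] objects.
#' @param accepted optional data frame (or TSV path) with columns
#'   `query_source`, `query_id`, `target_key` (a canonical SMILES); applied
#'   unconditionally as curator-approved assignments.
#' @param max_passes safety cap on the number of passes.
#' @return list with `models` (updated corpus) and `log`
#'   (`mrx_resolution_log`: data frames `assignments` (with pass numbers),
#'   `suggestions`, `conflicts`).
#' @export
iterative_resolve <- function(corpus, accepted = NULL, max_passes = 100L) {
  names(corpus) <- vapply(corpus, `[[`, character(1), "name")
  assignments <- list(); conflicts <- list(); suggestions <- list()
  assigned_key <- list()   # "source:id" -> connectivity key, this run

  if (!is.null(accepted)) {
    if (is.character(accepted))
      accepted <- utils::read.delim(accepted, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(accepted))) {
      src <- accepted$query_source[i]; qid <- accepted$query_id[i]
      if (is.null(corpus[[src]]) || is.null(corpus[[src]]$metabolites[[qid]]))
        next
      met <- corpus[[src]]$metabolites[[qid]]
      met$smiles <- accepted$target_key[i]
      met$resolution <- resolution_class(met)
      corpus[[src]]$metabolites[[qid]] <- met
      assignments[[length(assignments) + 1L]] <- data.frame(
        pass = 0L, source = src, met = qid, structure = met$smiles,
        from = "accepted-mapping", stringsAsFactors = FALSE)
      assigned_key[[paste(src, qid, sep = ":")]] <-
        structure_key(met$smiles, "connectivity")$key
    }
  }

  pass <- 0L
  repeat {
    pass <- pass + 1L
    if (pass > max_passes) break

    # index of leave-one-out signatures over fully resolved reactions
    index <- new.env(parent = emptyenv())
    for (m in corpus) {
      ids <- model_keys(m)
      res <- vapply(m$metabolites, `[[`, character(1), "resolution")
      for (r in m$reactions) {
        if (!all(res[r$participants$met] == "full")) next
        for (j in seq_len(nrow(r$participants))) {
          sig <- .context_signature(r, j, ids)
          if (is.null(sig)) next
          met <- m$metabolites[[r$participants$met[j]]]
          entry <- list(key = ids[[met$id]], smiles = met$smiles,
                        from = paste(m$name, r$id, sep = ":"))
          index[[sig]] <- c(index[[sig]], list(entry))
        }
      }
    }

    # sweep against the pass-start state; proposals apply at pass end, so a
    # resolution chain takes one pass per link (as in the source workflow,
    # where later passes reuse earlier associations)
    proposals <- list()
    for (mi in seq_along(corpus)) {
      m <- corpus[[mi]]
      ids <- model_keys(m)
      res <- vapply(m$metabolites, `[[`, character(1), "resolution")
      for (r in m$reactions) {
        status <- res[r$participants$met]
        unknown <- which(status == "none")
        if (length(unknown) == 0) next
        if (length(unknown) > 1 || any(status == "partial")) next
        j <- unknown[1]
        sig <- .context_signature(r, j, ids)
        if (is.null(sig)) next
        cands <- index[[sig]]
        if (is.null(cands)) next
        keys <- unique(vapply(cands, `[[`, character(1), "key"))
        met_id <- r$participants$met[j]
        tag <- paste(m$name, met_id, sep = ":")
        if (length(keys) > 1) {
          for (cand in cands)
            suggestions[[length(suggestions) + 1L]] <- data.frame(
              source = m$name, met = met_id, candidate_structure = cand$smiles,
              evidence = "reaction-context", stringsAsFactors = FALSE)
          next
        }
        prior <- assigned_key[[tag]]
        if (is.null(prior) && !is.null(proposals[[tag]]))
          prior <- proposals[[tag]]$key
        if (!is.null(prior) && prior != keys) {
          conflicts[[length(conflicts) + 1L]] <- data.frame(
            source = m$name, met = met_id, existing = prior,
            proposed = keys, stringsAsFactors = FALSE)
          if (is.null(proposals[[tag]]))
            proposals[[tag]] <- list(conflicted = TRUE)
          else proposals[[tag]]$conflicted <- TRUE
          next
        }
        if (!is.null(prior)) next
        proposals[[tag]] <- list(mi = mi, met_id = met_id, key = keys,
                                 smiles = cands[[1]]$smiles,
                                 from = cands[[1]]$from, conflicted = FALSE)
      }
    }
    changed <- FALSE
    for (tag in names(proposals)) {
      pr <- proposals[[tag]]
      if (isTRUE(pr$conflicted)) next
      met <- corpus[[pr$mi]]$metabolites[[pr$met_id]]
      met$smiles <- pr$smiles
      met$resolution <- resolution_class(met)
      corpus[[pr$mi]]$metabolites[[pr$met_id]] <- met
      assigned_key[[tag]] <- pr$key
      assignments[[length(assignments) + 1L]] <- data.frame(
        pass = pass, source = corpus[[pr$mi]]$name, met = pr$met_id,
        structure = pr$smiles, from = pr$from, stringsAsFactors = FALSE)
      changed <- TRUE
    }
    if (!changed) break
  }

  bind <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  log <- structure(list(
    assignments = bind(assignments, data.frame(
      pass = integer(), source = character(), met = character(),
      structure = character(), from = character(), stringsAsFactors = FALSE)),
    suggestions = bind(suggestions, data.frame(
      source = character(), met = character(),
      candidate_structure = character(), evidence = character(),
      stringsAsFactors = FALSE)),
    conflicts = bind(conflicts, data.frame(
      source = character(), met = character(), existing = character(),
      proposed = character(), stringsAsFactors = FALSE))),
    class = "mrx_resolution_log")
  list(models = corpus, log = log)
}

#' @export
print.mrx_resolution_log <- function(x, ...) {
  np <- if (nrow(x$assignments)) max(x$assignments$pass) else 0L
  cat(sprintf("<resolution log> %d assignments over %d passes, %d suggestions, %d conflicts\n",
              nrow(x$assignments), np, nrow(x$suggestions), nrow(x$conflicts)))
  invisible(x)
}

#' Resolve structure-less entries by exact normalized-name match
#'
#' Assigns a structure to every unresolved (resolution `"none"`) entry whose
#' normalized name signature matches exactly one distinct connectivity key
#' among the resolved entries of the corpus. String equality after
#' normalization is treated as evidence strong enough to apply (the
#' suppressed tokens never change chemical identity); phonetic similarity is
#' not - it only ever produces suggestions.
#'
#' @param corpus list of [new_model()] objects.
#' @return list with `models` and `assignments` data frame.
#' @export
resolve_by_name <- function(corpus) {
  names(corpus) <- vapply(corpus, `[[`, character(1), "name")
  # signature -> distinct structures among resolved entries
  sig_index <- list()
  for (m in corpus) {
    for (met in m$metabolites) {
      if (!identical(met$resolution, "full")) next
      key <- tryCatch(structure_key(met$smiles, "connectivity")$key,
                      error = function(e) NULL)
      if (is.null(key)) next
      for (nm in met$names) {
        s <- .name_signature(nm)
        if (!nzchar(s)) next
        sig_index[[s]] <- unique(rbind(
          sig_index[[s]],
          data.frame(key = key, smiles = met$smiles, stringsAsFactors = FALSE)))
      }
    }
  }
  assignments <- list()
  for (mi in seq_along(corpus)) {
    m <- corpus[[mi]]
    for (met_id in names(m$metabolites)) {
      met <- m$metabolites[[met_id]]
      if (!identical(met$resolution, "none")) next
      hits <- unique(do.call(rbind, lapply(met$names, function(nm) {
        s <- .name_signature(nm)
        if (nzchar(s)) sig_index[[s]] else NULL
      })))
      if (is.null(hits) || length(unique(hits$key)) != 1) next
      met$smiles <- hits$smiles[1]
      met$resolution <- resolution_class(met)
      corpus[[mi]]$metabolites[[met_id]] <- met
      assignments[[length(assignments) + 1L]] <- data.frame(
        source = m$name, met = met_id, structure = met$smiles,
        evidence = "exact-normalized", stringsAsFactors = FALSE)
    }
  }
  list(models = corpus,
       assignments = if (length(assignments)) do.call(rbind, assignments)
       else data.frame(source = character(), met = character(),
                       structure = character(), evidence = character(),
                       stringsAsFactors = FALSE))
}

#' Full reconciliation pipeline over a corpus
#'
#' Consolidates duplicates on structure keys, resolves structure-less entries
#' by exact normalized-name match, then runs context-based
#' [iterative_resolve()] to fixed point, alternating the two until no entry
#' changes. Phonetic evidence never changes a model - it surfaces in the
#' suggestion table only.
#'
#' @param corpus list of [new_model()] objects.
#' @param accepted optional curator accepted-mapping table (see
#'   [iterative_resolve()]).
#' @return list with `models`, `consolidation`, `name_assignments`, `log`.
#' @export
reconcile_corpus <- function(corpus, accepted = NULL) {
  name_assignments <- NULL
  log <- NULL
  repeat {
    nb <- resolve_by_name(corpus)
    corpus <- nb$models
    name_assignments <- rbind(name_assignments, nb$assignments)
    it <- iterative_resolve(corpus, accepted = accepted)
    accepted <- NULL                       # apply curator decisions once
    corpus <- it$models
    if (is.null(log)) log <- it$log
    else {
      log$assignments <- rbind(log$assignments, it$log$assignments)
      log$suggestions <- unique(rbind(log$suggestions, it$log$suggestions))
      log$conflicts <- unique(rbind(log$conflicts, it$log$conflicts))
    }
    if (nrow(nb$assignments) == 0 && nrow(it$log$assignments) == 0) break
  }
  list(models = corpus, consolidation = consolidate_metabolites(corpus),
       name_assignments = name_assignments, log = log)
}

#' Compare the metabolite or reaction content of sources
#'
#' Venn-style overlap counts over connectivity keys (metabolite level) or
#' strict reaction keys (reaction level). Compartment information and
#' reversibility are suppressed by the key construction. Entries (or
#' reactions touching entries) with resolution `"partial"` or `"none"` are
#' excluded from the comparison and reported separately: identity claims for
#' them would be guesses.
#'
#' @param sources list of two or more [new_model()] objects.
#' @param level `"metabolite"` or `"reaction"`.
#' @return an object of class `mrx_overlap`: data frame of `region` /
#'   `count` rows plus an `excluded` attribute (per-source tally of entries
#'   left out).
#' @export
compare_sources <- function(sources, level = c("metabolite", "reaction")) {
  level <- match.arg(level)
  .check(length(sources) >= 2, "need at least two sources to compare")
  nm <- vapply(sources, `[[`, character(1), "name")
  .check(!anyDuplicated(nm), "source names must be distinct")

  key_sets <- list(); excluded <- stats::setNames(integer(length(nm)), nm)
  for (m in sources) {
    res <- vapply(m$metabolites, `[[`, character(1), "resolution")
    ids <- model_keys(m)
    if (level == "metabolite") {
      ok <- names(res)[res == "full"]
      excluded[m$name] <- sum(res != "full")
      key_sets[[m$name]] <- unique(unname(ids[ok[ok %in% names(ids)]]))
    } else {
      keys <- character(); n_ex <- 0L
      for (r in m$reactions) {
        if (all(res[r$participants$met] == "full")) {
          k <- tryCatch(reaction_key(r, ids)$key,
                        error = function(e) NULL)
          if (is.null(k)) n_ex <- n_ex + 1L else keys <- c(keys, k)
        } else n_ex <- n_ex + 1L
      }
      excluded[m$name] <- n_ex
      key_sets[[m$name]] <- unique(keys)
    }
  }

  all_keys <- unique(unlist(key_sets))
  membership <- vapply(nm, function(s) all_keys %in% key_sets[[s]],
                       logical(length(all_keys)))
  membership <- matrix(membership, ncol = length(nm),
                       dimnames = list(NULL, nm))
  region <- apply(membership, 1, function(row) paste(nm[row], collapse = "&"))
  tab <- table(region)
  df <- data.frame(region = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-vapply(strsplit(df$region, "&"), length, integer(1)),
                 df$region), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, excluded = excluded, sources = nm,
            class = c("mrx_overlap", "data.frame"))
}

#' @export
print.mrx_overlap <- function(x, ...) {
  cat("<overlap of", paste(attr(x, "sources"), collapse = ", "), ">\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-40s %d\n", x$region[i], x$count[i]))
  ex <- attr(x, "excluded")
  cat("  excluded (partial/none):",
      paste(sprintf("%s=%d", names(ex), ex), collapse = ", "), "\n")
  invisible(x)
}
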