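# Seeded synthetic corpora with injected inconsistencies and ground truth.
#
# The generator builds one chemically coherent "true" network - polyol
# backbones transformed by kinase / dehydrogenase / phosphatase / transport
# templates, with a small set of synthetic stand-in cofactors whose
# phosphoryl- and redox-pair relations are real (a triphosphate/diphosphate
# ester pair, a pyridinium/dihydropyridine pair) - and derives per-model
# views with independently injected error classes that mirror the classic
# roadblocks: naming variants, unbalanced reactions, and incomplete
# structural information. Every injection is recorded, so recovery is
# measurable against ground truth. Model 1 is the structure-rich reference
# view (the role a curated model plays when a name-only model is resolved
# against it); errors are injected into the other views.

.ERROR_CLASSES <- c("missing-proton", "wrong-water-coeff", "name-variant",
                    "case-variant", "stereo-prefix", "id-style-swap",
                    "duplicate-entry", "r-group-masking")

.STEMS <- c("eth", "prop", "but", "pent", "hex", "hept", "oct", "non",
            "dec", "undec", "dodec", "tridec")

# synthetic stand-in cofactors (consistent relations, no organism claimed)
.COFACTORS <- list(
  atp = list(name = "triphosphate donor", smiles = "COP(=O)([O-])OP(=O)([O-])OP(=O)([O-])[O-]",
             formula = "CH3O10P3", charge = -4),
  adp = list(name = "diphosphate acceptor", smiles = "COP(=O)([O-])OP(=O)([O-])[O-]",
             formula = "CH3O7P2", charge = -3),
  pi  = list(name = "orthophosphate", smiles = "OP(=O)([O-])[O-]",
             formula = "HO4P", charge = -2),
  h   = list(name = "proton", smiles = "[H+]", formula = "H", charge = 1),
  h2o = list(name = "water", smiles = "O", formula = "H2O", charge = 0),
  nad = list(name = "pyridinium acceptor", smiles = "C[n+]1ccccc1",
             formula = "C6H8N", charge = 1),
  nadh = list(name = "dihydropyridine donor", smiles = "CN1CC=CC=C1",
              formula = "C6H9N", charge = 0))

# the four backbone-derived species families, per carbon count k
.backbone_species <- function(stem, k) {
  mid <- strrep("C", k - 2)
  list(
    diol = list(id = paste0(stem, "d"), name = paste0(stem, "anediol"),
                smiles = paste0("OC", mid, "CO"),
                formula = sprintf("C%dH%dO2", k, 2 * k + 2), charge = 0),
    ald = list(id = paste0(stem, "al"), name = paste0("hydroxy", stem, "anal"),
               smiles = paste0("OC", mid, "C=O"),
               formula = sprintf("C%dH%dO2", k, 2 * k), charge = 0),
    acid = list(id = paste0(stem, "ac"), name = paste0("hydroxy", stem, "anoate"),
                smiles = paste0("OC", mid, "C(=O)[O-]"),
                formula = sprintf("C%dH%dO3", k, 2 * k - 1), charge = -1),
    phos = list(id = paste0(stem, "dp"),
                name = paste0(stem, "anediol phosphate"),
                smiles = paste0("OC", mid, "COP(=O)([O-])[O-]"),
                formula = sprintf("C%dH%dO5P", k, 2 * k + 1), charge = -2))
}

# normalization-recoverable naming variants per species family
.name_variant <- function(family, sp, k) {
  switch(family,
         diol = sprintf("1,%d-%s", k, sp$name),
         ald = paste0("2-", sp$name),
         acid = sub("ate$", "ic acid", sp$name),
         phos = sprintf("1,%d-%s", k, gsub(" ", "-", sp$name)),
         sp$name)
}

.participants_df <- function(mets, nums, comps = NA_character_) {
  data.frame(met = mets, num = nums, den = 1,
             compartment = rep_len(comps, length(mets)),
             stringsAsFactors = FALSE)
}

# the five reaction templates for one backbone
.backbone_reactions <- function(stem, sp) {
  list(
    kin = reaction_entry(paste0(stem, "_kin"), .participants_df(
      c(sp$diol$id, "atp", sp$phos$id, "adp", "h"),
      c(-1, -1, 1, 1, 1), "c"), direction = "forward", ec = "2.7.1.-"),
    dh1 = reaction_entry(paste0(stem, "_dh1"), .participants_df(
      c(sp$diol$id, "nad", sp$ald$id, "nadh", "h"),
      c(-1, -1, 1, 1, 1), "c"), direction = "reversible", ec = "1.1.1.-"),
    dh2 = reaction_entry(paste0(stem, "_dh2"), .participants_df(
      c(sp$ald$id, "h2o", "nad", sp$acid$id, "nadh", "h"),
      c(-1, -1, -1, 1, 1, 2), "c"), direction = "forward", ec = "1.2.1.-"),
    ptase = reaction_entry(paste0(stem, "_ptase"), .participants_df(
      c(sp$phos$id, "h2o", sp$diol$id, "pi"),
      c(-1, -1, 1, 1), "c"), direction = "forward", ec = "3.1.3.-"),
    tpt = reaction_entry(paste0(stem, "_tpt"), data.frame(
      met = c(sp$diol$id, sp$diol$id), num = c(-1, 1), den = 1,
      compartment = c("e", "c"), stringsAsFactors = FALSE),
      direction = "reversible"))
}

#' Generate a synthetic model corpus with injected inconsistencies
#'
#' Builds a balanced true network of `n_reactions` reactions over polyol
#' backbones and stand-in cofactors, then derives `n_models` source views.
#' View 1 is the clean, structure-rich reference; each subsequent view gets
#' independent error injection at the given per-class rates. Naming error
#' classes (`name-variant`, `case-variant`, `stereo-prefix`) also remove the
#' entry's structure - they emulate name-only sources, which is what makes
#' recovery non-trivial. `id-style-swap` re-keys an entry (structure kept),
#' `duplicate-entry` adds a duplicate under a second id, `r-group-masking`
#' replaces the structure by a wildcard version (partial detail),
#' `missing-proton` deletes one proton from a proton-producing reaction, and
#' `wrong-water-coeff` doubles a water coefficient. Cofactors are never
#' corrupted (their naming is universal in practice). All injections target
#' backbone species/reactions and are logged in the ground truth.
#'
#' @param seed integer seed; the corpus is a deterministic function of it.
#' @param n_reactions number of true reactions (>= 5).
#' @param n_models number of source views (>= 1).
#' @param error_rates named numeric vector/list with entries among
#'   `missing-proton`, `wrong-water-coeff`, `name-variant`, `case-variant`,
#'   `stereo-prefix`, `id-style-swap`, `duplicate-entry`, `r-group-masking`;
#'   probabilities in `[0, 1]`, default 0.
#' @return list with `models` (list of [new_model()]) and `truth` (class
#'   `mrx_ground_truth`: `true_keys` data frame mapping (source, id) to the
#'   true connectivity key, `injected` data frame of all injections, `seed`).
#' @export
make_synthetic_corpus <- function(seed, n_reactions = 50, n_models = 3,
                                  error_rates = list()) {
  .check(n_reactions >= 5, "need at least 5 reactions")
  .check(n_models >= 1, "need at least one model view")
  rates <- stats::setNames(rep(0, length(.ERROR_CLASSES)), .ERROR_CLASSES)
  if (length(error_rates)) {
    bad <- setdiff(names(error_rates), .ERROR_CLASSES)
    .check(length(bad) == 0, "unknown error class(es): %s",
           paste(bad, collapse = ", "))
    rates[names(error_rates)] <- unlist(error_rates)
  }
  .check(all(rates >= 0 & rates <= 1), "error rates must lie in [0, 1]")
  .check(rates[["r-group-masking"]] < 1,
         "masking every structure leaves nothing resolvable")

  n_backbones <- ceiling(n_reactions / 5)
  .check(n_backbones <= length(.STEMS), "n_reactions too large for the stem alphabet")

  # --- true network -----------------------------------------------------
  true_mets <- list()
  for (cid in names(.COFACTORS)) {
    cf <- .COFACTORS[[cid]]
    true_mets[[cid]] <- metabolite_entry(cid, names = cf$name,
                                         formula = cf$formula,
                                         charge = cf$charge,
                                         smiles = cf$smiles, compartment = "c")
  }
  backbone_info <- list()
  true_rxns <- list()
  for (b in seq_len(n_backbones)) {
    stem <- .STEMS[b]; k <- b + 1L
    sp <- .backbone_species(stem, k)
    backbone_info[[stem]] <- list(sp = sp, k = k)
    for (fam in names(sp)) {
      s <- sp[[fam]]
      true_mets[[s$id]] <- metabolite_entry(s$id, names = s$name,
                                            formula = s$formula,
                                            charge = s$charge,
                                            smiles = s$smiles,
                                            compartment = "c")
    }
    true_rxns <- c(true_rxns, .backbone_reactions(stem, sp))
  }
  true_rxns <- true_rxns[seq_len(n_reactions)]
  used <- unique(unlist(lapply(true_rxns, function(r) r$participants$met)))
  true_mets <- true_mets[names(true_mets) %in% c(used, names(.COFACTORS))]

  fam_of <- function(id) {
    for (stem in names(backbone_info)) {
      sp <- backbone_info[[stem]]$sp
      for (fam in names(sp)) if (sp[[fam]]$id == id)
        return(list(stem = stem, fam = fam, sp = sp[[fam]],
                    k = backbone_info[[stem]]$k))
    }
    NULL
  }

  with_seed(seed, {
    models <- list()
    injected <- list()
    note <- function(src, kind, id, class)
      injected[[length(injected) + 1L]] <<- data.frame(
        source = src, kind = kind, target = id, class = class,
        stringsAsFactors = FALSE)

    for (v in seq_len(n_models)) {
      src <- if (v == 1) "ref" else paste0("src", v)
      mets <- true_mets
      rxns <- true_rxns
      if (v > 1) {
        for (mid in names(mets)) {
          info <- fam_of(mid)
          if (is.null(info)) next               # cofactors stay clean
          met <- mets[[mid]]
          roll <- stats::runif(length(.ERROR_CLASSES))
          names(roll) <- .ERROR_CLASSES
          # naming classes are mutually exclusive; first hit wins
          if (roll[["name-variant"]] < rates[["name-variant"]]) {
            met$names <- .name_variant(info$fam, info$sp, info$k)
            met$smiles <- NA_character_
            met$resolution <- resolution_class(met)
            note(src, "metabolite", mid, "name-variant")
          } else if (roll[["case-variant"]] < rates[["case-variant"]]) {
            met$names <- toupper(met$names[1])
            met$smiles <- NA_character_
            met$resolution <- resolution_class(met)
            note(src, "metabolite", mid, "case-variant")
          } else if (roll[["stereo-prefix"]] < rates[["stereo-prefix"]]) {
            met$names <- paste0(sample(c("L-", "D-", "cis-"), 1), met$names[1])
            met$smiles <- NA_character_
            met$resolution <- resolution_class(met)
            note(src, "metabolite", mid, "stereo-prefix")
          } else if (roll[["r-group-masking"]] < rates[["r-group-masking"]]) {
            met$smiles <- sub("^O", "*", met$smiles)
            met$formula <- NA_character_
            met$resolution <- resolution_class(met)
            note(src, "metabolite", mid, "r-group-masking")
          }
          if (roll[["id-style-swap"]] < rates[["id-style-swap"]]) {
            new_id <- sprintf("C%05d", 10000 + match(mid, names(true_mets)))
            met$id <- new_id
            mets[[mid]] <- NULL
            mets[[new_id]] <- met
            rxns <- lapply(rxns, function(r) {
              r$participants$met[r$participants$met == mid] <- new_id
              r
            })
            note(src, "metabolite", mid, "id-style-swap")
          } else mets[[mid]] <- met
          if (roll[["duplicate-entry"]] < rates[["duplicate-entry"]]) {
            dup <- mets[[met$id]]
            dup$id <- paste0(met$id, "_dup")
            mets[[dup$id]] <- dup
            note(src, "metabolite", met$id, "duplicate-entry")
          }
        }
        for (ri in seq_along(rxns)) {
          r <- rxns[[ri]]
          has_h <- any(r$participants$met == "h")
          has_w <- any(r$participants$met == "h2o")
          if (has_h && stats::runif(1) < rates[["missing-proton"]]) {
            p <- r$participants
            j <- which(p$met == "h")[1]
            p$num[j] <- p$num[j] - sign(p$num[j])
            if (p$num[j] == 0) p <- p[-j, , drop = FALSE]
            rxns[[ri]] <- reaction_entry(r$id, p, direction = r$direction,
                                         ec = r$ec, genes = r$genes,
                                         source = r$source)
            note(src, "reaction", r$id, "missing-proton")
          } else if (has_w && stats::runif(1) < rates[["wrong-water-coeff"]]) {
            p <- r$participants
            j <- which(p$met == "h2o")[1]
            p$num[j] <- 2 * p$num[j]
            rxns[[ri]] <- reaction_entry(r$id, p, direction = r$direction,
                                         ec = r$ec, genes = r$genes,
                                         source = r$source)
            note(src, "reaction", r$id, "wrong-water-coeff")
          }
        }
      }
      models[[src]] <- new_model(src, mets, rxns)
    }

    truth_rows <- list()
    for (src in names(models)) {
      for (mid in names(models[[src]]$metabolites)) {
        base <- sub("_dup$", "", mid)
        orig <- if (base %in% names(true_mets)) base else {
          # id-style-swap: recover the original via position
          idx <- suppressWarnings(as.integer(sub("^C", "", mid))) - 10000L
          if (!is.na(idx) && idx >= 1 && idx <= length(true_mets))
            names(true_mets)[idx] else NA_character_
        }
        if (is.na(orig)) next
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          source = src, id = mid,
          key = structure_key(true_mets[[orig]]$smiles, "connectivity")$key,
          stringsAsFactors = FALSE)
      }
    }
    truth <- structure(list(
      true_keys = do.call(rbind, truth_rows),
      injected = if (length(injected)) do.call(rbind, injected)
                 else data.frame(source = character(), kind = character(),
                                 target = character(), class = character(),
                                 stringsAsFactors = FALSE),
      seed = seed), class = "mrx_ground_truth")
    list(models = unname(models), truth = truth)
  })
}

#' @export
print.mrx_ground_truth <- function(x, ...) {
  cat(sprintf("<ground truth> seed %d, %d (source, id) identities, %d injected errors\n",
              x$seed, nrow(x$true_keys), nrow(x$injected)))
  if (nrow(x$injected))
    print(table(x$injected$class))
  invisible(x)
}

#' Fraction of corrupted identities recovered by reconciliation
#'
#' For every metabolite entry whose structure was removed by a naming error
#' class, checks whether the reconciled corpus assigned it a structure whose
#' connectivity key equals the ground-truth key.
#'
#' @param models reconciled corpus (e.g. `reconcile_corpus(...)$models`).
#' @param truth the `mrx_ground_truth` from [make_synthetic_corpus()].
#' @return list with `rate` (fraction in `[0, 1]`, `NaN` when nothing was
#'   corrupted), `n_target`, `n_recovered`.
#' @export
recovery_rate <- function(models, truth) {
  names(models) <- vapply(models, `[[`, character(1), "name")
  targets <- truth$injected[truth$injected$class %in%
    c("name-variant", "case-variant", "stereo-prefix"), , drop = FALSE]
  n_rec <- 0L
  for (i in seq_len(nrow(targets))) {
    src <- targets$source[i]; mid <- targets$target[i]
    met <- models[[src]]$metabolites[[mid]]
    if (is.null(met) || is.na(met$smiles) || !nzchar(met$smiles)) next
    got <- tryCatch(structure_key(met$smiles, "connectivity")$key,
                    error = function(e) NA_character_)
    want <- truth$true_keys$key[truth$true_keys$source == src &
                                  truth$true_keys$id == mid]
    if (length(want) == 1 && !is.na(got) && got == want) n_rec <- n_rec + 1L
  }
  list(rate = n_rec / nrow(targets), n_target = nrow(targets),
       n_recovered = n_rec)
}

#' Toy model in which a repair raises the energetic cost of growth
#'
#' A published-style view of a small network whose main conversion is
#' missing a proton on the reactant side. The repaired version must draw
#' that proton from a side route that consumes the same limiting substrate,
#' so the maximum objective after standardization drops - the qualitative
#' signature of restored proton costs (cf. proton-gradient maintenance in
#' real rebalanced models). With an uptake bound of 10 the published
#' objective is 10 and the repaired one is 5.
#'
#' @return an [new_model()] object with objective `"bio"` set.
#' @export
proton_cost_model <- function() {
  mets <- list(
    metabolite_entry("A", names = "substrate", formula = "CH2O", charge = 0),
    metabolite_entry("B", names = "precursor", formula = "CH3O", charge = 1),
    metabolite_entry("C", names = "byproduct", formula = "CHO", charge = -1),
    metabolite_entry("h", names = "proton", formula = "H", charge = 1))
  rxns <- list(
    reaction_entry("EX_A", .participants_df("A", -1), direction = "reversible"),
    reaction_entry("main", .participants_df(c("A", "B"), c(-1, 1))),
    reaction_entry("hgen", .participants_df(c("A", "C", "h"), c(-1, 1, 1))),
    reaction_entry("EX_C", .participants_df("C", -1)),
    reaction_entry("bio", .participants_df("B", -1)))
  new_model("proton-cost-fixture", mets, rxns, objective = "bio",
            bounds = list(EX_A = c(-10, 0)))
}

#' Load the nine-dialect glucose-6-phosphate dehydrogenase fixture
#'
#' Nine surface representations of one reaction as found across published
#' models (differing arrow conventions, compartment prefixes, metabolite
#' naming styles and cofactor usage), with a synonym/structure table. The
#' cofactor structures are synthetic stand-ins (distinct, chemically
#' consistent molecules), flagged as such in the data files.
#'
#' @return list with `model` (an [new_model()]), `equations` (the raw
#'   strings).
#' @export
table1_fixture <- function() {
  rf <- system.file("extdata", "g6pdh_dialects.tsv", package = "metreconcile",
                    mustWork = TRUE)
  mf <- system.file("extdata", "g6pdh_metabolites_synthetic.tsv",
                    package = "metreconcile", mustWork = TRUE)
  raw <- utils::read.delim(rf, stringsAsFactors = FALSE, quote = "")
  model <- suppressWarnings(load_model(rf, mf, name = "g6pdh-dialects"))
  list(model = model, equations = raw$equation)
}
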