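# Reaction keys, consolidation, context resolution and source comparison.

table1 <- function() table1_fixture()

test_that("the nine dialect strings are nine distinct raw representations", {
  fx <- table1()
  expect_length(fx$equations, 9)
  expect_length(unique(fx$equations), 9)
})

test_that("strict keys collapse synonym/dialect variants, keep cofactors apart", {
  fx <- table1()
  ids <- model_keys(fx$model)
  keys <- vapply(fx$model$reactions, function(r) reaction_key(r, ids)$key,
                 character(1))
  sizes <- sort(as.integer(table(keys)), decreasing = TRUE)
  # one large group (same chemistry under many surface forms), the
  # alternate-cofactor rows stay distinct
  expect_length(sizes, 3)
  expect_gte(sizes[1], 5)
  expect_equal(sizes[2:3], c(1L, 1L))
  grp <- split(names(keys), keys)
  big <- grp[[which.max(lengths(grp))]]
  expect_true(all(c("r1", "r2", "r3", "r5", "r6", "r9") %in% big))
  expect_false("r7" %in% big)   # NAD, not NADP
  expect_false("r4" %in% big)   # F420, not NADP
})

test_that("family mode collapses configured cofactor pairs to one class", {
  fx <- table1()
  ids <- model_keys(fx$model)
  fam <- make_cofactor_classes(list("redox-cofactor" = c(
    "CC[n+]1ccccc1", "CCN1CC=CC=C1", "C[n+]1ccccc1", "CN1CC=CC=C1",
    "C[n+]1ccncc1", "CN1CC=NC=C1")))
  strict7 <- reaction_key(fx$model$reactions[["r7"]], ids)$key
  strict1 <- reaction_key(fx$model$reactions[["r1"]], ids)$key
  expect_false(strict7 == strict1)
  fam7 <- reaction_key(fx$model$reactions[["r7"]], ids, mode = "family",
                       cofactor_classes = fam)$key
  fam1 <- reaction_key(fx$model$reactions[["r1"]], ids, mode = "family",
                       cofactor_classes = fam)$key
  expect_equal(fam7, fam1)
})

test_that("naive string matching finds nothing where key matching groups", {
  fx <- table1()
  expect_equal(max(table(fx$equations)), 1L)      # 0 string groups of size > 1
  ids <- model_keys(fx$model)
  keys <- vapply(fx$model$reactions, function(r) reaction_key(r, ids)$key,
                 character(1))
  expect_gte(max(table(keys)), 5L)
})

test_that("reaction keys are invariant under permutation and direction flip", {
  set.seed(19)
  fx <- make_synthetic_corpus(4, 15, 1)
  m <- fx$models[[1]]
  ids <- model_keys(m)
  for (r in m$reactions) {
    k0 <- reaction_key(r, ids)$key
    # permute participants
    perm <- r
    ord <- sample(nrow(r$participants))
    perm$participants <- r$participants[ord, ]
    expect_equal(reaction_key(perm, ids)$key, k0)
    # flip direction (swap sides)
    flip <- r
    flip$participants$num <- -flip$participants$num
    expect_equal(reaction_key(flip, ids)$key, k0)
    # uniform scaling of all coefficients does not change the key
    scaled <- r
    scaled$participants$num <- 3 * scaled$participants$num
    expect_equal(reaction_key(scaled, ids)$key, k0)
  }
})

test_that("unresolved participants raise the unresolvable signal", {
  r <- rxn("a + b -> c")
  expect_error(reaction_key(r, c(a = "OCCO", b = "OCC=O")),
               class = "mrx_unresolvable")
})

test_that("consolidation groups by structure and sub-flags stereo conflicts", {
  m1 <- new_model("m1", list(met("glc", "OC1OC(CO)C(O)C(O)C1O", names = "glucose")),
                  list(reaction_entry("r", data.frame(met = "glc", num = -1, den = 1))))
  m2 <- new_model("m2", list(met("dglc", "OC1OC(CO)C(O)C(O)C1O", names = "D-glucose")),
                  list(reaction_entry("r", data.frame(met = "dglc", num = -1, den = 1))))
  cm <- consolidate_metabolites(list(m1, m2))
  expect_equal(length(unique(cm$group)), 1)

  # enantiomers: one connectivity group, two stereo subgroups
  mL <- new_model("mL", list(met("lala", "N[C@@H](C)C(=O)O")), list(
    reaction_entry("r", data.frame(met = "lala", num = -1, den = 1))))
  mD <- new_model("mD", list(met("dala", "N[C@H](C)C(=O)O")), list(
    reaction_entry("r", data.frame(met = "dala", num = -1, den = 1))))
  cm2 <- consolidate_metabolites(list(mL, mD))
  expect_equal(length(unique(cm2$group)), 1)
  expect_equal(length(unique(cm2$subgroup)), 2)

  # one shared name over two structures: structure wins, two groups
  amp1 <- new_model("x1", list(met("AMP", "Nc1ncnc2n(cnc12)C1OC(COP(=O)(O)O)C(O)C1O",
                                   names = "AMP")),
                    list(reaction_entry("r", data.frame(met = "AMP", num = -1, den = 1))))
  amp2 <- new_model("x2", list(met("AMP", "CC1(C)SC2C(NC(=O)C(N)c3ccccc3)C(=O)N2C1C(=O)O",
                                   names = "AMP")),
                    list(reaction_entry("r", data.frame(met = "AMP", num = -1, den = 1))))
  cm3 <- consolidate_metabolites(list(amp1, amp2))
  expect_equal(length(unique(cm3$group)), 2)

  # nameless, structure-less entries never merge
  n1 <- new_model("n1", list(metabolite_entry("u1", names = "u1", resolution = "none"),
                             metabolite_entry("u2", names = "u2", resolution = "none")),
                  list(reaction_entry("r", data.frame(met = c("u1", "u2"),
                                                      num = c(-1, 1), den = 1))))
  cm4 <- consolidate_metabolites(list(n1))
  expect_equal(length(unique(cm4$group)), 2)
})

test_that("consolidation never unites different connectivity keys", {
  fx <- make_synthetic_corpus(8, 25, 3,
                              error_rates = list("duplicate-entry" = 0.4))
  cm <- consolidate_metabolites(fx$models)
  for (g in split(cm, cm$group)) {
    keys <- unique(g$key[!is.na(g$key)])
    expect_lte(length(keys), 1)
  }
})

test_that("context matching resolves the biotin-pathway identity in one pass", {
  smis <- c(atp = "COP(=O)([O-])OP(=O)([O-])OP(=O)([O-])[O-]", co2 = "O=C=O",
            dann = "NCCCCCCC(N)C(=O)[O-]", adp = "COP(=O)([O-])OP(=O)([O-])[O-]",
            dtbt = "OC(=O)CCCCC1NC(=O)NC1C", pi = "OP(=O)([O-])[O-]", h = "[H+]")
  mA <- new_model("curated",
    lapply(names(smis), function(i) met(i, smis[[i]])),
    list(rxn("atp + co2 + dann -> adp + dtbt + 3 h + pi", id = "rb")))
  mB <- new_model("name-only",
    list(met("DAPA", names = "7,8-aminopelargonic acid", resolution = "none"),
         met("ATP", smis[["atp"]]), met("CO2", smis[["co2"]]),
         met("DTBIOTIN", smis[["dtbt"]]), met("ADP", smis[["adp"]]),
         met("PI", smis[["pi"]])),
    list(rxn("DAPA + ATP + CO2 ⇔ DTBIOTIN + ADP + PI", id = "rq")))
  it <- iterative_resolve(list(mA, mB))
  expect_equal(nrow(it$log$assignments), 1)
  expect_equal(it$log$assignments$pass, 1)
  expect_equal(it$log$assignments$met, "DAPA")
  expect_equal(it$models[[2]]$metabolites[["DAPA"]]$smiles, smis[["dann"]])
  expect_equal(it$models[[2]]$metabolites[["DAPA"]]$resolution, "full")
})

test_that("a dependency chain resolves one link per pass", {
  sm <- c(a = "OCCO", b = "OCC=O", n1 = "C[n+]1ccccc1", n2 = "CN1CC=CC=C1",
          d = "OCCOP(=O)([O-])[O-]", hh = "[H+]")
  ref <- new_model("ref", c(lapply(names(sm), function(i) met(i, sm[[i]])),
                            list(met("e", "OC(=O)C(=O)[O-]"))),
    list(rxn("a + n1 -> b + n2 + hh", id = "p1"), rxn("a -> d", id = "p3"),
         rxn("d + n1 -> e + n2", id = "p4")))
  qry <- new_model("qry",
    list(met("X1", names = "u1", resolution = "none"),
         met("X2", names = "u2", resolution = "none"),
         met("X3", names = "u3", resolution = "none"),
         met("qn1", sm[["n1"]]), met("qn2", sm[["n2"]]),
         met("qb", sm[["b"]]), met("qh", sm[["hh"]])),
    list(rxn("X1 + qn1 -> qb + qn2 + qh", id = "q1"),
         rxn("X1 -> X2", id = "q2"),
         rxn("X2 + qn1 -> X3 + qn2", id = "q3")))
  it <- iterative_resolve(list(ref, qry))
  expect_equal(it$log$assignments$pass, 1:3)
  expect_equal(it$log$assignments$met, c("X1", "X2", "X3"))
})

test_that("a corpus without unknowns yields an empty log", {
  fx <- make_synthetic_corpus(1, 10, 2)
  it <- iterative_resolve(fx$models)
  expect_equal(nrow(it$log$assignments), 0)
})

test_that("ambiguous context produces suggestions, never an assignment", {
  sm <- c(a = "OCCO", b1 = "OCC=O", b2 = "OCC(=O)[O-]")
  ref <- new_model("ref", lapply(names(sm), function(i) met(i, sm[[i]])),
    list(rxn("a -> b1", id = "p1"), rxn("a -> b2", id = "p2")))
  qry <- new_model("qry",
    list(met("qa", sm[["a"]]), met("XX", names = "xx", resolution = "none")),
    list(rxn("qa -> XX", id = "q1")))
  it <- iterative_resolve(list(ref, qry))
  expect_equal(nrow(it$log$assignments), 0)
  expect_gte(nrow(it$log$suggestions), 2)
  expect_true(is.na(it$models[[2]]$metabolites[["XX"]]$smiles))
})

test_that("resolution grows monotonically and terminates", {
  fx <- make_synthetic_corpus(9, 30, 3, error_rates = list("name-variant" = 0.4))
  n_unres <- sum(vapply(fx$models, function(m)
    sum(vapply(m$metabolites, `[[`, character(1), "resolution") == "none"),
    integer(1)))
  it <- iterative_resolve(fx$models)
  if (nrow(it$log$assignments)) {
    expect_lte(max(it$log$assignments$pass), max(n_unres, 1))
    # no entry is assigned twice
    tags <- paste(it$log$assignments$source, it$log$assignments$met)
    expect_equal(anyDuplicated(tags), 0L)
  }
  succeed()
})

test_that("accepted curator mappings are applied before pass one", {
  qry <- new_model("q", list(met("X", names = "mystery", resolution = "none")),
                   list(reaction_entry("r", data.frame(met = "X", num = -1,
                                                       den = 1))))
  acc <- data.frame(query_source = "q", query_id = "X",
                    target_key = "OCCO", stringsAsFactors = FALSE)
  it <- iterative_resolve(list(qry), accepted = acc)
  expect_equal(it$models[[1]]$metabolites[["X"]]$smiles, "OCCO")
  expect_equal(it$log$assignments$pass, 0L)
})

test_that("source comparison counts shared and unique content", {
  fx <- make_synthetic_corpus(11, 20, 2)
  mA <- fx$models[[1]]; mB <- fx$models[[2]]
  # identical views: all shared, nothing unique
  ov <- compare_sources(list(mA, mB), level = "metabolite")
  expect_equal(ov$count[ov$region == "ref&src2"],
               length(unique(model_keys(mA))))
  expect_length(ov$count[ov$region == "ref"], 0)
  ovr <- compare_sources(list(mA, mB), level = "reaction")
  expect_gte(ovr$count[ovr$region == "ref&src2"], 1)

  # a self-comparison requires distinct names
  expect_error(compare_sources(list(mA, mA)), "distinct")
})

test_that("partial and unresolved entries are excluded and tallied", {
  fx <- make_synthetic_corpus(12, 20, 2,
                              error_rates = list("r-group-masking" = 0.5))
  ov <- compare_sources(fx$models, level = "reaction")
  ex <- attr(ov, "excluded")
  n_masked <- sum(fx$truth$injected$class == "r-group-masking")
  expect_gte(n_masked, 1)
  expect_gte(ex[["src2"]], 1)
  expect_equal(ex[["ref"]], 0L)
})

test_that("two fixture views sharing planted reactions count them as shared", {
  fx <- make_synthetic_corpus(13, 20, 2)
  ov <- compare_sources(fx$models, level = "reaction")
  shared <- ov$count[ov$region == "ref&src2"]
  # transport and its mirror collapse under side-sorting; every key is shared
  expect_equal(sum(ov$count), shared)
  expect_gte(shared, 15)
})
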