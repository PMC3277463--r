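# Imbalance arithmetic and the minimal proton/water repair.

test_that("the curated biotin-pathway string sums to zero imbalance", {
  r <- parse_reaction_string("atp + co2 + dann → adp + dtbt + 3 h + pi")
  imb <- imbalance(r, dapa_compositions())
  expect_length(imb$unresolved, 0)
  expect_length(imb$elements, 0)
  expect_equal(imb$charge, 0)
})

test_that("a trivial identity reaction is balanced", {
  imb <- imbalance(parse_reaction_string("A -> A"),
                   list(A = parse_formula("C6H12O6")))
  expect_length(imb$elements, 0)
  expect_equal(imb$charge, 0)
})

test_that("deleting the proton term shows up as a -3 hydrogen/charge delta", {
  r <- parse_reaction_string("atp + co2 + dann → adp + dtbt + pi")
  imb <- imbalance(r, dapa_compositions())
  expect_equal(imb$charge, -3)
  expect_equal(imb$elements[["H"]], -3)
  expect_length(setdiff(names(imb$elements), "H"), 0)
})

test_that("the name-only biotin reaction repairs with three product protons", {
  r <- parse_reaction_string("DAPA + ATP + CO2 ⇔ DTBIOTIN + ADP + PI")
  rep <- repair_reaction(r, dapa_compositions())
  expect_equal(rep$status, "repaired")
  expect_equal(rep$proton_delta, 3)
  expect_equal(rep$water_delta, 0)
  p <- rep$repaired$participants
  expect_equal(p$num[p$met == "h"], 3)
  # repaired reaction is exactly balanced
  imb <- imbalance(rep$repaired, dapa_compositions())
  expect_length(imb$elements, 0)
  expect_equal(imb$charge, 0)
})

test_that("a doubled water coefficient is repaired back to net -1", {
  r <- parse_reaction_string("gtp + 2 h2o → ahdt + for")
  rep <- repair_reaction(r, gtp_compositions())
  expect_equal(rep$status, "repaired")
  expect_equal(rep$water_delta, 1)
  expect_equal(rep$proton_delta, 1)
  p <- rep$repaired$participants
  expect_equal(p$num[p$met == "h2o"], -1)
  imb <- imbalance(rep$repaired, gtp_compositions())
  expect_length(imb$elements, 0)
  expect_equal(imb$charge, 0)
})

test_that("reactions unfixable by protons and water alone are infeasible", {
  comp <- list(co2 = parse_formula("CO2"), ch4 = parse_formula("CH4"))
  expect_equal(repair_reaction(parse_reaction_string("co2 -> ch4"),
                               comp)$status, "infeasible")
  # a carbon imbalance can never be repaired
  comp2 <- list(a = parse_formula("C2H4O2"), b = parse_formula("C3H6O2"))
  expect_equal(repair_reaction(parse_reaction_string("a -> b"),
                               comp2)$status, "infeasible")
})

test_that("participants without composition give the unresolvable signal", {
  r <- parse_reaction_string("mystery + co2 -> product")
  comp <- list(co2 = parse_formula("CO2"))
  imb <- imbalance(r, comp)
  expect_setequal(imb$unresolved, c("mystery", "product"))
  expect_equal(repair_reaction(r, comp)$status, "unresolvable")
})

test_that("repair is idempotent and conserves every element and charge", {
  cases <- list(
    list(eq = "DAPA + ATP + CO2 ⇔ DTBIOTIN + ADP + PI",
         comp = dapa_compositions()),
    list(eq = "gtp + 2 h2o → ahdt + for", comp = gtp_compositions()))
  for (cs in cases) {
    rep <- repair_reaction(parse_reaction_string(cs$eq), cs$comp)
    expect_equal(rep$status, "repaired")
    again <- repair_reaction(rep$repaired, cs$comp)
    expect_equal(again$status, "already-balanced")
  }
})

test_that("closed form matches the exhaustive +/-10 oracle on random reactions", {
  set.seed(71)
  n_checked <- 0
  for (i in 1:200) {
    cs <- random_reaction_case()
    imb <- imbalance(cs$reaction, cs$comp)
    oracle <- brute_force_repair(as.list(imb$elements), imb$charge)
    rep <- repair_reaction(cs$reaction, cs$comp)
    lp <- repair_reaction(cs$reaction, cs$comp, method = "lp")
    if (is.null(oracle)) {
      expect_true(rep$status %in% c("infeasible"))
      expect_equal(lp$status, rep$status)
    } else {
      # whenever feasible the (p, w) pair is unique and both routes find it
      expect_length(oracle, 1)
      expect_true(rep$status %in% c("repaired", "already-balanced"))
      expect_equal(c(rep$proton_delta, rep$water_delta), oracle[[1]])
      expect_equal(c(lp$proton_delta, lp$water_delta), oracle[[1]])
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 10)   # the case generator must exercise feasible repairs
})

test_that("repair merges into existing proton/water participants", {
  # reaction already carrying h: the delta merges, possibly flipping side
  comp <- list(a = parse_formula("C2H4O2"), b = parse_formula("C2H3O2", charge = -1),
               h = parse_formula("H", charge = 1))
  r <- parse_reaction_string("a + 2 h -> b")   # repair must flip h to products
  rep <- repair_reaction(r, comp)
  expect_equal(rep$status, "repaired")
  expect_equal(rep$proton_delta, 3)
  p <- rep$repaired$participants
  expect_length(which(p$met == "h"), 1)
  expect_equal(p$num[p$met == "h"], 1)
  # a -> b alone needs +1 h product
  r2 <- parse_reaction_string("a -> b")
  rep2 <- repair_reaction(r2, comp)
  expect_equal(rep2$status, "repaired")
  expect_equal(rep2$proton_delta, 1)
  p2 <- rep2$repaired$participants
  expect_equal(p2$num[p2$met == "h"], 1)
})

test_that("audit classifies balanced, repairable, unresolvable and boundary", {
  mets <- list(
    met("a", formula = "C2H4O2", charge = 0),
    met("b", formula = "C2H3O2", charge = -1),
    met("h", formula = "H", charge = 1),
    met("rg", smiles = "*CC(=O)O"),
    met("x", formula = "C2H4O2", charge = 0))
  rxns <- list(
    reaction_entry("ok", data.frame(met = c("a", "b", "h"),
                                    num = c(-1, 1, 1), den = 1)),
    reaction_entry("fix", data.frame(met = c("a", "b"), num = c(-1, 1), den = 1)),
    reaction_entry("rgroup", data.frame(met = c("rg", "x"), num = c(-1, 1), den = 1)),
    reaction_entry("EX_a", data.frame(met = "a", num = -1, den = 1)))
  m <- new_model("audit-fixture", mets, rxns)
  rep <- audit_model(m)
  counts <- attr(rep, "counts")
  expect_equal(unname(counts["balanced"]), 1L)
  expect_equal(unname(counts["repaired"]), 1L)
  expect_equal(unname(counts["unresolvable"]), 1L)
  expect_equal(unname(counts["boundary"]), 1L)
  expect_false(is.na(rep$after[rep$id == "fix"]))
})
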