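# The synthetic-corpus generator and its ground truth.

test_that("zero error rates give identical, fully balanced views", {
  fx <- make_synthetic_corpus(1, 10, 3)
  expect_length(fx$models, 3)
  base <- fx$models[[1]]
  for (m in fx$models) {
    expect_setequal(names(m$metabolites), names(base$metabolites))
    rep <- audit_model(m)
    counts <- attr(rep, "counts")
    expect_equal(unname(counts["balanced"]), length(m$reactions))
    expect_equal(sum(counts[c("repaired", "infeasible", "unresolvable")]), 0L)
  }
  expect_equal(nrow(fx$truth$injected), 0)
})

test_that("the corpus is a deterministic function of the seed", {
  a <- make_synthetic_corpus(42, 25, 3, error_rates = list("name-variant" = 0.5,
                                                           "missing-proton" = 0.3))
  b <- make_synthetic_corpus(42, 25, 3, error_rates = list("name-variant" = 0.5,
                                                           "missing-proton" = 0.3))
  expect_identical(a, b)
  d <- make_synthetic_corpus(43, 25, 3, error_rates = list("name-variant" = 0.5,
                                                           "missing-proton" = 0.3))
  expect_false(identical(a$truth$injected, d$truth$injected))
})

test_that("rates and sizes are validated", {
  expect_error(make_synthetic_corpus(1, 3, 2), "at least 5")
  expect_error(make_synthetic_corpus(1, 10, 2,
                                     error_rates = list("name-variant" = 1.5)),
               "\\[0, 1\\]")
  expect_error(make_synthetic_corpus(1, 10, 2,
                                     error_rates = list("bogus-class" = 0.5)),
               "unknown error class")
  expect_error(make_synthetic_corpus(1, 10, 2,
                                     error_rates = list("r-group-masking" = 1)),
               "nothing resolvable")
})

test_that("forced proton omissions are exactly the repaired reactions", {
  fx <- make_synthetic_corpus(2, 20, 2, error_rates = list("missing-proton" = 1))
  m2 <- fx$models[[2]]
  inj <- fx$truth$injected
  hit <- inj$target[inj$class == "missing-proton" & inj$source == "src2"]
  expect_gte(length(hit), 1)
  rep <- audit_model(m2)
  repaired <- rep$id[rep$status == "repaired"]
  expect_setequal(repaired, hit)
  expect_true(all(rep$proton_delta[rep$status == "repaired"] != 0))
  expect_true(all(rep$water_delta[rep$status == "repaired"] == 0))
  # the reference view is untouched
  expect_equal(sum(audit_model(fx$models[[1]])$status == "repaired"), 0L)
})

test_that("wrong water coefficients are repaired back", {
  fx <- make_synthetic_corpus(3, 20, 2,
                              error_rates = list("wrong-water-coeff" = 1))
  inj <- fx$truth$injected
  hit <- inj$target[inj$class == "wrong-water-coeff"]
  expect_gte(length(hit), 1)
  rep <- audit_model(fx$models[[2]])
  expect_setequal(rep$id[rep$status == "repaired"], hit)
  expect_true(all(rep$water_delta[rep$status == "repaired"] != 0))
})

test_that("naming-only corruption is fully recoverable by reconciliation", {
  fx <- make_synthetic_corpus(4, 50, 3,
                              error_rates = list("case-variant" = 0.3,
                                                 "stereo-prefix" = 0.3))
  rr <- recovery_rate(reconcile_corpus(fx$models)$models, fx$truth)
  expect_gte(rr$n_target, 10)
  expect_equal(rr$rate, 1)
})

test_that("masked R-group entries are never auto-resolved", {
  fx <- make_synthetic_corpus(5, 20, 2,
                              error_rates = list("r-group-masking" = 0.5))
  masked <- fx$truth$injected[fx$truth$injected$class == "r-group-masking", ]
  expect_gte(nrow(masked), 1)
  rc <- reconcile_corpus(fx$models)
  names(rc$models) <- vapply(rc$models, `[[`, character(1), "name")
  for (i in seq_len(nrow(masked))) {
    got <- rc$models[[masked$source[i]]]$metabolites[[masked$target[i]]]
    expect_equal(got$resolution, "partial")
    expect_true(grepl("*", got$smiles, fixed = TRUE))
  }
})

test_that("duplicate entries consolidate into their originals' groups", {
  fx <- make_synthetic_corpus(6, 15, 2,
                              error_rates = list("duplicate-entry" = 1))
  dups <- fx$truth$injected[fx$truth$injected$class == "duplicate-entry", ]
  expect_gte(nrow(dups), 1)
  cm <- consolidate_metabolites(fx$models)
  for (i in seq_len(nrow(dups))) {
    rows <- cm[cm$source == dups$source[i] &
                 cm$id %in% c(dups$target[i], paste0(dups$target[i], "_dup")), ]
    expect_equal(nrow(rows), 2)
    expect_length(unique(rows$group), 1)
  }
})

test_that("id-style swaps keep identity through the structure", {
  fx <- make_synthetic_corpus(7, 15, 2,
                              error_rates = list("id-style-swap" = 1))
  swaps <- fx$truth$injected[fx$truth$injected$class == "id-style-swap", ]
  expect_gte(nrow(swaps), 1)
  ov <- compare_sources(fx$models, level = "metabolite")
  # despite every backbone id differing, all metabolite keys remain shared
  expect_length(ov$count[ov$region %in% c("ref", "src2")], 0)
})
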