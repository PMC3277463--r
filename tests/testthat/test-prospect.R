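# Bipartite graph construction and exhaustive min-path enumeration.

test_that("graph arcs follow direction and reversibility", {
  g <- build_graph(list(rxn("A -> B", id = "r1")), currency = character())
  expect_equal(sum(lengths(g$out)), 2)
  g2 <- build_graph(list(rxn("A <=> B", id = "r1")), currency = character())
  expect_equal(sum(lengths(g2$out)), 4)
  expect_setequal(g2$reactions, c("r1#f", "r1#r"))
})

test_that("currency metabolites carry no arcs", {
  g <- build_graph(list(rxn("A + atp -> B + adp", id = "r1")))
  expect_equal(sum(lengths(g$out)), 2)
  expect_false("atp" %in% g$metabolites)
  expect_true(all(c("A", "B") %in% g$metabolites))
})

test_that("reactions with unresolved participants are skipped with warning", {
  ids <- c(A = "kA", B = "kB")
  expect_warning(
    g <- build_graph(list(rxn("A -> B", id = "r1"), rxn("A -> C", id = "r2")),
                     currency = character(), ids = ids),
    "skipping")
  expect_equal(g$reactions, "r1#f")
})

test_that("simple chains and diamonds enumerate correctly", {
  g <- build_graph(list(rxn("A -> B", id = "r1"), rxn("B -> C", id = "r2")),
                   currency = character())
  p <- enumerate_min_paths(g, "A", "C")
  expect_length(p, 1)
  expect_equal(p[[1]], c("A", "r1#f", "B", "r2#f", "C"))
  expect_equal(attr(p, "min_length"), 2L)

  g2 <- build_graph(list(rxn("A -> B", id = "r1"), rxn("A -> B", id = "r2"),
                         rxn("B -> C", id = "r3")), currency = character())
  p2 <- enumerate_min_paths(g2, "A", "C", slack = 0)
  expect_length(p2, 2)
})

test_that("unreachable targets return empty with the reachability flag", {
  g <- build_graph(list(rxn("A -> B", id = "r1"), rxn("C -> D", id = "r2")),
                   currency = character())
  p <- enumerate_min_paths(g, "A", "D")
  expect_length(p, 0)
  expect_false(attr(p, "reachable"))
  expect_error(enumerate_min_paths(g, "Z", "D"), "not in graph")
})

test_that("the cap truncates with an explicit flag", {
  rxns <- c(lapply(1:5, function(i) rxn("A -> B", id = paste0("ab", i))),
            lapply(1:5, function(i) rxn("B -> C", id = paste0("bc", i))))
  g <- build_graph(rxns, currency = character())
  p <- enumerate_min_paths(g, "A", "C", cap = 7)
  expect_length(p, 7)
  expect_true(attr(p, "truncated"))
  p_all <- enumerate_min_paths(g, "A", "C", cap = 1000)
  expect_length(p_all, 25)
  expect_false(attr(p_all, "truncated"))
})

test_that("enumeration matches the igraph oracle on random graphs", {
  set.seed(23)
  for (trial in 1:30) {
    n_rxn <- sample(4:12, 1)
    mets <- LETTERS[1:sample(4:7, 1)]
    rxns <- lapply(seq_len(n_rxn), function(i) {
      pair <- sample(mets, 2)
      arrow <- if (stats::runif(1) < 0.3) "<=>" else "->"
      rxn(paste(pair[1], arrow, pair[2]), id = paste0("t", i))
    })
    g <- build_graph(rxns, currency = character())
    if (!all(c("A", "B") %in% g$metabolites)) next
    slack <- sample(0:2, 1)
    mine <- enumerate_min_paths(g, "A", "B", slack = slack, cap = 100000)
    oracle <- igraph_oracle(g, "A", "B", slack)
    key <- function(p) paste(p, collapse = ">")
    expect_setequal(vapply(mine, key, character(1)),
                    vapply(oracle$paths, key, character(1)))
    if (length(mine))
      expect_equal(attr(mine, "min_length"), oracle$min_length)
  }
})

test_that("path counts are monotone in slack and corpus size", {
  set.seed(31)
  rxns <- lapply(1:10, function(i) {
    pair <- sample(LETTERS[1:6], 2)
    rxn(paste(pair[1], "->", pair[2]), id = paste0("m", i))
  })
  g_small <- build_graph(rxns[1:7], currency = character())
  g_big <- build_graph(rxns, currency = character())
  key <- function(p) paste(p, collapse = ">")
  for (pair in list(c("A", "D"), c("B", "E"))) {
    prev <- -1
    for (slack in 0:3) {
      if (!all(pair %in% g_big$metabolites)) next
      n <- length(enumerate_min_paths(g_big, pair[1], pair[2], slack = slack,
                                      cap = 100000))
      expect_gte(n, max(prev, 0))
      prev <- n
    }
    # adding reactions never removes a previously returned path
    if (all(pair %in% g_small$metabolites) && all(pair %in% g_big$metabolites)) {
      ps <- enumerate_min_paths(g_small, pair[1], pair[2], slack = 3, cap = 100000)
      pb <- enumerate_min_paths(g_big, pair[1], pair[2], slack = 3, cap = 100000)
      ls <- attr(ps, "min_length"); lb <- attr(pb, "min_length")
      if (length(ps) && length(pb) && !is.na(ls) && !is.na(lb) && ls == lb) {
        keep <- vapply(ps, function(p) (length(p) - 1L) %/% 2L,
                       integer(1)) <= lb + 3
        expect_true(all(vapply(ps[keep], key, character(1)) %in%
                          vapply(pb, key, character(1))))
      }
    }
  }
  succeed()
})

test_that("identical inputs give identical ordered output", {
  fx <- make_synthetic_corpus(2, 20, 1)
  m <- fx$models[[1]]
  g <- build_graph(m$reactions)
  a <- enumerate_min_paths(g, "ethd", "ethac", slack = 1)
  b <- enumerate_min_paths(g, "ethd", "ethac", slack = 1)
  expect_identical(a, b)
  # ordering: length ascending, then lexicographic reaction sequence
  lens <- vapply(a, function(p) (length(p) - 1L) %/% 2L, integer(1))
  expect_true(all(diff(lens) >= 0))
})
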