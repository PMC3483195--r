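test_that("Newick parsing handles minimal trees and validates input", {
  t2 <- parseNewick("(A:1,B:2);")
  expect_equal(ape::Ntip(t2), 2L)
  expect_equal(sort(t2$tip.label), c("A", "B"))
  expect_equal(sort(t2$edge.length), c(1, 2))

  t3 <- parseNewick("((A,B),C);")
  expect_equal(ape::Ntip(t3), 3L)
  expect_equal(sort(ape::extract.clade(t3, treeLca(t3, c("A", "B")))$tip.label),
               c("A", "B"))

  expect_error(parseNewick("((A,B),C;"), "unclosed")
  expect_error(parseNewick("(A,B));"), "unbalanced")
  expect_error(parseNewick("(A:1,A:2);"), "duplicate")
})

test_that("Newick round-trip preserves topology, labels and lengths", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    tr <- randomTree(n)
    back <- parseNewick(writeNewick(tr))
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)),
                 structure(0, names = "PH85"), ignore_attr = TRUE)
    expect_equal(sort(back$tip.label), sort(tr$tip.label))
    d1 <- ape::cophenetic.phylo(tr)
    d2 <- ape::cophenetic.phylo(back)[rownames(d1), colnames(d1)]
    expect_lt(max(abs(d1 - d2)), 1e-12)
  }
  nolen <- parseNewick("((A,B),(C,D));")
  expect_false(grepl(":", writeNewick(nolen), fixed = TRUE))
})

test_that("lca matches a brute-force ancestor-set intersection oracle", {
  set.seed(7)
  for (i in 1:30) {
    n <- sample(4:64, 1)
    tr <- randomTree(n)
    par <- integer(ape::Ntip(tr) + tr$Nnode)
    par[tr$edge[, 2]] <- tr$edge[, 1]
    ancestors <- function(v) { out <- v; while (par[v] != 0) { v <- par[v]; out <- c(out, v) }; out }
    leaves <- sample(tr$tip.label, sample(1:min(6, n), 1))
    got <- treeLca(tr, leaves)
    idx <- match(leaves, tr$tip.label)
    common <- Reduce(intersect, lapply(idx, ancestors))
    # deepest common ancestor = the one with the longest root path
    oracle <- common[which.max(vapply(common, function(v) length(ancestors(v)), 0))]
    expect_identical(got, oracle)
    # idempotent under adding a descendant leaf of the current lca
    clade <- if (got <= ape::Ntip(tr)) tr$tip.label[got]
             else ape::extract.clade(tr, got)$tip.label
    expect_identical(treeLca(tr, union(leaves, sample(clade, 1))), got)
  }
  expect_error(treeLca(randomTree(5), "nope"), "unknown leaf")
})

test_that("single leaf is its own lca", {
  tr <- parseNewick("((A,B),C);")
  expect_identical(treeLca(tr, "A"), match("A", tr$tip.label))
})

test_that("species tree fixture matches the packaged event table", {
  tr <- speciesTreeFixture()
  expect_equal(sort(tr$tip.label),
               sort(c("Sce", "Mbr", "Tsp", "Cbr", "Cel", "Bmo", "Aae",
                      "Dme", "Gga", "Hsa", "Mmu")))
  bt <- branchTable(tr)
  ev <- table2Events()
  expect_equal(nrow(ev), 17L)
  m <- match(ev$lineage, bt$lineage)
  expect_false(anyNA(m))
  expect_equal(bt$length[m], ev$branch_length)
  # the 17 analyzable metazoan lineages exclude the outgroup branches
  analyzable <- attr(tr, "analyzable")
  expect_length(analyzable, 17L)
  expect_false(any(c("Sce", "Mbr") %in% analyzable))
  # outgroup placeholder lengths
  expect_equal(bt$length[bt$lineage == "Sce"], 1.0)
  expect_equal(bt$length[bt$lineage == "Mbr"], 1.0)
})

test_that("canonical node names are sorted leaf sets", {
  tr <- parseNewick("((B,A),C);")
  root <- ape::Ntip(tr) + 1L
  expect_equal(canonicalNodeName(tr, root), "A,B,C")
  expect_equal(canonicalNodeName(tr, treeLca(tr, c("A", "B"))), "A,B")
})
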