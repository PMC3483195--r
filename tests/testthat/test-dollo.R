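test_that("presence matrices are binary, complete, and validated", {
  taxa <- c("A", "B", "C")
  P <- presenceMatrix(data.frame(character = c("f1", "f1", "f2"),
                                 species = c("A", "B", "C")), taxa)
  expect_equal(dim(P), c(2L, 3L))
  expect_equal(P["f1", ], c(A = 1L, B = 1L, C = 0L))
  expect_error(presenceMatrix(data.frame(character = "f", species = "Z"),
                              taxa), "unknown")
  expect_error(dolloReconstruct(character(0), parseNewick("(A,B);")),
               "all-absent")
})

test_that("Dollo reconstruction places the single gain and minimal losses", {
  tr <- parseNewick("(((A,B),C),(D,E));")
  root <- ape::Ntip(tr) + 1L

  all5 <- dolloReconstruct(c("A", "B", "C", "D", "E"), tr)
  expect_true(all5$birth_is_root)
  expect_length(all5$loss_nodes, 0L)

  only_x <- dolloReconstruct("D", tr)
  expect_equal(only_x$birth_node, match("D", tr$tip.label))
  expect_length(only_x$loss_nodes, 0L)

  abd <- dolloReconstruct(c("A", "B", "D"), tr)
  expect_true(abd$birth_is_root)
  expect_setequal(canonicalNodeName(tr, abd$loss_nodes), c("C", "E"))
  # brute-force confirms 2 is the single-gain minimum
  expect_equal(dolloOracle(tr, c("A", "B", "D"))$min_losses, 2L)
})

test_that("event counts are per-branch sums and births total the characters", {
  tr <- parseNewick("(((A,B),C),(D,E));")
  taxa <- tr$tip.label
  P1 <- matrix(1L, 3, 5, dimnames = list(paste0("u", 1:3), taxa))
  ev1 <- countDolloEvents(P1, tr)
  root_name <- canonicalNodeName(tr, ape::Ntip(tr) + 1L)
  expect_equal(ev1$birth[ev1$lineage == root_name], 3L)
  expect_equal(sum(ev1$death), 0L)

  P2 <- presenceMatrix(data.frame(character = rep("v", 3),
                                  species = c("A", "B", "D")), taxa)
  ev2 <- countDolloEvents(P2, tr)
  both <- countDolloEvents(rbind(P1, P2), tr)
  expect_equal(both$birth, ev1$birth + ev2$birth)   # additivity
  expect_equal(both$death, ev1$death + ev2$death)

  set.seed(5)
  for (i in 1:10) {
    n <- sample(4:9, 1)
    tr2 <- randomTree(n)
    P <- matrix(rbinom(6 * n, 1, 0.5), 6, n,
                dimnames = list(paste0("c", 1:6), tr2$tip.label))
    P <- P[rowSums(P) > 0, , drop = FALSE]
    ev <- countDolloEvents(P, tr2)
    expect_equal(sum(ev$birth), nrow(P))   # each character born exactly once
  }
})

test_that("per-character Dollo agrees with the brute-force oracle on random
           trees and characters", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    tr <- randomTree(n)
    present <- sample(tr$tip.label, sample(1:n, 1))
    got <- dolloReconstruct(present, tr)
    oracle <- dolloOracle(tr, present)
    expect_equal(length(got$loss_nodes), oracle$min_losses)
    expect_true(got$birth_node %in% oracle$best_nodes)
  }
})

test_that("family classification follows the published categories", {
  taxa <- c("Sce", "Mbr", "Tsp", "Cbr", "Cel", "Bmo", "Aae", "Dme",
            "Gga", "Hsa", "Mmu")
  mk <- function(sp) presenceMatrix(
    data.frame(character = "f", species = sp), taxa)
  expect_equal(as.character(classifyFamilies(mk(taxa))), "universal")
  expect_equal(as.character(classifyFamilies(mk("Tsp"))),
               "clade_specific_single_species")
  expect_equal(as.character(classifyFamilies(mk(c("Cbr", "Cel")))),
               "clade_specific_shared")
  expect_equal(as.character(classifyFamilies(mk(c("Cel", "Hsa")))), "other")
  expect_equal(as.character(classifyFamilies(mk(c("Sce", "Tsp")))), "other")
})

test_that("unique losses match a brute-force column scan", {
  set.seed(9)
  taxa <- paste0("s", 1:11)
  P <- matrix(rbinom(100 * 11, 1, 0.8), 100, 11,
              dimnames = list(paste0("c", 1:100), taxa))
  P <- P[rowSums(P) > 0, , drop = FALSE]
  got <- uniqueLosses(P)
  brute <- vapply(taxa, function(s) {
    sum(apply(P, 1, function(r) r[s] == 0 && sum(r == 0) == 1))
  }, 0)
  expect_equal(got, setNames(as.integer(brute), taxa))
  # a row with two zeros contributes nowhere
  P2 <- matrix(c(0, 0, 1, 1), 1, 4, dimnames = list("c", paste0("s", 1:4)))
  expect_equal(sum(uniqueLosses(P2)), 0L)
})

test_that("newborn-family domain sets intersect as planted", {
  birth <- c(f1 = "X", f2 = "X", f3 = "Y", u1 = "root")
  fam_dom <- list(f1 = c("d1", "d2"), f2 = "d2", f3 = c("d2", "d3"),
                  u1 = c("d2", "d9"))
  ov <- birthDomainOverlap(birth, fam_dom, universal_families = "u1",
                           branches = c("X", "Y"))
  expect_equal(ov$sets$X, c("d1", "d2"))
  expect_equal(ov$sizes, c(X = 2L, Y = 2L))
  expect_equal(ov$universal_overlap, c(X = 1L, Y = 1L))
  expect_equal(ov$pairwise["X", "Y"], 1L)
  disjoint <- birthDomainOverlap(c(a = "X", b = "Y"),
                                 list(a = "d1", b = "d2"),
                                 character(0), c("X", "Y"))
  expect_equal(disjoint$pairwise["X", "Y"], 0L)
})
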