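# a small three-level ontology used across these tests
writeMiniObo <- function() {
  f <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root process", "",
    "[Term]", "id: GO:0000002", "name: branch process",
    "is_a: GO:0000001 ! root process", "",
    "[Term]", "id: GO:0000003", "name: leaf process",
    "is_a: GO:0000002 ! branch process", "",
    "[Term]", "id: GO:0000004", "name: other branch",
    "is_a: GO:0000001 ! root process", "",
    "[Term]", "id: GO:0000005", "name: obsolete thing",
    "is_obsolete: true", ""), f)
  f
}

test_that("OBO parsing keeps id/name/is_a, skips obsolete, rejects cycles", {
  dag <- readObo(writeMiniObo())
  expect_setequal(dag$terms, paste0("GO:000000", 1:4))
  expect_equal(unname(dag$name["GO:0000003"]), "leaf process")
  expect_equal(dag$parents[["GO:0000003"]], "GO:0000002")
  anc <- termAncestors(dag)
  expect_setequal(anc[["GO:0000003"]], c("GO:0000002", "GO:0000001"))

  bad <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: A", "is_a: B", "",
               "[Term]", "id: B", "is_a: A"), bad)
  expect_error(readObo(bad), "cycle")
})

test_that("family annotation deduplicates members and closes ancestors", {
  dag <- readObo(writeMiniObo())
  fams <- data.frame(family = c("f1", "f1", "f1", "f2"),
                     protein = c("p1", "p2", "p3", "p4"))
  pt <- data.frame(protein = c("p1", "p2", "p3"),
                   term = c("GO:0000003", "GO:0000003", "GO:0000003"))
  ann <- annotateFamilies(pt, fams, dag)
  # three members with the same term count once; ancestors are included
  expect_equal(ann$f1, c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_equal(ann$f2, character(0))
  # ancestor closure holds for every family
  anc <- termAncestors(dag)
  for (ts in ann)
    for (t in ts) expect_true(all(anc[[t]] %in% ts))
  expect_warning(annotateFamilies(
    data.frame(protein = "p1", term = "GO:9999999"), fams, dag), "skipping")
  expect_error(annotateFamilies(
    data.frame(protein = "p1", term = "GO:9999999"), fams, dag,
    strict = TRUE), "not in ontology")
})

test_that("hypergeometric tails are exact against draw enumeration", {
  expect_equal(unname(hypergeomTest(2, 2, 2, 5)["p_enriched"]), 0.1)
  expect_equal(unname(hypergeomTest(0, 3, 4, 10)["p_enriched"]), 1)
  set.seed(12)
  for (i in 1:25) {
    N <- sample(5:12, 1)
    n <- sample(1:N, 1)
    K <- sample(0:N, 1)
    k <- sample(max(0, n + K - N):min(n, K), 1)
    got <- hypergeomTest(k, n, K, N)
    want <- hyperOracle(k, n, K, N)
    expect_equal(unname(got["p_enriched"]), unname(want["p_enriched"]),
                 tolerance = 1e-12)
    expect_equal(unname(got["p_depleted"]), unname(want["p_depleted"]),
                 tolerance = 1e-12)
  }
  expect_error(hypergeomTest(5, 3, 4, 10), "inconsistent")
})

test_that("elim refinement removes a parent driven only by its child", {
  dag <- readObo(writeMiniObo())
  # 40 families; 8 carry the leaf term (and its ancestors by closure);
  # the target contains exactly those 8 plus 12 others
  fams <- sprintf("f%02d", 1:40)
  ann <- setNames(rep(list(character(0)), 40), fams)
  for (f in fams[1:8]) ann[[f]] <- c("GO:0000001", "GO:0000002", "GO:0000003")
  for (f in fams[9:40]) ann[[f]] <- "GO:0000001"
  target <- fams[1:12]       # all 8 leaf-term families plus 4 others
  res <- enrichFamilies(target, ann)
  p2 <- res$p_enriched[res$term == "GO:0000002"]
  p3 <- res$p_enriched[res$term == "GO:0000003"]
  expect_lt(p3, 0.001)
  expect_lt(p2, 0.001)     # parent significant only through the leaf
  ref <- refineEnrichment(res, dag, ann, target, threshold = 0.001)
  expect_false(ref$refined_out[ref$term == "GO:0000003"])
  expect_true(ref$refined_out[ref$term == "GO:0000002"])
  # a term with no significant descendants is unchanged
  expect_equal(ref$p_refined[ref$term == "GO:0000004"] ,
               ref$p_enriched[ref$term == "GO:0000004"])
})

test_that("refinement over a flat ontology is the identity", {
  flat <- list(terms = c("t1", "t2"), name = c(t1 = "a", t2 = "b"),
               parents = list(t1 = character(0), t2 = character(0)))
  ann <- list(f1 = "t1", f2 = "t1", f3 = "t2", f4 = character(0))
  res <- enrichFamilies(c("f1", "f2"), ann)
  ref <- refineEnrichment(res, flat, ann, c("f1", "f2"))
  expect_equal(ref$p_refined, ref$p_enriched)
  expect_false(any(ref$refined_out))
})

test_that("permutation FDR is seeded-deterministic and filters jointly", {
  set.seed(99)
  fams <- sprintf("f%02d", 1:30)
  ann <- setNames(lapply(1:30, function(i)
    if (i <= 10) "t1" else "t2"), fams)
  res <- enrichFamilies(fams[1:8], ann)
  a <- permutationFdr(res, ann, 8, reps = 200, seed = 5)
  b <- permutationFdr(res, ann, 8, reps = 200, seed = 5)
  expect_identical(a$FDR, b$FDR)
  expect_warning(permutationFdr(res, ann, 8, reps = 50, seed = 1), "unstable")

  fake <- data.frame(term = c("a", "b", "c"),
                     p_refined = c(5e-4, 5e-4, 0.5),
                     FDR = c(0.05, 0.2, 0.01))
  kept <- filterSignificant(fake)
  expect_equal(kept$term, "a")   # joint thresholds: both must pass
  expect_equal(nrow(filterSignificant(fake[0, ])), 0L)
})
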