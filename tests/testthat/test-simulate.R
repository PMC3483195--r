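# small parameter sets keep these simulations fast
quietParams <- function(...) simParams(root_families = 8L, fam_birth_rate = 0,
                                       fam_death_rate = 0, dup_rate = 0,
                                       del_rate = 0, dom_birth_rate = 0,
                                       edge_drop = 0, edge_false = 0,
                                       dist_noise_sd = 0, ...)

test_that("with all rates zero every species carries exactly the root genome", {
  sim <- simulateFamDom(quietParams(), seed = 1)
  tr <- sim$dataset$tree
  ev <- sim$truth$events
  root_name <- canonicalNodeName(tr, ape::Ntip(tr) + 1L)
  expect_equal(ev$fam_birth[ev$lineage == root_name], 8L)
  expect_equal(sum(ev$fam_birth[ev$lineage != root_name]), 0L)
  expect_equal(sum(ev$fam_death), 0L)
  expect_equal(sum(ev$del), 0L)
  # founding members only: dup column holds the founding joins at the root
  expect_equal(sum(ev$dup[ev$lineage != root_name]), 0L)
  # every family present in every species
  pres <- presenceMatrix(sim$truth$presence_pairs, tr$tip.label)
  expect_true(all(pres == 1L))
})

test_that("identical seeds give byte-identical emitted datasets", {
  p <- simParams(root_families = 10L)
  d1 <- tempfile(); d2 <- tempfile()
  emitDataset(simulateFamDom(p, seed = 77), d1)
  emitDataset(simulateFamDom(p, seed = 77), d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  d3 <- tempfile()
  emitDataset(simulateFamDom(p, seed = 78), d3)
  expect_false(identical(readLines(file.path(d1, "edges.abc")),
                         readLines(file.path(d3, "edges.abc"))))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("duplication counts follow the Poisson branch expectation", {
  # two-taxon tree, duplication only: E[dups] = rate * length * lineages
  tree <- parseNewick("(X:2,Y:2);")
  rate <- 0.5
  tot <- 0
  reps <- 200
  for (s in seq_len(reps)) {
    sim <- simulateFamDom(simParams(root_families = 1L, founding_extra_mean = 1e-9,
                                    fam_birth_rate = 0, fam_death_rate = 0,
                                    dup_rate = rate, del_rate = 0,
                                    dom_birth_rate = 0, edge_drop = 0,
                                    edge_false = 0, dist_noise_sd = 0),
                          tree, seed = 1000 + s)
    ev <- sim$truth$events
    tot <- tot + sum(ev$dup[ev$lineage == "X"])
  }
  # 2 founding lineages on a branch of length 2; the process branches, so
  # the expected count is 2*(exp(rate*l) - 1) per starting lineage
  expected <- reps * 2 * (exp(rate * 2) - 1)
  se <- sqrt(expected)          # Poisson-scale spread
  expect_lt(abs(tot - expected), 4 * se)
})

test_that("zero-noise emission is additive and NJ recovers every true
           gene tree topology", {
  sim <- simulateFamDom(simParams(root_families = 6L, fam_birth_rate = 0.3,
                                  fam_death_rate = 0.05, dup_rate = 0.3,
                                  del_rate = 0, dom_birth_rate = 0,
                                  edge_drop = 0, edge_false = 0,
                                  dist_noise_sd = 0), seed = 5)
  for (fid in names(sim$dataset$distances)) {
    D <- sim$dataset$distances[[fid]]
    gt <- parseNewick(sim$dataset$gene_trees[[fid]])
    expect_lt(max(abs(ape::cophenetic.phylo(gt)[rownames(D), rownames(D)] - D)),
              1e-8)
    if (nrow(D) >= 4) {
      nj <- neighborJoining(D)
      expect_equal(ape::dist.topo(ape::unroot(gt), nj), structure(0),
                   ignore_attr = TRUE)
    }
  }
})

test_that("with no graph noise the similarity components are the true
           families", {
  sim <- simulateFamDom(simParams(root_families = 10L, edge_drop = 0,
                                  edge_false = 0), seed = 9)
  g <- igraph::graph_from_data_frame(sim$dataset$edges[, 1:2],
                                     directed = FALSE)
  comp <- igraph::components(g)$membership
  fam <- sim$truth$family_of[names(comp)]
  expect_equal(length(unique(comp)), length(unique(fam)))
  expect_true(all(tapply(fam, comp, function(x) length(unique(x))) == 1))
})

test_that("event-log tallies equal the per-family ground truth fields", {
  sim <- simulateFamDom(simParams(root_families = 15L), seed = 13)
  ev <- sim$truth$events
  fam <- sim$truth$families
  expect_equal(sum(ev$fam_birth), nrow(fam))
  expect_equal(sum(ev$fam_death), sum(fam$n_death))
  # every family's birth lineage appears in the event table's coordinates
  expect_true(all(fam$birth_lineage %in% ev$lineage))
})

test_that("planted enrichment annotates target families at the stated rate", {
  sim <- simulateFamDom(simParams(root_families = 20L, fam_birth_rate = 0.5),
                        seed = 21)
  branch <- "Cbr,Cel"
  sim <- plantEnrichment(sim, "T:1111111", branch, effect = 1.0,
                         base_rate = 0)
  ann <- sim$dataset$annotations
  planted <- ann[ann$term == "T:1111111", ]
  fam <- sim$truth$families
  target <- fam$family[fam$birth_lineage == branch]
  detectable <- intersect(target, unique(sim$truth$family_of))
  expect_setequal(unique(sim$truth$family_of[planted$protein]), detectable)
  expect_error(plantEnrichment(sim, "T:1", "NoSuchBranch", 1), "unknown branch")
})
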