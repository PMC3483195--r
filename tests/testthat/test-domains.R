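hit <- function(protein, domain, start, end, score = 50, evalue = 1e-10)
  data.frame(protein = protein, domain = domain, start = start, end = end,
             score = score, evalue = evalue, stringsAsFactors = FALSE)

test_that("hit validation and E-value thresholding", {
  h <- rbind(hit("p1", "PF_A", 1, 100, evalue = 1e-10),
             hit("p1", "PF_B", 150, 250, evalue = 1e-8),
             hit("p2", "PF_A", 1, 90, evalue = 1e-3))
  expect_equal(nrow(domainHits(h, 1e-5)), 2L)
  expect_equal(nrow(domainHits(h, "precomputed")), 3L)
  expect_error(domainHits(hit("p", "PF_X", 50, 10)), "coordinates")
})

test_that("architectures order by start, keep tandem repeats, and resolve
           overlaps by score, E-value, then accession", {
  h <- rbind(hit("p1", "PF_B", 150, 250), hit("p1", "PF_A", 1, 100))
  a <- buildArchitectures(h)
  expect_equal(attr(a, "arch")$p1, c("PF_A", "PF_B"))

  tandem <- rbind(hit("p2", "PF_A", 1, 100), hit("p2", "PF_A", 120, 220))
  expect_equal(attr(buildArchitectures(tandem), "arch")$p2, c("PF_A", "PF_A"))

  ov <- rbind(hit("p3", "PF_LOW", 1, 100, score = 30),
              hit("p3", "PF_HIGH", 10, 100, score = 50))
  expect_equal(attr(buildArchitectures(ov), "arch")$p3, "PF_HIGH")

  tie <- rbind(hit("p4", "PF_Z", 1, 100, score = 40, evalue = 1e-9),
               hit("p4", "PF_Y", 1, 100, score = 40, evalue = 1e-9))
  expect_equal(attr(buildArchitectures(tie), "arch")$p4, "PF_Y")

  # non-overlapping enough (<= 50% of shorter) keeps both
  half <- rbind(hit("p5", "PF_A", 1, 100), hit("p5", "PF_B", 60, 220))
  expect_equal(attr(buildArchitectures(half), "arch")$p5, c("PF_A", "PF_B"))
})

test_that("architecture construction ignores input row order", {
  set.seed(11)
  h <- rbind(hit("p", "PF_A", 1, 80, score = 20),
             hit("p", "PF_B", 40, 120, score = 60),
             hit("p", "PF_C", 200, 300, score = 10),
             hit("p", "PF_D", 260, 310, score = 90))
  ref <- attr(buildArchitectures(h), "arch")$p
  for (i in 1:10) {
    perm <- h[sample(nrow(h)), ]
    expect_equal(attr(buildArchitectures(perm), "arch")$p, ref)
  }
})

test_that("domain groups count per-species copies; totals match hits", {
  h <- rbind(hit("h1", "PF_X", 1, 100), hit("h2", "PF_X", 1, 100),
             hit("w1", "PF_X", 1, 100),
             hit("h1", "PF_Y", 120, 200), hit("h1", "PF_Y", 220, 300))
  sp <- c(h1 = "Hsa", h2 = "Hsa", w1 = "Cel")
  g <- domainGroups(h, sp)
  x <- g[g$domain == "PF_X", ]
  expect_setequal(x$species, c("Hsa", "Cel"))
  expect_equal(x$copies[x$species == "Hsa"], 2L)
  expect_equal(x$copies[x$species == "Cel"], 1L)
  # a protein with two copies contributes two copies
  expect_equal(g$copies[g$domain == "PF_Y"], 2L)
  expect_equal(sum(g$copies), nrow(h))
  expect_error(domainGroups(h, c(h1 = "Hsa")), "missing")
})

test_that("domtblout and 6-column dialects parse to the same hits", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("p1\tPF00001\t5\t90\t55.1\t1e-12",
               "p2\tPF00002\t10\t200\t80.5\t1e-30"), tsv)
  a <- readDomainHits(tsv)
  expect_equal(a$protein, c("p1", "p2"))
  expect_equal(a$start, c(5, 10))

  dt <- tempfile(fileext = ".domtblout")
  row1 <- paste("p1 - 300 PF00001.17 PF00001 90 1e-10 60 2 1 1 1.5e-12 1e-12",
                "55.1 0.1 3 88 4 89 5 90 0.9 desc here")
  writeLines(c("# comment", row1), dt)
  b <- readDomainHits(dt, dialect = "domtblout")
  expect_equal(b$protein, "p1")
  expect_equal(b$domain, "PF00001")
  expect_equal(b$start, 5)
  expect_equal(b$end, 90)
  expect_equal(b$score, 55.1)
  expect_equal(b$evalue, 1e-12)
})
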