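test_that("orthogroups table parses comma lists and empty cells", {
  f <- withr::local_tempfile(lines = c(
    "Orthogroup\tspA\tspB",
    "OG1\t0_0, 0_1\t1_0",
    "OG2\t0_2\t"))
  ogs <- readOrthogroups(f)
  expect_s4_class(ogs, "OrthogroupSet")
  expect_equal(length(ogs), 2L)
  m <- groupList(ogs)
  expect_equal(m$OG1$spA, c("0_0", "0_1"))
  expect_equal(m$OG1$spB, "1_0")
  expect_equal(m$OG2$spB, character(0L))
})

test_that("a gene in two orthogroups is fatal, citing both group ids", {
  f <- withr::local_tempfile(lines = c(
    "Orthogroup\tspA\tspB",
    "OG1\t0_0\t1_0",
    "OG2\t0_0\t1_1"))
  expect_error(readOrthogroups(f), "OG1.*OG2|more than one orthogroup")
})

test_that("unknown species column is fatal with the column name", {
  f <- withr::local_tempfile(lines = c(
    "Orthogroup\tspA\tspZ",
    "OG1\t0_0\t1_0"))
  expect_error(readOrthogroups(f, species = c("spA", "spB")), "spZ")
})

test_that("orthogroups round-trip through write/read, byte-identically", {
  f <- withr::local_tempfile(lines = c(
    "Orthogroup\tspA\tspB",
    "OG1\t0_0, 0_1\t1_0",
    "OG2\t0_2\t"))
  ogs <- readOrthogroups(f)
  f2 <- withr::local_tempfile()
  writeOrthogroups(ogs, f2)
  expect_identical(readLines(f2), readLines(f))
  expect_equal(groupList(readOrthogroups(f2)), groupList(ogs))
})

collinearity_lines <- c(
  "############### Parameters ###############",
  "# MATCH_SIZE: 5",
  "############### Statistics ###############",
  "# Number of collinear blocks: 2",
  "## Alignment 0: score=100.0 e_value=1e-20 N=3 x1&y1 plus",
  " 0-  0:\t0_0\t1_0\t1e-50",
  " 0-  1:\t0_1\t1_1\t1e-40",
  " 0-  2:\t0_2\t1_2\t0",
  "## Alignment 1: score=90.0 e_value=1e-10 N=5 x1&x1 minus",
  " 1-  0:\t0_0\t0_9\t0",
  " 1-  1:\t0_1\t0_8\t0",
  " 1-  2:\t0_2\t0_7\t0",
  " 1-  3:\t0_3\t0_6\t0",
  " 1-  4:\t0_4\t0_5\t0")

test_that("collinearity file parses blocks in order with intra flag", {
  f <- withr::local_tempfile(lines = collinearity_lines)
  col <- readCollinearity(f)
  expect_equal(length(col), 2L)
  b <- blocks(col)
  expect_equal(nrow(b[[1L]]$pairs), 3L)
  expect_equal(nrow(b[[2L]]$pairs), 5L)
  expect_false(b[[1L]]$intra)
  expect_true(b[[2L]]$intra)   # x1&x1: same region on both sides
  expect_equal(b[[1L]]$pairs$gene_a, c("0_0", "0_1", "0_2"))
  expect_equal(b[[1L]]$pairs$evalue, c(1e-50, 1e-40, 0))
  expect_equal(b[[2L]]$orientation, "minus")
})

test_that("malformed pair line is fatal with its line number", {
  bad <- collinearity_lines
  bad[7L] <- " 0-  1:\t0_1\t1_1"      # e-value field missing
  f <- withr::local_tempfile(lines = bad)
  expect_error(readCollinearity(f), "line 7")
})

test_that("block with zero pairs is skipped with a warning", {
  f <- withr::local_tempfile(lines = c(
    "## Alignment 0: score=1 e_value=0 N=0 x1&y1 plus",
    "## Alignment 1: score=1 e_value=0 N=1 x1&y1 plus",
    " 1-  0:\t0_0\t1_0\t0"))
  expect_warning(col <- readCollinearity(f), "no gene pairs")
  expect_equal(length(col), 1L)
})

test_that("collinearity set round-trips exactly", {
  f <- withr::local_tempfile(lines = collinearity_lines)
  col <- readCollinearity(f)
  f2 <- withr::local_tempfile()
  writeCollinearity(col, f2)
  expect_equal(blocks(readCollinearity(f2)), blocks(col))
  f3 <- withr::local_tempfile()
  writeCollinearity(readCollinearity(f2), f3)
  expect_identical(readLines(f3), readLines(f2))
})

test_that("tandem file yields pairs, chains stay separate rows", {
  f <- withr::local_tempfile(lines = c("0_0,0_1", "0_1,0_2"))
  p <- readTandem(f)
  expect_equal(nrow(p), 2L)
  expect_equal(p$gene_a, c("0_0", "0_1"))
  f2 <- withr::local_tempfile()
  writeTandem(p, f2)
  expect_identical(readLines(f2), readLines(f))
})

test_that("tandem rejects self-pairs and cross-species pairs", {
  f <- withr::local_tempfile(lines = "0_0,0_0")
  expect_error(readTandem(f), "self-pair")
  f2 <- withr::local_tempfile(lines = "0_0,1_0")
  expect_error(readTandem(f2), "two species")
  # same check through an explicit species map with non-canonical names
  f3 <- withr::local_tempfile(lines = "gA1,gB1")
  expect_error(readTandem(f3, c(gA1 = "spA", gB1 = "spB")), "two species")
})

test_that("ploidy file defaults absent species to 1 and validates values", {
  sp <- c("spA", "spB", "polyP")
  expect_equal(readPloidy(NULL, sp), setNames(c(1L, 1L, 1L), sp))
  f <- withr::local_tempfile(lines = "polyP\t2")
  expect_equal(readPloidy(f, sp)[["polyP"]], 2L)
  expect_equal(readPloidy(f, sp)[["spA"]], 1L)
  f2 <- withr::local_tempfile(lines = "polyP\t0")
  expect_error(readPloidy(f2, sp), ">= 1")
  f3 <- withr::local_tempfile(lines = "spZ\t2")
  expect_error(readPloidy(f3, sp), "spZ")
})

test_that("gene position file round-trips through the catalog", {
  cat0 <- toy_catalog(c("spA", "spB"), 4L)
  f <- withr::local_tempfile()
  writeGenePositions(cat0, f)
  cat1 <- readGenePositions(f, species_ids = c("0" = "spA", "1" = "spB"))
  expect_equal(geneTable(cat1)[, c("species", "chrom", "start", "end", "canonical", "ord")],
               geneTable(cat0)[, c("species", "chrom", "start", "end", "canonical", "ord")])
  f2 <- withr::local_tempfile()
  writeGenePositions(cat1, f2)
  expect_identical(readLines(f2), readLines(f))
})

test_that("SpeciesIDs and SequenceIDs files round-trip", {
  sp <- c("0" = "spA", "1" = "spB")
  f <- withr::local_tempfile()
  writeSpeciesIds(sp, f)
  expect_equal(readSpeciesIds(f), sp)
  sq <- c("0_0" = "gA1", "0_1" = "gA2", "1_0" = "gB1")
  f2 <- withr::local_tempfile()
  writeSequenceIds(sq, f2)
  expect_equal(readSequenceIds(f2), sq)
})
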