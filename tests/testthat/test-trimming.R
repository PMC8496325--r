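# end trimming, window trimming, internal splitting, full refinement

test_that("end rule keeps blocks whose ends reach a Pass first", {
  expect_equal(score_string(trimEnds(score_block("PNPP"))), "PNPP")
  expect_equal(score_string(trimEnds(score_block("CPPC"))), "CPPC")
})

test_that("end rule removes terminal Not Pass runs up to the first Pass", {
  expect_equal(score_string(trimEnds(score_block("NPPN"))), "PP")
  expect_equal(score_string(trimEnds(score_block("NNPP"))), "PP")
  expect_equal(score_string(trimEnds(score_block("NCNPP"))), "PP")
  expect_equal(score_string(trimEnds(score_block("CNPPC"))), "PPC")
})

test_that("window rule leaves blocks with fewer than three Not Pass alone", {
  expect_equal(score_string(trimWindow(score_block("PPPPNN"))), "PPPPNN")
})

test_that("window rule removes end pairs until Pass outnumbers Not Pass", {
  # first six scored pairs hold 3 Not Pass: trim, re-trim ends, re-check
  b <- score_block("PNNNPPPPPP")
  expect_equal(score_string(trimWindow(b)), "PPPPPP")
})

test_that("window rule applies to short blocks over all scored pairs", {
  # fewer than six scored pairs, three of them Not Pass
  b <- score_block("PNNNP")
  out <- trimWindow(b)
  expect_lt(length(out$scores), 5L)
})

test_that("internal runs of >=3 Not Pass split a block, No Call inside", {
  kids <- splitInternal(score_block("PPNNNPP"))
  expect_equal(length(kids), 2L)
  expect_equal(score_string(kids[[1L]]), "PP")
  expect_equal(score_string(kids[[2L]]), "PP")
  expect_equal(length(splitInternal(score_block("PNNPP"))), 1L)
  kids2 <- splitInternal(score_block("PPNCNNPP"))
  expect_equal(length(kids2), 2L)
})

test_that("refineBlocks reaches the documented fixed point on examples", {
  x <- new("CollinearitySet",
           blocks = list(score_block("NPPPPPNNNN", "b1")))
  ref <- refineBlocks(x)
  expect_equal(length(ref$blocks), 1L)
  expect_equal(score_string(blocks(ref$blocks)[[1L]]), "PPPPP")
  expect_equal(ref$log$action, "TRIM_END")
})

test_that("split children below five pairs are discarded", {
  x <- new("CollinearitySet",
           blocks = list(score_block("PPPPNNNPPPP", "b1")))
  ref <- refineBlocks(x)
  expect_equal(length(ref$blocks), 0L)
  expect_setequal(ref$log$action, c("SPLIT", "DISCARD"))
  expect_equal(sum(ref$log$action == "DISCARD"), 2L)
})

test_that("split children large enough to stand alone survive", {
  x <- new("CollinearitySet",
           blocks = list(score_block("PPPPPNNNPPPPP", "b1")))
  ref <- refineBlocks(x)
  expect_equal(length(ref$blocks), 2L)
  expect_equal(vapply(blocks(ref$blocks), score_string, character(1L)),
               c("PPPPP", "PPPPP"))
  expect_setequal(vapply(blocks(ref$blocks), `[[`, character(1L), "id"),
                  c("b1.1", "b1.2"))
})

test_that("clean blocks are kept unchanged with a KEEP action", {
  x <- new("CollinearitySet", blocks = list(score_block("PPPPP", "b1")))
  ref <- refineBlocks(x)
  expect_equal(ref$log$action, "KEEP")
  expect_equal(score_string(blocks(ref$blocks)[[1L]]), "PPPPP")
})

random_scored_set <- function(n, seed, min_len = 1L, max_len = 30L) {
  set.seed(seed)
  new("CollinearitySet", blocks = lapply(seq_len(n), function(i) {
    len <- sample(min_len:max_len, 1L)
    score_block(paste(sample(c("P", "N", "C"), len, replace = TRUE,
                             prob = c(0.5, 0.25, 0.25)), collapse = ""),
                id = paste0("r", i))
  }))
}

survivor_invariants_hold <- function(b) {
  sc <- b$scores
  n <- length(sc)
  scored <- sc[sc != "C"]
  r <- rle(scored)
  ok <- length(sc) >= 5L &&
    sum(sc == "P") >= 2L &&
    sum(sc == "N") <= sum(sc == "P") &&
    length(scored) > 0L &&
    r$values[1L] == "P" && r$values[length(r$values)] == "P" &&
    !any(r$values == "N" & r$lengths >= 3L)
  ok
}

test_that("refinement is idempotent and survivors satisfy every rule", {
  x <- random_scored_set(150L, seed = 20)
  ref1 <- refineBlocks(x)
  for (b in blocks(ref1$blocks))
    expect_true(survivor_invariants_hold(b), label = b$id)
  ref2 <- refineBlocks(ref1$blocks)
  expect_equal(blocks(ref2$blocks), blocks(ref1$blocks))
  expect_true(all(ref2$log$action == "KEEP"))
})

test_that("refinement never adds pairs (monotone subset of input)", {
  x <- random_scored_set(60L, seed = 21)
  ref <- refineBlocks(x)
  in_pairs <- unlist(lapply(blocks(x), function(b)
    paste(b$pairs$gene_a, b$pairs$gene_b, b$id)), use.names = FALSE)
  out_pairs <- unlist(lapply(blocks(ref$blocks), function(b)
    paste(b$pairs$gene_a, b$pairs$gene_b, sub("\\..*$", "", b$id))),
    use.names = FALSE)
  expect_true(all(out_pairs %in% in_pairs))
  expect_lte(length(out_pairs), length(in_pairs))
})
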