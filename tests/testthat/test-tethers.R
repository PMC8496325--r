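# tandem-array construction and ploidy-aware tether building

test_that("adjacent tandem pairs chain into maximal arrays", {
  cat5 <- toy_catalog("spA", 5L)             # genes 0_0 .. 0_4 in order
  tnd <- data.frame(gene_a = c("0_0", "0_1"), gene_b = c("0_1", "0_2"))
  arr <- buildTandemArrays(tnd, cat5)
  expect_equal(arr$arrays[["0_0"]], c("0_0", "0_1", "0_2"))
  expect_equal(unname(arr$arrayOf[c("0_0", "0_1", "0_2")]), rep("0_0", 3L))
  expect_equal(length(arr$arrays), 3L)       # chained run + 2 singletons
})

test_that("with no tandem pairs every gene is a singleton array", {
  cat4 <- toy_catalog("spA", 4L)
  arr <- buildTandemArrays(data.frame(gene_a = character(0L),
                                      gene_b = character(0L)), cat4)
  expect_equal(length(arr$arrays), 4L)
  expect_true(all(lengths(arr$arrays) == 1L))
})

test_that("disjoint pairs give the expected partition", {
  cat5 <- toy_catalog("spA", 5L)
  tnd <- data.frame(gene_a = c("0_0", "0_3"), gene_b = c("0_1", "0_4"))
  arr <- buildTandemArrays(tnd, cat5)
  expect_equal(unname(sort(vapply(arr$arrays, paste, character(1L),
                                  collapse = "+"))),
               c("0_0+0_1", "0_2", "0_3+0_4"))
})

test_that("array construction is invariant to pair order in the file", {
  cat8 <- toy_catalog("spA", 8L)
  tnd <- data.frame(gene_a = c("0_0", "0_1", "0_4", "0_5"),
                    gene_b = c("0_1", "0_2", "0_5", "0_6"))
  ref <- buildTandemArrays(tnd, cat8)$arrayOf
  set.seed(11)
  for (i in 1:5) {
    perm <- tnd[sample(nrow(tnd)), ]
    flip <- sample(c(TRUE, FALSE), nrow(perm), replace = TRUE)
    perm[flip, c("gene_a", "gene_b")] <- perm[flip, c("gene_b", "gene_a")]
    expect_equal(buildTandemArrays(perm, cat8)$arrayOf, ref)
  }
})

test_that("non-adjacent declared pairs are merged with a warning", {
  cat5 <- toy_catalog("spA", 5L)
  tnd <- data.frame(gene_a = "0_0", gene_b = "0_3")
  expect_warning(arr <- buildTandemArrays(tnd, cat5), "not adjacent")
  expect_equal(arr$arrayOf[["0_3"]], arr$arrayOf[["0_0"]])
})

make_ogs <- function(...) {
  groups <- list(...)
  new("OrthogroupSet", ids = paste0("OG", seq_along(groups)),
      membership = groups)
}

no_tandem_arrays <- function(catalog) {
  buildTandemArrays(data.frame(gene_a = character(0L),
                               gene_b = character(0L)), catalog)
}

test_that("orthogroup with one gene per diploid species becomes a tether", {
  cat3 <- toy_catalog(c("spA", "spB", "spC"), 3L)
  arr <- no_tandem_arrays(cat3)
  ogs <- make_ogs(list(spA = "0_0", spB = "1_0", spC = "2_0"))
  th <- buildTethers(ogs, arr)
  expect_equal(length(th), 1L)
  expect_equal(unname(tetherOf(th, c("0_0", "1_0", "2_0"))), rep("OG1", 3L))
})

test_that("a species with more gene sets than ploidy is excluded, others kept", {
  cat3 <- toy_catalog(c("spA", "spB", "spC"), 3L)
  arr <- no_tandem_arrays(cat3)
  # spA contributes 2 singleton gene sets at ploidy 1
  ogs <- make_ogs(list(spA = c("0_0", "0_2"), spB = "1_0", spC = "2_0"))
  th <- buildTethers(ogs, arr)
  expect_equal(length(th), 1L)
  expect_true(is.na(tetherOf(th, "0_0")[[1L]]))
  expect_true(is.na(tetherOf(th, "0_2")[[1L]]))
  expect_equal(unname(tetherOf(th, "1_0")), "OG1")
  expect_equal(th@excluded$OG1, "spA")
})

test_that("a tandem array counts as one gene set, keeping its species in", {
  cat3 <- toy_catalog(c("spA", "spB"), 3L)
  arr <- buildTandemArrays(data.frame(gene_a = "0_0", gene_b = "0_1"), cat3)
  ogs <- make_ogs(list(spA = c("0_0", "0_1"), spB = "1_0"))
  th <- buildTethers(ogs, arr)
  expect_equal(length(th), 1L)
  expect_equal(unname(tetherOf(th, c("0_0", "0_1"))), rep("OG1", 2L))
})

test_that("a tetraploid may contribute up to its ploidy in gene sets", {
  cat2 <- toy_catalog(c("polyT", "spA"), 4L)
  arr <- no_tandem_arrays(cat2)
  ogs <- make_ogs(list(polyT = c("0_0", "0_2"), spA = "1_0"))
  th1 <- buildTethers(ogs, arr, ploidy = c(polyT = 2L))
  expect_equal(length(th1), 1L)
  expect_equal(unname(tetherOf(th1, "0_2")), "OG1")
  # same orthogroup at ploidy 1 everywhere: polyT excluded, only one
  # nonzero species left -> no tether
  th2 <- buildTethers(ogs, arr)
  expect_equal(length(th2), 0L)
})

test_that("fewer than two nonzero within-ploidy species yields no tether", {
  cat3 <- toy_catalog(c("spA", "spB", "spC"), 3L)
  arr <- no_tandem_arrays(cat3)
  ogs <- make_ogs(list(spA = "0_0", spB = character(0L), spC = character(0L)))
  expect_equal(length(buildTethers(ogs, arr)), 0L)
})

test_that("dropping the ploidy table equals ploidy 1 everywhere", {
  cat3 <- toy_catalog(c("spA", "spB", "spC"), 4L)
  arr <- no_tandem_arrays(cat3)
  ogs <- make_ogs(list(spA = c("0_0", "0_1"), spB = "1_0", spC = "2_0"),
                  list(spA = "0_2", spB = "1_1", spC = "2_1"))
  th_default <- buildTethers(ogs, arr)
  th_ones <- buildTethers(ogs, arr,
                          ploidy = c(spA = 1L, spB = 1L, spC = 1L))
  expect_equal(th_default@tethers, th_ones@tethers)
  expect_equal(th_default@index, th_ones@index)
})

test_that("tether lookup returns NA for unknown and excluded genes", {
  cat3 <- toy_catalog(c("spA", "spB", "spC"), 3L)
  arr <- no_tandem_arrays(cat3)
  ogs <- make_ogs(list(spA = c("0_0", "0_1"), spB = "1_0", spC = "2_0"))
  th <- buildTethers(ogs, arr)   # spA excluded (2 sets > ploidy 1)
  look <- tetherOf(th, c("1_0", "0_0", "0_2"))
  expect_equal(unname(look), c("OG1", NA, NA))
})
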