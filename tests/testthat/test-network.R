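# synteny graph assembly, component decomposition, summaries, comparison

library(igraph)

test_that("block pairs become edges; duplicates collapse; tandems chain in", {
  cat2 <- toy_catalog(c("spA", "spB"), 6L)
  b1 <- score_block("PPPPP", "b1")  # pairs 0_i -- 1_i, i = 0..4
  b2 <- score_block("PP", "b2")     # repeats pairs 0_0--1_0, 0_1--1_1
  x <- new("CollinearitySet", blocks = list(b1, b2))
  arr <- buildTandemArrays(data.frame(gene_a = character(0L),
                                      gene_b = character(0L)), cat2)
  g <- buildSyntenyGraph(x, arr, cat2)
  expect_equal(igraph::ecount(g), 5L)              # dedup
  expect_equal(sum(igraph::degree(g) > 0L), 10L)
  # tandem array chain connects a gene with no block edge
  arr2 <- buildTandemArrays(data.frame(gene_a = "0_4", gene_b = "0_5"),
                            cat2)
  g2 <- buildSyntenyGraph(x, arr2, cat2)
  expect_equal(igraph::ecount(g2), 6L)
  cmp <- connectedComponents(g2)
  with_05 <- Filter(function(v) "0_5" %in% v, cmp)
  expect_true("0_4" %in% with_05[[1L]] && "1_4" %in% with_05[[1L]])
})

test_that("an edge naming an unknown gene is fatal", {
  cat2 <- toy_catalog("spA", 2L)
  b <- score_block("PP", "b1")   # references 1_0 etc., absent from catalog
  x <- new("CollinearitySet", blocks = list(b))
  expect_error(buildSyntenyGraph(x, NULL, cat2), "unknown gene")
})

test_that("components match hand cases and isolated vertices drop out", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b", "d"), to = c("b", "c", "e")),
    directed = FALSE, vertices = c("a", "b", "c", "d", "e", "lonely"))
  cmp <- connectedComponents(g)
  expect_equal(cmp, list(c("a", "b", "c"), c("d", "e")))
  g0 <- igraph::graph_from_data_frame(
    data.frame(from = character(0L), to = character(0L)),
    directed = FALSE, vertices = c("a", "b"))
  expect_equal(connectedComponents(g0), list())
})

test_that("components agree with a flood-fill oracle on random graphs", {
  set.seed(31)
  for (i in 1:25) {
    nv <- sample(5:50, 1L)
    vs <- sprintf("v%02d", seq_len(nv))
    ne <- sample(0:(2L * nv), 1L)
    ed <- unique(data.frame(from = sample(vs, ne, replace = TRUE),
                            to = sample(vs, ne, replace = TRUE)))
    ed <- ed[ed$from != ed$to, , drop = FALSE]
    g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = vs)
    expect_equal(connectedComponents(g), bfs_components(ed, vs))
  }
})

test_that("group summaries classify singleton, tether and specific groups", {
  cat3 <- toy_catalog(c("spA", "spB", "polyT"), 6L)
  tnd <- data.frame(gene_a = c("2_0", "0_2"), gene_b = c("2_1", "0_3"))
  arr <- buildTandemArrays(tnd, cat3)
  species_of <- geneSpecies(cat3)
  pl <- c(spA = 1L, spB = 1L, polyT = 2L)
  groups <- list(
    c("0_0", "1_0", "2_2", "2_3"),  # 1 gene per diploid, 2 for tetraploid
    c("2_0", "2_1"),                # species-specific tandem array
    c("0_2", "0_3", "1_1"),         # tandem array + one spB gene
    c("0_4", "0_5", "1_2"))         # two non-tandem spA genes at ploidy 1
  sm <- summarizeGroups(groups, arr, pl, species_of,
                        speciesNames(cat3))
  expect_equal(sm$tallies$total_groups, 4L)
  expect_equal(sm$tallies$singleton_groups, 1L)
  expect_equal(sm$tallies$species_specific_groups, 1L)
  # groups 1-3 are tether groups; group 4 exceeds ploidy in gene sets
  expect_equal(sm$tallies$tether_groups, 3L)
  expect_equal(unname(sm$geneCounts[1L, ]),
               unname(c(polyT = 2L, spA = 1L, spB = 1L)))
  expect_equal(unname(sm$setCounts[2L, "polyT"]), 1L)
})

test_that("identical runs compare as fully identical", {
  g <- list(c("a1", "b1"), c("a2", "b2"))
  sp <- setNames(c("A", "B", "A", "B"), c("a1", "b1", "a2", "b2"))
  cmp <- compareGroupSets(g, g, sp)
  expect_equal(cmp$n_identical, 2L)
  expect_equal(cmp$n_unique1 + cmp$n_unique2, 0L)
  expect_equal(cmp$fraction_identical, 1)
  expect_equal(nrow(cmp$clusters), 0L)
})

test_that("a group missing from one run is unique to the other", {
  g1 <- list(c("a1", "b1"), c("a2", "b2"))
  g2 <- list(c("a1", "b1"))
  sp <- setNames(c("A", "B", "A", "B"), c("a1", "b1", "a2", "b2"))
  cmp <- compareGroupSets(g1, g2, sp)
  expect_equal(cmp$n_identical, 1L)
  expect_equal(cmp$n_unique1, 1L)
  expect_equal(cmp$n_unique2, 0L)
})

test_that("a split group forms one complementary overlap cluster", {
  g1 <- list(c("a1", "b1", "c1", "a2", "b2", "c2"))
  g2 <- list(c("a1", "b1", "c1"), c("a2", "b2", "c2"))
  sp <- setNames(rep(c("A", "B", "C"), 2L),
                 c("a1", "b1", "c1", "a2", "b2", "c2"))
  cmp <- compareGroupSets(g1, g2, sp)
  expect_equal(nrow(cmp$clusters), 1L)
  expect_equal(cmp$clusters$kind, "complementary")
  expect_equal(cmp$clusters$n_groups2, 2L)
  # disagreement within a species is conflicting instead
  cmp2 <- compareGroupSets(list(c("a1", "b1")), list(c("a1", "b2")),
                           setNames(c("A", "B", "B"), c("a1", "b1", "b2")))
  expect_equal(cmp2$clusters$kind, "conflicting")
})

test_that("a gene universe mismatch is fatal", {
  g1 <- list(c("a1", "b1"))
  sp <- setNames("A", "a1")
  expect_error(compareGroupSets(g1, g1, sp), "universe mismatch")
})
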