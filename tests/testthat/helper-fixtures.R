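# Shared fixtures: tiny catalogs, hand-built tether sets, score-vector
# blocks, and an independent flood-fill component oracle.

# catalog with `n` genes per species, one chromosome each, genes 1 kb apart
toy_catalog <- function(species = c("spA", "spB"), n = 5L) {
  rows <- lapply(seq_along(species), function(i) {
    data.frame(species = species[i],
               chrom = paste0("c", i),
               start = (seq_len(n) - 1L) * 1000L + 1L,
               end = (seq_len(n) - 1L) * 1000L + 900L,
               original = paste0(species[i], ".g", seq_len(n)),
               canonical = paste0(i - 1L, "_", seq_len(n) - 1L),
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  GeneCatalog(d$species, d$chrom, d$start, d$end, d$original, d$canonical)
}

# TetherSets built directly from a membership list:
#   list(T1 = list(spA = c("0_0"), spB = c("1_0")), ...)
toy_tethers <- function(membership) {
  genes <- as.character(unlist(membership, use.names = FALSE))
  tids <- if (length(membership))
    rep(names(membership),
        vapply(membership, function(m) length(unlist(m, use.names = FALSE)),
               integer(1L)))
  else character(0L)
  new("TetherSets", tethers = membership,
      index = setNames(as.character(tids), genes),
      excluded = setNames(vector("list", length(membership)), names(membership)),
      report = data.frame())
}

# block record from a score string like "PPNCP"; gene pairs are dummies
score_block <- function(scores, id = "b1") {
  sc <- strsplit(scores, "")[[1L]]
  n <- length(sc)
  list(id = id, chrom_a = "x1", chrom_b = "y1", orientation = "plus",
       intra = FALSE, score = "0", e_value = "0",
       pairs = data.frame(gene_a = paste0("0_", seq_len(n) - 1L),
                          gene_b = paste0("1_", seq_len(n) - 1L),
                          evalue = 0, e_str = "0", stringsAsFactors = FALSE),
       scores = sc, counts = c(n_pass = sum(sc == "P"),
                               n_notpass = sum(sc == "N"),
                               n_nocall = sum(sc == "C")))
}

score_string <- function(block) paste(block$scores, collapse = "")

# independent connected-components oracle: breadth-first flood fill over
# an adjacency list, no igraph
bfs_components <- function(edges, vertices) {
  adj <- setNames(vector("list", length(vertices)), vertices)
  for (k in seq_len(nrow(edges))) {
    a <- edges$from[k]; b <- edges$to[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- setNames(logical(length(vertices)), vertices)
  comps <- list()
  for (v in vertices) {
    if (seen[v]) next
    queue <- v; seen[v] <- TRUE; comp <- character(0L)
    while (length(queue)) {
      x <- queue[1L]; queue <- queue[-1L]
      comp <- c(comp, x)
      for (nb in adj[[x]]) if (!seen[nb]) {
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
    if (length(comp) >= 2L) comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, `[`, character(1L), 1L))]
}

# run the full pipeline on a written simulation directory
run_sim_pipeline <- function(paths, ...) {
  runSyntenicPipeline(paths$orthogroups, paths$collinearity, paths$tandem,
                      paths$positions, ploidy = paths$ploidy,
                      species_ids = paths$species_ids,
                      sequence_ids = paths$sequence_ids,
                      verbose = FALSE, ...)
}

# Exhaustive decision-tree cases for pair scoring: every membership
# configuration of the two genes over {untethered, tether T1, tether T2},
# crossed with presence/absence of an other-species co-member, for both
# the inter-species and the intra-genome (species A = species B) setting.
# `expected` is the hand-derived classification.
score_pair_cases <- function() {
  cases <- list()
  add <- function(label, tethers, a, b, expected)
    cases[[length(cases) + 1L]] <<- list(label = label, tethers = tethers,
                                         a = a, b = b, expected = expected)
  # inter-species: a = 0_0 (spA), b = 1_0 (spB)
  add("both in same tether",
      list(T1 = list(spA = "0_0", spB = "1_0")), "0_0", "1_0", "P")
  add("same tether, with extra co-members",
      list(T1 = list(spA = c("0_0", "0_5"), spB = c("1_0", "1_5"))),
      "0_0", "1_0", "P")
  add("different tethers",
      list(T1 = list(spA = "0_0", spB = "1_9"),
           T2 = list(spA = "0_9", spB = "1_0")), "0_0", "1_0", "N")
  add("different tethers, no cross co-members",
      list(T1 = list(spA = "0_0"), T2 = list(spB = "1_0")),
      "0_0", "1_0", "N")
  add("neither tethered", list(T1 = list(spA = "0_9", spB = "1_9")),
      "0_0", "1_0", "C")
  add("neither tethered, no tethers at all", list(), "0_0", "1_0", "C")
  add("only a tethered; tether holds another spB gene",
      list(T1 = list(spA = "0_0", spB = "1_9")), "0_0", "1_0", "N")
  add("only a tethered; tether holds no spB gene",
      list(T1 = list(spA = c("0_0", "0_5"))), "0_0", "1_0", "C")
  add("only b tethered; tether holds another spA gene",
      list(T1 = list(spA = "0_9", spB = "1_0")), "0_0", "1_0", "N")
  add("only b tethered; tether holds no spA gene",
      list(T1 = list(spB = c("1_0", "1_5"))), "0_0", "1_0", "C")
  # intra-genome: both genes from spA (a = 0_0, b = 0_1)
  add("intra: both in same tether",
      list(T1 = list(spA = c("0_0", "0_1"))), "0_0", "0_1", "P")
  add("intra: different tethers",
      list(T1 = list(spA = "0_0"), T2 = list(spA = "0_1")),
      "0_0", "0_1", "N")
  add("intra: neither tethered", list(T1 = list(spA = "0_9")),
      "0_0", "0_1", "C")
  add("intra: only a tethered; tether holds a third spA gene",
      list(T1 = list(spA = c("0_0", "0_5"))), "0_0", "0_1", "N")
  add("intra: only a tethered; tether holds only a itself",
      list(T1 = list(spA = "0_0")), "0_0", "0_1", "C")
  add("intra: only b tethered; tether holds a third spA gene",
      list(T1 = list(spA = c("0_1", "0_5"))), "0_0", "0_1", "N")
  add("intra: only b tethered; tether holds only b itself",
      list(T1 = list(spA = "0_1")), "0_0", "0_1", "C")
  add("self pair, tethered", list(T1 = list(spA = "0_0")),
      "0_0", "0_0", "C")
  add("self pair, untethered", list(), "0_0", "0_0", "C")
  cases
}

score_case_species <- function() {
  g <- c(paste0("0_", 0:9), paste0("1_", 0:9))
  setNames(ifelse(startsWith(g, "0"), "spA", "spB"), g)
}
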