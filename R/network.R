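#' Build the genome-wide synteny graph
#'
#' Vertices are all genes of all species; undirected edges are (i) every
#' gene pair of every surviving collinear block, regardless of its
#' Pass/Not Pass/No Call score, and (ii) chain edges along consecutive
#' members of every tandem array (tandem duplication is itself a form of
#' syntenic orthology, so arrays are connected even when none of their
#' members touches a block edge).  Self-loops are dropped and duplicate
#' edges collapsed.
#'
#' @param x a [CollinearitySet-class] of surviving (refined) blocks.
#' @param arrays result of [buildTandemArrays()], or `NULL` for no tandem
#'   edges.
#' @param catalog a [GeneCatalog-class]; an edge naming a gene outside the
#'   catalog is fatal.
#' @return an `igraph` undirected graph whose vertices are all catalog
#'   genes.
#' @export
buildSyntenyGraph <- function(x, arrays = NULL, catalog) {
  ga <- unlist(lapply(x@blocks, function(b) b$pairs$gene_a), use.names = FALSE)
  gb <- unlist(lapply(x@blocks, function(b) b$pairs$gene_b), use.names = FALSE)
  if (!is.null(arrays)) {
    for (m in arrays$arrays) {
      if (length(m) >= 2L) {
        ga <- c(ga, m[-length(m)])
        gb <- c(gb, m[-1L])
      }
    }
  }
  genes <- geneTable(catalog)$canonical
  unknown <- setdiff(unique(c(ga, gb)), genes)
  if (length(unknown))
    stop("edge references unknown gene(s): ",
         paste(head(unknown, 3L), collapse = ", "))
  keep <- ga != gb
  ga <- ga[keep]; gb <- gb[keep]
  lo <- pmin(ga, gb); hi <- pmax(ga, gb)
  ed <- unique(data.frame(from = lo, to = hi, stringsAsFactors = FALSE))
  ed <- ed[order(ed$from, ed$to), , drop = FALSE]
  igraph::graph_from_data_frame(ed, directed = FALSE,
                                vertices = sort(genes))
}

#' Connected components of a synteny graph
#'
#' Components with at least two genes, in deterministic order (sorted by
#' each component's lexicographically smallest member); isolated vertices
#' yield no group.
#'
#' @param graph an undirected `igraph` graph.
#' @return list of character vectors of vertex names, each sorted.
#' @export
connectedComponents <- function(graph) {
  cmp <- igraph::components(graph)
  memb <- split(names(cmp$membership), cmp$membership)
  memb <- memb[cmp$csize[as.integer(names(memb))] >= 2L]
  memb <- lapply(memb, sort)
  memb <- memb[order(vapply(memb, `[`, character(1L), 1L))]
  unname(memb)
}

#' Per-group and global summaries of syntenic orthogroups
#'
#' Computes, for each group, the gene count and gene-set (tandem array)
#' count per species, and global tallies: total groups; singleton groups
#' (every species contributes exactly its ploidy in genes); tether groups
#' (every species contributes at most its ploidy in gene sets); and
#' species-specific groups (exactly one species represented).
#'
#' @param groups list of character vectors of canonical gene names.
#' @param arrays result of [buildTandemArrays()].
#' @param ploidy named integer vector, species -> relative ploidy.
#' @param species_of named character vector, gene -> species.
#' @param species character vector of all species (columns of the count
#'   matrices).
#' @return list with `geneCounts` and `setCounts` (integer matrices,
#'   groups x species) and `tallies`.
#' @export
summarizeGroups <- function(groups, arrays, ploidy, species_of, species) {
  n <- length(groups)
  geneCounts <- matrix(0L, n, length(species),
                       dimnames = list(NULL, species))
  setCounts <- geneCounts
  for (i in seq_len(n)) {
    sp <- species_of[groups[[i]]]
    by_sp <- split(groups[[i]], sp)
    for (s in names(by_sp)) {
      geneCounts[i, s] <- length(by_sp[[s]])
      setCounts[i, s] <- countGeneSets(by_sp[[s]], arrays$arrayOf)
    }
  }
  pl <- ifelse(species %in% names(ploidy), ploidy[species], 1L)
  singleton <- apply(geneCounts, 1L, function(r) all(r == pl))
  tether <- apply(setCounts, 1L, function(r) all(r <= pl))
  specific <- apply(geneCounts, 1L, function(r) sum(r > 0L) == 1L)
  list(geneCounts = geneCounts, setCounts = setCounts,
       tallies = list(total_groups = n,
                      singleton_groups = sum(singleton),
                      tether_groups = sum(tether),
                      species_specific_groups = sum(specific)))
}

#' Assemble the final syntenic orthogroups
#'
#' Builds the synteny graph from surviving blocks plus tandem edges,
#' decomposes it into connected components, and summarises the result.
#' Group ids are assigned in order of each group's smallest member.
#'
#' @param refined a [CollinearitySet-class] of surviving blocks (from
#'   [refineBlocks()]).
#' @param arrays result of [buildTandemArrays()].
#' @param catalog a [GeneCatalog-class].
#' @param ploidy named integer vector, species -> relative ploidy.
#' @return a [SyntenyOrthogroups-class].
#' @export
assembleOrthogroups <- function(refined, arrays, catalog, ploidy = integer(0L)) {
  graph <- buildSyntenyGraph(refined, arrays, catalog)
  comps <- connectedComponents(graph)
  species <- speciesNames(catalog)
  species_of <- geneSpecies(catalog)
  smry <- summarizeGroups(comps, arrays, ploidy, species_of, species)
  ids <- sprintf("SO%06d", seq_along(comps))
  groups <- lapply(comps, function(g) {
    m <- split(g, factor(species_of[g], levels = species))
    lapply(m, unname)
  })
  names(groups) <- ids
  rownames(smry$geneCounts) <- ids
  rownames(smry$setCounts) <- ids
  new("SyntenyOrthogroups", groups = groups, species = species,
      geneCounts = smry$geneCounts, setCounts = smry$setCounts,
      tallies = smry$tallies)
}

#' @describeIn assembleOrthogroups group membership, a named list of
#'   per-species gene lists
#' @param x a [SyntenyOrthogroups-class]
#' @export
setMethod("groupList", "SyntenyOrthogroups", function(x) x@groups)

#' Number of syntenic orthogroups
#' @param x a [SyntenyOrthogroups-class]
#' @export
setMethod("length", "SyntenyOrthogroups", function(x) length(x@groups))

#' @describeIn assembleOrthogroups total genes placed into groups
#' @export
setMethod("nGenes", "SyntenyOrthogroups",
          function(x) length(unlist(x@groups, use.names = FALSE)))

#' @describeIn assembleOrthogroups species of the analysis
#' @export
setMethod("speciesNames", "SyntenyOrthogroups", function(x) x@species)

setMethod("show", "SyntenyOrthogroups", function(object) {
  t <- object@tallies
  cat("SyntenyOrthogroups:", t$total_groups, "groups,",
      nGenes(object), "genes,", length(object@species), "species\n")
  cat("  singleton:", t$singleton_groups,
      "| tether:", t$tether_groups,
      "| species-specific:", t$species_specific_groups, "\n")
})

#' Compare two sets of orthogroups over one gene universe
#'
#' Groups are compared by exact gene membership after any name/label
#' normalisation by the caller.  Non-identical groups that share genes
#' are clustered (connected components of the group-overlap relation) and
#' each cluster is classified: `complementary` when, for every species,
#' the two runs' gene sets within the cluster are equal or one of them is
#' empty; `conflicting` when some species has nonempty, differing gene
#' sets in the two runs.
#'
#' @param groups1,groups2 lists of character vectors of gene names (or
#'   [SyntenyOrthogroups-class] objects).
#' @param species_of named character vector, gene -> species, covering
#'   every gene of both runs (a gene outside it is a universe mismatch
#'   and fatal).
#' @return list with counts `n1`, `n2`, `n_identical`, `n_unique1`,
#'   `n_unique2`, a `clusters` data.frame (groups and kind per overlap
#'   cluster), and `fraction_identical` (identical groups over the mean
#'   group count).
#' @export
compareGroupSets <- function(groups1, groups2, species_of) {
  flat <- function(g) {
    if (is(g, "SyntenyOrthogroups"))
      g <- lapply(g@groups, function(m) unlist(m, use.names = FALSE))
    lapply(g, function(v) sort(unname(v)))
  }
  g1 <- flat(groups1); g2 <- flat(groups2)
  all_genes <- unique(c(unlist(g1, use.names = FALSE),
                        unlist(g2, use.names = FALSE)))
  miss <- setdiff(all_genes, names(species_of))
  if (length(miss))
    stop("gene universe mismatch: ", paste(head(miss, 3L), collapse = ", "),
         " not covered by species_of")
  sig1 <- vapply(g1, paste, character(1L), collapse = "|")
  sig2 <- vapply(g2, paste, character(1L), collapse = "|")
  ident <- intersect(sig1, sig2)
  r1 <- which(!(sig1 %in% ident))
  r2 <- which(!(sig2 %in% ident))
  node <- c(paste0("a", r1, recycle0 = TRUE),
            paste0("b", r2, recycle0 = TRUE))
  gene2b <- list()
  for (j in r2) for (g in g2[[j]]) gene2b[[g]] <- c(gene2b[[g]], j)
  ed_from <- character(0L); ed_to <- character(0L)
  for (i in r1) for (g in g1[[i]]) for (j in gene2b[[g]] %||% integer(0L)) {
    ed_from <- c(ed_from, paste0("a", i))
    ed_to <- c(ed_to, paste0("b", j))
  }
  clusters <- data.frame(cluster = integer(0L), n_groups1 = integer(0L),
                         n_groups2 = integer(0L), kind = character(0L))
  n_unique1 <- 0L; n_unique2 <- 0L
  if (length(node)) {
    gr <- igraph::graph_from_data_frame(
      data.frame(from = ed_from, to = ed_to), directed = FALSE,
      vertices = node)
    cmp <- igraph::components(gr)
    for (k in seq_len(cmp$no)) {
      v <- names(cmp$membership)[cmp$membership == k]
      i1 <- as.integer(sub("^a", "", v[startsWith(v, "a")]))
      i2 <- as.integer(sub("^b", "", v[startsWith(v, "b")]))
      if (!length(i2)) { n_unique1 <- n_unique1 + length(i1); next }
      if (!length(i1)) { n_unique2 <- n_unique2 + length(i2); next }
      u1 <- unlist(g1[i1], use.names = FALSE)
      u2 <- unlist(g2[i2], use.names = FALSE)
      sp <- unique(species_of[c(u1, u2)])
      comp <- all(vapply(sp, function(s) {
        a <- sort(u1[species_of[u1] == s])
        b <- sort(u2[species_of[u2] == s])
        !length(a) || !length(b) || identical(a, b)
      }, logical(1L)))
      clusters <- rbind(clusters, data.frame(
        cluster = nrow(clusters) + 1L, n_groups1 = length(i1),
        n_groups2 = length(i2),
        kind = if (comp) "complementary" else "conflicting"))
    }
  }
  list(n1 = length(g1), n2 = length(g2), n_identical = length(ident),
       n_unique1 = n_unique1, n_unique2 = n_unique2,
       clusters = clusters,
       fraction_identical = if (length(g1) + length(g2) == 0L) 1 else
         length(ident) / mean(c(length(g1), length(g2))))
}
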