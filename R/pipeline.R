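#' Run the full syntenic-orthology pipeline
#'
#' The four stages: (1) orthogroups are collapsed over tandem arrays and
#' ploidy-filtered into tether sets; (2) every pair of every collinearity
#' block is scored Pass / Not Pass / No Call against the tethers and
#' blocks failing the acceptance filter are dropped; (3) surviving blocks
#' are recursively end-trimmed, window-trimmed and split until every rule
#' holds, discarding blocks left with fewer than `min_pairs` pairs;
#' (4) the surviving gene pairs plus tandem edges are assembled into a
#' graph whose connected components are the final orthogroups.
#'
#' All inputs are file paths; objects produced along the way are
#' returned.  With `out_prefix`, the standard report files are written
#' (`<prefix>.orthogroups.tsv`, `.gene_counts.tsv`,
#' `.gene_set_counts.tsv`, `.block_stats.tsv`, `.trim_log.tsv`,
#' `.used_blocks.txt`, `.tether_report.tsv`); on error, partial outputs
#' are removed.  The pipeline is fully deterministic: identical inputs
#' give byte-identical outputs.
#'
#' @param orthogroups path to the orthogroups table (OrthoFinder
#'   dialect).
#' @param collinearity path to the .collinearity file.
#' @param tandem path to the .tandem file.
#' @param gene_positions path to the gene position file (MCScanX
#'   dialect, canonical names).
#' @param ploidy optional path to the relative-ploidy file (absent =
#'   ploidy 1 everywhere).
#' @param species_ids optional path to a SpeciesIDs file (species
#'   labels); default labels are `sp<index>`.
#' @param sequence_ids optional path to a SequenceIDs file; when given,
#'   orthogroup gene names are translated original -> canonical and
#'   results can be mapped back.
#' @param out_prefix optional output path prefix for report files.
#' @param min_pairs minimum surviving block size in gene pairs (default
#'   5).
#' @param verbose log per-stage counts via [message()] (default TRUE).
#' @return list: `orthogroups` (a [SyntenyOrthogroups-class]), `catalog`,
#'   `tethers`, `stats` (per-block score statistics), `trim_log`,
#'   `refined` (surviving [CollinearitySet-class]), and `counts`
#'   (per-stage tallies).
#' @export
runSyntenicPipeline <- function(orthogroups, collinearity, tandem,
                                gene_positions, ploidy = NULL,
                                species_ids = NULL, sequence_ids = NULL,
                                out_prefix = NULL, min_pairs = 5L,
                                verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  written <- character(0L)
  emit <- function(writer, x, suffix) {
    p <- paste0(out_prefix, suffix)
    writer(x, p)
    written <<- c(written, p)
  }
  tryCatch({
    sp_ids <- if (!is.null(species_ids)) readSpeciesIds(species_ids) else NULL
    seq_ids <- if (!is.null(sequence_ids)) readSequenceIds(sequence_ids) else NULL
    catalog <- readGenePositions(gene_positions, sp_ids, seq_ids)
    say("catalog: ", nGenes(catalog), " genes, ",
        length(speciesNames(catalog)), " species")
    translation <- if (!is.null(seq_ids))
      setNames(names(seq_ids), unname(seq_ids)) else NULL
    ogs <- readOrthogroups(orthogroups, translation = translation,
                           species = speciesNames(catalog))
    col <- readCollinearity(collinearity)
    tnd <- readTandem(tandem, geneSpecies(catalog))
    pl <- readPloidy(ploidy, speciesNames(catalog))

    arrays <- buildTandemArrays(tnd, catalog)
    tethers <- buildTethers(ogs, arrays, pl)
    say("step 1: ", length(tethers), " tethers from ", length(ogs),
        " orthogroups")

    scored <- scoreBlocks(col, tethers, catalog)
    passing <- new("CollinearitySet",
                   blocks = Filter(blockPasses, blocks(scored)))
    say("step 2: ", length(passing), " of ", length(scored),
        " blocks pass scoring")

    ref <- refineBlocks(passing, min_pairs = min_pairs)
    n_edges_blocks <- sum(vapply(blocks(ref$blocks),
                                 function(b) nrow(b$pairs), integer(1L)))
    say("step 3: ", length(ref$blocks), " blocks survive trimming (",
        n_edges_blocks, " gene pairs)")

    result <- assembleOrthogroups(ref$blocks, arrays, catalog, pl)
    say("step 4: ", length(result), " orthogroups covering ",
        nGenes(result), " genes")

    if (!is.null(out_prefix)) {
      emit(writeOrthogroups, result, ".orthogroups.tsv")
      emit(function(x, p) write.table(x, p, sep = "\t", quote = FALSE),
           result@geneCounts, ".gene_counts.tsv")
      emit(function(x, p) write.table(x, p, sep = "\t", quote = FALSE),
           result@setCounts, ".gene_set_counts.tsv")
      emit(function(x, p) write.table(x, p, sep = "\t", quote = FALSE,
                                      row.names = FALSE),
           blockStats(scored), ".block_stats.tsv")
      emit(writeTrimLog, ref$log, ".trim_log.tsv")
      emit(function(x, p) writeLines(x, p),
           vapply(blocks(ref$blocks), `[[`, character(1L), "id"),
           ".used_blocks.txt")
      emit(writeTetherReport, tethers, ".tether_report.tsv")
    }
    list(orthogroups = result, catalog = catalog, tethers = tethers,
         stats = blockStats(scored), trim_log = ref$log,
         refined = ref$blocks,
         counts = list(genes = nGenes(catalog),
                       input_orthogroups = length(ogs),
                       tethers = length(tethers),
                       blocks_in = length(scored),
                       blocks_passing = length(passing),
                       blocks_surviving = length(ref$blocks),
                       block_edges = n_edges_blocks,
                       groups = length(result),
                       genes_grouped = nGenes(result)))
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
}

#' Map a run's groups back to original gene names
#'
#' @param result a [SyntenyOrthogroups-class].
#' @param catalog the run's [GeneCatalog-class] (carries the
#'   canonical/original bijection).
#' @return list of character vectors of original gene names.
#' @export
groupsAsOriginal <- function(result, catalog) {
  tr <- setNames(geneTable(catalog)$original, geneTable(catalog)$canonical)
  lapply(groupList(result), function(m) {
    unname(tr[unlist(m, use.names = FALSE)])
  })
}

#' Compare two pipeline runs after label normalisation
#'
#' Canonical gene names of both runs are mapped back to original
#' annotation names through each run's catalog, species labels are
#' normalised through `species_map` (old label -> new label; labels not
#' named in the map are kept), and the groups are compared with
#' [compareGroupSets()].  Typical use: one run with an allopolyploid as a
#' single species of ploidy 2 versus one with its subgenomes split a
#' priori into two "species" of ploidy 1.
#'
#' @param runA,runB results of [runSyntenicPipeline()] (lists carrying
#'   `orthogroups` and `catalog`).
#' @param species_map named character vector normalising species labels
#'   (e.g. `c(polyAt = "polyP", polyDt = "polyP")`); after mapping, the
#'   two runs must share one species set, otherwise the call is fatal.
#' @return the [compareGroupSets()] report.
#' @export
runComparison <- function(runA, runB, species_map = NULL) {
  norm_sp <- function(sp) {
    if (is.null(species_map)) return(sp)
    ifelse(sp %in% names(species_map), species_map[sp], sp)
  }
  spA <- sort(unique(norm_sp(speciesNames(runA$catalog))))
  spB <- sort(unique(norm_sp(speciesNames(runB$catalog))))
  if (!identical(spA, spB))
    stop("species sets differ after normalisation (",
         paste(spA, collapse = ","), " vs ", paste(spB, collapse = ","),
         "); species_map must reconcile them")
  gA <- groupsAsOriginal(runA$orthogroups, runA$catalog)
  gB <- groupsAsOriginal(runB$orthogroups, runB$catalog)
  tabA <- geneTable(runA$catalog)
  tabB <- geneTable(runB$catalog)
  species_of <- c(setNames(norm_sp(tabA$species), tabA$original),
                  setNames(norm_sp(tabB$species), tabB$original))
  species_of <- species_of[!duplicated(names(species_of))]
  compareGroupSets(gA, gB, species_of)
}

#' Write a comparison report
#' @param cmp result of [runComparison()] / [compareGroupSets()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeComparisonReport <- function(cmp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("groups_run1\t", cmp$n1),
               paste0("groups_run2\t", cmp$n2),
               paste0("identical_groups\t", cmp$n_identical),
               paste0("unique_to_run1\t", cmp$n_unique1),
               paste0("unique_to_run2\t", cmp$n_unique2),
               paste0("overlap_clusters\t", nrow(cmp$clusters)),
               paste0("conflicting_clusters\t",
                      sum(cmp$clusters$kind == "conflicting")),
               paste0("complementary_clusters\t",
                      sum(cmp$clusters$kind == "complementary")),
               paste0("fraction_identical\t",
                      format(cmp$fraction_identical, digits = 6L))), con)
  invisible(path)
}
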