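#' Score one gene pair against the tether sets
#'
#' The three-way decision tree:
#' * both genes in the same tether set -> `"P"` (Pass);
#' * both in tethers, but different ones -> `"N"` (Not Pass);
#' * neither gene in any tether -> `"C"` (No Call);
#' * exactly one gene tethered: if its tether contains any gene of the
#'   *other* gene's species — other than the two genes of the pair
#'   themselves — the pair is `"N"`, otherwise `"C"`.
#'
#' The tree is symmetric: swapping the two genes never changes the score.
#' Intra-genome blocks use the same tree with both species equal; a gene
#' paired with itself carries no orthology evidence and scores `"C"`.
#' Unknown genes are untethered by definition.
#'
#' @param gene_a,gene_b canonical gene names (scalars).
#' @param tethers a [TetherSets-class].
#' @param species_of named character vector, gene -> species (as from
#'   [geneSpecies()]).
#' @return one of `"P"`, `"N"`, `"C"`.
#' @export
scorePair <- function(gene_a, gene_b, tethers, species_of) {
  .score_pairs(gene_a, gene_b, tethers, species_of)
}

.score_pairs <- function(ga, gb, tethers, species_of) {
  ta <- unname(tethers@index[match(ga, names(tethers@index))])
  tb <- unname(tethers@index[match(gb, names(tethers@index))])
  res <- rep("C", length(ga))
  self <- ga == gb
  both <- !self & !is.na(ta) & !is.na(tb)
  res[both & ta == tb] <- "P"
  res[both & ta != tb] <- "N"
  one <- !self & xor(is.na(ta), is.na(tb))
  for (i in which(one)) {
    a_teth <- !is.na(ta[i])
    tid <- if (a_teth) ta[i] else tb[i]
    tg <- if (a_teth) ga[i] else gb[i]  # the tethered gene
    og <- if (a_teth) gb[i] else ga[i]  # the untethered gene
    osp <- unname(species_of[match(og, names(species_of))])
    members <- if (!is.na(osp)) tethers@tethers[[tid]][[osp]] %||% character(0L)
               else character(0L)
    members <- setdiff(members, c(tg, og))
    if (length(members)) res[i] <- "N"
  }
  res
}

.count_scores <- function(sc) {
  c(n_pass = sum(sc == "P"), n_notpass = sum(sc == "N"),
    n_nocall = sum(sc == "C"))
}

#' Score every pair of one collinear block
#'
#' @param block a block record (see [CollinearitySet-class]).
#' @param tethers a [TetherSets-class].
#' @param species_of named character vector, gene -> species.
#' @return the block with `scores` and `counts` filled in.
#' @export
scoreBlock <- function(block, tethers, species_of) {
  sc <- .score_pairs(block$pairs$gene_a, block$pairs$gene_b,
                     tethers, species_of)
  block$scores <- sc
  block$counts <- .count_scores(sc)
  block
}

#' Score every block of a CollinearitySet
#'
#' All pairs are scored in one pass with [scorePair()]'s decision tree;
#' scoring is pure, so block order cannot affect any score.
#'
#' @param x a [CollinearitySet-class].
#' @param tethers a [TetherSets-class].
#' @param catalog a [GeneCatalog-class] (source of gene species), or a
#'   named character vector gene -> species.
#' @return the [CollinearitySet-class] with scored blocks.
#' @export
scoreBlocks <- function(x, tethers, catalog) {
  species_of <- if (is(catalog, "GeneCatalog")) geneSpecies(catalog) else catalog
  np <- vapply(x@blocks, function(b) nrow(b$pairs), integer(1L))
  ga <- unlist(lapply(x@blocks, function(b) b$pairs$gene_a), use.names = FALSE)
  gb <- unlist(lapply(x@blocks, function(b) b$pairs$gene_b), use.names = FALSE)
  sc <- .score_pairs(ga, gb, tethers, species_of)
  sc_by_block <- split(sc, rep(seq_along(np), np))
  out <- x@blocks
  for (i in seq_along(out)) {
    out[[i]]$scores <- unname(sc_by_block[[as.character(i)]] %||% character(0L))
    out[[i]]$counts <- .count_scores(out[[i]]$scores)
  }
  new("CollinearitySet", blocks = out)
}

#' Block-level acceptance filter
#'
#' A scored block is kept iff it has at least two Pass pairs and its Not
#' Pass pairs do not outnumber its Pass pairs (a tie is kept); No Call
#' pairs are irrelevant.
#'
#' @param block a scored block record, or a `counts` vector with entries
#'   `n_pass` and `n_notpass`.
#' @return logical.
#' @export
blockPasses <- function(block) {
  cn <- if (is.list(block)) {
    if (is.null(block$counts)) {
      if (is.null(block$scores)) stop("block is not scored")
      .count_scores(block$scores)
    } else block$counts
  } else block
  unname(cn["n_pass"] >= 2L && !(cn["n_notpass"] > cn["n_pass"]))
}

#' Per-block score statistics
#'
#' @param x a scored [CollinearitySet-class].
#' @return data.frame: block id, chromosome/region pair, intra-genome
#'   flag, pair count, Pass/Not Pass/No Call tallies, accepted flag.
#' @export
blockStats <- function(x) {
  rows <- lapply(x@blocks, function(b) {
    if (is.null(b$scores)) stop("block ", b$id, " is not scored")
    data.frame(block_id = b$id, chrom_a = b$chrom_a, chrom_b = b$chrom_b,
               intra = b$intra, n_pairs = nrow(b$pairs),
               n_pass = unname(b$counts["n_pass"]),
               n_notpass = unname(b$counts["n_notpass"]),
               n_nocall = unname(b$counts["n_nocall"]),
               accepted = blockPasses(b), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows) %||% data.frame()
}
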