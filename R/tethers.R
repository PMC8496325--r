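#' Collapse tandem duplicates into gene sets (tandem arrays)
#'
#' A gene set is a gene together with all immediately neighbouring tandem
#' duplicates: adjacent tandem pairs are chained transitively into maximal
#' runs, and every gene not in any pair forms a singleton array, so arrays
#' partition the genome.  A declared pair whose members are not adjacent
#' in gene order (a tandem-caller/annotation disagreement) is still merged,
#' with a warning — the tandem call is trusted.
#'
#' @param tandem data.frame of tandem pairs (`gene_a`, `gene_b`), as from
#'   [readTandem()]; gene names canonical.
#' @param catalog a [GeneCatalog-class] defining gene order.
#' @return list with `arrayOf` (named character, gene -> array id) and
#'   `arrays` (named list, array id -> members in chromosomal order).
#'   Array ids are the canonical name of the array's first member.
#' @export
buildTandemArrays <- function(tandem, catalog) {
  g <- geneTable(catalog)
  genes <- g$canonical
  pos <- setNames(seq_along(genes), genes)
  miss <- setdiff(unique(c(tandem$gene_a, tandem$gene_b)), genes)
  if (length(miss))
    stop("tandem pair member(s) absent from gene catalog: ",
         paste(head(miss, 3L), collapse = ", "))

  parent <- seq_along(genes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(tandem)) {
    ia <- pos[tandem$gene_a]; ib <- pos[tandem$gene_b]
    adjacent <- g$species[ia] == g$species[ib] &
      g$chrom[ia] == g$chrom[ib] & abs(g$ord[ia] - g$ord[ib]) == 1L
    if (any(!adjacent))
      warning(sum(!adjacent),
              " tandem pair(s) not adjacent in gene order; merged anyway")
    for (k in seq_len(nrow(tandem))) {
      ra <- find(ia[k]); rb <- find(ib[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_along(genes), find, integer(1L))
  # order members within an array by (species, chrom, ord) = catalog row order
  grp <- split(seq_along(genes), root)
  members <- lapply(grp, function(ix) genes[sort(ix)])
  ids <- vapply(members, `[`, character(1L), 1L)
  names(members) <- ids
  arrayOf <- setNames(rep(ids, lengths(members)),
                      unlist(members, use.names = FALSE))
  list(arrayOf = arrayOf[genes], arrays = members)
}

#' Count distinct gene sets among a vector of genes
#' @param genes character vector of canonical gene names.
#' @param arrayOf named character vector, gene -> array id (from
#'   [buildTandemArrays()]).
#' @return integer, number of distinct tandem arrays intersected.
#' @export
countGeneSets <- function(genes, arrayOf) {
  if (!length(genes)) return(0L)
  length(unique(arrayOf[genes]))
}

#' Build ploidy-filtered tether sets from orthogroups
#'
#' For each orthogroup, the distinct gene sets (tandem arrays) contributed
#' by each species are counted.  A species whose gene-set count exceeds
#' its relative ploidy is excluded (its genes are dropped from the
#' tether); the orthogroup becomes a tether set iff at least two species
#' are left with a nonzero gene-set count within their ploidy.
#'
#' @param orthogroups an [OrthogroupSet-class].
#' @param arrays result of [buildTandemArrays()].
#' @param ploidy named integer vector, species -> relative ploidy; species
#'   not named default to 1.
#' @return a [TetherSets-class].
#' @export
buildTethers <- function(orthogroups, arrays, ploidy = integer(0L)) {
  arrayOf <- arrays$arrayOf
  ids <- orthogroups@ids
  tethers <- list(); excluded <- list()
  idx_genes <- character(0L); idx_tids <- character(0L)
  rep_rows <- vector("list", length(ids))
  for (r in seq_along(ids)) {
    m <- orthogroups@membership[[r]]
    sp <- names(m)
    counts <- integer(length(sp))
    for (j in seq_along(sp)) {
      g <- m[[j]]
      miss <- setdiff(g, names(arrayOf))
      if (length(miss))
        stop("orthogroup ", ids[r], ": gene(s) not in catalog: ",
             paste(head(miss, 3L), collapse = ", "))
      counts[j] <- countGeneSets(g, arrayOf)
    }
    pl <- ifelse(sp %in% names(ploidy), ploidy[sp], 1L)
    over <- counts > pl
    ok <- counts >= 1L & !over
    tethered <- sum(ok) >= 2L
    rep_rows[[r]] <- data.frame(
      orthogroup = ids[r], species = sp, n_genes = lengths(m),
      n_gene_sets = counts,
      status = ifelse(over, "excluded", ifelse(ok, "included", "empty")),
      tethered = tethered, stringsAsFactors = FALSE)
    if (tethered) {
      tid <- ids[r]
      tethers[[tid]] <- m[ok]
      excluded[[tid]] <- sp[over]
      tg <- unlist(m[ok], use.names = FALSE)
      idx_genes <- c(idx_genes, tg)
      idx_tids <- c(idx_tids, rep(tid, length(tg)))
    }
  }
  new("TetherSets", tethers = tethers,
      index = setNames(idx_tids, idx_genes),
      excluded = excluded,
      report = do.call(rbind, rep_rows) %||% data.frame())
}

#' @describeIn buildTethers tether id for each query gene (`NA` when none)
#' @param x a [TetherSets-class]
#' @param genes character vector of canonical gene names
#' @export
setMethod("tetherOf", "TetherSets", function(x, genes) {
  setNames(unname(x@index[match(genes, names(x@index))]), genes)
})

#' Number of tether sets
#' @param x a [TetherSets-class]
#' @export
setMethod("length", "TetherSets", function(x) length(x@tethers))

setMethod("show", "TetherSets", function(object) {
  cat("TetherSets:", length(object@tethers), "tethers anchoring",
      length(object@index), "genes\n")
  nexc <- sum(lengths(object@excluded) > 0L)
  if (nexc) cat("  ", nexc, "tether(s) with ploidy-excluded species\n")
})

#' Write the per-orthogroup tether report
#'
#' Tab-separated, one row per (source orthogroup, species): gene count,
#' gene-set count, included/excluded/empty status, and whether the
#' orthogroup became a tether.
#'
#' @param x a [TetherSets-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTetherReport <- function(x, path) {
  write.table(x@report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
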