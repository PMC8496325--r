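#' GeneCatalog: every gene of every genome in the analysis
#'
#' A `GeneCatalog` holds one row per gene with its species, chromosome,
#' 1-based inclusive coordinates, original annotation ID and canonical
#' (translated) name of the form `<speciesIndex>_<geneIndex>`.  Gene order
#' within a chromosome (`ord`) is ascending start, ties broken by end then
#' canonical name.  The original/canonical naming is a bijection across the
#' whole analysis.
#'
#' @slot genes data.frame with columns `species`, `chrom`, `start`, `end`,
#'   `original`, `canonical`, `ord`.
#' @seealso [GeneCatalog()], [readGenePositions()], [translateGff()]
#' @exportClass GeneCatalog
setClass("GeneCatalog", representation(genes = "data.frame"))

setValidity("GeneCatalog", function(object) {
  g <- object@genes
  need <- c("species", "chrom", "start", "end", "original", "canonical", "ord")
  if (!all(need %in% names(g)))
    return(paste("missing columns:", paste(setdiff(need, names(g)), collapse = ", ")))
  if (nrow(g) == 0L) return(TRUE)
  if (any(g$start > g$end)) return("start must be <= end for every gene")
  if (anyDuplicated(g$canonical)) return("canonical gene names must be unique")
  if (anyDuplicated(g$original)) return("original gene names must be unique")
  if (!all(grepl("^[0-9]+_[0-9]+$", g$canonical)))
    return("canonical names must have the form <speciesIndex>_<geneIndex>")
  sp_idx <- sub("_.*$", "", g$canonical)
  by_sp <- split(sp_idx, g$species)
  if (any(vapply(by_sp, function(x) length(unique(x)) != 1L, logical(1L))))
    return("speciesIndex must be constant within a species")
  if (anyDuplicated(vapply(by_sp, `[`, character(1L), 1L)))
    return("speciesIndex must differ between species")
  TRUE
})

#' OrthogroupSet: sequence-similarity orthogroups (OrthoFinder dialect)
#'
#' One orthogroup per element: a named list mapping species to character
#' vectors of canonical gene names.  Orthogroups partition their genes: no
#' gene may occur in two groups.
#'
#' @slot ids character vector of orthogroup identifiers.
#' @slot membership list (one element per group) of named lists
#'   (species -> character vector of genes).
#' @seealso [readOrthogroups()]
#' @exportClass OrthogroupSet
setClass("OrthogroupSet",
         representation(ids = "character", membership = "list"))

setValidity("OrthogroupSet", function(object) {
  if (length(object@ids) != length(object@membership))
    return("ids and membership must have equal length")
  if (anyDuplicated(object@ids)) return("orthogroup ids must be unique")
  all_genes <- unlist(object@membership, use.names = FALSE)
  if (anyDuplicated(all_genes)) {
    dup <- all_genes[duplicated(all_genes)][1L]
    hits <- which(vapply(object@membership,
                         function(m) dup %in% unlist(m, use.names = FALSE),
                         logical(1L)))
    return(sprintf("gene '%s' appears in more than one orthogroup (%s)",
                   dup, paste(object@ids[hits], collapse = ", ")))
  }
  TRUE
})

#' CollinearitySet: MCScanX collinearity blocks, optionally scored
#'
#' Each block is a list with elements `id`, `chrom_a`, `chrom_b`,
#' `orientation` ("plus"/"minus"), `intra` (logical), `score`, `e_value`
#' (header fields, carried for round-tripping) and `pairs`, a data.frame
#' with columns `gene_a`, `gene_b`, `evalue`, `e_str`.  After scoring, a
#' block additionally carries `scores` (one of "P", "N", "C" per pair;
#' Pass, Not Pass, No Call) and a `counts` vector (`n_pass`, `n_notpass`,
#' `n_nocall`).
#'
#' @slot blocks list of block records in file order.
#' @seealso [readCollinearity()], [scoreBlocks()], [refineBlocks()]
#' @exportClass CollinearitySet
setClass("CollinearitySet", representation(blocks = "list"))

setValidity("CollinearitySet", function(object) {
  for (b in object@blocks) {
    need <- c("id", "chrom_a", "chrom_b", "orientation", "intra", "pairs")
    if (!all(need %in% names(b)))
      return(paste("block missing fields:", paste(setdiff(need, names(b)), collapse = ", ")))
    if (!all(c("gene_a", "gene_b", "evalue") %in% names(b$pairs)))
      return(sprintf("block %s: pairs must have gene_a, gene_b, evalue", b$id))
    if (!is.null(b$scores)) {
      if (length(b$scores) != nrow(b$pairs))
        return(sprintf("block %s: scores length != number of pairs", b$id))
      if (!all(b$scores %in% c("P", "N", "C")))
        return(sprintf("block %s: scores must be P/N/C", b$id))
    }
  }
  ids <- vapply(object@blocks, `[[`, character(1L), "id")
  if (anyDuplicated(ids)) return("block ids must be unique")
  TRUE
})

#' TetherSets: ploidy-filtered orthogroups used as orthology anchors
#'
#' A tether set is an orthogroup in which at least two species have a
#' nonzero gene-set (tandem-array) count no greater than their relative
#' ploidy; species exceeding their ploidy are excluded (their genes drop
#' out of the tether but are kept in metadata for reporting).
#'
#' @slot tethers named list: tether id -> named list (species -> genes).
#' @slot index named character: gene -> id of the tether containing it.
#' @slot excluded named list: tether id -> character vector of excluded
#'   species.
#' @slot report data.frame with one row per source orthogroup and species:
#'   gene count, gene-set count, included flag.
#' @seealso [buildTethers()]
#' @exportClass TetherSets
setClass("TetherSets",
         representation(tethers = "list", index = "character",
                        excluded = "list", report = "data.frame"))

setValidity("TetherSets", function(object) {
  if (length(object@tethers) &&
      !all(object@index %in% names(object@tethers)))
    return("index points at unknown tether ids")
  TRUE
})

#' SyntenyOrthogroups: final syntenic orthogroups
#'
#' Connected components of the synteny graph (block-pair edges plus tandem
#' edges), each with at least two genes.  Groups partition their genes and
#' are numbered deterministically by their lexicographically smallest
#' member.
#'
#' @slot groups named list: group id -> named list (species -> canonical
#'   gene names).
#' @slot species character vector of all species in the analysis.
#' @slot geneCounts integer matrix, groups x species: genes per species.
#' @slot setCounts integer matrix, groups x species: tandem gene sets per
#'   species.
#' @slot tallies list of global summary counts (total, singleton, tether,
#'   species-specific groups).
#' @seealso [assembleOrthogroups()], [summarizeGroups()]
#' @exportClass SyntenyOrthogroups
setClass("SyntenyOrthogroups",
         representation(groups = "list", species = "character",
                        geneCounts = "matrix", setCounts = "matrix",
                        tallies = "list"))

setValidity("SyntenyOrthogroups", function(object) {
  genes <- unlist(object@groups, use.names = FALSE)
  if (anyDuplicated(genes)) return("groups must partition their genes")
  sizes <- vapply(object@groups, function(g) length(unlist(g, use.names = FALSE)),
                  integer(1L))
  if (length(sizes) && any(sizes < 2L))
    return("every group must contain at least two genes")
  TRUE
})
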