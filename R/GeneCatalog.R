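#' Build a GeneCatalog from per-gene records
#'
#' Rows are sorted and gene order within each chromosome (`ord`) is
#' assigned as ascending start, ties broken by end then canonical name.
#'
#' @param species character, species label per gene.
#' @param chrom character, chromosome/scaffold label per gene.
#' @param start,end integer, 1-based inclusive coordinates.
#' @param original character, annotation gene IDs (unique).
#' @param canonical character, translated names `<speciesIndex>_<geneIndex>`.
#' @return a [GeneCatalog-class] object.
#' @examples
#' GeneCatalog(species = c("A", "A"), chrom = c("c1", "c1"),
#'             start = c(1L, 100L), end = c(50L, 150L),
#'             original = c("gA1", "gA2"), canonical = c("0_0", "0_1"))
#' @export
GeneCatalog <- function(species, chrom, start, end, original, canonical) {
  g <- data.frame(species = as.character(species), chrom = as.character(chrom),
                  start = as.integer(start), end = as.integer(end),
                  original = as.character(original),
                  canonical = as.character(canonical),
                  stringsAsFactors = FALSE)
  g <- g[order(g$species, g$chrom, g$start, g$end, g$canonical), , drop = FALSE]
  key <- paste(g$species, g$chrom, sep = "\r")
  g$ord <- as.integer(stats::ave(seq_len(nrow(g)), key, FUN = seq_along))
  rownames(g) <- NULL
  new("GeneCatalog", genes = g)
}

#' @describeIn GeneCatalog number of genes
#' @param x a GeneCatalog
#' @export
setMethod("nGenes", "GeneCatalog", function(x) nrow(x@genes))

#' @describeIn GeneCatalog species labels, sorted
#' @export
setMethod("speciesNames", "GeneCatalog",
          function(x) sort(unique(x@genes$species)))

#' @describeIn GeneCatalog named vector canonical name -> species
#' @export
setMethod("geneSpecies", "GeneCatalog",
          function(x) setNames(x@genes$species, x@genes$canonical))

#' @describeIn GeneCatalog the underlying gene data.frame
#' @export
setMethod("geneTable", "GeneCatalog", function(x) x@genes)

setMethod("show", "GeneCatalog", function(object) {
  g <- object@genes
  cat("GeneCatalog with", nrow(g), "genes |",
      length(unique(g$species)), "species |",
      length(unique(paste(g$species, g$chrom))), "chromosomes\n")
  for (sp in sort(unique(g$species)))
    cat("  ", sp, ": ", sum(g$species == sp), " genes\n", sep = "")
})

#' Read an MCScanX-dialect gene position file into a GeneCatalog
#'
#' The dialect has one line per gene: `chrom<TAB>gene<TAB>start<TAB>end`,
#' with genes named canonically (`<speciesIndex>_<geneIndex>`).  Species
#' labels are resolved from `species_ids`; original annotation names from
#' `translation` when supplied (otherwise the canonical name is reused).
#'
#' @param path gene position file.
#' @param species_ids named character vector, species index -> label (as
#'   from [readSpeciesIds()]); when `NULL`, labels default to `sp<index>`.
#' @param translation named character vector canonical -> original name.
#' @return a [GeneCatalog-class].
#' @export
readGenePositions <- function(path, species_ids = NULL, translation = NULL) {
  if (!file.exists(path)) stop("gene position file not found: ", path)
  g <- read.table(path, sep = "\t", header = FALSE, comment.char = "",
                  quote = "", colClasses = c("character", "character",
                                             "integer", "integer"))
  names(g) <- c("chrom", "canonical", "start", "end")
  idx <- sub("_.*$", "", g$canonical)
  if (is.null(species_ids)) {
    sp <- paste0("sp", idx)
  } else {
    if (!all(idx %in% names(species_ids)))
      stop("species index not in species_ids: ",
           paste(unique(idx[!idx %in% names(species_ids)]), collapse = ", "))
    sp <- unname(species_ids[idx])
  }
  orig <- if (is.null(translation)) g$canonical else {
    miss <- setdiff(g$canonical, names(translation))
    if (length(miss)) stop("no translation for: ", paste(head(miss, 3L), collapse = ", "))
    unname(translation[g$canonical])
  }
  GeneCatalog(sp, g$chrom, g$start, g$end, orig, g$canonical)
}

#' Write a GeneCatalog as an MCScanX-dialect gene position file
#'
#' Emits `chrom<TAB>canonical<TAB>start<TAB>end`, sorted by chromosome then
#' start (ties: end, then name).
#'
#' @param x a [GeneCatalog-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenePositions <- function(x, path) {
  g <- geneTable(x)
  g <- g[order(g$chrom, g$start, g$end, g$canonical), , drop = FALSE]
  writeLines(paste(g$chrom, g$canonical, g$start, g$end, sep = "\t"), path)
  invisible(path)
}

#' Read an OrthoFinder-style SpeciesIDs file
#'
#' Lines of the form `0: speciesA.fa`; a single trailing FASTA extension is
#' stripped from the label.
#'
#' @param path SpeciesIDs file.
#' @return named character vector, species index -> species label.
#' @export
readSpeciesIds <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  m <- regmatches(ln, regexec("^([0-9]+): (.+)$", ln))
  bad <- vapply(m, length, integer(1L)) != 3L
  if (any(bad)) stop("malformed SpeciesIDs line: ", ln[which(bad)[1L]])
  lab <- vapply(m, `[`, character(1L), 3L)
  lab <- sub("\\.(fa|fasta|faa|pep)$", "", lab)
  setNames(lab, vapply(m, `[`, character(1L), 2L))
}

#' Write a SpeciesIDs file
#' @param species_ids named character vector, index -> label.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSpeciesIds <- function(species_ids, path) {
  o <- order(as.integer(names(species_ids)))
  writeLines(paste0(names(species_ids)[o], ": ", species_ids[o]), path)
  invisible(path)
}

#' Read an OrthoFinder-style SequenceIDs file
#'
#' Lines of the form `0_12: originalGeneName`.
#'
#' @param path SequenceIDs file.
#' @return named character vector, canonical name -> original name.
#' @export
readSequenceIds <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  m <- regmatches(ln, regexec("^([0-9]+_[0-9]+): (.+)$", ln))
  bad <- vapply(m, length, integer(1L)) != 3L
  if (any(bad)) stop("malformed SequenceIDs line: ", ln[which(bad)[1L]])
  setNames(vapply(m, `[`, character(1L), 3L),
           vapply(m, `[`, character(1L), 2L))
}

#' Write a SequenceIDs file
#' @param sequence_ids named character vector, canonical -> original.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSequenceIds <- function(sequence_ids, path) {
  key <- do.call(rbind, strsplit(names(sequence_ids), "_", fixed = TRUE))
  o <- order(as.integer(key[, 1L]), as.integer(key[, 2L]))
  writeLines(paste0(names(sequence_ids)[o], ": ", sequence_ids[o]), path)
  invisible(path)
}
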