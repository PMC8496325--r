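#' Translate GFF3 + protein FASTA inputs to canonical gene names
#'
#' Converts one genome per GFF3/FASTA pair into the compact naming used by
#' the rest of the pipeline: gene `j` of species `i` becomes `i_j`.
#' Species indices follow the order of `gff_paths`; gene indices restart at
#' 0 for each species and follow chromosomal order (chromosome, then start,
#' ties by end then ID).  Emits an MCScanX-dialect gene position file
#' covering all genomes, one renamed protein FASTA per genome, a
#' tab-separated translation table, and SpeciesIDs/SequenceIDs files, so
#' every downstream result can be mapped back to original annotation IDs.
#'
#' Only `gene` features are used; a gene with multiple mRNAs is represented
#' by the gene feature's span (primary-isoform convention).  FASTA records
#' whose header matches no GFF gene ID are excluded with a warning; a
#' duplicated gene ID within a GFF is fatal.
#'
#' @param gff_paths character vector of GFF3 files, one per genome.
#' @param fasta_paths character vector of protein FASTA files, parallel to
#'   `gff_paths`; may be `NULL` to translate annotations only.
#' @param out_dir output directory (created if needed).
#' @param species_labels character vector of species labels; defaults to
#'   the GFF file names without extension.
#' @return (invisibly) a list with `catalog` (a [GeneCatalog-class]),
#'   `species_ids`, `sequence_ids`, and the emitted file `paths`.
#' @export
translateGff <- function(gff_paths, fasta_paths = NULL, out_dir = ".",
                         species_labels = NULL) {
  stopifnot(length(gff_paths) >= 1L)
  if (!is.null(fasta_paths) && length(fasta_paths) != length(gff_paths))
    stop("fasta_paths must be parallel to gff_paths")
  if (is.null(species_labels))
    species_labels <- sub("\\.[^.]*$", "", basename(gff_paths))
  if (anyDuplicated(species_labels)) stop("species labels must be unique")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  per_sp <- vector("list", length(gff_paths))
  fasta_out <- character(0L)
  for (i in seq_along(gff_paths)) {
    sp_idx <- i - 1L
    gr <- rtracklayer::import(gff_paths[i], format = "gff3")
    gr <- gr[!is.na(mcols(gr)$type) & as.character(mcols(gr)$type) == "gene"]
    if (length(gr) == 0L) stop("no gene features in ", gff_paths[i])
    ids <- as.character(mcols(gr)$ID)
    if (anyDuplicated(ids))
      stop("duplicate gene ID in ", gff_paths[i], ": ",
           ids[duplicated(ids)][1L])
    d <- data.frame(chrom = as.character(seqnames(gr)),
                    start = start(gr), end = end(gr),
                    original = ids, stringsAsFactors = FALSE)
    d <- d[order(d$chrom, d$start, d$end, d$original), , drop = FALSE]
    d$canonical <- paste0(sp_idx, "_", seq_len(nrow(d)) - 1L)
    d$species <- species_labels[i]
    per_sp[[i]] <- d

    if (!is.null(fasta_paths)) {
      aa <- Biostrings::readAAStringSet(fasta_paths[i])
      hdr <- sub("\\s.*$", "", names(aa))
      known <- hdr %in% d$original
      if (any(!known))
        warning(sum(!known), " FASTA record(s) in ", fasta_paths[i],
                " match no GFF gene and were excluded")
      aa <- aa[known]
      names(aa) <- setNames(d$canonical, d$original)[hdr[known]]
      fa_path <- file.path(out_dir, paste0(species_labels[i], ".translated.fa"))
      Biostrings::writeXStringSet(aa, fa_path)
      fasta_out <- c(fasta_out, fa_path)
    }
  }

  all_d <- do.call(rbind, per_sp)
  catalog <- GeneCatalog(all_d$species, all_d$chrom, all_d$start, all_d$end,
                         all_d$original, all_d$canonical)
  species_ids <- setNames(species_labels, as.character(seq_along(species_labels) - 1L))
  sequence_ids <- setNames(all_d$original, all_d$canonical)

  gff_out <- file.path(out_dir, "translated_positions.gff")
  writeGenePositions(catalog, gff_out)
  tab_out <- file.path(out_dir, "translation_table.tsv")
  writeTranslationTable(catalog, tab_out)
  sp_out <- file.path(out_dir, "SpeciesIDs.txt")
  writeSpeciesIds(species_ids, sp_out)
  seq_out <- file.path(out_dir, "SequenceIDs.txt")
  writeSequenceIds(sequence_ids, seq_out)

  invisible(list(catalog = catalog, species_ids = species_ids,
                 sequence_ids = sequence_ids,
                 paths = list(positions = gff_out, fasta = fasta_out,
                              table = tab_out, species_ids = sp_out,
                              sequence_ids = seq_out)))
}

#' Write the original/canonical name translation table
#'
#' Tab-separated with header: `original`, `canonical`, `species`.
#'
#' @param x a [GeneCatalog-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTranslationTable <- function(x, path) {
  g <- geneTable(x)
  g <- g[order(g$canonical), c("original", "canonical", "species")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("original\tcanonical\tspecies", con)
  writeLines(paste(g$original, g$canonical, g$species, sep = "\t"), con)
  invisible(path)
}

#' Read a translation table written by [writeTranslationTable()]
#' @param path translation table file.
#' @return named character vector, canonical -> original.
#' @export
readTranslationTable <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, quote = "",
                  comment.char = "", colClasses = "character")
  setNames(d$original, d$canonical)
}
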