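#' Read an MCScanX .tandem file
#'
#' Each line holds comma-separated gene names; a line of `n` genes yields
#' the `n - 1` consecutive pairs (MCScanX itself writes one pair per
#' line).  Self-pairs and pairs spanning two species are fatal: a tandem
#' duplicate is by definition a same-species neighbour of its paralog.
#'
#' @param path .tandem file.
#' @param species_of optional named character vector (gene -> species)
#'   used for the cross-species check; when `NULL` and names are
#'   canonical, the species index prefix is used instead.
#' @return data.frame with columns `gene_a`, `gene_b`, one row per pair.
#' @export
readTandem <- function(path, species_of = NULL) {
  if (!file.exists(path)) stop("tandem file not found: ", path)
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  ga <- character(0L); gb <- character(0L)
  for (i in seq_along(ln)) {
    g <- trimws(strsplit(ln[i], ",", fixed = TRUE)[[1L]])
    g <- g[nzchar(g)]
    if (length(g) < 2L)
      stop("tandem line ", i, " needs at least two genes: ", ln[i])
    ga <- c(ga, g[-length(g)])
    gb <- c(gb, g[-1L])
  }
  if (any(ga == gb))
    stop("self-pair in tandem file: ", ga[ga == gb][1L])
  spof <- function(g) {
    if (!is.null(species_of)) {
      if (!all(g %in% names(species_of)))
        stop("tandem gene not in catalog: ",
             g[!g %in% names(species_of)][1L])
      unname(species_of[g])
    } else if (all(grepl("^[0-9]+_[0-9]+$", g))) {
      sub("_.*$", "", g)
    } else {
      rep(NA_character_, length(g))
    }
  }
  sa <- spof(ga); sb <- spof(gb)
  bad <- !is.na(sa) & !is.na(sb) & sa != sb
  if (any(bad))
    stop("tandem pair spans two species: ", ga[bad][1L], ",", gb[bad][1L])
  data.frame(gene_a = ga, gene_b = gb, stringsAsFactors = FALSE)
}

#' Write tandem pairs in the MCScanX .tandem dialect (one pair per line)
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTandem <- function(pairs, path) {
  writeLines(paste(pairs$gene_a, pairs$gene_b, sep = ","), path)
  invisible(path)
}

#' Read a relative-ploidy file
#'
#' Two tab-separated columns, species label and its positive integer
#' relative ploidy multiplier (2 for a tetraploid among diploids).  Every
#' species absent from the file defaults to 1; a missing file is
#' equivalent to ploidy 1 everywhere.
#'
#' @param path ploidy file, or `NULL`/missing file for all-1.
#' @param species character vector of all species in the analysis.
#' @return named integer vector, species -> ploidy (>= 1).
#' @export
readPloidy <- function(path = NULL, species) {
  pl <- setNames(rep(1L, length(species)), species)
  if (is.null(path)) return(pl)
  if (!file.exists(path)) stop("ploidy file not found: ", path)
  d <- read.table(path, sep = "\t", header = FALSE, quote = "",
                  comment.char = "#",
                  colClasses = c("character", "integer"))
  names(d) <- c("species", "ploidy")
  if (any(d$ploidy < 1L)) stop("ploidy values must be >= 1")
  unknown <- setdiff(d$species, species)
  if (length(unknown))
    stop("ploidy file names unknown species: ", paste(unknown, collapse = ", "))
  pl[d$species] <- d$ploidy
  pl
}

#' Write a relative-ploidy file
#' @param ploidy named integer vector, species -> ploidy.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePloidy <- function(ploidy, path) {
  writeLines(paste(names(ploidy), ploidy, sep = "\t"), path)
  invisible(path)
}
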