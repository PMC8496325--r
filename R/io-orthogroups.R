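#' Read an OrthoFinder-dialect orthogroups table
#'
#' Tab-separated with a header row: first column the orthogroup id, one
#' column per species, cells holding comma-separated gene lists (empty
#' cells mean no genes for that species).  Gene names are normalised to
#' canonical form through `translation` when supplied.
#'
#' @param path Orthogroups.tsv-style file.
#' @param translation named character vector, original name -> canonical
#'   name; `NULL` if the file already uses canonical names.
#' @param species optional character vector of known species labels; a
#'   header column outside this set is a fatal error.
#' @return an [OrthogroupSet-class].
#' @export
readOrthogroups <- function(path, translation = NULL, species = NULL) {
  if (!file.exists(path)) stop("orthogroups file not found: ", path)
  d <- read.table(path, sep = "\t", header = TRUE, quote = "",
                  comment.char = "", colClasses = "character",
                  check.names = FALSE)
  if (ncol(d) < 2L) stop("orthogroups file needs an id column and >=1 species column")
  sp_cols <- names(d)[-1L]
  if (!is.null(species)) {
    unknown <- setdiff(sp_cols, species)
    if (length(unknown))
      stop("unknown species column in ", path, ": ",
           paste(unknown, collapse = ", "))
  }
  membership <- lapply(seq_len(nrow(d)), function(r) {
    m <- lapply(sp_cols, function(sc) {
      cell <- d[[sc]][r]
      if (is.na(cell) || !nzchar(trimws(cell))) return(character(0L))
      g <- trimws(strsplit(cell, ",", fixed = TRUE)[[1L]])
      g <- g[nzchar(g)]
      if (!is.null(translation)) {
        miss <- setdiff(g, names(translation))
        if (length(miss))
          stop("orthogroup ", d[[1L]][r], ": no translation for gene(s) ",
               paste(head(miss, 3L), collapse = ", "))
        g <- unname(translation[g])
      }
      g
    })
    names(m) <- sp_cols
    m
  })
  new("OrthogroupSet", ids = d[[1L]], membership = membership)
}

#' Write an OrthogroupSet in the OrthoFinder dialect
#'
#' @param x an [OrthogroupSet-class] (or a [SyntenyOrthogroups-class]).
#' @param path output file.
#' @param id_col name of the id column in the header.
#' @return `path`, invisibly.
#' @export
writeOrthogroups <- function(x, path, id_col = "Orthogroup") {
  if (is(x, "SyntenyOrthogroups"))
    x <- new("OrthogroupSet", ids = names(x@groups), membership = unname(x@groups))
  sp <- speciesNames(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_col, sp), collapse = "\t"), con)
  rows <- vapply(seq_along(x@ids), function(r) {
    cells <- vapply(sp, function(s)
      paste(x@membership[[r]][[s]] %||% character(0L), collapse = ", "),
      character(1L))
    paste(c(x@ids[r], cells), collapse = "\t")
  }, character(1L))
  writeLines(rows, con)
  invisible(path)
}

#' @describeIn readOrthogroups number of orthogroups in the set
#' @param x an OrthogroupSet
#' @export
setMethod("nGenes", "OrthogroupSet",
          function(x) length(unlist(x@membership, use.names = FALSE)))

#' @describeIn readOrthogroups species columns of the table
#' @export
setMethod("speciesNames", "OrthogroupSet", function(x) {
  if (!length(x@membership)) return(character(0L))
  sort(unique(unlist(lapply(x@membership, names), use.names = FALSE)))
})

#' @describeIn readOrthogroups group membership as a named list
#' @export
setMethod("groupList", "OrthogroupSet",
          function(x) setNames(x@membership, x@ids))

setMethod("show", "OrthogroupSet", function(object) {
  cat("OrthogroupSet with", length(object@ids), "orthogroups,",
      nGenes(object), "genes,",
      length(speciesNames(object)), "species\n")
})

#' Length of an OrthogroupSet (number of groups)
#' @param x an [OrthogroupSet-class]
#' @export
setMethod("length", "OrthogroupSet", function(x) length(x@ids))
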