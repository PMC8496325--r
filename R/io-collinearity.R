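#' Read an MCScanX .collinearity file
#'
#' The dialect: `#`-prefixed comment header, then per block a
#' `## Alignment <id>: score=<s> e_value=<e> N=<n> <chromA>&<chromB> <plus|minus>`
#' line followed by one tab-separated gene-pair line per aligned pair
#' (`<index>:<TAB>geneA<TAB>geneB<TAB>e-value`).  Blocks whose two
#' chromosome/region tokens are identical are flagged intra-genome.
#' E-values are parsed as non-negative reals and kept (with their original
#' text, for exact round-tripping) but are not used by the scoring
#' algorithm.
#'
#' @param path .collinearity file.
#' @return a [CollinearitySet-class]; blocks in file order, pair order
#'   preserved.  Blocks with zero pairs are skipped with a warning.
#' @export
readCollinearity <- function(path) {
  if (!file.exists(path)) stop("collinearity file not found: ", path)
  ln <- readLines(path)
  hdr_pat <- "^## Alignment ([^:]+): score=(\\S+) e_value=(\\S+) N=(\\S+) (\\S+)&(\\S+) (plus|minus)\\s*$"
  blocks <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(invisible(NULL))
    if (length(cur$ga) == 0L) {
      warning("block ", cur$id, " has no gene pairs; skipped")
      return(invisible(NULL))
    }
    blocks[[length(blocks) + 1L]] <<- list(
      id = cur$id, chrom_a = cur$chrom_a, chrom_b = cur$chrom_b,
      orientation = cur$orientation, intra = cur$chrom_a == cur$chrom_b,
      score = cur$score, e_value = cur$e_value,
      pairs = data.frame(gene_a = cur$ga, gene_b = cur$gb,
                         evalue = cur$ev, e_str = cur$es,
                         stringsAsFactors = FALSE))
    invisible(NULL)
  }
  for (i in seq_along(ln)) {
    l <- ln[i]
    if (startsWith(l, "## Alignment")) {
      flush(cur)
      m <- regmatches(l, regexec(hdr_pat, l))[[1L]]
      if (length(m) != 8L)
        stop("malformed block header at line ", i, ": ", l)
      cur <- list(id = m[2L], score = m[3L], e_value = m[4L],
                  n_declared = m[5L], chrom_a = m[6L], chrom_b = m[7L],
                  orientation = m[8L],
                  ga = character(0L), gb = character(0L),
                  ev = numeric(0L), es = character(0L))
    } else if (startsWith(l, "#") || !nzchar(trimws(l))) {
      next
    } else {
      if (is.null(cur))
        stop("gene pair line before any block header at line ", i)
      parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
      if (length(parts) < 4L)
        stop("malformed gene pair line (need index, two genes, e-value) at line ",
             i, ": ", l)
      es <- trimws(parts[4L])
      ev <- suppressWarnings(as.numeric(es))
      if (is.na(ev) || ev < 0)
        stop("malformed e-value at line ", i, ": ", l)
      cur$ga <- c(cur$ga, trimws(parts[2L]))
      cur$gb <- c(cur$gb, trimws(parts[3L]))
      cur$ev <- c(cur$ev, ev)
      cur$es <- c(cur$es, es)
    }
  }
  flush(cur)
  new("CollinearitySet", blocks = blocks)
}

#' Write a CollinearitySet as an MCScanX-dialect .collinearity file
#'
#' Reading the emitted file with [readCollinearity()] reproduces the
#' object; re-writing what was read reproduces the bytes.
#'
#' @param x a [CollinearitySet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCollinearity <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("############### Parameters ###############",
               "# MATCH_SIZE: 5",
               "############### Statistics ###############",
               paste0("# Number of collinear blocks: ", length(x@blocks))),
             con)
  for (b in x@blocks) {
    writeLines(sprintf("## Alignment %s: score=%s e_value=%s N=%d %s&%s %s",
                       b$id, b$score %||% "0", b$e_value %||% "0",
                       nrow(b$pairs), b$chrom_a, b$chrom_b, b$orientation),
               con)
    es <- if ("e_str" %in% names(b$pairs)) b$pairs$e_str else
      format(b$pairs$evalue)
    writeLines(sprintf(" %s-%3d:\t%s\t%s\t%s", b$id,
                       seq_len(nrow(b$pairs)) - 1L,
                       b$pairs$gene_a, b$pairs$gene_b, es),
               con)
  }
  invisible(path)
}

#' @describeIn readCollinearity blocks of a CollinearitySet
#' @param x a CollinearitySet
#' @export
setMethod("blocks", "CollinearitySet", function(x) x@blocks)

#' Number of blocks in a CollinearitySet
#' @param x a [CollinearitySet-class]
#' @export
setMethod("length", "CollinearitySet", function(x) length(x@blocks))

setMethod("show", "CollinearitySet", function(object) {
  np <- vapply(object@blocks, function(b) nrow(b$pairs), integer(1L))
  scored <- sum(vapply(object@blocks, function(b) !is.null(b$scores), logical(1L)))
  cat("CollinearitySet with", length(object@blocks), "blocks,",
      sum(np), "gene pairs",
      if (scored) paste0("(", scored, " scored)") else "", "\n")
})
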