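# Block trimming: end rule (B), sliding-window rule (C), internal-split
# rule (D), applied with the block-level filter until a fixed point.
# Scores: "P" Pass, "N" Not Pass, "C" No Call.  No Call pairs are never
# counted in any threshold and are only removed inside a removed range.

# Rule B bounds: from each end, remove every pair through the innermost
# Not Pass that has no Pass more distal than it; returns c(lo, hi) of the
# retained range (lo > hi when nothing survives).
.trim_ends_idx <- function(sc) {
  n <- length(sc)
  p <- which(sc == "P")
  firstP <- if (length(p)) p[1L] else n + 1L
  lastP <- if (length(p)) p[length(p)] else 0L
  lo <- 1L; hi <- n
  nl <- which(sc == "N" & seq_len(n) < firstP)
  if (length(nl)) lo <- max(nl) + 1L
  nr <- which(sc == "N" & seq_len(n) > lastP)
  if (length(nr)) hi <- min(nr) - 1L
  c(lo, hi)
}

.apply_rule_b <- function(sc, idx) {
  if (!length(sc)) return(list(sc = sc, idx = idx))
  r <- .trim_ends_idx(sc)
  if (r[1L] > r[2L]) return(list(sc = character(0L), idx = integer(0L)))
  list(sc = sc[r[1L]:r[2L]], idx = idx[r[1L]:r[2L]])
}

# Rule C at the left end: look at the first six scored (P/N) pairs; once
# they hold >= 3 N, remove the endmost pair, re-apply rule B and
# recompute, repeating until P strictly outnumbers N in the window.
.apply_rule_c_left <- function(sc, idx) {
  triggered <- FALSE
  repeat {
    if (!length(sc)) break
    w <- head(sc[sc != "C"], 6L)
    np <- sum(w == "P"); nn <- sum(w == "N")
    if (np > nn) break
    if (!triggered && nn < 3L) break
    triggered <- TRUE
    sc <- sc[-1L]; idx <- idx[-1L]
    tmp <- .apply_rule_b(sc, idx)
    sc <- tmp$sc; idx <- tmp$idx
  }
  list(sc = sc, idx = idx)
}

.apply_rule_c <- function(sc, idx) {
  tmp <- .apply_rule_c_left(sc, idx)
  tmp <- .apply_rule_c_left(rev(tmp$sc), rev(tmp$idx))
  list(sc = rev(tmp$sc), idx = rev(tmp$idx))
}

# Leftmost internal run of >= 3 N with no intervening P (No Calls do not
# break the run); returns c(from, to) in current coordinates, or NULL.
.find_split_run <- function(sc) {
  scored <- which(sc != "C")
  if (!length(scored)) return(NULL)
  r <- rle(sc[scored])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- which(r$values == "N" & r$lengths >= 3L)
  if (!length(k)) return(NULL)
  k <- k[1L]
  c(scored[starts[k]], scored[ends[k]])
}

.subset_block <- function(b, idx, id = b$id) {
  b$id <- id
  b$pairs <- b$pairs[idx, , drop = FALSE]
  rownames(b$pairs) <- NULL
  b$scores <- b$scores[idx]
  b$counts <- .count_scores(b$scores)
  b
}

.ranges_str <- function(removed) {
  if (!length(removed)) return("")
  d <- split(removed, cumsum(c(1L, diff(removed) != 1L)))
  paste(vapply(d, function(r)
    if (length(r) == 1L) as.character(r) else paste0(r[1L], "-", r[length(r)]),
    character(1L)), collapse = ";")
}

#' Trim Not Pass pairs from block ends (rule B)
#'
#' From each end independently: if the endmost scored pair is Not Pass,
#' or no Pass lies between a Not Pass and that end, every pair through
#' that Not Pass is removed.  An end whose outermost scored pair is Pass
#' (No Calls beyond it are harmless) is untouched.
#'
#' @param block a scored block record.
#' @return the trimmed block (possibly with zero pairs).
#' @export
trimEnds <- function(block) {
  if (is.null(block$scores)) stop("block is not scored")
  tmp <- .apply_rule_b(block$scores, seq_along(block$scores))
  .subset_block(block, tmp$idx)
}

#' Trim block ends by the six-pair window rule (rule C)
#'
#' At each end, the window of the first six scored (Pass/Not Pass) pairs
#' is inspected; if it holds three or more Not Pass, the endmost pair is
#' removed, rule B is re-applied, and the window recomputed, until Pass
#' strictly outnumbers Not Pass in the window (or the block is
#' exhausted).
#'
#' @param block a scored, end-trimmed block record.
#' @return the trimmed block.
#' @export
trimWindow <- function(block) {
  if (is.null(block$scores)) stop("block is not scored")
  tmp <- .apply_rule_c(block$scores, seq_along(block$scores))
  .subset_block(block, tmp$idx)
}

#' Split a block at an internal Not Pass run (rule D)
#'
#' At the leftmost internal run of three or more Not Pass scores with no
#' intervening Pass (No Calls do not break the run), the block is split
#' into the segment before the run and the segment after it; the run's
#' pairs are dropped.  Callers re-trim both children.
#'
#' @param block a scored block record.
#' @return a list of one block (unchanged) or two child blocks (ids
#'   suffixed `.1`, `.2`).
#' @export
splitInternal <- function(block) {
  if (is.null(block$scores)) stop("block is not scored")
  run <- .find_split_run(block$scores)
  if (is.null(run)) return(list(block))
  n <- length(block$scores)
  left <- seq_len(run[1L] - 1L)
  right <- if (run[2L] < n) (run[2L] + 1L):n else integer(0L)
  list(.subset_block(block, left, paste0(block$id, ".1")),
       .subset_block(block, right, paste0(block$id, ".2")))
}

#' Refine scored blocks to the fixed point of all trimming rules
#'
#' Each block is end-trimmed (rule B), window-trimmed (rule C), and split
#' at internal Not Pass runs (rule D, children re-entering at B), until
#' no rule applies; a resulting block is kept only if it still has at
#' least two Pass pairs, no more Not Pass than Pass pairs, and at least
#' `min_pairs` gene pairs.  The result is idempotent: refining the
#' survivors again changes nothing.
#'
#' @param x a scored [CollinearitySet-class] (normally pre-filtered with
#'   [blockPasses()]).
#' @param min_pairs minimum surviving block size in gene pairs (default
#'   5).
#' @return list with `blocks` (surviving [CollinearitySet-class]) and
#'   `log`, a data.frame of trim actions: block id, action (KEEP /
#'   TRIM_END / SPLIT / DISCARD), removed pair ranges (in the block's own
#'   coordinates), resulting child ids.
#' @export
refineBlocks <- function(x, min_pairs = 5L) {
  stopifnot(is(x, "CollinearitySet"))
  queue <- x@blocks
  out <- list()
  log <- list()
  addlog <- function(id, action, removed, children) {
    log[[length(log) + 1L]] <<- data.frame(
      block_id = id, action = action, removed_pairs = removed,
      children = children, stringsAsFactors = FALSE)
  }
  while (length(queue)) {
    b <- queue[[1L]]
    queue <- queue[-1L]
    if (is.null(b$scores)) stop("block ", b$id, " is not scored")
    sc <- b$scores
    idx <- seq_along(sc)
    repeat {
      len <- length(idx)
      tmp <- .apply_rule_b(sc, idx); sc <- tmp$sc; idx <- tmp$idx
      tmp <- .apply_rule_c(sc, idx); sc <- tmp$sc; idx <- tmp$idx
      if (length(idx) == len) break
    }
    removed <- .ranges_str(setdiff(seq_along(b$scores), idx))
    run <- .find_split_run(sc)
    if (!is.null(run)) {
      n <- length(idx)
      left <- idx[seq_len(run[1L] - 1L)]
      right <- if (run[2L] < n) idx[(run[2L] + 1L):n] else integer(0L)
      kids <- character(0L)
      for (side in list(c("1", "l"), c("2", "r"))) {
        cid <- paste0(b$id, ".", side[1L])
        ki <- if (side[2L] == "l") left else right
        if (length(ki)) {
          queue[[length(queue) + 1L]] <- .subset_block(b, ki, cid)
          kids <- c(kids, cid)
        }
      }
      dropped <- .ranges_str(c(setdiff(seq_along(b$scores), idx),
                               idx[run[1L]:run[2L]]))
      addlog(b$id, "SPLIT", dropped, paste(kids, collapse = ","))
      next
    }
    cn <- .count_scores(sc)
    keep <- length(idx) >= min_pairs && cn["n_pass"] >= 2L &&
      cn["n_notpass"] <= cn["n_pass"]
    if (keep) {
      out[[length(out) + 1L]] <- .subset_block(b, idx)
      addlog(b$id, if (nzchar(removed)) "TRIM_END" else "KEEP", removed, "")
    } else {
      addlog(b$id, "DISCARD", removed, "")
    }
  }
  list(blocks = new("CollinearitySet", blocks = out),
       log = do.call(rbind, log) %||%
         data.frame(block_id = character(0L), action = character(0L),
                    removed_pairs = character(0L), children = character(0L)))
}

#' Write the trim-action log
#' @param log data.frame from [refineBlocks()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTrimLog <- function(log, path) {
  write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
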