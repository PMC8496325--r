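#' Configuration for the multi-genome simulator
#'
#' The simulated system mirrors a cotton-like design: three diploids (two
#' polyploid progenitors `genA`, `genD` and an outgroup `genO`) plus one
#' allotetraploid `polyP` whose two subgenomes descend from the `genA`
#' and `genD` lineages.  An ancestral genome of
#' `n_chromosomes * genes_per_chromosome` genes evolves along each of the
#' five genome units (A, D, O, At, Dt) by per-gene loss, adjacent tandem
#' duplication, segmental inversion and translocation; the simulator then
#' emits exactly the file dialects the pipeline consumes, with planted
#' ground truth.
#'
#' @param n_chromosomes number of chromosomes (default 5).
#' @param genes_per_chromosome ancestral genes per chromosome (default
#'   100).
#' @param tandem_rate per-gene probability of an adjacent tandem
#'   duplicate in each genome unit (default 0.05).
#' @param loss_rate per-gene, per-unit probability of gene loss (default
#'   0.05).
#' @param inversions segmental inversions per genome unit (default 2;
#'   segment length 5-25 genes).
#' @param translocations segment translocations per genome unit (default
#'   1; 5-15 genes moved to another chromosome).
#' @param og_noise probability that a planted orthogroup is corrupted in
#'   the simulated similarity-orthogroup file, by merging with its
#'   neighbour or dropping one gene (default 0).
#' @param min_block_pairs smallest emitted collinearity block, in gene
#'   pairs (default 5, the usual collinearity-caller match size).
#' @param seed RNG seed; the seed fully determines every emitted byte.
#' @return a `simConfig` list.
#' @export
simConfig <- function(n_chromosomes = 5L, genes_per_chromosome = 100L,
                      tandem_rate = 0.05, loss_rate = 0.05,
                      inversions = 2L, translocations = 1L,
                      og_noise = 0, min_block_pairs = 5L, seed = 1L) {
  rates <- c(tandem_rate, loss_rate, og_noise)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  if (n_chromosomes < 1L || genes_per_chromosome < 1L)
    stop("need at least one chromosome and one gene")
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 genes_per_chromosome = as.integer(genes_per_chromosome),
                 tandem_rate = tandem_rate, loss_rate = loss_rate,
                 inversions = as.integer(inversions),
                 translocations = as.integer(translocations),
                 og_noise = og_noise,
                 min_block_pairs = as.integer(min_block_pairs),
                 seed = as.integer(seed)),
            class = "simConfig")
}

# genome units and their chromosome-label tags
.sim_units <- c(A = "gA", D = "gD", O = "gO", At = "pA", Dt = "pD")

.sim_species_of_unit <- function(mode) {
  if (mode == "unsplit")
    c(A = "genA", D = "genD", O = "genO", At = "polyP", Dt = "polyP")
  else
    c(A = "genA", D = "genD", O = "genO", At = "polyAt", Dt = "polyDt")
}

#' Simulate a four-species genome set with planted orthology
#'
#' See [simConfig()] for the evolutionary model.  Gene loss creates gaps
#' inside collinearity blocks; inversions and translocations break
#' blocks; tandem duplicates are planted adjacent to their parent and
#' listed in the tandem file.  The emitted collinearity file holds the
#' true pairwise homology blocks between every pair of the five genome
#' units (subgenomes included, so the tetraploid's homoeologous blocks
#' appear as intra-genome blocks when the genome is not split); the
#' orthogroups file holds the true groups, optionally perturbed at
#' `og_noise`.
#'
#' @param config a [simConfig()] list.
#' @return a `syntenySim` list: `config`, `genes` (per-gene table with
#'   unit, ancestral gene, chromosome, position, tandem flag), `order`
#'   (per unit, per chromosome gene order), `truth` (planted groups of
#'   >= 2 genes, original names), and `tandem_pairs`.
#' @export
simulateGenomes <- function(config = simConfig()) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  C <- config$n_chromosomes
  G <- config$genes_per_chromosome
  anc <- lapply(seq_len(C), function(c)
    sprintf("c%02d.%04d", c, seq_len(G)))

  units <- names(.sim_units)
  order_of <- list()     # unit -> chrom tag -> character vector (originals)
  rows <- list()
  tg_a <- character(0L); tg_b <- character(0L)
  for (u in units) {
    chroms <- list()
    for (c in seq_len(C)) {
      keep <- stats::runif(G) >= config$loss_rate
      surv <- anc[[c]][keep]
      dup <- stats::runif(length(surv)) < config$tandem_rate
      ord <- character(0L)
      for (k in seq_along(surv)) {
        g0 <- paste0(u, ".", surv[k])
        ord <- c(ord, g0)
        if (dup[k]) {
          g1 <- paste0(g0, ".t")
          ord <- c(ord, g1)
          tg_a <- c(tg_a, g0); tg_b <- c(tg_b, g1)
        }
      }
      chroms[[paste0(.sim_units[[u]], sprintf("%02d", c))]] <- ord
    }
    # inversions: reverse a random internal segment
    for (i in seq_len(config$inversions)) {
      cc <- sample(names(chroms), 1L)
      n <- length(chroms[[cc]])
      if (n < 10L) next
      len <- sample(5:25, 1L)
      len <- min(len, n - 1L)
      at <- sample(seq_len(n - len + 1L), 1L)
      seg <- at:(at + len - 1L)
      chroms[[cc]][seg] <- rev(chroms[[cc]][seg])
    }
    # translocations: move a segment to the end of another chromosome
    if (C >= 2L) for (i in seq_len(config$translocations)) {
      cc <- sample(names(chroms), 1L)
      n <- length(chroms[[cc]])
      if (n < 20L) next
      len <- sample(5:15, 1L)
      at <- sample(seq_len(n - len + 1L), 1L)
      seg <- at:(at + len - 1L)
      dest <- sample(setdiff(names(chroms), cc), 1L)
      chroms[[dest]] <- c(chroms[[dest]], chroms[[cc]][seg])
      chroms[[cc]] <- chroms[[cc]][-seg]
    }
    order_of[[u]] <- chroms
    for (cc in names(chroms)) {
      g <- chroms[[cc]]
      if (!length(g)) next
      rows[[length(rows) + 1L]] <- data.frame(
        original = g, unit = u, chrom = cc, pos = seq_along(g),
        ancestral = sub("\\.t$", "", sub("^[A-Za-z]+\\.", "", g)),
        is_tandem = grepl("\\.t$", g), stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, rows)
  truth <- split(genes$original, genes$ancestral)
  truth <- unname(truth[lengths(truth) >= 2L])
  truth <- lapply(truth, sort)
  truth <- truth[order(vapply(truth, `[`, character(1L), 1L))]
  structure(list(config = config, genes = genes, order = order_of,
                 truth = truth,
                 tandem_pairs = data.frame(gene_a = tg_a, gene_b = tg_b,
                                           stringsAsFactors = FALSE)),
            class = "syntenySim")
}

# per-mode gene catalog (canonical naming: sorted species labels get
# indices 0..k-1; gene indices restart at 0 per species in chromosomal
# order) and original -> canonical map
.sim_mode_catalog <- function(sim, mode = c("unsplit", "split")) {
  mode <- match.arg(mode)
  sp_of_unit <- .sim_species_of_unit(mode)
  g <- sim$genes
  g$species <- unname(sp_of_unit[g$unit])
  g$start <- (g$pos - 1L) * 1000L + 1L
  g$end <- g$start + 899L
  g <- g[order(g$species, g$chrom, g$start), , drop = FALSE]
  sp <- sort(unique(g$species))
  sp_idx <- setNames(seq_along(sp) - 1L, sp)
  gidx <- unlist(lapply(split(seq_len(nrow(g)), g$species),
                        seq_along), use.names = FALSE)
  # split() orders by species, matching the row sort above
  g$canonical <- paste0(sp_idx[g$species], "_", gidx - 1L)
  catalog <- GeneCatalog(g$species, g$chrom, g$start, g$end,
                         g$original, g$canonical)
  list(catalog = catalog,
       canonical_of = setNames(g$canonical, g$original),
       species_ids = setNames(sp, as.character(sp_idx)),
       ploidy = if (mode == "unsplit")
         setNames(c(1L, 1L, 1L, 2L), sp) else setNames(rep(1L, 5L), sp))
}

# true pairwise homology blocks between two genome units, as monotone
# runs of shared-anchor positions (anchors are the non-tandem copies)
.sim_unit_blocks <- function(sim, u, v) {
  g <- sim$genes
  a <- g[g$unit == u & !g$is_tandem, ]
  b <- g[g$unit == v & !g$is_tandem, ]
  shared <- intersect(a$ancestral, b$ancestral)
  if (!length(shared)) return(list())
  ia <- a[match(shared, a$ancestral), ]
  ib <- b[match(shared, b$ancestral), ]
  d <- data.frame(ga = ia$original, gb = ib$original,
                  ca = ia$chrom, cb = ib$chrom,
                  pa = ia$pos, pb = ib$pos, stringsAsFactors = FALSE)
  out <- list()
  for (key in unique(paste(d$ca, d$cb))) {
    dd <- d[paste(d$ca, d$cb) == key, , drop = FALSE]
    dd <- dd[order(dd$pa), , drop = FALSE]
    n <- nrow(dd)
    brk <- if (n > 2L) sign(diff(dd$pb)[-1L]) != sign(diff(dd$pb)[-(n - 1L)])
           else logical(0L)
    run_id <- cumsum(c(0L, 0L, as.integer(brk)))[seq_len(n)]
    for (r in split(seq_len(n), run_id)) {
      if (length(r) < sim$config$min_block_pairs) next
      dir <- if (length(r) >= 2L && dd$pb[r[2L]] < dd$pb[r[1L]])
        "minus" else "plus"
      out[[length(out) + 1L]] <- list(chrom_a = dd$ca[r[1L]],
                                      chrom_b = dd$cb[r[1L]],
                                      orientation = dir,
                                      ga = dd$ga[r], gb = dd$gb[r])
    }
  }
  out
}

#' Write a simulation in the pipeline's input dialects
#'
#' Emits, under `dir`: the gene position file, GFF3 and protein FASTA
#' per genome, the collinearity and tandem files, the orthogroups table
#' (original annotation names, as a similarity clusterer reports them,
#' perturbed at the configured noise rate), the ploidy
#' file, SpeciesIDs/SequenceIDs and translation table, and the planted
#' truth groups (original names, one comma-separated group per line).
#' In `unsplit` mode the tetraploid is one species of relative ploidy 2;
#' in `split` mode its two subgenomes are separate species of ploidy 1.
#' Identical simulations yield byte-identical files.
#'
#' @param sim a `syntenySim` from [simulateGenomes()].
#' @param dir output directory (created if needed).
#' @param mode `"unsplit"` or `"split"`.
#' @return named list of emitted paths, invisibly.
#' @export
writeSimulation <- function(sim, dir, mode = c("unsplit", "split")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sim, "syntenySim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mt <- .sim_mode_catalog(sim, mode)
  canon <- mt$canonical_of
  cat_tab <- geneTable(mt$catalog)

  paths <- list()
  paths$positions <- file.path(dir, "genes.gff")
  writeGenePositions(mt$catalog, paths$positions)
  paths$translation <- file.path(dir, "translation_table.tsv")
  writeTranslationTable(mt$catalog, paths$translation)
  paths$species_ids <- file.path(dir, "SpeciesIDs.txt")
  writeSpeciesIds(mt$species_ids, paths$species_ids)
  paths$sequence_ids <- file.path(dir, "SequenceIDs.txt")
  writeSequenceIds(setNames(cat_tab$original, cat_tab$canonical),
                   paths$sequence_ids)
  paths$ploidy <- file.path(dir, "ploidy.tsv")
  writePloidy(mt$ploidy, paths$ploidy)
  paths$tandem <- file.path(dir, "genes.tandem")
  writeTandem(data.frame(gene_a = unname(canon[sim$tandem_pairs$gene_a]),
                         gene_b = unname(canon[sim$tandem_pairs$gene_b])),
              paths$tandem)

  # collinearity: all unit pairs, subgenomes as their own units
  units <- names(.sim_units)
  blocks <- list()
  for (i in seq_along(units)) for (j in seq_along(units)) {
    if (i >= j) next
    for (bl in .sim_unit_blocks(sim, units[i], units[j])) {
      blocks[[length(blocks) + 1L]] <- list(
        id = as.character(length(blocks)),
        chrom_a = bl$chrom_a, chrom_b = bl$chrom_b,
        orientation = bl$orientation,
        intra = bl$chrom_a == bl$chrom_b,
        score = "0", e_value = "0",
        pairs = data.frame(gene_a = unname(canon[bl$ga]),
                           gene_b = unname(canon[bl$gb]),
                           evalue = 0, e_str = "0",
                           stringsAsFactors = FALSE))
    }
  }
  paths$collinearity <- file.path(dir, "genes.collinearity")
  writeCollinearity(new("CollinearitySet", blocks = blocks),
                    paths$collinearity)

  # orthogroups table: truth groups (original names, as a similarity
  # clusterer would report them) + optional noise
  og <- sim$truth
  if (sim$config$og_noise > 0 && length(og) >= 2L) {
    set.seed(sim$config$seed + 7919L)
    corrupt <- which(stats::runif(length(og)) < sim$config$og_noise)
    drop_these <- integer(0L)
    for (k in corrupt) {
      if (stats::runif(1L) < 0.5 && k < length(og) &&
          !(k + 1L) %in% drop_these && !k %in% drop_these) {
        og[[k]] <- c(og[[k]], og[[k + 1L]])     # merge failure mode
        drop_these <- c(drop_these, k + 1L)
      } else if (length(og[[k]]) > 2L) {
        og[[k]] <- og[[k]][-sample(length(og[[k]]), 1L)]  # drop failure mode
      }
    }
    if (length(drop_these)) og <- og[-drop_these]
  }
  sp_levels <- sort(unique(cat_tab$species))
  sp_of <- setNames(cat_tab$species, cat_tab$original)
  membership <- lapply(og, function(g) {
    m <- split(g, factor(sp_of[g], levels = sp_levels))
    lapply(m, function(v) sort(unname(v)))
  })
  ogs <- new("OrthogroupSet",
             ids = sprintf("OG%07d", seq_along(membership) - 1L),
             membership = membership)
  paths$orthogroups <- file.path(dir, "Orthogroups.tsv")
  writeOrthogroups(ogs, paths$orthogroups)

  paths$truth <- file.path(dir, "truth_groups.txt")
  writeLines(vapply(sim$truth, paste, character(1L), collapse = ","),
             paths$truth)

  # per-genome GFF3 + protein FASTA (original names)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  sp_units <- split(names(.sim_species_of_unit(mode)),
                    .sim_species_of_unit(mode))
  paths$gff3 <- character(0L); paths$fasta <- character(0L)
  for (sp in names(sp_units)) {
    rowsel <- cat_tab$species == sp
    d <- cat_tab[rowsel, , drop = FALSE]
    gff <- file.path(dir, paste0(sp, ".gff3"))
    writeLines(c("##gff-version 3",
                 paste(d$chrom, "sim", "gene", d$start, d$end, ".", "+",
                       ".", paste0("ID=", d$original), sep = "\t")), gff)
    fa <- file.path(dir, paste0(sp, ".faa"))
    seqs <- vapply(seq_len(nrow(d)), function(i)
      paste(aa[(i + 0:39) %% 20L + 1L], collapse = ""), character(1L))
    writeLines(paste0(">", d$original, "\n", seqs), fa)
    paths$gff3 <- c(paths$gff3, gff)
    paths$fasta <- c(paths$fasta, fa)
  }
  invisible(paths)
}

#' Compare recovered orthogroups with the planted truth
#'
#' @param groups list of character vectors of gene names (or a
#'   [SyntenyOrthogroups-class]); must use the same namespace as `truth`
#'   (translate canonical names back to originals first when needed).
#' @param truth list of planted groups (character vectors), e.g.
#'   `sim$truth`.
#' @return list: `exact_recovery` (fraction of planted groups recovered
#'   with identical membership), `pair_precision` and `pair_recall` of
#'   gene co-membership, `n_truth`, `n_groups`.
#' @export
evaluateAgainstTruth <- function(groups, truth) {
  if (is(groups, "SyntenyOrthogroups"))
    groups <- lapply(groups@groups, function(m) unlist(m, use.names = FALSE))
  sig <- function(gs) vapply(gs, function(v) paste(sort(v), collapse = "|"),
                             character(1L))
  pairs_of <- function(gs) {
    unlist(lapply(gs, function(v) {
      v <- sort(v)
      if (length(v) < 2L) return(character(0L))
      cmb <- utils::combn(v, 2L)
      paste(cmb[1L, ], cmb[2L, ], sep = "|")
    }), use.names = FALSE)
  }
  pg <- pairs_of(groups); pt <- pairs_of(truth)
  tp <- length(intersect(pg, pt))
  list(exact_recovery = if (length(truth)) mean(sig(truth) %in% sig(groups))
       else NA_real_,
       pair_precision = if (length(pg)) tp / length(pg) else NA_real_,
       pair_recall = if (length(pt)) tp / length(pt) else NA_real_,
       n_truth = length(truth), n_groups = length(groups))
}
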