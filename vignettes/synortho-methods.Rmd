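---
title: "Methods: ploidy-aware syntenic orthology networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ploidy-aware syntenic orthology networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Model and assumptions

`synortho` infers orthogroups — sets of genes descended from one gene in
the common ancestor — by combining two imperfect witnesses of orthology:
sequence-similarity orthogroups, which see homology but not gene order,
and pairwise collinearity blocks, which see gene order but only two
genomes at a time. The central assumption is that for closely related
species, true orthologs lie in conserved collinear context, while
similarity clusters that conflate several ortholog sets can be
disentangled by asking which block pairs the clusters corroborate.

Polyploidy enters through a single per-species parameter, the *relative
ploidy* multiplier: the expected number of gene copies relative to the
base lineage (2 for a tetraploid among diploids). All copy-number
filtering is expressed in units of *gene sets* — a gene together with
its immediately neighbouring tandem duplicates — because a tandem array
is one unit of orthology evidence, not several.

The pipeline is deterministic end to end; no step uses randomness, and
all outputs are emitted under fixed sort orders (blocks in file order,
groups by lexicographically smallest member) so reruns are
byte-identical.

## Tether construction

For each input orthogroup, the distinct tandem arrays contributed by each
species are counted. A species whose gene-set count exceeds its ploidy is
excluded — its genes are dropped from the tether but kept in the report —
and the orthogroup becomes a *tether set* iff at least two species remain
with a nonzero within-ploidy count. We read "at least two species within
the expectation" as requiring *nonzero* counts because a tether has to
anchor collinearity on both sides of a gene pair; species with zero genes
are legitimate members (orthologs may simply be lost) but contribute no
anchoring. The alternative reading, in which zero-count species count
toward the threshold, would admit tethers that can never corroborate any
pair and only dilute the Not Pass signal.

Tandem arrays are built by transitive chaining of the declared adjacent
pairs; a declared pair whose members are *not* adjacent in the
annotation's gene order (callers and annotations occasionally disagree)
is merged anyway, with a warning, on the principle that the tandem caller
saw sequence evidence the gene order does not capture.

## Pair scoring

Each block pair (A1, B1) is scored by a symmetric three-way decision
tree: Pass when both genes share a tether; Not Pass when they lie in
different tethers; No Call when neither is tethered. When exactly one
gene is tethered, the pair is Not Pass if that tether contains a gene of
the partner's species *other than the pair itself* — evidence that the
tethered gene's orthologue is elsewhere — and No Call otherwise.

Two branches deserve comment:

* **Intra-genome blocks** (two regions of one polyploid genome) use the
  same tree with both species equal. In the one-sided branch this makes
  the tethered gene itself a same-species co-member; we exclude it (and
  the partner) from the co-member check, because a gene's own tether
  membership is not evidence against its partner. The alternative —
  counting the tethered gene as a blocking co-member — would force every
  one-sided intra-genome pair to Not Pass and systematically erode
  homoeologous blocks.
* **Self-pairs** (degenerate caller output pairing a gene with itself)
  score No Call: they carry no orthology information.

A block is retained when it has at least two Pass pairs and Not Pass does
not outnumber Pass; the tie is kept because only a strict excess of
contradicting evidence justifies discarding a block.

## Block trimming

Three rules are applied to every retained block until a fixed point:

* **Ends.** From each end, if no Pass lies between a Not Pass and that
  end, everything through that Not Pass is removed. No Call pairs are
  transparent: they are never counted and are only removed when inside a
  removed range.
* **Window.** The first six scored (Pass/Not Pass) pairs at each end are
  inspected; if they hold three or more Not Pass, the endmost pair is
  removed, the end rule is re-applied, and the window is *recomputed
  after every single removal*, continuing until Pass strictly outnumbers
  Not Pass in the window. Recomputing per removal (rather than once per
  sweep) is the reading consistent with "repeated until Pass outnumber
  Not Pass", and it makes the result independent of sweep bookkeeping.
  In blocks with fewer than six scored pairs the window is simply all
  scored pairs.
* **Split.** An internal run of three or more Not Pass with no
  intervening Pass (No Calls do not break the run) splits the block; the
  run itself is dropped, since attached to either child it would
  immediately violate the end rule, and both children re-enter the
  pipeline at the end rule.

Rules are applied ends → window → split, matching the order in which
each rule's precondition is established. After refinement, any block
with fewer than five gene pairs is discarded. "Five genes" is
implemented as five *pairs* — a block is stored as pairs, and an
intra-genome block of five pairs involves ten genes either way; the
distinct-gene alternative differs only for pathological self-overlapping
blocks. Refinement is idempotent, never adds pairs, and terminates
because every iteration strictly removes at least one pair.

## Graph assembly

Every pair of every surviving block becomes an edge regardless of its
individual score — surviving a block-level filter is the unit of trust —
plus chain edges along every tandem array. Tandem edges are added
unconditionally, for arrays that touch no block as well: a tandem array
is itself a minimal syntenic-orthology statement, and this is what
produces species-specific tandem-only groups in real analyses. Connected
components with at least two genes are the final orthogroups; isolated
vertices are unplaced genes.

## Name translation

`translateGff()` assigns `<speciesIndex>_<geneIndex>` names: species
indices follow input order, gene indices restart at zero within each
species and follow (chromosome, start, end, ID) order. Per-species
numbering was chosen over a global counter because it keeps the
gene index meaningful (a rank along the genome) and matches the
SequenceIDs convention of similarity pipelines; either is valid as long
as the mapping is a bijection, which is enforced and written out as a
translation table. Supplied SpeciesIDs/SequenceIDs files take precedence
over fresh assignment so results interoperate with an existing
similarity run. Genes with multiple transcripts are represented by the
gene feature's span (primary-isoform convention).

## The simulator

`simulateGenomes()` emulates the study design the method targets: three
diploids (two progenitors and an outgroup) plus one allotetraploid whose
subgenomes descend from the two progenitor lineages. An ancestral genome
(default 5 chromosomes × 100 genes) evolves along each of the five
genome units by per-gene loss (default 0.05), adjacent tandem
duplication (default 0.05), segmental inversion (default 2 per unit,
5–25 genes) and translocation (default 1 per unit, 5–15 genes). The
defaults are modest, realistic rates for closely related congeners —
enough loss to create block gaps and solitary genes, enough rearrangement
to break blocks — and the noiseless settings used for exact-recovery
checks simply switch these to zero. Collinearity blocks are emitted
directly as the true monotone runs of shared anchors (at least five
pairs, mirroring the usual caller match size): the collinearity caller
itself is out of scope, so the simulator writes what it would output.
Orthogroup noise, when enabled, applies the two realistic failure modes
of similarity clustering: merging two groups and dropping a gene.

What the simulator does *not* model: sequence evolution (similarity
scores are not simulated), assembly artefacts, fractionation bias,
nested or partial tandem arrays spanning rearrangement breakpoints, and
spurious collinearity between paralogous regions. Passing the planted
recovery tests therefore shows the pipeline's logic is faithful, not
that real-genome error modes are handled; the block filters exist
precisely for failure modes the simulator produces only in stylised
form.

## Problem sizes and test design

The test suite exercises the scoring tree against an exhaustively
enumerated truth table, the block filter against 10,000 random score
vectors, refinement idempotence and survivor invariants on 1,000 random
blocks, and component decomposition against an independent flood-fill
oracle on 200 random graphs. End-to-end properties run on simulated
systems of 500 ancestral genes (2,500–2,650 genes across the five genome
units): a noiseless fixture must be recovered exactly, and the
ploidy-aware (unsplit, ploidy 2) and a-priori subgenome-split analyses
of one fixture with loss, tandem duplication and rearrangement must
agree on at least 95% of groups after label normalisation. These sizes
give every structural event a double-digit expected count while keeping
the whole suite fast.

## Known limitations

* Orthologs that moved by transposition, or that sit in rearranged
  segments shorter than the five-pair minimum, cannot be placed —
  synteny is blind there by construction.
* A merged similarity orthogroup that still satisfies every species'
  ploidy bound is accepted as a tether; only copy-number excess, not
  internal heterogeneity, is detected at step 1 (later steps can still
  outvote it).
* The comparison report treats groups as unordered gene sets; it does
  not attempt homoeolog assignment within polyploid groups.
* Relative ploidy is a per-species constant; lineages with segmental or
  partial duplications are better run with subgenomes split where
  possible.
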