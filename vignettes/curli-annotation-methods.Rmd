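---
title: "Annotating curli functional-amyloid systems: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating curli functional-amyloid systems: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curliscan)
```

## The problem

Curli are extracellular functional amyloid fibrils assembled by many
bacteria. The fibril subunit CsgA and its nucleator CsgB are built from
tandem repeats with a conserved glutamine/asparagine/glycine core, and the
subunit genes sit in characteristic *csg* gene clusters together with the
accessory factors CsgC--CsgG (and, in some Alphaproteobacteria, an extra
gene next to the subunit gene, csgH). Homologs diverge fast outside the
repeat regions — pairwise identity between distant subunit homologs can
fall into the 10--30% range — so plain sequence search misses much of the
family. `curliscan` implements the annotation strategy that works at that
divergence: profile hidden Markov models built from curated seed
alignments, a motif scanner for the 22-residue minimalistic curli repeat,
gene-neighborhood curation, iterative model refinement to convergence, and
operon/phylogeny analyses — all testable offline against a synthetic
benchmark with planted truth.

## The minimalistic curli repeat

The repeat scanner matches the 22-residue pattern
$X_6\,Q\,X\,G\,X_2\,N\,X_{10}$: literal Q, G, N anchors at window offsets
6, 8 and 11 (0-based), wildcards elsewhere. Two design points matter:

* **Every window start is tested.** Some subunits carry *superimposed*
  repeats — two motif windows overlapping inside one larger repeat unit. A
  left-to-right consuming regex would silently skip the second window, so
  `scan_repeats()` is an exhaustive position-by-position scan and reports
  all matches, overlapping or not. (Not every overlap offset is realisable:
  a shift of +2 would demand both Q and G at the same position. Offsets
  such as +1 or +4 are compatible with the anchors.)
* **A protein with fewer than two repeat windows is flagged
  non-functional** (`architecture()$functional`): a single repeat unit
  cannot form the amyloid core, and repeat-less homologs of the subunit
  family are treated as degenerate.

`extract_repeat_regions()` merges overlapping/adjacent windows into
maximal regions; these regions — not whole proteins — are the training
material for the combined CsgA/B model, because the sequence outside the
repeats cannot be aligned confidently. `repeat_consensus()` reports
per-column conservation tiers at $\ge 50\%$, $\ge 80\%$ and $= 100\%$
(inclusive thresholds; gaps count in the denominator, so a half-gapped
column can never reach tier 100).

## Alignment model

`global_align()` is Needleman--Wunsch with affine gaps under
$\mathrm{cost}(L) = \mathrm{GOC} + (L-1)\,\mathrm{GEC}$ for a gap of
length $L$, terminal gaps charged. Defaults are GOC = 15, GEC = 1
(seed-alignment settings) with BLOSUM62; repeat-region alignments use
GOC = 50 to keep 22-residue units intact, and BLOSUM45 is available for
distant-homolog work. The convention "opening cost covers the first gapped
position" is fixed and stated here because cost conventions differ between
aligners; only score-optimality of pairwise steps is contractual, not
equivalence with any particular aligner's output. `progressive_msa()`
merges profiles in neighbor-joining guide-tree order with
average-of-pairs column scoring — a deliberately simple progressive
scheme, adequate for the near-fixed-length family alignments this pipeline
produces.

## The profile HMM

`build_profile()` follows the classic construction: alignment columns with
gap fraction < 0.5 become match states; match emissions are estimated with
background-proportional pseudocounts,
$p_k(a) = (c_{k,a} + w\,q_a)/(n_k + w)$ with weight $w = 1$ by default;
transitions come from the row-wise gap structure with Laplace (+1)
smoothing. Scoring (`viterbi()`, `forward()`, in bits) uses a local,
"free-flanking" semantics defined by this package: a path enters the model
at any match state (uniform entry over the $K$ match states), traverses
match/insert/delete states under the core transition probabilities, and
exits from any match state (uniform exit); residues outside the aligned
interval contribute 0 bits and insert states emit the background. Both
Viterbi and Forward are defined over these core alignments, which keeps
$\mathrm{forward} \ge \mathrm{viterbi}$ exactly and makes tiny models
checkable against brute-force path enumeration (the test suite does this
exhaustively for models with up to 3 match states).

Score cutoffs are **decoy-calibrated**, not theory-based:
`calibrate()` scores i.i.d. background decoys and returns the upper
empirical quantile — the smallest decoy score such that at most a fraction
`fpr` of decoys reach it. The reported `evalue_surrogate`
($n_\mathrm{targets} \cdot 2^{-\mathrm{bits}}$) is bookkeeping on that
empirical null, deliberately named so it is not mistaken for a fitted
extreme-value E-value.

**Why `cutoff_fpr = 0.001`.** A genome screen tests every protein against
every family model. With ~7 models and a hundred-plus non-csg proteins per
run, a per-test false-positive rate of 1% would admit several score-passing
decoys per run before curation; 0.001 keeps the expected count below one.
This is the usual multiple-testing argument, applied before any results
were in. The calibration set (1000 decoys, lengths 100--400) is drawn from
the run's single seed, so runs are reproducible end to end.

## Curation and iteration

Manual curation — "accept a hit if its genomic neighborhood looks like a
csg cluster" — is mechanized as an explicit two-clause rule
(`curate_hits()`): a hit is accepted iff its bit score passes the
calibrated cutoff **and** either (a) another accepted csg homolog lies
within `neighborhood_window = 5` genes on the same contig, or (b) for
CsgA/B candidates, the protein carries at least `min_repeats_for_AB = 2`
minimalistic repeats. Clause (b) bootstraps the process: subunit proteins
are self-evidencing through their repeats, and once accepted they provide
the neighborhood evidence for the accessory families. Every decision is
logged with its evidence; hits whose genome lacks an annotation are held
as *unplaceable* rather than dropped.

`iterate_search()` then loops: build models from (seed + accepted)
alignments, calibrate, search, curate, extend, realign, rebuild — until an
iteration adds nothing or `max_iterations` is reached. The accepted set
only grows, so the loop is monotone; `n_iterations` counts productive
rounds. The CsgA/B family trains on concatenated repeat regions
(realigned with GOC = 50), and members whose repeat regions are empty
contribute nothing to the model. CsgD is searched and reported but flagged
non-probative: it belongs to a very large regulator family, so a CsgD hit
alone is no evidence of a curli system. For the same reason, downstream
operon and content analyses only use CsgA/B labels from homologs carrying
at least the minimum repeat count — a repeat-less "subunit" is treated as
non-functional and does not label a gene.

## Operon architecture

With no transcription-unit data available, an operon is defined as a
maximal run of same-contig, same-strand genes with intergenic gaps
$\le$ `max_gap` (default 200 bp; configurable and logged). Two operons are
*divergent* when they transcribe away from a shared intergenic region with
proximal ends within `divergence_window` (default 1000 bp).
`classify_architecture()` maps the csg-labelled operons onto the five
recurring layouts: the divergent csgBA(C)/csgDEFG pair, the same pair
co-oriented, csgD detached as its own transcription unit divergent from
csgEFG, a single csgBAEFG operon with divergent csgD, and a single operon
holding everything; anything else is `other`. Classification uses only
csg-labelled genes, so interleaved hypotheticals are tolerated. CsgA
versus CsgB roles are resolved only inside the Gammaproteobacteria, where
the operon layout fixes the nucleator as the promoter-proximal repeat
gene; elsewhere the honest label is `csgA/B`.

## Trees and congruence

Subunit trees are neighbor-joining trees on p-distances (mismatches over
gap-free column pairs) of aligned repeat regions, one representative per
genome; 16S trees are built the same way from pre-aligned 16S input.
Congruence is reported as the Robinson--Foulds distance on the shared leaf
set plus genus monophyly: a genus is monophyletic iff some edge
bipartition isolates exactly its leaves, a rerooting-invariant criterion.
Negative NJ branch estimates are clamped to zero and counted. NJ and RF
are delegated to `ape` and `phangorn`; the tests validate reconstruction
against independently generated additive matrices.

## The synthetic benchmark

`synth_benchmark()` generates the fixture world everything is tested on:
ten genomes, two per architecture class, one genus per class, with decoy
genes interspersed and complete truth tables. Design choices, and what
they do and do not emulate:

* **Three-level divergence hierarchy.** Each family has a family-wide
  consensus; each genus draws a variant of it (repeat-flank identity 0.3
  to the family consensus — deep divergence, with only the Q/G/N anchors
  literal); each protein copy sits near its genus consensus (identity
  0.9). The 0.3 level reproduces the family-wide flank divergence that
  makes motif anchors necessary; the 0.9 level reflects that homologs
  within a genus are close, which is what makes genus-level tree clusters
  real. Repeat counts per genus span 6--22 units, emulating the observed
  range from short enterobacterial subunits to very long homologs.
* **Guaranteed seeds for the subunit model.** About a third of each repeat
  protein's units (never fewer than two) are drawn near the family-wide
  unit consensus, the rest near the genus consensus. A model trained on
  seed repeat regions therefore always has a conserved anchor block in
  every true subunit — the generator-level guarantee behind the
  sensitivity-1.0 expectation — and the conserved fraction is comparable
  across proteins of different repeat counts, so tree distances are not
  distorted by repeat count.
* **A two-tier divergence ladder for csgF/csgG.** A *mid* lineage drifts
  from the family consensus at rate 0.53 — near the edge of what
  seed-trained models detect — and populates two genera. A *remote*
  lineage keeps all of the mid lineage's drift and resamples half of the
  still-family-like positions, so it is invisible to seed models but well
  covered once the mid-tier homologs have been absorbed. One step cannot
  do this: broadening a model with members near the family consensus does
  not move it toward an unrelated lineage; the ladder is what forces (and
  rewards) multi-round iteration. Tier lineages use low within-lineage
  noise (0.04) so the tiers are crisp.
* **A planted genus split.** The second genome of the single-operon genus
  draws its subunit paralogs from an independent unit lineage, so they
  form their own tight cluster elsewhere in the Csg tree while the
  genome's 16S stays with its genus — the classic signature of a genus
  splitting into two distant subunit clades.
* **Decoys are rejection-sampled to contain zero motif windows**, making
  them guaranteed negatives for the scanner and the subunit repeat clause.

What the generator does *not* emulate: indels inside family proteins
(members are length-conserved, so family alignments are near-trivial),
compositional bias, paralogy beyond the csgA/B copies, horizontal
transfer, or annotation noise. Passing the benchmark therefore
demonstrates the machinery — exhaustive scanning, calibrated search,
neighborhood curation, iterative broadening, layout classification, tree
congruence — under controlled divergence, not performance on real
proteomes, where curated seed quality dominates.

Problem sizes were chosen for a desk-scale run: ten genomes of ~18 genes,
family proteins of 110--260 residues, 1000 calibration decoys; a full
pipeline run takes a few minutes on one CPU and is a pure function of its
integer seed (the generator saves and restores the caller's RNG state).

## Numerical and degenerate-input conventions

* Alignment tie-breaks prefer the diagonal, then a gap in the second
  sequence; HMM traceback prefers match over insert over delete.
* Letters outside the 20-residue alphabet map to `X` with a warning
  (metagenome inputs are dirty); `X` scores 0 bits against any model and
  matches any motif wildcard, but cannot satisfy a literal anchor.
* Internal coordinates are 0-based half-open; GFF3 I/O converts to and
  from 1-based inclusive exactly.
* The plain-text model format stores probabilities at 17 significant
  digits; write/read round trips are exact to < 1e-12 relative error.
* `calibrate(fpr = 0)` returns the decoy maximum; an all-equal decoy set
  returns the common score.
* Empty proteomes, repeat-less proteins, genomes without csg labels, and
  missing annotations all take defined paths (empty tables,
  `functional = FALSE`, a classification error, `unplaceable`) rather
  than silent drops.

## Known limitations

* The HMM is uni-hit: one best local alignment per target, no multi-domain
  decomposition. Proteins with two distant repeat clusters are reported by
  their best cluster.
* The E-value surrogate is only as good as the decoy null; compositionally
  biased targets can shift it.
* Operon calling from a fixed intergenic gap is a heuristic; real
  transcription units need expression data. The architecture classes are
  reproduced on annotations, not asserted to match any manual reading.
* Progressive alignment has no sequence weighting or refinement; for the
  deep, gappy alignments of real subunit families, a dedicated aligner
  remains preferable upstream.
* 16S inputs must be pre-aligned (or equal-length); the package does not
  ship an rRNA aligner.
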