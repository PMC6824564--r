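---
title: "Methods: small-inversion, repeat and diversity analysis of plastomes"
author: "plastoflip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-inversion, repeat and diversity analysis of plastomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastoflip)
```

## The biological problem

Land-plant plastomes are circular molecules of roughly 120–180 kb with a
conserved quadripartite layout: a large and a small single-copy region
(LSC, SSC) separated by two identical inverted repeats (IRa, IRb).  Short
palindromic repeats in and around intergenic spacers fold into stem–loop
(hairpin) structures.  Intramolecular recombination across the stem
reverses the loop — a *flip-flop* mutation — producing a **small
inversion (SI)**: the same locus carries the loop in one orientation (the
common *A form*) in some species and in the reverse-complement orientation
(the rare *B form*) in others.  Because the stem pairs identically either
way, the two orientations have the same predicted free energy, the flips
are close to selectively neutral, and the same locus can flip repeatedly
on a phylogeny.  SIs are therefore strong species-identification markers
and weak (indeed misleading) phylogenetic characters; the analyses in this
package quantify both sides of that claim.

## Module-by-module methods

### Quadripartite partitioning

The two IR copies are located as the maximal-length *exact* inverted-repeat
pair of the circular sequence: the genome is doubled, seeded k-mer matches
between the doubled sequence and its reverse complement are extended
ungapped, and candidate pairs are mapped back to the circle.  The larger
single-copy gap is labelled LSC; reading around the circle gives LSC, IRb,
SSC, IRa.  Exact matching (no mismatch tolerance by default) is
appropriate because within a genome the two IR copies are kept identical
by concerted evolution; the detector's `min_ir_len` (default 10,000 bp, the
scale of real plastome IRs) should be lowered for small synthetic genomes.
Ties between equal-length maximal pairs are broken toward the smallest
start coordinate, and `canonicalize_rotation()` rotates a genome so the
LSC begins at position 1, the standard reporting convention.  A+T content
is (A+T)/(A+C+G+T) with N excluded from both counts.

### Hairpin detection and the free-energy model

`find_hairpins()` enumerates every candidate loop interval (default 4–30
bp), extends the flanking arms outward while they pair (Watson–Crick, with
an optional mismatch budget; stems never end on a mismatch), and keeps
loci that are maximal: arms not extendable outward under the budget nor
inward into the loop.  Alternative folds conflict when the paired arms of
one overlap the span of the other; among conflicting candidates the
longest stem wins, then the most compact fold (shortest loop — the lower
loop penalty), then the leftmost.  A hairpin lying entirely inside
another's unpaired loop is structurally compatible (a cloverleaf) and both
are reported.  The default `min_stem = 8` reflects the shortest stems seen
at real SI loci; `min_loop = 4` admits the 4 bp loops observed there.

Free energy uses a unified DNA nearest-neighbour model at 37 °C:
ΔG = Σ stack energies over consecutive matched stem pairs + a
length-indexed hairpin-loop initiation penalty (linear interpolation
within the table, Jacobson–Stockmayer `1.75·RT·log(n/30)` extrapolation
beyond it).  Both tables ship as TSVs under `inst/extdata/` and can be
swapped.  Two properties matter and are tested: flip-invariance is exact
(the model sees only the stem and the loop *length*), and longer perfect
stems are never less stable than their prefixes (all stacks are negative).
Agreement with published mFOLD values is approximate by design — parameter
sets differ — and is reported, not asserted; on the shipped catalog the
largest deviation is about 2.2 kcal/mol.

### SI calling

Hairpins are detected per taxon on ungapped sequences and mapped through
the alignment; hairpins from different taxa belong to one locus when their
stem-arm column sets overlap with Jaccard ≥ 0.5.  Column overlap rather
than sequence identity is deliberate: loop divergence is the signal, not
noise.  Orientation is classified per taxon against a reference loop by
*relative* Levenshtein distance — closer to the reference than to its
reverse complement is A, the converse is B, ties (in particular loops that
are their own reverse complement) are `ambiguous` and excluded.  The
reference orientation is then fixed so that A is the majority form (ties:
the first taxon in input order).  Monomorphic loci are discarded; subtypes
within an orientation group identical observed loops, numbered by
decreasing taxon count.  Because A is defined by majority, the per-taxon
labels are strand-stable: reverse-complementing every input genome yields
the same loci and the same taxon partition, with each locus's reference
loop reverse-complemented (the property suite asserts exactly this).

`min_taxa_with_stem` (default 15, tuned to 20-taxon datasets) drops loci
whose stem is eroded in many taxa; lower it proportionally for smaller
datasets.

### SSR scanning

For each unit length 1–5 the scanner finds maximal runs of the predicate
`s[i] == s[i−u]` (broken at `N`), yielding maximal perfect repeats; a run
is reported when its full-copy count meets the class threshold
(10/5/4/3/2 for mono- through penta-).  The thresholds follow the
"at least" reading — a 10 bp mononucleotide run qualifies — because
observed mono-SSR lengths start at 10 bp.  Units must be primitive (not a
repetition of a shorter unit), so a poly-A run is never double-reported as
(AA)n; the canonical motif is the lexicographically smallest rotation of
the unit on the given strand (A-runs and T-runs stay distinct; AT and TA
collapse).  Compound/adjacent repeats stay separate.  Summaries split loci
by class, by functional region (CDS / intron / IGS, gene bodies including
tRNA, rRNA and pseudogenes counting as genic) and by compartment
(LSC / IR / SSC), flagging IR-duplicated loci.  Cross-taxon comparison
matches loci of unit length ≥ 2 by alignment-column overlap and identical
canonical motif and classifies each locus as conserved, autapomorphic
(exactly one taxon deviates, absence counting as copy number 0) or
synapomorphic.

### Nucleotide diversity

`pi_sliding()` computes Nei's π per window (default 600 bp window, 200 bp
step, the standard plastome screen): the average pairwise proportion of
differing sites, over the sites where *every* row has A/C/G/T
(complete-deletion; a `pairwise_deletion` mode exists).  The denominator
is the valid-site count, not the window length, so gap-rich spacers are
not artificially deflated; windows with zero valid sites are `NA`
(undefined, not 0), and partial tail windows are dropped.  `hotspot_rank()`
merges maximal runs of windows at or above a π threshold (default 0.015, a
practical hotspot cutoff for congeneric plastomes) and ranks them by peak
π.

### Character mapping

`fitch_acctran()` computes the minimum number of binary state changes on a
rooted tree (missing states are unrestricted; polytomies handled natively)
via dynamic programming over state costs, then assigns ancestral states in
preorder.  On ties the change is taken on the current — most rootward
admissible — branch, the accelerated-transformation preference; tied root
states resolve to A for deterministic output.  The change list carries
per-branch directions (A→B vs B→A).  Characters are classified from their
observed states alone: invariant, autapomorphic (exactly one taxon with
the minority state; such characters always map with a single change on the
deviant terminal branch), or synapomorphic.  The exhaustive-enumeration
oracle in the test suite confirms the minimum on random trees up to 12
leaves and on a 20-taxon bit-parallel check.

### Synthetic data

The simulator assembles an ancestral genome from a block blueprint (genes,
spacers, a two-exon gene with an intron, an IR block), plants hairpin and
SSR loci at fixed offsets, and evolves the single-copy core plus one IR
copy along a rooted tree under Jukes–Cantor, mirroring the IRa from the
IRb within each taxon (concerted evolution).  Defaults emulate the scale
and structure of a congeneric plastome study: 20 taxa in ten cherries,
branch lengths 0.003 substitutions/site (within-genus plastome
divergence), ~60.8% A+T base composition, a ~9.6 kb genome with a
quadripartite layout, 11 planted SI loci using published Lauraceae
stem/loop sequences — five flipped on a single terminal branch and six
flipped 5–7 times — and eight planted SSRs covering every motif class in
LSC and SSC.  Genome and sample sizes are scaled to keep a full
simulation-plus-analysis cycle under a second while leaving thousands of
background sites per genome.

Three simulator properties make the truth table exact rather than
approximate, and all are deliberate conveniences documented as such:

* **Protection**: planted elements (plus 1 bp guard flanks chosen so arms
  cannot extend outward and runs cannot extend by a unit) never mutate, so
  orientations change only via planted flips.
* **Sanitisation**: the ancestral background is patched until it contains
  no hairpin with stem ≥ 6, no stem ≥ 7 reachable within one substitution
  (scanned with a 1-mismatch budget), and no repeat run within two copies
  of a class threshold.  Single substitutions on branches therefore cannot
  conjure a competing structure at a planted locus.
* **Cherry placement**: multi-flip characters flip only terminal branches
  of distinct cherries.  On such placements the Fitch length provably
  equals the planted flip count (each B-cherry contributes exactly one
  union event), so ACCTRAN recovery can be asserted exactly for any seed.

No indels are simulated, so the alignment is column-exact by construction.
What passing these tests does *not* show: robustness to alignment error,
indel-riddled spacers, stem erosion (exercise `max_mismatch` and
`min_taxa_with_stem` for that), IR boundary shifts, or base-compositional
heterogeneity — all present in real data.

## Numerical and design choices

* **Coordinates** are 1-based closed intervals everywhere (GenBank and
  R/Bioconductor convention); reports print the same convention.
* **Circularity** is handled by doubling the sequence for interval
  arithmetic; reported coordinates stay within `[1, length]`.
* **Orientation reference**: the A form is the majority orientation.  The
  published catalog prints per-taxon counts consistent with this rule at
  every locus where counts are given.
* **Edit distances** use `utils::adist` (Levenshtein); subtype grouping
  merges only identical loops, so printed-catalog duplicates (two
  identically-sequenced subtypes) are represented but never forced.
* **Determinism**: every stochastic draw in the simulator flows from one
  integer seed; the pipeline writes byte-identical TSVs on identical
  inputs, and tie-breaks throughout (IR pairs, fold suppression, subtype
  numbering, ACCTRAN) are total orders.
* **GenBank support** is a purpose-built reader/writer for the flat-file
  subset the package needs (LOCUS/FEATURES/ORIGIN; gene, CDS, tRNA, rRNA
  keys; join/complement locations; `/pseudo`); introns are derived from
  gaps between exon intervals rather than stored.

## Known limitations

* IR detection is exact-match only; genomes with diverged IR copies need a
  future mismatch-tolerant mode (`--ir-max-mismatch` is reserved).
* The free-energy model scores stems and loop lengths only — no bulges,
  multiloops or dangling ends — so absolute ΔG values are comparable
  within the model, not across published tools.
* SI calling assumes a trustworthy whole-genome alignment; in gap-dense
  regions the stem-arm column mapping inherits the aligner's errors.
* π windows are alignment-column windows; converting hotspot coordinates
  to a particular genome requires that genome's column map when the
  alignment contains gaps.

## A minimal end-to-end run

```{r example, eval = FALSE}
ds <- simulate_dataset(sim_config(seed = 1))
prof <- call_si_loci(ds$alignment, ds$records, min_taxa_with_stem = 15)
m <- si_matrix(prof, taxa = ds$alignment$labels)
cm <- classify_characters(ds$tree, m)
cm$per_character
```
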