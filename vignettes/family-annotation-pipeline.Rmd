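---
title: "Annotating a gene family genome-wide: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating a gene family genome-wide: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

famscan re-implements, as a reusable pipeline, a genome-wide survey of a
domain-defined transcription-factor family (the MADS-box family is the
motivating case): candidate-locus discovery by translated similarity search,
functionality triage, gene-model curation, cross-species orthology, bootstrap
phylogeny with clade-based classification and nomenclature, and an
expression atlas with two-tier co-expression clustering. This vignette
records the models, the tunable parameters, and the design decisions taken
where the underlying procedure was described only qualitatively.

## Discovery model and alignment statistics

Discovery is a translated similarity search of seed family proteins against
all six reading frames of the genome, in the BLAST tradition: exact
amino-acid word seeding (word size 4), two seeds on nearby diagonals
(bandwidth 8, along-diagonal distance <= 100 residues) required before a
candidate window is aligned, then one Smith--Waterman local alignment per
window with BLOSUM62 and affine gap penalties 11 (open) / 1 (extend). Each
HSP's E-value uses the Karlin--Altschul closed form
`E = K * m * n * exp(-lambda * S)` with the gapped BLOSUM62 constants
`lambda = 0.267`, `K = 0.041`, `m` the query length and `n` the total
translated residues searched; hits above the discovery cutoff `1e-3` are
dropped. The two-seed requirement assumes queries of at least ~50 residues
with moderate conservation; for the high-identity homologs this pipeline
targets, seeding recall on planted sequences is exactly 1 across all six
frames (a property the tests assert).

HSPs on one chromosome and strand within 10 kb merge into a "candidate
region". The source survey never formalizes how overlapping hits became its
candidate regions; the 10-kb single-strand merge is this package's
operationalization, chosen to match typical gene spans at the locus
granularity the survey reports, and is deliberately a parameter
(`merge_regions(max_gap = )`) rather than a claim about the original
procedure.

## Family-domain profile and triage

The family domain is modelled as a position-specific scoring matrix over the
columns of a curated seed-domain alignment with at least 50 % occupancy:
`score = log2((freq + c * bg) / ((1 + c) * bg))` per column with pseudocount
weight `c = 1` and uniform background `bg = 1/20`. The detection threshold
defaults to 0.6 x the consensus self-score (the sum of per-column maxima) --
high enough that unrelated sequence never fires, low enough that a
three-quarter domain still does. Profile matching is gapless local
alignment over all diagonals (any contiguous run of profile columns may
match), with stops scoring -4 and ambiguous residues -1; this yields both a
score and a *profile coverage*, the fraction of columns matched.

Triage assigns exactly one class per region:

* `no_domain` -- no frame reaches the profile threshold;
* `nonfunctional` / truncation -- the domain match covers < 80 % of the
  profile. The survey says "truncation" without a number; 80 % keeps
  near-complete domains functional while catching genuine fragments;
* `nonfunctional` / internal stop -- the translated HSP span in the domain's
  frame contains a stop codon away from the span edges (a 2-residue margin
  avoids counting the terminal stop);
* `possibly_assembly` -- the disruption interval (missing domain flank, stop
  codon, or ambiguity run) overlaps a run of >= 20 `N`: the lesion may be an
  assembly artifact rather than a pseudogene. It is a refinement of
  `nonfunctional` and is counted within it in summaries;
* `functional` otherwise.

## Gene models and coverage validation

Gene models use 0-based half-open coordinates internally and 1-based
inclusive GFF3 on disk (via `rtracklayer`); exons are kept in transcript
orientation and CDS translation follows the standard genetic code with
ambiguous codons as `X`. Exon support against an RNA-seq coverage track is
the *median* per-base depth >= 5: the median (not the mean) is robust to
edge tapering, and the depth cutoff is configurable because the source
procedure reports only that exon structures were "double-checked" against
RNA-seq. Structure comparison says `confirmed` only on identical exon and
CDS interval sets; `changed_exons` counts intervals present in one model but
not the other, taking the larger direction so a modified exon counts once.

## Orthology

"Sequence homology higher than 40 %" is read as percent identity over the
aligned region (the value is characteristic of identity-style cutoffs); the
alternative reading (BLAST "positives") is noted but not implemented. Both
retention thresholds are strict inequalities, following the literal "lower
than 1e-20" / "higher than 40 %". Best matches use the explicit tie-break
chain bitscore, then E-value, then lexicographic gene id -- the source is
silent and determinism is required. Protein-protein local alignment stands
in for the survey's BLASTx of gene sets, since deduced proteins exist for
every input here and frame handling adds nothing.

## Phylogeny

The multiple aligner is a built-in progressive aligner (3-mer count distance
guide tree, average linkage; profile-profile Needleman-Wunsch with BLOSUM62
expected scores, gap open 10 / extend 0.5) behind a provider interface, so a
different aligner can be dropped in as a function. Columns with non-gap
coverage below 0.95 are eliminated (strictly below; the operation is
idempotent). Trees are neighbor-joining on JTT maximum-likelihood pairwise
distances (via `phangorn::dist.ml`), bootstrapped by resampling filtered
columns with replacement under a stated seed; the consensus is
majority-rule-extended (greedy addition of compatible splits by frequency),
keeping more resolution than plain majority rule, with support = replicate
frequency x 100. The full maximum-likelihood heuristic of the original
survey is intentionally not re-implemented: at the scales this package
targets, clade recovery -- not topology identity -- is the meaningful
outcome, and distance NJ with JTT distances recovers planted clades
reliably. Branches with support strictly below 30 collapse into polytomies.

Clade assignment is rooting-independent: for each unlabeled leaf the
candidate clades are the sides (containing it) of all splits of the
collapsed tree; the smallest candidate containing an anchor supplies the
label if its anchors agree, else the leaf is `unplaced`.

## Nomenclature

Symbol assignment is a strict precedence: conserved prior symbols (dot
serials like `VviSOC1.1` convert to `VviSOC1a`), then Arabidopsis-ortholog
symbols with the species prefix, then subfamily serials for MIKC-C loci,
then subclass+clade serials (`MADSD`, `MADS1A`, `MADS1G` + clade digit +
letter). The source attributed serial letters "randomly"; here letters
follow genomic order (chromosome, then start) so that identical catalogs
always yield identical symbols. Serials overflow a..z to aa, ab, ...

## Expression atlas

Replicates average arithmetically into conditions. Calls per cell: arrays
`expressed` strictly above log2 = 8, `detected` in [5, 8], `background`
below 5; counts `expressed` at >= 10 reads (inclusive, "at least"),
`detected` 1..9, `background` 0. These strict/inclusive readings follow the
source's wording literally. Gene status is `gene` with any expressed cell,
`putative` with only detected cells, `hypothetical` otherwise, and PO terms
attach from expressed conditions only.

For clustering, sub-basal array values smooth to log2 = 5 (noise below the
basal level carries no co-expression signal); counts first transform to
`log2(reads + 1)` and share the floor. The basal value doubles as the
background/detected boundary because the source colours "background" without
stating its bound -- tying it to the stated floor of 5 is the least
arbitrary choice. Condition collapse (Pearson distance < 0.05, average
linkage, merges strictly below the cut) runs within platform only, matching
the per-platform centering of the original displays, and uses the family
genes' profiles, following the source's phrasing that the distance was "of
the family expression". Gene grouping repeats the same metric at 0.15.
Zero-variance profiles have no defined correlation and become singletons
rather than errors. Strict cuts are implemented by applying exactly the
merges whose height is below the threshold, so behaviour at the printed
thresholds (0.05 / 0.15) is not at the mercy of floating-point `cutree`
boundaries.

## The synthetic-data module

The generators are first-class, tested code; their defaults are the study
conditions used throughout the tests and the acceptance script:

* **Genome**: 2 Mb in two chromosomes of i.i.d. uniform ACGT (the simplest
  null for a similarity scan), with 10 functional, 5 internal-stop,
  3 truncated and 2 gap-disrupted planted genes; a 60-residue domain
  consensus plus a 120-residue tail; six seed proteins at 5 % domain / 10 %
  tail divergence. Internal stops are a single TAA substitution at least 30
  codons from either end, downstream of the domain, so the domain stays
  detectable while translation fails. Truncated genes keep 75 % of the
  domain then stop; gap-disrupted genes carry a 24-base `N` run in the tail;
  decoys share the tail (hence are found by the scan) but carry an unrelated
  domain region (< 25 % identity to the consensus).
* **Proteomes**: one-to-one orthologs as copies of a shared ancestor mutated
  at 10 % each (pairwise identity near 80 %), homolog-only families at 25 %,
  species-specific genes as unrelated randoms (< 30 % cross-species
  identity) -- bands separated widely enough that reciprocal-best-hit
  recovery of the planted map is exact.
* **Clade sets**: four clades of five genes plus two anchors each; clade
  ancestors at 40 % divergence from a family root, members at 8 % within
  clades.
* **Expression**: three array platforms (16 conditions each) and one
  RNA-seq platform (11 conditions), 3 replicates per array condition, over
  an 8-tissue vocabulary with real PO identifiers; four planted groups of
  three genes share distinct tissue on/off profiles (on = log2 11,
  off = 3.5, Gaussian noise SD 0.2 by default); putative-tier genes peak at
  log2 = 6 (detected but not expressed on both platform types) and
  hypothetical genes stay flat. On/off tissue sets are drawn without
  replacement so that distinct genes are never accidentally identical at
  zero noise.

What the generators do *not* emulate: codon usage and splice-site signal
(planted genes are single-exon), read-level RNA-seq (coverage is emitted
directly as per-base depth), genome repeats, paralog interference in the
scan, and array-specific normalization artifacts. Passing the synthetic
suites therefore demonstrates correctness of the algorithms under separated
signal bands, not robustness to the full messiness of a real assembly.

## Problem sizes and determinism

The test and acceptance runs use desk-scale sizes chosen to exercise every
code path: the 2-Mb / 20-gene genome for scan and triage, 20 x 20-gene
proteome pairs for orthology, 28-taxon clade sets with 100 bootstrap
replicates for phylogeny, and about 60 expression conditions across four
platforms. All randomness flows from a single integer seed through one
generator stream per module (offsets +1, +2, +3 keep the streams
independent), and every generator restores the caller's RNG state, so
identical configurations are bit-identical -- the pipeline manifest hashes
its outputs to prove it.

## Known limitations

* The scan's two-seed requirement can miss homologs below roughly 50 %
  identity to every seed; the survey's own sensitivity rested on BLAST's
  one-hit mode and a large seed set.
* Regions closer than the merge gap on the same strand fuse; tandem family
  clusters need a smaller `max_gap`.
* NJ/JTT is a stand-in for full maximum likelihood; deep or rate-variable
  clades may place differently, which is why clade recovery (with anchors)
  rather than topology identity is the supported use.
* The packaged locus table is a faithful transcription of the published
  table, including its disagreement with the running text on the number of
  chromosomes carrying family genes (16 in the table, 17 in the text); the
  package reports what the table contains.
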