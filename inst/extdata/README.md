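# Fixture tables

Transcriptions of summary tables and counts from the published grapevine
MADS-box family survey that this pipeline re-implements. They are inputs for
`read_table1_catalog()`, `read_triage_counts()` and `read_subclass_counts()`
and for the worked examples; nothing in them is computed by this package.

## table1_catalog.tsv

The 90 family loci with their printed positions. Columns:

- `locus_id`, `chromosome`, `start`, `end` (1-based inclusive, as printed),
  `strand` (`-` where the position carried a minus mark, `+` otherwise),
- `new_v0` — locus was typeset bold (new gene relative to the earlier v0
  annotation study),
- `new_v1` — locus was typeset bold italic (new relative to the v1
  annotation),
- `position_curated` — the position (not the locus id) was typeset bold
  (CDS structure curated relative to v0).

Transcription notes:

- All 90 printed entries parse cleanly; locus-id chromosome prefixes agree
  with the printed positions; there are no duplicates.
- The table spans 16 distinct numbered chromosomes (chr06, chr09 and chr11
  have no entries) plus chr00 (3 unplaced loci), while the survey's running
  text states the family maps to 17 of the 19 chromosomes. The discrepancy
  is transcribed as-is, not reconciled.

## triage_counts.tsv

Candidate-region triage accounting from the survey's gene-identification
results: 169 regions sharing homology with at least one known family gene,
of which 42 without the family domain, 37 with the domain but nonfunctional
(truncations / internal stops; 15 of these possibly reflecting incomplete
assembly sequence) and 90 functional genes.

## subclass_counts_source.tsv

Subclass and clade membership as enumerated in the survey's nomenclature and
phylogeny sections: 42 MIKC-C genes (count only; the text does not enumerate
all symbols), 6 MIKC* (clades 1-3), 23 M-alpha (clades 1-3: 7 + 9 + 7) and
19 M-gamma (clades 1-3: 10 + 8 + 1).

Transcription notes:

- The single M-gamma clade-3 gene is printed once as "MADS1G3h" and twice as
  "MADS1G3a"; the fixture uses MADS1G3a.
- "MADSA2f/g/h" are read as MADS1A2f/g/h (a dropped "1" in the source), and
  a lone "MADS1A3i" in the co-expression section is not added (the M-alpha-3
  clade is enumerated as a..g, 7 genes).
- The abstract counts the MIKC* S clade as 4 genes and P as 2; the results
  text enumerates S = {MADSD1a,b,c}, P = {MADSD2a,b} and a third clade
  {MADSD3a}. The fixture follows the enumeration.
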