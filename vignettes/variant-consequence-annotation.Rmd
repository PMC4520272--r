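---
title: "Annotating sequence variants with Sequence Ontology consequence terms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating sequence variants with Sequence Ontology consequence terms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvfkit)
```

## The model

The Sequence Ontology (SO) deliberately separates two things that variant
files often conflate: the **sequence alteration** — the nucleotide-level
event observed in an individual relative to a reference (`SNV`, `insertion`,
`deletion`, `substitution`, and the copy-number types) — and the **sequence
variant** — the observed or predicted change that event brings about in
annotated reference features (`missense_variant`, `intron_variant`,
`transcript_ablation`, ...). GVF encodes the first in column 3 of each
record and the second in `Variant_effect` attributes, each tying an effect
term to an allele index, a feature type and one or more feature ids.

Effect terms form a multi-parent `is_a` DAG. This is not an implementation
detail but the query model: `stop_retained_variant` is both a
`synonymous_variant` and a `terminator_codon_variant`, so a subsumption
query for either parent retrieves it. All query operations in gvfkit
(`so_ancestors`, `so_descendants`, `so_is_a`, `filter_by_effect`) are
reflexive-transitive closures over `is_a` edges only; other OBO
relationships (`part_of`, `derives_from`) are parsed and stored but never
traversed, because the query semantics of consequence annotation are
subsumption, not partonomy.

Effects come at two scales. When the alteration falls **within** a feature,
feature-internal rules apply: codon arithmetic inside the CDS, the 2-bp
donor/acceptor cores at intron ends, UTR/intron/non-coding-exon placement.
When the alteration's extent **rivals the feature itself**, whole-feature
rules apply: a deletion containing a transcript ablates it, a copy-gain
alteration containing it amplifies it, a deletion crossing one feature end
truncates it, a copy-gain event inside it elongates it.

## The packaged ontology and vocabulary

`load_so()` returns a pinned, hand-curated subset of the public SO (78
terms, real accessions) covering the `sequence_variant` and
`sequence_alteration` branches plus the feature terms gene models use. It
is versioned data: its term set is frozen, deliberately not synchronized
with the live SO, and structural claims about the live ontology (such as
subtype counts under `gene_variant`) are not asserted against it. Three
terms renamed by the SO after the Ensembl vocabulary was first published
are stored under their current names (`start_lost`,
`non_coding_transcript_variant`, `non_coding_transcript_exon_variant`)
with the historical names kept as synonyms, so either spelling resolves.

`load_ensembl_vocabulary()` returns the 34-term consequence vocabulary used
by the Ensembl variation pipeline, ordered by conventional severity. The
engine emits only terms from this list; the ordering doubles as the ranking
used by the `most_severe` reporting mode.

## Consequence-calling rules and their parameters

For each GVF line, `call_consequences()` emits one call per
(alternate allele, overlapping transcript), plus window-based calls:

* **Coding, same length** (SNV/MNV): the affected codons are rebuilt from
  the spliced, phase-trimmed CDS (alternate bases complemented for
  minus-strand transcripts) and translated with the standard genetic code.
  Identical amino acids give `synonymous_variant`, or
  `stop_retained_variant` when the codon is a terminator; destroying the
  initiator ATG is `start_lost`; losing the terminator is `stop_lost`;
  creating one is `stop_gained`; any other change is `missense_variant`.
  Codons containing N are reported as `coding_sequence_variant` rather than
  guessed. Exactly one of these terms is emitted per pair.
* **Coding indels** are classified purely by length difference: not a
  multiple of three is `frameshift_variant`; otherwise
  `inframe_insertion`/`inframe_deletion`. The declared column-3 type is
  not trusted for this; sequence lengths are.
* **Splice** (`splice_region_exon = 3`, `splice_region_intron = 8` by
  default, both configurable): the donor core is the 2 bp at the 5'
  (transcript-direction) end of an intron — the two *highest* genomic
  coordinates for a minus-strand transcript — and the acceptor core the
  2 bp at the 3' end. The splice region spans the adjacent 3 exonic bases
  and intron bases 3–8; in short introns region windows are clipped so they
  never reach the opposite core. Core hits take precedence over coding
  terms for the same pair; both appear only when the alteration separately
  covers CDS bases (e.g. a deletion across an exon/intron junction). An
  insertion anchored at the last exonic base is exonic; anchored inside
  the donor dinucleotide it is a donor variant.
* **Positional**: exonic positions 5'/3' of the CDS give the UTR terms;
  exons of non-coding transcripts give
  `non_coding_transcript_exon_variant` (`mature_miRNA_variant` for miRNA
  features, whose annotated extent is the mature product); anything else
  inside the transcript is `intron_variant`.
* **Whole-feature**: containment is boundary-inclusive on closed intervals.
  Only copy-gain types (descendants of `duplication` or
  `copy_number_gain`) trigger amplification/elongation; plain insertions
  never do. When a whole-feature term fires for a pair it is the only term
  emitted for that pair — the interior rules describe changes *within* a
  feature and are not meaningful once the event operates at feature scale.
* **Proximity** (`gene_window = 5000` bp, configurable): a variant
  overlapping no transcript but within the window of a gene gets one
  `upstream_gene_variant`/`downstream_gene_variant` call per such gene
  (strand-aware); otherwise a single `intergenic_variant` with no feature
  id. The window default follows common annotation practice; nothing in
  the consequence model depends on its exact value.
* `regulatory_region_variant` and the regulatory ablation/amplification
  terms exist in the vocabulary and in `classify_span()`'s
  `feature_kind = "regulatory_region"` hook, but no regulatory build is
  modeled.

All reporting is exhaustive by default — every applicable term for every
(allele, feature) pair — because consequence sets, not single labels, are
what downstream cross-tabulation counts. `most_severe = TRUE` collapses a
line to its single highest-ranked term for users who want one row per
variant.

When `Reference_seq` disagrees with the genome, the engine warns and uses
the genome base: the reference assembly, not the file, is ground truth.
The engine is fully deterministic; transcript iteration is sorted by id.

## Coordinates and formats

All interval arithmetic uses 1-based, fully-closed coordinates end to end —
the GFF3/GVF file convention and the R/Bioconductor (IRanges) convention —
so there is no conversion boundary anywhere in the package. Insertions are
anchored with `start == end ==` the base immediately 5' of the inserted
material and `Reference_seq="-"`, symmetrically on read and write.

GVF attribute values are percent-decoded on read and re-encoded on write
(`; = % & ,` plus tab/newline), and round-trip byte-faithfully. One
deliberate dialect decision: `Variant_effect` values are *not* comma-split
like ordinary GFF3 attribute values, because the effect grammar
(`term index feature_type id1,id2`) comma-joins feature ids inside its
fourth field; each `Variant_effect` tag occurrence therefore carries
exactly one effect record, and multiple effects appear as repeated tags.
Unknown pragmas and attributes pass through untouched.

GFF3 gene models and FASTA references are read through rtracklayer and
Biostrings respectively; gvfkit assembles the gene → transcript → exon/CDS
hierarchy, derives introns, and honors the GFF3 phase of the first CDS
segment by trimming leading bases. A CDS length that is not a codon
multiple is flagged with a warning, not an error, since partial models
occur in real annotation. Only the standard genetic code is supported
(stops TAA/TAG/TGA); `lnc_RNA` is treated as an `ncRNA` synonym; unknown
transcript-level types are skipped with a warning.

## What the synthetic fixtures emulate

`make_genome_and_genes()` lays out archetypal configurations on separate
small landmarks (each well under 50 kb, so the whole suite runs in
seconds): a rich 3-exon coding gene on each strand; a two-isoform gene
whose second transcript skips the only coding exon (so one SNV is exonic
for one isoform and intronic for the other); ncRNA, miRNA and
primary-transcript genes; a gene nested inside a 12 kb host intron;
an opposite-strand ncRNA across a coding gene's 3' UTR; and isolated
single-exon genes for ablation/amplification/truncation/elongation events.
Designed CDSs start with ATG, contain no internal stop, end with a stop,
and are stamped over an otherwise random genome.

`plant_variants()` finds sites by scanning: codons against the genetic code
for the coding terms, intron ends for splice cores, exon/UTR interiors for
positional terms. Every candidate footprint is then validated against the
*whole* layout — any other transcript it touches must classify cleanly
(deep intron, clean non-coding exon, clean UTR), and window-proximal genes
are recorded — so the stored ground truth is the complete consequence set,
forced by construction rather than produced by the engine under test.
Ambiguous placements are rejected; candidate sites keep ≥ 4 bp clearance
from splice windows so each planted site has a single forced
interpretation. The default plan plants 48 variants covering 24 distinct
effect terms across all four alteration classes (one missense site is
emitted as a dinucleotide substitution for exactly this reason), plus
copy-number types for the whole-feature events.

What the fixtures do **not** emulate: realistic mutation spectra or allele
frequencies, overlapping CDSs on both strands, phase != 0 models, partial
terminal codons, NMD annotation, or regulatory builds. A green closed loop
therefore demonstrates the correctness of the coordinate arithmetic and
rule logic, not robustness to the full messiness of real genome annotation;
the tolerant paths (N codons, reference mismatches, phase trimming, unknown
types) are exercised by separate unit tests on hand-built corner cases.

## Numerical and degenerate-input choices

* Interval containment is boundary-inclusive; a deletion exactly coextensive
  with a transcript ablates it.
* Same-length substitutions only partially inside the CDS fall back to
  `coding_sequence_variant` rather than a codon-level call.
* A `Variant_seq` of `~` (sequence same as reference, used by copy-number
  records) is an allele; `.` (unknown) is not; an allele spelling out the
  reference is skipped.
* Ties between splice and coding terms follow the precedence above; all
  remaining term sets are emitted sorted, and feature ids are sorted within
  each written `Variant_effect`, so output is byte-deterministic.
* Problem sizes in the test-suite and acceptance script — 20 fixture seeds,
  1000 oracle SNVs, 100 random DAGs, 200 round-trip documents — were chosen
  so the whole battery completes in well under a minute on one core while
  every rule path is crossed many times.

## Known limitations

The SO snapshot is a subset; resolving terms outside the variant branches
requires supplying a fuller OBO file to `parse_obo()`. The engine does not
model NMD transcripts, selenocysteine, alternative genetic codes, phased or
compound effects, or regulatory features beyond the hook. Splice-region and
gene-window extents are conventions, not biology; both are configuration
knobs with documented defaults.
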