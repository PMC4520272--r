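# gvfkit

An R toolkit for the **Genome Variation Format (GVF)** and the **Sequence
Ontology (SO)** sequence-variant terminology, for anyone who produces,
validates or mines ontology-typed variant annotation: parse/write/validate
GVF, reason over the SO `is_a` graph, call SO consequence terms for
sequence alterations against reference gene models (GFF3 + FASTA), and run
ontology-aware queries and dataset cross-tabulations.

## The model in brief

The SO separates the **sequence alteration** — the observed nucleotide
event (`SNV`, `insertion`, `deletion`, `substitution`) carried in GVF
column 3 — from the **sequence variant** — its effect on annotated
reference features, carried in `Variant_effect` attributes with the grammar

```
Variant_effect=<effect_term> <allele_index> <feature_type> <id>[,<id>]*
```

Effect terms live in a multi-parent `is_a` DAG, so queries are subsumption
queries: *stop_retained_variant* is both a *synonymous variant* and a
*terminator codon variant*, and answers both queries. Coding effects come
from codon arithmetic over the spliced, strand-aware CDS
(missense/synonymous/stop gained/stop lost/start lost; indels classify by
length mod 3 into frameshift vs inframe); splice effects from the 2-bp
donor/acceptor cores at intron ends plus a configurable splice region
(exon 1–3 / intron 3–8); whole-feature effects (ablation, amplification,
truncation, elongation) from interval containment at feature scale; and
everything a variant touches is reported — one call per (allele,
overlapping transcript), a single alteration perturbing many features.

The package ships a pinned SO subset (78 terms, real accessions) and the
34-term Ensembl consequence vocabulary, plus a deterministic
synthetic-fixture generator (`fixture_spec()` → `make_genome_and_genes()` →
`plant_variants()`) that plants variants whose full consequence set is
known by construction — the toolkit's primary correctness instrument.

## Worked example

```r
library(gvfkit)

dag  <- load_so()
spec <- fixture_spec(seed = 1)
mk   <- make_genome_and_genes(spec)          # toy genome + gene models
pl   <- plant_variants(spec, mk$genes, mk$genome)
ann  <- annotate_document(pl$doc, mk$genes, mk$genome, dag)
```

One annotated line — an SNV in the coding exon of one isoform that is
intronic for the exon-skipping sibling isoform, so it carries two effects:

```
chrT3  gvfkit_fixture  SNV  6334  6334  .  +  .  ID=var0042;Variant_seq=A;
    Reference_seq=G;Variant_effect=intron_variant 0 transcript gC.t2;
    Variant_effect=missense_variant 0 mRNA gC.t1
```

```r
gvf_summarize(ann)
#> GVF dataset: 48 variant line(s)
#>   copy_number_gain       1
#>   deletion               4
#>   insertion              1
#>   SNV                    40
#>   substitution           1
#>   tandem_duplication     1
#> distinct effect terms:  24
#> distinct feature types: 6
#> effect records:         60
```

48 variant lines produce 60 effect records because one alteration may
perturb several features; 24 distinct effect kinds across 6 feature kinds
are planted. The alteration-by-effect cross-tabulation (the data behind a
treemap-style breakdown):

```r
head(as.data.frame(gvf_crosstab(ann)), 5)
#>    alteration_type              effect_term n
#> 1 copy_number_gain transcript_amplification 1
#> 2         deletion       feature_truncation 1
#> 3         deletion       frameshift_variant 1
#> 4         deletion         inframe_deletion 1
#> 5         deletion      transcript_ablation 1
```

Subsumption retrieval — the synonymous-variant query retains the
stop-retained line via its dual parentage, no string matching involved:

```r
syn <- filter_by_effect(ann, dag, "synonymous_variant")
length(syn$lines)                                        # 5
so_is_a(dag, "stop_retained_variant", "synonymous_variant")  # TRUE
```

A command-line interface wraps the same functions
(`exec/gvfkit`): `gvfkit validate`, `gvfkit annotate`, `gvfkit query`,
`gvfkit summarize [--crosstab] [--json]`, `gvfkit so
--ancestors/--descendants/--is-a`, and `gvfkit fixtures --seed N -o DIR`.

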