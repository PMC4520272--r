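# Consequence engine: coding, splice, span-scale and positional rules

# single-exon toy: CDS ATG GCC TAC GCA TAA at 11..25
toy_coding <- function() {
  list(genome = c(chrZ = paste0(strrep("T", 10), "ATGGCCTACGCATAA",
                                strrep("T", 20))),
       tx = transcript_model("t1", "g1", "chrZ", "+", "mRNA",
                             exons = rbind(c(6L, 30L)),
                             cds = rbind(c(11L, 25L))))
}

test_that("codon-level SNV classification covers the rule table", {
  toy <- toy_coding()
  cls <- function(ref, alt, pos)
    classify_coding_change(toy$tx, toy$genome, allele(ref, alt), pos)
  expect_equal(cls("G", "A", 14L), "missense_variant")       # GCC -> ACC
  expect_equal(cls("C", "A", 16L), "synonymous_variant")     # GCC -> GCA
  expect_equal(cls("C", "A", 19L), "stop_gained")            # TAC -> TAA
  expect_equal(cls("T", "C", 23L), "stop_lost")              # TAA -> CAA
  expect_equal(cls("A", "G", 25L), "stop_retained_variant")  # TAA -> TAG
  expect_equal(cls("A", "C", 11L), "start_lost")             # ATG -> CTG
  expect_error(cls("T", "A", 7L), class = "contract_violation")
})

test_that("stop_retained keeps its dual parentage under the packaged SO", {
  toy <- toy_coding()
  dag <- so_dag_cached()
  term <- classify_coding_change(toy$tx, toy$genome, allele("A", "G"), 25L)
  expect_equal(term, "stop_retained_variant")
  expect_true(so_is_a(dag, term, "synonymous_variant"))
  expect_true(so_is_a(dag, term, "terminator_codon_variant"))
})

test_that("indel length arithmetic separates frameshift from inframe", {
  toy <- toy_coding()
  cls <- function(ref, alt, pos)
    classify_coding_change(toy$tx, toy$genome, allele(ref, alt), pos)
  expect_equal(cls("GC", "-", 14L), "frameshift_variant")
  expect_equal(cls("GCC", "-", 14L), "inframe_deletion")
  expect_equal(cls("-", "AAA", 14L), "inframe_insertion")
  expect_equal(cls("-", "AAAA", 14L), "frameshift_variant")
  expect_equal(cls("G", "GTT", 14L), "frameshift_variant")  # length-changing substitution
})

test_that("codons containing N yield an undetermined coding call", {
  toy <- toy_coding()
  g <- toy$genome
  substr(g[["chrZ"]], 15L, 15L) <- "N"
  expect_equal(classify_coding_change(toy$tx, g, allele("G", "A"), 14L),
               "coding_sequence_variant")
})

test_that("splice windows: cores, region bases and strand flips", {
  # exons 1..20, 41..60; intron 21..40
  mk <- function(strand) transcript_model("t", "g", "chrZ", strand, "mRNA",
                                          exons = rbind(c(1L, 20L), c(41L, 60L)))
  cfg <- consequence_config()
  expect_equal(classify_splice(mk("+"), c(21L, 21L), cfg), "splice_donor_variant")
  expect_equal(classify_splice(mk("+"), c(22L, 22L), cfg), "splice_donor_variant")
  expect_equal(classify_splice(mk("+"), c(40L, 40L), cfg), "splice_acceptor_variant")
  # intron base 5 is splice region under the default 3..8 window
  expect_equal(classify_splice(mk("+"), c(25L, 25L), cfg), "splice_region_variant")
  expect_equal(classify_splice(mk("+"), c(28L, 28L), cfg), "splice_region_variant")
  expect_length(classify_splice(mk("+"), c(29L, 29L), cfg), 0L)
  # exonic bases 1-3 next to the boundary are splice region
  expect_equal(classify_splice(mk("+"), c(19L, 19L), cfg), "splice_region_variant")
  expect_length(classify_splice(mk("+"), c(17L, 17L), cfg), 0L)
  # minus strand: donor at the intron's two highest coordinates
  expect_equal(classify_splice(mk("-"), c(40L, 40L), cfg), "splice_donor_variant")
  expect_equal(classify_splice(mk("-"), c(39L, 39L), cfg), "splice_donor_variant")
  expect_equal(classify_splice(mk("-"), c(21L, 21L), cfg), "splice_acceptor_variant")
  # the window is configurable
  wide <- consequence_config(splice_region_intron = 12L)
  expect_equal(classify_splice(mk("+"), c(31L, 31L), wide), "splice_region_variant")
})

test_that("span-scale rules over the interval relations", {
  dag <- so_dag_cached()
  f <- c(100L, 900L)
  expect_equal(classify_span(c(1L, 1000L), f, "deletion", dag),
               "transcript_ablation")
  # boundary-inclusive containment
  expect_equal(classify_span(c(100L, 900L), f, "deletion", dag),
               "transcript_ablation")
  expect_equal(classify_span(c(50L, 150L), f, "deletion", dag),
               "feature_truncation")
  expect_equal(classify_span(c(850L, 950L), f, "deletion", dag),
               "feature_truncation")
  expect_null(classify_span(c(200L, 300L), f, "deletion", dag))  # interior
  expect_null(classify_span(c(1L, 50L), f, "deletion", dag))     # disjoint
  expect_equal(classify_span(c(50L, 950L), f, "copy_number_gain", dag),
               "transcript_amplification")
  expect_equal(classify_span(c(200L, 300L), f, "tandem_duplication", dag),
               "feature_elongation")
  # plain insertions never trigger span-scale terms
  expect_null(classify_span(c(200L, 200L), f, "insertion", dag))
  expect_equal(classify_span(c(50L, 950L), f, "deletion", dag,
                             feature_kind = "regulatory_region"),
               "regulatory_region_ablation")
})

test_that("span classification agrees with relation enumeration for deletions", {
  dag <- so_dag_cached()
  f <- c(10L, 20L)
  # enumerate all interval placements around the feature
  for (s in 1:25) for (e in s:26) {
    got <- classify_span(c(s, e), f, "deletion", dag)
    expected <- if (e < f[1] || s > f[2]) NULL
                else if (s <= f[1] && e >= f[2]) "transcript_ablation"
                else if (s < f[1] || e > f[2]) "feature_truncation"
                else NULL
    expect_identical(got, expected,
                     info = sprintf("deletion %d..%d", s, e))
  }
})

test_that("UTR and non-coding placements classify positionally", {
  toy <- toy_coding()  # exon 6..30, CDS 11..25
  expect_equal(classify_noncoding(toy$tx, c(8L, 8L)), "5_prime_UTR_variant")
  expect_equal(classify_noncoding(toy$tx, c(28L, 28L)), "3_prime_UTR_variant")
  minus <- transcript_model("m", "g", "chrZ", "-", "mRNA",
                            exons = rbind(c(6L, 30L)), cds = rbind(c(11L, 25L)))
  expect_equal(classify_noncoding(minus, c(28L, 28L)), "5_prime_UTR_variant")
  nc <- transcript_model("n", "g", "chrZ", "+", "ncRNA",
                         exons = rbind(c(1L, 20L), c(41L, 60L)))
  expect_equal(classify_noncoding(nc, c(10L, 10L)),
               "non_coding_transcript_exon_variant")
  expect_equal(classify_noncoding(nc, c(30L, 30L)), "intron_variant")
  mir <- transcript_model("mi", "g", "chrZ", "+", "miRNA",
                          exons = rbind(c(1L, 22L)))
  expect_equal(classify_noncoding(mir, c(10L, 10L)), "mature_miRNA_variant")
})

test_that("one call per (allele, overlapping transcript); window rules beyond", {
  dag <- so_dag_cached()
  fx <- fixture_for_seed(1)
  # SNV in the CDS-bearing middle exon of the two-isoform gene: exonic for
  # one transcript, intronic for the other
  gC <- Filter(function(g) g$id == "gC", fx$genes)[[1]]
  tx1 <- gC$transcripts[[1]]
  pos <- cds_to_genomic(tx1, 15L)
  ref <- substr(fx$genome[[gC$seqid]], pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[[1]]
  v <- variant_line(seqid = gC$seqid, type = "SNV", start = pos, end = pos,
                    attributes = list(list(tag = "ID", values = "q1"),
                                      list(tag = "Variant_seq", values = alt),
                                      list(tag = "Reference_seq", values = ref)))
  calls <- call_consequences(v, fx$genes, fx$genome, dag)
  expect_length(calls, 2L)
  by_tx <- setNames(lapply(calls, `[[`, "effect_terms"),
                    vapply(calls, `[[`, character(1), "feature_id"))
  expect_true("intron_variant" %in% by_tx[["gC.t2"]])
  expect_false("intron_variant" %in% by_tx[["gC.t1"]])

  # far from every gene: single intergenic call with no feature
  v2 <- variant_line(seqid = "chrT1", type = "SNV",
                     start = nchar(fx$genome[["chrT1"]]) - 200L,
                     end = nchar(fx$genome[["chrT1"]]) - 200L,
                     attributes = list(list(tag = "Variant_seq", values = "A"),
                                       list(tag = "Reference_seq", values = "C")))
  calls2 <- suppressWarnings(call_consequences(v2, fx$genes, fx$genome, dag))
  expect_length(calls2, 1L)
  expect_equal(calls2[[1]]$effect_terms, "intergenic_variant")
  expect_true(is.na(calls2[[1]]$feature_id))

  # deletion spanning an entire transcript
  gK <- Filter(function(g) g$id == "gK", fx$genes)[[1]]
  v3 <- variant_line(seqid = gK$seqid, type = "deletion",
                     start = gK$start - 10L, end = gK$end + 10L,
                     attributes = list(list(tag = "Variant_seq", values = "-"),
                                       list(tag = "Reference_seq", values = "~")))
  calls3 <- call_consequences(v3, fx$genes, fx$genome, dag)
  expect_length(calls3, 1L)
  expect_equal(calls3[[1]]$effect_terms, "transcript_ablation")
})

test_that("reference mismatches warn and defer to the genome", {
  dag <- so_dag_cached()
  fx <- fixture_for_seed(1)
  gA <- Filter(function(g) g$id == "gA", fx$genes)[[1]]
  tx <- gA$transcripts[[1]]
  pos <- cds_to_genomic(tx, 15L)
  truth_base <- substr(fx$genome[[gA$seqid]], pos, pos)
  wrong <- setdiff(c("A", "C", "G", "T"), truth_base)[[1]]
  alt <- setdiff(c("A", "C", "G", "T"), c(truth_base, wrong))[[1]]
  v <- variant_line(seqid = gA$seqid, type = "SNV", start = pos, end = pos,
                    attributes = list(list(tag = "Variant_seq", values = alt),
                                      list(tag = "Reference_seq", values = wrong)))
  expect_warning(calls <- call_consequences(v, fx$genes, fx$genome, dag),
                 "disagrees with genome")
  expect_length(calls, 1L)
})

test_that("coding exclusivity: a pair never mixes the mutually exclusive codon terms", {
  exclusive <- c("missense_variant", "synonymous_variant", "stop_gained",
                 "stop_lost", "stop_retained_variant")
  dag <- so_dag_cached()
  fx <- fixture_for_seed(3)
  ann <- annotate_document(fx$doc, fx$genes, fx$genome, dag)
  for (l in ann$lines) {
    for (cl in split_calls_by_pair(l)) {
      expect_lte(sum(cl %in% exclusive), 1L)
    }
  }
})

test_that("emitted terms stay inside the packaged Ensembl vocabulary", {
  dag <- so_dag_cached()
  vocab <- load_ensembl_vocabulary(dag)
  fx <- fixture_for_seed(2)
  ann <- annotate_document(fx$doc, fx$genes, fx$genome, dag)
  terms <- unlist(lapply(ann$lines, function(l)
    vapply(variant_effects(l), `[[`, character(1), "effect_term")))
  expect_true(all(terms %in% vocab$name))
  expect_true(all(vapply(terms, function(t)
    so_is_a(dag, t, "sequence_variant"), logical(1))))
})

test_that("most-severe mode collapses each line to one ranked term", {
  dag <- so_dag_cached()
  fx <- fixture_for_seed(1)
  cfg <- consequence_config(most_severe = TRUE)
  ann <- annotate_document(fx$doc, fx$genes, fx$genome, dag, cfg)
  vocab <- load_ensembl_vocabulary(dag)
  full <- annotate_document(fx$doc, fx$genes, fx$genome, dag)
  for (i in seq_along(ann$lines)) {
    terms <- unique(vapply(variant_effects(ann$lines[[i]]), `[[`,
                           character(1), "effect_term"))
    expect_length(terms, 1L)
    all_terms <- vapply(variant_effects(full$lines[[i]]), `[[`,
                        character(1), "effect_term")
    expect_equal(match(terms, vocab$name), min(match(all_terms, vocab$name)))
  }
})

test_that("annotating an empty document is the identity", {
  dag <- so_dag_cached()
  fx <- fixture_for_seed(1)
  empty <- gvf_document()
  out <- annotate_document(empty, fx$genes, fx$genome, dag)
  expect_length(out$lines, 0L)
})
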