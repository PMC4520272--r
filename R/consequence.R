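# Consequence calling: assign SO sequence_variant terms to each
# (variant allele, feature) pair.
#
# The SO separates the alteration (what changed in the sequence: SNV,
# insertion, deletion, substitution) from its effect on annotated reference
# features (sequence_variant terms). This engine implements both scales of
# effect: feature-internal rules (coding/splice/UTR/intron/non-coding) for
# alterations that fall within a feature, and whole-feature rules
# (ablation/amplification/truncation/elongation) for alterations whose
# extent rivals the feature itself.

#' Engine configuration
#'
#' @param gene_window Distance in bp around a gene within which a
#'   non-overlapping variant is called upstream/downstream rather than
#'   intergenic. Default 5000.
#' @param splice_region_exon Exonic bases adjacent to a splice site counted
#'   as splice region. Default 3.
#' @param splice_region_intron Intronic extent (bases from the exon/intron
#'   boundary) of the splice region; the first two bases are the
#'   donor/acceptor core. Default 8 (so intron bases 3-8 are splice region).
#' @param most_severe When TRUE, [annotate_document()] collapses each line's
#'   calls to the single most severe term, ranked by the packaged Ensembl
#'   vocabulary order.
#' @return A `consequence_config` list.
#' @export
consequence_config <- function(gene_window = 5000L, splice_region_exon = 3L,
                               splice_region_intron = 8L,
                               most_severe = FALSE) {
  structure(list(gene_window = as.integer(gene_window),
                 splice_region_exon = as.integer(splice_region_exon),
                 splice_region_intron = as.integer(splice_region_intron),
                 most_severe = isTRUE(most_severe)),
            class = "consequence_config")
}

#' Construct a variant allele
#'
#' @param reference_seq Reference bases, or `"-"` for an insertion, or `"~"`
#'   when the sequence is not spelled out (structural records).
#' @param variant_seq Alternate bases, `"-"` for a deletion, `"~"` for
#'   not-spelled-out.
#' @return An `Allele` with an inferred `alteration_type` of SNV, insertion,
#'   deletion or substitution (classification is by sequence lengths, not by
#'   any declared type).
#' @export
allele <- function(reference_seq, variant_seq) {
  ref <- toupper(reference_seq); var <- toupper(variant_seq)
  cls <- if (ref == "~" || var == "~") "structural"
         else if (var == "-") "deletion"
         else if (ref == "-") "insertion"
         else if (nchar(ref) == 1L && nchar(var) == 1L && ref != var) "SNV"
         else "substitution"
  if (cls == "substitution" && ref == var)
    stop_gvfkit("allele_error", "variant_seq equals reference_seq")
  structure(list(reference_seq = ref, variant_seq = var,
                 alteration_type = cls),
            class = "Allele")
}

overlaps <- function(as_, ae, bs, be) as_ <= be && ae >= bs
contains <- function(as_, ae, bs, be) as_ <= bs && ae >= be  # a contains b

type_is <- function(dag, type, ancestor) {
  tryCatch(so_is_a(dag, type, ancestor), error = function(e) FALSE)
}

#' Whole-feature (span-scale) classification
#'
#' A deletion fully containing a feature ablates it; a copy-gain alteration
#' (duplication or copy-number gain) fully containing it amplifies it; a
#' deletion overlapping but extending beyond a feature end truncates it; a
#' copy-gain alteration inside the feature elongates it. Containment is
#' boundary-inclusive on closed intervals. Returns `NULL` when the variant
#' lies within the feature and is the business of the finer rules.
#'
#' @param variant_interval,feature_interval Length-2 integer vectors
#'   (start, end), 1-based closed, same landmark.
#' @param alteration_type SO sequence_alteration term (column-3 type).
#' @param dag An `OntologyDAG`.
#' @param feature_kind `"transcript"` (default) or `"regulatory_region"`
#'   (hook for regulatory features).
#' @return A term name, or `NULL`.
#' @export
classify_span <- function(variant_interval, feature_interval, alteration_type,
                          dag, feature_kind = "transcript") {
  vs <- variant_interval[[1L]]; ve <- variant_interval[[2L]]
  fs <- feature_interval[[1L]]; fe <- feature_interval[[2L]]
  if (!overlaps(vs, ve, fs, fe)) return(NULL)
  del <- type_is(dag, alteration_type, "deletion") ||
         type_is(dag, alteration_type, "copy_number_loss")
  gain <- type_is(dag, alteration_type, "copy_number_gain") ||
          type_is(dag, alteration_type, "duplication")
  abl <- if (feature_kind == "regulatory_region") "regulatory_region_ablation"
         else "transcript_ablation"
  amp <- if (feature_kind == "regulatory_region") "regulatory_region_amplification"
         else "transcript_amplification"
  if (del && contains(vs, ve, fs, fe)) return(abl)
  if (gain && contains(vs, ve, fs, fe)) return(amp)
  if (del && (vs < fs || ve > fe)) return("feature_truncation")
  if (gain) return("feature_elongation")
  NULL
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Classify a coding change
#'
#' For same-length alterations (SNV/MNV) the affected codons are rebuilt
#' from the spliced CDS (strand-aware: alternate bases are complemented for
#' minus-strand transcripts) and the translated reference and alternate
#' amino acids compared: identical translation of a stop codon is
#' `stop_retained_variant`, otherwise `synonymous_variant`; destroying the
#' initiator ATG is `start_lost`; losing the terminator is `stop_lost`;
#' creating a stop is `stop_gained`; any other amino-acid change is
#' `missense_variant`. Indels are classified purely by length difference:
#' not a multiple of three is `frameshift_variant`, otherwise
#' `inframe_insertion`/`inframe_deletion`. Codons containing N are reported
#' as `coding_sequence_variant` (undetermined) rather than guessed.
#'
#' @param tx A coding `TranscriptModel`.
#' @param genome Genome from [read_genome_fasta()].
#' @param al An [allele()] (sequences on the plus strand of the landmark).
#' @param pos Genomic start position of the alteration; must map into the
#'   CDS for same-length alterations.
#' @return Character scalar, one SO term name.
#' @export
classify_coding_change <- function(tx, genome, al, pos) {
  ref_len <- if (al$reference_seq %in% c("-", "~", ".")) 0L else nchar(al$reference_seq)
  var_len <- if (al$variant_seq %in% c("-", "~", ".")) 0L else nchar(al$variant_seq)
  if (al$alteration_type == "structural" ||
      al$variant_seq %in% c("~", "."))
    return("coding_sequence_variant")
  delta <- var_len - ref_len
  if (delta != 0L) {
    if (abs(delta) %% 3L != 0L) return("frameshift_variant")
    return(if (delta > 0L) "inframe_insertion" else "inframe_deletion")
  }
  gpos <- seq.int(pos, pos + ref_len - 1L)
  offs <- vapply(gpos, function(p) genomic_to_cds(tx, p), integer(1))
  if (all(is.na(offs)))
    stop_gvfkit("contract_violation",
                sprintf("position %d does not map into the CDS of %s",
                        pos, tx$id))
  if (any(is.na(offs))) return("coding_sequence_variant")
  cds <- cds_sequence(tx, genome)
  mut <- strsplit(cds, "", fixed = TRUE)[[1L]]
  vbases <- strsplit(al$variant_seq, "", fixed = TRUE)[[1L]]
  for (i in seq_along(gpos)) {
    b <- if (tx$strand == "-") comp_base(vbases[[i]]) else vbases[[i]]
    mut[[offs[[i]] + 1L]] <- b
  }
  mut <- paste(mut, collapse = "")
  idx <- sort(unique(offs %/% 3L))
  ref_codons <- substring(cds, idx * 3L + 1L, idx * 3L + 3L)
  alt_codons <- substring(mut, idx * 3L + 1L, idx * 3L + 3L)
  if (any(grepl("N", c(ref_codons, alt_codons), fixed = TRUE)))
    return("coding_sequence_variant")
  ref_aa <- vapply(ref_codons, translate_codon, character(1))
  alt_aa <- vapply(alt_codons, translate_codon, character(1))
  if (identical(unname(ref_aa), unname(alt_aa))) {
    return(if ("*" %in% ref_aa) "stop_retained_variant" else "synonymous_variant")
  }
  if (0L %in% idx) {
    k <- match(0L, idx)
    if (ref_codons[[k]] == "ATG" && alt_codons[[k]] != "ATG")
      return("start_lost")
  }
  if ("*" %in% ref_aa && !("*" %in% alt_aa)) return("stop_lost")
  if ("*" %in% alt_aa && !("*" %in% ref_aa)) return("stop_gained")
  "missense_variant"
}

#' Classify splice-site proximity
#'
#' The donor core is the 2-bp region at the 5' (transcript-direction) end of
#' an intron — the lowest genomic coordinates for a plus-strand transcript,
#' the highest for minus strand. The acceptor core is the 2 bp at the 3'
#' end. The splice region extends over the adjacent
#' `splice_region_exon` exonic bases and intron bases 3..`splice_region_intron`.
#'
#' @param tx A `TranscriptModel` with at least one intron (no introns yields
#'   no hits).
#' @param variant_interval Length-2 integer vector (start, end).
#' @param config A [consequence_config()].
#' @return Character vector: subset of `splice_donor_variant`,
#'   `splice_acceptor_variant`, `splice_region_variant` (possibly empty).
#' @export
classify_splice <- function(tx, variant_interval,
                            config = consequence_config()) {
  vs <- variant_interval[[1L]]; ve <- variant_interval[[2L]]
  terms <- character(0)
  introns <- tx_introns(tx)
  ex_n <- config$splice_region_exon
  in_n <- config$splice_region_intron
  for (k in seq_len(nrow(introns))) {
    is_ <- introns[k, 1L]; ie <- introns[k, 2L]
    ilen <- ie - is_ + 1L
    low_core <- c(is_, min(is_ + 1L, ie))
    high_core <- c(max(ie - 1L, is_), ie)
    donor <- if (tx$strand == "-") high_core else low_core
    acceptor <- if (tx$strand == "-") low_core else high_core
    if (overlaps(vs, ve, donor[[1L]], donor[[2L]]))
      terms <- c(terms, "splice_donor_variant")
    if (overlaps(vs, ve, acceptor[[1L]], acceptor[[2L]]))
      terms <- c(terms, "splice_acceptor_variant")
    windows <- list()
    if (ilen > 4L) {
      # intronic region windows never reach into the opposite core
      windows <- c(windows,
                   list(c(is_ + 2L, min(is_ + in_n - 1L, ie - 2L)),
                        c(max(ie - in_n + 1L, is_ + 2L), ie - 2L)))
    }
    windows <- c(windows, list(c(is_ - ex_n, is_ - 1L), c(ie + 1L, ie + ex_n)))
    for (w in windows) {
      if (w[[1L]] <= w[[2L]] && overlaps(vs, ve, w[[1L]], w[[2L]]))
        terms <- c(terms, "splice_region_variant")
    }
  }
  unique(terms)
}

#' Classify a variant inside a transcript when no coding/splice rule fired
#'
#' Exonic positions 5' of the CDS (in transcript direction) are
#' `5_prime_UTR_variant`, 3' of it `3_prime_UTR_variant`; exonic positions
#' of non-coding transcripts are `non_coding_transcript_exon_variant`
#' (`mature_miRNA_variant` for miRNA features, whose annotated extent is the
#' mature product); everything else in the transcript is `intron_variant`.
#'
#' @param tx A `TranscriptModel` overlapping the variant.
#' @param variant_interval Length-2 integer vector (start, end).
#' @return Character scalar.
#' @export
classify_noncoding <- function(tx, variant_interval) {
  vs <- variant_interval[[1L]]; ve <- variant_interval[[2L]]
  in_exon <- any(vapply(seq_len(nrow(tx$exons)), function(k)
    overlaps(vs, ve, tx$exons[k, 1L], tx$exons[k, 2L]), logical(1)))
  if (!is_coding(tx)) {
    if (in_exon)
      return(if (tx$feature_type == "miRNA") "mature_miRNA_variant"
             else "non_coding_transcript_exon_variant")
    return("intron_variant")
  }
  if (in_exon) {
    cds_lo <- min(tx$cds[, 1L]); cds_hi <- max(tx$cds[, 2L])
    five_side <- if (tx$strand == "-") vs > cds_hi else ve < cds_lo
    return(if (five_side) "5_prime_UTR_variant" else "3_prime_UTR_variant")
  }
  "intron_variant"
}

# Terms for one (allele, transcript) pair. A span-scale term supersedes the
# interior rules; splice cores take precedence over coding terms, with both
# emitted only when the alteration separately covers CDS bases.
classify_pair <- function(tx, al, vs, ve, declared_type, genome, dag, config) {
  span <- classify_span(c(vs, ve), c(tx_start(tx), tx_end(tx)),
                        declared_type, dag)
  if (!is.null(span)) return(span)
  spl <- classify_splice(tx, c(vs, ve), config)
  core <- intersect(spl, c("splice_donor_variant", "splice_acceptor_variant"))
  coding_hit <- is_coding(tx) &&
    any(vapply(seq_len(nrow(tx$cds)), function(k)
      overlaps(vs, ve, tx$cds[k, 1L], tx$cds[k, 2L]), logical(1)))
  if (length(core)) {
    terms <- core
    if (coding_hit)
      terms <- c(terms, classify_coding_change(tx, genome, al, vs))
    return(sort(unique(terms)))
  }
  terms <- if (coding_hit) classify_coding_change(tx, genome, al, vs)
           else classify_noncoding(tx, c(vs, ve))
  if ("splice_region_variant" %in% spl)
    terms <- c(terms, "splice_region_variant")
  sort(unique(terms))
}

consequence_call <- function(variant_id, allele_index, feature_id,
                             feature_type, terms) {
  structure(list(variant_id = variant_id, allele_index = allele_index,
                 feature_id = feature_id, feature_type = feature_type,
                 effect_terms = terms),
            class = "ConsequenceCall")
}

#' Call SO consequence terms for one GVF variant line
#'
#' Emits one call per (alternate allele, overlapping transcript), plus one
#' upstream/downstream call per allele for each gene whose
#' `gene_window`-extended interval covers the variant without the gene
#' itself overlapping it. A variant overlapping nothing within the window
#' yields a single `intergenic_variant` call with no feature id. An SNV
#' intersecting two alternate transcripts — one in an exon, the other in an
#' intron — therefore yields two calls with different terms.
#'
#' When `Reference_seq` disagrees with the genome, a warning is emitted and
#' the genome base is used (the genome is ground truth).
#'
#' @param variant A `VariantLine`.
#' @param genes List of [gene_model()] objects.
#' @param genome Genome from [read_genome_fasta()].
#' @param dag An `OntologyDAG`.
#' @param config A [consequence_config()].
#' @return List of `ConsequenceCall` objects, ordered by feature id.
#' @export
call_consequences <- function(variant, genes, genome, dag,
                              config = consequence_config()) {
  vs <- variant$start; ve <- variant$end
  vid <- gvf_attr(variant, "ID")
  vid <- if (length(vid)) vid[[1L]] else NA_character_
  vseq <- gvf_attr(variant, "Variant_seq")
  ref <- gvf_attr(variant, "Reference_seq")
  ref <- if (length(ref)) toupper(ref[[1L]]) else "."

  # genome is ground truth for the reference bases
  if (!ref %in% c("-", "~", ".") && variant$seqid %in% names(genome)) {
    gref <- genome_subseq(genome, variant$seqid, vs, ve)
    if (!identical(ref, gref) && !grepl("N", gref, fixed = TRUE)) {
      warning(sprintf("%s: Reference_seq '%s' disagrees with genome '%s'; using genome",
                      ifelse(is.na(vid), variant$seqid, vid), ref, gref))
      ref <- gref
    }
  }

  alleles <- list()
  for (i in seq_along(vseq)) {
    v <- toupper(vseq[[i]])
    # "~" means sequence-same-as-reference (copy-number records): still an
    # allele; "." (unknown) and a spelled-out reference allele are not.
    if (v == "." || (identical(v, ref) && v != "~")) next
    alleles[[length(alleles) + 1L]] <-
      list(index = i - 1L, al = allele(ref, v))
  }
  if (!length(alleles)) return(list())

  seq_genes <- Filter(function(g) g$seqid == variant$seqid, genes)
  if (!length(seq_genes) &&
      !variant$seqid %in% vapply(genes, `[[`, character(1), "seqid"))
    warning(sprintf("landmark '%s' absent from gene set; calling intergenic",
                    variant$seqid))

  calls <- list()
  for (g in seq_genes) {
    if (overlaps(vs, ve, g$start, g$end)) {
      txs <- g$transcripts[order(vapply(g$transcripts, `[[`, character(1), "id"))]
      for (tx in txs) {
        if (!overlaps(vs, ve, tx_start(tx), tx_end(tx))) next
        for (a in alleles) {
          terms <- classify_pair(tx, a$al, vs, ve, variant$type,
                                 genome, dag, config)
          calls[[length(calls) + 1L]] <- consequence_call(
            vid, a$index, tx$id, tx$feature_type, terms)
        }
      }
    } else if (overlaps(vs, ve, g$start - config$gene_window,
                        g$end + config$gene_window)) {
      before <- ve < g$start
      term <- if ((g$strand == "+") == before) "upstream_gene_variant"
              else "downstream_gene_variant"
      for (a in alleles) {
        calls[[length(calls) + 1L]] <- consequence_call(
          vid, a$index, g$id, "gene", term)
      }
    }
  }
  if (!length(calls)) {
    for (a in alleles) {
      calls[[length(calls) + 1L]] <- consequence_call(
        vid, a$index, NA_character_, ".", "intergenic_variant")
    }
  }
  ord <- order(vapply(calls, function(c.) c.$feature_id %||% NA_character_,
                      character(1)),
               vapply(calls, `[[`, integer(1), "allele_index"))
  calls[ord]
}

#' Annotate every line of a GVF document with Variant_effect attributes
#'
#' Replaces any existing `Variant_effect` attributes with freshly computed
#' ones: one attribute per (effect term, allele index, feature type) group,
#' feature ids comma-joined and sorted. With `config$most_severe`, each
#' line is collapsed to the single most severe term using the packaged
#' Ensembl vocabulary order as the severity ranking.
#'
#' @inheritParams call_consequences
#' @param doc A [gvf_document()].
#' @return A new `GvfDocument` with the same pragmas and annotated lines.
#' @export
annotate_document <- function(doc, genes, genome, dag,
                              config = consequence_config()) {
  vocab <- load_ensembl_vocabulary(dag)
  new_lines <- lapply(doc$lines, function(l) {
    calls <- call_consequences(l, genes, genome, dag, config)
    recs <- list()
    for (cl in calls) {
      for (t in cl$effect_terms) {
        key <- paste(t, cl$allele_index, cl$feature_type, sep = "\r")
        recs[[key]] <- c(recs[[key]], cl$feature_id)
      }
    }
    if (config$most_severe && length(recs)) {
      term_of <- vapply(strsplit(names(recs), "\r", fixed = TRUE),
                        `[[`, character(1), 1L)
      sev <- match(term_of, vocab$name)
      keep <- term_of == term_of[[which.min(sev)]]
      recs <- recs[keep]
    }
    keys <- sort(names(recs))
    effs <- lapply(keys, function(k) {
      p <- strsplit(k, "\r", fixed = TRUE)[[1L]]
      ids <- sort(unique(recs[[k]][!is.na(recs[[k]])]))
      list(tag = "Variant_effect",
           values = paste(p[[1L]], p[[2L]], p[[3L]],
                          if (length(ids)) paste(ids, collapse = ",") else "."))
    })
    l$attributes <- c(Filter(function(a) a$tag != "Variant_effect",
                             l$attributes), effs)
    l
  })
  gvf_document(pragmas = doc$pragmas, lines = new_lines)
}
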