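# Variant planting with by-construction ground truth.
#
# Candidate sites are found by scanning the designed gene models (codons
# against the genetic code, intron ends for splice cores, UTR/exon interiors
# for positional terms). Each candidate is then validated against the whole
# layout: every other transcript or window-proximal gene the footprint
# touches must classify cleanly (interior intron, clean exon of a
# non-coding transcript, clean UTR), and those side effects are recorded in
# the ground truth. Ambiguous placements are rejected, so the recorded
# truth is forced by construction, not by running the consequence engine.

all_tx <- function(genes) {
  out <- list()
  for (g in genes) for (tx in g$transcripts)
    out[[length(out) + 1L]] <- list(gene = g, tx = tx)
  ord <- order(vapply(out, function(e) e$tx$seqid, character(1)),
               vapply(out, function(e) tx_start(e$tx), integer(1)),
               vapply(out, function(e) e$tx$id, character(1)))
  out[ord]
}

# is [vs,ve] inside an exon of tx with >= 3 bp clearance from any
# intron-adjacent exon edge?
exon_margin_ok <- function(tx, vs, ve, margin = 3L) {
  n <- nrow(tx$exons)
  for (j in seq_len(n)) {
    es <- tx$exons[j, 1L]; ee <- tx$exons[j, 2L]
    if (vs >= es && ve <= ee) {
      lo <- if (j > 1L) es + margin else es
      hi <- if (j < n) ee - margin else ee
      return(vs >= lo && ve <= hi)
    }
  }
  FALSE
}

# Conservative side classification used for companion transcripts: returns
# a single term when the footprint is unambiguous for tx, else NULL.
side_classify <- function(tx, vs, ve, intron_clear = 8L) {
  introns <- tx_introns(tx)
  for (k in seq_len(nrow(introns))) {
    is_ <- introns[k, 1L]; ie <- introns[k, 2L]
    if (vs >= is_ && ve <= ie) {
      if (vs >= is_ + intron_clear && ve <= ie - intron_clear)
        return("intron_variant")
      return(NULL)
    }
  }
  if (!exon_margin_ok(tx, vs, ve)) return(NULL)
  if (!is_coding(tx)) {
    return(if (tx$feature_type == "miRNA") "mature_miRNA_variant"
           else "non_coding_transcript_exon_variant")
  }
  cds_lo <- min(tx$cds[, 1L]); cds_hi <- max(tx$cds[, 2L])
  if (ve < cds_lo || vs > cds_hi) {
    five <- if (tx$strand == "-") vs > cds_hi else ve < cds_lo
    return(if (five) "5_prime_UTR_variant" else "3_prime_UTR_variant")
  }
  NULL
}

# Validate a footprint against the whole layout. Returns the complete list
# of companion (term, feature) pairs beyond the target transcripts, or NULL
# when any touched feature cannot be classified cleanly.
companion_pairs <- function(seqid, vs, ve, genes, target_tx_ids,
                            window = 5000L) {
  pairs <- list()
  for (g in genes) {
    if (g$seqid != seqid) next
    if (overlaps(vs, ve, g$start, g$end)) {
      for (tx in g$transcripts) {
        if (tx$id %in% target_tx_ids) next
        if (!overlaps(vs, ve, tx_start(tx), tx_end(tx))) next
        t <- side_classify(tx, vs, ve)
        if (is.null(t)) return(NULL)
        pairs[[length(pairs) + 1L]] <- c(t, tx$id)
      }
    } else if (overlaps(vs, ve, g$start - window, g$end + window)) {
      before <- ve < g$start
      term <- if ((g$strand == "+") == before) "upstream_gene_variant"
              else "downstream_gene_variant"
      pairs[[length(pairs) + 1L]] <- c(term, g$id)
    }
  }
  pairs
}

local_codon_term <- function(cds, offset, alt_base) {
  ci <- offset %/% 3L
  codon <- substr(cds, ci * 3L + 1L, ci * 3L + 3L)
  altc <- codon
  substr(altc, offset %% 3L + 1L, offset %% 3L + 1L) <- alt_base
  aa_ref <- Biostrings::GENETIC_CODE[[codon]]
  aa_alt <- Biostrings::GENETIC_CODE[[altc]]
  if (is.null(aa_ref) || is.null(aa_alt)) return(NA_character_)
  if (aa_ref == aa_alt)
    return(if (aa_ref == "*") "stop_retained_variant" else "synonymous_variant")
  if (ci == 0L && codon == "ATG") return("start_lost")
  if (aa_ref == "*") return("stop_lost")
  if (aa_alt == "*") return("stop_gained")
  "missense_variant"
}

new_candidate <- function(seqid, start, end, type, ref, alt, pairs, group) {
  list(seqid = seqid, start = start, end = end, type = type,
       ref = ref, alt = alt, pairs = pairs, group = group)
}

# pairs: list of c(term, feature); target first, then companions
finish_candidate <- function(cand, target_pairs, genes, target_tx_ids) {
  comp <- companion_pairs(cand$seqid, cand$start, cand$end, genes,
                          target_tx_ids)
  if (is.null(comp)) return(NULL)
  cand$pairs <- c(target_pairs, comp)
  cand
}

pick_alt <- function(ref_base) BASES[BASES != ref_base][[1L]]

# Enumerate candidates for every term, grouped by transcript (round-robin
# planting spreads counts > 1 across transcripts). cap = candidates kept
# per (term, transcript).
enumerate_candidates <- function(genes, genome, cap = 3L) {
  cands <- list()  # term -> group key -> list of candidates
  keep <- function(term, cand) {
    if (is.null(cand)) return(invisible(NULL))
    grp <- cand$group
    have <- length(cands[[term]][[grp]] %||% list())
    if (have >= cap) return(invisible(NULL))
    cands[[term]][[grp]] <<- c(cands[[term]][[grp]] %||% list(), list(cand))
    invisible(NULL)
  }

  entries <- all_tx(genes)
  coding <- Filter(function(e) is_coding(e$tx), entries)
  noncod <- Filter(function(e) !is_coding(e$tx), entries)

  snv_terms <- c("missense_variant", "synonymous_variant", "stop_gained",
                 "stop_lost", "stop_retained_variant", "start_lost")

  for (e in coding) {
    tx <- e$tx
    cds <- cds_sequence(tx, genome)
    L <- nchar(cds)
    full <- function(term) length(cands[[term]][[tx$id]] %||% list()) >= cap
    for (o in seq_len(L) - 1L) {
      if (all(vapply(snv_terms, full, logical(1)))) break
      p <- cds_to_genomic(tx, o)
      if (!exon_margin_ok(tx, p, p)) next
      ref_tx <- substr(cds, o + 1L, o + 1L)
      for (alt_tx in BASES[BASES != ref_tx]) {
        term <- local_codon_term(cds, o, alt_tx)
        if (is.na(term) || !term %in% snv_terms || full(term)) next
        ref_plus <- genome_subseq(genome, tx$seqid, p, p)
        alt_plus <- if (tx$strand == "-") comp_base(alt_tx) else alt_tx
        keep(term, finish_candidate(
          new_candidate(tx$seqid, p, p, "SNV", ref_plus, alt_plus,
                        NULL, tx$id),
          list(c(term, tx$id)), genes, tx$id))
      }
    }

    # dinucleotide substitution (MNV) missense sites, plus strand only
    if (tx$strand == "+") {
      n_codon <- L %/% 3L
      for (ci in seq_len(max(0L, n_codon - 2L))) {  # skip initiator codon
        if (length(cands[["mnv_missense"]][[tx$id]] %||% list()) >= 1L) break
        o1 <- 3L * ci
        p1 <- cds_to_genomic(tx, o1)
        if (cds_to_genomic(tx, o1 + 1L) != p1 + 1L) next
        if (!exon_margin_ok(tx, p1, p1 + 1L)) next
        codon <- substr(cds, o1 + 1L, o1 + 3L)
        if (Biostrings::GENETIC_CODE[[codon]] == "*") next
        for (alt2 in c("AA", "CC", "GG", "TT", "CA", "AC")) {
          altc <- codon
          substr(altc, 1L, 2L) <- alt2
          if (altc == codon) next
          aa_ref <- Biostrings::GENETIC_CODE[[codon]]
          aa_alt <- Biostrings::GENETIC_CODE[[altc]]
          if (is.null(aa_alt) || aa_alt == aa_ref || aa_alt == "*") next
          keep("mnv_missense", finish_candidate(
            new_candidate(tx$seqid, p1, p1 + 1L, "substitution",
                          substr(codon, 1L, 2L), alt2, NULL, tx$id),
            list(c("missense_variant", tx$id)), genes, tx$id))
          break
        }
      }
    }

    # CDS-internal indels: 2 bp deletion (frameshift), 3 bp deletion and
    # 3 bp insertion (inframe)
    indels <- list(
      list(term = "frameshift_variant", len = 2L, kind = "del"),
      list(term = "inframe_deletion", len = 3L, kind = "del"),
      list(term = "inframe_insertion", len = 1L, kind = "ins"))
    for (sp in indels) {
      for (o in seq(9L, max(9L, L - 12L))) {
        if (length(cands[[sp$term]][[tx$id]] %||% list()) >= 1L) break
        ps <- vapply(seq_len(sp$len) - 1L, function(d)
          cds_to_genomic(tx, o + d), integer(1))
        lo <- min(ps); hi <- max(ps)
        if (hi - lo + 1L != sp$len) next   # must be exon-contiguous
        if (!exon_margin_ok(tx, lo, hi, margin = 4L)) next
        cand <- if (sp$kind == "del") {
          new_candidate(tx$seqid, lo, hi, "deletion",
                        genome_subseq(genome, tx$seqid, lo, hi), "-",
                        NULL, tx$id)
        } else {
          new_candidate(tx$seqid, lo, hi, "insertion", "-", "GGG",
                        NULL, tx$id)
        }
        keep(sp$term, finish_candidate(cand, list(c(sp$term, tx$id)),
                                       genes, tx$id))
      }
    }

    # UTR SNVs
    cds_lo <- min(tx$cds[, 1L]); cds_hi <- max(tx$cds[, 2L])
    for (j in seq_len(nrow(tx$exons))) {
      for (p in seq(tx$exons[j, 1L], tx$exons[j, 2L])) {
        if (p >= cds_lo && p <= cds_hi) next
        term <- if ((tx$strand == "+") == (p < cds_lo)) "5_prime_UTR_variant"
                else "3_prime_UTR_variant"
        if (length(cands[[term]][[tx$id]] %||% list()) >= cap) next
        if (!exon_margin_ok(tx, p, p)) next
        ref <- genome_subseq(genome, tx$seqid, p, p)
        keep(term, finish_candidate(
          new_candidate(tx$seqid, p, p, "SNV", ref, pick_alt(ref),
                        NULL, tx$id),
          list(c(term, tx$id)), genes, tx$id))
      }
    }
  }

  # splice and intron candidates (coding or not)
  for (e in entries) {
    tx <- e$tx
    introns <- tx_introns(tx)
    for (k in seq_len(nrow(introns))) {
      is_ <- introns[k, 1L]; ie <- introns[k, 2L]
      donor <- if (tx$strand == "-") c(ie, ie - 1L) else c(is_, is_ + 1L)
      acceptor <- if (tx$strand == "-") c(is_, is_ + 1L) else c(ie, ie - 1L)
      for (p in donor) {
        ref <- genome_subseq(genome, tx$seqid, p, p)
        keep("splice_donor_variant", finish_candidate(
          new_candidate(tx$seqid, p, p, "SNV", ref, pick_alt(ref),
                        NULL, tx$id),
          list(c("splice_donor_variant", tx$id)), genes, tx$id))
      }
      for (p in acceptor) {
        ref <- genome_subseq(genome, tx$seqid, p, p)
        keep("splice_acceptor_variant", finish_candidate(
          new_candidate(tx$seqid, p, p, "SNV", ref, pick_alt(ref),
                        NULL, tx$id),
          list(c("splice_acceptor_variant", tx$id)), genes, tx$id))
      }
      # intron base 5 on the donor side: splice region + intron
      p5 <- if (tx$strand == "-") ie - 4L else is_ + 4L
      ref <- genome_subseq(genome, tx$seqid, p5, p5)
      keep("splice_region_variant", finish_candidate(
        new_candidate(tx$seqid, p5, p5, "SNV", ref, pick_alt(ref),
                      NULL, tx$id),
        list(c("splice_region_variant", tx$id), c("intron_variant", tx$id)),
        genes, tx$id))
      # deep intron
      mid <- (is_ + ie) %/% 2L
      if (mid >= is_ + 8L && mid <= ie - 8L) {
        ref <- genome_subseq(genome, tx$seqid, mid, mid)
        keep("intron_variant", finish_candidate(
          new_candidate(tx$seqid, mid, mid, "SNV", ref, pick_alt(ref),
                        NULL, tx$id),
          list(c("intron_variant", tx$id)), genes, tx$id))
      }
    }
  }

  # exonic SNVs in non-coding transcripts
  for (e in noncod) {
    tx <- e$tx
    term <- if (tx$feature_type == "miRNA") "mature_miRNA_variant"
            else "non_coding_transcript_exon_variant"
    for (j in seq_len(nrow(tx$exons))) {
      for (p in seq(tx$exons[j, 1L], tx$exons[j, 2L])) {
        if (length(cands[[term]][[tx$id]] %||% list()) >= cap) break
        if (!exon_margin_ok(tx, p, p)) next
        ref <- genome_subseq(genome, tx$seqid, p, p)
        keep(term, finish_candidate(
          new_candidate(tx$seqid, p, p, "SNV", ref, pick_alt(ref),
                        NULL, tx$id),
          list(c(term, tx$id)), genes, tx$id))
      }
    }
  }

  # whole-feature events on single-transcript genes
  for (g in genes) {
    if (length(g$transcripts) != 1L) next
    tx <- g$transcripts[[1L]]
    span <- list(
      list(term = "transcript_ablation", type = "deletion",
           s = g$start - 100L, e = g$end + 100L, ref = "~", alt = "-"),
      list(term = "transcript_amplification", type = "copy_number_gain",
           s = g$start - 100L, e = g$end + 100L, ref = "~", alt = "~"),
      list(term = "feature_truncation", type = "deletion",
           s = g$start - 50L, e = g$start + 30L, ref = "~", alt = "-"),
      list(term = "feature_elongation", type = "tandem_duplication",
           s = g$start + 50L, e = g$start + 150L, ref = "~", alt = "~"))
    for (sp in span) {
      if (sp$s < 1L || sp$e <= sp$s || sp$e > g$end + 100L) next
      if (sp$term == "feature_elongation" && sp$e >= g$end) next
      if (sp$term == "feature_truncation" && sp$e >= g$end) next
      keep(sp$term, finish_candidate(
        new_candidate(g$seqid, sp$s, sp$e, sp$type, sp$ref, sp$alt,
                      NULL, g$id),
        list(c(sp$term, tx$id)), genes, tx$id))
    }
  }

  # proximal (upstream/downstream) and intergenic
  for (g in genes) {
    up_pos <- if (g$strand == "+") g$start - 1500L else g$end + 1500L
    dn_pos <- if (g$strand == "+") g$end + 1500L else g$start - 1500L
    for (sp in list(list(term = "upstream_gene_variant", p = up_pos),
                    list(term = "downstream_gene_variant", p = dn_pos))) {
      if (sp$p < 1L) next
      comp <- companion_pairs(g$seqid, sp$p, sp$p, genes, character(0))
      if (is.null(comp) || length(comp) != 1L) next
      if (!identical(comp[[1L]], c(sp$term, g$id))) next
      ref <- tryCatch(genome_subseq(genome, g$seqid, sp$p, sp$p),
                      error = function(e.) NULL)
      if (is.null(ref)) next
      cand <- new_candidate(g$seqid, sp$p, sp$p, "SNV", ref, pick_alt(ref),
                            comp, g$id)
      cands[[sp$term]][[g$id]] <- c(cands[[sp$term]][[g$id]] %||% list(),
                                    list(cand))
    }
  }
  for (seqid in names(genome)) {
    p <- nchar(genome[[seqid]]) - 500L
    comp <- companion_pairs(seqid, p, p, genes, character(0))
    if (is.null(comp) || length(comp)) next
    ref <- genome_subseq(genome, seqid, p, p)
    cand <- new_candidate(seqid, p, p, "SNV", ref, pick_alt(ref),
                          list(c("intergenic_variant", ".")), seqid)
    cands[["intergenic_variant"]][[seqid]] <-
      c(cands[["intergenic_variant"]][[seqid]] %||% list(), list(cand))
    break
  }

  cands
}

round_robin <- function(groups, n) {
  out <- list()
  depth <- 1L
  while (length(out) < n) {
    added <- FALSE
    for (grp in groups) {
      if (length(out) >= n) break
      if (length(grp) >= depth) {
        out[[length(out) + 1L]] <- grp[[depth]]
        added <- TRUE
      }
    }
    if (!added) break
    depth <- depth + 1L
  }
  out
}

#' Plant variants with known consequences into the fixture layout
#'
#' For every effect term in `spec$plan`, places the requested number of
#' variants at sites where the consequence is forced by construction
#' (third-position degeneracy for synonymous sites, the intron's first base
#' for donor sites, a deletion spanning a whole transcript for ablation,
#' ...), spreading counts across transcripts, strands and landmarks. One
#' missense placement is emitted as a dinucleotide substitution so all four
#' alteration classes appear in the output.
#'
#' @param spec A [fixture_spec()].
#' @param genes Gene models from [make_genome_and_genes()].
#' @param genome Named genome vector from [make_genome_and_genes()].
#' @return List: `gvf` (character lines), `doc` (the `GvfDocument`),
#'   `truth` (named list, variant id -> data.frame(term, feature_id) of the
#'   complete expected consequence set).
#' @export
plant_variants <- function(spec, genes, genome) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed + 1000003L)

  vocab <- load_ensembl_vocabulary()
  bad <- setdiff(names(spec$plan), vocab$name)
  if (length(bad))
    stop_gvfkit("spec_error",
                sprintf("plan terms not in packaged vocabulary: %s",
                        paste(bad, collapse = ", ")))

  cands <- enumerate_candidates(genes, genome)
  chosen <- list()
  for (term in names(spec$plan)) {
    n <- spec$plan[[term]]
    if (n == 0L) next
    if (term == "missense_variant") {
      n_mnv <- min(1L, n)
      picked <- round_robin(cands[["missense_variant"]] %||% list(),
                            n - n_mnv)
      picked <- c(picked, round_robin(cands[["mnv_missense"]] %||% list(),
                                      n_mnv))
    } else {
      picked <- round_robin(cands[[term]] %||% list(), n)
    }
    if (length(picked) < n)
      stop_gvfkit("placement_error",
                  sprintf("could not place %d variant(s) for term '%s' (found %d)",
                          n, term, length(picked)))
    chosen <- c(chosen, picked)
  }

  ord <- order(vapply(chosen, `[[`, character(1), "seqid"),
               vapply(chosen, `[[`, integer(1), "start"),
               vapply(chosen, `[[`, integer(1), "end"))
  chosen <- chosen[ord]

  lines <- list()
  truth <- list()
  for (i in seq_along(chosen)) {
    cd <- chosen[[i]]
    vid <- sprintf("var%04d", i)
    lines[[i]] <- variant_line(
      seqid = cd$seqid, source = "gvfkit_fixture", type = cd$type,
      start = cd$start, end = cd$end, strand = "+",
      attributes = list(
        list(tag = "ID", values = vid),
        list(tag = "Variant_seq", values = cd$alt),
        list(tag = "Reference_seq", values = cd$ref)))
    truth[[vid]] <- data.frame(
      term = vapply(cd$pairs, `[[`, character(1), 1L),
      feature_id = vapply(cd$pairs, `[[`, character(1), 2L),
      stringsAsFactors = FALSE)
  }
  doc <- gvf_document(
    pragmas = data.frame(name = c("gvf-version", "genome-build"),
                         value = c("1.07", "gvfkit synthetic 1"),
                         stringsAsFactors = FALSE),
    lines = lines)
  list(gvf = write_gvf(doc), doc = doc, truth = truth)
}

#' Write a complete fixture set to a directory
#'
#' Emits `ref.fa`, `genes.gff3`, `variants.gvf` and `truth.json`.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [fixture_spec()].
#' @return Invisibly, the list from [plant_variants()] plus `genes` and
#'   `genome`.
#' @export
write_fixture_set <- function(dir, spec = fixture_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mk <- make_genome_and_genes(spec)
  pl <- plant_variants(spec, mk$genes, mk$genome)
  writeLines(mk$fasta, file.path(dir, "ref.fa"))
  writeLines(mk$gff3, file.path(dir, "genes.gff3"))
  writeLines(pl$gvf, file.path(dir, "variants.gvf"))
  jsonlite::write_json(
    lapply(pl$truth, function(df)
      lapply(seq_len(nrow(df)), function(k)
        list(term = df$term[[k]], feature_id = df$feature_id[[k]]))),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(c(pl, list(genes = mk$genes, genome = mk$genome)))
}
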