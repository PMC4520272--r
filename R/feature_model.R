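# Reference gene models and strand-aware coordinate arithmetic.
#
# A TranscriptModel holds sorted, disjoint exon intervals and (for coding
# transcripts) CDS intervals nested within them, all 1-based fully closed on
# the genomic landmark. The mapping genomic position <-> spliced CDS offset
# <-> codon is the workhorse behind coding consequence calls.

TRANSCRIPT_TYPES <- c("mRNA", "transcript", "primary_transcript", "miRNA",
                      "ncRNA", "lnc_RNA")

#' Read a reference genome from FASTA
#'
#' @param path Multi-record, line-wrapped FASTA.
#' @return Named character vector, landmark id -> uppercase sequence.
#'   Record names are truncated at the first whitespace.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

genome_subseq <- function(genome, seqid, start, end) {
  if (!seqid %in% names(genome))
    stop_gvfkit("lookup_error", sprintf("landmark '%s' not in genome", seqid))
  n <- nchar(genome[[seqid]])
  if (start < 1L || end > n)
    stop_gvfkit("lookup_error",
                sprintf("coordinates %d..%d beyond landmark '%s' (length %d)",
                        start, end, seqid, n))
  substr(genome[[seqid]], start, end)
}

revcomp <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

comp_base <- function(x) chartr("ACGTNacgtn", "TGCANtgcan", x)

#' Construct a transcript model
#'
#' @param id Transcript id.
#' @param gene_id Parent gene id.
#' @param seqid Landmark id.
#' @param strand `"+"` or `"-"`.
#' @param feature_type One of mRNA, transcript, primary_transcript, miRNA,
#'   ncRNA (lnc_RNA is normalized to ncRNA on load).
#' @param exons Two-column matrix (start, end), 1-based closed; sorted and
#'   non-overlapping.
#' @param cds Two-column matrix of CDS segments nested within exons; zero
#'   rows for non-coding transcripts.
#' @param phase Phase of the first CDS segment in transcript order (leading
#'   bases trimmed before translation).
#' @return A `TranscriptModel`.
#' @export
transcript_model <- function(id, gene_id, seqid, strand, feature_type,
                             exons, cds = matrix(integer(0), ncol = 2),
                             phase = 0L) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] <= exons[-nrow(exons), 2L]))
    stop_gvfkit("model_error", sprintf("transcript %s: overlapping exons", id))
  cds <- matrix(as.integer(cds), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
  cds <- cds[order(cds[, 1L]), , drop = FALSE]
  for (k in seq_len(nrow(cds))) {
    inside <- any(exons[, 1L] <= cds[k, 1L] & cds[k, 2L] <= exons[, 2L])
    if (!inside)
      stop_gvfkit("model_error",
                  sprintf("transcript %s: CDS %d..%d outside exons",
                          id, cds[k, 1L], cds[k, 2L]))
  }
  structure(list(id = id, gene_id = gene_id, seqid = seqid, strand = strand,
                 feature_type = feature_type, exons = exons, cds = cds,
                 phase = as.integer(phase)),
            class = "TranscriptModel")
}

tx_start <- function(tx) tx$exons[1L, 1L]
tx_end <- function(tx) tx$exons[nrow(tx$exons), 2L]
is_coding <- function(tx) nrow(tx$cds) > 0L

#' Construct a gene model
#' @param id Gene id.
#' @param seqid Landmark id.
#' @param strand `"+"` or `"-"`.
#' @param start,end Genomic extent (1-based closed).
#' @param transcripts List of [transcript_model()] objects.
#' @return A `GeneModel`.
#' @export
gene_model <- function(id, seqid, strand, start, end, transcripts) {
  for (tx in transcripts) {
    if (tx_start(tx) < start || tx_end(tx) > end)
      stop_gvfkit("model_error",
                  sprintf("gene %s: transcript %s outside gene interval",
                          id, tx$id))
  }
  structure(list(id = id, seqid = seqid, strand = strand,
                 start = as.integer(start), end = as.integer(end),
                 transcripts = transcripts),
            class = "GeneModel")
}

#' Read gene models from GFF3
#'
#' Assembles the gene -> transcript -> exon/CDS hierarchy linked by
#' ID/Parent attributes. Recognized transcript-level types are mRNA,
#' transcript, primary_transcript, miRNA, ncRNA and lnc_RNA (normalized to
#' ncRNA); other children of genes are skipped with a warning. A transcript
#' with no exon rows gets a single exon covering its extent. A `Parent`
#' referencing an unknown `ID` raises a `linkage_error`; a CDS segment not
#' nested in an exon raises a `model_error`.
#'
#' @param x Path to a GFF3 file, or a character vector of GFF3 lines.
#' @return List of [gene_model()] objects, sorted by (seqid, start).
#' @export
read_gff3_genes <- function(x) {
  path <- x
  if (length(x) > 1L || grepl("\n", x[[1L]], fixed = TRUE) || !file.exists(x)) {
    path <- tempfile(fileext = ".gff3")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(x, "\n", fixed = TRUE)), path)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(md)) as.list(md$Parent)
             else vector("list", length(gr))
  phase0 <- if ("phase" %in% names(md)) md$phase else rep(NA_integer_, length(gr))

  seqid <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  start <- GenomicRanges::start(gr)
  end <- GenomicRanges::end(gr)

  gene_rows <- which(type == "gene")
  known_ids <- ids[!is.na(ids)]
  gene_ids <- ids[gene_rows]

  tx_rows <- which(type %in% TRANSCRIPT_TYPES)
  tx_parent <- vapply(tx_rows, function(r) {
    p <- unlist(parents[[r]])
    if (!length(p)) NA_character_ else p[[1L]]
  }, character(1))
  bad <- tx_parent[!is.na(tx_parent) & !(tx_parent %in% known_ids)]
  if (length(bad))
    stop_gvfkit("linkage_error",
                sprintf("Parent references unknown ID(s): %s",
                        paste(unique(bad), collapse = ", ")))

  # children of transcripts
  part_rows <- which(type %in% c("exon", "CDS"))
  tx_ids <- ids[tx_rows]
  exon_map <- list(); cds_map <- list(); phase_map <- list()
  for (r in part_rows) {
    ps <- unlist(parents[[r]])
    if (!length(ps))
      stop_gvfkit("linkage_error",
                  sprintf("%s row at %s:%d-%d has no Parent",
                          type[[r]], seqid[[r]], start[[r]], end[[r]]))
    for (p in ps) {
      if (!p %in% known_ids)
        stop_gvfkit("linkage_error",
                    sprintf("Parent references unknown ID '%s'", p))
      if (!p %in% tx_ids) next  # e.g. exon attached to a gene; skip
      if (type[[r]] == "exon") {
        exon_map[[p]] <- rbind(exon_map[[p]], c(start[[r]], end[[r]]))
      } else {
        cds_map[[p]] <- rbind(cds_map[[p]], c(start[[r]], end[[r]]))
        phase_map[[p]] <- c(phase_map[[p]],
                            stats::setNames(phase0[[r]], start[[r]]))
      }
    }
  }

  # warn on unrecognized transcript-level children of genes
  other <- which(!(type %in% c("gene", "exon", "CDS", TRANSCRIPT_TYPES)))
  for (r in other) {
    ps <- unlist(parents[[r]])
    if (any(ps %in% gene_ids))
      warning(sprintf("skipping unrecognized transcript-level type '%s' (%s)",
                      type[[r]], ids[[r]]))
  }

  genes <- list()
  for (g in gene_rows) {
    gid <- ids[[g]]
    mine <- tx_rows[!is.na(tx_parent) & tx_parent == gid]
    txs <- list()
    for (r in mine) {
      tid <- ids[[r]]
      ex <- exon_map[[tid]]
      if (is.null(ex)) ex <- matrix(c(start[[r]], end[[r]]), ncol = 2)
      cd <- cds_map[[tid]]
      if (is.null(cd)) cd <- matrix(integer(0), ncol = 2)
      ph <- 0L
      if (!is.null(phase_map[[tid]])) {
        phv <- phase_map[[tid]]
        key <- if (strand[[r]] == "-") max(as.integer(names(phv)))
               else min(as.integer(names(phv)))
        ph <- phv[[as.character(key)]]
        if (is.na(ph)) ph <- 0L
      }
      ftype <- type[[r]]
      if (ftype == "lnc_RNA") ftype <- "ncRNA"
      txs[[length(txs) + 1L]] <- transcript_model(
        id = tid, gene_id = gid, seqid = seqid[[r]], strand = strand[[r]],
        feature_type = ftype, exons = ex, cds = cd, phase = ph)
    }
    genes[[length(genes) + 1L]] <- gene_model(
      id = gid, seqid = seqid[[g]], strand = strand[[g]],
      start = start[[g]], end = end[[g]], transcripts = txs)
  }
  ord <- order(vapply(genes, `[[`, character(1), "seqid"),
               vapply(genes, `[[`, integer(1), "start"))
  genes[ord]
}

#' Introns of a transcript
#'
#' The gaps between consecutive exons, in genomic coordinate order. The
#' donor (5' in transcript direction) end of each intron is at the lower
#' genomic coordinates for a plus-strand transcript and at the higher
#' genomic coordinates for a minus-strand transcript.
#'
#' @param tx A `TranscriptModel`.
#' @return Two-column integer matrix (start, end); zero rows for
#'   single-exon transcripts.
#' @export
tx_introns <- function(tx) {
  n <- nrow(tx$exons)
  if (n < 2L) return(matrix(integer(0), ncol = 2,
                            dimnames = list(NULL, c("start", "end"))))
  cbind(start = unname(tx$exons[-n, 2L]) + 1L,
        end = unname(tx$exons[-1L, 1L]) - 1L)
}

#' Spliced CDS sequence of a transcript
#'
#' CDS segments concatenated in transcript order (reverse-complemented for
#' minus-strand transcripts) with the leading `phase` bases trimmed. A
#' trimmed length not divisible by three is flagged with a warning and an
#' `incomplete` attribute, not an error.
#'
#' @param tx A coding `TranscriptModel`.
#' @param genome Named character vector from [read_genome_fasta()].
#' @return Character scalar (possibly with attribute `incomplete = TRUE`).
#' @export
cds_sequence <- function(tx, genome) {
  if (!is_coding(tx))
    stop_gvfkit("model_error", sprintf("transcript %s has no CDS", tx$id))
  parts <- vapply(seq_len(nrow(tx$cds)), function(k)
    genome_subseq(genome, tx$seqid, tx$cds[k, 1L], tx$cds[k, 2L]),
    character(1))
  s <- paste(parts, collapse = "")
  if (tx$strand == "-") s <- revcomp(s)
  if (tx$phase > 0L) s <- substr(s, tx$phase + 1L, nchar(s))
  if (nchar(s) %% 3L != 0L) {
    warning(sprintf("transcript %s: CDS length %d not a codon multiple",
                    tx$id, nchar(s)))
    attr(s, "incomplete") <- TRUE
  }
  s
}

cds_segments_tx_order <- function(tx) {
  cds <- tx$cds
  if (tx$strand == "-") cds <- cds[rev(seq_len(nrow(cds))), , drop = FALSE]
  cds
}

#' Map a genomic position to its spliced CDS offset
#'
#' @param tx A coding `TranscriptModel`.
#' @param pos Genomic position (1-based).
#' @return 0-based offset into the phase-trimmed spliced CDS, or
#'   `NA_integer_` when `pos` does not fall in a CDS segment (or falls in
#'   the phase-trimmed leader). Offsets strictly increase along the
#'   transcript direction.
#' @export
genomic_to_cds <- function(tx, pos) {
  cds <- cds_segments_tx_order(tx)
  cum <- 0L
  for (k in seq_len(nrow(cds))) {
    w <- cds[k, 2L] - cds[k, 1L] + 1L
    if (pos >= cds[k, 1L] && pos <= cds[k, 2L]) {
      within <- if (tx$strand == "-") cds[k, 2L] - pos else pos - cds[k, 1L]
      off <- cum + within - tx$phase
      return(if (off < 0L) NA_integer_ else as.integer(off))
    }
    cum <- cum + w
  }
  NA_integer_
}

#' Map a spliced CDS offset back to its genomic position
#'
#' Exact inverse of [genomic_to_cds()] over valid offsets.
#'
#' @param tx A coding `TranscriptModel`.
#' @param offset 0-based offset into the phase-trimmed spliced CDS.
#' @return Genomic position (integer).
#' @export
cds_to_genomic <- function(tx, offset) {
  raw <- as.integer(offset) + tx$phase
  cds <- cds_segments_tx_order(tx)
  cum <- 0L
  for (k in seq_len(nrow(cds))) {
    w <- cds[k, 2L] - cds[k, 1L] + 1L
    if (raw < cum + w) {
      within <- raw - cum
      return(as.integer(if (tx$strand == "-") cds[k, 2L] - within
                        else cds[k, 1L] + within))
    }
    cum <- cum + w
  }
  stop_gvfkit("range_error",
              sprintf("CDS offset %d beyond CDS length %d", offset, cum))
}

cds_length <- function(tx) {
  sum(tx$cds[, 2L] - tx$cds[, 1L] + 1L) - tx$phase
}

#' Codon containing a CDS offset
#'
#' @param tx A coding `TranscriptModel`.
#' @param genome Genome from [read_genome_fasta()].
#' @param cds_offset 0-based offset into the phase-trimmed spliced CDS.
#' @return List: `codon` (3-base string), `pos_in_codon` (0..2),
#'   `protein_index` (0-based amino-acid index).
#' @export
codon_at <- function(tx, genome, cds_offset) {
  cds <- cds_sequence(tx, genome)
  if (cds_offset < 0L || cds_offset >= nchar(cds))
    stop_gvfkit("range_error",
                sprintf("CDS offset %d outside CDS of length %d",
                        cds_offset, nchar(cds)))
  ci <- cds_offset %/% 3L
  list(codon = substr(cds, ci * 3L + 1L, ci * 3L + 3L),
       pos_in_codon = cds_offset %% 3L,
       protein_index = ci)
}
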