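# Deterministic synthetic fixtures: toy genomes, GFF3 gene models and GVF
# variant sets whose consequence is known by construction.
#
# The generator lays out archetypal gene configurations on separate toy
# landmarks (chrT1..chrTn, each well under 50 kb): a rich multi-exon coding
# gene on each strand, a two-isoform gene whose second transcript skips the
# coding exon, non-coding/miRNA/primary-transcript genes, a gene nested in
# the intron of a host gene, an opposite-strand overlapping pair, and
# isolated genes for whole-feature events. Coding sequences are designed
# (ATG start, no internal stop, terminator at the end, length a codon
# multiple) and stamped into an otherwise random genome, so codon-level
# ground truth can be read off by scanning with the genetic code. Every
# placement is additionally validated against the full gene layout so the
# recorded truth includes all side effects (a second transcript's intron,
# an overlapped non-coding exon, proximity to a neighbouring gene).

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Fixture generation parameters
#'
#' @param seed Integer seed; the same seed yields byte-identical outputs.
#' @param n_extra_genes Additional randomized simple coding genes, one per
#'   extra landmark.
#' @param transcripts_per_gene Length-2 range; when the maximum is 2, extra
#'   genes with >= 3 exons also get a non-coding exon-skipping isoform.
#' @param exon_count Length-2 range of exon numbers for extra genes.
#' @param exon_cds_codons Length-2 range of codons per exon for extra genes.
#' @param intron_length Intron length (bp) for extra genes.
#' @param strand_mix Probability that an extra gene is on the plus strand.
#' @param plan Named integer vector: effect term -> number of variants to
#'   plant. Every name must be in the packaged Ensembl vocabulary.
#' @return A `FixtureSpec` list.
#' @export
fixture_spec <- function(seed = 1L, n_extra_genes = 2L,
                         transcripts_per_gene = c(1L, 2L),
                         exon_count = c(2L, 4L),
                         exon_cds_codons = c(4L, 10L),
                         intron_length = 300L,
                         strand_mix = 0.5,
                         plan = default_variant_plan()) {
  structure(list(seed = as.integer(seed),
                 n_extra_genes = as.integer(n_extra_genes),
                 transcripts_per_gene = as.integer(transcripts_per_gene),
                 exon_count = as.integer(exon_count),
                 exon_cds_codons = as.integer(exon_cds_codons),
                 intron_length = as.integer(intron_length),
                 strand_mix = strand_mix,
                 plan = plan),
            class = "FixtureSpec")
}

#' Default variant plan: one coverage set over the implemented effect terms
#'
#' 24 distinct effect terms across all four alteration classes (SNV,
#' deletion, insertion, substitution) plus copy-number types for the
#' whole-feature events. Counts above one spread placements across
#' transcripts (both strands, the two-isoform gene, the nested gene, the
#' overlapping pair).
#'
#' @return Named integer vector.
#' @export
default_variant_plan <- function() {
  c(missense_variant = 8L, synonymous_variant = 4L, stop_gained = 1L,
    stop_lost = 1L, stop_retained_variant = 1L, start_lost = 1L,
    frameshift_variant = 1L, inframe_deletion = 1L, inframe_insertion = 1L,
    splice_donor_variant = 4L, splice_acceptor_variant = 4L,
    splice_region_variant = 1L, intron_variant = 4L,
    `5_prime_UTR_variant` = 1L, `3_prime_UTR_variant` = 1L,
    non_coding_transcript_exon_variant = 6L, mature_miRNA_variant = 1L,
    transcript_ablation = 1L, transcript_amplification = 1L,
    feature_truncation = 1L, feature_elongation = 1L,
    upstream_gene_variant = 1L, downstream_gene_variant = 1L,
    intergenic_variant = 1L)
}

rand_bases <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

design_cds <- function(n_codons) {
  stopifnot(n_codons >= 3L)
  nonstop <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
  codons <- c("ATG", sample(nonstop, n_codons - 2L, replace = TRUE), "TAA")
  if (n_codons >= 8L) {
    codons[[4L]] <- "TAC"  # one substitution from a stop (stop_gained site)
    codons[[5L]] <- "GCC"  # 4-fold degenerate third position (synonymous site)
  }
  paste(codons, collapse = "")
}

# Build a coding gene. codons_per_exon is in transcript order; zeros are
# allowed at the ends (UTR-only exons). Returns list(gene=, stamps=).
build_coding <- function(id, seqid, gstart, strand, codons_per_exon,
                         utr5 = 30L, utr3 = 30L, intron_len = 300L,
                         feature_type = "mRNA", skip_isoform = FALSE) {
  n <- length(codons_per_exon)
  sizes_tx <- 3L * codons_per_exon
  sizes_tx[[1L]] <- sizes_tx[[1L]] + utr5
  sizes_tx[[n]] <- sizes_tx[[n]] + utr3
  sizes_g <- if (strand == "+") sizes_tx else rev(sizes_tx)

  exons <- matrix(0L, nrow = n, ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  cur <- gstart
  for (j in seq_len(n)) {
    exons[j, ] <- c(cur, cur + sizes_g[[j]] - 1L)
    cur <- exons[j, 2L] + 1L + intron_len
  }

  cds <- NULL
  for (j in seq_len(n)) {
    k <- if (strand == "+") j else n - j + 1L  # transcript index of exon j
    if (codons_per_exon[[k]] == 0L) next
    if (strand == "+") {
      s <- exons[j, 1L] + if (k == 1L) utr5 else 0L
      e <- exons[j, 2L] - if (k == n) utr3 else 0L
    } else {
      s <- exons[j, 1L] + if (k == n) utr3 else 0L
      e <- exons[j, 2L] - if (k == 1L) utr5 else 0L
    }
    cds <- rbind(cds, c(s, e))
  }

  designed <- design_cds(sum(codons_per_exon))
  to_write <- if (strand == "+") designed else revcomp(designed)
  stamps <- list()
  off <- 0L
  for (j in seq_len(nrow(cds))) {
    w <- cds[j, 2L] - cds[j, 1L] + 1L
    stamps[[length(stamps) + 1L]] <- list(
      start = cds[j, 1L], end = cds[j, 2L],
      seq = substr(to_write, off + 1L, off + w))
    off <- off + w
  }
  # canonical splice dinucleotides (cosmetic; classification is positional)
  if (n > 1L) {
    for (j in seq_len(n - 1L)) {
      is_ <- exons[j, 2L] + 1L; ie <- exons[j + 1L, 1L] - 1L
      dn <- if (strand == "+") c("GT", "AG") else c("CT", "AC")
      stamps <- c(stamps,
                  list(list(start = is_, end = is_ + 1L, seq = dn[[1L]]),
                       list(start = ie - 1L, end = ie, seq = dn[[2L]])))
    }
  }

  txs <- list(transcript_model(
    id = paste0(id, ".t1"), gene_id = id, seqid = seqid, strand = strand,
    feature_type = feature_type, exons = exons, cds = cds, phase = 0L))
  if (skip_isoform && n >= 3L) {
    txs[[2L]] <- transcript_model(
      id = paste0(id, ".t2"), gene_id = id, seqid = seqid, strand = strand,
      feature_type = "transcript",
      exons = exons[c(1L, n), , drop = FALSE])
  }
  gene <- gene_model(id = id, seqid = seqid, strand = strand,
                     start = exons[1L, 1L], end = exons[n, 2L],
                     transcripts = txs)
  list(gene = gene, stamps = stamps)
}

build_noncoding <- function(id, seqid, gstart, strand, exon_sizes,
                            intron_len = 300L, feature_type = "ncRNA") {
  n <- length(exon_sizes)
  exons <- matrix(0L, nrow = n, ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  cur <- gstart
  for (j in seq_len(n)) {
    exons[j, ] <- c(cur, cur + exon_sizes[[j]] - 1L)
    cur <- exons[j, 2L] + 1L + intron_len
  }
  tx <- transcript_model(id = paste0(id, ".t1"), gene_id = id, seqid = seqid,
                         strand = strand, feature_type = feature_type,
                         exons = exons)
  list(gene = gene_model(id = id, seqid = seqid, strand = strand,
                         start = exons[1L, 1L], end = exons[n, 2L],
                         transcripts = list(tx)),
       stamps = list())
}

#' Generate the toy genome and gene models
#'
#' @param spec A [fixture_spec()].
#' @return List: `fasta` (character lines), `gff3` (character lines),
#'   `genes` (list of [gene_model()], identical to what
#'   [read_gff3_genes()] returns for the emitted GFF3).
#' @export
make_genome_and_genes <- function(spec) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  margin <- 6000L
  built <- list()    # per landmark: list(builds=, margin_right=)
  add_landmark <- function(seqid, builds, margin_right = margin) {
    built[[seqid]] <<- list(builds = builds, margin_right = margin_right)
  }

  # chrT1: rich plus-strand coding gene; room for proximal and intergenic
  add_landmark("chrT1", list(function(s) build_coding(
    "gA", "chrT1", s, "+", c(6L, 12L, 6L))), margin_right = 14000L)
  # chrT2: the same architecture on the minus strand
  add_landmark("chrT2", list(function(s) build_coding(
    "gB", "chrT2", s, "-", c(6L, 12L, 6L))))
  # chrT3: two-isoform gene, CDS confined to the (skippable) middle exon
  add_landmark("chrT3", list(function(s) build_coding(
    "gC", "chrT3", s, "+", c(0L, 24L, 0L), skip_isoform = TRUE)))
  # chrT4: non-coding feature kinds
  add_landmark("chrT4", list(
    function(s) build_noncoding("gD", "chrT4", s, "+", c(150L, 150L)),
    function(s) build_noncoding("gE", "chrT4", s, "-", c(80L),
                                feature_type = "miRNA"),
    function(s) build_noncoding("gF", "chrT4", s, "+", c(200L),
                                feature_type = "primary_transcript")))
  # chrT5: host gene with a 12 kb intron and a gene nested inside it
  add_landmark("chrT5", list(function(s) {
    host <- build_coding("gG", "chrT5", s, "+", c(8L, 8L),
                         intron_len = 12000L)
    nested <- build_coding("gH", "chrT5",
                           host$gene$transcripts[[1L]]$exons[1L, 2L] + 5900L,
                           "-", c(6L, 6L), utr5 = 20L, utr3 = 20L,
                           intron_len = 200L)
    list(gene = list(host$gene, nested$gene),
         stamps = c(host$stamps, nested$stamps))
  }))
  # chrT6: opposite-strand overlap: ncRNA across the 3' UTR of a coding gene
  add_landmark("chrT6", list(function(s) {
    g1 <- build_coding("gI", "chrT6", s, "+", c(6L, 6L),
                       utr5 = 20L, utr3 = 60L, intron_len = 200L)
    tx <- g1$gene$transcripts[[1L]]
    utr3_lo <- max(tx$cds[, 2L]) + 1L
    g2 <- build_noncoding("gJ", "chrT6", utr3_lo, "-",
                          c(tx_end(tx) - utr3_lo + 1L + 100L))
    list(gene = list(g1$gene, g2$gene), stamps = g1$stamps)
  }))
  # chrT7/chrT8: isolated single-exon genes for whole-feature events
  add_landmark("chrT7", list(
    function(s) build_coding("gK", "chrT7", s, "+", c(60L)),
    function(s) build_coding("gL", "chrT7", s, "+", c(60L))))
  add_landmark("chrT8", list(
    function(s) build_coding("gM", "chrT8", s, "+", c(60L)),
    function(s) build_coding("gN", "chrT8", s, "-", c(60L))))

  # extra randomized simple coding genes, one per landmark
  for (i in seq_len(spec$n_extra_genes)) {
    n_ex <- sample(seq(spec$exon_count[[1L]], spec$exon_count[[2L]]), 1L)
    codons <- sample(seq(spec$exon_cds_codons[[1L]], spec$exon_cds_codons[[2L]]),
                     n_ex, replace = TRUE)
    strand <- if (stats::runif(1L) < spec$strand_mix) "+" else "-"
    two_tx <- spec$transcripts_per_gene[[2L]] >= 2L && n_ex >= 3L
    sid <- paste0("chrE", i)
    local({
      codons_i <- codons; strand_i <- strand; two_i <- two_tx
      gid <- paste0("gX", i); sid_i <- sid; il <- spec$intron_length
      add_landmark(sid_i, list(function(s) build_coding(
        gid, sid_i, s, strand_i, codons_i, intron_len = il,
        skip_isoform = two_i)))
    })
  }

  genes <- list()
  genome <- character(0)
  gap <- 12000L
  for (seqid in names(built)) {
    cur <- margin + 1L
    stamps <- list()
    for (bld in built[[seqid]]$builds) {
      res <- bld(cur)
      gs <- if (is.list(res$gene) && !inherits(res$gene, "GeneModel"))
        res$gene else list(res$gene)
      for (g in gs) genes[[length(genes) + 1L]] <- g
      stamps <- c(stamps, res$stamps)
      cur <- max(vapply(gs, `[[`, integer(1), "end")) + 1L + gap
    }
    len <- max(vapply(Filter(function(g) g$seqid == seqid, genes),
                      `[[`, integer(1), "end")) + built[[seqid]]$margin_right
    s <- rand_bases(len)
    for (st in stamps) {
      substr(s, st$start, st$end) <- st$seq
    }
    genome[[seqid]] <- s
  }

  ord <- order(vapply(genes, `[[`, character(1), "seqid"),
               vapply(genes, `[[`, integer(1), "start"))
  genes <- genes[ord]

  list(fasta = genome_to_fasta(genome),
       gff3 = genes_to_gff3(genes),
       genes = genes,
       genome = genome)
}

genome_to_fasta <- function(genome) {
  out <- character(0)
  for (seqid in names(genome)) {
    out <- c(out, paste0(">", seqid))
    s <- genome[[seqid]]
    starts <- seq(1L, nchar(s), by = 70L)
    out <- c(out, substring(s, starts, pmin(starts + 69L, nchar(s))))
  }
  out
}

genes_to_gff3 <- function(genes) {
  out <- "##gff-version 3"
  row <- function(seqid, type, s, e, strand, phase, attrs)
    paste(seqid, "gvfkit_fixture", type, s, e, ".", strand, phase, attrs,
          sep = "\t")
  for (g in genes) {
    out <- c(out, row(g$seqid, "gene", g$start, g$end, g$strand, ".",
                      paste0("ID=", g$id)))
    for (tx in g$transcripts) {
      ftype <- tx$feature_type
      out <- c(out, row(g$seqid, ftype, tx_start(tx), tx_end(tx), tx$strand,
                        ".", paste0("ID=", tx$id, ";Parent=", g$id)))
    }
    # one exon row per distinct interval, Parent comma-joined across isoforms
    exon_parents <- list()
    for (tx in g$transcripts) {
      for (k in seq_len(nrow(tx$exons))) {
        key <- paste(tx$exons[k, 1L], tx$exons[k, 2L])
        exon_parents[[key]] <- c(exon_parents[[key]], tx$id)
      }
    }
    keys <- names(exon_parents)
    ord <- order(as.integer(vapply(strsplit(keys, " "), `[[`, character(1), 1L)))
    for (key in keys[ord]) {
      iv <- as.integer(strsplit(key, " ")[[1L]])
      out <- c(out, row(g$seqid, "exon", iv[[1L]], iv[[2L]], g$strand, ".",
                        paste0("Parent=",
                               paste(exon_parents[[key]], collapse = ","))))
    }
    for (tx in g$transcripts) {
      for (k in seq_len(nrow(tx$cds))) {
        out <- c(out, row(g$seqid, "CDS", tx$cds[k, 1L], tx$cds[k, 2L],
                          tx$strand, "0", paste0("Parent=", tx$id)))
      }
    }
  }
  out
}
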