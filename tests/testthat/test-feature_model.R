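# Gene-model loading and strand-aware coordinate arithmetic

# toy: 60 bp landmark, 2-exon coding transcript on each strand
toy_genome <- c(chrZ = paste(rep("ACGT", 15), collapse = ""))

toy_tx <- function(strand) {
  # exons 11..22 and 31..42; CDS fills both (12 + 12 = 24 bases = 8 codons)
  transcript_model(id = paste0("t", strand), gene_id = "g", seqid = "chrZ",
                   strand = strand, feature_type = "mRNA",
                   exons = rbind(c(11L, 22L), c(31L, 42L)),
                   cds = rbind(c(11L, 22L), c(31L, 42L)))
}

test_that("GFF3 hierarchies assemble into gene models", {
  gff <- c("##gff-version 3",
           "chrZ\tt\tgene\t11\t42\t.\t+\t.\tID=g1",
           "chrZ\tt\tmRNA\t11\t42\t.\t+\t.\tID=g1.t1;Parent=g1",
           "chrZ\tt\tmRNA\t11\t42\t.\t+\t.\tID=g1.t2;Parent=g1",
           "chrZ\tt\texon\t11\t22\t.\t+\t.\tParent=g1.t1,g1.t2",
           "chrZ\tt\texon\t31\t42\t.\t+\t.\tParent=g1.t1",
           "chrZ\tt\tCDS\t14\t22\t.\t+\t0\tParent=g1.t1")
  genes <- read_gff3_genes(gff)
  expect_length(genes, 1L)
  expect_length(genes[[1]]$transcripts, 2L)
  tx1 <- genes[[1]]$transcripts[[1]]
  expect_equal(nrow(tx1$exons), 2L)
  expect_equal(nrow(tx1$cds), 1L)
  # the shared first exon is carried independently by both isoforms
  expect_equal(genes[[1]]$transcripts[[2]]$exons[1, ], c(start = 11L, end = 22L))
})

test_that("orphan Parent references and stray CDS raise classed errors", {
  gff <- c("##gff-version 3",
           "chrZ\tt\tgene\t11\t42\t.\t+\t.\tID=g1",
           "chrZ\tt\tmRNA\t11\t42\t.\t+\t.\tID=g1.t1;Parent=g1",
           "chrZ\tt\texon\t11\t22\t.\t+\t.\tParent=missing")
  expect_error(read_gff3_genes(gff), class = "linkage_error")

  gff2 <- c("##gff-version 3",
            "chrZ\tt\tgene\t11\t42\t.\t+\t.\tID=g1",
            "chrZ\tt\tmRNA\t11\t42\t.\t+\t.\tID=g1.t1;Parent=g1",
            "chrZ\tt\texon\t11\t22\t.\t+\t.\tParent=g1.t1",
            "chrZ\tt\tCDS\t25\t30\t.\t+\t0\tParent=g1.t1")
  expect_error(read_gff3_genes(gff2), class = "model_error")
})

test_that("introns are exon gaps; donor side follows the strand", {
  tx <- toy_tx("+")
  expect_equal(tx_introns(tx), cbind(start = 23L, end = 30L))
  single <- transcript_model("s", "g", "chrZ", "+", "ncRNA",
                             exons = rbind(c(5L, 20L)))
  expect_equal(nrow(tx_introns(single)), 0L)
  # minus strand: donor dinucleotide = two highest intron coordinates
  cfg <- consequence_config()
  expect_equal(classify_splice(toy_tx("-"), c(30L, 30L), cfg),
               "splice_donor_variant")
  expect_equal(classify_splice(toy_tx("+"), c(30L, 30L), cfg),
               "splice_acceptor_variant")
})

test_that("cds_sequence splices, reverse-complements and trims phase", {
  g <- c(chrZ = paste0(strrep("T", 10), "ATGGCCTAA", strrep("T", 10)))
  plus <- transcript_model("p", "g", "chrZ", "+", "mRNA",
                           exons = rbind(c(11L, 19L)), cds = rbind(c(11L, 19L)))
  expect_equal(cds_sequence(plus, g), "ATGGCCTAA")

  # minus-strand segment whose plus-strand genomic sequence is TTACAT
  g2 <- c(chrZ = paste0(strrep("G", 5), "TTACAT", strrep("G", 5)))
  minus <- transcript_model("m", "g", "chrZ", "-", "mRNA",
                            exons = rbind(c(6L, 11L)), cds = rbind(c(6L, 11L)))
  expect_equal(cds_sequence(minus, g2), "ATGTAA")

  # two segments spliced across an intron: ATG|GCC + TAA
  g3 <- c(chrZ = paste0("ATGGCC", strrep("C", 6), "TAA", "GG"))
  two <- transcript_model("u", "g", "chrZ", "+", "mRNA",
                          exons = rbind(c(1L, 6L), c(13L, 15L)),
                          cds = rbind(c(1L, 6L), c(13L, 15L)))
  expect_equal(cds_sequence(two, g3), "ATGGCCTAA")

  ph <- transcript_model("ph", "g", "chrZ", "+", "mRNA",
                         exons = rbind(c(1L, 9L)), cds = rbind(c(1L, 9L)),
                         phase = 1L)
  expect_warning(s <- cds_sequence(ph, g3), "codon multiple")
  expect_equal(nchar(s), 8L)
})

test_that("genomic_to_cds and cds_to_genomic are mutually inverse on both strands", {
  for (strand in c("+", "-")) {
    tx <- toy_tx(strand)
    n <- 24L
    offs <- vapply(c(11:22, 31:42), function(p) genomic_to_cds(tx, p),
                   integer(1))
    expect_setequal(offs, 0:(n - 1))
    for (o in 0:(n - 1)) {
      expect_equal(genomic_to_cds(tx, cds_to_genomic(tx, o)), o)
    }
    # first CDS base in transcript direction maps to offset 0
    expect_equal(cds_to_genomic(tx, 0L), if (strand == "-") 42L else 11L)
  }
  expect_true(is.na(genomic_to_cds(toy_tx("+"), 25L)))  # intronic
  expect_true(is.na(genomic_to_cds(toy_tx("+"), 5L)))   # outside
})

test_that("codon_at does the integer arithmetic of the codon grid", {
  g <- c(chrZ = paste0(strrep("T", 10), "ATGGCCTAA", strrep("T", 41)))
  tx <- transcript_model("p", "g", "chrZ", "+", "mRNA",
                         exons = rbind(c(11L, 19L)), cds = rbind(c(11L, 19L)))
  expect_equal(codon_at(tx, g, 4L),
               list(codon = "GCC", pos_in_codon = 1L, protein_index = 1L))
  expect_equal(codon_at(tx, g, 0L),
               list(codon = "ATG", pos_in_codon = 0L, protein_index = 0L))
  expect_equal(codon_at(tx, g, 8L),
               list(codon = "TAA", pos_in_codon = 2L, protein_index = 2L))
  expect_error(codon_at(tx, g, 9L), class = "range_error")
})

test_that("strand symmetry: mirrored genome and intervals give identical CDS", {
  set.seed(23)
  for (rep in 1:20) {
    L <- 120L
    seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
    g <- c(chrW = seq)
    e1 <- sort(sample(1:40, 2)); e2 <- sort(sample(60:100, 2))
    tx <- transcript_model("f", "g", "chrW", "+", "mRNA",
                           exons = rbind(e1, e2), cds = rbind(e1, e2))
    # mirror: reverse-complement the landmark, flip intervals and strand
    mirror <- function(iv) c(L - iv[2] + 1L, L - iv[1] + 1L)
    g_m <- c(chrW = as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq))))
    tx_m <- transcript_model("f", "g", "chrW", "-", "mRNA",
                             exons = rbind(mirror(e2), mirror(e1)),
                             cds = rbind(mirror(e2), mirror(e1)))
    expect_identical(suppressWarnings(cds_sequence(tx, g)),
                     suppressWarnings(cds_sequence(tx_m, g_m)))
  }
})

test_that("fixture FASTA reader matches the in-memory genome", {
  fx <- fixture_for_seed(1)
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(fx$fasta, path)
  g <- read_genome_fasta(path)
  expect_identical(g, fx$genome)
})
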