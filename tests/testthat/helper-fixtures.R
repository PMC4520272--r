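# Shared helpers: cached fixture sets, set comparison of consequence calls,
# random-DAG and random-GVF generators used by the property tests.

.fixture_cache <- new.env(parent = emptyenv())

fixture_for_seed <- function(seed) {
  key <- paste0("s", seed)
  if (is.null(get0(key, envir = .fixture_cache))) {
    spec <- fixture_spec(seed = seed)
    mk <- make_genome_and_genes(spec)
    pl <- plant_variants(spec, mk$genes, mk$genome)
    assign(key, list(spec = spec, genes = mk$genes,
                     genome = mk$genome, fasta = mk$fasta,
                     gff3 = mk$gff3, doc = pl$doc,
                     gvf = pl$gvf, truth = pl$truth),
           envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

so_dag_cached <- local({
  dag <- NULL
  function() {
    if (is.null(dag)) dag <<- load_so()
    dag
  }
})

# (effect term, feature id) pairs carried by an annotated line, as a
# canonical sorted character set ("." for no feature)
line_pair_set <- function(line) {
  out <- character(0)
  for (e in variant_effects(line)) {
    ids <- if (length(e$feature_ids)) e$feature_ids else "."
    out <- c(out, paste(e$effect_term, ids))
  }
  sort(unique(out))
}

truth_pair_set <- function(truth_df) {
  sort(unique(paste(truth_df$term, truth_df$feature_id)))
}

# terms grouped per (allele index, feature id) pair for one annotated line
split_calls_by_pair <- function(line) {
  groups <- list()
  for (e in variant_effects(line)) {
    ids <- if (length(e$feature_ids)) e$feature_ids else "."
    for (id in ids) {
      key <- paste(e$allele_index, id)
      groups[[key]] <- c(groups[[key]], e$effect_term)
    }
  }
  groups
}

# random multi-parent DAG emitted as OBO text; node i may have parents with
# larger index only, so acyclicity holds by construction
random_dag_obo <- function(n) {
  lines <- character(0)
  for (i in seq_len(n)) {
    lines <- c(lines, "[Term]", sprintf("id: T%03d", i),
               sprintf("name: term_%03d", i))
    if (i < n) {
      pool <- seq(i + 1L, n)
      k <- min(sample(1:2, 1), length(pool))
      parents <- pool[sample.int(length(pool), k)]
      lines <- c(lines, sprintf("is_a: T%03d", parents))
    }
  }
  lines
}

# naive recursive closure over explicit parent/child edge lists
naive_closure <- function(edges_from, id) {
  seen <- character(0)
  recurse <- function(v) {
    if (v %in% seen) return(invisible(NULL))
    seen <<- c(seen, v)
    for (w in edges_from[[v]] %||% character(0)) recurse(w)
    invisible(NULL)
  }
  recurse(id)
  sort(seen)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random valid GVF document exercising escaping, repeated tags and scores
random_gvf_doc <- function(n_lines = 5L) {
  types <- c("SNV", "deletion", "insertion", "substitution")
  lines <- lapply(seq_len(n_lines), function(i) {
    type <- sample(types, 1)
    start <- sample.int(100000L, 1)
    width <- if (type == "SNV") 1L else sample.int(20L, 1)
    end <- if (type == "insertion") start else start + width - 1L
    ref <- if (type == "insertion") "-"
           else paste(sample(c("A", "C", "G", "T"), end - start + 1L,
                             replace = TRUE), collapse = "")
    alt <- switch(type,
      SNV = sample(setdiff(c("A", "C", "G", "T"), ref), 1),
      deletion = "-",
      insertion = paste(sample(c("A", "C", "G", "T"), 3L, replace = TRUE),
                        collapse = ""),
      substitution = paste(rev(strsplit(chartr("ACGT", "TGCA", ref), "")[[1]]),
                           collapse = ""))
    attrs <- list(list(tag = "ID", values = sprintf("rv%05d", i)),
                  list(tag = "Variant_seq", values = alt),
                  list(tag = "Reference_seq", values = ref))
    if (stats::runif(1) < 0.5) {
      attrs <- c(attrs, list(list(
        tag = "Note", values = sample(c("plain", "semi;colon", "eq=sign",
                                        "comma,inside", "pct%20"), 1))))
    }
    if (stats::runif(1) < 0.3) {
      attrs <- c(attrs, list(list(
        tag = "Variant_effect",
        values = "missense_variant 0 mRNA tx1,tx2")))
    }
    variant_line(seqid = sample(c("chr1", "chr2"), 1), source = "rand",
                 type = type, start = start, end = end,
                 score = if (stats::runif(1) < 0.5) NA_real_
                         else round(stats::runif(1), 3),
                 attributes = attrs)
  })
  gvf_document(lines = lines)
}
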