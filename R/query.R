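# Ontology-aware filtering and dataset summaries.
#
# Queries are subsumption queries, not string matches: filtering for
# synonymous variants retains lines annotated with the more specific
# stop_retained_variant because of its dual parentage in the SO. Summaries
# and cross-tabulations can stream a file line-by-line (constant memory), so
# genome-scale GVF exports are processable without loading whole documents.

effect_terms_of_line <- function(line) {
  vapply(gvf_attr(line, "Variant_effect"), function(v)
    strsplit(trimws(v), "\\s+")[[1L]][[1L]], character(1))
}

#' Filter a GVF document by effect term subsumption
#'
#' Retains the lines carrying at least one `Variant_effect` whose term is
#' the query term or any of its `is_a` descendants.
#'
#' @param doc A [gvf_document()].
#' @param dag An `OntologyDAG`.
#' @param query_term Term key (id, name, or spaced name).
#' @return A `GvfDocument` with the retained lines (pragmas preserved).
#' @export
filter_by_effect <- function(doc, dag, query_term) {
  wanted <- so_descendants(dag, query_term)
  wanted_names <- vapply(wanted, function(id) dag$terms[[id]]$name, character(1))
  keep <- vapply(doc$lines, function(l) {
    any(effect_terms_of_line(l) %in% c(wanted, wanted_names))
  }, logical(1))
  gvf_document(pragmas = doc$pragmas, lines = doc$lines[keep])
}

count_stream <- function(x, per_line) {
  if (inherits(x, "GvfDocument")) {
    for (l in x$lines) per_line(l)
    return(invisible(NULL))
  }
  con <- file(x, open = "r")
  on.exit(close(con), add = TRUE)
  repeat {
    chunk <- readLines(con, n = 20000L, warn = FALSE)
    if (!length(chunk)) break
    chunk <- chunk[nzchar(chunk) & !startsWith(chunk, "#")]
    if (!length(chunk)) next
    for (ln in chunk) {
      cols <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(cols) != 9L) next
      per_line(variant_line(seqid = cols[[1L]], source = cols[[2L]],
                            type = cols[[3L]],
                            start = suppressWarnings(as.integer(cols[[4L]])),
                            end = suppressWarnings(as.integer(cols[[5L]])),
                            strand = cols[[7L]], phase = cols[[8L]],
                            attributes = parse_attributes(cols[[9L]], NA_integer_)))
    }
  }
  invisible(NULL)
}

#' Cross-tabulate alteration type against effect term
#'
#' One increment per Variant_effect record, keyed by the line's column-3
#' sequence_alteration type and the record's effect term. The cell sum
#' always equals the total number of effect records in the document — the
#' treemap-style breakdown of which kinds of alteration cause which effects.
#'
#' @param x A [gvf_document()] or a path to a GVF file (streamed).
#' @return data.frame of class `gvf_crosstab` with columns
#'   `alteration_type`, `effect_term`, `n`, sorted by keys, and attribute
#'   `total` (the cell sum).
#' @export
gvf_crosstab <- function(x) {
  env <- new.env(parent = emptyenv())
  count_stream(x, function(l) {
    for (t in effect_terms_of_line(l)) {
      key <- paste(l$type, t, sep = "\r")
      env[[key]] <- get0(key, envir = env, ifnotfound = 0L) + 1L
    }
  })
  keys <- sort(ls(env))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    alteration_type = vapply(parts, `[[`, character(1), 1L),
    effect_term = vapply(parts, `[[`, character(1), 2L),
    n = vapply(keys, function(k) get(k, envir = env), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "total") <- sum(out$n)
  class(out) <- c("gvf_crosstab", "data.frame")
  out
}

#' Summary statistics of a GVF dataset
#'
#' @param x A [gvf_document()] or a path to a GVF file (streamed).
#' @return List of class `gvf_summary`: `n_variant_lines`,
#'   `counts_by_type` (named integer, per column-3 alteration type),
#'   `n_distinct_effect_terms`, `n_distinct_feature_types`,
#'   `n_effect_records`.
#' @export
gvf_summarize <- function(x) {
  n_lines <- 0L
  type_counts <- new.env(parent = emptyenv())
  terms <- new.env(parent = emptyenv())
  ftypes <- new.env(parent = emptyenv())
  n_effects <- 0L
  count_stream(x, function(l) {
    n_lines <<- n_lines + 1L
    type_counts[[l$type]] <- get0(l$type, envir = type_counts, ifnotfound = 0L) + 1L
    for (v in gvf_attr(l, "Variant_effect")) {
      f <- strsplit(trimws(v), "\\s+")[[1L]]
      n_effects <<- n_effects + 1L
      terms[[f[[1L]]]] <- TRUE
      if (length(f) >= 3L && f[[3L]] != ".") ftypes[[f[[3L]]]] <- TRUE
    }
  })
  cnt <- vapply(sort(ls(type_counts)), function(k) type_counts[[k]], integer(1))
  structure(list(n_variant_lines = n_lines,
                 counts_by_type = cnt,
                 n_distinct_effect_terms = length(ls(terms)),
                 n_distinct_feature_types = length(ls(ftypes)),
                 n_effect_records = n_effects),
            class = "gvf_summary")
}

#' @export
print.gvf_summary <- function(x, ...) {
  cat(sprintf("GVF dataset: %d variant line(s)\n", x$n_variant_lines))
  for (k in names(x$counts_by_type))
    cat(sprintf("  %-22s %d\n", k, x$counts_by_type[[k]]))
  cat(sprintf("distinct effect terms:  %d\n", x$n_distinct_effect_terms))
  cat(sprintf("distinct feature types: %d\n", x$n_distinct_feature_types))
  cat(sprintf("effect records:         %d\n", x$n_effect_records))
  invisible(x)
}
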