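# Classed conditions used across the package ---------------------------------

stop_gvfkit <- function(class, message, ...) {
  stop(structure(
    class = c(class, "gvfkit_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' Parse an OBO 1.2 document into an ontology DAG
#'
#' Reads `[Term]` stanzas (id, name, def, synonym, is_a, relationship,
#' is_obsolete) into a directed acyclic graph over `is_a` edges. Multi-parent
#' terms are permitted; non-`is_a` relationships (`part_of`, `derives_from`,
#' ...) are parsed and stored on each term but never traversed by the
#' subsumption operations. Obsolete terms are dropped with a warning.
#'
#' @param x Path to an OBO file, or a character vector of OBO lines (a single
#'   string containing newlines is also accepted).
#' @return An object of class `OntologyDAG`: a list with elements `terms`
#'   (named list of term records), `children` (named list, id -> child ids),
#'   `roots` (ids with no parents) and `name2id` (lookup environment).
#' @details A cyclic `is_a` graph raises an error of class
#'   `so_structural_error` naming the cycle members; an `is_a` line whose
#'   target id is not defined in the document raises `so_resolution_error`
#'   listing the dangling ids.
#' @examples
#' obo <- c("[Term]", "id: A", "name: child", "is_a: B",
#'          "[Term]", "id: B", "name: root")
#' dag <- parse_obo(obo)
#' so_ancestors(dag, "A")
#' @export
parse_obo <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE)
           else unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  lines <- sub("\r$", "", lines)

  # split into stanzas
  hdr <- grep("^\\[", lines)
  terms <- list()
  n_obsolete <- 0L
  for (i in seq_along(hdr)) {
    if (lines[hdr[i]] != "[Term]") next
    from <- hdr[i] + 1L
    to <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(lines)
    body <- lines[from:to]
    body <- body[nzchar(body)]
    tag_of <- sub("^([^:]+):.*$", "\\1", body)
    val_of <- sub("^[^:]+:\\s*", "", body)

    get1 <- function(tag) {
      v <- val_of[tag_of == tag]
      if (length(v)) v[[1L]] else NA_character_
    }
    id <- get1("id")
    if (is.na(id)) next
    if (tolower(get1("is_obsolete")) %in% "true") {
      n_obsolete <- n_obsolete + 1L
      next
    }
    name <- get1("name")
    if (is.na(name) || !nzchar(name))
      stop_gvfkit("so_structural_error", sprintf("term %s has no name", id))
    def <- get1("def")
    if (!is.na(def)) def <- sub('^"(.*)".*$', "\\1", def)
    syn_raw <- val_of[tag_of == "synonym"]
    synonyms <- sub('^"([^"]*)".*$', "\\1", syn_raw)
    isa_raw <- val_of[tag_of == "is_a"]
    parents <- sub("\\s*!.*$", "", isa_raw)
    parents <- trimws(parents)
    rel_raw <- val_of[tag_of == "relationship"]
    rels <- lapply(rel_raw, function(r) {
      p <- strsplit(trimws(sub("\\s*!.*$", "", r)), "\\s+")[[1L]]
      list(type = p[[1L]], target = if (length(p) > 1L) p[[2L]] else NA_character_)
    })
    if (!is.null(terms[[id]]))
      stop_gvfkit("so_structural_error", sprintf("duplicate term id %s", id))
    terms[[id]] <- list(id = id, name = name, definition = def,
                        synonyms = synonyms, parents = parents,
                        relationships = rels)
  }
  if (n_obsolete > 0L)
    warning(sprintf("dropped %d obsolete term(s)", n_obsolete))

  ids <- names(terms)
  dangling <- setdiff(unique(unlist(lapply(terms, `[[`, "parents"))), ids)
  if (length(dangling))
    stop_gvfkit("so_resolution_error",
                sprintf("is_a targets not defined in document: %s",
                        paste(dangling, collapse = ", ")))

  # children map + acyclicity (Kahn's algorithm)
  children <- stats::setNames(vector("list", length(ids)), ids)
  indeg <- stats::setNames(integer(length(ids)), ids)
  for (t in terms) {
    for (p in t$parents) {
      children[[p]] <- c(children[[p]], t$id)
      indeg[[t$id]] <- indeg[[t$id]] + 1L
    }
  }
  queue <- ids[indeg == 0L]
  seen <- 0L
  deg <- indeg
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children[[v]]) {
      deg[[ch]] <- deg[[ch]] - 1L
      if (deg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(ids))
    stop_gvfkit("so_structural_error",
                sprintf("cyclic is_a structure involving: %s",
                        paste(ids[deg > 0L], collapse = ", ")))

  name2id <- new.env(parent = emptyenv(), size = 2L * length(ids))
  for (t in terms) {
    assign(t$name, t$id, envir = name2id)
    assign(gsub("_", " ", t$name, fixed = TRUE), t$id, envir = name2id)
    for (s in t$synonyms) if (nzchar(s)) assign(s, t$id, envir = name2id)
  }

  structure(list(terms = terms, children = children,
                 roots = ids[indeg == 0L], name2id = name2id),
            class = "OntologyDAG")
}

#' @export
print.OntologyDAG <- function(x, ...) {
  cat(sprintf("OntologyDAG: %d terms, %d root(s): %s\n",
              length(x$terms), length(x$roots),
              paste(utils::head(x$roots, 5L), collapse = ", ")))
  invisible(x)
}

#' Load the packaged Sequence Ontology subset
#'
#' The package ships a pinned snapshot of the SO `is_a` graph covering the
#' `sequence_variant` and `sequence_alteration` branches plus the genomic
#' feature terms used in gene models (gene, mRNA, ncRNA, miRNA,
#' primary_transcript, exon, CDS, ...). The snapshot is versioned data; its
#' term set is fixed, not synchronized with the live SO.
#'
#' @return An `OntologyDAG`.
#' @export
load_so <- function() {
  path <- system.file("extdata", "so-subset.obo", package = "gvfkit",
                      mustWork = TRUE)
  parse_obo(path)
}

#' Resolve a term key to an SO accession
#'
#' Accepts an SO id (`"SO:0001583"`), an exact term name
#' (`"missense_variant"`), a name with spaces and underscores interchanged
#' (`"missense variant"`, the styling used in prose), or a recorded synonym.
#'
#' @param dag An `OntologyDAG`.
#' @param key Character scalar to resolve.
#' @return The SO id (character scalar).
#' @export
so_resolve <- function(dag, key) {
  stopifnot(is.character(key), length(key) == 1L)
  if (!is.null(dag$terms[[key]])) return(key)
  for (k in unique(c(key, gsub(" ", "_", key, fixed = TRUE),
                     gsub("_", " ", key, fixed = TRUE)))) {
    hit <- mget(k, envir = dag$name2id, ifnotfound = list(NULL))[[1L]]
    if (!is.null(hit)) return(hit)
  }
  stop_gvfkit("so_lookup_error", sprintf("unknown ontology term: '%s'", key))
}

#' Look up a term record
#' @inheritParams so_resolve
#' @return The term record: a list with `id`, `name`, `definition`,
#'   `synonyms`, `parents`, `relationships`.
#' @export
so_term <- function(dag, key) dag$terms[[so_resolve(dag, key)]]

walk_closure <- function(start, step) {
  out <- character(0)
  frontier <- start
  while (length(frontier)) {
    out <- c(out, frontier)
    nxt <- unique(unlist(lapply(frontier, step), use.names = FALSE))
    frontier <- setdiff(nxt, out)
  }
  unique(out)
}

#' Reflexive-transitive ancestors of a term
#'
#' The `is_a` closure of a term, including the term itself, so that a
#' subsumption query for e.g. all synonymous variants naturally includes
#' exact matches. Only `is_a` edges are traversed.
#'
#' @inheritParams so_resolve
#' @return Character vector of SO ids (sorted).
#' @export
so_ancestors <- function(dag, key) {
  id <- so_resolve(dag, key)
  sort(walk_closure(id, function(v) dag$terms[[v]]$parents))
}

#' Reflexive-transitive descendants of a term
#' @inheritParams so_resolve
#' @return Character vector of SO ids (sorted).
#' @export
so_descendants <- function(dag, key) {
  id <- so_resolve(dag, key)
  sort(walk_closure(id, function(v) dag$children[[v]]))
}

#' Subsumption test over the is_a graph
#'
#' `TRUE` iff `ancestor` is reachable from `child` over `is_a` edges
#' (reflexive: every term is_a itself). This is the query semantics that
#' makes a stop-retained variant answer both a synonymous-variant and a
#' terminator-codon-variant query.
#'
#' @param dag An `OntologyDAG`.
#' @param child,ancestor Term keys (id, name, or spaced name).
#' @return Logical scalar.
#' @export
so_is_a <- function(dag, child, ancestor) {
  so_resolve(dag, ancestor) %in% so_ancestors(dag, child)
}

#' Load the packaged Ensembl consequence vocabulary
#'
#' The ordered list of SO effect terms used by the Ensembl variation
#' annotation pipeline, shipped as package data. Every member is verified to
#' be present in the packaged SO subset and a descendant of
#' `sequence_variant`; a violation raises an error of class
#' `so_integrity_error`.
#'
#' @param dag An `OntologyDAG`; defaults to the packaged SO subset.
#' @return A data.frame with columns `so_id` and `name`, one row per term,
#'   of class `EnsemblVocabulary`.
#' @export
load_ensembl_vocabulary <- function(dag = load_so()) {
  path <- system.file("extdata", "ensembl-consequence-terms.tsv",
                      package = "gvfkit", mustWork = TRUE)
  vocab <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(vocab$so_id, names(dag$terms))
  if (length(missing))
    stop_gvfkit("so_integrity_error",
                sprintf("vocabulary terms absent from packaged SO subset: %s",
                        paste(missing, collapse = ", ")))
  sv <- so_resolve(dag, "sequence_variant")
  bad <- vocab$so_id[!vapply(vocab$so_id, function(id) so_is_a(dag, id, sv),
                             logical(1))]
  if (length(bad))
    stop_gvfkit("so_integrity_error",
                sprintf("vocabulary terms not under sequence_variant: %s",
                        paste(bad, collapse = ", ")))
  class(vocab) <- c("EnsemblVocabulary", "data.frame")
  vocab
}
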