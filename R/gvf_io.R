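# GVF reading, writing and validation.
#
# GVF is a GFF3 dialect: 9 tab-separated columns, ## pragma lines, and
# percent-escaped attribute values. Column 3 carries an SO sequence_alteration
# term; the predicted effects live in Variant_effect attributes with the
# grammar `<term> <allele_index> <feature_type> <id>[,<id>]*`. Because that
# grammar comma-joins feature ids inside one value, Variant_effect values are
# kept whole (one effect record per tag occurrence) while every other
# attribute value list is comma-split per GFF3.

GFF3_RESERVED <- c("%", ";", "=", "&", ",", "\t", "\n")

percent_encode <- function(x) {
  for (ch in GFF3_RESERVED) {
    x <- gsub(ch, sprintf("%%%02X", utf8ToInt(ch)), x, fixed = TRUE)
  }
  x
}

percent_decode <- function(x) {
  vapply(x, function(s) {
    if (!grepl("%", s, fixed = TRUE)) return(s)
    utils::URLdecode(s)
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a GVF variant line
#'
#' @param seqid Landmark (chromosome/contig) id.
#' @param source Annotation source string.
#' @param type SO sequence_alteration term (name or accession).
#' @param start,end 1-based fully-closed coordinates. Insertions follow the
#'   anchoring convention `start == end ==` the base immediately 5' of the
#'   inserted material, with `Reference_seq="-"`.
#' @param score Numeric score or `NA`.
#' @param strand One of `"+"`, `"-"`, `"."`, `"?"`.
#' @param phase GFF3 phase column; `"."` for variants.
#' @param attributes List of attribute entries, each `list(tag=, values=)`;
#'   order and repeated tags are preserved (GVF uses repeated
#'   `Variant_effect` tags).
#' @return A `VariantLine` object.
#' @export
variant_line <- function(seqid, source = "gvfkit", type, start, end,
                         score = NA_real_, strand = "+", phase = ".",
                         attributes = list()) {
  structure(list(seqid = seqid, source = source, type = type,
                 start = as.integer(start), end = as.integer(end),
                 score = score, strand = strand, phase = phase,
                 attributes = attributes),
            class = "VariantLine")
}

#' Construct a GVF document
#'
#' @param pragmas data.frame with columns `name`, `value` (from `##` lines);
#'   a `gvf-version` pragma is required when writing.
#' @param lines List of [variant_line()] objects, order preserved.
#' @return A `GvfDocument`.
#' @export
gvf_document <- function(pragmas = data.frame(name = "gvf-version",
                                              value = "1.07",
                                              stringsAsFactors = FALSE),
                         lines = list()) {
  structure(list(pragmas = pragmas, lines = lines), class = "GvfDocument")
}

#' @export
print.GvfDocument <- function(x, ...) {
  cat(sprintf("GvfDocument: %d pragma(s), %d variant line(s)\n",
              nrow(x$pragmas), length(x$lines)))
  invisible(x)
}

parse_attributes <- function(col9, line_no) {
  if (col9 %in% c("", ".")) return(list())
  parts <- strsplit(col9, ";", fixed = TRUE)[[1L]]
  parts <- parts[nzchar(parts)]
  lapply(parts, function(p) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq < 0L)
      stop_gvfkit("gvf_parse_error",
                  sprintf("line %d: attribute without '=': '%s'", line_no, p))
    tag <- substr(p, 1L, eq - 1L)
    val <- substr(p, eq + 1L, nchar(p))
    values <- if (tag == "Variant_effect") val
              else strsplit(val, ",", fixed = TRUE)[[1L]]
    list(tag = tag, values = percent_decode(values))
  })
}

format_attributes <- function(attributes) {
  if (!length(attributes)) return(".")
  paste(vapply(attributes, function(a) {
    paste0(a$tag, "=", paste(percent_encode(a$values), collapse = ","))
  }, character(1)), collapse = ";")
}

#' Read a GVF document
#'
#' @param x Path to a GVF file or a character vector of GVF lines.
#' @return A [gvf_document()] with all pragmas and body lines parsed,
#'   attribute values percent-decoded, unknown tags preserved verbatim.
#' @details Malformed body lines raise `gvf_parse_error` naming the
#'   1-based line number in the input.
#' @export
read_gvf <- function(x) {
  raw <- if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x))
           readLines(x, warn = FALSE)
         else unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  pragmas <- data.frame(name = character(0), value = character(0),
                        stringsAsFactors = FALSE)
  lines <- list()
  for (i in seq_along(raw)) {
    ln <- raw[[i]]
    if (!nzchar(ln)) next
    if (startsWith(ln, "##")) {
      body <- sub("^##\\s*", "", ln)
      sp <- regexpr("\\s", body)
      if (sp < 0L) {
        pragmas <- rbind(pragmas, data.frame(name = body, value = "",
                                             stringsAsFactors = FALSE))
      } else {
        pragmas <- rbind(pragmas, data.frame(
          name = substr(body, 1L, sp - 1L),
          value = trimws(substr(body, sp + 1L, nchar(body))),
          stringsAsFactors = FALSE))
      }
      next
    }
    if (startsWith(ln, "#")) next
    cols <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(cols) != 9L)
      stop_gvfkit("gvf_parse_error",
                  sprintf("line %d: expected 9 tab-separated columns, got %d",
                          i, length(cols)))
    start <- suppressWarnings(as.integer(cols[[4L]]))
    end <- suppressWarnings(as.integer(cols[[5L]]))
    if (is.na(start) || is.na(end))
      stop_gvfkit("gvf_parse_error",
                  sprintf("line %d: non-integer coordinates '%s'..'%s'",
                          i, cols[[4L]], cols[[5L]]))
    score <- if (cols[[6L]] == ".") NA_real_ else {
      s <- suppressWarnings(as.numeric(cols[[6L]]))
      if (is.na(s))
        stop_gvfkit("gvf_parse_error",
                    sprintf("line %d: non-numeric score '%s'", i, cols[[6L]]))
      s
    }
    lines[[length(lines) + 1L]] <- variant_line(
      seqid = cols[[1L]], source = cols[[2L]], type = cols[[3L]],
      start = start, end = end, score = score, strand = cols[[7L]],
      phase = cols[[8L]], attributes = parse_attributes(cols[[9L]], i))
  }
  gvf_document(pragmas = pragmas, lines = lines)
}

format_score <- function(s) {
  if (is.na(s)) "." else format(s, scientific = FALSE, trim = TRUE, digits = 15)
}

#' Write a GVF document
#'
#' Serialization is the exact inverse of [read_gvf()]: reading the written
#' text reproduces the document field-for-field (attribute values are
#' re-escaped canonically). A document without a `gvf-version` pragma, or
#' with a line violating basic field invariants, is refused.
#'
#' @param doc A [gvf_document()].
#' @param path Optional output path; when `NULL` the GVF text is returned as
#'   a character vector of lines.
#' @return Invisibly, the character vector of lines.
#' @export
write_gvf <- function(doc, path = NULL) {
  stopifnot(inherits(doc, "GvfDocument"))
  if (!"gvf-version" %in% doc$pragmas$name)
    stop_gvfkit("gvf_invariant_error", "document lacks a gvf-version pragma")
  out <- character(nrow(doc$pragmas) + length(doc$lines))
  for (i in seq_len(nrow(doc$pragmas))) {
    v <- doc$pragmas$value[[i]]
    out[[i]] <- if (nzchar(v)) paste0("##", doc$pragmas$name[[i]], " ", v)
                else paste0("##", doc$pragmas$name[[i]])
  }
  off <- nrow(doc$pragmas)
  for (j in seq_along(doc$lines)) {
    l <- doc$lines[[j]]
    if (is.na(l$start) || is.na(l$end) || l$start < 1L || l$start > l$end)
      stop_gvfkit("gvf_invariant_error",
                  sprintf("line %d (%s): bad coordinates %s..%s",
                          j, l$type, l$start, l$end))
    out[[off + j]] <- paste(
      l$seqid, l$source, l$type, l$start, l$end, format_score(l$score),
      l$strand, l$phase, format_attributes(l$attributes), sep = "\t")
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Get attribute values from a variant line
#'
#' @param line A `VariantLine`.
#' @param tag Attribute tag, e.g. `"Variant_seq"`.
#' @return Character vector of all values across every occurrence of the tag
#'   (empty when absent).
#' @export
gvf_attr <- function(line, tag) {
  unlist(lapply(line$attributes, function(a) if (a$tag == tag) a$values),
         use.names = FALSE) %||% character(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a Variant_effect attribute value
#'
#' Grammar: `<effect_term> <allele_index> <feature_type> <id>[,<id>]*`.
#' `allele_index` is 0-based into the line's comma-separated `Variant_seq`
#' value list. The feature_type/id pair `". ."` denotes an effect with no
#' associated feature (used by `intergenic_variant`).
#'
#' @param value The attribute value string.
#' @param dag Optional `OntologyDAG`; when supplied, the effect term must be
#'   a descendant of `sequence_variant` (a `sequence_alteration` term here is
#'   a category error: alteration and effect live in separate SO branches)
#'   and the feature type must be a known SO feature term.
#' @return A `VariantEffect`: list with `effect_term`, `allele_index`
#'   (integer), `feature_type`, `feature_ids` (character, empty for `"."`).
#' @export
parse_variant_effect <- function(value, dag = NULL) {
  fields <- strsplit(trimws(value), "\\s+")[[1L]]
  if (length(fields) != 4L)
    stop_gvfkit("gvf_attribute_error",
                sprintf("Variant_effect needs 4 space-separated fields: '%s'",
                        value))
  if (!grepl("^[0-9]+$", fields[[2L]]))
    stop_gvfkit("gvf_attribute_error",
                sprintf("Variant_effect allele index not an integer: '%s'",
                        value))
  ids <- if (fields[[4L]] == ".") character(0)
         else strsplit(fields[[4L]], ",", fixed = TRUE)[[1L]]
  eff <- structure(list(effect_term = fields[[1L]],
                        allele_index = as.integer(fields[[2L]]),
                        feature_type = fields[[3L]],
                        feature_ids = ids),
                   class = "VariantEffect")
  if (!is.null(dag)) {
    if (!so_is_a(dag, eff$effect_term, "sequence_variant"))
      stop_gvfkit("gvf_semantic_error",
                  sprintf("'%s' is not a sequence_variant term",
                          eff$effect_term))
    if (eff$feature_type != "." &&
        !so_is_a(dag, eff$feature_type, "sequence_feature"))
      stop_gvfkit("gvf_semantic_error",
                  sprintf("'%s' is not a known SO feature term",
                          eff$feature_type))
  }
  eff
}

#' Extract the parsed Variant_effect records of a line
#'
#' @param line A `VariantLine`.
#' @param dag Optional `OntologyDAG` for semantic validation.
#' @return List of `VariantEffect` objects (possibly empty).
#' @export
variant_effects <- function(line, dag = NULL) {
  lapply(gvf_attr(line, "Variant_effect"), parse_variant_effect, dag = dag)
}

SEQ_ALPHABET_RE <- "^[ACGTNacgtn.~-]+$"

violation <- function(level, line, message) {
  data.frame(level = level, line = line, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a GVF document against the ontology
#'
#' Checks, per body line: column-3 type resolves under
#' `sequence_alteration`; every `Variant_effect` term resolves under
#' `sequence_variant`; `Variant_effect` allele indices are in range for the
#' line's `Variant_seq` list; `Reference_seq`/`Variant_seq` use the alphabet
#' `A C G T N - . ~` (case-insensitive); `ID` attributes are unique within
#' the document; `start >= 1` and `start <= end`. Violations are returned,
#' never raised.
#'
#' @param doc A [gvf_document()].
#' @param dag An `OntologyDAG`.
#' @return data.frame with columns `level` (`"ERROR"`/`"WARNING"`), `line`
#'   (1-based index into `doc$lines`), `message`. Zero rows when clean.
#' @export
validate_gvf <- function(doc, dag) {
  out <- violation(character(0), integer(0), character(0))
  seen_ids <- character(0)
  alt_root <- "sequence_alteration"
  for (i in seq_along(doc$lines)) {
    l <- doc$lines[[i]]
    ok_type <- tryCatch(so_is_a(dag, l$type, alt_root), error = function(e) FALSE)
    if (!ok_type)
      out <- rbind(out, violation("ERROR", i,
        sprintf("type '%s' is not a sequence_alteration term", l$type)))
    if (is.na(l$start) || l$start < 1L)
      out <- rbind(out, violation("ERROR", i,
        sprintf("start %s is not a positive coordinate", l$start)))
    if (!is.na(l$start) && !is.na(l$end) && l$start > l$end)
      out <- rbind(out, violation("ERROR", i,
        sprintf("start %d greater than end %d", l$start, l$end)))
    if (!l$strand %in% c("+", "-", ".", "?"))
      out <- rbind(out, violation("ERROR", i,
        sprintf("strand '%s' not one of + - . ?", l$strand)))
    ids <- gvf_attr(l, "ID")
    for (id in ids) {
      if (id %in% seen_ids)
        out <- rbind(out, violation("ERROR", i,
          sprintf("duplicate ID attribute '%s'", id)))
      seen_ids <- c(seen_ids, id)
    }
    vseq <- gvf_attr(l, "Variant_seq")
    for (tag in c("Reference_seq", "Variant_seq")) {
      for (v in gvf_attr(l, tag)) {
        if (!grepl(SEQ_ALPHABET_RE, v))
          out <- rbind(out, violation("ERROR", i,
            sprintf("%s value '%s' outside alphabet ACGTN-.~", tag, v)))
      }
    }
    for (raw in gvf_attr(l, "Variant_effect")) {
      eff <- tryCatch(parse_variant_effect(raw, dag), error = function(e) e)
      if (inherits(eff, "error")) {
        out <- rbind(out, violation("ERROR", i, conditionMessage(eff)))
        next
      }
      if (length(vseq) && eff$allele_index >= length(vseq))
        out <- rbind(out, violation("ERROR", i,
          sprintf("Variant_effect allele_index %d out of range for %d Variant_seq value(s)",
                  eff$allele_index, length(vseq))))
    }
  }
  out
}
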