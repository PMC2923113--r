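#' Ontology DAGs, annotation maps and expression matrices
#'
#' @description
#' `read_obo()` parses a flat OBO 1.2 file into an `ontology_dag`: the
#' `[Term]` stanzas' `id`, `namespace` and `is_a` tags are kept, every
#' other tag and relationship type (including `part_of`) is ignored, and
#' obsolete terms are dropped. The three namespaces `molecular_function`,
#' `biological_process` and `cellular_component` map onto the codes
#' `"MF"`, `"BP"` and `"CC"`; each namespace has one root (a term without
#' is_a parents).
#'
#' `read_annotations()` reads a two-column TSV of protein -> term
#' assignments (one row per assignment) into an `annotation_map`; every
#' term must exist in the ontology when one is supplied.
#'
#' `read_expression()` reads a TSV whose first column is the protein id
#' and whose remaining columns are tissue expression scores (platform
#' units, assumed log scale) into a numeric matrix with protein row names.
#'
#' @param path file path.
#' @param ontology an `ontology_dag`, or `NULL` to skip term validation.
#' @return see Description; `read_expression()` returns a numeric matrix.
#' @name ontology_io
NULL

NAMESPACE_CODES <- c(molecular_function = "MF", biological_process = "BP",
                     cellular_component = "CC")

#' @rdname ontology_io
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  # stanza starts; everything before the first [Term] is header
  starts <- grep("^\\[", lines)
  ids <- character(); ns <- character(); parents <- list()
  for (s in seq_along(starts)) {
    if (lines[starts[s]] != "[Term]") next
    to <- if (s < length(starts)) starts[s + 1L] - 1L else length(lines)
    block <- lines[(starts[s] + 1L):to]
    tag <- function(t) sub(paste0("^", t, ":\\s*"), "",
                           grep(paste0("^", t, ":"), block, value = TRUE))
    if (length(tag("is_obsolete")) && any(tag("is_obsolete") == "true"))
      next
    id <- tag("id")[1L]
    if (is.na(id)) next
    nsi <- tag("namespace")[1L]
    isa <- sub("\\s*!.*$", "", tag("is_a"))
    ids <- c(ids, id)
    ns <- c(ns, if (is.na(nsi)) NA_character_ else
      unname(NAMESPACE_CODES[nsi]))
    parents <- c(parents, list(isa))
  }
  if (!length(ids)) stop("no [Term] stanzas found in ", path)
  names(parents) <- ids
  names(ns) <- ids
  roots <- ids[lengths(parents) == 0L]
  dag <- structure(list(terms = ids, parents = parents, namespace = ns,
                        roots = stats::setNames(roots, ns[roots])),
                   class = "ontology_dag")
  dag$ancestors <- compute_ancestors(dag)
  dag
}

# transitive is_a closure per term (excluding the term itself), computed
# once by topological propagation; cycles are rejected
compute_ancestors <- function(dag) {
  anc <- stats::setNames(vector("list", length(dag$terms)), dag$terms)
  state <- stats::setNames(integer(length(dag$terms)), dag$terms)
  visit <- function(t) {
    if (state[[t]] == 2L) return(anc[[t]])
    if (state[[t]] == 1L) stop("is_a cycle at term ", t)
    state[[t]] <<- 1L
    ps <- intersect(dag$parents[[t]], dag$terms)
    up <- unique(unlist(c(list(ps), lapply(ps, visit))))
    anc[[t]] <<- if (is.null(up)) character() else up
    state[[t]] <<- 2L
    anc[[t]]
  }
  for (t in dag$terms) visit(t)
  anc
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("ontology_dag: %d terms (%s)\n", length(x$terms),
              paste(sprintf("%s:%d", names(table(x$namespace)),
                            table(x$namespace)), collapse = ", ")))
  invisible(x)
}

#' @rdname ontology_io
#' @export
read_annotations <- function(path, ontology = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("protein", "term"),
                          colClasses = "character", comment.char = "#")
  annotation_map(df$protein, df$term, ontology)
}

#' Build an annotation map from parallel protein/term vectors
#'
#' @param protein,term character vectors, one entry per assignment.
#' @inheritParams ontology_io
#' @return an `annotation_map`: named list protein -> character vector of
#'   assigned terms (any namespace).
#' @export
annotation_map <- function(protein, term, ontology = NULL) {
  if (!is.null(ontology)) {
    bad <- setdiff(term, ontology$terms)
    if (length(bad)) stop("unknown ontology term(s): ",
                          paste(utils::head(bad, 5L), collapse = ", "))
  }
  structure(lapply(split(term, protein), unique), class = "annotation_map")
}

#' @rdname ontology_io
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  if (anyNA(m)) stop("expression matrix contains missing values")
  m
}

#' Write helpers for the annotation layer
#'
#' `write_obo()` emits a minimal OBO 1.2 file (id/namespace/is_a tags)
#' that [read_obo()] round-trips; `write_annotations()` the two-column
#' protein/term TSV; `write_expression()` the protein x tissue TSV.
#'
#' @param ontology an `ontology_dag`.
#' @param annotations an `annotation_map`.
#' @param expression numeric matrix with protein row names.
#' @param path output file path.
#' @return `path`, invisibly.
#' @name annotation_write
NULL

#' @rdname annotation_write
#' @export
write_obo <- function(ontology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  inv <- names(NAMESPACE_CODES)
  for (t in ontology$terms) {
    writeLines(c("", "[Term]", paste0("id: ", t),
                 paste0("namespace: ",
                        inv[match(ontology$namespace[[t]], NAMESPACE_CODES)]),
                 paste0("is_a: ", ontology$parents[[t]])), con)
  }
  invisible(path)
}

#' @rdname annotation_write
#' @export
write_annotations <- function(annotations, path) {
  df <- data.frame(
    protein = rep(names(annotations), lengths(annotations)),
    term = unlist(annotations, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname annotation_write
#' @export
write_expression <- function(expression, path) {
  df <- data.frame(protein = rownames(expression), expression,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Ancestor graph of a protein's annotation in one namespace
#'
#' The union of the protein's directly assigned terms in the namespace and
#' all their is_a ancestors. The namespace root is excluded: it is shared
#' by every annotated protein and would put a floor under every
#' similarity, so dropping it keeps the \[0,1\] co-annotation scale
#' informative.
#'
#' @param protein protein identifier.
#' @param namespace `"MF"`, `"BP"` or `"CC"`.
#' @param ontology an `ontology_dag`.
#' @param annotations an `annotation_map`.
#' @return character vector of terms; empty if the protein carries no
#'   annotation in the namespace.
#' @export
ancestor_graph <- function(protein, namespace, ontology, annotations) {
  if (!namespace %in% c("MF", "BP", "CC")) {
    stop("unknown namespace: ", namespace)
  }
  terms <- annotations[[protein]]
  terms <- terms[!is.na(ontology$namespace[terms]) &
                   ontology$namespace[terms] == namespace]
  if (!length(terms)) return(character())
  graph <- unique(c(terms, unlist(ontology$ancestors[terms],
                                  use.names = FALSE)))
  setdiff(graph, ontology$roots)
}

#' Co-annotation similarity of two proteins
#'
#' Jaccard similarity of the two proteins' ontology ancestor graphs within
#' one namespace: the size of the intersection of the graphs divided by
#' the size of their union. Symmetric, bounded in \[0,1\], and 1 exactly
#' on identical annotation. `NA` if either protein has an empty ancestor
#' graph in the namespace.
#'
#' @inheritParams ancestor_graph
#' @param p1,p2 protein identifiers.
#' @return a number in \[0,1\], or `NA_real_`.
#' @export
coannotation_similarity <- function(p1, p2, namespace, ontology,
                                    annotations) {
  a <- ancestor_graph(p1, namespace, ontology, annotations)
  b <- ancestor_graph(p2, namespace, ontology, annotations)
  if (!length(a) || !length(b)) return(NA_real_)
  length(intersect(a, b)) / length(union(a, b))
}
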