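#' Interactome network objects
#'
#' A `ppi_network` is an undirected simple graph of protein identifiers
#' tagged with an interactome-class label. Protein identifiers are opaque,
#' case-sensitive strings; no gene-symbol normalization is attempted.
#' Self-loops and duplicate edges are removed on construction. Isolated
#' nodes are allowed (they matter for coverage bookkeeping) but never
#' appear in modules.
#'
#' @param edges two-column character matrix or data.frame of endpoints;
#'   may have zero rows.
#' @param nodes character vector of node identifiers; defaults to the
#'   identifiers appearing in `edges`. Extra identifiers become isolated
#'   nodes.
#' @param class_label interactome class tag, e.g. `"LIT"`, `"ORTHO"`,
#'   `"HTP"`, `"INT"` or a `"SYNTHETIC-<tag>"` string.
#' @param quiet suppress the dropped self-loop/duplicate message.
#' @return An object of class `ppi_network`: a list with elements `nodes`
#'   (sorted character vector), `edges` (two-column character matrix, each
#'   row sorted so `from < to`, rows deduplicated and ordered) and
#'   `class_label`.
#' @export
ppi_network <- function(edges, nodes = NULL, class_label = "SYNTHETIC-NA",
                        quiet = TRUE) {
  edges <- as.matrix(edges)
  if (ncol(edges) == 0L || nrow(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  } else {
    if (ncol(edges) < 2L) stop("edge table needs two endpoint columns")
    edges <- cbind(as.character(edges[, 1L]), as.character(edges[, 2L]))
  }
  n_in <- nrow(edges)
  loops <- edges[, 1L] == edges[, 2L]
  edges <- edges[!loops, , drop = FALSE]
  # canonical unordered representation: (a,b) and (b,a) are the same edge
  flip <- edges[, 1L] > edges[, 2L]
  edges[flip, ] <- edges[flip, c(2L, 1L)]
  dup <- duplicated(paste(edges[, 1L], edges[, 2L], sep = "\r"))
  edges <- edges[!dup, , drop = FALSE]
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  if (!quiet && (any(loops) || any(dup))) {
    message(sprintf("dropped %d self-loop(s) and %d duplicate edge(s)",
                    sum(loops), sum(dup)))
  }
  nodes <- sort(unique(c(as.character(nodes), edges[, 1L], edges[, 2L])))
  structure(list(nodes = nodes, edges = edges,
                 class_label = as.character(class_label)[1L]),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network [%s]: %d nodes, %d edges\n",
              x$class_label, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Convert a ppi_network to an igraph graph
#'
#' Isolated nodes are preserved as zero-degree vertices.
#'
#' @param network a [ppi_network()].
#' @return an undirected simple `igraph` graph with vertex name attribute.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  igraph::graph_from_data_frame(
    as.data.frame(network$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = network$nodes, stringsAsFactors = FALSE))
}

#' Read an interactome edge list
#'
#' Accepts a two-column TSV edge list or a three-column SIF (node,
#' interaction type, node; the middle column is ignored). Lines starting
#' with `#` are comments; the delimiter is any run of tabs or spaces.
#' Duplicate edges and self-loops are dropped with a message reporting the
#' counts.
#'
#' @param path file path.
#' @param class_label interactome class tag for the resulting network.
#' @param sif if `TRUE`, treat the file as SIF and use columns 1 and 3.
#' @return a [ppi_network()].
#' @export
load_edgelist <- function(path, class_label, sif = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop("empty edge list: ", path)
  toks <- strsplit(trimws(lines), "[\t ]+")
  need <- if (sif) 3L else 2L
  short <- which(vapply(toks, length, 1L) < need)
  if (length(short)) {
    stop(sprintf("parse error at line %d of %s: fewer than %d columns",
                 lineno[short[1L]], path, need))
  }
  a <- vapply(toks, `[[`, "", 1L)
  b <- vapply(toks, `[[`, "", if (sif) 3L else 2L)
  ppi_network(cbind(a, b), class_label = class_label, quiet = FALSE)
}

#' Write a network as a two-column TSV edge list
#'
#' @param network a [ppi_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(network, path) {
  stopifnot(inherits(network, "ppi_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# class: %s", network$class_label), con)
  if (nrow(network$edges)) {
    writeLines(paste(network$edges[, 1L], network$edges[, 2L], sep = "\t"),
               con)
  }
  invisible(path)
}

#' Fuse interactome classes into an integrated network
#'
#' Node and edge sets are unioned (set semantics: commutative, associative,
#' idempotent); no attempt is made to reconcile conflicting evidence beyond
#' the union.
#'
#' @param networks list of [ppi_network()] objects.
#' @param class_label label for the fused network, default `"INT"`.
#' @return a [ppi_network()].
#' @export
integrate_networks <- function(networks, class_label = "INT") {
  if (length(networks) == 0L) stop("need at least one network to integrate")
  stopifnot(all(vapply(networks, inherits, TRUE, "ppi_network")))
  edges <- do.call(rbind, lapply(networks, `[[`, "edges"))
  nodes <- unique(unlist(lapply(networks, `[[`, "nodes")))
  ppi_network(edges, nodes = nodes, class_label = class_label)
}
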