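#' Spearman rank correlation of two expression profiles
#'
#' Pearson correlation of the midrank-transformed vectors (ties receive
#' average ranks). Returns `NA` for profiles shorter than 3 tissues or
#' when either profile has zero rank variance (a flat profile carries no
#' ordering information).
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation in \[-1,1\], or `NA_real_`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("profiles must have equal length")
  if (length(x) < 3L) return(NA_real_)
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' Module annotation variables
#'
#' Computes, for one module, the seven quantities used for confidence
#' scoring:
#' \describe{
#'   \item{n}{number of proteins in the module}
#'   \item{n_ex}{number of module proteins present in the expression
#'     compendium}
#'   \item{ex_mean}{pooled mean expression score of those proteins over
#'     all tissues}
#'   \item{cor_mean}{mean pairwise Spearman correlation of tissue
#'     expression over all unordered pairs of expressed members (`NA` when
#'     fewer than 2 members are expressed, or every pair is degenerate)}
#'   \item{mf_mean, bp_mean, cc_mean}{mean co-annotation, i.e. the mean
#'     [coannotation_similarity()] over the intra-module interaction edges
#'     whose two endpoints both carry annotation in the namespace (`NA`
#'     when no such edge exists)}
#' }
#' Co-annotation is averaged over interacting pairs (network edges inside
#' the module) because it measures the annotation agreement of
#' interactions, while `cor_mean` averages over all member pairs; pairs
#' with missing information are dropped from the means rather than scored
#' zero. Values are kept at full precision; rounding to 2 decimals is a
#' presentation concern only.
#'
#' @param members character vector of module member proteins (or a
#'   single-row [module_set()]).
#' @param ontology an `ontology_dag`.
#' @param annotations an `annotation_map`.
#' @param expression numeric matrix with protein row names (see
#'   [read_expression()]).
#' @param network the [ppi_network()] the module came from; members must
#'   be nodes of it.
#' @param module_id id carried into the result.
#' @return list of class `module_variables` with elements `module_id`,
#'   `n`, `n_ex`, `ex_mean`, `cor_mean`, `mf_mean`, `bp_mean`, `cc_mean`.
#' @export
module_variables <- function(members, ontology, annotations, expression,
                             network, module_id = NA_character_) {
  if (inherits(members, "module_set")) {
    stopifnot(nrow(members) == 1L)
    module_id <- members$module_id[1L]
    members <- members$members[[1L]]
  }
  members <- sort(unique(as.character(members)))
  if (!all(members %in% network$nodes)) {
    stop("module members must be nodes of the network")
  }
  n <- length(members)
  expressed <- intersect(members, rownames(expression))
  n_ex <- length(expressed)
  ex_mean <- if (n_ex) mean(expression[expressed, , drop = FALSE]) else
    NA_real_
  cor_mean <- NA_real_
  if (n_ex >= 2L) {
    pairs <- utils::combn(expressed, 2L)
    cors <- vapply(seq_len(ncol(pairs)), function(i) {
      spearman_cor(expression[pairs[1L, i], ], expression[pairs[2L, i], ])
    }, numeric(1L))
    cors <- cors[!is.na(cors)]
    if (length(cors)) cor_mean <- mean(cors)
  }
  # intra-module interaction edges
  e <- network$edges
  inside <- e[, 1L] %in% members & e[, 2L] %in% members
  e <- e[inside, , drop = FALSE]
  go_mean <- function(ns) {
    if (nrow(e) == 0L) return(NA_real_)
    sims <- vapply(seq_len(nrow(e)), function(i) {
      coannotation_similarity(e[i, 1L], e[i, 2L], ns, ontology,
                              annotations)
    }, numeric(1L))
    sims <- sims[!is.na(sims)]
    if (length(sims)) mean(sims) else NA_real_
  }
  structure(list(module_id = module_id, n = n, n_ex = n_ex,
                 ex_mean = ex_mean, cor_mean = cor_mean,
                 mf_mean = go_mean("MF"), bp_mean = go_mean("BP"),
                 cc_mean = go_mean("CC")),
            class = "module_variables")
}

#' @export
print.module_variables <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.2f", v)
  cat(sprintf(
    "%s: n=%d n.ex=%d ex.mean=%s cor.mean=%s mf=%s bp=%s cc=%s\n",
    x$module_id, x$n, x$n_ex, fmt(x$ex_mean), fmt(x$cor_mean),
    fmt(x$mf_mean), fmt(x$bp_mean), fmt(x$cc_mean)))
  invisible(x)
}

#' Annotation variables for every module of a set
#'
#' @param modules a [module_set()].
#' @inheritParams module_variables
#' @return data.frame with one row per module and columns `module_id`,
#'   `n`, `n_ex`, `ex_mean`, `cor_mean`, `mf_mean`, `bp_mean`, `cc_mean`.
#' @export
annotate_modules <- function(modules, ontology, annotations, expression,
                             network) {
  stopifnot(inherits(modules, "module_set"))
  rows <- lapply(seq_len(nrow(modules)), function(i) {
    v <- module_variables(modules$members[[i]], ontology, annotations,
                          expression, network, modules$module_id[i])
    data.frame(module_id = v$module_id, n = v$n, n_ex = v$n_ex,
               ex_mean = v$ex_mean, cor_mean = v$cor_mean,
               mf_mean = v$mf_mean, bp_mean = v$bp_mean,
               cc_mean = v$cc_mean, stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(module_id = character(), n = integer(),
                      n_ex = integer(), ex_mean = numeric(),
                      cor_mean = numeric(), mf_mean = numeric(),
                      bp_mean = numeric(), cc_mean = numeric()))
  }
  do.call(rbind, rows)
}
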